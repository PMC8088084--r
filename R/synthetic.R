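#' Simulation configuration for the synthetic leg transcriptome study
#'
#' Builds the configuration object consumed by [generate_annotation()],
#' [generate_counts()], [generate_coverage()] and [generate_dnds()].  The
#' defaults emulate the study design the downstream analyses assume: 13 large
#' scaffolds (12 autosomes plus one X at half male genomic coverage), roughly
#' one gene every 20 kb, and a 36-sample RNA-seq design of 2 sexes x 3 leg
#' pairs x 2 inbred lines x 3 replicates with negative-binomial counts.
#'
#' Sex-biased genes are planted per leg: a gene planted male-biased in leg L
#' has its expected count multiplied by \code{2^effect_log2fc} in the male
#' leg-L samples.  The per-leg bias fractions default to a gradient that is
#' stronger in the third legs, mirroring the exaggerated-trait tissue.  The X
#' scaffold is simulated fully dosage-compensated: expected expression is
#' equal in the two sexes (males carry one X but transcribe it at the
#' autosomal rate), so the dosage-compensation test is a calibrated null
#' unless \code{x_male_downshift_log2} is set.
#'
#' @param n_autosomes number of autosomal scaffolds (default 12).
#' @param scaffold_lengths scaffold lengths in bp; default 5 Mb each for
#'   \code{n_autosomes + 1} scaffolds (+1 more if \code{y_like}).
#' @param mean_gene_spacing mean inter-start distance between consecutive
#'   genes in bp (default 20000, i.e. ~1 gene / 20 kb).
#' @param n_replicates biological replicates per (sex, leg, line) cell.
#' @param lines inbred line labels.
#' @param nb_mean_log,nb_mean_sdlog log-normal (meanlog, sdlog) of per-gene
#'   baseline expected counts.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_sdlog sdlog of the log-normal library-size factors.
#' @param frac_male_biased,frac_female_biased per-leg fractions of genes
#'   planted male-/female-biased (length 1 or 3).
#' @param effect_log2fc planted |log2 fold change| for sex-biased genes.
#' @param frac_line_affected fraction of genes carrying a line effect.
#' @param line_effect_log2fc log2 shift applied to line-affected genes in
#'   all samples of the first line.
#' @param frac_leg_biased fraction of genes differing between legs 1 and 3.
#' @param leg_effect_log2fc log2 shift applied to leg-biased genes in leg-3
#'   samples of both sexes.
#' @param planted_regions list of lists with fields \code{scaffold} (index),
#'   \code{start}, \code{end} (bp), \code{direction} ("male"/"female"),
#'   \code{effect} (|log2FC|) and optional \code{n_genes} (how many genes in
#'   the span to plant; default all).
#' @param planted_clusters list of lists with fields \code{scaffold},
#'   \code{start_index} (gene rank on that scaffold), \code{size} (2--4) and
#'   \code{direction}.
#' @param x_scaffold_index which scaffold is the X (default the 13th).
#' @param x_feminization_factor per-leg multiplier (length 1 or 3) on the
#'   sampling weight of X genes when drawing female-biased genes; 1 = no
#'   feminization.
#' @param x_male_downshift_log2 log2 down-shift of X expression in males
#'   (0 = dosage compensated; 1 = uncompensated halving).
#' @param y_like add an extra half-coverage scaffold whose expressed genes
#'   are exclusively male-biased, for the Y-scan test.
#' @param mean_depth mean male genomic read depth on autosomes (x).
#' @param dnds list of dN/dS generator settings: \code{n_genes},
#'   \code{n_male} (default 253), \code{n_female} (default 463),
#'   \code{shape}, \code{scale} of the unbiased gamma, multiplicative
#'   \code{male_median_ratio} and \code{female_median_ratio}, and
#'   \code{frac_ds_zero} (genes with dS = 0, excluded downstream).
#' @param seed integer master seed; each generator derives its own child
#'   seed from it so stages are independently reproducible.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_autosomes = 12,
                              scaffold_lengths = NULL,
                              mean_gene_spacing = 20000,
                              n_replicates = 3,
                              lines = c("big", "small"),
                              nb_mean_log = 3,
                              nb_mean_sdlog = 1.8,
                              nb_dispersion = 0.05,
                              libsize_sdlog = 0.2,
                              frac_male_biased = c(0.02, 0.02, 0.06),
                              frac_female_biased = c(0.04, 0.04, 0.10),
                              effect_log2fc = 2,
                              frac_line_affected = 0.10,
                              line_effect_log2fc = 1,
                              frac_leg_biased = 0.05,
                              leg_effect_log2fc = 1.5,
                              planted_regions = NULL,
                              planted_clusters = NULL,
                              x_scaffold_index = n_autosomes + 1,
                              x_feminization_factor = 1,
                              x_male_downshift_log2 = 0,
                              y_like = FALSE,
                              mean_depth = 100,
                              dnds = list(),
                              seed = 1L) {
  n_scaffolds <- n_autosomes + 1L + as.integer(y_like)
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- rep(5e6, n_autosomes + 1L)
    if (y_like) scaffold_lengths <- c(scaffold_lengths, 1e6)
  }
  dnds_defaults <- list(n_genes = 2000L, n_male = 253L, n_female = 463L,
                        shape = 2, scale = 0.075,
                        male_median_ratio = 1, female_median_ratio = 1,
                        frac_ds_zero = 0.01)
  dnds <- utils::modifyList(dnds_defaults, dnds)
  cfg <- list(
    n_autosomes = as.integer(n_autosomes),
    scaffold_lengths = scaffold_lengths,
    scaffold_ids = sprintf("scaffold_%02d", seq_along(scaffold_lengths)),
    mean_gene_spacing = mean_gene_spacing,
    sexes = c("M", "F"), legs = 1:3, lines = lines,
    n_replicates = as.integer(n_replicates),
    nb_mean_log = nb_mean_log, nb_mean_sdlog = nb_mean_sdlog,
    nb_dispersion = nb_dispersion, libsize_sdlog = libsize_sdlog,
    frac_male_biased = rep_len(frac_male_biased, 3),
    frac_female_biased = rep_len(frac_female_biased, 3),
    effect_log2fc = effect_log2fc,
    frac_line_affected = frac_line_affected,
    line_effect_log2fc = line_effect_log2fc,
    frac_leg_biased = frac_leg_biased,
    leg_effect_log2fc = leg_effect_log2fc,
    planted_regions = planted_regions,
    planted_clusters = planted_clusters,
    x_scaffold_index = as.integer(x_scaffold_index),
    x_feminization_factor = rep_len(x_feminization_factor, 3),
    x_male_downshift_log2 = x_male_downshift_log2,
    y_like = isTRUE(y_like),
    y_scaffold_index = if (y_like) n_scaffolds else NA_integer_,
    mean_depth = mean_depth,
    dnds = dnds,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  fr <- c(cfg$frac_male_biased, cfg$frac_female_biased,
          cfg$frac_line_affected, cfg$frac_leg_biased)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(cfg$scaffold_lengths < 0)) stop("scaffold lengths must be >= 0")
  if (cfg$x_scaffold_index < 1 ||
      cfg$x_scaffold_index > length(cfg$scaffold_lengths)) {
    stop("x_scaffold_index out of range")
  }
  for (reg in cfg$planted_regions) {
    L <- cfg$scaffold_lengths[reg$scaffold]
    if (reg$start < 1 || reg$end > L || reg$start >= reg$end) {
      stop("planted region outside scaffold bounds")
    }
  }
  if (length(cfg$planted_clusters) > 1) {
    key <- vapply(cfg$planted_clusters, function(cl) {
      paste(cl$scaffold, cl$start_index, cl$start_index + cl$size - 1)
    }, character(1))
    spans <- do.call(rbind, lapply(cfg$planted_clusters, function(cl) {
      data.frame(s = cl$scaffold, a = cl$start_index,
                 b = cl$start_index + cl$size - 1)
    }))
    for (i in seq_len(nrow(spans) - 1)) {
      for (j in (i + 1):nrow(spans)) {
        if (spans$s[i] == spans$s[j] &&
            spans$a[i] <= spans$b[j] && spans$b[i] >= spans$a[j]) {
          stop("planted clusters overlap each other")
        }
      }
    }
  }
  invisible(cfg)
}

#' Generate a synthetic gene annotation
#'
#' Places genes along each scaffold with exponential inter-start gaps of mean
#' \code{mean_gene_spacing} (minimum 1 kb), so that per-window gene counts
#' show realistic variance rather than a fixed grid.  Gene spans are drawn
#' from a gamma distribution and truncated so that genes never overlap and
#' stay inside the scaffold.  Coordinates are 1-based inclusive.
#'
#' @param config a [simulation_config()].
#' @return a \code{data.frame} of class \code{"gene_annotation"} with columns
#'   \code{gene_id}, \code{scaffold}, \code{start}, \code{end},
#'   \code{strand}, sorted by (scaffold, start); scaffold lengths are kept in
#'   \code{attr(, "scaffold_lengths")}.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1L), {
    per_scaffold <- lapply(seq_along(config$scaffold_lengths), function(i) {
      L <- config$scaffold_lengths[i]
      sp <- config$mean_gene_spacing
      if (sp >= L || L < 1500) {
        warning(sprintf("scaffold %s shorter than gene spacing; left empty",
                        config$scaffold_ids[i]))
        return(NULL)
      }
      n_draw <- ceiling(L / sp * 2) + 10
      gaps <- pmax(rexp(n_draw, rate = 1 / sp), 1000)
      starts <- round(cumsum(gaps))
      starts <- starts[starts <= L - 300]
      if (!length(starts)) return(NULL)
      n <- length(starts)
      lens <- round(rgamma(n, shape = 4, rate = 4 / 2000))
      max_len <- c(diff(starts) - 100, L - starts[n] + 1)
      lens <- pmax(pmin(lens, max_len), 200)
      ends <- pmin(starts + lens - 1, L)
      data.frame(scaffold = config$scaffold_ids[i],
                 start = starts, end = ends,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, per_scaffold)
    if (is.null(ann)) {
      ann <- data.frame(scaffold = character(), start = integer(),
                        end = integer(), strand = character())
    }
    ann <- ann[order(match(ann$scaffold, config$scaffold_ids), ann$start), ,
               drop = FALSE]
    ann <- data.frame(gene_id = sprintf("gene_%05d", seq_len(nrow(ann))),
                      ann, row.names = NULL, stringsAsFactors = FALSE)
    attr(ann, "scaffold_lengths") <-
      stats::setNames(config$scaffold_lengths, config$scaffold_ids)
    class(ann) <- c("gene_annotation", "data.frame")
    ann
  })
}

# Sample-sheet for the full factorial design.
make_sample_sheet <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      line = config$lines,
                      leg = config$legs,
                      sex = config$sexes,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("sex", "leg", "line", "replicate")]
  grid$sample_id <- sprintf("%s_leg%d_%s_r%d", grid$sex, grid$leg,
                            grid$line, grid$replicate)
  grid[, c("sample_id", "sex", "leg", "line", "replicate")]
}

#' Generate synthetic RNA-seq counts with planted effects
#'
#' Draws negative-binomial counts for the full 2 sexes x 3 legs x 2 lines x
#' replicates design and records every planted effect in a ground-truth
#' object.  A gene planted male-biased in leg L has its expected count
#' multiplied by \code{2^effect_log2fc} in male leg-L samples (female-biased
#' genes symmetrically in females).  Per-leg planted label counts equal
#' \code{round(fraction * n_genes)} exactly.  X-linked genes are simulated
#' dosage-compensated unless \code{x_male_downshift_log2 > 0}; the
#' feminization factor up-weights X genes when female-biased genes are drawn
#' but does not change the per-leg totals.  Planted regions and clusters
#' override the labels of their member genes afterwards.
#'
#' @param annotation output of [generate_annotation()].
#' @param config the [simulation_config()].
#' @return a list with \code{counts} (integer matrix genes x samples),
#'   \code{samples} (sample sheet), \code{libsize_factors}, and \code{truth},
#'   a \code{"truth_set"} list recording per-gene per-leg bias labels, leg
#'   bias, line-affected genes, planted regions/clusters and the X scaffold.
#' @export
generate_counts <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"), nrow(annotation) > 0)
  if (config$n_replicates < 2) {
    stop("need >= 2 replicates per design cell (no resampling basis below)")
  }
  samples <- make_sample_sheet(config)
  n_genes <- nrow(annotation)
  n_samp <- nrow(samples)
  x_id <- config$scaffold_ids[config$x_scaffold_index]
  on_x <- annotation$scaffold == x_id
  on_y <- if (config$y_like) {
    annotation$scaffold == config$scaffold_ids[config$y_scaffold_index]
  } else {
    rep(FALSE, n_genes)
  }

  with_seed(derive_seed(config$seed, 2L), {
    base_mu <- rlnorm(n_genes, config$nb_mean_log, config$nb_mean_sdlog)
    lib <- rlnorm(n_samp, 0, config$libsize_sdlog)

    # per-leg planted sex-bias labels (mutually exclusive within a leg)
    bias <- matrix("unbiased", n_genes, 3,
                   dimnames = list(annotation$gene_id, paste0("leg", 1:3)))
    for (leg in 1:3) {
      pool <- which(!on_y)
      n_m <- round(config$frac_male_biased[leg] * n_genes)
      n_f <- round(config$frac_female_biased[leg] * n_genes)
      m_idx <- if (n_m > 0) sample(pool, n_m) else integer()
      rest <- setdiff(pool, m_idx)
      w <- ifelse(on_x[rest], config$x_feminization_factor[leg], 1)
      f_idx <- if (n_f > 0) sample(rest, n_f, prob = w) else integer()
      bias[m_idx, leg] <- "male"
      bias[f_idx, leg] <- "female"
      if (config$y_like) bias[on_y, leg] <- "male"
    }

    # leg-biased genes (upregulated in leg 3, both sexes)
    n_leg <- round(config$frac_leg_biased * n_genes)
    leg_idx <- if (n_leg > 0) sample.int(n_genes, n_leg) else integer()
    leg_bias <- rep("none", n_genes)
    leg_bias[leg_idx] <- "leg3"

    # line effect on a random subset, all samples of the first line
    n_line <- round(config$frac_line_affected * n_genes)
    line_idx <- if (n_line > 0) sample.int(n_genes, n_line) else integer()

    # planted regions: member genes forced to the region's direction
    region_truth <- list()
    for (reg in config$planted_regions) {
      scaf <- config$scaffold_ids[reg$scaffold]
      mid <- (annotation$start + annotation$end) %/% 2
      members <- which(annotation$scaffold == scaf &
                       mid >= reg$start & mid <= reg$end)
      n_want <- min(reg$n_genes %||% length(members), length(members))
      chosen <- if (n_want < length(members)) {
        sort(sample(members, n_want))
      } else {
        members
      }
      bias[chosen, ] <- reg$direction
      region_truth[[length(region_truth) + 1L]] <-
        list(scaffold = scaf, start = reg$start, end = reg$end,
             direction = reg$direction,
             effect = reg$effect %||% config$effect_log2fc,
             gene_ids = annotation$gene_id[chosen])
    }

    # planted clusters of consecutive same-direction genes
    cluster_truth <- list()
    for (cl in config$planted_clusters) {
      scaf <- config$scaffold_ids[cl$scaffold]
      idx_on <- which(annotation$scaffold == scaf)
      take <- idx_on[seq(cl$start_index, length.out = cl$size)]
      if (anyNA(take)) stop("planted cluster exceeds scaffold gene count")
      bias[take, ] <- cl$direction
      cluster_truth[[length(cluster_truth) + 1L]] <-
        list(scaffold = scaf, start_index = cl$start_index, size = cl$size,
             direction = cl$direction, gene_ids = annotation$gene_id[take])
    }

    # effect sizes per (gene, leg): planted regions/clusters may carry their
    # own effect; default is the global effect_log2fc
    eff <- matrix(config$effect_log2fc, n_genes, 3)
    for (rt in region_truth) {
      eff[match(rt$gene_ids, annotation$gene_id), ] <- rt$effect
    }

    # expected counts
    mu <- matrix(base_mu, n_genes, n_samp) *
      matrix(lib, n_genes, n_samp, byrow = TRUE)
    for (j in seq_len(n_samp)) {
      sx <- samples$sex[j]; lg <- samples$leg[j]; ln <- samples$line[j]
      fac <- rep(1, n_genes)
      is_m <- bias[, lg] == "male"; is_f <- bias[, lg] == "female"
      if (sx == "M") fac[is_m] <- fac[is_m] * 2^eff[is_m, lg]
      if (sx == "F") fac[is_f] <- fac[is_f] * 2^eff[is_f, lg]
      if (lg == 3 && length(leg_idx)) {
        fac[leg_idx] <- fac[leg_idx] * 2^config$leg_effect_log2fc
      }
      if (ln == config$lines[1] && length(line_idx)) {
        fac[line_idx] <- fac[line_idx] * 2^config$line_effect_log2fc
      }
      if (sx == "M" && config$x_male_downshift_log2 != 0) {
        fac[on_x] <- fac[on_x] * 2^(-config$x_male_downshift_log2)
      }
      mu[, j] <- mu[, j] * fac
    }

    counts <- matrix(rnbinom(n_genes * n_samp, mu = mu,
                             size = 1 / config$nb_dispersion),
                     n_genes, n_samp,
                     dimnames = list(annotation$gene_id, samples$sample_id))

    truth <- list(
      bias = data.frame(gene_id = annotation$gene_id, bias,
                        row.names = NULL, stringsAsFactors = FALSE,
                        check.names = FALSE),
      leg_bias = data.frame(gene_id = annotation$gene_id, label = leg_bias,
                            stringsAsFactors = FALSE),
      line_affected = annotation$gene_id[line_idx],
      regions = region_truth,
      clusters = cluster_truth,
      x_scaffold_id = x_id,
      effect_log2fc = config$effect_log2fc
    )
    class(truth) <- "truth_set"
    list(counts = counts, samples = samples, libsize_factors = lib,
         truth = truth)
  })
}

#' Generate per-scaffold male genomic coverage
#'
#' Autosomes get Poisson read depth around \code{mean_depth}; the X scaffold
#' (and the optional Y-like scaffold) gets expectation \code{mean_depth/2},
#' the hemizygous signal used to identify the X.  Depth is the mean of one
#' Poisson draw per 10 kb window.
#'
#' @param annotation a gene annotation (used for scaffold ids and lengths).
#' @param config the [simulation_config()].
#' @return \code{data.frame} with \code{scaffold_id}, \code{length},
#'   \code{mean_depth}.
#' @export
generate_coverage <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  lens <- attr(annotation, "scaffold_lengths") %||%
    stats::setNames(config$scaffold_lengths, config$scaffold_ids)
  with_seed(derive_seed(config$seed, 3L), {
    half <- config$scaffold_ids[c(config$x_scaffold_index,
                                  config$y_scaffold_index)]
    depth <- vapply(seq_along(lens), function(i) {
      lambda <- if (names(lens)[i] %in% half) config$mean_depth / 2
                else config$mean_depth
      nw <- max(1L, floor(lens[i] / 10000))
      mean(rpois(nw, lambda))
    }, numeric(1))
    data.frame(scaffold_id = names(lens), length = unname(lens),
               mean_depth = depth, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic per-gene dN/dS table with category labels
#'
#' Draws gamma-distributed dN/dS ratios for three gene categories --
#' male-biased (default 253 genes), female-biased (default 463) and unbiased
#' (the remainder) -- on a focal branch.  Category medians are shifted
#' multiplicatively via \code{male_median_ratio}/\code{female_median_ratio}
#' (gamma medians scale with the scale parameter).  A small fraction of
#' genes gets dS = 0 and must be excluded by consumers.
#'
#' @param config the [simulation_config()]; settings under \code{config$dnds}.
#' @return list with \code{records} (\code{data.frame}: \code{gene_id},
#'   \code{species}, \code{dN}, \code{dS}, \code{ratio}) and \code{labels}
#'   (named character vector of true categories).
#' @export
generate_dnds <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- config$dnds
  if (d$n_male + d$n_female > d$n_genes) {
    stop("requested category sizes exceed gene count")
  }
  with_seed(derive_seed(config$seed, 4L), {
    ids <- sprintf("rbh_%05d", seq_len(d$n_genes))
    lab <- rep("unbiased", d$n_genes)
    chosen <- sample.int(d$n_genes, d$n_male + d$n_female)
    lab[chosen[seq_len(d$n_male)]] <- "male"
    lab[chosen[d$n_male + seq_len(d$n_female)]] <- "female"
    scale_of <- c(unbiased = d$scale,
                  male = d$scale * d$male_median_ratio,
                  female = d$scale * d$female_median_ratio)
    ratio <- rgamma(d$n_genes, shape = d$shape, scale = scale_of[lab])
    dS <- rgamma(d$n_genes, shape = 5, scale = 0.04)
    zero <- runif(d$n_genes) < d$frac_ds_zero
    dS[zero] <- 0
    records <- data.frame(gene_id = ids, species = "focal",
                          dN = ratio * dS, dS = dS,
                          ratio = ifelse(dS > 0, ratio, NA_real_),
                          stringsAsFactors = FALSE)
    list(records = records, labels = stats::setNames(lab, ids))
  })
}

#' True per-gene adjusted log2 fold changes implied by a truth set
#'
#' Returns the reassigned log2FC profile a perfect analysis would produce on
#' the planted data for one leg: planted male-biased genes get
#' \code{+effect}, female-biased \code{-effect} (region-specific effects
#' honoured), all other genes 0.  Used to feed the region scanner and the
#' cluster detector with a noise-free profile in recovery experiments.
#'
#' @param truth a \code{"truth_set"} from [generate_counts()].
#' @param annotation the matching annotation.
#' @param leg leg index (1--3).
#' @return named numeric vector over \code{annotation$gene_id}.
#' @export
truth_adjusted_log2fc <- function(truth, annotation, leg = 3) {
  lab <- truth$bias[[paste0("leg", leg)]]
  eff <- rep(truth$effect_log2fc, nrow(annotation))
  for (rt in truth$regions) {
    eff[match(rt$gene_ids, annotation$gene_id)] <- rt$effect
  }
  v <- ifelse(lab == "male", eff, ifelse(lab == "female", -eff, 0))
  stats::setNames(v, annotation$gene_id)
}
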