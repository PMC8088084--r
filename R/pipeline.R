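#' Pipeline configuration
#'
#' Either synthetic mode (a [simulation_config()] drives stage 1) or file
#' mode (paths to annotation, counts, sample sheet, coverage and dN/dS
#' tables).  File paths are validated before any stage runs.
#'
#' @param synthetic a [simulation_config()], or NULL for file mode.
#' @param annotation_path,counts_path,samples_path,coverage_path,dnds_path
#'   input files for file mode (dN/dS optional).
#' @param outdir output directory (created if missing).
#' @param filter_cfg an [expression_filter_config()].
#' @param bias_cfg a [bias_call_config()].
#' @param region_cfg a [region_scan_config()].
#' @param cluster_n_iter iterations of the cluster permutation null.
#' @param dnds_cfg a [dnds_bootstrap_config()].
#' @param seed global seed, recorded in every output and used by all
#'   stochastic stages (overrides the seeds inside the sub-configs).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(synthetic = simulation_config(),
                            annotation_path = NULL, counts_path = NULL,
                            samples_path = NULL, coverage_path = NULL,
                            dnds_path = NULL,
                            outdir = tempfile("sexbiasarch_run_"),
                            filter_cfg = expression_filter_config(),
                            bias_cfg = bias_call_config(),
                            region_cfg = region_scan_config(n_perm = 2000),
                            cluster_n_iter = 1000,
                            dnds_cfg = dnds_bootstrap_config(),
                            seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(synthetic)) {
    paths <- c(annotation_path, counts_path, samples_path, coverage_path)
    if (length(paths) < 4) stop("file mode needs annotation, counts, ",
                                "sample sheet and coverage paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "))
  } else {
    synthetic$seed <- seed
  }
  region_cfg$seed <- seed
  dnds_cfg$seed <- seed
  structure(list(synthetic = synthetic,
                 annotation_path = annotation_path,
                 counts_path = counts_path, samples_path = samples_path,
                 coverage_path = coverage_path, dnds_path = dnds_path,
                 outdir = outdir, filter_cfg = filter_cfg,
                 bias_cfg = bias_cfg, region_cfg = region_cfg,
                 cluster_n_iter = cluster_n_iter, dnds_cfg = dnds_cfg,
                 seed = seed),
            class = "pipeline_config")
}

# md5 of the serialized config, for output provenance.  The output
# directory is not part of the hash: two runs of the same analysis into
# different directories are the same analysis.
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  x <- unclass(cfg)
  x$outdir <- NULL
  saveRDS(rapply(x, identity, how = "list"), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stage order: synthesize/load inputs, abundance, expression filter,
#' differential expression (sex within each leg, leg 3 vs 1 within each
#' sex), bias calls, per-leg summaries, chromosome analyses (X
#' identification, Y scan, dosage compensation, X enrichment, crosstalk),
#' region scan, consecutive clusters, dN/dS.  Each stage writes its outputs
#' under \code{cfg$outdir}; the manifest (config echo, seed, input
#' checksums, per-stage status and runtime) is written even when a stage
#' fails, and downstream stages are skipped after a failure.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class \code{"pipeline_result"} with \code{manifest} and
#'   all stage results; also writes \code{manifest.json} and a consolidated
#'   report (see [write_report()]).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  hdr <- sprintf("seed=%d config_hash=%s", cfg$seed, hash)
  manifest <- list(seed = cfg$seed, config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("sexbiasarch")),
                   stages = list(), input_checksums = list())
  res <- list()
  failed <- FALSE
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(write_manifest())
  run_stage <- function(name, fn) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      NULL
    })
    if (!failed) {
      manifest$stages[[name]] <<- list(
        status = "complete",
        seconds = round(proc.time()[["elapsed"]] - t0, 3))
    }
    out
  }

  res$inputs <- run_stage("inputs", function() {
    if (!is.null(cfg$synthetic)) {
      ann <- generate_annotation(cfg$synthetic)
      sim <- generate_counts(ann, cfg$synthetic)
      cov <- generate_coverage(ann, cfg$synthetic)
      dnds <- generate_dnds(cfg$synthetic)
      write_annotation(ann, file.path(cfg$outdir, "annotation.gff3"))
      write_annotation(ann, file.path(cfg$outdir, "annotation.bed"), "bed")
      write_counts(sim$counts, file.path(cfg$outdir, "counts.tsv"), hdr)
      write_tsv(sim$samples, file.path(cfg$outdir, "samples.tsv"), hdr)
      write_tsv(cov, file.path(cfg$outdir, "coverage.tsv"), hdr)
      write_tsv(dnds$records, file.path(cfg$outdir, "dnds.tsv"), hdr)
      write_truth(sim$truth, file.path(cfg$outdir, "truth.json"))
      list(annotation = ann, counts = sim$counts, samples = sim$samples,
           coverage = cov, dnds = dnds$records,
           dnds_labels = dnds$labels, truth = sim$truth)
    } else {
      list(annotation = read_annotation(cfg$annotation_path),
           counts = read_counts(cfg$counts_path),
           samples = read_tsv(cfg$samples_path),
           coverage = read_tsv(cfg$coverage_path),
           dnds = if (!is.null(cfg$dnds_path)) read_tsv(cfg$dnds_path),
           dnds_labels = NULL, truth = NULL)
    }
  })
  if (!failed && is.null(cfg$synthetic)) {
    paths <- c(cfg$annotation_path, cfg$counts_path, cfg$samples_path,
               cfg$coverage_path, cfg$dnds_path)
    manifest$input_checksums <- as.list(tools::md5sum(paths))
  }

  res$abundance <- run_stage("abundance", function() {
    inp <- res$inputs
    lens <- inp$annotation$end - inp$annotation$start + 1
    names(lens) <- inp$annotation$gene_id
    ab <- compute_abundance(inp$counts, lens)
    write_counts(round(ab$fpkm, 4), file.path(cfg$outdir, "fpkm.tsv"), hdr)
    write_counts(round(ab$tpm, 4), file.path(cfg$outdir, "tpm.tsv"), hdr)
    ab
  })

  res$expressed <- run_stage("filter", function() {
    out <- lapply(1:3, function(lg) {
      filter_expressed(res$abundance, res$inputs$samples, lg,
                       cfg$filter_cfg)
    })
    names(out) <- paste0("leg", 1:3)
    for (lg in 1:3) {
      writeLines(out[[lg]],
                 file.path(cfg$outdir, sprintf("expressed_leg%d.txt", lg)))
    }
    out
  })

  res$de <- run_stage("de", function() {
    inp <- res$inputs
    de_sex <- lapply(1:3, function(lg) {
      run_de_standin(inp$counts, inp$samples,
                     list(type = "sex", leg = lg))
    })
    names(de_sex) <- paste0("leg", 1:3)
    de_leg <- lapply(c("M", "F"), function(sx) {
      run_de_standin(inp$counts, inp$samples,
                     list(type = "leg", sex = sx, legs = c(3, 1)))
    })
    names(de_leg) <- c("M", "F")
    for (lg in 1:3) {
      write_tsv(de_sex[[lg]],
                file.path(cfg$outdir, sprintf("de_sex_leg%d.tsv", lg)), hdr)
    }
    for (sx in c("M", "F")) {
      write_tsv(de_leg[[sx]],
                file.path(cfg$outdir, sprintf("de_leg3v1_%s.tsv", sx)), hdr)
    }
    list(sex = de_sex, leg = de_leg)
  })

  res$bias <- run_stage("bias_calls", function() {
    universe <- res$inputs$annotation$gene_id
    sex_calls <- lapply(1:3, function(lg) {
      call_sex_bias(res$de$sex[[lg]], res$expressed[[lg]], universe,
                    leg = lg, cfg = cfg$bias_cfg)
    })
    names(sex_calls) <- paste0("leg", 1:3)
    leg_calls <- lapply(c("M", "F"), function(sx) {
      expressed <- union(res$expressed$leg1, res$expressed$leg3)
      call_sex_bias(res$de$leg[[sx]], expressed, universe, leg = NA,
                    cfg = cfg$bias_cfg)
    })
    names(leg_calls) <- c("M", "F")
    write_tsv(do.call(rbind, sex_calls),
              file.path(cfg$outdir, "bias_calls.tsv"), hdr)
    list(sex = sex_calls, leg = leg_calls)
  })

  res$summary <- run_stage("summaries", function() {
    summ <- summarize_bias(do.call(rbind, res$bias$sex))
    write_tsv(summ, file.path(cfg$outdir, "bias_summary.tsv"), hdr)
    ov <- list(male = bias_overlap(res$bias$sex, "male")$cells,
               female = bias_overlap(res$bias$sex, "female")$cells)
    jsonlite::write_json(ov, file.path(cfg$outdir, "bias_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    list(table = summ, overlap = ov)
  })

  res$chrom <- run_stage("chromosome", function() {
    inp <- res$inputs
    xa <- identify_x(inp$coverage)
    all_calls <- do.call(rbind, res$bias$sex)
    yc <- if (!is.na(xa$x_scaffold_id)) {
      scan_y_candidates(inp$coverage, all_calls, inp$annotation,
                        xa$x_scaffold_id)
    } else {
      character()
    }
    dos <- fx <- NULL
    if (!is.na(xa$x_scaffold_id)) {
      dos <- test_dosage_compensation(res$abundance, inp$annotation,
                                      xa$x_scaffold_id, inp$samples)
      fx <- do.call(rbind, lapply(1:3, function(lg) {
        do.call(rbind, lapply(c("male", "female"), function(d) {
          fr <- fisher_x_enrichment(res$bias$sex[[lg]], inp$annotation,
                                    xa$x_scaffold_id, d)
          data.frame(leg = lg, direction = d, odds_ratio = fr$odds_ratio,
                     p.value = fr$p.value, label = fr$direction_label)
        }))
      }))
      write_tsv(dos, file.path(cfg$outdir, "dosage_compensation.tsv"), hdr)
      write_tsv(fx, file.path(cfg$outdir, "fisher_x.tsv"), hdr)
    }
    ct <- crosstalk_enrichment(res$bias$sex$leg3, res$bias$leg$M)
    jsonlite::write_json(
      list(x_scaffold_id = xa$x_scaffold_id, x_ratio = xa$ratio,
           y_candidates = yc,
           crosstalk = list(overlap = ct$overlap,
                            n_sex_biased = ct$n_sex_biased,
                            fraction_pct = ct$fraction_pct,
                            p.value = ct$fisher$p.value),
           seed = cfg$seed),
      file.path(cfg$outdir, "chromosome.json"), auto_unbox = TRUE,
      digits = NA)
    list(x = xa, y_candidates = yc, dosage = dos, fisher_x = fx,
         crosstalk = ct)
  })

  res$regions <- run_stage("region_scan", function() {
    inp <- res$inputs
    bm <- stats::setNames(res$de$sex$leg3$baseMean, res$de$sex$leg3$gene_id)
    sc <- scan_regions(inp$annotation, res$bias$sex$leg3, bm,
                       cfg$region_cfg)
    win <- sc$windows
    attr(win, "incidence") <- NULL
    attr(win, "gene_order") <- NULL
    write_tsv(win, file.path(cfg$outdir, "window_stats.tsv"), hdr)
    sig <- sc$regions
    bed <- data.frame(chrom = sig$scaffold, start = sig$start,
                      end = sig$end,
                      name = if (nrow(sig)) paste0(sig$direction, "_region")
                             else character(),
                      score = rep(0, nrow(sig)),
                      strand = rep(".", nrow(sig)))
    utils::write.table(bed, file.path(cfg$outdir, "enriched_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(cfg$region_cfg), seed = cfg$seed,
           n_regions = nrow(sig),
           regions = sig),
      file.path(cfg$outdir, "regions.json"), auto_unbox = TRUE, digits = NA)
    sc
  })

  res$clusters <- run_stage("clusters", function() {
    inp <- res$inputs
    lens <- attr(inp$annotation, "scaffold_lengths") %||%
      tapply(inp$annotation$end, inp$annotation$scaffold, max)
    top13 <- names(sort(lens, decreasing = TRUE))[seq_len(min(13,
                                                              length(lens)))]
    per_leg <- lapply(1:3, function(lg) {
      ord <- gene_order(inp$annotation, res$bias$sex[[lg]], top13)
      rec <- find_clusters(ord)
      obs <- cluster_summary(rec, list(male = sum(ord$label == "male"),
                                       female = sum(ord$label == "female")))
      null <- cluster_null(ord, n_iter = cfg$cluster_n_iter,
                           seed = cfg$seed)
      list(records = rec, observed = obs, null = null,
           test = test_cluster_enrichment(obs, null))
    })
    names(per_leg) <- paste0("leg", 1:3)
    write_tsv(do.call(rbind, lapply(1:3, function(lg) {
      r <- per_leg[[lg]]$records
      if (nrow(r)) cbind(leg = lg, r) else NULL
    })), file.path(cfg$outdir, "clusters.tsv"), hdr)
    jsonlite::write_json(
      lapply(per_leg, function(x) {
        list(observed_proportion = as.list(x$observed$proportion),
             null_mean = as.list(x$null$mean_proportion),
             interval = x$null$interval, n_iter = x$null$n_iter,
             significant = x$test$proportion$significant, seed = cfg$seed)
      }),
      file.path(cfg$outdir, "cluster_summary.json"), auto_unbox = TRUE,
      digits = NA)
    per_leg
  })

  res$dnds <- run_stage("dnds", function() {
    inp <- res$inputs
    if (is.null(inp$dnds)) return(NULL)
    labels <- inp$dnds_labels
    if (is.null(labels)) return(NULL)
    cmp_m <- compare_dnds(inp$dnds, labels, c("male", "unbiased"))
    cmp_f <- compare_dnds(inp$dnds, labels, c("female", "unbiased"))
    boot <- label_bootstrap(inp$dnds, cfg$dnds_cfg)
    out <- list(male_vs_unbiased = list(p = cmp_m$p.value,
                                        medians = as.list(cmp_m$medians),
                                        n_excluded = cmp_m$n_excluded),
                female_vs_unbiased = list(p = cmp_f$p.value,
                                          medians = as.list(cmp_f$medians)),
                bootstrap_cutoff_male = boot$cutoff_male,
                bootstrap_cutoff_female = boot$cutoff_female,
                male_non_random = assess_bootstrap(cmp_m$p.value,
                                                   boot)$non_random,
                seed = cfg$seed)
    jsonlite::write_json(out, file.path(cfg$outdir, "dnds_results.json"),
                         auto_unbox = TRUE, digits = NA)
    list(male = cmp_m, female = cmp_f, bootstrap = boot, report = out)
  })

  manifest$n_complete <- sum(vapply(manifest$stages, function(s) {
    identical(s$status, "complete")
  }, logical(1)))
  res$manifest <- manifest
  write_manifest()
  if (!failed) write_report(res, cfg$outdir)
  class(res) <- "pipeline_result"
  res
}

#' Write the consolidated analysis report
#'
#' One JSON report (validated against the schema shipped in
#' \code{inst/schema/report-schema.json}) plus a short human-readable text
#' summary.  Every number in the report is also present in a stage output
#' file.
#'
#' @param res a \code{"pipeline_result"} (or the partial \code{res} list).
#' @param outdir output directory.
#' @return the report list, invisibly.
#' @export
write_report <- function(res, outdir) {
  report <- list(
    seed = res$manifest$seed,
    config_hash = res$manifest$config_hash,
    bias_summary = res$summary$table %||% list(),
    x_chromosome = list(
      scaffold = res$chrom$x$x_scaffold_id %||% NA,
      coverage_ratio = res$chrom$x$ratio %||% NA,
      y_candidates = res$chrom$y_candidates %||% character()),
    enriched_regions = if (!is.null(res$regions)) {
      res$regions$regions
    } else {
      list()
    },
    clusters = if (!is.null(res$clusters)) {
      lapply(res$clusters, function(x) {
        list(observed = as.list(x$observed$proportion),
             significant = x$test$proportion$significant)
      })
    } else {
      list()
    },
    dnds = res$dnds$report %||% list()
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    sprintf("sexbiasarch report (seed %s)", report$seed),
    "",
    "Per-leg bias summary:",
    utils::capture.output(print(report$bias_summary)),
    "",
    sprintf("X chromosome: %s (coverage ratio %.3f)",
            report$x_chromosome$scaffold,
            ifelse(is.na(report$x_chromosome$coverage_ratio), NA,
                   report$x_chromosome$coverage_ratio)),
    sprintf("Enriched regions called: %s",
            if (is.data.frame(report$enriched_regions)) {
              nrow(report$enriched_regions)
            } else {
              0
            }))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(report)
}

#' Validate a report against the shipped schema
#'
#' Light structural validation: all keys required by
#' \code{inst/schema/report-schema.json} must be present.
#'
#' @param report a report list or path to a report.json.
#' @return TRUE (invisibly) or an error listing missing keys.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema",
                                            "report-schema.json",
                                            package = "sexbiasarch"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  if (length(missing)) {
    stop("report missing required keys: ", paste(missing, collapse = ", "))
  }
  sub <- schema$properties$x_chromosome$required
  if (!is.null(sub)) {
    missing <- setdiff(unlist(sub), names(report$x_chromosome))
    if (length(missing)) {
      stop("report$x_chromosome missing: ", paste(missing, collapse = ", "))
    }
  }
  invisible(TRUE)
}
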