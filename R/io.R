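#' Read a gene annotation from GFF3 or BED
#'
#' Both formats are normalized to the package's internal convention:
#' 1-based inclusive coordinates in a plain \code{data.frame} (the native R
#' and GFF3 convention; BED's 0-based half-open intervals are converted on
#' input and output).  Only records of type "gene" are used from GFF3.
#'
#' @param path file path.
#' @param format "gff3" or "bed"; default guessed from the extension.
#' @return a \code{"gene_annotation"} data.frame (gene_id, scaffold, start,
#'   end, strand).
#' @export
read_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    ids <- df$ID %||% df$Name
  } else {
    ids <- df$name
  }
  if (is.null(ids) || anyNA(ids)) {
    ids <- sprintf("gene_%05d", seq_len(nrow(df)))
  }
  out <- data.frame(gene_id = as.character(ids),
                    scaffold = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                                    as.character(df$strand), "+"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Write a gene annotation as GFF3 or BED6
#'
#' @param annotation a \code{"gene_annotation"} data.frame.
#' @param path output path.
#' @param format "gff3" (1-based inclusive, type "gene") or "bed"
#'   (0-based half-open).
#' @return the path, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$scaffold,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end),
    strand = annotation$strand)
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- annotation$gene_id
    gr$Name <- annotation$gene_id
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- annotation$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

# TSV writers/readers with a seed/config-hash comment header.  read.table's
# default comment.char "#" skips the header transparently.
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a counts matrix as TSV (gene_id first column)
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path output path.
#' @param header optional comment header (e.g. seed).
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path, header = NULL) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path, header)
}

#' Read a counts matrix written by [write_counts()]
#'
#' @param path TSV path (first column gene_id).
#' @return integer matrix with gene ids as rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a truth set as JSON
#'
#' @param truth a \code{"truth_set"} from [generate_counts()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
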