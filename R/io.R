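# Standard-format I/O: FASTA via Biostrings, BED6 (0-based half-open),
# headered TSV with '.' for missing, JSON for truth/verdict/provenance.

#' Read gene intervals from BED
#'
#' Expects at least 4 columns (scaffold, start, end, name); column 6 is
#' taken as strand when present. Coordinates stay 0-based, half-open.
#'
#' @param path BED file path.
#' @return Tibble: `scaffold`, `start`, `end`, `gene_id`, `strand`.
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED needs at least 4 columns", call. = FALSE)
  tibble::tibble(
    scaffold = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    gene_id = as.character(df[[4]]),
    strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+"
  )
}

#' Read gene intervals from GFF3
#'
#' Imports records of the given feature type and converts them to the BED
#' convention used throughout the package (0-based, half-open). Requires
#' the rtracklayer package.
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`).
#' @return Tibble: `scaffold`, `start`, `end`, `gene_id`, `strand`.
#' @export
read_genes_gff3 <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_genes_gff3() needs the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  tibble::tibble(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr) - 1L),
    end = as.integer(GenomicRanges::end(gr)),
    gene_id = ids,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write intervals as BED6
#'
#' @param df Tibble with `scaffold`, `start`, `end` and optionally a name
#'   column and a numeric score.
#' @param path Output path.
#' @param name_col,score_col Column names to use for the BED name/score
#'   fields; scores are clipped to \[0, 300\].
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL, score_col = NULL) {
  n <- nrow(df)
  name <- if (!is.null(name_col)) df[[name_col]] else rep(".", n)
  score <- if (!is.null(score_col)) {
    pmin(pmax(df[[score_col]], 0), 300)
  } else rep(0, n)
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", n)
  out <- data.frame(df$scaffold, df$start, df$end, name,
                    format(score, trim = TRUE), strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count (or TPM) table
#'
#' Headered TSV: `gene_id` then one numeric column per sample.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
}

write_tsv_dot <- function(df, path) {
  readr::write_tsv(tibble::as_tibble(df), path, na = ".")
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
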