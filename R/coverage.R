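# Coverage channel: median normalization per sample, per-sex bin means,
# hemizygosity / sex-specificity classification, and region-level coverage.

cov_bin_cols <- c("scaffold", "start", "end")

cov_sample_cols <- function(cov) {
  setdiff(names(cov), c(cov_bin_cols, "mean_M", "mean_F", "label"))
}

#' Median-normalize a binned coverage table
#'
#' Divides every sample column by its own median over all bins (zero-depth
#' bins included), then computes the per-bin arithmetic mean of the
#' normalized values within each sex. After normalization the per-sample
#' median is exactly 1, so autosomal bins sit near 1, hemizygous bins near
#' 0.5, absent bins near 0 — independent of each sample's sequencing depth.
#'
#' @param cov Coverage tibble: `scaffold`, `start`, `end`, then one raw
#'   depth column per sample (e.g. from [simulate_coverage()] or
#'   [read_coverage_tsv()]).
#' @param sex_labels Named `"M"`/`"F"` vector, one entry per sample column;
#'   defaults to the table's `sex` attribute.
#' @return A `coverage_norm` tibble: bin columns, normalized sample
#'   columns, `mean_M`, `mean_F`.
#' @export
normalize_coverage <- function(cov, sex_labels = attr(cov, "sex")) {
  samples <- cov_sample_cols(cov)
  if (is.null(sex_labels))
    stop("sex_labels required (or a 'sex' attribute on the table)",
         call. = FALSE)
  sex <- sex_labels[samples]
  if (anyNA(sex) || !all(c("M", "F") %in% sex))
    stop("sex_labels must cover every sample column and include both sexes",
         call. = FALSE)
  m <- as.matrix(cov[, samples, drop = FALSE])
  med <- apply(m, 2, stats::median)
  if (any(med == 0))
    stop("sample(s) with zero median depth: ",
         paste(samples[med == 0], collapse = ", "), call. = FALSE)
  norm <- sweep(m, 2, med, "/")
  out <- dplyr::bind_cols(
    tibble::as_tibble(cov[, cov_bin_cols]),
    tibble::as_tibble(norm)
  )
  out$mean_M <- rowMeans(norm[, sex == "M", drop = FALSE])
  out$mean_F <- rowMeans(norm[, sex == "F", drop = FALSE])
  attr(out, "sex") <- stats::setNames(sex, samples)
  class(out) <- c("coverage_norm", class(out))
  out
}

#' Classify bins by sex-compared normalized coverage
#'
#' Labels every bin from its per-sex mean normalized coverage:
#' * `hemizygous_M` — half coverage in males, diploid in females (the X
#'   pattern of an XY system); `hemizygous_F` mirrored (Z in ZW).
#' * `specific_M` — essentially absent in females while present (half or
#'   diploid) in males (the Y pattern); `specific_F` mirrored (W).
#' * `autosomal` — diploid in both sexes.
#' * `ambiguous` — anything else.
#'
#' @param cov A `coverage_norm`.
#' @param half_band Closed interval taken as "half coverage"
#'   (default `c(0.35, 0.65)`).
#' @param diploid_band Closed interval taken as "diploid coverage"
#'   (default `c(0.8, 1.2)`).
#' @param absent_max Upper bound for "absent" (default 0.1).
#' @return A `coverage_class` tibble: the input plus a `label` column.
#' @export
classify_bins <- function(cov, half_band = c(0.35, 0.65),
                          diploid_band = c(0.8, 1.2), absent_max = 0.1) {
  stopifnot(all(c("mean_M", "mean_F") %in% names(cov)))
  in_band <- function(x, b) x >= b[1] & x <= b[2]
  m <- cov$mean_M
  f <- cov$mean_F
  present_m <- in_band(m, half_band) | in_band(m, diploid_band)
  present_f <- in_band(f, half_band) | in_band(f, diploid_band)
  label <- rep("ambiguous", length(m))
  label[in_band(m, diploid_band) & in_band(f, diploid_band)] <- "autosomal"
  label[in_band(m, half_band) & in_band(f, diploid_band)] <- "hemizygous_M"
  label[in_band(f, half_band) & in_band(m, diploid_band)] <- "hemizygous_F"
  label[f <= absent_max & present_m] <- "specific_M"
  label[m <= absent_max & present_f] <- "specific_F"
  out <- dplyr::mutate(tibble::as_tibble(cov), label = label)
  attr(out, "sex") <- attr(cov, "sex")
  attr(out, "bands") <- list(half = half_band, diploid = diploid_band,
                             absent_max = absent_max)
  class(out) <- c("coverage_class", class(out))
  out
}

#' Sex-mean coverage over genomic regions
#'
#' For each region (e.g. the merged enriched windows of the expression
#' channel), averages the per-sex normalized coverage over all bins the
#' region overlaps and reports the fraction of those bins classified
#' autosomal — the check that expression-biased loci are genomically
#' present in both sexes.
#'
#' @param cov A `coverage_class` (or `coverage_norm`; labels then reported
#'   as `NA`).
#' @param regions Tibble with `scaffold`, `start`, `end`.
#' @return Tibble: region columns plus `n_bins`, `mean_M`, `mean_F`,
#'   `frac_autosomal`.
#' @export
coverage_of_regions <- function(cov, regions) {
  if (nrow(regions) == 0)
    return(tibble::tibble(scaffold = character(), start = integer(),
                          end = integer(), n_bins = integer(),
                          mean_M = double(), mean_F = double(),
                          frac_autosomal = double()))
  unknown <- setdiff(unique(regions$scaffold), unique(cov$scaffold))
  if (length(unknown) > 0)
    stop("region(s) on scaffold(s) without coverage: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  has_label <- "label" %in% names(cov)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sel <- cov$scaffold == r$scaffold & cov$start < r$end & cov$end > r$start
    tibble::tibble(
      scaffold = r$scaffold, start = r$start, end = r$end,
      n_bins = sum(sel),
      mean_M = mean(cov$mean_M[sel]),
      mean_F = mean(cov$mean_F[sel]),
      frac_autosomal = if (has_label && any(sel))
        mean(cov$label[sel] == "autosomal") else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Read / write a binned coverage table
#'
#' TSV with `scaffold`, `start`, `end` then one numeric depth column per
#' sample. `sex_labels` (named `"M"`/`"F"`) are attached as the `sex`
#' attribute on read.
#'
#' @param path File path.
#' @param sex_labels Named character vector (`sample -> "M"/"F"`).
#' @return A `coverage_raw` tibble.
#' @export
read_coverage_tsv <- function(path, sex_labels) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  stopifnot(all(cov_bin_cols %in% names(df)))
  attr(df, "sex") <- sex_labels
  class(df) <- c("coverage_raw", class(df))
  df
}
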