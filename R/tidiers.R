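# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy / summarize a differential-expression table
#'
#' `tidy()` returns the per-gene table as a plain tibble; `glance()` gives
#' one-row totals.
#'
#' @param x A `de_table`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.de_table <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @rdname tidy.de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_up_male = sum(x$significant & x$log2fc_mf > 0),
    n_up_female = sum(x$significant & x$log2fc_mf < 0),
    fdr_threshold = attr(x, "fdr_threshold") %||% 0.05
  )
}

#' Tidy / summarize a window enrichment result
#'
#' `tidy()` returns the per-window table; `glance()` the per-sex summary
#' (enriched bins, scaffolds, merged regions).
#'
#' @param x A `window_enrichment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.window_enrichment <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @rdname tidy.window_enrichment
#' @export
glance.window_enrichment <- function(x, ...) {
  summarize_enrichment(x)
}

#' Tidy / summarize a YGS scan
#'
#' `tidy()` returns the joint per-contig table (P_VSC_UK in both
#' directions, flags); `glance()` one row of counts and the anomaly flag.
#'
#' @param x A `ygs_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ygs_scan <- function(x, ...) {
  joint <- x$bidir$table
  joint$flagged_xy <- x$xy$flagged[match(joint$contig_id, x$xy$contig_id)]
  joint$flagged_zw <- x$zw$flagged[match(joint$contig_id, x$zw$contig_id)]
  joint
}

#' @rdname tidy.ygs_scan
#' @export
glance.ygs_scan <- function(x, ...) {
  tibble::tibble(
    n_contigs = nrow(x$xy),
    n_flagged_xy = sum(x$xy$flagged),
    n_flagged_zw = sum(x$zw$flagged),
    frac_in_band = x$bidir$frac_in_band,
    anomaly = x$bidir$anomaly
  )
}

#' Tidy / summarize a pipeline verdict
#'
#' @param x A `sexscan_verdict`.
#' @param ... Unused.
#' @return A tibble (one row of evidence counts for `glance()`).
#' @export
glance.sexscan_verdict <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(architecture_call = x$architecture_call,
                   anomaly = x$anomaly),
    tibble::as_tibble(x$evidence)
  )
}
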