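# k-mer sex-specificity scan. For each contig, of its single-copy k-mers
# (assembly-wide count 1), those also present in the carrier sex's trusted
# read k-mers are "validated" (VSC); the percentage of VSC k-mers unmatched
# by the opposite sex's trusted reads is P_VSC_UK — near 100 for a Y/W
# candidate, near 0 for an autosome.

#' Per-contig validated single-copy unmatched k-mer percentage
#'
#' @param contig_id Contig name (must exist in `assembly_kmers`).
#' @param assembly_kmers An `assembly_kmers` object from
#'   [count_assembly_kmers()].
#' @param carrier_trusted Sorted trusted k-mer codes of the sex expected to
#'   carry the contig (from [trusted_kmers()]).
#' @param opposite_trusted Trusted k-mer codes of the opposite sex.
#' @return One-row tibble: `contig_id`, `contig_len_bp`, `n_sc`, `n_vsc`,
#'   `n_vsc_uk`, `p_vsc_uk` (`NA` when `n_vsc` is 0).
#' @export
p_vsc_uk <- function(contig_id, assembly_kmers, carrier_trusted,
                     opposite_trusted) {
  stopifnot(inherits(assembly_kmers, "assembly_kmers"))
  km <- assembly_kmers$contig_kmers[[contig_id]]
  if (is.null(km))
    stop("unknown contig: ", contig_id, call. = FALSE)
  tab <- assembly_kmers$table
  cnt <- tab$count[match(km, tab$kmer)]
  sc <- km[cnt == 1]
  vsc <- sc[sc %in% carrier_trusted]
  vsc_uk <- vsc[!vsc %in% opposite_trusted]
  n_vsc <- length(vsc)
  tibble::tibble(
    contig_id = contig_id,
    contig_len_bp = unname(assembly_kmers$contig_len[contig_id]),
    n_sc = length(sc),
    n_vsc = n_vsc,
    n_vsc_uk = length(vsc_uk),
    p_vsc_uk = if (n_vsc == 0) NA_real_ else 100 * length(vsc_uk) / n_vsc
  )
}

#' Run the k-mer scan in one direction
#'
#' Direction `"XY"` takes male reads as the carrier sex and female reads as
#' the opposite (flagging Y candidates); `"ZW"` is the mirror (flagging W
#' candidates). A contig is `flagged` when its P_VSC_UK exceeds `threshold`,
#' it is at least `min_len` bp long, and it has at least `min_vsc` validated
#' single-copy k-mers (percentages on tiny denominators are unstable).
#'
#' @param assembly_kmers An `assembly_kmers` object.
#' @param reads_M,reads_F Per-sex read `kmer_table`s.
#' @param direction `"XY"` or `"ZW"`.
#' @param threshold P_VSC_UK percentage above which a contig is flagged
#'   (default 80).
#' @param min_len Minimum contig length in bp (default 1000).
#' @param min_count Trusted-k-mer count cutoff passed to [trusted_kmers()]
#'   (default 2).
#' @param min_vsc Minimum VSC k-mers for a contig to be flaggable
#'   (default 20).
#' @return A `ygs_result` tibble with one row per contig: the [p_vsc_uk()]
#'   columns plus `direction` and `flagged`.
#' @export
run_direction <- function(assembly_kmers, reads_M, reads_F, direction,
                          threshold = 80, min_len = 1000, min_count = 2,
                          min_vsc = 20) {
  if (!direction %in% c("XY", "ZW"))
    stop("direction must be 'XY' or 'ZW'", call. = FALSE)
  carrier <- if (direction == "XY") reads_M else reads_F
  opposite <- if (direction == "XY") reads_F else reads_M
  ct <- trusted_kmers(carrier, min_count)
  ot <- trusted_kmers(opposite, min_count)
  out <- dplyr::bind_rows(lapply(
    names(assembly_kmers$contig_kmers),
    p_vsc_uk, assembly_kmers = assembly_kmers,
    carrier_trusted = ct, opposite_trusted = ot
  ))
  out$direction <- direction
  out$flagged <- !is.na(out$p_vsc_uk) & out$p_vsc_uk > threshold &
    out$contig_len_bp >= min_len & out$n_vsc >= min_vsc
  attr(out, "threshold") <- threshold
  attr(out, "min_len") <- min_len
  attr(out, "min_count") <- min_count
  attr(out, "min_vsc") <- min_vsc
  class(out) <- c("ygs_result", class(out))
  out
}

#' Joint XY/ZW table and the bidirectional ~50% anomaly diagnostic
#'
#' Contigs with P_VSC_UK near 50% in *both* directions carry sequence
#' private to each sex's read pool — the signature of individual
#' variability / heterozygosity rather than sex linkage. When the fraction
#' of such contigs (both values inside `band`) exceeds `anomaly_frac`, the
#' anomaly flag is raised and flagged contigs should be treated with
#' caution.
#'
#' @param records_xy,records_zw `ygs_result`s over the same contig universe.
#' @param band Percentage interval called "approximately 50%"
#'   (default `c(40, 60)`).
#' @param anomaly_frac Fraction of in-band contigs that triggers the flag
#'   (default 0.10).
#' @return A `ygs_bidir` list: `table` (per-contig `p_xy`, `p_zw`,
#'   `in_band`), `frac_in_band`, `anomaly`.
#' @export
bidirectional_stats <- function(records_xy, records_zw, band = c(40, 60),
                                anomaly_frac = 0.10) {
  if (!setequal(records_xy$contig_id, records_zw$contig_id))
    stop("XY and ZW records cover different contig universes", call. = FALSE)
  joint <- dplyr::inner_join(
    dplyr::select(records_xy, "contig_id", "contig_len_bp",
                  p_xy = "p_vsc_uk"),
    dplyr::select(records_zw, "contig_id", p_zw = "p_vsc_uk"),
    by = "contig_id"
  )
  joint$in_band <- !is.na(joint$p_xy) & !is.na(joint$p_zw) &
    joint$p_xy >= band[1] & joint$p_xy <= band[2] &
    joint$p_zw >= band[1] & joint$p_zw <= band[2]
  frac <- mean(joint$in_band)
  structure(list(
    table = joint,
    frac_in_band = frac,
    anomaly = frac > anomaly_frac,
    band = band,
    anomaly_frac = anomaly_frac
  ), class = "ygs_bidir")
}

#' @export
print.ygs_bidir <- function(x, ...) {
  cat("<ygs_bidir> ", nrow(x$table), " contigs; ",
      round(100 * x$frac_in_band, 1), "% with both directions in [",
      x$band[1], ", ", x$band[2], "]%",
      if (x$anomaly) " — ANOMALY (individual variability suspected)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Full bidirectional k-mer sex-specificity scan
#'
#' Convenience wrapper: counts assembly k-mers, runs both the XY
#' (female-to-male) and ZW (male-to-female) directions, and computes the
#' bidirectional anomaly diagnostic.
#'
#' @param assembly Named character vector or `Biostrings::DNAStringSet`.
#' @param reads_M,reads_F Per-sex read `kmer_table`s.
#' @param k Odd k-mer length (default 15); must match the read tables.
#' @param ... Passed to [run_direction()].
#' @return A `ygs_scan` list: `xy`, `zw` (`ygs_result`s) and `bidir`
#'   (`ygs_bidir`).
#' @export
ygs_scan <- function(assembly, reads_M, reads_F, k = 15, ...) {
  ak <- count_assembly_kmers(assembly, k)
  xy <- run_direction(ak, reads_M, reads_F, "XY", ...)
  zw <- run_direction(ak, reads_M, reads_F, "ZW", ...)
  structure(list(xy = xy, zw = zw,
                 bidir = bidirectional_stats(xy, zw)),
            class = "ygs_scan")
}

#' @export
print.ygs_scan <- function(x, ...) {
  cat("<ygs_scan> ", nrow(x$xy), " contigs; flagged XY: ",
      sum(x$xy$flagged), ", ZW: ", sum(x$zw$flagged),
      if (x$bidir$anomaly) "; bidirectional ~50% anomaly" else "",
      "\n", sep = "")
  invisible(x)
}
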