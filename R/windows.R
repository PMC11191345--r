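# Genomic-loci enrichment: sliding windows, gene-to-window assignment,
# per-window one-sided Fisher tests with BH correction, and region merging.
# All coordinates are 0-based, half-open.

#' Build a sliding window grid over scaffolds
#'
#' Windows start at every multiple of `step_bp` below the scaffold length
#' and are truncated at the scaffold end, so trailing windows may be shorter
#' than `window_bp` (they are kept and tested like any other bin).
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths, or a
#'   tibble with `scaffold` and `length` columns.
#' @param window_bp Window width (default 200000).
#' @param step_bp Step between window starts (default 100000); must not
#'   exceed `window_bp`.
#' @return A `window_grid` tibble: `scaffold`, `start`, `end`.
#' @examples
#' make_windows(c(s1 = 450000), 200000, 100000)
#' @export
make_windows <- function(scaffold_lengths, window_bp = 200000,
                         step_bp = 100000) {
  if (is.data.frame(scaffold_lengths))
    scaffold_lengths <- stats::setNames(scaffold_lengths$length,
                                        scaffold_lengths$scaffold)
  if (step_bp < 1 || window_bp < step_bp)
    stop("need window_bp >= step_bp >= 1", call. = FALSE)
  out <- dplyr::bind_rows(purrr::imap(as.list(scaffold_lengths), function(L, s) {
    if (L < 1) return(NULL)
    starts <- seq(0, L - 1, by = step_bp)
    tibble::tibble(scaffold = s, start = as.integer(starts),
                   end = as.integer(pmin(starts + window_bp, L)))
  }))
  if (nrow(out) == 0)
    out <- tibble::tibble(scaffold = character(), start = integer(),
                          end = integer())
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  class(out) <- c("window_grid", class(out))
  out
}

#' Assign genes to overlapping windows
#'
#' A gene belongs to every window it overlaps by at least 1 bp (half-open
#' interval semantics), so a gene spanning several sliding windows is
#' counted in each.
#'
#' @param genes Tibble with `scaffold`, `start`, `end`, `gene_id`.
#' @param grid A `window_grid` from [make_windows()].
#' @return Tibble with `bin` (row index into `grid`) and `gene_id`, one row
#'   per (window, gene) overlap.
#' @export
assign_genes <- function(genes, grid) {
  unknown <- setdiff(unique(genes$scaffold), unique(grid$scaffold))
  if (length(unknown) > 0 && nrow(genes) > 0) {
    bad <- genes$gene_id[genes$scaffold %in% unknown]
    stop("gene(s) on scaffold(s) absent from the grid: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(genes) == 0 || nrow(grid) == 0)
    return(tibble::tibble(bin = integer(), gene_id = character()))
  res <- lapply(unique(grid$scaffold), function(s) {
    gi <- which(grid$scaffold == s)
    ge <- genes[genes$scaffold == s, ]
    if (nrow(ge) == 0) return(NULL)
    # half-open [start, end) -> 1-based closed [start + 1, end]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(ge$start + 1L, ge$end),
      IRanges::IRanges(grid$start[gi] + 1L, grid$end[gi]),
      minoverlap = 1L
    )
    tibble::tibble(bin = gi[S4Vectors::subjectHits(hits)],
                   gene_id = ge$gene_id[S4Vectors::queryHits(hits)])
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$bin, .data$gene_id)
}

#' Per-window Fisher enrichment of a biased gene set
#'
#' For every window, tests whether its genes are enriched for the given
#' biased set against the genome-wide gene universe, using the one-sided
#' (greater) Fisher exact test on the 2x2 table
#' `[[biased_in, nonbiased_in], [biased_out, nonbiased_out]]`. The "out"
#' margin uses the de-duplicated universe (each gene counted once outside
#' regardless of how many windows it spans), so margins are conserved.
#' P-values are BH-adjusted across all windows of the analysis; windows with
#' no genes get p = 1 and stay in the family. A window is `enriched` when
#' its Q-value is below `q_threshold`.
#'
#' @param grid A `window_grid`.
#' @param gene_map Assignment tibble from [assign_genes()].
#' @param biased_genes Character vector of biased gene ids (one sex's set).
#' @param universe Character vector of all gene ids considered.
#' @param q_threshold Q-value cutoff for the enrichment flag (default 0.01).
#' @param sex Optional label stored on the result (`"M"`/`"F"`).
#' @return A `window_enrichment` tibble: the grid columns plus
#'   `n_biased_in`, `n_total_in`, `n_biased_out`, `n_total_out`, `pvalue`,
#'   `qvalue`, `enriched`.
#' @export
window_fisher <- function(grid, gene_map, biased_genes, universe,
                          q_threshold = 0.01, sex = NA_character_) {
  if (!all(gene_map$gene_id %in% universe))
    stop("gene universe must contain every assigned gene", call. = FALSE)
  biased_genes <- intersect(biased_genes, universe)
  N <- length(unique(universe))
  K <- length(unique(biased_genes))
  per_bin <- dplyr::summarise(
    dplyr::group_by(gene_map, .data$bin),
    n_total_in = dplyr::n_distinct(.data$gene_id),
    n_biased_in = sum(unique(.data$gene_id) %in% biased_genes),
    .groups = "drop"
  )
  out <- tibble::as_tibble(grid)
  out$n_total_in <- 0L
  out$n_biased_in <- 0L
  out$n_total_in[per_bin$bin] <- per_bin$n_total_in
  out$n_biased_in[per_bin$bin] <- per_bin$n_biased_in
  out$n_biased_out <- K - out$n_biased_in
  out$n_total_out <- N - out$n_total_in
  # one-sided upper tail of Hypergeom(N, K, n_total_in) at n_biased_in
  out$pvalue <- stats::phyper(out$n_biased_in - 1, K, N - K, out$n_total_in,
                              lower.tail = FALSE)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out$enriched <- out$qvalue < q_threshold
  out <- out[, c("scaffold", "start", "end", "n_biased_in", "n_total_in",
                 "n_biased_out", "n_total_out", "pvalue", "qvalue",
                 "enriched")]
  attr(out, "q_threshold") <- q_threshold
  attr(out, "sex") <- sex
  attr(out, "universe_size") <- N
  attr(out, "n_biased") <- K
  class(out) <- c("window_enrichment", class(out))
  out
}

#' Merge enriched windows into maximal regions
#'
#' @param result A `window_enrichment`.
#' @return Tibble of merged (union of overlapping or adjacent enriched
#'   windows) regions: `scaffold`, `start`, `end`, `n_bins`.
#' @export
enriched_regions <- function(result) {
  hit <- result[result$enriched, ]
  if (nrow(hit) == 0)
    return(tibble::tibble(scaffold = character(), start = integer(),
                          end = integer(), n_bins = integer()))
  parts <- lapply(unique(hit$scaffold), function(s) {
    h <- hit[hit$scaffold == s, ]
    red <- IRanges::reduce(IRanges::IRanges(h$start + 1L, h$end))
    tibble::tibble(scaffold = s,
                   start = as.integer(IRanges::start(red) - 1L),
                   end = as.integer(IRanges::end(red)),
                   n_bins = as.integer(S4Vectors::countQueryHits(
                     IRanges::findOverlaps(red,
                                           IRanges::IRanges(h$start + 1L,
                                                            h$end)))))
  })
  dplyr::arrange(dplyr::bind_rows(parts), .data$scaffold, .data$start)
}

#' Summarize a window-enrichment analysis
#'
#' @param result A `window_enrichment`.
#' @return One-row tibble: `sex`, `n_enriched_bins`,
#'   `n_scaffolds_with_enriched_bins`, `n_regions`.
#' @export
summarize_enrichment <- function(result) {
  regions <- enriched_regions(result)
  tibble::tibble(
    sex = attr(result, "sex"),
    n_enriched_bins = sum(result$enriched),
    n_scaffolds_with_enriched_bins =
      dplyr::n_distinct(result$scaffold[result$enriched]),
    n_regions = nrow(regions)
  )
}
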