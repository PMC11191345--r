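# Expression channel: TPM, pseudocount fold-changes, a built-in DE test,
# the >10x biased gene sets, and the cross-sex specificity statistic.

counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "gene_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Transcripts-per-million normalization
#'
#' `tpm[g, s] = 1e6 * r[g, s] / sum_g r[g, s]` with
#' `r = counts / eff_length`; every sample column sums to one million.
#'
#' @param counts Tibble with a `gene_id` column followed by one integer
#'   count column per sample.
#' @param eff_lengths Tibble with `gene_id` and `eff_length_bp` (> 0), or a
#'   vector named by gene id.
#' @return Tibble of the same shape as `counts` holding TPM values.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10L, 10L))
#' lens <- tibble::tibble(gene_id = c("a", "b"), eff_length_bp = c(1000, 2000))
#' compute_tpm(counts, lens)
#' @export
compute_tpm <- function(counts, eff_lengths) {
  m <- counts_to_matrix(counts)
  if (is.data.frame(eff_lengths)) {
    len <- stats::setNames(eff_lengths$eff_length_bp, eff_lengths$gene_id)
  } else len <- eff_lengths
  len <- len[rownames(m)]
  if (anyNA(len) || any(len <= 0))
    stop("every gene needs a positive effective length", call. = FALSE)
  r <- m / len
  tot <- colSums(r)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  tpm <- sweep(r, 2, tot, "/") * 1e6
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(tpm))
}

sex_means <- function(tpm_mat, sex_labels) {
  sex <- sex_labels[colnames(tpm_mat)]
  if (anyNA(sex) || !all(c("M", "F") %in% sex))
    stop("sex_labels must cover every sample and include both sexes",
         call. = FALSE)
  list(M = rowMeans(tpm_mat[, sex == "M", drop = FALSE]),
       F = rowMeans(tpm_mat[, sex == "F", drop = FALSE]))
}

#' Male/female log2 fold-change with pseudocount
#'
#' `log2((mean TPM male + pseudocount) / (mean TPM female + pseudocount))`
#' using the per-sex arithmetic mean of sample TPMs.
#'
#' @param tpm TPM tibble from [compute_tpm()].
#' @param sex_labels Character vector of `"M"`/`"F"` named by sample id.
#' @param pseudocount Added to both means before the ratio (default 0.1).
#' @return Tibble with `gene_id`, `mean_tpm_M`, `mean_tpm_F`, `log2fc_mf`.
#' @export
fold_change <- function(tpm, sex_labels, pseudocount = 0.1) {
  m <- counts_to_matrix(tpm)
  mu <- sex_means(m, sex_labels)
  tibble::tibble(
    gene_id = rownames(m),
    mean_tpm_M = unname(mu$M),
    mean_tpm_F = unname(mu$F),
    log2fc_mf = unname(log2((mu$M + pseudocount) / (mu$F + pseudocount)))
  )
}

#' Differential expression between sexes (built-in test)
#'
#' A deliberately simple, pluggable DE stage: Welch's two-sample t-test on
#' `log2(TPM + 1)` per gene, two-sided, with Benjamini-Hochberg adjustment
#' and a significance flag at `fdr < 0.05`. Genes constant across all
#' samples get p = 1 by convention. An externally produced DE table (e.g. a
#' negative-binomial model fit) can be used instead via [read_de_table()];
#' downstream stages only consume `log2fc_mf`, `fdr` and `significant`.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param eff_lengths As in [compute_tpm()].
#' @param sex_labels Named `"M"`/`"F"` vector, one entry per sample; at
#'   least two samples per sex.
#' @param fdr_threshold Significance cutoff on the BH-adjusted p (default
#'   0.05).
#' @param pseudocount Pseudocount for the reported fold-change (default 0.1).
#' @return A `de_table` tibble: `gene_id`, `mean_tpm_M`, `mean_tpm_F`,
#'   `log2fc_mf`, `pvalue`, `fdr`, `significant`.
#' @export
de_test <- function(counts, eff_lengths, sex_labels,
                    fdr_threshold = 0.05, pseudocount = 0.1) {
  tpm <- compute_tpm(counts, eff_lengths)
  m <- counts_to_matrix(tpm)
  sex <- sex_labels[colnames(m)]
  if (sum(sex == "M") < 2 || sum(sex == "F") < 2)
    stop("the built-in test needs >= 2 samples per sex", call. = FALSE)
  y <- log2(m + 1)
  ym <- y[, sex == "M", drop = FALSE]
  yf <- y[, sex == "F", drop = FALSE]
  pvalue <- vapply(seq_len(nrow(y)), function(i) {
    a <- ym[i, ]; b <- yf[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) return(1)
      return(0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  fc <- fold_change(tpm, sex_labels, pseudocount)
  out <- dplyr::mutate(
    fc,
    pvalue = pvalue,
    fdr = stats::p.adjust(pvalue, method = "BH"),
    significant = .data$fdr < fdr_threshold
  )
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("de_table", class(out))
  out
}

#' Read an externally produced differential-expression table
#'
#' Ingests a TSV with columns `gene_id`, `log2fc_mf`, `pvalue` (optional)
#' and `fdr`, recomputing the significance flag at `fdr_threshold`.
#'
#' @param path TSV file path.
#' @param fdr_threshold Cutoff for the `significant` flag (default 0.05).
#' @return A `de_table` tibble.
#' @export
read_de_table <- function(path, fdr_threshold = 0.05) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("gene_id", "log2fc_mf", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- dplyr::mutate(tibble::as_tibble(df),
                       significant = .data$fdr < fdr_threshold)
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("de_table", class(out))
  out
}

#' Select strongly sex-biased genes
#'
#' Keeps significant genes whose pseudocount fold-change exceeds
#' `fc_threshold` in either direction: male-biased when
#' `log2fc_mf > log2(fc_threshold)`, female-biased when
#' `log2fc_mf < -log2(fc_threshold)`.
#'
#' @param de A `de_table`.
#' @param fc_threshold Linear fold-change cutoff (default 10).
#' @return A `biased_gene_sets` list: `male_biased`, `female_biased`
#'   (character vectors) and `fc_threshold`.
#' @export
select_biased <- function(de, fc_threshold = 10) {
  lt <- log2(fc_threshold)
  structure(list(
    male_biased = de$gene_id[de$significant & de$log2fc_mf > lt],
    female_biased = de$gene_id[de$significant & de$log2fc_mf < -lt],
    fc_threshold = fc_threshold
  ), class = "biased_gene_sets")
}

#' @export
print.biased_gene_sets <- function(x, ...) {
  cat("<biased_gene_sets> >", x$fc_threshold, "x fold change: ",
      length(x$male_biased), " male-biased, ",
      length(x$female_biased), " female-biased\n", sep = "")
  invisible(x)
}

#' Cross-sex expression of the biased gene sets
#'
#' Fraction of each sex's biased genes whose mean TPM in the *opposite* sex
#' exceeds `tpm_threshold` — a specificity check: genes truly restricted to
#' one sex should rarely clear it.
#'
#' @param biased A `biased_gene_sets`.
#' @param tpm TPM tibble.
#' @param sex_labels Named `"M"`/`"F"` vector.
#' @param tpm_threshold Opposite-sex mean TPM cutoff (default 10).
#' @return Tibble with one row per sex: `sex`, `n_biased`, `n_cross`,
#'   `fraction` (`NA` when the set is empty).
#' @export
cross_sex_fraction <- function(biased, tpm, sex_labels, tpm_threshold = 10) {
  m <- counts_to_matrix(tpm)
  mu <- sex_means(m, sex_labels)
  one <- function(ids, opposite_mean) {
    n <- length(ids)
    if (n == 0) return(c(n, NA_real_, NA_real_))
    x <- opposite_mean[match(ids, rownames(m))]
    c(n, sum(x > tpm_threshold), sum(x > tpm_threshold) / n)
  }
  a <- one(biased$male_biased, mu$F)
  b <- one(biased$female_biased, mu$M)
  tibble::tibble(
    sex = c("M", "F"),
    n_biased = c(a[1], b[1]),
    n_cross = c(a[2], b[2]),
    fraction = c(a[3], b[3])
  )
}
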