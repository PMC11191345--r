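#' PCA of sample profiles
#'
#' Mean-centered principal component analysis of samples over features
#' (genes or coverage bins), as used to check that samples separate (or do
#' not) by sex. Each component's sign is fixed deterministically: the
#' loading with the largest magnitude is made positive.
#'
#' @param x Wide tibble whose first column identifies the feature and whose
#'   remaining columns are samples, or a features-by-samples numeric matrix.
#' @param n_components Number of components to return (default 2).
#' @param scale. Scale features to unit variance (default `FALSE`;
#'   zero-variance features are never scaled).
#' @return A `pca_profiles` list: `scores` (tibble: `sample_id`, `PC1`,
#'   ...), `explained_variance` (fractions, non-increasing) and `sdev`.
#' @export
pca_profiles <- function(x, n_components = 2, scale. = FALSE) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[1]])
  } else m <- x
  if (ncol(m) < 2 || nrow(m) < 2)
    stop("need at least 2 samples and 2 features", call. = FALSE)
  s <- t(m)  # samples x features
  sds <- apply(s, 2, stats::sd)
  if (all(sds == 0)) {
    k <- min(n_components, nrow(s) - 1)
    scores <- matrix(0, nrow(s), k,
                     dimnames = list(rownames(s), paste0("PC", seq_len(k))))
    return(structure(list(
      scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(s)),
                                tibble::as_tibble(scores)),
      explained_variance = rep(0, k),
      sdev = rep(0, k)
    ), class = "pca_profiles"))
  }
  if (scale.) s <- s[, sds > 0, drop = FALSE]
  p <- stats::prcomp(s, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$x))
  flip <- vapply(seq_len(k), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(scores)),
                              tibble::as_tibble(scores)),
    explained_variance = ev[seq_len(k)],
    sdev = p$sdev[seq_len(k)]
  ), class = "pca_profiles")
}

#' @export
print.pca_profiles <- function(x, ...) {
  cat("<pca_profiles> ", nrow(x$scores), " samples; explained variance: ",
      paste(round(100 * x$explained_variance, 1), "%", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
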