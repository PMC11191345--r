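# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the library
# calls) they validate.

# one-sided (greater) Fisher p: exact hypergeometric tail by direct
# enumeration with binomial coefficients
oracle_fisher_greater <- function(b_in, t_in, K, N) {
  hi <- min(K, t_in)
  x <- max(0, b_in):hi
  if (b_in > hi) return(0)
  sum(choose(K, x) * choose(N - K, t_in - x)) / choose(N, t_in)
}

# Benjamini-Hochberg by the step-up definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# quadratic all-pairs overlap of half-open intervals
oracle_assign <- function(genes, grid) {
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(grid))) {
      if (genes$scaffold[i] == grid$scaffold[j] &&
          genes$start[i] < grid$end[j] &&
          grid$start[j] < genes$end[i]) {
        hits[[length(hits) + 1L]] <- c(j, i)
      }
    }
  }
  if (length(hits) == 0)
    return(tibble::tibble(bin = integer(), gene_id = character()))
  m <- do.call(rbind, hits)
  out <- tibble::tibble(bin = m[, 1], gene_id = genes$gene_id[m[, 2]])
  dplyr::arrange(out, bin, gene_id)
}

# string-level reverse complement and canonical k-mer enumeration
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  m <- n - k + 1
  w <- substring(seq, 1:m, k:n)
  # the reverse complement of window i is window m - i + 1 of revcomp(seq)
  wrc <- substring(oracle_revcomp(seq), 1:m, k:n)[m:1]
  keep <- !grepl("[^ACGT]", w)
  pmin(w[keep], wrc[keep])
}

# naive substring/set-arithmetic YGS quantities over string k-mer sets
oracle_ygs <- function(contig_seqs, contig_id, carrier_set, opposite_set, k) {
  all_km <- unlist(lapply(contig_seqs, oracle_kmers, k = k))
  tab <- table(all_km)
  km <- unique(oracle_kmers(contig_seqs[[contig_id]], k))
  sc <- km[tab[km] == 1]
  vsc <- intersect(sc, carrier_set)
  vsc_uk <- setdiff(vsc, opposite_set)
  list(n_sc = length(sc), n_vsc = length(vsc), n_vsc_uk = length(vsc_uk),
       p = if (length(vsc) == 0) NA_real_
           else 100 * length(vsc_uk) / length(vsc))
}

# random nucleotide string
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# kmer_table from explicit string -> count pairs (input construction only)
make_kmer_table <- function(counts, source = "reads") {
  tbl <- tibble::tibble(kmer = sexscan::kmer_encode(names(counts)),
                        count = as.numeric(counts))
  tbl <- dplyr::arrange(tbl, kmer)
  attr(tbl, "k") <- nchar(names(counts)[1])
  attr(tbl, "source") <- source
  class(tbl) <- c("kmer_table", class(tbl))
  tbl
}

# small, fast config for structural tests
tiny_config <- function(seed, architecture = "NONE", ...) {
  sim_config(seed = seed, architecture = architecture,
             n_autosomes = 2, scaffold_length_bp = 30000,
             n_genes_per_scaffold = 5, kmer_k = 15, ...)
}
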