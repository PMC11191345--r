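# 2-bit nucleotide codes: A=0, C=1, G=2, T=3. A k-mer is packed into a single
# double; doubles are exact to 2^53, so k <= 26 keeps every code exact.
KMER_MAX_K <- 26L

base_codes <- function(seq) {
  x <- utf8ToInt(seq)
  out <- rep(NA_real_, length(x))
  out[x == 65L | x == 97L] <- 0   # A/a
  out[x == 67L | x == 99L] <- 1   # C/c
  out[x == 71L | x == 103L] <- 2  # G/g
  out[x == 84L | x == 116L] <- 3  # T/t
  out
}

check_k <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > KMER_MAX_K)
    stop("k must be in [1, ", KMER_MAX_K, "]", call. = FALSE)
  if (k %% 2L == 0L)
    stop("k must be odd (so no k-mer equals its own reverse complement)",
         call. = FALSE)
  k
}

#' Canonical k-mer codes of a nucleotide sequence
#'
#' Slides a k-bp window along `seq` and returns, for every window free of
#' non-ACGT characters, the canonical k-mer as a packed 2-bit integer code.
#' The canonical form is the lexicographic minimum of the k-mer and its
#' reverse complement, which for 2-bit codes (A<C<G<T) is the numeric
#' minimum of the two codes. Windows containing any non-ACGT symbol are
#' skipped entirely.
#'
#' @param seq A single character string (nucleotide sequence).
#' @param k Odd k-mer length, at most 26.
#' @return A numeric vector of canonical codes, one per retained window,
#'   in sequence order.
#' @seealso [kmer_decode()], [count_assembly_kmers()]
#' @export
kmer_codes <- function(seq, k) {
  k <- check_k(k)
  codes <- base_codes(seq)
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  fwd <- numeric(m)
  rc <- numeric(m)
  for (j in seq_len(k) - 1L) {
    cj <- codes[(1L + j):(m + j)]
    fwd <- fwd * 4 + cj
    rc <- rc + (3 - cj) * 4^j
  }
  keep <- !is.na(fwd)
  pmin(fwd[keep], rc[keep])
}

#' Decode packed k-mer codes to ACGT strings
#'
#' @param code Numeric vector of 2-bit packed codes.
#' @param k The k-mer length the codes were packed with.
#' @return Character vector of uppercase k-mer strings.
#' @export
kmer_decode <- function(code, k) {
  k <- as.integer(k)
  mat <- matrix("", nrow = length(code), ncol = k)
  rem <- code
  for (j in k:1) {
    d <- rem %% 4
    mat[, j] <- c("A", "C", "G", "T")[d + 1]
    rem <- (rem - d) / 4
  }
  apply(mat, 1L, paste0, collapse = "")
}

#' Encode k-mer strings to packed codes (canonicalized)
#'
#' @param kmer Character vector of k-mer strings, all the same odd length.
#' @return Numeric vector of canonical packed codes.
#' @export
kmer_encode <- function(kmer) {
  if (length(kmer) == 0) return(numeric(0))
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("all k-mers must have the same length", call. = FALSE)
  vapply(kmer, function(s) {
    v <- kmer_codes(s, k)
    if (length(v) != 1L) stop("invalid k-mer: ", s, call. = FALSE)
    v
  }, numeric(1), USE.NAMES = FALSE)
}

# reverse-complement of packed codes (vectorized, used by the simulator)
kmer_revcomp_code <- function(code, k) {
  rc <- numeric(length(code))
  rem <- code
  for (j in seq_len(k) - 1L) {
    d <- rem %% 4
    rc <- rc * 4 + (3 - d)
    rem <- (rem - d) / 4
  }
  rc
}

kmer_canonical_code <- function(code, k) {
  pmin(code, kmer_revcomp_code(code, k))
}

# sum `weight` (default 1) over equal codes; returns kmer-sorted tibble.
# sort + cumsum instead of hash grouping: the code vectors run to millions.
aggregate_codes <- function(code, weight = NULL) {
  if (length(code) == 0)
    return(tibble::tibble(kmer = numeric(0), count = numeric(0)))
  o <- order(code, method = "radix")
  ks <- code[o]
  w <- if (is.null(weight)) rep(1, length(ks)) else weight[o]
  new_grp <- c(TRUE, ks[-1L] != ks[-length(ks)])
  ends <- c(which(new_grp[-1L]), length(ks))
  cw <- cumsum(w)
  tibble::tibble(kmer = ks[new_grp], count = diff(c(0, cw[ends])))
}

new_kmer_table <- function(df, k, source) {
  stopifnot(all(c("kmer", "count") %in% names(df)))
  out <- tibble::as_tibble(df)
  attr(out, "k") <- as.integer(k)
  attr(out, "source") <- source
  class(out) <- c("kmer_table", class(out))
  out
}

#' Count canonical k-mers of an assembly
#'
#' Enumerates all canonical k-mers of every contig and tallies them over the
#' whole assembly. Also retains, per contig, the set of distinct canonical
#' k-mers it contains, which the sex-specificity scan uses to find
#' single-copy (assembly-wide count one) k-mers.
#'
#' @param assembly A named character vector of contig sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param k Odd k-mer length (default 15).
#' @return An object of class `assembly_kmers`: a list with `k`, `table`
#'   (a [tibble][tibble::tibble] of `kmer` code and `count`), `contig_kmers`
#'   (named list of distinct canonical codes per contig) and `contig_len`
#'   (named integer vector of contig lengths).
#' @export
count_assembly_kmers <- function(assembly, k = 15) {
  k <- check_k(k)
  if (inherits(assembly, "DNAStringSet")) {
    seqs <- as.character(assembly)
  } else {
    seqs <- assembly
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("assembly must have unique contig names", call. = FALSE)
  streams <- lapply(seqs, kmer_codes, k = k)
  tab <- aggregate_codes(unlist(streams, use.names = FALSE))
  structure(
    list(
      k = k,
      table = new_kmer_table(tab, k, "assembly"),
      contig_kmers = lapply(streams, function(v) sort(unique(v))),
      contig_len = vapply(seqs, nchar, integer(1))
    ),
    class = "assembly_kmers"
  )
}

#' Trusted k-mers of a read-derived count table
#'
#' Filters a read k-mer count table down to k-mers whose count reaches
#' `min_count`, discarding likely sequencing-error k-mers (which appear
#' mostly as singletons at typical 15-20x depth).
#'
#' @param table A `kmer_table` (tibble with `kmer` code and `count`).
#' @param min_count Minimum count for a k-mer to be trusted (default 2).
#' @return Sorted numeric vector of trusted canonical k-mer codes.
#' @export
trusted_kmers <- function(table, min_count = 2) {
  if (nrow(table) == 0) stop("empty k-mer table", call. = FALSE)
  sort(table$kmer[table$count >= min_count])
}

#' Write / read a k-mer count table as TSV
#'
#' K-mers are written as uppercase ACGT strings with their counts; reading
#' re-encodes them to packed canonical codes.
#'
#' @param table A `kmer_table`.
#' @param path File path.
#' @return `write_kmer_table()` returns `path` invisibly; `read_kmer_table()`
#'   returns a `kmer_table`.
#' @export
write_kmer_table <- function(table, path) {
  k <- attr(table, "k")
  out <- tibble::tibble(
    kmer = kmer_decode(table$kmer, k),
    count = table$count
  )
  out <- dplyr::arrange(out, .data$kmer)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_kmer_table
#' @param source Label recorded on the table (`"reads_M"`, `"reads_F"`, ...).
#' @export
read_kmer_table <- function(path, source = "reads") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    kmer = readr::col_character(), count = readr::col_double()
  ))
  k <- unique(nchar(df$kmer))
  if (length(k) != 1L) stop("mixed k-mer lengths in ", path, call. = FALSE)
  new_kmer_table(
    tibble::tibble(kmer = kmer_encode(df$kmer), count = df$count),
    k, source
  )
}
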