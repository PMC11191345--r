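#' Simulation configuration
#'
#' Declares a synthetic study: a genome under a chosen sex-determination
#' architecture, sex-separated RNA-Seq counts with a minority of strongly
#' sex-biased genes, sex-separated genomic coverage, and per-sex read k-mer
#' tables. The defaults mirror the study design the pipeline is built for:
#' 4 male and 3 female RNA-Seq replicates, ~20x genomic depth, 15-mers, and
#' a 16-fold expression effect for biased genes (the downstream filter keeps
#' genes above 10-fold).
#'
#' @param seed Integer seed; every downstream `simulate_*()` call is fully
#'   determined by the config (including this seed).
#' @param architecture `"XY"`, `"ZW"` or `"NONE"`. Under `"XY"` the genome
#'   gains an X scaffold (1 copy in males, 2 in females) and a male-only Y
#'   scaffold; `"ZW"` is the mirror image; `"NONE"` has autosomes only.
#' @param n_autosomes Number of autosomal scaffolds.
#' @param scaffold_length_bp Length of each autosomal scaffold.
#' @param sex_scaffold_length_bp Length of the X/Y (or Z/W) scaffolds.
#' @param n_genes_per_scaffold Genes placed on every scaffold
#'   (non-overlapping, each 300-3000 bp).
#' @param frac_biased_male,frac_biased_female Fractions of all genes made
#'   male- or female-biased in expression. Kept symmetric by default so the
#'   biased minority does not shift library composition between sexes.
#' @param bias_fold Expression fold-change of biased genes (> 1).
#' @param bias_cluster_scaffolds List with components `M` and `F`: scaffold
#'   ids whose genes preferentially receive that sex's biased labels
#'   (probability `bias_cluster_prob` per biased gene). `NULL` components
#'   mean unclustered placement.
#' @param bias_cluster_prob Probability that a biased gene is drawn from the
#'   cluster scaffolds rather than uniformly elsewhere.
#' @param n_male_samples,n_female_samples Replicates per sex (both RNA-Seq
#'   and coverage).
#' @param mean_depth Expected sequencing depth (reads per base) of a
#'   two-copy region.
#' @param nb_dispersion Negative-binomial dispersion of RNA-Seq counts
#'   (0 gives Poisson counts).
#' @param kmer_k Odd k-mer length for read k-mer tables (default 15).
#' @param kmer_error_rate Fraction of total k-mer mass emitted as uniform
#'   random singleton "error" k-mers.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, architecture = "XY")
#' cfg$architecture
#' @export
sim_config <- function(seed,
                       architecture = c("NONE", "XY", "ZW"),
                       n_autosomes = 4,
                       scaffold_length_bp = 200000,
                       sex_scaffold_length_bp = scaffold_length_bp,
                       n_genes_per_scaffold = 30,
                       frac_biased_male = 0.03,
                       frac_biased_female = 0.03,
                       bias_fold = 16,
                       bias_cluster_scaffolds = list(M = NULL, F = NULL),
                       bias_cluster_prob = 0.9,
                       n_male_samples = 4,
                       n_female_samples = 3,
                       mean_depth = 20,
                       nb_dispersion = 0.05,
                       kmer_k = 15,
                       kmer_error_rate = 0.002) {
  architecture <- match.arg(architecture)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  kmer_k <- check_k(kmer_k)
  if (is.atomic(bias_cluster_scaffolds) || is.null(bias_cluster_scaffolds))
    bias_cluster_scaffolds <- list(M = bias_cluster_scaffolds, F = NULL)

  cfg <- list(
    seed = seed,
    architecture = architecture,
    n_autosomes = as.integer(n_autosomes),
    scaffold_length_bp = as.integer(scaffold_length_bp),
    sex_scaffold_length_bp = as.integer(sex_scaffold_length_bp),
    n_genes_per_scaffold = as.integer(n_genes_per_scaffold),
    frac_biased_male = frac_biased_male,
    frac_biased_female = frac_biased_female,
    bias_fold = bias_fold,
    bias_cluster_scaffolds = bias_cluster_scaffolds[c("M", "F")],
    bias_cluster_prob = bias_cluster_prob,
    n_male_samples = as.integer(n_male_samples),
    n_female_samples = as.integer(n_female_samples),
    mean_depth = mean_depth,
    nb_dispersion = nb_dispersion,
    kmer_k = kmer_k,
    kmer_error_rate = kmer_error_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_biased_male, cfg$frac_biased_female,
          cfg$kmer_error_rate, cfg$bias_cluster_prob)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$scaffold_length_bp < 10 * cfg$kmer_k ||
      cfg$sex_scaffold_length_bp < 10 * cfg$kmer_k)
    stop("scaffold lengths must be >= 10 * kmer_k", call. = FALSE)
  if (cfg$n_male_samples < 1 || cfg$n_female_samples < 1)
    stop("need at least one sample per sex", call. = FALSE)
  if (cfg$bias_fold <= 1) stop("bias_fold must exceed 1", call. = FALSE)
  if (cfg$n_autosomes < 1) stop("need at least one autosome", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> architecture=", x$architecture,
      " seed=", x$seed,
      " scaffolds=", x$n_autosomes,
      if (x$architecture != "NONE") "+2" else "",
      " genes/scaffold=", x$n_genes_per_scaffold,
      " samples=", x$n_male_samples, "M/", x$n_female_samples, "F\n",
      sep = "")
  invisible(x)
}
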