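# Synthetic study generator: genome + annotation + truth, expression counts,
# binned coverage, and per-sex read k-mer tables, all deterministic in the
# config (stage seeds are derived from config$seed so stages can be rerun
# independently and still agree byte-for-byte).

stage_seed <- function(cfg, stage) {
  offset <- c(genome = 0L, expression = 1L, coverage = 2L, kmers = 3L)[[stage]]
  as.integer((as.numeric(cfg$seed) + offset * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

scaffold_plan <- function(cfg) {
  auto <- sprintf("scaf_auto_%02d", seq_len(cfg$n_autosomes))
  plan <- tibble::tibble(
    scaffold = auto,
    length = cfg$scaffold_length_bp,
    copies_M = 2L, copies_F = 2L
  )
  if (cfg$architecture == "XY") {
    plan <- dplyr::bind_rows(plan, tibble::tibble(
      scaffold = c("scaf_X", "scaf_Y"),
      length = cfg$sex_scaffold_length_bp,
      copies_M = c(1L, 1L), copies_F = c(2L, 0L)
    ))
  } else if (cfg$architecture == "ZW") {
    plan <- dplyr::bind_rows(plan, tibble::tibble(
      scaffold = c("scaf_Z", "scaf_W"),
      length = cfg$sex_scaffold_length_bp,
      copies_M = c(2L, 0L), copies_F = c(1L, 1L)
    ))
  }
  plan
}

place_genes <- function(scaffold, length, n_genes) {
  lens <- sample(300:3000, n_genes, replace = TRUE)
  slack <- length - sum(lens)
  if (slack < 0)
    stop("cannot pack ", n_genes, " genes into ", length,
         " bp on ", scaffold, call. = FALSE)
  gap_raw <- stats::runif(n_genes + 1)
  gaps <- floor(slack * cumsum(gap_raw) / sum(gap_raw))
  starts <- utils::head(gaps, n_genes) + c(0, cumsum(utils::head(lens, -1)))
  tibble::tibble(
    scaffold = scaffold,
    start = as.integer(starts),
    end = as.integer(starts + lens),
    gene_id = sprintf("%s_g%03d", scaffold, seq_len(n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

draw_biased <- function(eligible, cluster_scaffolds, n_biased, cluster_prob) {
  if (n_biased == 0) return(character(0))
  pool_cluster <- eligible$gene_id[eligible$scaffold %in% cluster_scaffolds]
  pool_other <- setdiff(eligible$gene_id, pool_cluster)
  if (length(pool_cluster) == 0) {
    return(sample(pool_other, min(n_biased, length(pool_other))))
  }
  n_cluster <- min(stats::rbinom(1, n_biased, cluster_prob),
                   length(pool_cluster))
  n_other <- min(n_biased - n_cluster, length(pool_other))
  c(sample(pool_cluster, n_cluster), sample(pool_other, n_other))
}

#' Simulate a genome, gene annotation and ground truth
#'
#' Generates random-uniform nucleotide scaffolds under the configured
#' architecture (XY: one male-hemizygous X and one male-only Y; ZW mirrored;
#' NONE: autosomes only), places non-overlapping genes of 300-3000 bp on
#' every scaffold, and labels a fraction of genes as expression-biased per
#' sex. Biased genes are drawn only from scaffolds present in both sexes
#' (copy-number effects are left to the coverage and k-mer channels) and,
#' when cluster scaffolds are configured for a sex, land there with
#' probability `bias_cluster_prob`.
#'
#' @param config A [sim_config()].
#' @param sequences Generate nucleotide sequences (default `TRUE`). With
#'   `FALSE` the `assembly` element is `NULL`; annotation, truth and all
#'   expression-side outputs are identical to the `TRUE` case, which makes
#'   expression-only studies cheap.
#' @return A `sim_genome`: list with `assembly`
#'   (`Biostrings::DNAStringSet`), `genes` (tibble of 0-based half-open
#'   intervals: `scaffold`, `start`, `end`, `gene_id`, `strand`), `truth`
#'   (`sim_truth`) and `config`.
#' @examples
#' g <- simulate_genome(sim_config(seed = 1, architecture = "XY"))
#' g$truth$sex_specific_scaffolds
#' @export
simulate_genome <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config, "genome"), {
    plan <- scaffold_plan(config)
    genes <- dplyr::bind_rows(purrr::pmap(
      list(plan$scaffold, plan$length),
      function(s, L) place_genes(s, L, config$n_genes_per_scaffold)
    ))
    eligible <- dplyr::semi_join(
      genes,
      dplyr::filter(plan, .data$copies_M > 0L, .data$copies_F > 0L),
      by = "scaffold"
    )
    n_genes <- nrow(genes)
    male_biased <- draw_biased(
      eligible, config$bias_cluster_scaffolds$M,
      round(config$frac_biased_male * n_genes), config$bias_cluster_prob
    )
    eligible_f <- eligible[!eligible$gene_id %in% male_biased, ]
    female_biased <- draw_biased(
      eligible_f, config$bias_cluster_scaffolds$F,
      round(config$frac_biased_female * n_genes), config$bias_cluster_prob
    )
    truth <- structure(list(
      architecture = config$architecture,
      sex_specific_scaffolds =
        plan$scaffold[plan$copies_M == 0L | plan$copies_F == 0L],
      hemizygous_scaffolds =
        plan$scaffold[(plan$copies_M == 1L & plan$copies_F == 2L) |
                        (plan$copies_M == 2L & plan$copies_F == 1L)],
      biased_gene_ids = list(M = sort(male_biased), F = sort(female_biased)),
      copy_number = plan
    ), class = "sim_truth")
    assembly <- NULL
    if (sequences) {
      seqs <- vapply(plan$length, function(L) {
        intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, L, replace = TRUE)])
      }, character(1))
      names(seqs) <- plan$scaffold
      assembly <- Biostrings::DNAStringSet(seqs)
    }
    structure(list(
      assembly = assembly,
      genes = genes,
      truth = truth,
      config = config
    ), class = "sim_genome")
  })
}

sample_sheet <- function(cfg) {
  tibble::tibble(
    sample_id = c(sprintf("M%d", seq_len(cfg$n_male_samples)),
                  sprintf("F%d", seq_len(cfg$n_female_samples))),
    sex = c(rep("M", cfg$n_male_samples), rep("F", cfg$n_female_samples))
  )
}

#' Simulate sex-separated RNA-Seq counts
#'
#' Per-gene baseline means are log-normal; counts are negative binomial
#' around `baseline * sex_multiplier`, where the multiplier is `bias_fold`
#' for the biased sex of a biased gene and 1 otherwise. Genes on scaffolds
#' absent from a sex's genome have mean zero (hence all-zero counts) in that
#' sex. Effective lengths equal gene lengths.
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @return A `sim_expression`: list with `counts` (tibble: `gene_id` plus one
#'   integer column per sample), `eff_lengths` (tibble: `gene_id`,
#'   `eff_length_bp`) and `samples` (tibble: `sample_id`, `sex`).
#' @export
simulate_expression <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  cfg <- genome$config
  with_seed(stage_seed(cfg, "expression"), {
    genes <- genome$genes
    truth <- genome$truth
    samples <- sample_sheet(cfg)
    n <- nrow(genes)
    baseline <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)

    present <- truth$copy_number
    mult <- matrix(1, nrow = n, ncol = 2,
                   dimnames = list(genes$gene_id, c("M", "F")))
    mult[genes$gene_id %in% truth$biased_gene_ids$M, "M"] <- cfg$bias_fold
    mult[genes$gene_id %in% truth$biased_gene_ids$F, "F"] <- cfg$bias_fold
    absent_m <- present$scaffold[present$copies_M == 0L]
    absent_f <- present$scaffold[present$copies_F == 0L]
    mult[genes$scaffold %in% absent_m, "M"] <- 0
    mult[genes$scaffold %in% absent_f, "F"] <- 0

    counts <- sapply(seq_len(nrow(samples)), function(i) {
      mu <- baseline * mult[, samples$sex[i]]
      if (cfg$nb_dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    })
    colnames(counts) <- samples$sample_id
    structure(list(
      counts = dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                                tibble::as_tibble(counts)),
      eff_lengths = tibble::tibble(gene_id = genes$gene_id,
                                   eff_length_bp = genes$end - genes$start),
      samples = samples
    ), class = "sim_expression")
  })
}

#' Simulate sex-separated binned genome coverage
#'
#' Tiles every scaffold with non-overlapping bins and draws per-bin,
#' per-sample read depth as `Poisson(mean_depth * copies/2 * width) / width`,
#' with the scaffold's per-sex copy number from the ground truth. Male-only
#' scaffolds therefore have zero depth in females, hemizygous scaffolds half
#' depth in the heterogametic sex.
#'
#' @param genome A `sim_genome`.
#' @param bin_bp Bin width in bp (default 10000, minimum 1000).
#' @return A `coverage_raw` tibble: `scaffold`, `start`, `end`, then one raw
#'   depth column per sample; sample sexes in `attr(, "sex")`.
#' @export
simulate_coverage <- function(genome, bin_bp = 10000) {
  stopifnot(inherits(genome, "sim_genome"))
  if (bin_bp < 1000) stop("bin_bp must be >= 1000", call. = FALSE)
  cfg <- genome$config
  with_seed(stage_seed(cfg, "coverage"), {
    plan <- genome$truth$copy_number
    bins <- dplyr::bind_rows(purrr::pmap(
      list(plan$scaffold, plan$length),
      function(s, L) {
        starts <- seq(0L, L - 1L, by = bin_bp)
        tibble::tibble(scaffold = s, start = as.integer(starts),
                       end = as.integer(pmin(starts + bin_bp, L)))
      }
    ))
    samples <- sample_sheet(cfg)
    copies <- plan[match(bins$scaffold, plan$scaffold), ]
    width <- bins$end - bins$start
    depth <- sapply(seq_len(nrow(samples)), function(i) {
      cp <- if (samples$sex[i] == "M") copies$copies_M else copies$copies_F
      stats::rpois(nrow(bins), cfg$mean_depth * cp / 2 * width) / width
    })
    colnames(depth) <- samples$sample_id
    out <- dplyr::bind_cols(bins, tibble::as_tibble(depth))
    attr(out, "sex") <- stats::setNames(samples$sex, samples$sample_id)
    class(out) <- c("coverage_raw", class(out))
    out
  })
}

#' Simulate pooled per-sex read k-mer tables
#'
#' For each sex, every canonical k-mer of the scaffolds present in that
#' sex's genome receives a count drawn from
#' `Poisson(mean_depth * copies / 2)` (summed over its occurrences), with
#' zero draws raised to one so genuinely present k-mers are never dropped.
#' A fraction `kmer_error_rate` of the total k-mer mass is then added as
#' uniform random singleton k-mers, emulating sequencing-error k-mers.
#'
#' @param genome A `sim_genome`.
#' @return Named list with elements `M` and `F`, each a `kmer_table`
#'   (tibble of canonical `kmer` code and `count`).
#' @export
simulate_read_kmers <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  cfg <- genome$config
  k <- cfg$kmer_k
  with_seed(stage_seed(cfg, "kmers"), {
    plan <- genome$truth$copy_number
    streams <- lapply(as.character(genome$assembly), kmer_codes, k = k)
    per_sex <- lapply(c(M = "copies_M", F = "copies_F"), function(col) {
      present <- plan$scaffold[plan[[col]] > 0L]
      code <- unlist(streams[present], use.names = FALSE)
      copies <- rep(plan[[col]][match(present, plan$scaffold)],
                    times = lengths(streams[present]))
      agg <- aggregate_codes(code, copies)  # count = summed copy number
      count <- stats::rpois(nrow(agg), cfg$mean_depth * agg$count / 2)
      count[count == 0] <- 1L
      n_err <- round(cfg$kmer_error_rate * sum(count))
      kmer <- agg$kmer
      if (n_err > 0) {
        err <- kmer_canonical_code(floor(stats::runif(n_err) * 4^k), k)
        tbl <- aggregate_codes(c(kmer, err), c(count, rep(1, n_err)))
      } else {
        tbl <- tibble::tibble(kmer = kmer, count = as.numeric(count))
      }
      new_kmer_table(tbl, k, paste0("reads_", substr(col, 8, 8)))
    })
    per_sex
  })
}
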