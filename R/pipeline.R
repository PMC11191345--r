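# End-to-end orchestration: expression -> window enrichment, coverage scan,
# k-mer scan, then the combined verdict and an on-disk report bundle.

#' Combine the three evidence channels into a verdict
#'
#' Verdict logic, a pure function of the stage outputs:
#' * YGS flags are screened first: a contig flagged in one direction is
#'   discounted when its P_VSC_UK in the opposite direction is also inside
#'   or above the ~50% anomaly band — that pattern marks individual
#'   variability, not sex linkage.
#' * `XY_candidate`: screened XY flags and/or (specific_M together with
#'   hemizygous_M coverage bins), with no equivalent ZW/female support.
#' * `ZW_candidate`: mirrored.
#' * `no_sex_specific_regions`: both channels ran, no screened flags in
#'   either direction and no sex-specific coverage bins — regardless of how
#'   many expression-enriched regions exist.
#' * `inconclusive`: conflicting support, or a missing channel preventing
#'   the negative call. With both coverage and k-mer channels absent the
#'   call is never a sex-chromosome architecture.
#'
#' @param enrich_summary Tibble from [summarize_enrichment()] rows (both
#'   sexes), or `NULL`.
#' @param coverage_class A `coverage_class`, or `NULL` if the coverage
#'   channel was skipped.
#' @param ygs A `ygs_scan`, or `NULL` if the k-mer channel was skipped.
#' @return A `sexscan_verdict` list: `architecture_call`, `evidence`
#'   (counts per channel), `anomaly`.
#' @export
call_verdict <- function(enrich_summary = NULL, coverage_class = NULL,
                         ygs = NULL) {
  ev <- list(
    n_enriched_bins_M = NA_integer_, n_enriched_bins_F = NA_integer_,
    n_flagged_xy = NA_integer_, n_flagged_zw = NA_integer_,
    n_flagged_xy_screened = NA_integer_, n_flagged_zw_screened = NA_integer_,
    n_specific_M = NA_integer_, n_specific_F = NA_integer_,
    n_hemizygous_M = NA_integer_, n_hemizygous_F = NA_integer_
  )
  anomaly <- NA
  if (!is.null(enrich_summary)) {
    ev$n_enriched_bins_M <-
      sum(enrich_summary$n_enriched_bins[enrich_summary$sex == "M"])
    ev$n_enriched_bins_F <-
      sum(enrich_summary$n_enriched_bins[enrich_summary$sex == "F"])
  }
  if (!is.null(ygs)) {
    band_hi <- ygs$bidir$band[1]  # lower edge of the ~50% band
    joint <- ygs$bidir$table
    xy_flag <- ygs$xy$contig_id[ygs$xy$flagged]
    zw_flag <- ygs$zw$contig_id[ygs$zw$flagged]
    opp_zw <- joint$p_zw[match(xy_flag, joint$contig_id)]
    opp_xy <- joint$p_xy[match(zw_flag, joint$contig_id)]
    xy_scr <- xy_flag[is.na(opp_zw) | opp_zw < band_hi]
    zw_scr <- zw_flag[is.na(opp_xy) | opp_xy < band_hi]
    ev$n_flagged_xy <- length(xy_flag)
    ev$n_flagged_zw <- length(zw_flag)
    ev$n_flagged_xy_screened <- length(xy_scr)
    ev$n_flagged_zw_screened <- length(zw_scr)
    anomaly <- ygs$bidir$anomaly
  }
  if (!is.null(coverage_class)) {
    ev$n_specific_M <- sum(coverage_class$label == "specific_M")
    ev$n_specific_F <- sum(coverage_class$label == "specific_F")
    ev$n_hemizygous_M <- sum(coverage_class$label == "hemizygous_M")
    ev$n_hemizygous_F <- sum(coverage_class$label == "hemizygous_F")
  }

  have_ygs <- !is.null(ygs)
  have_cov <- !is.null(coverage_class)
  xy_support <- (have_ygs && ev$n_flagged_xy_screened > 0) ||
    (have_cov && ev$n_specific_M > 0 && ev$n_hemizygous_M > 0)
  zw_support <- (have_ygs && ev$n_flagged_zw_screened > 0) ||
    (have_cov && ev$n_specific_F > 0 && ev$n_hemizygous_F > 0)

  call <- if (!have_ygs && !have_cov) {
    "inconclusive"
  } else if (xy_support && !zw_support) {
    "XY_candidate"
  } else if (zw_support && !xy_support) {
    "ZW_candidate"
  } else if (xy_support && zw_support) {
    "inconclusive"
  } else if (have_ygs && have_cov &&
             ev$n_flagged_xy_screened == 0 && ev$n_flagged_zw_screened == 0 &&
             ev$n_specific_M == 0 && ev$n_specific_F == 0) {
    "no_sex_specific_regions"
  } else {
    "inconclusive"
  }
  structure(list(architecture_call = call, evidence = ev, anomaly = anomaly),
            class = "sexscan_verdict")
}

#' @export
print.sexscan_verdict <- function(x, ...) {
  cat("<sexscan_verdict> ", x$architecture_call, "\n", sep = "")
  ev <- x$evidence
  cat("  enriched bins M/F: ", ev$n_enriched_bins_M, "/",
      ev$n_enriched_bins_F,
      "; YGS flags XY/ZW (screened): ", ev$n_flagged_xy_screened, "/",
      ev$n_flagged_zw_screened,
      "; coverage specific M/F: ", ev$n_specific_M, "/", ev$n_specific_F,
      "; hemizygous M/F: ", ev$n_hemizygous_M, "/", ev$n_hemizygous_F,
      "\n", sep = "")
  invisible(x)
}

#' Run the full pipeline
#'
#' Runs the expression channel (TPM, differential expression, the >10x
#' biased sets, window Fisher enrichment for both sexes), the coverage
#' channel (median normalization, bin classification, coverage of the
#' male-enriched regions), and the k-mer channel (bidirectional P_VSC_UK
#' scan), then combines them into a verdict. For a [sim_config()] all
#' inputs are generated; stage-by-stage functions remain available for real
#' data.
#'
#' @param x A [sim_config()].
#' @param out_dir Optional directory: when given, a deterministic report
#'   bundle (FASTA/BED/TSV/JSON) is written there.
#' @param fc_threshold Fold-change cutoff for the biased sets (default 10).
#' @param q_threshold Window enrichment Q-value cutoff (default 0.01).
#' @param bin_bp Coverage bin width (default 10000).
#' @param write_kmers Also write the (large) per-sex k-mer tables into the
#'   bundle (default `FALSE`).
#' @param ... Unused.
#' @return A `sexscan_result` list with every stage output and the verdict.
#' @export
run_all <- function(x, ...) UseMethod("run_all")

#' @rdname run_all
#' @export
run_all.sim_config <- function(x, out_dir = NULL, fc_threshold = 10,
                               q_threshold = 0.01, bin_bp = 10000,
                               write_kmers = FALSE, ...) {
  config <- x
  genome <- simulate_genome(config)
  expr <- simulate_expression(genome)
  sexv <- stats::setNames(expr$samples$sex, expr$samples$sample_id)

  de <- de_test(expr$counts, expr$eff_lengths, sexv)
  tpm <- compute_tpm(expr$counts, expr$eff_lengths)
  biased <- select_biased(de, fc_threshold)
  cross <- cross_sex_fraction(biased, tpm, sexv)

  lens <- stats::setNames(genome$truth$copy_number$length,
                          genome$truth$copy_number$scaffold)
  grid <- make_windows(lens)
  gmap <- assign_genes(genome$genes, grid)
  universe <- genome$genes$gene_id
  enr <- list(
    M = window_fisher(grid, gmap, biased$male_biased, universe,
                      q_threshold, sex = "M"),
    F = window_fisher(grid, gmap, biased$female_biased, universe,
                      q_threshold, sex = "F")
  )
  enr_summary <- dplyr::bind_rows(lapply(enr, summarize_enrichment))
  regions <- lapply(enr, enriched_regions)

  cov <- simulate_coverage(genome, bin_bp)
  norm <- normalize_coverage(cov)
  cls <- classify_bins(norm)
  region_cov <- coverage_of_regions(cls, regions$M)

  kmers <- simulate_read_kmers(genome)
  scan <- ygs_scan(genome$assembly, kmers$M, kmers$F, k = config$kmer_k)

  cov_samples <- names(attr(norm, "sex"))
  pca <- list(
    expression = pca_profiles(tpm),
    coverage = pca_profiles(dplyr::bind_cols(
      tibble::tibble(bin = seq_len(nrow(norm))),
      norm[, cov_samples]
    ))
  )

  verdict <- call_verdict(enr_summary, cls, scan)
  res <- structure(list(
    config = config,
    genome = genome,
    expression = expr,
    tpm = tpm,
    de = de,
    biased = biased,
    cross_sex = cross,
    grid = grid,
    enrichment = enr,
    enrichment_summary = enr_summary,
    regions = regions,
    coverage = cls,
    region_coverage = region_cov,
    kmers = kmers,
    ygs = scan,
    pca = pca,
    verdict = verdict
  ), class = "sexscan_result")
  if (!is.null(out_dir))
    write_report_bundle(res, out_dir, write_kmers = write_kmers)
  res
}

#' @export
print.sexscan_result <- function(x, ...) {
  cat("<sexscan_result> architecture=", x$config$architecture,
      " seed=", x$config$seed, "\n", sep = "")
  print(x$verdict)
  invisible(x)
}

config_provenance <- function(config) {
  list(
    package = "sexscan",
    version = as.character(utils::packageVersion("sexscan")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config))
  )
}

#' Write the on-disk report bundle
#'
#' Writes every stage output in plain-text standard formats: assembly FASTA,
#' genes BED6, count/TPM/DE/coverage/YGS TSVs (missing values as `.`),
#' enriched regions BED6 (score = -log10 Q clipped at 300), and JSON for
#' ground truth, verdict and provenance. Output is deterministic: the same
#' result writes byte-identical files.
#'
#' @param res A `sexscan_result` from [run_all()].
#' @param out_dir Directory (created if needed).
#' @param write_kmers Also write the per-sex read k-mer tables
#'   (default `FALSE`; they dominate bundle size).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(res, out_dir, write_kmers = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  Biostrings::writeXStringSet(res$genome$assembly, p("assembly.fasta"),
                              width = 80)
  write_bed(res$genome$genes, p("genes.bed"), name_col = "gene_id")
  write_tsv_dot(res$expression$counts, p("counts.tsv"))
  write_tsv_dot(res$tpm, p("tpm.tsv"))
  write_tsv_dot(res$expression$samples, p("samples.tsv"))
  write_tsv_dot(res$de, p("de_table.tsv"))
  write_tsv_dot(res$cross_sex, p("cross_sex_fraction.tsv"))
  for (s in c("M", "F")) {
    e <- res$enrichment[[s]]
    write_tsv_dot(e, p(sprintf("window_enrichment_%s.tsv", s)))
    hit <- dplyr::mutate(e[e$enriched, ],
                         score = -log10(pmax(.data$qvalue, 1e-300)))
    write_bed(hit, p(sprintf("enriched_bins_%s.bed", s)),
              score_col = "score")
    write_bed(res$regions[[s]], p(sprintf("enriched_regions_%s.bed", s)))
  }
  write_tsv_dot(res$enrichment_summary, p("enrichment_summary.tsv"))
  write_tsv_dot(res$coverage, p("coverage_bins.tsv"))
  write_tsv_dot(res$region_coverage, p("region_coverage.tsv"))
  write_tsv_dot(res$ygs$xy, p("ygs_xy.tsv"))
  write_tsv_dot(res$ygs$zw, p("ygs_zw.tsv"))
  write_tsv_dot(res$ygs$bidir$table, p("ygs_bidirectional.tsv"))
  if (write_kmers) {
    write_kmer_table(res$kmers$M, p("kmers_M.tsv"))
    write_kmer_table(res$kmers$F, p("kmers_F.tsv"))
  }
  write_tsv_dot(res$pca$expression$scores, p("pca_expression.tsv"))
  write_tsv_dot(res$pca$coverage$scores, p("pca_coverage.tsv"))

  truth <- res$genome$truth
  write_json_report(list(
    architecture = truth$architecture,
    sex_specific_scaffolds = truth$sex_specific_scaffolds,
    hemizygous_scaffolds = truth$hemizygous_scaffolds,
    biased_gene_ids = truth$biased_gene_ids
  ), p("sim_truth.json"))
  write_json_report(unclass(res$verdict), p("verdict.json"))
  write_json_report(config_provenance(res$config), p("provenance.json"))
  invisible(out_dir)
}
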