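test_that("architecture determines scaffold truth labels", {
  g_none <- simulate_genome(tiny_config(1, "NONE"))
  expect_length(g_none$truth$sex_specific_scaffolds, 0)
  expect_length(g_none$truth$hemizygous_scaffolds, 0)
  expect_length(g_none$assembly, 2)

  g_xy <- simulate_genome(sim_config(seed = 1, architecture = "XY",
                                     n_autosomes = 4,
                                     scaffold_length_bp = 30000,
                                     n_genes_per_scaffold = 5),
                          sequences = FALSE)
  expect_equal(nrow(g_xy$truth$copy_number), 6)
  expect_equal(g_xy$truth$sex_specific_scaffolds, "scaf_Y")
  expect_equal(g_xy$truth$hemizygous_scaffolds, "scaf_X")

  g_zw <- simulate_genome(tiny_config(1, "ZW"), sequences = FALSE)
  expect_equal(g_zw$truth$sex_specific_scaffolds, "scaf_W")
  expect_equal(g_zw$truth$hemizygous_scaffolds, "scaf_Z")
  cn <- g_zw$truth$copy_number
  expect_equal(cn$copies_M[cn$scaffold == "scaf_W"], 0L)
})

test_that("identical configs give byte-identical FASTA and BED outputs", {
  cfg <- tiny_config(42, "XY")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    g <- simulate_genome(cfg)
    Biostrings::writeXStringSet(g$assembly, file.path(d, "asm.fasta"))
    write_bed(g$genes, file.path(d, "genes.bed"), name_col = "gene_id")
  }
  for (f in c("asm.fasta", "genes.bed")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("gene placement conserves counts, bounds and non-overlap", {
  for (seed in 1:5) {
    g <- simulate_genome(tiny_config(seed, "XY"), sequences = FALSE)
    cfg <- g$config
    expect_equal(nrow(g$genes),
                 nrow(g$truth$copy_number) * cfg$n_genes_per_scaffold)
    expect_true(all(g$genes$end - g$genes$start >= 300))
    by_scaf <- split(g$genes, g$genes$scaffold)
    for (s in names(by_scaf)) {
      gs <- by_scaf[[s]][order(by_scaf[[s]]$start), ]
      L <- g$truth$copy_number$length[g$truth$copy_number$scaffold == s]
      expect_true(all(gs$start >= 0) && all(gs$end <= L))
      if (nrow(gs) > 1)
        expect_true(all(utils::head(gs$end, -1) <= gs$start[-1]))
    }
  }
})

test_that("impossible gene packing raises an explicit error", {
  cfg <- sim_config(seed = 1, architecture = "NONE", n_autosomes = 1,
                    scaffold_length_bp = 2000, n_genes_per_scaffold = 10)
  expect_error(simulate_genome(cfg), "cannot pack")
})

test_that("expression effect sizes match construction", {
  # near-zero dispersion + many replicates: biased-gene count ratio ~ 16,
  # unbiased ~ 1, both within 5%; genes on the female-absent Y are all-zero
  # in females
  cfg <- sim_config(seed = 3, architecture = "XY", n_autosomes = 2,
                    scaffold_length_bp = 30000, n_genes_per_scaffold = 5,
                    frac_biased_male = 0.2, frac_biased_female = 0.2,
                    nb_dispersion = 0, n_male_samples = 1000,
                    n_female_samples = 1000)
  g <- simulate_genome(cfg, sequences = FALSE)
  e <- simulate_expression(g)
  m <- as.matrix(e$counts[, -1])
  rownames(m) <- e$counts$gene_id
  sex <- e$samples$sex
  mu_m <- rowMeans(m[, sex == "M"])
  mu_f <- rowMeans(m[, sex == "F"])

  y_genes <- g$genes$gene_id[g$genes$scaffold == "scaf_Y"]
  expect_true(all(m[y_genes, sex == "F"] == 0))

  bm <- g$truth$biased_gene_ids$M
  bf <- g$truth$biased_gene_ids$F
  expect_gt(length(bm), 0)
  ratio_bm <- mu_m[bm] / mu_f[bm]
  expect_true(all(abs(ratio_bm / cfg$bias_fold - 1) < 0.05))
  ratio_bf <- mu_f[bf] / mu_m[bf]
  expect_true(all(abs(ratio_bf / cfg$bias_fold - 1) < 0.05))
  un <- setdiff(g$genes$gene_id[g$genes$scaffold != "scaf_Y" &
                                  g$genes$scaffold != "scaf_X"],
                c(bm, bf))
  expect_true(all(abs(mu_m[un] / mu_f[un] - 1) < 0.05))
})

test_that("biased genes cluster on the configured scaffolds", {
  cfg <- sim_config(seed = 9, architecture = "NONE", n_autosomes = 6,
                    scaffold_length_bp = 200000, n_genes_per_scaffold = 50,
                    frac_biased_male = 0.1,
                    bias_cluster_scaffolds =
                      list(M = c("scaf_auto_01", "scaf_auto_02"), F = NULL))
  g <- simulate_genome(cfg, sequences = FALSE)
  bm <- g$truth$biased_gene_ids$M
  expect_equal(length(bm), 30)
  on_cluster <- g$genes$scaffold[match(bm, g$genes$gene_id)] %in%
    c("scaf_auto_01", "scaf_auto_02")
  expect_gt(mean(on_cluster), 0.6)  # ~Binomial(30, 0.9)
})

test_that("coverage depth tracks copy number", {
  cfg <- sim_config(seed = 4, architecture = "XY", n_autosomes = 4,
                    scaffold_length_bp = 200000, n_genes_per_scaffold = 5)
  g <- simulate_genome(cfg, sequences = FALSE)
  cov <- simulate_coverage(g, bin_bp = 10000)
  sex <- attr(cov, "sex")
  f_cols <- names(sex)[sex == "F"]
  m_cols <- names(sex)[sex == "M"]
  y <- cov$scaffold == "scaf_Y"
  expect_true(all(as.matrix(cov[y, f_cols]) == 0))
  # autosomal empirical mean within 3 SE of mean_depth (Poisson)
  auto <- as.matrix(cov[grepl("auto", cov$scaffold), c(m_cols, f_cols)])
  se <- sqrt(cfg$mean_depth / 10000) / sqrt(length(auto))
  expect_lt(abs(mean(auto) - cfg$mean_depth), 3 * se)
  # X in males: half the autosomal expectation
  x_m <- as.matrix(cov[cov$scaffold == "scaf_X", m_cols])
  se_x <- sqrt(cfg$mean_depth / 2 / 10000) / sqrt(length(x_m))
  expect_lt(abs(mean(x_m) - cfg$mean_depth / 2), 3 * se_x)
})

test_that("read k-mer tables reflect per-sex genomes", {
  cfg <- sim_config(seed = 5, architecture = "NONE", n_autosomes = 2,
                    scaffold_length_bp = 12000, n_genes_per_scaffold = 3,
                    kmer_error_rate = 0)
  g <- simulate_genome(cfg)
  km <- simulate_read_kmers(g)
  expect_identical(km$M$kmer, km$F$kmer)  # identical genomes
  expect_true(all(km$M$count >= 1))

  cfg_xy <- sim_config(seed = 5, architecture = "XY", n_autosomes = 2,
                       scaffold_length_bp = 12000, n_genes_per_scaffold = 3,
                       kmer_error_rate = 0)
  g_xy <- simulate_genome(cfg_xy)
  km_xy <- simulate_read_kmers(g_xy)
  y_km <- kmer_codes(as.character(g_xy$assembly[["scaf_Y"]]), cfg_xy$kmer_k)
  other <- unlist(lapply(setdiff(names(g_xy$assembly), "scaf_Y"), function(s)
    kmer_codes(as.character(g_xy$assembly[[s]]), cfg_xy$kmer_k)))
  y_only <- setdiff(y_km, other)
  expect_gt(length(y_only), 0)
  expect_false(any(y_only %in% km_xy$F$kmer))
  expect_true(all(y_only %in% km_xy$M$kmer))

  # canonical-form contract on emitted k-mers
  dec <- kmer_decode(utils::head(km_xy$M$kmer, 200), cfg_xy$kmer_k)
  rc <- vapply(dec, oracle_revcomp, character(1), USE.NAMES = FALSE)
  expect_true(all(dec == pmin(dec, rc)))
})
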