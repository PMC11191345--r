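# toy two-sex genomes used across these tests: shared autosome A, shared X,
# male-only Y, built from raw strings so the string-level oracle applies
make_toy <- function(seed = 31, len_a = 6000, len_x = 4000, len_y = 3000,
                     k = 15) {
  set.seed(seed)
  contigs <- list(A = rand_seq(len_a), X = rand_seq(len_x),
                  Y = rand_seq(len_y))
  male_set <- unique(unlist(lapply(contigs, oracle_kmers, k = k)))
  female_set <- unique(unlist(lapply(contigs[c("A", "X")], oracle_kmers,
                                     k = k)))
  reads_M <- make_kmer_table(stats::setNames(rep(5, length(male_set)),
                                             male_set), "reads_M")
  reads_F <- make_kmer_table(stats::setNames(rep(5, length(female_set)),
                                             female_set), "reads_F")
  list(contigs = contigs, reads_M = reads_M, reads_F = reads_F, k = k,
       male_set = male_set, female_set = female_set)
}

test_that("P_VSC_UK follows its set-arithmetic definition", {
  # GATTACA, k=5 -> canonical k-mers GATTA, ATTAC, TGTAA (all single copy);
  # carrier reads hold all three (VSC = {GATTA, ATTAC, TGTAA}), the
  # opposite sex holds one -> 2/3 unmatched
  asm <- count_assembly_kmers(c(c1 = "GATTACA", c2 = "CCCCC"), k = 5)
  carrier <- trusted_kmers(make_kmer_table(
    stats::setNames(rep(3, 3), c("GATTA", "ATTAC", "TGTAA"))), 2)
  opposite <- trusted_kmers(make_kmer_table(
    stats::setNames(3, "TGTAA")), 2)
  rec <- p_vsc_uk("c1", asm, carrier, opposite)
  expect_equal(rec$n_sc, 3)
  expect_equal(rec$n_vsc, 3)
  expect_equal(rec$n_vsc_uk, 2)
  expect_equal(rec$p_vsc_uk, 100 * 2 / 3, tolerance = 1e-12)

  # all contig k-mers shared between sexes -> 0
  rec2 <- p_vsc_uk("c1", asm, carrier, carrier)
  expect_equal(rec2$p_vsc_uk, 0)

  # no validated k-mers -> percentage missing
  rec3 <- p_vsc_uk("c1", asm, numeric(0), opposite)
  expect_true(is.na(rec3$p_vsc_uk))
  expect_error(p_vsc_uk("zzz", asm, carrier, opposite), "unknown contig")
})

test_that("scan matches the naive substring/set oracle exactly", {
  toy <- make_toy()
  asm <- count_assembly_kmers(toy$contigs, toy$k)
  xy <- run_direction(asm, toy$reads_M, toy$reads_F, "XY")
  for (cid in names(toy$contigs)) {
    o <- oracle_ygs(toy$contigs, cid, toy$male_set, toy$female_set, toy$k)
    row <- xy[xy$contig_id == cid, ]
    expect_equal(row$n_sc, o$n_sc)
    expect_equal(row$n_vsc, o$n_vsc)
    expect_equal(row$n_vsc_uk, o$n_vsc_uk)
    expect_equal(row$p_vsc_uk, o$p)
  }
  expect_equal(xy$p_vsc_uk[xy$contig_id == "Y"], 100)
  expect_true(all(xy$p_vsc_uk[xy$contig_id != "Y"] == 0))
  expect_equal(xy$contig_id[xy$flagged], "Y")
})

test_that("scan is strand-invariant and sex-swap symmetric", {
  toy <- make_toy(32)
  asm1 <- count_assembly_kmers(toy$contigs, toy$k)
  flipped <- toy$contigs
  flipped$Y <- oracle_revcomp(flipped$Y)
  asm2 <- count_assembly_kmers(flipped, toy$k)
  xy1 <- run_direction(asm1, toy$reads_M, toy$reads_F, "XY")
  xy2 <- run_direction(asm2, toy$reads_M, toy$reads_F, "XY")
  expect_equal(tibble::as_tibble(xy1), tibble::as_tibble(xy2))

  # swapping the sexes' tables swaps the directions exactly
  zw_swapped <- run_direction(asm1, toy$reads_F, toy$reads_M, "ZW")
  expect_equal(tibble::as_tibble(zw_swapped), dplyr::mutate(
    tibble::as_tibble(xy1), direction = "ZW"))
})

test_that("direction semantics flag Y only in XY, nothing in ZW", {
  toy <- make_toy(33)
  asm <- count_assembly_kmers(toy$contigs, toy$k)
  xy <- run_direction(asm, toy$reads_M, toy$reads_F, "XY")
  zw <- run_direction(asm, toy$reads_M, toy$reads_F, "ZW")
  expect_equal(xy$contig_id[xy$flagged], "Y")
  expect_length(zw$contig_id[zw$flagged], 0)
  # Y has no female-validated k-mers in the ZW direction
  expect_true(is.na(zw$p_vsc_uk[zw$contig_id == "Y"]))

  none <- run_direction(asm, toy$reads_F, toy$reads_F, "XY")
  expect_true(all(none$p_vsc_uk[!is.na(none$p_vsc_uk)] == 0))

  high <- run_direction(asm, toy$reads_M, toy$reads_F, "XY",
                        threshold = 101)
  expect_false(any(high$flagged))
  expect_error(run_direction(asm, toy$reads_M, toy$reads_F, "WX"),
               "direction")
})

test_that("length and denominator guards suppress unstable flags", {
  toy <- make_toy(34, len_y = 3000)
  asm <- count_assembly_kmers(toy$contigs, toy$k)
  xy_long <- run_direction(asm, toy$reads_M, toy$reads_F, "XY",
                           min_len = 5000)
  expect_false(any(xy_long$flagged))  # Y is 3 kb < min_len
  xy_vsc <- run_direction(asm, toy$reads_M, toy$reads_F, "XY",
                          min_vsc = 10^7)
  expect_false(any(xy_vsc$flagged))
})

test_that("enlarging the opposite trusted set never raises P_VSC_UK", {
  toy <- make_toy(35)
  asm <- count_assembly_kmers(toy$contigs, toy$k)
  ct <- trusted_kmers(toy$reads_M, 2)
  ot_small <- trusted_kmers(toy$reads_F, 2)
  set.seed(99)
  extra <- kmer_encode(replicate(200, rand_seq(toy$k)))
  ot_big <- sort(unique(c(ot_small, extra)))
  for (cid in names(toy$contigs)) {
    p1 <- p_vsc_uk(cid, asm, ct, ot_small)$p_vsc_uk
    p2 <- p_vsc_uk(cid, asm, ct, ot_big)$p_vsc_uk
    expect_lte(p2, p1)
  }
})

test_that("bidirectional ~50% pattern raises the anomaly flag", {
  mk <- function(p_xy, p_zw) {
    ids <- sprintf("c%02d", seq_along(p_xy))
    list(
      xy = tibble::tibble(contig_id = ids, contig_len_bp = 10000,
                          n_sc = 100, n_vsc = 100,
                          n_vsc_uk = round(p_xy), p_vsc_uk = p_xy,
                          direction = "XY", flagged = FALSE),
      zw = tibble::tibble(contig_id = ids, contig_len_bp = 10000,
                          n_sc = 100, n_vsc = 100,
                          n_vsc_uk = round(p_zw), p_vsc_uk = p_zw,
                          direction = "ZW", flagged = FALSE)
    )
  }
  quiet <- mk(rep(0, 10), rep(0, 10))
  bd <- bidirectional_stats(quiet$xy, quiet$zw)
  expect_false(bd$anomaly)

  noisy <- mk(c(rep(50, 3), rep(0, 7)), c(rep(50, 3), rep(0, 7)))
  bd2 <- bidirectional_stats(noisy$xy, noisy$zw)
  expect_true(bd2$anomaly)
  expect_equal(bd2$frac_in_band, 0.3)

  expect_error(bidirectional_stats(quiet$xy, noisy$zw[1:5, ]),
               "universes")
})

test_that("sex-shared private k-mers push both directions toward 50%", {
  # emulate individual variability: each sex's read pool gains private
  # k-mers that the assembly also contains -- by building each sex's table
  # from a genome with a private extra contig that the assembly includes
  set.seed(36)
  shared <- rand_seq(2500)
  priv_m <- rand_seq(2500)
  priv_f <- rand_seq(2500)
  k <- 15
  contigs <- list(A = paste0(shared, priv_m, priv_f))
  mset <- unique(c(oracle_kmers(shared, k), oracle_kmers(priv_m, k)))
  fset <- unique(c(oracle_kmers(shared, k), oracle_kmers(priv_f, k)))
  rm_tbl <- make_kmer_table(stats::setNames(rep(5, length(mset)), mset))
  rf_tbl <- make_kmer_table(stats::setNames(rep(5, length(fset)), fset))
  asm <- count_assembly_kmers(contigs, k)
  xy <- run_direction(asm, rm_tbl, rf_tbl, "XY")
  zw <- run_direction(asm, rm_tbl, rf_tbl, "ZW")
  bd <- bidirectional_stats(xy, zw)
  expect_gt(xy$p_vsc_uk, 20)
  expect_gt(zw$p_vsc_uk, 20)
  expect_true(bd$table$in_band)
  expect_true(bd$anomaly)
})
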