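test_that("pixel tiling conserves bins and handles partial bins", {
  g <- tile_genome(genome_build("t", "c1", 2500), 1000)
  expect_equal(g$total_bins, 3)
  g2 <- tile_genome(genome_build("t", "c1", 1000), 1000)
  expect_equal(g2$total_bins, 1)
  g3 <- tile_genome(toy_build(), 1000)
  expect_equal(g3$total_bins, sum(g3$n_bins))
  expect_equal(pos_to_pixel(g3, "chr2", 0), g3$offsets["chr2"] + 1,
               ignore_attr = TRUE)
  expect_equal(pos_to_pixel(g3, "chr1", 49999999), 50000,
               ignore_attr = TRUE)
})

test_that("tracks average into pixels by coverage weight", {
  b <- genome_build("t", "c1", 10000)
  g <- tile_genome(b, 1000)
  const <- write_lines_tmp("c1\t0\t10000\t5", ".bedGraph")
  tr <- read_track(const, g)
  expect_true(all(tr$values == 5))
  halves <- write_lines_tmp(c("c1\t0\t500\t0", "c1\t500\t1000\t10"), ".bedGraph")
  tr2 <- read_track(halves, g)
  expect_equal(tr2$values[1], 5)
  expect_true(all(is.na(tr2$values[-1])))
  empty <- write_lines_tmp(character(0), ".bedGraph")
  expect_warning(tr3 <- read_track(empty, g), "empty")
  expect_true(all(is.na(tr3$values)))
  badval <- write_lines_tmp("c1\t0\t100\tnotanumber", ".bedGraph")
  expect_error(read_track(badval, g), "line 1")
})

test_that("breakpoints concentrated at extreme track values are detected", {
  b <- toy_build()
  g <- tile_genome(b)
  rt <- sim_rt_track(g)
  chrom_of <- rep(names(g$n_bins), g$n_bins)
  pos_of <- (unlist(lapply(g$n_bins, seq_len)) - 0.5) * 1000
  rng <- svpatterns:::local_rng(3)
  low <- which(rt$values <= stats::quantile(rt$values, 0.05))
  pick <- low[rng$sample_int(length(low), 200, replace = TRUE)]
  j <- junctions(paste0("j", seq_along(pick)), "s", chrom_of[pick],
                 pos_of[pick], "left", chrom_of[pick],
                 pmin(pos_of[pick] + 100, 5e7 - 1), "right", build = b)
  r <- property_quantile_test(j, rt, g, n_random = 1e4, seed = 4)
  expect_lt(r$p, 1e-6)
  expect_lt(r$median_quantile, 0.2)
  expect_lt(r$statistic, 0)  # signed low
})

test_that("KS p-values are calibrated under the null", {
  b <- toy_build()
  g <- tile_genome(b)
  rt <- sim_rt_track(g)
  chrom_of <- rep(names(g$n_bins), g$n_bins)
  pos_of <- (unlist(lapply(g$n_bins, seq_len)) - 0.5) * 1000
  ps <- vapply(1:100, function(r) {
    rng <- svpatterns:::local_rng(700 + r)
    pick <- rng$sample_int(g$total_bins, 100, replace = TRUE)
    j <- junctions(paste0("j", 1:100), "s", chrom_of[pick], pos_of[pick],
                   "left", chrom_of[pick], pmin(pos_of[pick] + 100, 5e7 - 1),
                   "right", build = b)
    property_quantile_test(j, rt, g, n_random = 2000, seed = 700 + r)$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.05) / 100
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2] + 0.03)
})

test_that("constant tracks are uninformative and few observations flagged", {
  b <- toy_build(); g <- tile_genome(b)
  ct <- property_track("const", rep(7, g$total_bins), g)
  j <- junctions(paste0("j", 1:50), "s", rep("chr1", 50),
                 seq(1e6, 5e6, length.out = 50), "left", rep("chr1", 50),
                 seq(1e6, 5e6, length.out = 50) + 100, "right", build = b)
  r <- property_quantile_test(j, ct, g, n_random = 1000, seed = 2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  few <- property_quantile_test(j[1:4, ], ct, g, n_random = 100, seed = 2)
  expect_equal(few$flag, "underpowered")
})

test_that("the association suite applies Benjamini-Yekutieli bookkeeping", {
  b <- toy_build(); g <- tile_genome(b)
  rt <- sim_rt_track(g)
  gc <- property_track("gc", rev(rt$values), g)
  rng <- svpatterns:::local_rng(8)
  mk <- function(n) {
    pick <- rng$sample_int(g$total_bins, n, replace = TRUE)
    chrom_of <- rep(names(g$n_bins), g$n_bins)
    pos_of <- (unlist(lapply(g$n_bins, seq_len)) - 0.5) * 1000
    junctions(paste0("j", 1:n), "s", chrom_of[pick], pos_of[pick], "left",
              chrom_of[pick], pmin(pos_of[pick] + 100, 5e7 - 1), "right",
              build = b)
  }
  cj <- list(deletion = mk(60), td = mk(60), inv = mk(60))
  out <- association_suite(cj, list(rt = rt, gc = gc), g, n_random = 2000,
                           seed = 5)
  expect_equal(nrow(out), 6)
  expect_true(all(out$q >= out$p, na.rm = TRUE))
  single <- association_suite(cj[1], list(rt = rt), g, n_random = 2000, seed = 5)
  expect_equal(single$q, single$p)
})

test_that("partner permutation finds planted same-class pairing", {
  b <- toy_build(); g <- tile_genome(b)
  annot <- rep(c("X", "Y"), length.out = g$total_bins)
  chrom_of <- rep(names(g$n_bins), g$n_bins)
  pos_of <- (unlist(lapply(g$n_bins, seq_len)) - 0.5) * 1000
  x_pix <- which(annot == "X")
  y_pix <- which(annot == "Y")
  rng <- svpatterns:::local_rng(12)
  # planted assortative pairing: X joins X, Y joins Y, never X-Y
  px <- matrix(x_pix[rng$sample_int(length(x_pix), 80, replace = TRUE)], ncol = 2)
  py <- matrix(y_pix[rng$sample_int(length(y_pix), 80, replace = TRUE)], ncol = 2)
  pick <- rbind(px, py)
  j <- junctions(paste0("j", 1:80), "s", chrom_of[pick[, 1]], pos_of[pick[, 1]],
                 "left", chrom_of[pick[, 2]], pos_of[pick[, 2]], "right",
                 build = b)
  res <- partner_permutation_enrichment(j, annot, g, n_perm = 200, seed = 3)
  xx <- res[res$pair == "X~X", ]
  expect_gt(xx$fold_change, 1.5)
  expect_gt(xx$z, 3)

  # random pairing: no strong enrichment anywhere
  pick2 <- rng$sample_int(g$total_bins, 160, replace = TRUE)
  j2 <- junctions(paste0("j", 1:80), "s", chrom_of[pick2[1:80]],
                  pos_of[pick2[1:80]], "left", chrom_of[pick2[81:160]],
                  pos_of[pick2[81:160]], "right", build = b)
  res2 <- partner_permutation_enrichment(j2, annot, g, n_perm = 200, seed = 3)
  expect_true(mean(abs(res2$z) < 3, na.rm = TRUE) >= 2 / 3)

  one <- partner_permutation_enrichment(j2[1, ], annot, g, n_perm = 100, seed = 1)
  expect_true(all(one$flag == "degenerate"))
})

test_that("footprint connectivity enrichment uses the same machinery", {
  b <- toy_build()
  # constructed cohort: L-type footprints always connect to L-type and
  # R-type to R-type, never across
  mk_cl <- function(i, side) {
    pa <- 1e6 + i * 2e6
    j <- junctions(paste0("f", i, "_1"), "s", "chr1", pa, side,
                   "chr2", pa + 1e6, side, build = b)
    one_cluster(j, id = paste0("fc", i))
  }
  cls <- c(lapply(1:6, function(i) mk_cl(i, "left")),
           lapply(7:12, function(i) mk_cl(i, "right")))
  res <- footprint_connectivity(cls, n_perm = 300, seed = 2)
  ll <- res[res$pair == "L~L", ]
  expect_gt(ll$fold_change, 1.5)
  expect_gt(ll$z, 3)
})

test_that("microhomology regimes are recovered exactly and under noise", {
  x <- 0:18
  y <- ifelse(x < 2, 4.2 - 0.05 * x, ifelse(x < 10, 4.6 - 0.3 * x, 3.2 - 0.12 * x))
  counts <- 10^y - 1
  f <- fit_microhomology_regimes(counts)
  expect_equal(f$b1, 2)
  expect_equal(f$b2, 10)
  expect_equal(unname(f$slopes["MMEJ"]), -0.3, tolerance = 1e-10)
  expect_equal(unname(f$slopes["SSA"]), -0.12, tolerance = 1e-10)
  expect_lt(f$rss, 1e-18)

  flat <- fit_microhomology_regimes(rep(100, 16))
  expect_equal(flat$b1, 1)
  expect_equal(flat$b2, 8)
  expect_true(all(abs(flat$slopes) < 1e-12))

  hits <- 0
  for (r in 1:60) {
    rng <- svpatterns:::local_rng(400 + r)
    noisy <- rng$rpois(length(counts), pmax(counts, 0.1))
    fn <- fit_microhomology_regimes(noisy)
    if (abs(fn$b1 - 2) <= 1 && abs(fn$b2 - 10) <= 1) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)

  expect_error(fit_microhomology_regimes(rep(1, 5)), "shorter")
})
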