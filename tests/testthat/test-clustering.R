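test_that("segment-bypassing junctions are removed with a logged path", {
  b <- toy_build()
  seg <- cn_segments("s1", rep("chr1", 3), c(0, 1e5, 3e5), c(1e5, 3e5, 5e7),
                     c(2, 1, 2))
  j <- junctions(c("J1", "J2", "J3"), "s1",
                 rep("chr1", 3), c(1e5 + 5, 2e5, 1e5), c("left", "left", "left"),
                 rep("chr1", 3), c(2e5, 3e5 + 8, 3e5), c("right", "right", "right"),
                 build = b)
  res <- remove_segment_bypassing(j, seg, tol_bp = 50)
  expect_equal(res$removed$id, "J3")
  expect_setequal(res$junctions$id, c("J1", "J2"))
  expect_match(res$removed$path, "J1")

  # breakends 5 kb away: no bypass at tol 50
  j2 <- j
  j2$pos1[3] <- 1e5 + 5000
  res2 <- remove_segment_bypassing(j2, seg, tol_bp = 50)
  expect_equal(nrow(res2$removed), 0)
})

test_that("random non-coincident junctions survive bypass filtering", {
  b <- toy_build()
  rng <- svpatterns:::local_rng(99)
  n <- 50
  pos <- round(rng$runif(2 * n, 1e5, 4.9e7))
  j <- junctions(paste0("r", 1:n), "s1", rep("chr1", n), pos[1:n],
                 ifelse(rng$runif(n) < 0.5, "left", "right"),
                 rep("chr1", n), pos[n + 1:n],
                 ifelse(rng$runif(n) < 0.5, "left", "right"), build = b)
  seg <- flat_cn(b)
  res <- remove_segment_bypassing(j, seg)
  # independent brute-force check: no pair of breakends from different
  # junctions coincides within tolerance, so no bypass path can exist
  be <- svpatterns:::breakend_table(j)
  coincident <- FALSE
  for (a in seq_len(nrow(be) - 1)) for (bb in (a + 1):nrow(be)) {
    if (be$junction[a] != be$junction[bb] &&
        be$side[a] == be$side[bb] &&
        abs(be$pos[a] - be$pos[bb]) <= 50) coincident <- TRUE
  }
  expect_false(coincident)
  expect_equal(nrow(res$junctions), n)
})

test_that("fold-back artefact filter requires a nearby CN step", {
  b <- toy_build()
  flat <- flat_cn(b)
  fb <- junctions("f1", "s1", "chr1", 1e6, "left", "chr1", 1000400, "left",
                  build = b)
  expect_equal(nrow(filter_foldback_artefacts(fb, flat)), 0)
  step <- cn_segments("s1", c("chr1", "chr1"), c(0, 1000200), c(1000200, 5e7),
                      c(2, 3))
  expect_equal(nrow(filter_foldback_artefacts(fb, step)), 1)
  wide <- junctions("f2", "s1", "chr1", 1e6, "left", "chr1", 3e6, "left",
                    build = b)
  expect_equal(nrow(filter_foldback_artefacts(wide, flat)), 1)
})

test_that("balanced overlaps and short insertions are tagged", {
  b <- toy_build()
  recip <- junctions(c("t1", "t2"), "s1",
                     c("chr1", "chr1"), c(1e6, 1e6 + 20), c("left", "right"),
                     c("chr2", "chr2"), c(2e6, 2e6 + 15), c("right", "left"),
                     build = b)
  tags <- resolve_balanced_overlaps(recip)$overlap_tag
  expect_equal(tags, c("balanced_overlap", "balanced_overlap"))

  ins <- junctions(c("i1", "i2"), "s1",
                   c("chr1", "chr1"), c(1e6, 1e6 + 1), c("left", "right"),
                   c("chr2", "chr2"), c(5e6, 5e6 + 25), c("right", "left"),
                   build = b)
  # the two chrB breakends flank a 25-bp donor segment
  tags2 <- resolve_balanced_overlaps(ins)$overlap_tag
  expect_true(all(tags2 %in% c("candidate_short_insertion", "balanced_overlap")))

  solo <- junctions("d1", "s1", "chr1", 1e6, "left", "chr1", 2e6, "right",
                    build = b)
  expect_equal(resolve_balanced_overlaps(solo)$overlap_tag, "plain")
})

test_that("merge probability follows the closed form 1 - exp(-lambda d)", {
  m <- cluster_model(20, 1e8, p_merge = 1e-3)
  expect_equal(merge_p(m, 1e3), 1 - exp(-2e-7 * 1e3))
  expect_lt(merge_p(m, 1e3), 1e-3)
  expect_gt(merge_p(m, 1e7), 0.5)
})

test_that("clustering honours the null model and intra-junction exclusion", {
  b <- genome_build("g", "c1", 1e8)
  seg <- cn_segments("s1", "c1", 0, 1e8, 2)
  # 10 junctions; two have nearest breakends 1 kb apart
  pos1 <- c(1e6, 1.2e6 + 1e3, seq(2e7, 9e7, by = 1e7))
  pos2 <- pos1 + 2e5
  pos2[2] <- pos1[2] + 3e5
  j <- junctions(paste0("j", 1:10), "s1", rep("c1", 10), pos1, "left",
                 rep("c1", 10), pos2, "right", build = b)
  j$pos1[2] <- j$pos2[1] + 1e3  # 1 kb gap between junction 1 and 2
  sv <- sv_set("s1", j, seg, b)
  cl <- cluster_junctions(sv, callable_size = 1e8)
  sizes <- sort(vapply(cl, function(x) x$n_junctions, integer(1)))
  expect_equal(sizes, c(rep(1L, 8), 2L))

  # junctions 10 Mb apart never merge
  j2 <- junctions(c("a", "b"), "s1", c("c1", "c1"), c(1e6, 4e7), "left",
                  c("c1", "c1"), c(1.2e6, 4.02e7), "right", build = b)
  sv2 <- sv_set("s1", j2, seg, b)
  expect_equal(length(cluster_junctions(sv2, callable_size = 1e8)), 2)

  # a single 5-Mb deletion is one cluster with two one-breakend footprints
  j3 <- junctions("d", "s1", "c1", 1e6, "left", "c1", 6e6, "right", build = b)
  sv3 <- sv_set("s1", j3, seg, b)
  cl3 <- cluster_junctions(sv3, callable_size = 1e8)
  expect_equal(length(cl3), 1)
  expect_equal(nrow(cl3[[1]]$footprints), 2)
  expect_equal(cl3[[1]]$footprints$n_breakends, c(1, 1))
})

test_that("clustering is invariant under doubling scale", {
  b <- genome_build("g", "c1", 1e8)
  seg <- cn_segments("s1", "c1", 0, 1e8, 2)
  rng <- svpatterns:::local_rng(31)
  pos <- sort(round(rng$runif(40, 1e5, 9e7)))
  j <- junctions(paste0("j", 1:20), "s1", rep("c1", 20), pos[1:20], "left",
                 rep("c1", 20), pos[21:40], "right", build = b)
  sv <- sv_set("s1", j, seg, b)
  cl1 <- cluster_junctions(sv, callable_size = 1e8)
  b2 <- genome_build("g2", "c1", 2e8)
  j2 <- j
  j2$pos1 <- j$pos1 * 2
  j2$pos2 <- j$pos2 * 2
  sv2 <- sv_set("s1", junctions(j2$id, "s1", j2$chrom1, j2$pos1, j2$side1,
                                j2$chrom2, j2$pos2, j2$side2, build = b2),
                cn_segments("s1", "c1", 0, 2e8, 2), b2)
  cl2 <- cluster_junctions(sv2, callable_size = 2e8)
  part <- function(cl) lapply(cl, function(x) sort(x$junctions$id))
  expect_identical(part(cl1), part(cl2))
})

test_that("uniform junctions produce spurious merges at the null rate", {
  n <- 200; G <- 1e8
  b <- genome_build("u", "c1", G)
  seg <- cn_segments("s", "c1", 0, G, 2)
  n_multi <- 0
  n_genomes <- 40
  for (r in seq_len(n_genomes)) {
    rng <- svpatterns:::local_rng(5000 + r)
    pos <- round(rng$runif(2 * n, 1, G - 2))
    j <- junctions(paste0("j", 1:n), "s", rep("c1", n), pos[1:n],
                   ifelse(rng$runif(n) < 0.5, "left", "right"),
                   rep("c1", n), pos[n + 1:n],
                   ifelse(rng$runif(n) < 0.5, "left", "right"), build = b)
    cl <- cluster_junctions(sv_set("s", j, seg, b), callable_size = G)
    n_multi <- n_multi + sum(vapply(cl, function(x) x$n_junctions,
                                    integer(1)) > 1)
  }
  # each genome has ~2n adjacent breakend gaps, each merging with
  # probability ~ p_merge under the null
  expected <- n_genomes * 2 * n * 1e-3
  expect_lt(n_multi, 2 * expected + 3 * sqrt(expected))
  pb <- stats::binom.test(n_multi, n_genomes * 2 * n, p = 1e-3)$p.value
  expect_gt(pb, 0.01)
})

test_that("refinement splits independent simple events and merges overlaps", {
  b <- toy_build()
  # two CN-consistent deletions whose left breakends are close
  seg <- cn_segments("s1", rep("chr1", 5), c(0, 1e6, 1.2e6, 1.25e6, 2.2e6),
                     c(1e6, 1.2e6, 1.25e6, 2.2e6, 5e7), c(2, 1, 2, 1, 2))
  j <- junctions(c("d1", "d2"), "s1", c("chr1", "chr1"), c(1e6, 1.25e6),
                 "left", c("chr1", "chr1"), c(1.2e6, 2.2e6), "right", build = b)
  cl <- one_cluster(j)
  out <- refine_clusters(list(cl), seg, 2)
  expect_equal(length(out), 2)
  expect_true(all(vapply(out, function(x) x$n_junctions, integer(1)) == 1))

  # clusters with overlapping footprints merge: B's breakend falls inside
  # the span of one of A's footprints
  ja <- junctions("a", "s1", "chr1", 1e6, "left", "chr1", 1.02e6, "right",
                  build = b)
  jb <- junctions("b", "s1", "chr1", 1.01e6, "left", "chr1", 8e6, "right",
                  build = b)
  merged <- refine_clusters(list(one_cluster(ja, "cA"), one_cluster(jb, "cB")),
                            flat_cn(b), 2)
  expect_equal(length(merged), 1)
  expect_equal(merged[[1]]$n_junctions, 2)
})
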