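cycle_fixture <- function() {
  b <- toy_build()
  j <- junctions(c("J1", "J2"), "s",
                 c("chr1", "chr2"), c(2010000, 5050000), c("left", "left"),
                 c("chr2", "chr1"), c(5000000, 2000000), c("right", "right"),
                 build = b)
  seg <- cn_segments("s", c(rep("chr1", 3), rep("chr2", 3), "chr3"),
                     c(0, 2000000, 2010000, 0, 5000000, 5050000, 0),
                     c(2000000, 2010000, 5e7, 5000000, 5050000, 5e7, 5e7),
                     c(2, 3, 2, 2, 3, 2, 2))
  list(cluster = one_cluster(j), cn = seg, build = b)
}

bridge_fixture <- function() {
  b <- toy_build()
  j <- junctions(c("J1", "J2"), "s",
                 c("chr1", "chr2"), c(2000000, 5050000), c("left", "left"),
                 c("chr2", "chr1"), c(5000000, 2010000), c("right", "right"),
                 build = b)
  seg <- cn_segments("s", c(rep("chr1", 3), rep("chr2", 3), "chr3"),
                     c(0, 2000000, 2010000, 0, 5000000, 5050000, 0),
                     c(2000000, 2010000, 5e7, 5000000, 5050000, 5e7, 5e7),
                     c(2, 1, 2, 2, 3, 2, 2))
  list(cluster = one_cluster(j), cn = seg, build = b)
}

test_that("segment graphs carry gains and junction attachments", {
  b <- toy_build()
  seg <- cn_segments("s", rep("chr1", 3), c(0, 1e6, 2e6), c(1e6, 2e6, 5e7),
                     c(2, 1, 2))
  j <- junctions("d", "s", "chr1", 1e6, "left", "chr1", 2e6, "right", build = b)
  g <- build_segment_graph(one_cluster(j), seg, 2)
  expect_equal(nrow(g$nodes), 3)
  expect_equal(sum(g$nodes$terminal), 2)
  expect_equal(g$nodes$gain[!g$nodes$terminal], -1)
  expect_equal(nrow(g$edges), 2)

  fx <- cycle_fixture()
  gc <- build_segment_graph(fx$cluster, fx$cn, 2)
  expect_equal(sum(gc$nodes$gain == 1), 2)

  # flat reciprocal inversion: all gains zero
  ji <- junctions(c("a", "b"), "s", c("chr1", "chr1"), c(1e6, 1e6 + 10),
                  c("left", "right"), c("chr1", "chr1"), c(3e6, 3e6 + 10),
                  c("left", "right"), build = b)
  # flat CN has no boundaries near these breakends: boundary imputation warns
  gi <- suppressWarnings(build_segment_graph(one_cluster(ji), flat_cn(b), 2))
  expect_true(all(gi$nodes$gain == 0))
})

test_that("templated-insertion topology is read from the segment graph", {
  fx <- cycle_fixture()
  p <- find_templated_insertion_path(build_segment_graph(fx$cluster, fx$cn, 2))
  expect_equal(p$topology, "cycle")
  expect_equal(nrow(p$templates), 1)
  expect_equal(p$templates$chrom, "chr2")
  expect_equal(p$host_chrom, "chr1")
  expect_true(path_replay_consistent(p, fx$cluster, fx$cn, 2))

  fb <- bridge_fixture()
  pb <- find_templated_insertion_path(build_segment_graph(fb$cluster, fb$cn, 2))
  expect_equal(pb$topology, "bridge")
  expect_true(path_replay_consistent(pb, fb$cluster, fb$cn, 2))
})

test_that("single-junction classes follow orientation plus CN context", {
  b <- toy_build()
  seg <- cn_segments("s", rep("chr1", 3), c(0, 1e6, 2e6), c(1e6, 2e6, 5e7),
                     c(2, 1, 2))
  del <- junctions("d", "s", "chr1", 1e6, "left", "chr1", 2e6, "right", build = b)
  expect_equal(classify_cluster(one_cluster(del), seg, 2)$event_class, "deletion")

  seg_td <- cn_segments("s", rep("chr1", 3), c(0, 1e6, 2e6), c(1e6, 2e6, 5e7),
                        c(2, 3, 2))
  td <- junctions("t", "s", "chr1", 2e6, "left", "chr1", 1e6, "right", build = b)
  expect_equal(classify_cluster(one_cluster(td), seg_td, 2)$event_class,
               "tandem_duplication")

  seg_ub <- cn_segments("s", c("chr1", "chr1", "chr2", "chr2", "chr3"),
                        c(0, 48e6, 0, 5e5, 0), c(48e6, 5e7, 5e5, 5e7, 5e7),
                        c(2, 1, 1, 2, 2))
  ub <- junctions("u", "s", "chr1", 48e6, "left", "chr2", 5e5, "right", build = b)
  expect_equal(classify_cluster(one_cluster(ub), seg_ub, 2)$event_class,
               "unbalanced_translocation")

  seg_fb <- cn_segments("s", c("chr1", "chr1", "chr2", "chr3"),
                        c(0, 1e6, 0, 0), c(1e6, 5e7, 5e7, 5e7), c(3, 2, 2, 2))
  fb <- junctions("f", "s", "chr1", 1e6, "left", "chr1", 1000500, "left",
                  build = b)
  expect_equal(classify_cluster(one_cluster(fb), seg_fb, 2)$event_class,
               "foldback_inversion")
})

test_that("two-junction reciprocal and 2-jump patterns classify by key", {
  b <- toy_build()
  ri <- junctions(c("a", "b"), "s", c("chr1", "chr1"), c(1e6, 1e6 + 10),
                  c("left", "right"), c("chr1", "chr1"), c(3e6, 3e6 + 10),
                  c("left", "right"), build = b)
  expect_equal(classify_cluster(one_cluster(ri), flat_cn(b), 2)$event_class,
               "reciprocal_inversion")

  rt <- junctions(c("a", "b"), "s", c("chr1", "chr1"), c(1e6, 1e6 + 5),
                  c("left", "right"), c("chr2", "chr2"), c(2e6, 2e6 + 5),
                  c("right", "left"), build = b)
  expect_equal(classify_cluster(one_cluster(rt), flat_cn(b), 2)$event_class,
               "reciprocal_translocation")

  p <- 1e6 + (0:3) * 700
  seg <- cn_segments("s", c("chr1", rep("chr1", 3), "chr1", "chr2", "chr3"),
                     c(0, p[1], p[2], p[3], p[4], 0, 0),
                     c(p[1], p[2], p[3], p[4], 5e7, 5e7, 5e7),
                     c(2, 3, 4, 3, 2, 2, 2))
  j <- junctions(c("a", "b"), "s", c("chr1", "chr1"), c(p[3], p[1]),
                 c("left", "right"), c("chr1", "chr1"), c(p[4], p[2]),
                 c("left", "right"), build = b)
  expect_equal(classify_cluster(one_cluster(j), seg, 2)$event_class,
               "local_2jump_dup_trp_dup")
})

test_that("chromoplexy needs three balanced junctions over two chromosomes", {
  b <- toy_build()
  pos <- c(1e6, 2e6, 3e6)
  ch <- c("chr1", "chr2", "chr3")
  j <- junctions(paste0("c", 1:3), "s", ch, pos, "left",
                 ch[c(2, 3, 1)], pos[c(2, 3, 1)], "right", build = b)
  expect_equal(classify_cluster(one_cluster(j), flat_cn(b), 2)$event_class,
               "chromoplexy")
})

test_that("classification is mutually exclusive and robust to missing CN", {
  b <- toy_build()
  j <- junctions("x", "s", "chr1", 1e6, "left", "chr1", 2e6, "right", build = b)
  no_cn <- cn_segments("s", "chr2", 0, 5e7, 2)
  cls <- classify_cluster(one_cluster(j), no_cn, 2)
  expect_equal(cls$event_class, "complex_unclassified")
  expect_equal(cls$details$flag, "missing_cn")
  expect_length(cls$event_class, 1)
})

test_that("classify_all recovers a clean simulated genome exactly", {
  cfg <- sim_config(seed = 77, intensities = c(deletion = 20,
                                               tandem_duplication = 10,
                                               reciprocal_translocation = 2),
                    cn_noise_sd = 0)
  sim <- simulate_genome(cfg)
  res <- classify_all(sim$sv)
  truth <- table(sim$truth$event_class)
  got <- res$class_counts
  for (cl in names(truth))
    expect_equal(unname(got[cl]), unname(as.integer(truth[cl])), label = cl)
  expect_equal(sum(got), sum(truth))
  # breakpoint table separates simple from complex membership
  expect_true(all(res$breakpoints$membership[res$breakpoints$cluster_id %in%
    res$table$cluster_id[res$table$n_junctions == 1]] == "simple"))
})

test_that("a five-template chain is recovered end to end", {
  cfg <- sim_config(seed = 21, n_templates_range = c(5, 5))
  sim <- simulate_genome(cfg, event_list = data.frame(
    class = "templated_insertion_chain", count = 1))
  res <- classify_all(sim$sv)
  expect_equal(unname(res$class_counts["templated_insertion_chain"]), 1L)
  cls <- res$classifications[[which(res$table$event_class ==
                                      "templated_insertion_chain")]]
  expect_equal(nrow(cls$details$path$templates), 5)
})

test_that("empty input yields empty classification", {
  b <- toy_build()
  sv <- sv_set("s", svpatterns:::empty_junctions(), flat_cn(b), b)
  res <- classify_all(sv)
  expect_equal(nrow(res$table), 0)
  expect_equal(sum(res$class_counts), 0)
})
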