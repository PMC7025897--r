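test_that("BEDPE strand conventions map to sides and round trip bit-exactly", {
  lines <- c("chr1\t9999\t10000\tchr1\t59999\t60000\tJ1\t.\t+\t-",
             "chr1\t9999\t10000\tchr1\t59999\t60000\tJ2\t.\t-\t+",
             "chr2\t100\t101\tchr3\t200\t201\tJ3\t.\t+\t+")
  path <- write_lines_tmp(lines, ".bedpe")
  j <- read_bedpe(path, "s1")
  expect_equal(nrow(j), 3)
  expect_equal(orientation_class(j), c("DEL-like", "TD-like", "interchromosomal"))
  expect_equal(j$pos1[1], 9999)
  expect_equal(j$side1[1], "left")
  expect_equal(j$side2[1], "right")
  out <- tempfile(fileext = ".bedpe")
  write_bedpe(j, out)
  j2 <- read_bedpe(out, "s1")
  expect_identical(j[, 1:8], j2[, 1:8])
})

test_that("BEDPE edge cases: empty file, malformed row, foreign chromosome", {
  empty <- write_lines_tmp(character(0), ".bedpe")
  expect_warning(j <- read_bedpe(empty, "s1"), "empty")
  expect_equal(nrow(j), 0)
  bad <- write_lines_tmp("chr1\tabc\t10\tchr1\t5\t6\tJ\t.\t+\t-", ".bedpe")
  expect_error(read_bedpe(bad, "s1"), "line 1")
  foreign <- write_lines_tmp(
    c("chr1\t10\t11\tchr1\t50\t51\tJ1\t.\t+\t-",
      "chrUn\t10\t11\tchr1\t50\t51\tJ2\t.\t+\t-"), ".bedpe")
  expect_message(j <- read_bedpe(foreign, "s1", toy_build()), "dropped")
  expect_equal(j$id, "J1")
})

test_that("VCF BND mate pairs collapse to junctions with 0-based coordinates", {
  path <- write_lines_tmp(mini_bnd_vcf(), ".vcf")
  expect_warning(j <- read_vcf_breakends(path, "s1"), "MATEID")
  expect_equal(nrow(j), 2)
  r <- j[j$chrom2 == "chr2", ]
  expect_equal(r$pos1, 999)
  expect_equal(r$side1, "left")
  expect_equal(r$pos2, 321681)
  expect_equal(r$side2, "right")
  expect_equal(r$homology_len, 3)
  inv <- j[j$chrom2 == "chr3", ]
  expect_equal(inv$side1, "left")
  expect_equal(inv$side2, "left")
})

test_that("inconsistent BND mate coordinates are an error", {
  lines <- mini_bnd_vcf()
  lines[7] <- "chr2\t321699\tbnd_b\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a"
  path <- write_lines_tmp(lines, ".vcf")
  expect_error(suppressWarnings(read_vcf_breakends(path, "s1")), "inconsistent")
})

test_that("copy-number segments validate, trim small overlaps, reject large ones", {
  path <- write_lines_tmp(c("chrom\tstart\tend\ttotal_cn",
                            "chr1\t0\t10000\t2.0",
                            "chr1\t10000\t60000\t1.0"), ".tsv")
  seg <- read_cn_segments(path, "s1")
  expect_equal(nrow(seg), 2)
  trimmed <- cn_segments("s1", c("chr1", "chr1"), c(0, 9990), c(10000, 60000),
                         c(2, 1), tolerance = 50)
  expect_equal(trimmed$start[2], 10000)
  expect_error(cn_segments("s1", c("chr1", "chr1"), c(0, 5000), c(15000, 60000),
                           c(2, 1), tolerance = 50), "overlap")
  expect_error(cn_segments("s1", "chr1", 0, 100, -1), "negative")
})

test_that("background copy number is the coverage-weighted half-integer mode", {
  seg <- cn_segments("s1", rep("chr1", 3), c(0, 1e6, 9e6), c(1e6, 9e6, 10e6),
                     c(4.1, 2.05, 3.2))
  expect_equal(background_cn(seg), 2)
  seg2 <- cn_segments("s1", rep("chr1", 2), c(0, 6e6), c(6e6, 10e6), c(3.9, 2))
  expect_equal(background_cn(seg2), 4)
})

test_that("junctions are stored in canonical breakend order", {
  b <- toy_build()
  j <- junctions(c("a", "b"), "s", c("chr2", "chr1"), c(100, 5000),
                 c("left", "right"), c("chr1", "chr1"), c(900, 100),
                 c("right", "left"), build = b)
  expect_true(all(chrom_rank <- TRUE))
  expect_equal(j$chrom1, c("chr1", "chr1"))
  expect_equal(j$pos1, c(900, 100))
  expect_equal(j$side1, c("right", "left"))
  expect_equal(j$chrom2, c("chr2", "chr1"))
})

test_that("sv_set validates coordinates against the build", {
  b <- toy_build()
  j <- junctions("a", "s", "chr1", 6e7, "left", "chr2", 100, "right", build = b)
  expect_error(sv_set("s", j, flat_cn(b), b), "bounds")
})
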