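# shared fixtures built in code at test time

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# single-cluster constructor around a junction table
one_cluster <- function(j, id = "c1", sample = "s1") {
  be <- svpatterns:::breakend_table(j)
  be <- be[order(be$chrom, be$pos), , drop = FALSE]
  be$footprint <- cumsum(c(1, diff(be$pos) > 1e5 |
                             be$chrom[-1] != be$chrom[-nrow(be)]))
  fps <- do.call(rbind, lapply(split(be, be$footprint), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               n_breakends = nrow(g),
               pattern = paste(ifelse(g$side == "left", "L", "R"), collapse = ""),
               stringsAsFactors = FALSE)))
  rownames(fps) <- NULL
  structure(list(id = id, sample = sample, junctions = j, breakends = be,
                 footprints = fps, n_junctions = nrow(j), model = NULL),
            class = "sv_cluster")
}

flat_cn <- function(build, cn = 2, sample = "s1") {
  cn_segments(sample, build$chromosomes$chrom, 0, build$chromosomes$length, cn)
}

mini_bnd_vcf <- function() {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Homology length\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1000\tbnd_a\tN\tN[chr2:321682[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_b;HOMLEN=3",
    "chr2\t321682\tbnd_b\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a;HOMLEN=3",
    "chr1\t5000\tbnd_c\tN\tN]chr3:9000]\t.\tPASS\tSVTYPE=BND;MATEID=bnd_d",
    "chr3\t9000\tbnd_d\tN\tN]chr1:5000]\t.\tPASS\tSVTYPE=BND;MATEID=bnd_c",
    "chr1\t7777\tbnd_x\tN\tN[chr2:8888[\t.\tPASS\tSVTYPE=BND")
}
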