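# Core genomic data types and readers/writers.
#
# Coordinate conventions used throughout the package:
#   * all internal coordinates are 0-based; intervals are half-open [start, end)
#   * a breakend is a single base position plus a side:
#       side "left"  -- the retained/joined sequence lies at coordinates <= pos
#       side "right" -- the retained/joined sequence lies at coordinates >= pos
#   * BEDPE strand "+" maps to side "left", "-" to side "right"

SIDE_LEVELS <- c("left", "right")

#' Create a genome build
#'
#' A genome build is an ordered table of chromosome names and lengths. The
#' chromosome order defines the canonical ordering used for breakends and
#' junctions.
#'
#' @param name Text label for the build.
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(name, chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be > 0")
  structure(
    list(name = name,
         chromosomes = data.frame(chrom = chrom, length = length,
                                  stringsAsFactors = FALSE)),
    class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build '%s': %d chromosomes, %.1f Mb>\n",
              x$name, nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' Total genome size of a build
#' @param build A `genome_build`.
#' @return Total length in bp.
#' @export
build_size <- function(build) sum(build$chromosomes$length)

chrom_rank <- function(build, chrom) {
  match(chrom, build$chromosomes$chrom)
}

chrom_length <- function(build, chrom) {
  build$chromosomes$length[chrom_rank(build, chrom)]
}

#' Toy three-chromosome build
#'
#' Three 50-Mb chromosomes; the default substrate for the simulator so that
#' full pipelines run in seconds.
#' @return A `genome_build`.
#' @export
toy_build <- function() {
  genome_build("toy3x50Mb", c("chr1", "chr2", "chr3"), rep(5e7, 3))
}

#' hg19 build (autosomes and chromosome X)
#'
#' Chromosome lengths are read from the plain-text fixture shipped with the
#' package (`inst/extdata/hg19_chrom_lengths.tsv`).
#' @return A `genome_build`.
#' @export
hg19_build <- function() {
  path <- system.file("extdata", "hg19_chrom_lengths.tsv", package = "svpatterns")
  read_genome_build(path, name = "hg19")
}

#' Read a genome build from a chromosome-length TSV
#' @param path Two-column TSV (chrom, length), no header.
#' @param name Build label.
#' @return A `genome_build`.
#' @export
read_genome_build <- function(path, name = basename(path)) {
  tab <- data.table::fread(path, header = FALSE, col.names = c("chrom", "length"),
                           data.table = FALSE)
  genome_build(name, tab$chrom, tab$length)
}

empty_junctions <- function() {
  data.frame(id = character(), sample = character(),
             chrom1 = character(), pos1 = numeric(), side1 = character(),
             chrom2 = character(), pos2 = numeric(), side2 = character(),
             inserted_seq = character(), homology_len = numeric(),
             ccf = numeric(), caller_count = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a junction table
#'
#' Junction tables are plain data frames with one row per breakpoint junction
#' (two breakends each). Breakends are stored in canonical order: breakend 1
#' precedes breakend 2 under (chromosome rank, position).
#'
#' @param id,sample Character vectors.
#' @param chrom1,pos1,side1,chrom2,pos2,side2 Breakend fields; sides are
#'   `"left"` or `"right"`.
#' @param inserted_seq Non-templated inserted sequence at the junction.
#' @param homology_len Junction microhomology length in bp.
#' @param ccf Clonal fraction in `[0,1]` (NA if absent).
#' @param caller_count Number of callers supporting the junction (NA if absent).
#' @param build Optional `genome_build` defining chromosome order; when absent,
#'   chromosome order is lexicographic.
#' @return A junction data frame in canonical breakend order.
#' @export
junctions <- function(id, sample, chrom1, pos1, side1, chrom2, pos2, side2,
                      inserted_seq = "", homology_len = 0,
                      ccf = NA_real_, caller_count = NA_real_, build = NULL) {
  n <- length(id)
  j <- data.frame(id = as.character(id), sample = rep_len(as.character(sample), n),
                  chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                  side1 = as.character(side1),
                  chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                  side2 = as.character(side2),
                  inserted_seq = rep_len(as.character(inserted_seq), n),
                  homology_len = rep_len(as.numeric(homology_len), n),
                  ccf = rep_len(as.numeric(ccf), n),
                  caller_count = rep_len(as.numeric(caller_count), n),
                  stringsAsFactors = FALSE)
  if (!all(j$side1 %in% SIDE_LEVELS) || !all(j$side2 %in% SIDE_LEVELS))
    stop("breakend sides must be 'left' or 'right'")
  canonicalize_junctions(j, build)
}

canonicalize_junctions <- function(j, build = NULL) {
  if (nrow(j) == 0) return(j)
  r1 <- if (is.null(build)) rank(j$chrom1, ties.method = "min") else chrom_rank(build, j$chrom1)
  r2 <- if (is.null(build)) rank(j$chrom2, ties.method = "min") else chrom_rank(build, j$chrom2)
  if (is.null(build)) {
    # lexicographic fallback when no build is supplied
    r1 <- match(j$chrom1, sort(unique(c(j$chrom1, j$chrom2))))
    r2 <- match(j$chrom2, sort(unique(c(j$chrom1, j$chrom2))))
  }
  swap <- r2 < r1 | (r1 == r2 & j$pos2 < j$pos1)
  if (any(swap)) {
    tmp <- j[swap, c("chrom1", "pos1", "side1")]
    j[swap, c("chrom1", "pos1", "side1")] <- j[swap, c("chrom2", "pos2", "side2")]
    j[swap, c("chrom2", "pos2", "side2")] <- tmp
  }
  rownames(j) <- NULL
  j
}

#' Orientation class of each junction
#'
#' Derived from the breakend sides in canonical order: `DEL-like` (left at the
#' lower coordinate, right at the higher), `TD-like` (right/left),
#' `head-head` (left/left), `tail-tail` (right/right), or `interchromosomal`.
#'
#' @param j A junction data frame.
#' @return Character vector of orientation classes.
#' @export
orientation_class <- function(j) {
  if (nrow(j) == 0) return(character())
  out <- rep("interchromosomal", nrow(j))
  same <- j$chrom1 == j$chrom2
  out[same & j$side1 == "left" & j$side2 == "right"] <- "DEL-like"
  out[same & j$side1 == "right" & j$side2 == "left"] <- "TD-like"
  out[same & j$side1 == "left" & j$side2 == "left"] <- "head-head"
  out[same & j$side1 == "right" & j$side2 == "right"] <- "tail-tail"
  out
}

is_inverted <- function(j) {
  j$chrom1 == j$chrom2 & j$side1 == j$side2
}

#' Read SV junctions from a BEDPE file
#'
#' Expects the standard 10+ column BEDPE dialect
#' (chrom1,start1,end1,chrom2,start2,end2,name,score,strand1,strand2) with
#' 0-based half-open coordinates. The breakend position is the start of the
#' 1-bp breakend interval; strand `+` maps to side `left`, `-` to `right`.
#'
#' @param path BEDPE file path.
#' @param sample Sample label to attach.
#' @param build Optional `genome_build`; rows on chromosomes absent from the
#'   build are dropped with a message reporting the count.
#' @return A junction data frame.
#' @export
read_bedpe <- function(path, sample, build = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                      colClasses = "character"),
    error = function(e) stop("failed to parse BEDPE '", path, "': ", conditionMessage(e)))
  if (nrow(raw) == 0) {
    warning("empty BEDPE file: ", path)
    return(empty_junctions())
  }
  if (ncol(raw) < 10)
    stop("BEDPE must have >= 10 columns, got ", ncol(raw))
  num_cols <- c(2L, 3L, 5L, 6L)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed BEDPE row at line %d: non-numeric coordinate in column %d",
                   bad[1], cc))
    raw[[cc]] <- v
  }
  strands_ok <- raw[[9]] %in% c("+", "-") & raw[[10]] %in% c("+", "-")
  if (any(!strands_ok))
    stop(sprintf("malformed BEDPE row at line %d: invalid strand", which(!strands_ok)[1]))
  if (!is.null(build)) {
    keep <- raw[[1]] %in% build$chromosomes$chrom & raw[[4]] %in% build$chromosomes$chrom
    if (any(!keep)) {
      message(sum(!keep), " BEDPE row(s) dropped: chromosome absent from build")
      raw <- raw[keep, , drop = FALSE]
    }
    if (nrow(raw) == 0) return(empty_junctions())
  }
  side_of <- function(s) ifelse(s == "+", "left", "right")
  j <- junctions(id = raw[[7]], sample = sample,
                 chrom1 = raw[[1]], pos1 = raw[[2]], side1 = side_of(raw[[9]]),
                 chrom2 = raw[[4]], pos2 = raw[[5]], side2 = side_of(raw[[10]]),
                 build = build)
  if (ncol(raw) >= 11) {
    hl <- suppressWarnings(as.numeric(raw[[11]]))
    j$homology_len <- ifelse(is.na(hl), 0, hl)
  }
  j
}

#' Write junctions to BEDPE
#'
#' Inverse of [read_bedpe()]: breakend coordinates, strands and names round
#' trip bit-exactly.
#'
#' @param j Junction data frame.
#' @param path Output path.
#' @export
write_bedpe <- function(j, path) {
  strand_of <- function(s) ifelse(s == "left", "+", "-")
  out <- data.frame(j$chrom1, format_bp(j$pos1), format_bp(j$pos1 + 1),
                    j$chrom2, format_bp(j$pos2), format_bp(j$pos2 + 1),
                    j$id, ".", strand_of(j$side1), strand_of(j$side2),
                    format_bp(j$homology_len), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

# VCF 4.2 breakend bracket notation -> sides of (this record, mate).
#   t[p[  -> (left,  right)
#   t]p]  -> (left,  left)
#   ]p]t  -> (right, left)
#   [p[t  -> (right, right)
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^(.*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])(.*)$",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  before <- m[2]; br <- m[3]; chrom <- m[4]; pos <- as.numeric(m[5]); after <- m[7]
  if (nzchar(before) && !nzchar(after)) {
    this_side <- "left"
    mate_side <- if (br == "[") "right" else "left"
  } else if (!nzchar(before) && nzchar(after)) {
    this_side <- "right"
    mate_side <- if (br == "]") "left" else "right"
  } else {
    return(NULL)
  }
  list(mate_chrom = chrom, mate_pos = pos, this_side = this_side, mate_side = mate_side)
}

#' Read SV junctions from VCF breakend (BND) records
#'
#' Mate pairs are joined via the `MATEID` INFO key and collapsed to one
#' junction per pair. VCF 1-based positions are converted to the package's
#' 0-based convention; `HOMLEN` and `INSSEQ`/`SVINSSEQ` populate the homology
#' and inserted-sequence fields when present.
#'
#' @param path VCF file path (plain text).
#' @param sample Sample label.
#' @param build Optional `genome_build`.
#' @return A junction data frame.
#' @export
read_vcf_breakends <- function(path, sample, build = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warning("no records in VCF: ", path)
    return(empty_junctions())
  }
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x)) x[2] else NA_character_, character(1))
  }
  svtype <- info_get(fix$INFO, "SVTYPE")
  bnd <- fix[!is.na(svtype) & svtype == "BND", , drop = FALSE]
  if (nrow(bnd) == 0) {
    warning("no BND records in VCF: ", path)
    return(empty_junctions())
  }
  mateid <- info_get(bnd$INFO, "MATEID")
  unpaired <- is.na(mateid) | !(mateid %in% bnd$ID)
  if (any(unpaired)) {
    warning(sum(unpaired), " BND record(s) without a resolvable MATEID dropped")
    bnd <- bnd[!unpaired, , drop = FALSE]
    mateid <- mateid[!unpaired]
  }
  if (nrow(bnd) == 0) return(empty_junctions())
  rownames(bnd) <- bnd$ID
  done <- character(0)
  rows <- list()
  for (i in seq_len(nrow(bnd))) {
    id <- bnd$ID[i]
    mid <- mateid[i]
    key <- paste(sort(c(id, mid)), collapse = "|")
    if (key %in% done) next
    done <- c(done, key)
    alt <- parse_bnd_alt(bnd$ALT[i])
    if (is.null(alt)) stop("unparseable BND ALT for record ", id, ": ", bnd$ALT[i])
    mate <- bnd[mid, , drop = FALSE]
    # cross-check against the mate's own coordinates
    if (mate$CHROM != alt$mate_chrom || as.numeric(mate$POS) != alt$mate_pos)
      stop("inconsistent mate coordinates for BND pair ", key)
    malt <- parse_bnd_alt(mate$ALT)
    if (is.null(malt) || malt$this_side != alt$mate_side || malt$mate_side != alt$this_side)
      stop("inconsistent mate orientation for BND pair ", key)
    info <- bnd$INFO[i]
    hl <- suppressWarnings(as.numeric(info_get(info, "HOMLEN")))
    ins <- info_get(info, "INSSEQ")
    if (is.na(ins)) ins <- info_get(info, "SVINSSEQ")
    rows[[length(rows) + 1L]] <- data.frame(
      id = key, chrom1 = bnd$CHROM[i], pos1 = as.numeric(bnd$POS[i]) - 1,
      side1 = alt$this_side,
      chrom2 = alt$mate_chrom, pos2 = alt$mate_pos - 1, side2 = alt$mate_side,
      homology_len = ifelse(is.na(hl), 0, hl),
      inserted_seq = ifelse(is.na(ins), "", ins),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  junctions(id = tab$id, sample = sample,
            chrom1 = tab$chrom1, pos1 = tab$pos1, side1 = tab$side1,
            chrom2 = tab$chrom2, pos2 = tab$pos2, side2 = tab$side2,
            inserted_seq = tab$inserted_seq, homology_len = tab$homology_len,
            build = build)
}

#' Read total copy-number segments from a TSV
#'
#' Four columns (chrom, start, end, total_cn), 0-based half-open. Segments are
#' sorted and validated; per-chromosome overlaps up to `tolerance` bp are
#' trimmed (the later segment's start is moved), larger overlaps are an error.
#'
#' @param path TSV path (a header line is tolerated).
#' @param sample Sample label.
#' @param tolerance Maximum bp of overlap to trim silently (default 50).
#' @return A data frame of segments (sample, chrom, start, end, total_cn).
#' @export
read_cn_segments <- function(path, sample, tolerance = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(tab) < 4) stop("copy-number TSV must have 4 columns")
  tab <- tab[, 1:4]
  names(tab) <- c("chrom", "start", "end", "total_cn")
  cn_segments(sample, tab$chrom, tab$start, tab$end, tab$total_cn,
              tolerance = tolerance)
}

#' Construct and validate a copy-number segment table
#' @param sample,chrom,start,end,total_cn Segment fields (0-based half-open).
#' @param tolerance Overlap-trim tolerance in bp.
#' @return A validated, sorted segment data frame.
#' @export
cn_segments <- function(sample, chrom, start, end, total_cn, tolerance = 50) {
  seg <- data.frame(sample = rep_len(as.character(sample), length(chrom)),
                    chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    total_cn = as.numeric(total_cn), stringsAsFactors = FALSE)
  if (any(is.na(seg$total_cn)) || any(seg$total_cn < 0))
    stop("negative or missing total_cn in copy-number segments")
  if (any(seg$end <= seg$start)) stop("copy-number segment with end <= start")
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  for (ch in unique(seg$chrom)) {
    idx <- which(seg$chrom == ch)
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      ov <- seg$end[i] - seg$start[j]
      if (ov > tolerance)
        stop(sprintf("copy-number segments overlap by %.0f bp on %s (tolerance %d)",
                     ov, ch, tolerance))
      if (ov > 0) seg$start[j] <- seg$end[i]
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Total copy number at genomic positions
#' @param seg Segment data frame.
#' @param chrom,pos Vectors of positions.
#' @return Numeric CN values (NA where uncovered).
#' @export
cn_at <- function(seg, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    hit <- seg$chrom == chrom[i] & seg$start <= pos[i] & seg$end > pos[i]
    if (!any(hit)) NA_real_ else seg$total_cn[which(hit)[1]]
  }, numeric(1))
}

#' Modal background copy number of a sample
#'
#' Coverage-weighted mode of total copy number, rounded to the nearest 0.5.
#' Rearrangement patterns are read relative to this chromosome background.
#'
#' @param seg Segment data frame.
#' @return Background CN (single number).
#' @export
background_cn <- function(seg) {
  if (nrow(seg) == 0) return(2)
  lev <- round(seg$total_cn * 2) / 2
  w <- tapply(seg$end - seg$start, lev, sum)
  as.numeric(names(w)[which.max(w)])
}

#' Bundle one sample's junctions and copy-number segments
#'
#' @param sample Sample label.
#' @param junctions Junction data frame.
#' @param segments Copy-number segment data frame.
#' @param build A `genome_build`.
#' @return An `sv_set` object.
#' @export
sv_set <- function(sample, junctions, segments, build) {
  stopifnot(inherits(build, "genome_build"))
  for (cc in c("chrom1", "chrom2")) {
    bad <- !(junctions[[cc]] %in% build$chromosomes$chrom)
    if (any(bad)) stop("junction chromosome absent from build: ",
                       junctions[[cc]][bad][1])
  }
  pos_ok <- junctions$pos1 >= 0 & junctions$pos1 < chrom_length(build, junctions$chrom1) &
    junctions$pos2 >= 0 & junctions$pos2 < chrom_length(build, junctions$chrom2)
  if (any(!pos_ok)) stop("junction breakend outside chromosome bounds")
  bg <- background_cn(segments)
  if (bg <= 0) bg <- 2
  structure(list(sample = sample,
                 junctions = canonicalize_junctions(junctions, build),
                 segments = segments, build = build, background_cn = bg),
            class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("<sv_set '%s': %d junctions, %d CN segments, background CN %.1f>\n",
              x$sample, nrow(x$junctions), nrow(x$segments), x$background_cn))
  invisible(x)
}
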