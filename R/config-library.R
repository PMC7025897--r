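# In silico library of genomic configurations reachable by sequential simple
# rearrangements, and canonical pattern keys for matching observed clusters
# against it.
#
# Enumeration runs on an abstract alphabet: each reference chromosome is a
# string of atomic segments and every cut falls at an interior segment
# boundary.  Two cut placements are equivalent precisely when they induce the
# same segment partition, which is what keeps depth-3 enumeration tractable.
# Derivative chromosomes are signed integer vectors of atom ids (negative =
# reverse orientation).  A derivative is converted back to the observable
# evidence -- breakpoint junctions plus per-atom copy number -- and that
# evidence is serialized into a PatternKey that is invariant under chromosome
# relabeling, global mirror, and junction input order.

#' Abstract reference genome for configuration enumeration
#'
#' @param atoms Integer vector: number of atomic segments per chromosome
#'   (default `c(3, 2)`, the shipped enumeration substrate).
#' @param chrom_names Optional chromosome labels.
#' @return An `enum_ref` object.
#' @export
enum_ref <- function(atoms = c(3, 2), chrom_names = NULL) {
  if (is.null(chrom_names)) chrom_names <- paste0("ch", seq_along(atoms))
  n <- sum(atoms)
  atom_chrom <- rep(seq_along(atoms), atoms)
  atom_idx <- unlist(lapply(atoms, seq_len))
  structure(list(atoms = atoms, chrom_names = chrom_names,
                 n_atoms = n, atom_chrom = atom_chrom, atom_idx = atom_idx),
            class = "enum_ref")
}

#' Identity derivative genome for a reference
#' @param ref An `enum_ref`.
#' @return A derivative genome: list of signed atom-id vectors.
#' @export
initial_derivative <- function(ref) {
  offs <- c(0, cumsum(ref$atoms))
  lapply(seq_along(ref$atoms), function(c) seq.int(offs[c] + 1, offs[c + 1]))
}

#' Apply a simple rearrangement operation to a derivative genome
#'
#' Operations: `DEL(c,i,j)` removes derivative segments i+1..j of chromosome c
#' (cuts at interior boundaries i < j); `TD(c,i,j)` duplicates them in place;
#' `INV(c,i,j)` reverses them flipping orientation; `TRA_bal(c1,i,c2,k)`
#' exchanges the tails of two chromosomes; `TRA_unbal(c1,i,c2,k)` joins the
#' head of c1 to the tail of c2, discarding the rest; `GAIN(c)` / `LOSS(c)`
#' duplicate or remove a whole chromosome.
#'
#' @param dg Derivative genome.
#' @param op A list with `type` and the indices above.
#' @return The rearranged derivative genome.
#' @export
apply_operation <- function(dg, op) {
  type <- op$type
  if (type %in% c("DEL", "TD", "INV")) {
    ch <- dg[[op$c]]
    L <- length(ch)
    if (!(op$i >= 0 && op$j <= L && op$i < op$j)) stop("cut indices out of range")
    seg <- ch[(op$i + 1):op$j]
    dg[[op$c]] <- switch(type,
      DEL = c(ch[seq_len(op$i)], if (op$j < L) ch[(op$j + 1):L]),
      TD  = c(ch[seq_len(op$j)], seg, if (op$j < L) ch[(op$j + 1):L]),
      INV = c(ch[seq_len(op$i)], -rev(seg), if (op$j < L) ch[(op$j + 1):L]))
  } else if (type == "TRA_bal") {
    a <- dg[[op$c1]]; b <- dg[[op$c2]]
    if (op$i > length(a) || op$k > length(b)) stop("cut indices out of range")
    dg[[op$c1]] <- c(a[seq_len(op$i)], b[-seq_len(op$k)])
    dg[[op$c2]] <- c(b[seq_len(op$k)], a[-seq_len(op$i)])
  } else if (type == "TRA_unbal") {
    a <- dg[[op$c1]]; b <- dg[[op$c2]]
    if (op$i > length(a) || op$k > length(b)) stop("cut indices out of range")
    dg[[op$c1]] <- c(a[seq_len(op$i)], b[-seq_len(op$k)])
    dg[[op$c2]] <- NULL
  } else if (type == "GAIN") {
    dg[[length(dg) + 1L]] <- dg[[op$c]]
  } else if (type == "LOSS") {
    if (length(dg) < 2) stop("cannot lose the last chromosome")
    dg[[op$c]] <- NULL
  } else stop("unknown operation type: ", type)
  dg[lengths(dg) > 0]
}

format_op <- function(op) {
  switch(op$type,
    DEL = , TD = , INV = sprintf("%s(%d,%d,%d)", op$type, op$c, op$i, op$j),
    TRA_bal = , TRA_unbal = sprintf("%s(%d,%d,%d,%d)", op$type, op$c1, op$i, op$c2, op$k),
    GAIN = , LOSS = sprintf("%s(%d)", op$type, op$c))
}

# every available operation on the current derivative (interior cuts only)
list_operations <- function(dg) {
  ops <- list()
  nc <- length(dg)
  for (c in seq_len(nc)) {
    L <- length(dg[[c]])
    if (L >= 3) {
      for (i in 1:(L - 2)) for (j in (i + 1):(L - 1)) {
        for (ty in c("DEL", "TD", "INV"))
          ops[[length(ops) + 1L]] <- list(type = ty, c = c, i = i, j = j)
      }
    }
  }
  if (nc >= 2) {
    for (c1 in 1:(nc - 1)) for (c2 in (c1 + 1):nc) {
      L1 <- length(dg[[c1]]); L2 <- length(dg[[c2]])
      if (L1 >= 2 && L2 >= 2) {
        for (i in 1:(L1 - 1)) for (k in 1:(L2 - 1))
          ops[[length(ops) + 1L]] <- list(type = "TRA_bal", c1 = c1, i = i, c2 = c2, k = k)
      }
    }
    for (c1 in seq_len(nc)) for (c2 in seq_len(nc)) {
      if (c1 == c2) next
      L1 <- length(dg[[c1]]); L2 <- length(dg[[c2]])
      if (L1 >= 2 && L2 >= 2) {
        for (i in 1:(L1 - 1)) for (k in 1:(L2 - 1))
          ops[[length(ops) + 1L]] <- list(type = "TRA_unbal", c1 = c1, i = i, c2 = c2, k = k)
      }
    }
  }
  for (c in seq_len(nc)) {
    ops[[length(ops) + 1L]] <- list(type = "GAIN", c = c)
    if (nc >= 2) ops[[length(ops) + 1L]] <- list(type = "LOSS", c = c)
  }
  ops
}

# Observable evidence of a derivative genome: junctions between reference
# boundaries plus per-atom copy number.  Boundary b on a chromosome lies
# between its atoms b and b+1 (b ranges 0..n_atoms).
derivative_evidence <- function(dg, ref) {
  cn <- tabulate(abs(unlist(dg)), nbins = ref$n_atoms)
  jn <- list()
  for (ch in dg) {
    if (length(ch) < 2) next
    for (k in seq_len(length(ch) - 1)) {
      u <- ch[k]; v <- ch[k + 1]
      au <- abs(u); av <- abs(v)
      ref_adj <- (u > 0 && v > 0 && ref$atom_chrom[au] == ref$atom_chrom[av] &&
                    ref$atom_idx[av] == ref$atom_idx[au] + 1) ||
                 (u < 0 && v < 0 && ref$atom_chrom[au] == ref$atom_chrom[av] &&
                    ref$atom_idx[au] == ref$atom_idx[av] + 1)
      if (ref_adj) next
      b1 <- if (u > 0) list(chrom = ref$atom_chrom[au], b = ref$atom_idx[au], side = "L")
            else       list(chrom = ref$atom_chrom[au], b = ref$atom_idx[au] - 1L, side = "R")
      b2 <- if (v > 0) list(chrom = ref$atom_chrom[av], b = ref$atom_idx[av] - 1L, side = "R")
            else       list(chrom = ref$atom_chrom[av], b = ref$atom_idx[av], side = "L")
      jn[[length(jn) + 1L]] <- list(b1 = b1, b2 = b2)
    }
  }
  # dedup junctions (unordered breakend pairs); observation cannot see multiplicity
  if (length(jn)) {
    keys <- vapply(jn, function(x) {
      a <- sprintf("%d:%d:%s", x$b1$chrom, x$b1$b, x$b1$side)
      b <- sprintf("%d:%d:%s", x$b2$chrom, x$b2$b, x$b2$side)
      paste(sort(c(a, b)), collapse = "~")
    }, character(1))
    jn <- jn[!duplicated(keys)]
  }
  list(cn = cn, junctions = jn)
}

cap_level <- function(x) pmin(pmax(x, -3L), 3L)

compress_runs <- function(v) {
  if (length(v) == 0) return("")
  v <- cap_level(as.integer(v))
  paste(v[c(TRUE, diff(v) != 0)], collapse = ",")
}

# Pattern intermediate shared by enumerated derivatives and observed clusters:
#   groups: list per involved chromosome of
#     loci  -- ordinal position of each breakend (ties = same locus)
#     sides -- "L"/"R" per breakend
#     ivls  -- k+1 compressed CN-run strings (flank, between-locus..., flank)
#   junctions: data.frame(g1, b1, g2, b2) referencing group / breakend ordinal
derivative_pattern <- function(dg, ref) {
  ev <- derivative_evidence(dg, ref)
  if (length(ev$junctions) == 0)
    return(list(groups = list(), junctions = data.frame()))
  bes <- do.call(rbind, lapply(seq_along(ev$junctions), function(i) {
    x <- ev$junctions[[i]]
    data.frame(jid = i, end = 1:2,
               chrom = c(x$b1$chrom, x$b2$chrom),
               b = c(x$b1$b, x$b2$b),
               side = c(x$b1$side, x$b2$side), stringsAsFactors = FALSE)
  }))
  chroms <- sort(unique(bes$chrom))
  groups <- list()
  bes$group <- NA_integer_; bes$ord <- NA_integer_
  for (gi in seq_along(chroms)) {
    cc <- chroms[gi]
    sub_i <- which(bes$chrom == cc)
    sub <- bes[sub_i, , drop = FALSE]
    o <- order(sub$b, sub$side)  # ties: L before R
    sub <- sub[o, , drop = FALSE]
    n_at <- ref$atoms[cc]
    rel <- ev$cn[ref$atom_chrom == cc] - 1L
    # intervals: flank before first locus, between distinct loci, flank after
    k <- nrow(sub)
    ivls <- character(k + 1)
    ivls[1] <- if (sub$b[1] >= 1) compress_runs(rel[sub$b[1]]) else ""
    for (m in seq_len(k - 1)) {
      lo <- sub$b[m]; hi <- sub$b[m + 1]
      ivls[m + 1] <- if (hi > lo) compress_runs(rel[(lo + 1):hi]) else ""
    }
    ivls[k + 1] <- if (sub$b[k] < n_at) compress_runs(rel[sub$b[k] + 1]) else ""
    groups[[gi]] <- list(loci = match(sub$b, unique(sub$b)),
                         sides = sub$side, ivls = ivls)
    bes$group[sub_i[o]] <- gi
    bes$ord[sub_i[o]] <- seq_len(k)
  }
  jt <- do.call(rbind, lapply(unique(bes$jid), function(id) {
    p <- bes[bes$jid == id, ]
    data.frame(g1 = p$group[1], b1 = p$ord[1], g2 = p$group[2], b2 = p$ord[2])
  }))
  list(groups = groups, junctions = jt)
}

serialize_pattern <- function(groups, junctions, perm, mirror) {
  # apply permutation of groups and optional global mirror, then serialize
  k <- length(groups)
  gmap <- integer(k); gmap[perm] <- seq_len(k)
  parts <- character(k)
  bmap <- vector("list", k)  # breakend ordinal remap per original group
  for (new_g in seq_len(k)) {
    g <- groups[[perm[new_g]]]
    n <- length(g$sides)
    if (mirror) {
      sides <- rev(ifelse(g$sides == "L", "R", "L"))
      ivls <- rev(vapply(g$ivls, function(s) {
        if (s == "") "" else paste(rev(strsplit(s, ",")[[1]]), collapse = ",")
      }, character(1)))
      bmap[[perm[new_g]]] <- rev(seq_len(n))
    } else {
      sides <- g$sides
      ivls <- g$ivls
      bmap[[perm[new_g]]] <- seq_len(n)
    }
    parts[new_g] <- paste0("S", paste(sides, collapse = ""),
                           "|I", paste(ivls, collapse = ";"))
  }
  jp <- character(nrow(junctions))
  for (r in seq_len(nrow(junctions))) {
    a <- sprintf("%d.%d", gmap[junctions$g1[r]], bmap[[junctions$g1[r]]][junctions$b1[r]])
    b <- sprintf("%d.%d", gmap[junctions$g2[r]], bmap[[junctions$g2[r]]][junctions$b2[r]])
    jp[r] <- paste(sort(c(a, b)), collapse = "-")
  }
  paste0(paste(parts, collapse = "/"), "#", paste(sort(jp), collapse = ","))
}

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms_of(n - 1L)) out[[length(out) + 1L]] <- c(i, p + (p >= i))
  }
  out
}

#' Canonical key of a rearrangement pattern
#'
#' Minimizes the serialized form over chromosome-group permutations and the
#' global mirror image (coordinate reversal flips all sides and reverses
#' orders), so that relabeled, mirrored, or reordered inputs share one key.
#'
#' @param pattern A pattern as produced internally from a derivative genome or
#'   an observed cluster.
#' @return A single character key.
#' @export
canonical_pattern_key <- function(pattern) {
  if (length(pattern$groups) == 0) return("(identity)")
  k <- length(pattern$groups)
  perms <- if (k <= 6) perms_of(k) else {
    # beyond 6 involved chromosomes: sort groups by their own serialization
    ord <- order(vapply(pattern$groups, function(g)
      paste0(paste(g$sides, collapse = ""), "|", paste(g$ivls, collapse = ";")),
      character(1)))
    list(ord)
  }
  best <- NULL
  for (mirror in c(FALSE, TRUE)) {
    for (p in perms) {
      s <- serialize_pattern(pattern$groups, pattern$junctions, p, mirror)
      if (is.null(best) || s < best) best <- s
    }
  }
  best
}

#' Pattern key of an abstract derivative genome
#' @param dg Derivative genome.
#' @param ref The `enum_ref` it was built on.
#' @return Canonical pattern key.
#' @export
pattern_key_of <- function(dg, ref) {
  canonical_pattern_key(derivative_pattern(dg, ref))
}

#' Enumerate the configuration library
#'
#' Breadth-first closure of [apply_operation()] over all distinct interior cut
#' placements, starting from the identity derivative of `ref`. Resulting
#' derivatives are deduplicated by exact genome state for expansion and by
#' canonical pattern key for storage; each key records representative
#' operation sequences of minimal length only.
#'
#' @param ref An `enum_ref` (default `enum_ref()`).
#' @param depth Maximum number of operations (default 3; more than 5 is
#'   refused unless `override = TRUE` -- the state space grows combinatorially).
#' @param override Allow depth > 5.
#' @param max_seqs Cap on stored sequences per key (default 64).
#' @return A `config_library`: list with `depth`, `ref`, and `entries`
#'   (named list key -> list(min_ops, sequences)).
#' @export
enumerate_library <- function(ref = enum_ref(), depth = 3, override = FALSE,
                              max_seqs = 64) {
  if (depth > 5 && !override)
    stop("enumeration depth > 5 refused (combinatorial guard); set override = TRUE")
  entries <- list()
  add_entry <- function(key, d, seq_str) {
    e <- entries[[key]]
    if (is.null(e)) {
      entries[[key]] <<- list(min_ops = d, sequences = list(seq_str))
    } else if (d == e$min_ops && length(e$sequences) < max_seqs &&
               !(seq_str %in% unlist(e$sequences))) {
      e$sequences[[length(e$sequences) + 1L]] <- seq_str
      entries[[key]] <<- e
    }
  }
  state_key <- function(dg) paste(vapply(dg, paste, character(1), collapse = ","),
                                  collapse = "|")
  init <- initial_derivative(ref)
  add_entry(pattern_key_of(init, ref), 0L, "")
  seen <- new.env(parent = emptyenv())
  assign(state_key(init), TRUE, envir = seen)
  frontier <- list(list(dg = init, seq = character(0)))
  d <- 0L
  while (d < depth && length(frontier)) {
    d <- d + 1L
    nxt <- list()
    for (node in frontier) {
      for (op in list_operations(node$dg)) {
        dg2 <- apply_operation(node$dg, op)
        sq <- c(node$seq, format_op(op))
        add_entry(pattern_key_of(dg2, ref), d, paste(sq, collapse = ";"))
        sk <- state_key(dg2)
        if (!exists(sk, envir = seen, inherits = FALSE)) {
          assign(sk, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(dg = dg2, seq = sq)
        }
      }
    }
    frontier <- nxt
  }
  structure(list(depth = depth, ref = ref, entries = entries,
                 version = "svpatterns-library-1"),
            class = "config_library")
}

#' @export
print.config_library <- function(x, ...) {
  cat(sprintf("<config_library: depth %d, %d pattern keys>\n",
              x$depth, length(x$entries)))
  invisible(x)
}

#' Naive sequence enumerator (independent oracle)
#'
#' Recursively applies every operation sequence up to `depth` with no state
#' deduplication or memoization, collecting the set of pattern keys and their
#' minimal generating lengths. Exponential in `depth`; used to cross-check
#' [enumerate_library()] at small depth.
#'
#' @param ref An `enum_ref`.
#' @param depth Maximum sequence length.
#' @return Named integer vector: key -> minimal length.
#' @export
naive_enumerate <- function(ref = enum_ref(), depth = 2) {
  acc <- new.env(parent = emptyenv())
  note <- function(key, d) {
    cur <- if (exists(key, envir = acc, inherits = FALSE)) get(key, envir = acc) else Inf
    if (d < cur) assign(key, d, envir = acc)
  }
  recurse <- function(dg, d) {
    note(pattern_key_of(dg, ref), d)
    if (d == depth) return()
    for (op in list_operations(dg)) recurse(apply_operation(dg, op), d + 1L)
  }
  recurse(initial_derivative(ref), 0L)
  keys <- ls(acc)
  stats::setNames(vapply(keys, function(k) as.integer(get(k, envir = acc)),
                         integer(1)), keys)
}

#' Serialize a configuration library to JSON
#' @param library A `config_library`.
#' @param path Output path.
#' @export
write_library <- function(library, path) {
  out <- list(version = library$version, depth = library$depth,
              atoms = library$ref$atoms,
              entries = lapply(library$entries, function(e)
                list(min_ops = e$min_ops, sequences = unlist(e$sequences))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a configuration library from JSON
#' @param path JSON path written by [write_library()].
#' @return A `config_library`.
#' @export
read_library <- function(path) {
  raw <- jsonlite::read_json(path)
  entries <- lapply(raw$entries, function(e)
    list(min_ops = as.integer(e$min_ops),
         sequences = lapply(e$sequences, as.character)))
  structure(list(depth = as.integer(raw$depth),
                 ref = enum_ref(unlist(raw$atoms)),
                 entries = entries, version = raw$version),
            class = "config_library")
}

# ---- observed-cluster patterns ------------------------------------------

cn_runs_between <- function(cn, chrom, lo, hi, bg) {
  if (hi <= lo) return("")
  segs <- cn[cn$chrom == chrom & cn$end > lo & cn$start < hi, , drop = FALSE]
  if (nrow(segs) == 0) return("")
  segs <- segs[order(segs$start), ]
  compress_runs(round(segs$total_cn - bg))
}

#' Pattern of an observed cluster
#'
#' Builds the same pattern intermediate as the enumerator from a cluster's
#' junctions and the sample's copy-number context: breakend loci (positions
#' within `locus_tol` bp collapse to one locus), side strings, and relative
#' copy-number run levels for each inter-locus interval and flank.
#'
#' @param cluster An `sv_cluster`.
#' @param cn Copy-number segments.
#' @param bg Background copy number.
#' @param locus_tol Breakends closer than this share a locus (default 100).
#' @return A pattern list (groups + junction wiring).
#' @export
cluster_pattern <- function(cluster, cn, bg, locus_tol = 100) {
  j <- cluster$junctions
  be <- breakend_table(j)
  cov <- cn_at(cn, be$chrom, pmax(be$pos - 1, 0))
  cov2 <- cn_at(cn, be$chrom, be$pos)
  if (any(is.na(cov) & is.na(cov2))) {
    bad <- which(is.na(cov) & is.na(cov2))[1]
    stop(sprintf("breakend %s:%.0f lacks copy-number coverage",
                 be$chrom[bad], be$pos[bad]))
  }
  chroms <- sort(unique(be$chrom))
  groups <- list()
  be$group <- NA_integer_; be$ord <- NA_integer_
  for (gi in seq_along(chroms)) {
    cc <- chroms[gi]
    sub_i <- which(be$chrom == cc)
    sub <- be[sub_i, , drop = FALSE]
    o <- order(sub$pos, sub$side)
    sub <- sub[o, , drop = FALSE]
    # collapse nearby positions into loci
    loci <- integer(nrow(sub)); loci[1] <- 1L
    if (nrow(sub) > 1) for (m in 2:nrow(sub))
      loci[m] <- if (sub$pos[m] - sub$pos[m - 1] <= locus_tol) loci[m - 1] else loci[m - 1] + 1L
    # within a locus order by side (L before R) to mirror the enumerator
    oo <- order(loci, sub$side)
    sub <- sub[oo, , drop = FALSE]; loci <- loci[oo]
    k <- nrow(sub)
    locus_pos <- tapply(sub$pos, loci, stats::median)
    ivls <- character(k + 1)
    first_pos <- locus_pos[as.character(loci[1])]
    last_pos <- locus_pos[as.character(loci[k])]
    lv <- cn_at(cn, cc, max(first_pos - 1, 0))
    ivls[1] <- if (is.na(lv)) "" else compress_runs(round(lv - bg))
    for (m in seq_len(k - 1)) {
      if (loci[m + 1] == loci[m]) { ivls[m + 1] <- ""; next }
      ivls[m + 1] <- cn_runs_between(cn, cc, locus_pos[as.character(loci[m])],
                                     locus_pos[as.character(loci[m + 1])], bg)
    }
    rv <- cn_at(cn, cc, last_pos + 1)
    ivls[k + 1] <- if (is.na(rv)) "" else compress_runs(round(rv - bg))
    groups[[gi]] <- list(loci = loci, sides = ifelse(sub$side == "left", "L", "R"),
                         ivls = ivls)
    be$group[sub_i[o][oo]] <- gi
    be$ord[sub_i[o][oo]] <- seq_len(k)
  }
  jt <- do.call(rbind, lapply(seq_len(nrow(j)), function(id) {
    p <- be[be$junction == id, ]
    data.frame(g1 = p$group[1], b1 = p$ord[1], g2 = p$group[2], b2 = p$ord[2])
  }))
  list(groups = groups, junctions = jt)
}

#' Canonical pattern key of an observed cluster
#' @inheritParams cluster_pattern
#' @return Character key comparable with [pattern_key_of()] output.
#' @export
pattern_key <- function(cluster, cn, bg, locus_tol = 100) {
  canonical_pattern_key(cluster_pattern(cluster, cn, bg, locus_tol))
}

#' Match a cluster against the configuration library
#'
#' @param cluster An `sv_cluster`.
#' @param library A `config_library`.
#' @param cn,bg Copy-number context.
#' @return Data frame of matching operation sequences sorted by length;
#'   zero rows when the cluster is unexplained at the library depth
#'   (a candidate complex / copy-and-paste event).
#' @export
match_cluster <- function(cluster, library, cn, bg) {
  key <- tryCatch(pattern_key(cluster, cn, bg), error = function(e) NA_character_)
  empty <- data.frame(sequence = character(), n_ops = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(key)) return(empty)
  e <- library$entries[[key]]
  if (is.null(e)) return(empty)
  data.frame(sequence = unlist(e$sequences), n_ops = e$min_ops,
             stringsAsFactors = FALSE)
}
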