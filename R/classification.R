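# Cluster classification: junction orientations, copy-number context, path
# reconstruction over a segment graph, and configuration-library matching.

EVENT_CLASSES <- c(
  "deletion", "tandem_duplication", "reciprocal_inversion",
  "reciprocal_translocation", "unbalanced_translocation", "foldback_inversion",
  "templated_insertion_cycle", "templated_insertion_bridge",
  "templated_insertion_chain", "local_2jump_dup_trp_dup",
  "local_2jump_inverted_dups", "local_2jump_del_invdup", "local_n_jump",
  "local_distant", "chromoplexy", "chromothripsis_like", "complex_unclassified")

# CN immediately left / right of a position (breakends sit on segment
# boundaries, so the segment containing pos is the right-hand side)
cn_flanks <- function(cn, chrom, pos) {
  c(left = cn_at(cn, chrom, max(pos - 1, 0)), right = cn_at(cn, chrom, pos))
}

cn_step_at <- function(cn, chrom, pos) {
  f <- cn_flanks(cn, chrom, pos)
  if (any(is.na(f))) return(NA_real_)
  f["right"] - f["left"]
}

# length-weighted modal rounded relative CN over an interval
interval_gain <- function(cn, chrom, lo, hi, bg) {
  if (hi <= lo) return(NA_integer_)
  segs <- cn[cn$chrom == chrom & cn$end > lo & cn$start < hi, , drop = FALSE]
  if (nrow(segs) == 0) return(NA_integer_)
  w <- pmin(segs$end, hi) - pmax(segs$start, lo)
  lev <- round(segs$total_cn - bg)
  ww <- tapply(w, lev, sum)
  as.integer(names(ww)[which.max(ww)])
}

#' Build the copy-number segment graph of a cluster
#'
#' Nodes are the intervals between consecutive cluster breakends per
#' chromosome (plus terminal flank nodes at background copy number), carrying
#' the integer copy-number gain relative to background; edges are the member
#' junctions, attached to the node ends matching each breakend's side.
#'
#' @param cluster An `sv_cluster`.
#' @param cn Copy-number segments.
#' @param bg Background copy number.
#' @return A `segment_graph` with `nodes` and `edges` data frames.
#' @export
build_segment_graph <- function(cluster, cn, bg) {
  be <- breakend_table(cluster$junctions)
  nodes <- list()
  for (cc in unique(be$chrom)) {
    pos <- sort(unique(be$pos[be$chrom == cc]))
    # warn when a breakend is far from any CN segment boundary
    bnd <- c(cn$start[cn$chrom == cc], cn$end[cn$chrom == cc])
    for (p in pos) {
      if (length(bnd) && min(abs(bnd - p)) > 10000)
        warning(sprintf("breakend %s:%.0f is > 10 kb from any CN boundary; boundary imputed",
                        cc, p))
    }
    edges0 <- c(-Inf, pos, Inf)
    for (k in seq_len(length(edges0) - 1)) {
      lo <- edges0[k]; hi <- edges0[k + 1]
      terminal <- !is.finite(lo) || !is.finite(hi)
      qlo <- if (is.finite(lo)) lo else max(hi - 1000, 0)
      qhi <- if (is.finite(hi)) hi else lo + 1000
      g <- interval_gain(cn, cc, qlo, qhi, bg)
      nodes[[length(nodes) + 1L]] <- data.frame(
        chrom = cc, start = lo, end = hi, gain = ifelse(is.na(g), 0L, g),
        terminal = terminal, stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, nodes)
  nodes$node <- seq_len(nrow(nodes))
  # attach each breakend: side left -> right end of the node ending at pos;
  # side right -> left end of the node starting at pos
  edges <- do.call(rbind, lapply(seq_len(nrow(be)), function(i) {
    if (be$side[i] == "left") {
      nd <- nodes$node[nodes$chrom == be$chrom[i] & nodes$end == be$pos[i]]
      at <- "right"
    } else {
      nd <- nodes$node[nodes$chrom == be$chrom[i] & nodes$start == be$pos[i]]
      at <- "left"
    }
    data.frame(junction = be$junction[i], end = be$end[i], node = nd[1],
               node_end = at, stringsAsFactors = FALSE)
  }))
  structure(list(nodes = nodes, edges = edges, cluster = cluster,
                 cn = cn, bg = bg), class = "segment_graph")
}

#' Find a templated-insertion path in a segment graph
#'
#' Searches for a simple alternating walk (junction, gained template segment,
#' junction, ...) using every cluster junction exactly once, in which each
#' interior template has copy-number gain >= 1. The walk's two free breakends
#' determine the topology: `cycle` when both land on one host chromosome with
#' the inter-end host segment gained, `bridge` when the inter-end host segment
#' is lost or absent, `chain` when the ends terminate on two different
#' chromosomes at unbalanced copy-number transitions.
#'
#' @param graph A `segment_graph`.
#' @return A `templated_insertion_path` list (host, templates, topology) or
#'   `NULL` when no walk covers all junctions.
#' @export
find_templated_insertion_path <- function(graph) {
  j <- graph$cluster$junctions
  n <- nrow(j)
  if (n < 2) return(NULL)
  cn <- graph$cn; bg <- graph$bg
  be <- breakend_table(j)

  # candidate templates: elementary intervals with gain >= 1 flanked by a
  # (start, right) breakend of one junction and an (end, left) of another
  templates <- list()
  for (cc in unique(be$chrom)) {
    pos <- sort(unique(be$pos[be$chrom == cc]))
    if (length(pos) < 2) next
    for (k in seq_len(length(pos) - 1)) {
      lo <- pos[k]; hi <- pos[k + 1]
      g <- interval_gain(cn, cc, lo, hi, bg)
      if (is.na(g) || g < 1) next
      starters <- which(be$chrom == cc & be$pos == lo & be$side == "right")
      enders <- which(be$chrom == cc & be$pos == hi & be$side == "left")
      for (s in starters) for (e in enders) {
        if (be$junction[s] == be$junction[e]) next
        templates[[length(templates) + 1L]] <- list(
          chrom = cc, start = lo, end = hi, gain = g,
          be_s = s, be_e = e, j_s = be$junction[s], j_e = be$junction[e])
      }
    }
  }
  if (n > 1 && length(templates) < n - 1) return(NULL)

  # DFS for a walk using all junctions, consecutive junctions joined by a
  # template (entered at either end); deterministic order.  Breakend index
  # mapping: breakend_table rows 1..n are end 1, n+1..2n are end 2.
  other_end <- function(bi) ifelse(bi > n, bi - n, bi + n)
  found <- NULL
  dfs <- function(order_j, exit_be, used_t) {
    if (!is.null(found)) return()
    if (length(order_j) == n) {
      found <<- list(order = order_j, exit = exit_be, templates = used_t)
      return()
    }
    for (ti in seq_along(templates)) {
      if (ti %in% abs(used_t)) next
      tp <- templates[[ti]]
      fwd <- tp$be_s == exit_be   # template traversed start -> end
      rv <- tp$be_e == exit_be    # template traversed end -> start (inverted)
      if (!fwd && !rv) next
      nxt_be <- if (fwd) tp$be_e else tp$be_s
      nxt_j <- be$junction[nxt_be]
      if (nxt_j %in% order_j) next
      dfs(c(order_j, nxt_j), other_end(nxt_be), c(used_t, if (fwd) ti else -ti))
      if (!is.null(found)) return()
    }
  }
  free1 <- NULL
  for (start_j in seq_len(n)) {
    for (entry in c(start_j, start_j + n)) {
      dfs(start_j, other_end(entry), integer(0))
      if (!is.null(found)) { free1 <- entry; break }
    }
    if (!is.null(found)) break
  }
  if (is.null(found)) return(NULL)

  free2 <- found$exit
  f1 <- be[free1, ]; f2 <- be[free2, ]
  tpl_signed <- found$templates
  # normalize walk direction: traversal runs from the "left"-side free end
  if (f1$side == "right" && f2$side == "left") {
    tmp <- f1; f1 <- f2; f2 <- tmp
    tpl_signed <- rev(-tpl_signed)
  }

  tpl_df <- do.call(rbind, lapply(tpl_signed, function(sti) {
    tp <- templates[[abs(sti)]]
    data.frame(chrom = tp$chrom, start = tp$start, end = tp$end,
               orientation = if (sti > 0) "forward" else "reverse",
               cn_gain = tp$gain, stringsAsFactors = FALSE)
  }))

  topology <- NULL; host <- NULL; host_be <- NULL
  if (f1$chrom == f2$chrom) {
    lo <- min(f1$pos, f2$pos); hi <- max(f1$pos, f2$pos)
    gap <- interval_gain(cn, f1$chrom, lo, hi, bg)
    left_be <- if (f1$side == "left") f1 else f2
    right_be <- if (f1$side == "left") f2 else f1
    if (f1$side != f2$side) {
      if (right_be$pos < left_be$pos && !is.na(gap) && gap >= 1) {
        topology <- "cycle"
      } else if (right_be$pos > left_be$pos && (is.na(gap) || gap <= -1)) {
        topology <- "bridge"
      }
      host <- f1$chrom
      host_be <- data.frame(pos = c(f1$pos, f2$pos), side = c(f1$side, f2$side))
    }
  } else {
    s1 <- cn_step_at(cn, f1$chrom, f1$pos)
    s2 <- cn_step_at(cn, f2$chrom, f2$pos)
    if (!is.na(s1) && !is.na(s2) && abs(s1) >= 0.5 && abs(s2) >= 0.5) {
      topology <- "chain"
      host <- paste(f1$chrom, f2$chrom, sep = "|")
      host_be <- data.frame(pos = c(f1$pos, f2$pos), side = c(f1$side, f2$side),
                            chrom = c(f1$chrom, f2$chrom))
    }
  }
  if (is.null(topology)) return(NULL)
  structure(list(host_chrom = host, host_breakends = host_be,
                 templates = tpl_df, topology = topology,
                 junction_order = j$id[found$order]),
            class = "templated_insertion_path")
}

#' Replay a templated-insertion path as a derivative chromosome
#'
#' Reconstructs the derivative implied by a `templated_insertion_path`
#' (host flank, templates in walk order, host return or second terminal) and
#' emits the junctions and copy-number gains that derivative would show.
#' Comparing the emission against the observed cluster is the module's
#' internal oracle: a reported path must regenerate its cluster exactly.
#'
#' @param path A `templated_insertion_path`.
#' @return List with `junctions` (chrom1,pos1,side1,chrom2,pos2,side2) and
#'   `gains` (chrom,start,end,gain).
#' @export
replay_path <- function(path) {
  tpl <- path$templates
  k <- nrow(tpl)
  hb <- path$host_breakends
  jn <- list()
  gains <- list()
  # walk ends: identify the end with side "left" (sequence departs rightward
  # into the first template) and the end with side "right" (return)
  li <- which(hb$side == "left")[1]
  ri <- which(hb$side == "right")[1]
  left_chrom <- if (!is.null(hb$chrom)) hb$chrom[li] else path$host_chrom
  right_chrom <- if (!is.null(hb$chrom)) hb$chrom[ri] else path$host_chrom
  # walk order: the path stores templates in traversal order from the
  # "left"-side free end to the "right"-side free end
  ends_of <- function(t) {
    if (tpl$orientation[t] == "forward") c(tpl$start[t], tpl$end[t])
    else c(tpl$end[t], tpl$start[t])
  }
  sides_of <- function(t) {
    if (tpl$orientation[t] == "forward") c("right", "left")
    else c("left", "right")
  }
  prev_chrom <- left_chrom; prev_pos <- hb$pos[li]; prev_side <- "left"
  for (t in seq_len(k)) {
    e <- ends_of(t); s <- sides_of(t)
    jn[[length(jn) + 1L]] <- data.frame(
      chrom1 = prev_chrom, pos1 = prev_pos, side1 = prev_side,
      chrom2 = tpl$chrom[t], pos2 = e[1], side2 = s[1],
      stringsAsFactors = FALSE)
    gains[[length(gains) + 1L]] <- data.frame(
      chrom = tpl$chrom[t], start = tpl$start[t], end = tpl$end[t], gain = 1L,
      stringsAsFactors = FALSE)
    prev_chrom <- tpl$chrom[t]; prev_pos <- e[2]; prev_side <- s[2]
  }
  jn[[length(jn) + 1L]] <- data.frame(
    chrom1 = prev_chrom, pos1 = prev_pos, side1 = prev_side,
    chrom2 = right_chrom, pos2 = hb$pos[ri], side2 = "right",
    stringsAsFactors = FALSE)
  if (path$topology == "cycle") {
    gains[[length(gains) + 1L]] <- data.frame(
      chrom = right_chrom, start = hb$pos[ri], end = hb$pos[li], gain = 1L,
      stringsAsFactors = FALSE)
  } else if (path$topology == "bridge") {
    gains[[length(gains) + 1L]] <- data.frame(
      chrom = left_chrom, start = hb$pos[li], end = hb$pos[ri], gain = -1L,
      stringsAsFactors = FALSE)
  }
  list(junctions = do.call(rbind, jn), gains = do.call(rbind, gains))
}

#' Check that a path replay regenerates its cluster
#'
#' @param path A `templated_insertion_path`.
#' @param cluster The `sv_cluster` it was found in.
#' @param cn,bg Copy-number context.
#' @return TRUE when the replayed junctions equal the cluster's junctions
#'   (positions and sides) and every replayed gain matches the rounded
#'   observed copy-number change.
#' @export
path_replay_consistent <- function(path, cluster, cn, bg) {
  rp <- replay_path(path)
  key_of <- function(c1, p1, s1, c2, p2, s2) {
    a <- sprintf("%s:%.0f:%s", c1, p1, s1)
    b <- sprintf("%s:%.0f:%s", c2, p2, s2)
    ifelse(a < b, paste(a, b, sep = "~"), paste(b, a, sep = "~"))
  }
  obs <- sort(key_of(cluster$junctions$chrom1, cluster$junctions$pos1,
                     cluster$junctions$side1, cluster$junctions$chrom2,
                     cluster$junctions$pos2, cluster$junctions$side2))
  rep_ <- sort(key_of(rp$junctions$chrom1, rp$junctions$pos1, rp$junctions$side1,
                      rp$junctions$chrom2, rp$junctions$pos2, rp$junctions$side2))
  if (!identical(obs, rep_)) return(FALSE)
  for (r in seq_len(nrow(rp$gains))) {
    g <- interval_gain(cn, rp$gains$chrom[r], rp$gains$start[r],
                       rp$gains$end[r], bg)
    if (is.na(g)) return(FALSE)
    if (rp$gains$gain[r] > 0 && g < rp$gains$gain[r]) return(FALSE)
    if (rp$gains$gain[r] < 0 && g > rp$gains$gain[r]) return(FALSE)
  }
  TRUE
}

# prototype pattern keys for two-junction classes, computed once per session
.proto_env <- new.env(parent = emptyenv())

proto_cluster <- function(jdf, segs) {
  structure(list(id = "proto", sample = "proto", junctions = jdf,
                 footprints = NULL, n_junctions = nrow(jdf)),
            class = "sv_cluster")
}

two_junction_prototype_keys <- function() {
  if (!is.null(.proto_env$keys)) return(.proto_env$keys)
  bg <- 2
  mk <- function(class, j, cnlev) {
    segs <- cn_segments("proto", rep("A", length(cnlev)),
                        seq(0, by = 1e5, length.out = length(cnlev)),
                        seq(1e5, by = 1e5, length.out = length(cnlev)),
                        bg + cnlev)
    key <- pattern_key(proto_cluster(j), segs, bg)
    stats::setNames(class, key)
  }
  p <- function(i) i * 1e5  # breakpoints on the prototype CN grid
  keys <- c(
    mk("reciprocal_inversion",
       junctions(c("a", "b"), "proto",
                 c("A", "A"), c(p(1), p(1)), c("left", "right"),
                 c("A", "A"), c(p(3), p(3)), c("left", "right")),
       c(0, 0, 0, 0, 0)),
    mk("local_2jump_dup_trp_dup",
       junctions(c("a", "b"), "proto",
                 c("A", "A"), c(p(3), p(1)), c("left", "right"),
                 c("A", "A"), c(p(4), p(2)), c("left", "right")),
       c(0, 1, 2, 1, 0)),
    mk("local_2jump_inverted_dups",
       junctions(c("a", "b"), "proto",
                 c("A", "A"), c(p(2), p(1)), c("left", "right"),
                 c("A", "A"), c(p(4), p(3)), c("left", "right")),
       c(0, 1, 0, 1, 0)),
    mk("local_2jump_del_invdup",
       junctions(c("a", "b"), "proto",
                 c("A", "A"), c(p(1), p(2)), c("left", "right"),
                 c("A", "A"), c(p(4), p(3)), c("left", "right")),
       c(0, -1, 0, 1, 0)))
  .proto_env$keys <- keys
  keys
}

# special-case: reciprocal translocation prototype needs junctions on two
# chromosomes; segments must cover both
two_junction_keys_interchrom <- function() {
  if (!is.null(.proto_env$keys2)) return(.proto_env$keys2)
  bg <- 2
  j <- junctions(c("a", "b"), "proto",
                 c("A", "A"), c(2e5, 2e5), c("left", "right"),
                 c("B", "B"), c(2e5, 2e5), c("right", "left"))
  segs <- cn_segments("proto", c("A", "B"), c(0, 0), c(5e5, 5e5), c(bg, bg))
  key <- pattern_key(proto_cluster(j), segs, bg)
  .proto_env$keys2 <- stats::setNames("reciprocal_translocation", key)
  .proto_env$keys2
}

count_oscillations <- function(cn, chrom, pos, bg) {
  # rounded CN levels of elementary intervals between sorted breakends
  pos <- sort(unique(pos))
  if (length(pos) < 3) return(0L)
  lev <- vapply(seq_len(length(pos) - 1), function(k)
    interval_gain(cn, chrom, pos[k], pos[k + 1], bg), integer(1))
  lev <- lev[!is.na(lev)]
  if (length(lev) < 2) return(0L)
  top2 <- as.integer(names(sort(table(lev), decreasing = TRUE)))[1:2]
  lev2 <- lev[lev %in% top2]
  if (length(lev2) < 2) return(0L)
  sum(diff(lev2) != 0)
}

#' Classify one cluster
#'
#' Applies the decision cascade: single-junction rules (deletion, tandem
#' duplication, unbalanced translocation, fold-back inversion), two-junction
#' reciprocal and local 2-jump patterns, templated-insertion path topology
#' (cycle/bridge/chain), local and local--distant clusters, chromoplexy,
#' a coarse chromothripsis flag, and finally complex/unclassified.
#'
#' @param cluster An `sv_cluster`.
#' @param cn Copy-number segments.
#' @param bg Background copy number.
#' @param library Optional `config_library`; matches recorded in details.
#' @param flat_tol CN steps below this count as flat (default 0.5 copies).
#' @param foldback_span Fold-back span threshold in bp (default 5000).
#' @param local_span Local-cluster span threshold in bp (default 1e6).
#' @return A `classification` list (cluster_id, event_class, n_junctions,
#'   details).
#' @export
classify_cluster <- function(cluster, cn, bg, library = NULL,
                             flat_tol = 0.5, foldback_span = 5000,
                             local_span = 1e6) {
  j <- cluster$junctions
  n <- nrow(j)
  details <- list()
  res <- function(class) {
    if (!is.null(library)) {
      m <- match_cluster(cluster, library, cn, bg)
      if (nrow(m)) details$library_matches <- m
    }
    structure(list(cluster_id = cluster$id, sample = cluster$sample,
                   event_class = class, n_junctions = n,
                   footprints = cluster$footprints, details = details),
              class = "classification")
  }
  be <- breakend_table(j)
  cn_ok <- !any(is.na(cn_at(cn, be$chrom, pmax(be$pos - 1, 0))) &
                  is.na(cn_at(cn, be$chrom, be$pos)))
  if (!cn_ok) {
    details$flag <- "missing_cn"
    return(res("complex_unclassified"))
  }

  if (n == 1) {
    oc <- orientation_class(j)
    if (oc == "DEL-like") {
      g <- interval_gain(cn, j$chrom1, j$pos1, j$pos2, bg)
      if (!is.na(g) && g <= -1) return(res("deletion"))
    }
    if (oc == "TD-like") {
      g <- interval_gain(cn, j$chrom1, j$pos1, j$pos2, bg)
      if (!is.na(g) && g >= 1) return(res("tandem_duplication"))
    }
    if (oc == "interchromosomal") {
      s1 <- cn_step_at(cn, j$chrom1, j$pos1)
      s2 <- cn_step_at(cn, j$chrom2, j$pos2)
      if (!is.na(s1) && !is.na(s2) && abs(s1) >= flat_tol && abs(s2) >= flat_tol)
        return(res("unbalanced_translocation"))
    }
    if (oc %in% c("head-head", "tail-tail") &&
        abs(j$pos2 - j$pos1) < foldback_span) {
      s1 <- cn_step_at(cn, j$chrom1, j$pos1)
      s2 <- cn_step_at(cn, j$chrom2, j$pos2)
      if ((!is.na(s1) && abs(s1) >= flat_tol) || (!is.na(s2) && abs(s2) >= flat_tol))
        return(res("foldback_inversion"))
    }
  }

  if (n == 2) {
    key <- tryCatch(pattern_key(cluster, cn, bg), error = function(e) NA_character_)
    if (!is.na(key)) {
      protos <- c(two_junction_prototype_keys(), two_junction_keys_interchrom())
      hit <- protos[names(protos) == key]
      if (length(hit)) {
        details$pattern_key <- key
        return(res(unname(hit[1])))
      }
    }
  }

  if (n >= 2) {
    graph <- suppressWarnings(build_segment_graph(cluster, cn, bg))
    path <- find_templated_insertion_path(graph)
    if (!is.null(path)) {
      details$path <- path
      return(res(paste0("templated_insertion_", path$topology)))
    }
  }

  chroms <- unique(be$chrom)
  span_of <- function(cc) {
    p <- be$pos[be$chrom == cc]
    max(p) - min(p)
  }
  if (length(chroms) == 1 && span_of(chroms) < local_span)
    return(res("local_n_jump"))
  # exactly one distant footprint: all but one footprint within one local
  # region on one chromosome
  fp <- cluster$footprints
  if (!is.null(fp) && nrow(fp) >= 2) {
    for (d in seq_len(nrow(fp))) {
      rest <- fp[-d, , drop = FALSE]
      if (length(unique(rest$chrom)) == 1 &&
          (max(rest$end) - min(rest$start)) < local_span &&
          (fp$chrom[d] != rest$chrom[1] ||
             min(abs(c(fp$start[d], fp$end[d]) -
                       c(min(rest$start), max(rest$end)))) > local_span))
        return(res("local_distant"))
    }
  }
  if (n >= 3 && length(chroms) >= 2) {
    steps <- vapply(seq_len(nrow(be)), function(i)
      cn_step_at(cn, be$chrom[i], be$pos[i]), numeric(1))
    if (all(!is.na(steps)) && all(abs(steps) < flat_tol))
      return(res("chromoplexy"))
  }
  if (n >= 10) {
    for (cc in chroms) {
      if (count_oscillations(cn, cc, be$pos[be$chrom == cc], bg) >= 10)
        return(res("chromothripsis_like"))
    }
  }
  res("complex_unclassified")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification %s: %s (%d junction(s))>\n",
              x$cluster_id, x$event_class, x$n_junctions))
  invisible(x)
}

#' Run the full classification pipeline on one sample
#'
#' Filters (segment bypass removal, fold-back artefact filter, balanced
#' overlap annotation), clusters, refines, and classifies every cluster.
#'
#' @param sv An `sv_set`.
#' @param library Optional `config_library`.
#' @param p_merge Cluster merge threshold.
#' @param callable_size Callable genome size (default 0.9 x build size).
#' @return A list with `classifications` (list of `classification`),
#'   `table` (data frame), `class_counts` (named vector over
#'   `EVENT_CLASSES`), `clusters`, `removed` (bypass log), and `breakpoints`
#'   (per-breakend simple/complex membership table).
#' @export
classify_all <- function(sv, library = NULL, p_merge = 1e-3,
                         callable_size = NULL) {
  bg <- sv$background_cn
  filt <- remove_segment_bypassing(sv$junctions, sv$segments)
  jj <- filter_foldback_artefacts(filt$junctions, sv$segments)
  jj <- resolve_balanced_overlaps(jj)
  sv2 <- sv
  sv2$junctions <- jj
  clusters <- cluster_junctions(sv2, p_merge = p_merge,
                                callable_size = callable_size)
  clusters <- refine_clusters(clusters, sv$segments, bg)
  cls <- lapply(clusters, function(cl)
    tryCatch(classify_cluster(cl, sv$segments, bg, library),
             error = function(e) {
               structure(list(cluster_id = cl$id, sample = cl$sample,
                              event_class = "complex_unclassified",
                              n_junctions = cl$n_junctions,
                              footprints = cl$footprints,
                              details = list(flag = conditionMessage(e))),
                         class = "classification")
             }))
  tab <- do.call(rbind, lapply(cls, function(x)
    data.frame(cluster_id = x$cluster_id, sample = x$sample,
               event_class = x$event_class, n_junctions = x$n_junctions,
               stringsAsFactors = FALSE)))
  if (is.null(tab)) tab <- data.frame(cluster_id = character(),
                                      sample = character(),
                                      event_class = character(),
                                      n_junctions = integer())
  counts <- table(factor(tab$event_class, levels = EVENT_CLASSES))
  bp <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    be <- breakend_table(cl$junctions)
    data.frame(sample = cl$sample, cluster_id = cl$id, chrom = be$chrom,
               pos = be$pos, side = be$side,
               membership = if (cl$n_junctions == 1) "simple" else "complex",
               stringsAsFactors = FALSE)
  }))
  list(classifications = cls, table = tab,
       class_counts = stats::setNames(as.integer(counts), names(counts)),
       clusters = clusters, removed = filt$removed, breakpoints = bp)
}
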