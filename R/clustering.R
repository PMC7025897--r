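# Junction pre-filtering and clustering into clusters and footprints.
#
# The clustering null: breakends placed uniformly on the callable genome form
# a homogeneous Poisson process with rate lambda = n_breakpoints /
# callable_size.  The nearest-neighbour distance d then has
# P(D <= d) = 1 - exp(-lambda * d); two breakends merge when that probability
# falls below p_merge, i.e. they are significantly closer than expected by
# chance given the per-genome event count.  The distance between a junction's
# own two breakends is excluded from merge decisions, so a large simple
# deletion stays a single cluster regardless of its span.

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[rj] <- ri
  p
}
uf_components <- function(p) {
  roots <- vapply(seq_along(p), function(i) uf_find(p, i), integer(1))
  match(roots, unique(roots))
}

#' Clustering null model parameters
#' @param n_breakpoints Number of breakends in the genome.
#' @param callable_size Callable genome size G in bp.
#' @param p_merge Merge significance threshold (default `1e-3`).
#' @return A `cluster_model` list with the per-bp rate `lambda` and the
#'   implied merge distance `d_max` such that `1 - exp(-lambda d_max) = p_merge`.
#' @export
cluster_model <- function(n_breakpoints, callable_size, p_merge = 1e-3) {
  stopifnot(callable_size > 0, p_merge > 0, p_merge < 1)
  lambda <- n_breakpoints / callable_size
  d_max <- if (lambda > 0) -log1p(-p_merge) / lambda else Inf
  structure(list(n_breakpoints = n_breakpoints, callable_size = callable_size,
                 rate = lambda, p_merge = p_merge, d_max = d_max),
            class = "cluster_model")
}

#' Merge p-value for a breakend distance
#' @param model A `cluster_model`.
#' @param d Distance(s) in bp.
#' @return `P(D <= d) = 1 - exp(-lambda d)` under the Poisson placement null.
#' @export
merge_p <- function(model, d) -expm1(-model$rate * d)

breakend_table <- function(j) {
  if (nrow(j) == 0)
    return(data.frame(junction = integer(), end = integer(), chrom = character(),
                      pos = numeric(), side = character(), stringsAsFactors = FALSE))
  data.frame(junction = rep(seq_len(nrow(j)), 2),
             end = rep(1:2, each = nrow(j)),
             chrom = c(j$chrom1, j$chrom2),
             pos = c(j$pos1, j$pos2),
             side = c(j$side1, j$side2),
             stringsAsFactors = FALSE)
}

matches_breakend <- function(chrom, pos, side, chrom2, pos2, side2, tol) {
  chrom == chrom2 & side == side2 & abs(pos - pos2) <= tol
}

#' Remove redundant segment-bypassing junctions
#'
#' A junction is removed when a path of two or more other junctions reproduces
#' its two terminal breakends (same side, position within `tol_bp`) while
#' traversing copy-number segments end-to-end; such a junction carries no
#' information beyond the path that bypasses it.
#'
#' @param j Junction data frame (one sample).
#' @param cn Copy-number segments for the sample.
#' @param tol_bp Breakend matching tolerance (default 50).
#' @param max_path Maximum bypassing path length searched (default 6).
#' @return List with `junctions` (filtered) and `removed` (log data frame with
#'   the bypassing path ids).
#' @export
remove_segment_bypassing <- function(j, cn, tol_bp = 50, max_path = 6) {
  removed <- data.frame(id = character(), path = character(), stringsAsFactors = FALSE)
  if (nrow(j) < 3)
    return(list(junctions = j, removed = removed))

  # interior connection between consecutive path junctions: exit breakend with
  # side 'right' at x continues rightward along the reference and must meet the
  # next junction's breakend with side 'left' at y >= x, with [x, y] either
  # negligible (a shared CN boundary) or a whole CN segment traversed
  # end-to-end; and symmetrically in the other direction.
  connects <- function(ch1, x, s1, ch2, y, s2) {
    if (ch1 != ch2 || s1 == s2) return(FALSE)
    if (s1 == "right") { from <- x; to <- y } else { from <- y; to <- x }
    if (to < from - tol_bp) return(FALSE)
    if (abs(to - from) <= tol_bp) return(TRUE)
    hit <- cn$chrom == ch1 & abs(cn$start - from) <= tol_bp & abs(cn$end - to) <= tol_bp
    any(hit)
  }

  drop <- logical(nrow(j))
  for (t in seq_len(nrow(j))) {
    target <- j[t, ]
    others <- setdiff(seq_len(nrow(j)), t)
    # DFS over paths starting at junctions matching target breakend 1
    found <- NULL
    dfs <- function(cur, exit_ch, exit_pos, exit_side, used) {
      if (!is.null(found)) return()
      if (length(used) >= 2 &&
          matches_breakend(exit_ch, exit_pos, exit_side,
                           target$chrom2, target$pos2, target$side2, tol_bp)) {
        found <<- used
        return()
      }
      if (length(used) >= max_path) return()
      for (nx in setdiff(others, used)) {
        for (e in 1:2) {
          ch <- if (e == 1) j$chrom1[nx] else j$chrom2[nx]
          po <- if (e == 1) j$pos1[nx] else j$pos2[nx]
          si <- if (e == 1) j$side1[nx] else j$side2[nx]
          if (connects(exit_ch, exit_pos, exit_side, ch, po, si)) {
            och <- if (e == 1) j$chrom2[nx] else j$chrom1[nx]
            opo <- if (e == 1) j$pos2[nx] else j$pos1[nx]
            osi <- if (e == 1) j$side2[nx] else j$side1[nx]
            dfs(nx, och, opo, osi, c(used, nx))
            if (!is.null(found)) return()
          }
        }
      }
    }
    for (st in others) {
      for (e in 1:2) {
        ch <- if (e == 1) j$chrom1[st] else j$chrom2[st]
        po <- if (e == 1) j$pos1[st] else j$pos2[st]
        si <- if (e == 1) j$side1[st] else j$side2[st]
        if (matches_breakend(ch, po, si, target$chrom1, target$pos1, target$side1, tol_bp)) {
          och <- if (e == 1) j$chrom2[st] else j$chrom1[st]
          opo <- if (e == 1) j$pos2[st] else j$pos1[st]
          osi <- if (e == 1) j$side2[st] else j$side1[st]
          dfs(st, och, opo, osi, st)
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      drop[t] <- TRUE
      removed <- rbind(removed, data.frame(
        id = target$id, path = paste(j$id[found], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  list(junctions = j[!drop, , drop = FALSE], removed = removed)
}

#' Filter artefactual fold-back junctions
#'
#' Inverted junctions (both breakends on the same side) spanning less than
#' `max_span_bp` are retained only when a total copy-number step of at least
#' 0.5 occurs within `cn_window_bp` of the fold-back point; otherwise they are
#' removed as likely library artefacts.
#'
#' @param j Junction data frame.
#' @param cn Copy-number segments.
#' @param max_span_bp Span threshold (default 5000).
#' @param cn_window_bp Window around the fold-back point searched for a CN
#'   step (default 10000).
#' @return Filtered junction data frame.
#' @export
filter_foldback_artefacts <- function(j, cn, max_span_bp = 5000, cn_window_bp = 10000) {
  if (nrow(j) == 0) return(j)
  inv <- is_inverted(j) & abs(j$pos2 - j$pos1) < max_span_bp
  if (!any(inv)) return(j)
  keep <- rep(TRUE, nrow(j))
  for (i in which(inv)) {
    mid <- (j$pos1[i] + j$pos2[i]) / 2
    segs <- cn[cn$chrom == j$chrom1[i], , drop = FALSE]
    has_step <- FALSE
    if (nrow(segs) > 1) {
      segs <- segs[order(segs$start), ]
      steps <- abs(diff(segs$total_cn))
      at <- segs$end[-nrow(segs)]
      has_step <- any(steps >= 0.5 & abs(at - mid) <= cn_window_bp)
    }
    keep[i] <- has_step
  }
  j[keep, , drop = FALSE]
}

#' Annotate balanced overlapping breakpoints
#'
#' Distinguishes mutually overlapping balanced breakpoints from very short
#' templated insertions. Junction pairs sharing two breakend loci within
#' `max_overlap_bp` with mutually reciprocal sides are tagged
#' `balanced_overlap`; pairs delimiting a shared short segment (< `max_overlap_bp`)
#' whose outer flanks reach elsewhere are tagged `candidate_short_insertion`;
#' everything else is `plain`.
#'
#' @param j Junction data frame.
#' @param max_overlap_bp Overlap threshold (default 100).
#' @return `j` with an added `overlap_tag` column.
#' @export
resolve_balanced_overlaps <- function(j, max_overlap_bp = 100) {
  tag <- rep("plain", nrow(j))
  if (nrow(j) >= 2) {
    for (a in seq_len(nrow(j) - 1)) {
      for (b in (a + 1):nrow(j)) {
        # reciprocal: both breakend loci shared, sides mutually flipped
        recip <-
          j$chrom1[a] == j$chrom1[b] && j$chrom2[a] == j$chrom2[b] &&
          abs(j$pos1[a] - j$pos1[b]) <= max_overlap_bp &&
          abs(j$pos2[a] - j$pos2[b]) <= max_overlap_bp &&
          j$side1[a] != j$side1[b] && j$side2[a] != j$side2[b]
        if (recip) {
          tag[c(a, b)] <- "balanced_overlap"
          next
        }
        # short insertion: the two junctions flank a short donor segment and
        # their other breakends reach elsewhere
        for (da in 1:2) for (db in 1:2) {
          cha <- if (da == 1) j$chrom1[a] else j$chrom2[a]
          poa <- if (da == 1) j$pos1[a] else j$pos2[a]
          sia <- if (da == 1) j$side1[a] else j$side2[a]
          chb <- if (db == 1) j$chrom1[b] else j$chrom2[b]
          pob <- if (db == 1) j$pos1[b] else j$pos2[b]
          sib <- if (db == 1) j$side1[b] else j$side2[b]
          if (cha == chb && sia != sib && abs(poa - pob) < max_overlap_bp &&
              abs(poa - pob) > 0 &&
              min(poa, pob) == ifelse(sia == "right", poa, pob)) {
            ocha <- if (da == 1) j$chrom2[a] else j$chrom1[a]
            ochb <- if (db == 1) j$chrom2[b] else j$chrom1[b]
            opoa <- if (da == 1) j$pos2[a] else j$pos1[a]
            opob <- if (db == 1) j$pos2[b] else j$pos1[b]
            reaches_elsewhere <- (ocha != cha || abs(opoa - poa) > max_overlap_bp) &&
              (ochb != chb || abs(opob - pob) > max_overlap_bp)
            if (reaches_elsewhere && all(tag[c(a, b)] == "plain"))
              tag[c(a, b)] <- "candidate_short_insertion"
          }
        }
      }
    }
  }
  j$overlap_tag <- tag
  j
}

#' Cluster junctions into clusters and footprints
#'
#' Agglomerative single-linkage over breakends: two breakends at distance `d`
#' merge when `1 - exp(-lambda d) < p_merge` with
#' `lambda = n_breakpoints / callable_size`, excluding each junction's own
#' intra-junction distance; the two breakends of a junction are always
#' co-clustered. Clusters are the connected components of proximity and
#' junction links; footprints are the maximal proximity-linked runs of a
#' cluster's breakends per chromosome.
#'
#' @param sv An `sv_set` (or a junction data frame plus `build`).
#' @param p_merge Merge threshold (default `1e-3`).
#' @param callable_size Callable genome size; defaults to 0.9 x the build size.
#' @return List of `sv_cluster` objects, each with members `id`, `sample`,
#'   `junctions` (row indices resolved to a junction data frame), and
#'   `footprints` (data frame: chrom, start, end, pattern plus breakend map).
#' @export
cluster_junctions <- function(sv, p_merge = 1e-3, callable_size = NULL) {
  stopifnot(inherits(sv, "sv_set"))
  j <- sv$junctions
  if (nrow(j) == 0) return(list())
  if (is.null(callable_size)) callable_size <- 0.9 * build_size(sv$build)
  model <- cluster_model(2L * nrow(j), callable_size, p_merge)
  be <- breakend_table(j)
  n <- nrow(be)
  ord <- order(chrom_rank(sv$build, be$chrom), be$pos)
  parent <- uf_new(n)
  # proximity links: windowed scan over sorted breakends per chromosome
  prox_pair <- matrix(integer(0), ncol = 2)
  for (k in seq_len(n - 1)) {
    i <- ord[k]
    for (m in (k + 1):n) {
      g <- ord[m]
      if (be$chrom[i] != be$chrom[g]) break
      d <- be$pos[g] - be$pos[i]
      if (d >= model$d_max) break
      if (be$junction[i] == be$junction[g]) next  # intra-junction exclusion
      parent <- uf_union(parent, i, g)
      prox_pair <- rbind(prox_pair, c(i, g))
    }
  }
  # junction links: the two breakends of a junction always co-cluster
  for (q in seq_len(nrow(j))) parent <- uf_union(parent, q, q + nrow(j))
  comp <- uf_components(parent)

  clusters <- list()
  for (cid in sort(unique(comp))) {
    bidx <- which(comp == cid)
    jidx <- sort(unique(be$junction[bidx]))
    sub <- be[bidx, , drop = FALSE]
    sub <- sub[order(chrom_rank(sv$build, sub$chrom), sub$pos), , drop = FALSE]
    # footprints: runs of breakends with consecutive plain distance < d_max
    fp_id <- integer(nrow(sub))
    cur <- 1L
    fp_id[1] <- cur
    if (nrow(sub) > 1) {
      for (k in 2:nrow(sub)) {
        new_fp <- sub$chrom[k] != sub$chrom[k - 1] ||
          (sub$pos[k] - sub$pos[k - 1]) >= model$d_max
        if (new_fp) cur <- cur + 1L
        fp_id[k] <- cur
      }
    }
    sub$footprint <- fp_id
    fps <- do.call(rbind, lapply(split(sub, sub$footprint), function(g) {
      data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
                 n_breakends = nrow(g),
                 pattern = paste(ifelse(g$side == "left", "L", "R"), collapse = ""),
                 stringsAsFactors = FALSE)
    }))
    rownames(fps) <- NULL
    clusters[[length(clusters) + 1L]] <- structure(
      list(id = sprintf("%s_c%03d", sv$sample, length(clusters) + 1L),
           sample = sv$sample,
           junctions = j[jidx, , drop = FALSE],
           breakends = sub,
           footprints = fps,
           n_junctions = length(jidx),
           model = model),
      class = "sv_cluster")
  }
  clusters
}

#' @export
print.sv_cluster <- function(x, ...) {
  cat(sprintf("<sv_cluster %s: %d junction(s), %d footprint(s)>\n",
              x$id, x$n_junctions, nrow(x$footprints)))
  invisible(x)
}

# is junction row (in canonical order) an independently simple CN-consistent
# deletion or tandem duplication?
independently_simple <- function(jrow, cn, bg, flat_tol = 0.5) {
  if (jrow$chrom1 != jrow$chrom2) return(FALSE)
  oc <- orientation_class(jrow)
  if (!(oc %in% c("DEL-like", "TD-like"))) return(FALSE)
  inside <- cn_at(cn, jrow$chrom1, (jrow$pos1 + jrow$pos2) / 2)
  left <- cn_at(cn, jrow$chrom1, max(jrow$pos1 - 1, 0))
  right <- cn_at(cn, jrow$chrom2, jrow$pos2 + 1)
  if (any(is.na(c(inside, left, right)))) return(FALSE)
  if (abs(left - right) >= flat_tol) return(FALSE)
  delta <- inside - (left + right) / 2
  (oc == "DEL-like" && abs(delta + 1) < flat_tol) ||
    (oc == "TD-like" && abs(delta - 1) < flat_tol)
}

#' Heuristically refine clusters
#'
#' (a) A multi-junction cluster splits into singletons when every member
#' junction is independently classifiable as a CN-consistent simple deletion
#' or tandem duplication and the junction interiors are pairwise
#' non-overlapping; (b) clusters whose footprints overlap are merged.
#'
#' @param clusters List of `sv_cluster`.
#' @param cn Copy-number segments.
#' @param bg Background copy number.
#' @return Refined list of clusters.
#' @export
refine_clusters <- function(clusters, cn, bg = 2) {
  if (length(clusters) == 0) return(clusters)
  # (b) merge clusters with overlapping footprints
  k <- length(clusters)
  parent <- uf_new(k)
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      fa <- clusters[[a]]$footprints; fb <- clusters[[b]]$footprints
      ov <- FALSE
      for (x in seq_len(nrow(fa))) for (y in seq_len(nrow(fb))) {
        if (fa$chrom[x] == fb$chrom[y] &&
            fa$start[x] <= fb$end[y] && fb$start[y] <= fa$end[x]) ov <- TRUE
      }
      if (ov) parent <- uf_union(parent, a, b)
    }
  }
  comp <- uf_components(parent)
  merged <- lapply(sort(unique(comp)), function(cc) {
    members <- clusters[comp == cc]
    if (length(members) == 1) return(members[[1]])
    base <- members[[1]]
    base$junctions <- do.call(rbind, lapply(members, `[[`, "junctions"))
    base$breakends <- do.call(rbind, lapply(members, `[[`, "breakends"))
    base$breakends <- base$breakends[order(base$breakends$chrom, base$breakends$pos), ]
    base$footprints <- do.call(rbind, lapply(members, `[[`, "footprints"))
    base$n_junctions <- nrow(base$junctions)
    base
  })
  # (a) split fully-simple co-clusters
  out <- list()
  for (cl in merged) {
    if (cl$n_junctions >= 2) {
      simple <- vapply(seq_len(cl$n_junctions), function(i)
        independently_simple(cl$junctions[i, , drop = FALSE], cn, bg), logical(1))
      ivl <- cbind(cl$junctions$pos1, cl$junctions$pos2)
      disjoint <- TRUE
      if (all(simple)) {
        for (a in seq_len(cl$n_junctions - 1)) for (b in (a + 1):cl$n_junctions) {
          if (cl$junctions$chrom1[a] == cl$junctions$chrom1[b] &&
              ivl[a, 1] < ivl[b, 2] && ivl[b, 1] < ivl[a, 2]) disjoint <- FALSE
        }
      }
      if (all(simple) && disjoint) {
        for (i in seq_len(cl$n_junctions)) {
          sub <- cl
          sub$junctions <- cl$junctions[i, , drop = FALSE]
          sub$breakends <- cl$breakends[cl$breakends$junction ==
                                          cl$breakends$junction[
                                            match(cl$junctions$id[i],
                                                  cl$junctions$id)], , drop = FALSE]
          be <- breakend_table(sub$junctions)
          sub$breakends <- be[order(be$chrom, be$pos), ]
          sub$footprints <- data.frame(
            chrom = sub$breakends$chrom, start = sub$breakends$pos,
            end = sub$breakends$pos, n_breakends = 1,
            pattern = ifelse(sub$breakends$side == "left", "L", "R"),
            stringsAsFactors = FALSE)
          sub$n_junctions <- 1L
          sub$id <- sprintf("%s_s%d", cl$id, i)
          out[[length(out) + 1L]] <- sub
        }
        next
      }
    }
    out[[length(out) + 1L]] <- cl
  }
  out
}
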