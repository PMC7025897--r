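# Rearrangement simulator: constructs each event's derivative explicitly and
# emits the junctions and copy-number changes that derivative implies, so the
# simulated evidence is internally consistent by construction.  Ground truth
# (class, member junctions, parameters) is recorded per event.

SIM_CLASSES <- c("deletion", "tandem_duplication", "reciprocal_inversion",
                 "reciprocal_translocation", "unbalanced_translocation",
                 "foldback_inversion", "templated_insertion_cycle",
                 "templated_insertion_bridge", "templated_insertion_chain",
                 "local_2jump_dup_trp_dup", "local_2jump_inverted_dups",
                 "local_2jump_del_invdup", "chromoplexy")

#' Simulator configuration
#'
#' Defaults describe a moderately rearranged tumour genome on the toy build:
#' deletion and tandem-duplication sizes follow two-mode log-normal mixtures
#' (modes near 10 kb and 200 kb), templated-insertion templates are
#' log-normal around 20 kb, copy-number noise is Gaussian with sd 0.1
#' truncated at zero, and placement is biased toward late-replicating DNA for
#' deletions and early-replicating DNA for tandem duplications and unbalanced
#' translocations.
#'
#' @param seed Integer seed.
#' @param build Genome build (default [toy_build()]).
#' @param intensities Named numeric vector of expected event counts per class
#'   (Poisson means).
#' @param background Background total copy number (default 2).
#' @param cn_noise_sd Gaussian noise sd on segment copy number (default 0.1).
#' @param rt_bias Named vector of replication-timing placement biases per
#'   class (positive = early, negative = late, 0 = neutral).
#' @param n_templates_range Range of template counts for templated-insertion
#'   events.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, build = toy_build(),
                       intensities = c(deletion = 20, tandem_duplication = 10,
                                       reciprocal_translocation = 2),
                       background = 2, cn_noise_sd = 0.1,
                       rt_bias = c(deletion = -1, tandem_duplication = 1,
                                   unbalanced_translocation = 1),
                       n_templates_range = c(1, 4)) {
  stopifnot(all(intensities >= 0))
  structure(list(seed = seed, build = build, intensities = intensities,
                 background = background, cn_noise_sd = cn_noise_sd,
                 rt_bias = rt_bias, n_templates_range = n_templates_range,
                 size_dists = list(
                   deletion = list(w = c(0.5, 0.5), meanlog = log(c(1e4, 2e5)),
                                   sdlog = c(0.7, 0.7)),
                   tandem_duplication = list(w = c(0.5, 0.5),
                                             meanlog = log(c(1e4, 2e5)),
                                             sdlog = c(0.7, 0.7)),
                   reciprocal_inversion = list(w = 1, meanlog = log(1e5), sdlog = 0.8),
                   # templated-insertion templates and local 2-jump segments
                   # sit at the small (sub-kilobase) mode of the template size
                   # spectrum, keeping intra-cluster breakend spacings within
                   # the proximity-null merge radius at realistic event counts
                   template = list(w = 1, meanlog = log(700), sdlog = 0.5),
                   two_jump = list(w = 1, meanlog = log(600), sdlog = 0.4))),
            class = "sim_config")
}

sample_size_mix <- function(dist, rng, lo = 1000, hi = 2e6) {
  k <- if (length(dist$w) > 1) rng$sample_int(length(dist$w), 1, prob = dist$w) else 1
  min(max(round(rng$rlnorm(1, dist$meanlog[k], dist$sdlog[k])), lo), hi)
}

#' Replication-timing surrogate track over a build
#'
#' A smooth periodic wave (period 10 Mb, range -1..1); higher values mean
#' earlier replication. Used both for biased event placement and as a test
#' property track.
#'
#' @param grid A `pixel_grid`.
#' @return A `property_track`.
#' @export
sim_rt_track <- function(grid) {
  vals <- numeric(grid$total_bins)
  for (cc in names(grid$n_bins)) {
    n <- grid$n_bins[cc]
    mids <- (seq_len(n) - 0.5) * grid$bin_size
    vals[grid$offsets[cc] + seq_len(n)] <- cos(2 * pi * mids / 1e7)
  }
  property_track("replication_timing", vals, grid, "higher = earlier")
}

rt_value_at <- function(pos) cos(2 * pi * pos / 1e7)

# ---- per-class event constructors ---------------------------------------
# each returns list(junctions = data.frame rows, deltas = data.frame, truth)

jrow <- function(id, c1, p1, s1, c2, p2, s2) {
  data.frame(id = id, chrom1 = c1, pos1 = p1, side1 = s1,
             chrom2 = c2, pos2 = p2, side2 = s2, stringsAsFactors = FALSE)
}
drow <- function(chrom, start, end, delta) {
  data.frame(chrom = chrom, start = start, end = end, delta = delta,
             stringsAsFactors = FALSE)
}

make_event <- function(class, eid, placement, rng, config) {
  id <- function(k) sprintf("%s_j%d", eid, k)
  p <- placement
  switch(class,
    deletion = list(
      junctions = jrow(id(1), p$chrom[1], p$pos[1], "left",
                       p$chrom[1], p$pos[1] + p$size[1], "right"),
      deltas = drow(p$chrom[1], p$pos[1], p$pos[1] + p$size[1], -1),
      params = list(size = p$size[1])),
    tandem_duplication = list(
      junctions = jrow(id(1), p$chrom[1], p$pos[1] + p$size[1], "left",
                       p$chrom[1], p$pos[1], "right"),
      deltas = drow(p$chrom[1], p$pos[1], p$pos[1] + p$size[1], +1),
      params = list(size = p$size[1])),
    reciprocal_inversion = {
      x <- p$pos[1]; y <- p$pos[1] + p$size[1]
      list(junctions = rbind(jrow(id(1), p$chrom[1], x, "left", p$chrom[1], y, "left"),
                             jrow(id(2), p$chrom[1], x + 20, "right",
                                  p$chrom[1], y + 20, "right")),
           deltas = NULL, params = list(size = p$size[1]))
    },
    reciprocal_translocation = {
      list(junctions = rbind(
        jrow(id(1), p$chrom[1], p$pos[1], "left", p$chrom[2], p$pos[2], "right"),
        jrow(id(2), p$chrom[1], p$pos[1] + 10, "right",
             p$chrom[2], p$pos[2] + 10, "left")),
        deltas = NULL, params = list())
    },
    unbalanced_translocation = {
      lenA <- chrom_length(config$build, p$chrom[1])
      list(junctions = jrow(id(1), p$chrom[1], p$pos[1], "left",
                            p$chrom[2], p$pos[2], "right"),
           deltas = rbind(drow(p$chrom[1], p$pos[1], lenA, -1),
                          drow(p$chrom[2], 0, p$pos[2], -1)),
           params = list())
    },
    foldback_inversion = {
      x <- p$pos[1]
      span <- 400 + round(rng$runif(1) * 2000)
      list(junctions = jrow(id(1), p$chrom[1], x, "left",
                            p$chrom[1], x + span, "left"),
           deltas = drow(p$chrom[1], p$gain_from, x, +1),
           params = list(span = span))
    },
    templated_insertion_cycle = ,
    templated_insertion_bridge = ,
    templated_insertion_chain = {
      k <- length(p$templates)
      tpl <- p$templates
      jn <- list()
      deltas <- list()
      if (class == "templated_insertion_cycle") {
        h1 <- p$pos[1]; h2 <- p$pos[1] + p$host_size
        jn[[1]] <- jrow(id(1), p$chrom[1], h2, "left",
                        tpl[[1]]$chrom, tpl[[1]]$start, "right")
        deltas[[1]] <- drow(p$chrom[1], h1, h2, +1)
        last_end <- c(tpl[[k]]$chrom, tpl[[k]]$end)
        ret <- jrow(id(k + 1), tpl[[k]]$chrom, tpl[[k]]$end, "left",
                    p$chrom[1], h1, "right")
      } else if (class == "templated_insertion_bridge") {
        h1 <- p$pos[1]; h2 <- p$pos[1] + p$host_size
        jn[[1]] <- jrow(id(1), p$chrom[1], h1, "left",
                        tpl[[1]]$chrom, tpl[[1]]$start, "right")
        deltas[[1]] <- drow(p$chrom[1], h1, h2, -1)
        ret <- jrow(id(k + 1), tpl[[k]]$chrom, tpl[[k]]$end, "left",
                    p$chrom[1], h2, "right")
      } else {
        lenA <- chrom_length(config$build, p$chrom[1])
        jn[[1]] <- jrow(id(1), p$chrom[1], p$pos[1], "left",
                        tpl[[1]]$chrom, tpl[[1]]$start, "right")
        deltas[[1]] <- rbind(drow(p$chrom[1], p$pos[1], lenA, -1),
                             drow(p$chrom[2], 0, p$pos[2], -1))
        ret <- jrow(id(k + 1), tpl[[k]]$chrom, tpl[[k]]$end, "left",
                    p$chrom[2], p$pos[2], "right")
      }
      for (t in seq_len(k)) {
        deltas[[length(deltas) + 1L]] <- drow(tpl[[t]]$chrom, tpl[[t]]$start,
                                              tpl[[t]]$end, +1)
        if (t < k)
          jn[[length(jn) + 1L]] <- jrow(id(t + 1), tpl[[t]]$chrom, tpl[[t]]$end,
                                        "left", tpl[[t + 1]]$chrom,
                                        tpl[[t + 1]]$start, "right")
      }
      jn[[length(jn) + 1L]] <- ret
      list(junctions = do.call(rbind, jn), deltas = do.call(rbind, deltas),
           params = list(n_templates = k,
                         template_span = sum(vapply(tpl, function(t)
                           t$end - t$start, numeric(1)))))
    },
    local_2jump_dup_trp_dup = {
      q <- p$pos[1] + cumsum(c(0, p$seg_sizes))
      list(junctions = rbind(
        jrow(id(1), p$chrom[1], q[4], "left", p$chrom[1], q[3], "left"),
        jrow(id(2), p$chrom[1], q[1], "right", p$chrom[1], q[2], "right")),
        deltas = rbind(drow(p$chrom[1], q[1], q[2], +1),
                       drow(p$chrom[1], q[2], q[3], +2),
                       drow(p$chrom[1], q[3], q[4], +1)),
        params = list(seg_sizes = p$seg_sizes))
    },
    local_2jump_inverted_dups = {
      q <- p$pos[1] + cumsum(c(0, p$seg_sizes))
      list(junctions = rbind(
        jrow(id(1), p$chrom[1], q[4], "left", p$chrom[1], q[2], "left"),
        jrow(id(2), p$chrom[1], q[1], "right", p$chrom[1], q[3], "right")),
        deltas = rbind(drow(p$chrom[1], q[1], q[2], +1),
                       drow(p$chrom[1], q[3], q[4], +1)),
        params = list(seg_sizes = p$seg_sizes))
    },
    local_2jump_del_invdup = {
      q <- p$pos[1] + cumsum(c(0, p$seg_sizes))
      list(junctions = rbind(
        jrow(id(1), p$chrom[1], q[1], "left", p$chrom[1], q[4], "left"),
        jrow(id(2), p$chrom[1], q[2], "right", p$chrom[1], q[3], "right")),
        deltas = rbind(drow(p$chrom[1], q[1], q[2], -1),
                       drow(p$chrom[1], q[3], q[4], +1)),
        params = list(seg_sizes = p$seg_sizes))
    },
    chromoplexy = {
      k <- length(p$chrom)
      jn <- lapply(seq_len(k), function(i) {
        nx <- if (i == k) 1 else i + 1
        jrow(id(i), p$chrom[i], p$pos[i], "left", p$chrom[nx], p$pos[nx], "right")
      })
      list(junctions = do.call(rbind, jn), deltas = NULL,
           params = list(n_breaks = k))
    },
    stop("unknown simulated class: ", class))
}

#' Simulate one rearranged genome
#'
#' Event counts are Poisson with the configured intensities; events are
#' placed without overlap (retry cap) with replication-timing bias, their
#' junctions and copy-number deltas are merged onto the background, and
#' Gaussian noise is applied per final copy-number segment.
#'
#' @param config A `sim_config`.
#' @param sample Sample label.
#' @param event_list Optional explicit data frame (class, count) overriding
#'   Poisson sampling.
#' @return List with `sv` (an `sv_set`) and `truth` (data frame: event id,
#'   class, junction ids, size parameters).
#' @export
simulate_genome <- function(config, sample = "sim1", event_list = NULL) {
  rng <- local_rng(config$seed)
  build <- config$build
  if (is.null(event_list)) {
    classes <- names(config$intensities)
    counts <- rng$rpois(length(classes), config$intensities)
    event_list <- data.frame(class = classes, count = counts,
                             stringsAsFactors = FALSE)
  }
  occupied <- lapply(stats::setNames(build$chromosomes$chrom,
                                     build$chromosomes$chrom),
                     function(x) data.frame(start = numeric(), end = numeric()))
  margin <- 2e4
  reserve <- function(chrom, start, end) {
    occ <- occupied[[chrom]]
    if (any(occ$start < end + margin & start - margin < occ$end)) return(FALSE)
    occupied[[chrom]] <<- rbind(occ, data.frame(start = start, end = end))
    TRUE
  }
  place_interval <- function(span, bias = 0, max_try = 100) {
    for (try in seq_len(max_try)) {
      ci <- rng$sample_int(nrow(build$chromosomes), 1)
      chrom <- build$chromosomes$chrom[ci]
      len <- build$chromosomes$length[ci]
      if (span + 2e6 >= len) next
      pos <- round(rng$runif(1, 1e6, len - span - 1e6))
      if (bias != 0) {
        accept <- exp(bias * rt_value_at(pos)) / exp(abs(bias))
        if (rng$runif(1) > accept) next
      }
      if (reserve(chrom, pos, pos + span)) return(list(chrom = chrom, pos = pos))
    }
    NULL
  }
  # terminal-loss breakpoints go near a telomere and reserve the lost tail,
  # so their copy-number effect cannot contaminate other events
  place_tail_loss <- function(side, max_try = 100, avoid_chrom = NULL) {
    for (try in seq_len(max_try)) {
      ci <- rng$sample_int(nrow(build$chromosomes), 1)
      chrom <- build$chromosomes$chrom[ci]
      if (!is.null(avoid_chrom) && chrom %in% avoid_chrom) next
      len <- build$chromosomes$length[ci]
      off <- round(rng$runif(1, 2e5, 6e5))
      if (side == "tail") {
        pos <- len - off
        if (reserve(chrom, pos, len)) return(list(chrom = chrom, pos = pos))
      } else {
        pos <- off
        if (reserve(chrom, 0, pos)) return(list(chrom = chrom, pos = pos))
      }
    }
    NULL
  }
  junctions_all <- list()
  deltas_all <- list()
  truth <- list()
  eid_n <- 0
  for (r in seq_len(nrow(event_list))) {
    class <- event_list$class[r]
    bias <- if (class %in% names(config$rt_bias)) config$rt_bias[[class]] else 0
    for (k in seq_len(event_list$count[r])) {
      eid_n <- eid_n + 1
      eid <- sprintf("e%04d", eid_n)
      placement <- NULL
      if (class %in% c("deletion", "tandem_duplication", "reciprocal_inversion")) {
        dist <- config$size_dists[[class]]
        span <- sample_size_mix(dist, rng)
        loc <- place_interval(span, bias)
        if (is.null(loc)) stop("genome saturated: reduce event intensities")
        placement <- list(chrom = loc$chrom, pos = loc$pos, size = span)
      } else if (class == "foldback_inversion") {
        # reserve the gained flank so its CN step stays private to the event
        loc <- place_interval(2.1e5, bias)
        if (is.null(loc)) stop("genome saturated: reduce event intensities")
        placement <- list(chrom = loc$chrom, pos = loc$pos + 2e5,
                          gain_from = loc$pos)
      } else if (class == "reciprocal_translocation") {
        l1 <- place_interval(1e4, bias); l2 <- place_interval(1e4, bias)
        if (is.null(l1) || is.null(l2) || l1$chrom == l2$chrom) {
          eid_n <- eid_n - 1
          next
        }
        placement <- list(chrom = c(l1$chrom, l2$chrom), pos = c(l1$pos, l2$pos))
      } else if (class == "unbalanced_translocation") {
        l1 <- place_tail_loss("tail")
        l2 <- if (!is.null(l1)) place_tail_loss("head", avoid_chrom = l1$chrom)
        if (is.null(l1) || is.null(l2)) {
          eid_n <- eid_n - 1
          next
        }
        placement <- list(chrom = c(l1$chrom, l2$chrom), pos = c(l1$pos, l2$pos))
      } else if (grepl("^templated_insertion", class)) {
        k_t <- config$n_templates_range[1] +
          rng$sample_int(diff(config$n_templates_range) + 1, 1) - 1
        if (class == "templated_insertion_chain") {
          host <- place_tail_loss("tail")
          host2 <- if (!is.null(host)) place_tail_loss("head", avoid_chrom = host$chrom)
        } else {
          host <- place_interval(5e4, bias)
          host2 <- NULL
        }
        tpls <- list()
        ok <- !is.null(host) &&
          (class != "templated_insertion_chain" || !is.null(host2))
        for (t in seq_len(k_t)) {
          if (!ok) break
          sz <- sample_size_mix(config$size_dists$template, rng, lo = 200)
          lt <- place_interval(sz)
          if (is.null(lt)) { ok <- FALSE; break }
          tpls[[t]] <- list(chrom = lt$chrom, start = lt$pos, end = lt$pos + sz)
        }
        if (!ok) {
          eid_n <- eid_n - 1
          next
        }
        placement <- list(chrom = c(host$chrom,
                                    if (!is.null(host2)) host2$chrom),
                          pos = c(host$pos, if (!is.null(host2)) host2$pos),
                          host_size = 300 + round(rng$runif(1) * 500),
                          templates = tpls)
      } else if (grepl("^local_2jump", class)) {
        sizes <- vapply(1:3, function(i)
          sample_size_mix(config$size_dists$two_jump, rng, lo = 300), numeric(1))
        loc <- place_interval(sum(sizes), bias)
        if (is.null(loc)) stop("genome saturated: reduce event intensities")
        placement <- list(chrom = loc$chrom, pos = loc$pos, seg_sizes = sizes)
      } else if (class == "chromoplexy") {
        nb <- max(3, min(nrow(build$chromosomes), 3))
        locs <- lapply(seq_len(nb), function(i) place_interval(1e4))
        chroms <- vapply(locs, function(l) if (is.null(l)) NA_character_ else l$chrom,
                         character(1))
        if (any(is.na(chroms)) || length(unique(chroms)) < 2) {
          eid_n <- eid_n - 1
          next
        }
        placement <- list(chrom = chroms,
                          pos = vapply(locs, `[[`, numeric(1), "pos"))
      } else stop("unknown simulated class: ", class)
      ev <- make_event(class, eid, placement, rng, config)
      junctions_all[[length(junctions_all) + 1L]] <- ev$junctions
      if (!is.null(ev$deltas)) deltas_all[[length(deltas_all) + 1L]] <- ev$deltas
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = eid, event_class = class,
        junction_ids = paste(ev$junctions$id, collapse = ","),
        n_junctions = nrow(ev$junctions),
        size = if (!is.null(ev$params$size)) ev$params$size
               else if (!is.null(ev$params$template_span)) ev$params$template_span
               else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  jdf <- if (length(junctions_all)) do.call(rbind, junctions_all) else NULL
  jx <- if (is.null(jdf)) empty_junctions()
        else junctions(jdf$id, sample, jdf$chrom1, jdf$pos1, jdf$side1,
                       jdf$chrom2, jdf$pos2, jdf$side2, build = build)
  deltas <- if (length(deltas_all)) do.call(rbind, deltas_all) else NULL
  segments <- build_cn_profile(build, deltas, config$background,
                               config$cn_noise_sd, rng, sample)
  list(sv = sv_set(sample, jx, segments, build),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(event_id = character(), event_class = character(),
                    junction_ids = character(), n_junctions = integer(),
                    size = numeric()))
}

# merge per-event CN deltas onto a flat background and add truncated noise
build_cn_profile <- function(build, deltas, background, noise_sd, rng, sample) {
  segs <- list()
  for (ci in seq_len(nrow(build$chromosomes))) {
    cc <- build$chromosomes$chrom[ci]
    len <- build$chromosomes$length[ci]
    d <- if (is.null(deltas)) NULL else deltas[deltas$chrom == cc, , drop = FALSE]
    bks <- sort(unique(c(0, len, if (!is.null(d)) c(d$start, d$end))))
    for (k in seq_len(length(bks) - 1)) {
      lo <- bks[k]; hi <- bks[k + 1]
      cnv <- background
      if (!is.null(d) && nrow(d)) {
        inside <- d$start <= lo & d$end >= hi
        cnv <- cnv + sum(d$delta[inside])
      }
      if (noise_sd > 0) cnv <- max(cnv + rng$rnorm(1, 0, noise_sd), 0)
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sample, chrom = cc, start = lo, end = hi, total_cn = cnv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, segs)
}

#' Map catalogue categories to simulable event specifications
#'
#' @param category Category names from [default_catalogue()].
#' @return Data frame: category, class, size_lo, size_hi.
#' @export
category_event_spec <- function(category) {
  spec1 <- function(cat) {
    size <- c(NA, NA)
    cls <- switch(sub("_(<|>|50|early|late|=).*$", "", cat),
      del = "deletion", td = "tandem_duplication",
      recip_inv = "reciprocal_inversion",
      cycle = "templated_insertion_cycle",
      bridge = "templated_insertion_bridge",
      chain = "templated_insertion_chain", NULL)
    if (is.null(cls)) cls <- switch(cat,
      unbal_translocation = "unbalanced_translocation",
      recip_translocation = "reciprocal_translocation",
      chromoplexy = "chromoplexy",
      foldback_inv = "foldback_inversion",
      two_jump_dup_trp_dup = "local_2jump_dup_trp_dup",
      two_jump_inverted_dups = "local_2jump_inverted_dups",
      two_jump_del_invdup = "local_2jump_del_invdup",
      "deletion")
    if (grepl("<50kb", cat)) size <- c(5e3, 5e4)
    if (grepl("50-500kb", cat)) size <- c(5e4, 5e5)
    if (grepl(">500kb", cat)) size <- c(5e5, 2e6)
    data.frame(category = cat, class = cls, size_lo = size[1], size_hi = size[2],
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(category, spec1))
}

#' Simulate a cohort with planted signature exposures
#'
#' Per patient, exposures are Gamma-distributed, category counts are Poisson
#' with mean `exposures %*% signatures`, and (optionally) events are
#' instantiated per category through [simulate_genome()].
#'
#' @param config A `sim_config` (seed and build are used).
#' @param n_patients Number of patients.
#' @param signatures K x categories probability matrix (rows sum to 1);
#'   default: three planted signatures over the default catalogue (small
#'   deletion / early tandem-duplication + templated insertion / balanced
#'   rearrangement processes).
#' @param exposure_shape,exposure_mean Gamma exposure parameters (shape 2,
#'   mean 30 events per signature).
#' @param instantiate Also build per-patient `sv_set`s (default FALSE: the
#'   truth count matrix is the cohort-level object of interest).
#' @return List: `counts` (patients x categories truth matrix), `exposures`,
#'   `signatures`, and `sv_sets` when instantiated.
#' @export
simulate_cohort <- function(config, n_patients, signatures = NULL,
                            exposure_shape = 2, exposure_mean = 30,
                            instantiate = FALSE) {
  if (is.null(signatures)) signatures <- planted_signatures()
  rng <- local_rng(derive_seed(config$seed, 90001))
  K <- nrow(signatures); C <- ncol(signatures)
  if (n_patients == 0)
    return(list(counts = matrix(0L, 0, C, dimnames = list(NULL, colnames(signatures))),
                exposures = matrix(0, 0, K), signatures = signatures,
                sv_sets = list()))
  expo <- matrix(rng$rgamma(n_patients * K, exposure_shape,
                            rate = exposure_shape / exposure_mean),
                 n_patients, K)
  mu <- expo %*% signatures
  counts <- matrix(rng$rpois(length(mu), mu), n_patients, C,
                   dimnames = list(sprintf("P%03d", seq_len(n_patients)),
                                   colnames(signatures)))
  sv_sets <- list()
  if (instantiate) {
    spec <- category_event_spec(colnames(signatures))
    for (p in seq_len(n_patients)) {
      ev <- data.frame(class = spec$class, count = counts[p, ],
                       stringsAsFactors = FALSE)
      ev <- stats::aggregate(count ~ class, ev, sum)
      cfg <- config
      cfg$seed <- derive_seed(config$seed, 1e5 + p)
      sv_sets[[rownames(counts)[p]]] <-
        simulate_genome(cfg, sample = rownames(counts)[p], event_list = ev)
    }
  }
  list(counts = counts, exposures = expo, signatures = signatures,
       sv_sets = sv_sets)
}

#' Three planted signatures over the default catalogue
#'
#' Signature 1: small/mid deletions (with small reciprocal inversions);
#' signature 2: early tandem duplications with templated-insertion cycles,
#' bridges and chains; signature 3: balanced rearrangements (reciprocal
#' translocations and chromoplexy) with unbalanced translocations.
#'
#' @return 3 x C probability matrix.
#' @export
planted_signatures <- function() {
  cats <- default_catalogue()$categories
  S <- matrix(0, 3, length(cats), dimnames = list(paste0("true", 1:3), cats))
  S[1, c("del_<50kb", "del_50-500kb", "recip_inv_<500kb")] <- c(0.6, 0.3, 0.1)
  S[2, c("td_<50kb_early", "td_50-500kb_early", "cycle_<=100kb",
         "bridge_<=100kb", "chain_<=100kb")] <- c(0.4, 0.2, 0.2, 0.1, 0.1)
  S[3, c("recip_translocation", "chromoplexy", "unbal_translocation")] <-
    c(0.4, 0.3, 0.3)
  S
}

#' Group a simulated genome's junctions into clusters by ground truth
#'
#' Builds one `sv_cluster` per true event from the simulator's truth table;
#' used to evaluate the classifier independently of the clustering step.
#' Footprints are breakend runs separated by more than `fp_gap` bp.
#'
#' @param sv The simulated `sv_set`.
#' @param truth The truth table from [simulate_genome()].
#' @param fp_gap Footprint gap threshold (default 1e5).
#' @return List of `sv_cluster` objects in truth order.
#' @export
clusters_from_truth <- function(sv, truth, fp_gap = 1e5) {
  lapply(seq_len(nrow(truth)), function(r) {
    ids <- strsplit(truth$junction_ids[r], ",")[[1]]
    j <- sv$junctions[sv$junctions$id %in% ids, , drop = FALSE]
    be <- breakend_table(j)
    be <- be[order(chrom_rank(sv$build, be$chrom), be$pos), , drop = FALSE]
    fp_id <- integer(nrow(be)); cur <- 1L; fp_id[1] <- cur
    if (nrow(be) > 1) for (k in 2:nrow(be)) {
      if (be$chrom[k] != be$chrom[k - 1] ||
          (be$pos[k] - be$pos[k - 1]) > fp_gap) cur <- cur + 1L
      fp_id[k] <- cur
    }
    be$footprint <- fp_id
    fps <- do.call(rbind, lapply(split(be, be$footprint), function(g)
      data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
                 n_breakends = nrow(g),
                 pattern = paste(ifelse(g$side == "left", "L", "R"),
                                 collapse = ""),
                 stringsAsFactors = FALSE)))
    rownames(fps) <- NULL
    structure(list(id = truth$event_id[r], sample = sv$sample,
                   junctions = j, breakends = be, footprints = fps,
                   n_junctions = nrow(j), model = NULL),
              class = "sv_cluster")
  })
}

#' Write simulator outputs to a directory
#'
#' Emits BEDPE junctions, a copy-number TSV, the truth table, and a YAML echo
#' of the configuration; identical config and seed reproduce the files
#' byte-identically.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The `sim_config` used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_outputs <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bedpe = file.path(dir, "junctions.bedpe"),
             cn = file.path(dir, "copy_number.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "sim_config.yaml"))
  write_bedpe(sim$sv$junctions, paths["bedpe"])
  utils::write.table(
    data.frame(chrom = sim$sv$segments$chrom,
               start = format_bp(sim$sv$segments$start),
               end = format_bp(sim$sv$segments$end),
               total_cn = sprintf("%.4f", sim$sv$segments$total_cn)),
    paths["cn"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(seed = config$seed, build = config$build$name,
                        intensities = as.list(config$intensities),
                        background = config$background,
                        cn_noise_sd = config$cn_noise_sd),
                   paths["config"])
  invisible(paths)
}
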