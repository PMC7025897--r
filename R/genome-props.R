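# Genome-property association testing on a 1-kb pixel grid, junction-partner
# permutation enrichment, footprint connectivity, and the three-regime fit to
# the junction microhomology spectrum.

#' Tile a genome build into fixed-size pixels
#'
#' Consecutive bins per chromosome; the final partial bin counts as one bin.
#'
#' @param build A `genome_build`.
#' @param bin_size Bin size in bp (default 1000).
#' @return A `pixel_grid` with per-chromosome bin counts, cumulative offsets
#'   and `total_bins`.
#' @export
tile_genome <- function(build, bin_size = 1000) {
  stopifnot(bin_size > 0)
  nb <- ceiling(build$chromosomes$length / bin_size)
  structure(list(build = build, bin_size = bin_size,
                 n_bins = stats::setNames(nb, build$chromosomes$chrom),
                 offsets = stats::setNames(c(0, cumsum(nb))[seq_along(nb)],
                                           build$chromosomes$chrom),
                 total_bins = sum(nb)),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid: %d bins of %d bp over %d chromosomes>\n",
              x$total_bins, x$bin_size, length(x$n_bins)))
  invisible(x)
}

#' Map genomic positions to pixel indices
#' @param grid A `pixel_grid`.
#' @param chrom,pos Position vectors.
#' @return Integer pixel indices in `1..total_bins`.
#' @export
pos_to_pixel <- function(grid, chrom, pos) {
  as.integer(grid$offsets[chrom] + floor(pos / grid$bin_size) + 1)
}

#' Create a property track over a pixel grid
#' @param name Track name.
#' @param values Numeric vector of length `total_bins` (NA = missing pixel).
#' @param grid The `pixel_grid`.
#' @param orientation Free-text note on what high values mean.
#' @return A `property_track`.
#' @export
property_track <- function(name, values, grid, orientation = "") {
  stopifnot(length(values) == grid$total_bins)
  structure(list(name = name, values = as.numeric(values),
                 orientation = orientation, bin_size = grid$bin_size),
            class = "property_track")
}

#' Read a bedGraph/BED numeric track onto a pixel grid
#'
#' Four columns (chrom, start, end, value); values are averaged into the grid
#' pixels weighted by coverage. Pixels with no data are flagged missing (NA).
#'
#' @param path bedGraph or 4-column BED path.
#' @param grid A `pixel_grid`.
#' @param name Track name (default: file name).
#' @return A `property_track`.
#' @export
read_track <- function(path, grid, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    data.table::fread(path, header = FALSE, data.table = FALSE),
    error = function(e) data.frame())
  vals <- rep(NA_real_, grid$total_bins)
  if (nrow(tab) == 0) {
    warning("empty track file: ", path)
    return(property_track(name, vals, grid))
  }
  if (ncol(tab) < 4) stop("track file must have 4 columns (chrom,start,end,value)")
  v <- suppressWarnings(as.numeric(tab[[4]]))
  if (any(is.na(v) & !is.na(tab[[4]])))
    stop("non-numeric track value at line ", which(is.na(v) & !is.na(tab[[4]]))[1])
  tab <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]), end = as.numeric(tab[[3]]),
                    value = v, stringsAsFactors = FALSE)
  tab <- tab[tab$chrom %in% names(grid$n_bins), , drop = FALSE]
  bs <- grid$bin_size
  num <- rep(0, grid$total_bins)
  den <- rep(0, grid$total_bins)
  for (r in seq_len(nrow(tab))) {
    p1 <- floor(tab$start[r] / bs)
    p2 <- floor((tab$end[r] - 1) / bs)
    px <- grid$offsets[tab$chrom[r]] + (p1:p2) + 1
    lo <- pmax(tab$start[r], (p1:p2) * bs)
    hi <- pmin(tab$end[r], (p1:p2 + 1) * bs)
    keep <- px >= 1 & px <= grid$total_bins
    num[px[keep]] <- num[px[keep]] + tab$value[r] * (hi - lo)[keep]
    den[px[keep]] <- den[px[keep]] + (hi - lo)[keep]
  }
  vals[den > 0] <- num[den > 0] / den[den > 0]
  property_track(name, vals, grid)
}

# one-sided two-sample KS on pooled mid-rank quantiles: D+ favours observed
# values shifted HIGH, D- shifted LOW
ks_directional <- function(obs_q, rand_q) {
  all_t <- sort(unique(c(obs_q, rand_q)))
  Fo <- stats::ecdf(obs_q)(all_t)
  Fr <- stats::ecdf(rand_q)(all_t)
  d_low <- max(Fo - Fr)    # observed mass at small values
  d_high <- max(Fr - Fo)
  n_eff <- length(obs_q) * length(rand_q) / (length(obs_q) + length(rand_q))
  p_of <- function(d) exp(-2 * n_eff * d^2)
  if (d_high >= d_low) {
    list(statistic = d_high, p = min(p_of(d_high), 1), direction = "high")
  } else {
    list(statistic = -d_low, p = min(p_of(d_low), 1), direction = "low")
  }
}

#' Test association between breakpoint positions and a genome property
#'
#' One side of each junction is chosen at random (to reduce dependence
#' between observations), observed positions are pooled with uniform random
#' positions from the non-missing pixels, jointly rank-transformed to
#' `[0, 1]` with mid-ranks, and the observed quantiles are compared to the
#' random ones with a one-sided Kolmogorov-Smirnov test (the larger of the
#' two one-sided statistics, reported with sign: negative = enriched at low
#' property values).
#'
#' @param j Junction data frame.
#' @param track A `property_track`.
#' @param grid The `pixel_grid`.
#' @param n_random Number of random positions (default 1e4; the study-scale
#'   default of 1e6 is a parameter away).
#' @param seed Integer seed.
#' @return An `association_result` list: n_obs, statistic, p, median_quantile,
#'   flag.
#' @export
property_quantile_test <- function(j, track, grid, n_random = 1e4, seed = 1) {
  rng <- local_rng(seed)
  pick2 <- rng$runif(nrow(j)) < 0.5
  chrom <- ifelse(pick2, j$chrom2, j$chrom1)
  pos <- ifelse(pick2, j$pos2, j$pos1)
  px <- pos_to_pixel(grid, chrom, pos)
  obs <- track$values[px]
  obs <- obs[!is.na(obs)]
  flag <- if (length(obs) < 10) "underpowered" else ""
  ok_pix <- which(!is.na(track$values))
  if (length(ok_pix) == 0 || length(obs) == 0)
    return(structure(list(n_obs = length(obs), statistic = NA_real_, p = NA_real_,
                          median_quantile = NA_real_, flag = "no_data"),
                     class = "association_result"))
  rnd <- track$values[ok_pix[ceiling(rng$runif(n_random) * length(ok_pix))]]
  pooled <- c(obs, rnd)
  q <- (rank(pooled, ties.method = "average") - 0.5) / length(pooled)
  obs_q <- q[seq_along(obs)]
  rand_q <- q[-seq_along(obs)]
  ks <- ks_directional(obs_q, rand_q)
  structure(list(n_obs = length(obs), statistic = ks$statistic, p = ks$p,
                 median_quantile = stats::median(obs_q), flag = flag),
            class = "association_result")
}

#' Association suite over event classes and property tracks
#'
#' Runs [property_quantile_test()] for every (event class, track) pair and
#' applies a Benjamini-Yekutieli false-discovery-rate correction across the
#' entire suite; pairs with `q < alpha` are flagged significant.
#'
#' @param class_junctions Named list: event class -> junction data frame.
#' @param tracks Named list of `property_track`.
#' @param grid The `pixel_grid`.
#' @param alpha Significance threshold on q (default 0.01).
#' @param n_random,seed Passed to the per-pair test.
#' @return Data frame with one row per pair: class, property, n_obs,
#'   statistic, p, q, median_quantile, significant.
#' @export
association_suite <- function(class_junctions, tracks, grid, alpha = 0.01,
                              n_random = 1e4, seed = 1) {
  rows <- list()
  i <- 0
  for (cl in names(class_junctions)) {
    for (tr in names(tracks)) {
      i <- i + 1
      r <- property_quantile_test(class_junctions[[cl]], tracks[[tr]], grid,
                                  n_random = n_random, seed = seed + i)
      rows[[i]] <- data.frame(class = cl, property = tr, n_obs = r$n_obs,
                              statistic = r$statistic, p = r$p,
                              median_quantile = r$median_quantile,
                              flag = r$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BY")
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}

# shared permutation machinery: endpoints come in linked consecutive pairs
pair_label_enrichment <- function(labels, n_perm = 1000, seed = 1) {
  m <- length(labels)
  if (m %% 2 != 0) stop("odd number of endpoints after filtering")
  n_pairs <- m / 2
  rng <- local_rng(seed)
  pair_key <- function(lab) {
    a <- lab[seq(1, m, 2)]; b <- lab[seq(2, m, 2)]
    paste(pmin(a, b), pmax(a, b), sep = "~")
  }
  obs <- table(pair_key(labels))
  classes <- sort(unique(names(obs)))
  perm_counts <- matrix(0, n_perm, length(classes),
                        dimnames = list(NULL, classes))
  for (p in seq_len(n_perm)) {
    shuffled <- labels[order(rng$runif(m))]
    tt <- table(pair_key(shuffled))
    hit <- intersect(names(tt), classes)
    perm_counts[p, hit] <- as.integer(tt[hit])
  }
  mu <- colMeans(perm_counts)
  sd_ <- apply(perm_counts, 2, stats::sd)
  data.frame(pair = classes,
             observed = as.integer(obs[classes]),
             perm_mean = mu, perm_sd = sd_,
             fold_change = as.numeric(obs[classes]) / ifelse(mu > 0, mu, NA),
             z = (as.numeric(obs[classes]) - mu) / ifelse(sd_ > 0, sd_, NA),
             flag = if (n_pairs < 2) "degenerate" else "",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Junction-partner permutation enrichment
#'
#' Counts junctions joining pairs of pixel annotation classes and compares
#' against a permuted background that preserves every breakend's position and
#' side but re-pairs breakends uniformly at random within the sample.
#'
#' @param j Junction data frame (one sample, or pooled with care).
#' @param annot Character vector of per-pixel annotation labels (length
#'   `total_bins`; NA pixels are filtered together with their junction).
#' @param grid The `pixel_grid`.
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param seed Integer seed.
#' @return Data frame: pair, observed, perm_mean, perm_sd, fold_change, z.
#' @export
partner_permutation_enrichment <- function(j, annot, grid, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  l1 <- annot[pos_to_pixel(grid, j$chrom1, j$pos1)]
  l2 <- annot[pos_to_pixel(grid, j$chrom2, j$pos2)]
  keep <- !is.na(l1) & !is.na(l2)
  labels <- as.vector(rbind(l1[keep], l2[keep]))  # consecutive pairs linked
  pair_label_enrichment(labels, n_perm = n_perm, seed = seed)
}

#' Footprint connectivity enrichment
#'
#' Applies the junction-partner permutation machinery to footprint structure
#' types: footprints joined by inter-footprint junctions are counted as linked
#' pairs of their local side-pattern types and compared against random
#' re-pairing.
#'
#' @param clusters List of `sv_cluster` (typically pooled across samples).
#' @param n_perm,seed Permutation parameters.
#' @return Data frame as for [partner_permutation_enrichment()].
#' @export
footprint_connectivity <- function(clusters, n_perm = 1000, seed = 1) {
  labels <- character(0)
  for (cl in clusters) {
    be <- cl$breakends
    if (is.null(be$footprint) || length(unique(be$footprint)) < 2) next
    fp_type <- stats::setNames(cl$footprints$pattern, seq_len(nrow(cl$footprints)))
    for (q in unique(be$junction)) {
      rows <- be[be$junction == q, ]
      if (nrow(rows) == 2 && rows$footprint[1] != rows$footprint[2]) {
        labels <- c(labels, fp_type[as.character(rows$footprint[1])],
                    fp_type[as.character(rows$footprint[2])])
      }
    }
  }
  if (length(labels) < 2) stop("no inter-footprint junctions found")
  out <- pair_label_enrichment(labels, n_perm = n_perm, seed = seed)
  if (length(unique(labels)) == 1) out$flag <- "degenerate"
  out
}

#' Fit the three-regime model to a junction microhomology spectrum
#'
#' Rearrangement counts as a function of junction microhomology length are
#' fit with three straight lines on log10(count + 1): an NHEJ regime below
#' `b1`, an MMEJ regime on `[b1, b2)` and an SSA regime at `>= b2`.
#' Changepoints are found by exhaustive grid search minimizing the summed
#' residual sum of squares; ties keep the first (smallest) grid values.
#'
#' @param counts Non-negative counts indexed by homology length 0..max bp.
#' @param b1_range Candidate first changepoints (default 1:8).
#' @param b2_range Candidate second changepoints (default 8:15).
#' @return A `microhomology_fit`: b1, b2, per-regime slope/intercept, labels,
#'   rss, fitted values.
#' @export
fit_microhomology_regimes <- function(counts, b1_range = 1:8, b2_range = 8:15) {
  if (any(counts < 0)) stop("counts must be non-negative")
  max_len <- length(counts) - 1
  if (max_len < min(b2_range)) stop("histogram shorter than the b2 search range")
  b2_range <- b2_range[b2_range <= max_len]
  x <- 0:max_len
  y <- log10(counts + 1)
  fit_piece <- function(idx) {
    if (length(idx) == 1)
      return(list(slope = 0, intercept = y[idx], rss = 0,
                  fitted = y[idx]))
    f <- stats::lm.fit(cbind(1, x[idx]), y[idx])
    list(slope = unname(f$coefficients[2]), intercept = unname(f$coefficients[1]),
         rss = sum(f$residuals^2), fitted = f$fitted.values)
  }
  best <- NULL
  for (b1 in b1_range) for (b2 in b2_range) {
    if (b1 >= b2) next
    i1 <- which(x < b1); i2 <- which(x >= b1 & x < b2); i3 <- which(x >= b2)
    if (!length(i1) || !length(i2) || !length(i3)) next
    f1 <- fit_piece(i1); f2 <- fit_piece(i2); f3 <- fit_piece(i3)
    rss <- f1$rss + f2$rss + f3$rss
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(b1 = b1, b2 = b2, rss = rss,
                   slopes = c(NHEJ = f1$slope, MMEJ = f2$slope, SSA = f3$slope),
                   intercepts = c(NHEJ = f1$intercept, MMEJ = f2$intercept,
                                  SSA = f3$intercept),
                   fitted = c(f1$fitted, f2$fitted, f3$fitted))
    }
  }
  structure(c(best, list(labels = c("NHEJ", "MMEJ", "SSA"), x = x, y = y)),
            class = "microhomology_fit")
}

#' @export
print.microhomology_fit <- function(x, ...) {
  cat(sprintf("<microhomology_fit: b1=%d b2=%d, slopes NHEJ %.3f / MMEJ %.3f / SSA %.3f>\n",
              x$b1, x$b2, x$slopes[1], x$slopes[2], x$slopes[3]))
  invisible(x)
}
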