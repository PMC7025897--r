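# Structural-variant signature analysis: the category catalogue, the
# patients x categories count matrix, NMF extraction with stability-based
# rank selection, an optional hierarchical Dirichlet process backend,
# split-half stability, and driver-gene association.

#' Default structural-variant category catalogue
#'
#' Deletions and tandem duplications are split into 11 categories by size
#' (< 50 kb, 50-500 kb, > 500 kb), replication timing (early/late, tandem
#' duplications only) and fragile-site overlap; further categories cover
#' reciprocal inversions (small/large at 500 kb), translocations,
#' chromoplexy, fold-back inversions (with a translocation-adjacent
#' subtype), templated-insertion cycles/bridges/chains split at 100 kb of
#' total template span, the local 2-jump subtypes, local n-jumps,
#' local-distant clusters, and a complex/unclassified remainder.
#'
#' @return A `category_catalogue` with `categories` (ordered names),
#'   `version`, and `assign(event_class, size, rt, fragile)` returning one
#'   category per event.
#' @export
default_catalogue <- function() {
  categories <- c(
    "del_<50kb", "del_50-500kb", "del_>500kb",
    "td_<50kb_early", "td_<50kb_late", "td_50-500kb_early", "td_50-500kb_late",
    "td_>500kb_early", "td_>500kb_late",
    "fragile_del", "fragile_td",
    "recip_inv_<500kb", "recip_inv_>500kb",
    "unbal_translocation", "recip_translocation", "chromoplexy",
    "foldback_inv", "tra_adjacent_foldback",
    "cycle_<=100kb", "cycle_>100kb", "bridge_<=100kb", "bridge_>100kb",
    "chain_<=100kb", "chain_>100kb",
    "two_jump_dup_trp_dup", "two_jump_inverted_dups", "two_jump_del_invdup",
    "local_n_jump", "local_distant", "chromothripsis_like",
    "complex_unclassified")
  size_bin <- function(size) {
    ifelse(is.na(size), "50-500kb",
           ifelse(size < 5e4, "<50kb", ifelse(size <= 5e5, "50-500kb", ">500kb")))
  }
  assign_one <- function(event_class, size, rt, fragile) {
    switch(event_class,
      deletion = if (isTRUE(fragile)) "fragile_del"
                 else paste0("del_", size_bin(size)),
      tandem_duplication = if (isTRUE(fragile)) "fragile_td"
                           else paste0("td_", size_bin(size), "_",
                                       if (identical(rt, "late")) "late" else "early"),
      reciprocal_inversion = if (!is.na(size) && size > 5e5) "recip_inv_>500kb"
                             else "recip_inv_<500kb",
      unbalanced_translocation = "unbal_translocation",
      reciprocal_translocation = "recip_translocation",
      chromoplexy = "chromoplexy",
      foldback_inversion = "foldback_inv",
      templated_insertion_cycle = if (!is.na(size) && size > 1e5) "cycle_>100kb"
                                  else "cycle_<=100kb",
      templated_insertion_bridge = if (!is.na(size) && size > 1e5) "bridge_>100kb"
                                   else "bridge_<=100kb",
      templated_insertion_chain = if (!is.na(size) && size > 1e5) "chain_>100kb"
                                  else "chain_<=100kb",
      local_2jump_dup_trp_dup = "two_jump_dup_trp_dup",
      local_2jump_inverted_dups = "two_jump_inverted_dups",
      local_2jump_del_invdup = "two_jump_del_invdup",
      local_n_jump = "local_n_jump",
      local_distant = "local_distant",
      chromothripsis_like = "chromothripsis_like",
      "complex_unclassified")
  }
  structure(list(
    categories = categories,
    version = "catalogue-1",
    assign = function(event_class, size, rt, fragile) {
      vapply(seq_along(event_class), function(i)
        assign_one(event_class[i], size[i], rt[i], isTRUE(fragile[i])),
        character(1))
    }), class = "category_catalogue")
}

# per-cluster size used for category binning: breakend span for intra-
# chromosomal simple events, total template span for templated insertions
cluster_event_size <- function(x) {
  cls <- x$event_class
  if (cls %in% c("templated_insertion_cycle", "templated_insertion_bridge",
                 "templated_insertion_chain")) {
    p <- x$details$path
    if (!is.null(p)) return(sum(p$templates$end - p$templates$start))
    return(NA_real_)
  }
  fp <- x$footprints
  j <- NULL
  if (!is.null(fp) && nrow(fp) >= 1 && length(unique(fp$chrom)) == 1)
    return(max(fp$end) - min(fp$start))
  NA_real_
}

#' Build the patients x categories count matrix
#'
#' @param per_sample Named list: sample -> `classify_all()` result (or a list
#'   with `classifications`).
#' @param catalogue A `category_catalogue`.
#' @param fragile_sites Optional data frame (chrom, start, end); a cluster
#'   overlapping any interval with any breakend is flagged fragile.
#' @param rt_track Optional `property_track` of replication timing (higher =
#'   earlier); the early/late split is at the track median over non-missing
#'   pixels.
#' @param grid `pixel_grid` (required with `rt_track`).
#' @param min_cohort_count Categories outside the deletion/TD core with fewer
#'   total cohort counts are folded into `complex_unclassified` (default 0 =
#'   keep all; the study-scale setting is 50).
#' @return Integer matrix patients x categories.
#' @export
build_category_counts <- function(per_sample, catalogue,
                                  fragile_sites = NULL, rt_track = NULL,
                                  grid = NULL, min_cohort_count = 0) {
  cats <- catalogue$categories
  rt_split <- NA_real_
  if (!is.null(rt_track)) rt_split <- stats::median(rt_track$values, na.rm = TRUE)
  mat <- matrix(0L, length(per_sample), length(cats),
                dimnames = list(names(per_sample), cats))
  for (s in names(per_sample)) {
    cls <- per_sample[[s]]$classifications
    if (length(cls) == 0) next
    for (x in cls) {
      size <- cluster_event_size(x)
      fp <- x$footprints
      rt <- "early"
      fragile <- FALSE
      if (!is.null(fp) && nrow(fp)) {
        if (!is.null(rt_track) && !is.null(grid) && !is.na(rt_split)) {
          v <- rt_track$values[pos_to_pixel(grid, fp$chrom[1], fp$start[1])]
          if (!is.na(v) && v < rt_split) rt <- "late"
        }
        if (!is.null(fragile_sites)) {
          for (r in seq_len(nrow(fp))) {
            hit <- fragile_sites$chrom == fp$chrom[r] &
              fragile_sites$start <= fp$end[r] & fragile_sites$end >= fp$start[r]
            if (any(hit)) fragile <- TRUE
          }
        }
      }
      cat_name <- catalogue$assign(x$event_class, size, rt, fragile)
      mat[s, cat_name] <- mat[s, cat_name] + 1L
    }
  }
  if (min_cohort_count > 0) {
    core <- grepl("^(del_|td_|fragile_)", cats)
    weak <- !core & colSums(mat) < min_cohort_count & cats != "complex_unclassified"
    if (any(weak)) {
      mat[, "complex_unclassified"] <- mat[, "complex_unclassified"] +
        rowSums(mat[, weak, drop = FALSE])
      mat <- mat[, !weak, drop = FALSE]
    }
  }
  mat
}

kl_div <- function(V, WH) {
  eps <- 1e-12
  sum(V * log((V + eps) / (WH + eps)) - V + WH)
}

nmf_kl_once <- function(V, K, rng, n_iter = 500, tol = 1e-6) {
  n <- nrow(V); C <- ncol(V)
  W <- matrix(rng$runif(n * K, 0.1, 1), n, K)
  H <- matrix(rng$runif(K * C, 0.1, 1), K, C)
  eps <- 1e-12
  last <- Inf
  for (it in seq_len(n_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H) + eps, n, K, byrow = TRUE)
    if (it %% 25 == 0) {
      d <- kl_div(V, W %*% H)
      if (abs(last - d) < tol * (abs(last) + 1)) break
      last <- d
    }
  }
  list(W = W, H = H, kl = kl_div(V, W %*% H + eps))
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match two signature sets by cosine similarity
#'
#' Exhaustive assignment for up to 7 signatures (optimal), greedy beyond.
#'
#' @param A,B Matrices with one signature per row (same column space).
#' @return List with `perm` (row of B matched to each row of A) and
#'   `cosines`.
#' @export
match_signatures <- function(A, B) {
  KA <- nrow(A); KB <- nrow(B)
  cm <- matrix(0, KA, KB)
  for (i in seq_len(KA)) for (j in seq_len(KB)) cm[i, j] <- cosine(A[i, ], B[j, ])
  if (KA == KB && KA <= 7) {
    best <- NULL
    for (p in perms_of(KA)) {
      sc <- sum(cm[cbind(seq_len(KA), p)])
      if (is.null(best) || sc > best$score) best <- list(perm = p, score = sc)
    }
    perm <- best$perm
  } else {
    # unequal sizes (or large K): greedy best-first without reuse
    perm <- rep(NA_integer_, KA)
    left <- seq_len(KB)
    for (i in order(-apply(cm, 1, max))) {
      if (!length(left)) break
      j <- left[which.max(cm[i, left])]
      perm[i] <- j
      left <- setdiff(left, j)
    }
  }
  matched <- !is.na(perm)
  cosines <- rep(NA_real_, KA)
  cosines[matched] <- cm[cbind(which(matched), perm[matched])]
  list(perm = perm, cosines = cosines)
}

#' Extract structural-variant signatures by NMF
#'
#' KL-divergence (Poisson likelihood) non-negative matrix factorization with
#' multiplicative updates and multiple seeded restarts per rank. For each
#' candidate K, stability is the mean cosine of restart signatures matched to
#' the best-likelihood restart; the chosen K maximizes stability (ties go to
#' the smaller rank). Signature rows are renormalized to sum to one with
#' exposures rescaled compensatingly.
#'
#' @param counts Patients x categories count matrix.
#' @param k_range Candidate ranks (default 2:5).
#' @param n_restarts Restarts per rank (default 30).
#' @param seed Integer seed.
#' @param n_iter Update iterations per restart.
#' @return A `signature_set`: `signatures` (K x C, rows sum to 1),
#'   `exposures` (patients x K), `k`, and a per-rank `report` (stability,
#'   reconstruction error, flags).
#' @export
extract_signatures_nmf <- function(counts, k_range = 2:5, n_restarts = 30,
                                   seed = 1, n_iter = 500) {
  V <- as.matrix(counts)
  zero_rows <- rowSums(V) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero patient row(s) dropped")
    V <- V[!zero_rows, , drop = FALSE]
  }
  if (nrow(V) == 0 || ncol(V) < 2) stop("count matrix too small for extraction")
  k_range <- k_range[k_range >= 1 & k_range <= min(dim(V)) - 1]
  if (length(k_range) == 0) stop("no admissible K in k_range")
  report <- data.frame(k = k_range, stability = NA_real_, kl = NA_real_)
  best_fit <- list()
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    fits <- lapply(seq_len(n_restarts), function(r)
      nmf_kl_once(V, K, local_rng(derive_seed(seed, K * 1000 + r)), n_iter = n_iter))
    ref <- fits[[which.min(vapply(fits, `[[`, numeric(1), "kl"))]]
    cos_all <- unlist(lapply(fits, function(f)
      match_signatures(ref$H, f$H)$cosines))
    report$stability[ki] <- mean(cos_all)
    report$kl[ki] <- ref$kl
    best_fit[[ki]] <- ref
  }
  # rank selection: among stable ranks (restart stability >= 0.95), take the
  # largest K whose reconstruction error still improves substantially (>= 20%
  # KL drop) over the next-smaller rank; the first rank in range is measured
  # against the closed-form rank-1 baseline.  When no rank is both stable and
  # improving, the data carry no resolvable multi-signature structure: the
  # report is flagged and the most stable rank is returned.
  h0 <- colSums(V) / sum(V)
  kl0 <- kl_div(V, outer(rowSums(V), h0))
  degenerate <- kl0 <= 1e-8 * max(1, sum(V))
  rel_impr <- c((kl0 - report$kl[1]) / max(kl0, 1e-12),
                -diff(report$kl) / pmax(report$kl[-length(report$kl)], 1e-12))
  stable <- report$stability >= 0.95
  cand <- which(stable & rel_impr >= 0.2)
  no_stable <- length(cand) == 0
  if (degenerate) {
    # the rank-1 spectrum reconstructs the data exactly: return the smallest
    # rank in range with every signature row equal to that spectrum
    pick <- 1L
    K1 <- k_range[1]
    best_fit[[1]] <- list(H = matrix(rep(h0, each = K1), K1, ncol(V)),
                          W = outer(rowSums(V), rep(1 / K1, K1)),
                          kl = kl0)
    warning("count matrix is effectively rank 1; returning the smallest rank ",
            "in k_range with collinear signatures")
  } else {
    pick <- if (!no_stable) max(cand)
            else which.max(report$stability)
    if (no_stable)
      warning("no rank in k_range is both stable and substantially improving; ",
              "no stable multi-signature solution")
  }
  K <- k_range[pick]
  fit <- best_fit[[pick]]
  rs <- rowSums(fit$H)
  H <- fit$H / rs
  W <- sweep(fit$W, 2, rs, "*")
  rownames(H) <- paste0("S", seq_len(K))
  colnames(H) <- colnames(V)
  colnames(W) <- rownames(H)
  rownames(W) <- rownames(V)
  structure(list(signatures = H, exposures = W, k = K, report = report,
                 no_stable = no_stable, method = "nmf-kl", seed = seed),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set: %d signatures x %d categories (%s)>\n",
              nrow(x$signatures), ncol(x$signatures), x$method))
  invisible(x)
}

#' Extract signatures with a hierarchical Dirichlet process (optional backend)
#'
#' Direct-assignment Gibbs sampler over a two-level Dirichlet-process mixture
#' of categorical distributions: patients are groups, individual events are
#' draws from shared global signatures whose number is inferred. Reports
#' posterior mean spectra and exposures conditional on the modal number of
#' signatures, with 95% posterior intervals per spectrum cell.
#'
#' @param counts Patients x categories count matrix.
#' @param n_chains Number of chains (default 2).
#' @param n_iter Iterations per chain (default 300; first half burn-in).
#' @param seed Integer seed.
#' @param alpha,gamma_conc,eta DP concentration (patient level, top level) and
#'   categorical Dirichlet prior.
#' @return A `signature_set` with `k` (posterior mode), `signatures`,
#'   `exposures`, `ci` (lower/upper 95% arrays) and `rhat_flag`.
#' @export
extract_signatures_hdp <- function(counts, n_chains = 2, n_iter = 300, seed = 1,
                                   alpha = 1, gamma_conc = 1, eta = 0.2) {
  V <- as.matrix(counts)
  if (nrow(V) == 0 || sum(V) == 0) stop("empty count matrix")
  C <- ncol(V)
  n_pat <- nrow(V)
  pat_of <- rep(seq_len(n_pat), rowSums(V))
  cat_of <- unlist(lapply(seq_len(n_pat), function(p)
    rep(seq_len(C), V[p, ])))
  N <- length(cat_of)
  run_chain <- function(chain) {
    rng <- local_rng(derive_seed(seed, chain))
    # start from a single dish; structure is discovered through the
    # new-dish move as items with distinctive categories seed new dishes
    K <- 1L
    z <- rep(1L, N)
    q_kc <- matrix(0, K, C)       # category counts per dish
    n_pk <- matrix(0, n_pat, K)   # items per patient per dish
    for (i in seq_len(N)) {
      q_kc[z[i], cat_of[i]] <- q_kc[z[i], cat_of[i]] + 1
      n_pk[pat_of[i], z[i]] <- n_pk[pat_of[i], z[i]] + 1
    }
    beta <- rep(1 / (K + 1), K + 1)  # K dish weights + remainder mass
    keep <- list()
    half <- floor(n_iter / 2)
    for (it in seq_len(n_iter)) {
      ord <- rng$sample_int(N, N)
      for (i in ord) {
        k0 <- z[i]; p0 <- pat_of[i]; c0 <- cat_of[i]
        q_kc[k0, c0] <- q_kc[k0, c0] - 1
        n_pk[p0, k0] <- n_pk[p0, k0] - 1
        if (sum(q_kc[k0, ]) == 0 && K > 1) {
          # retire empty dish; its weight returns to the remainder mass
          q_kc <- q_kc[-k0, , drop = FALSE]
          n_pk <- n_pk[, -k0, drop = FALSE]
          beta <- c(beta[-c(k0, K + 1)], beta[K + 1] + beta[k0])
          K <- K - 1L
          z[z > k0] <- z[z > k0] - 1L
        }
        lik <- (q_kc[, c0] + eta) / (rowSums(q_kc) + C * eta)
        pr <- (n_pk[p0, ] + alpha * beta[seq_len(K)]) * lik
        pr_new <- alpha * beta[K + 1] / C
        probs <- c(pr, pr_new)
        k1 <- rng$sample_int(K + 1L, 1L, prob = probs)
        if (k1 == K + 1L) {
          K <- K + 1L
          q_kc <- rbind(q_kc, 0)
          n_pk <- cbind(n_pk, 0)
          b <- rng$runif(1) ^ (1 / gamma_conc)  # stick-break the remainder
          beta <- c(beta[seq_len(K - 1)], beta[K] * (1 - b), beta[K] * b)
        }
        z[i] <- k1
        q_kc[k1, cat_of[i]] <- q_kc[k1, cat_of[i]] + 1
        n_pk[p0, k1] <- n_pk[p0, k1] + 1
      }
      # resample global weights from dish usage
      m_k <- colSums(n_pk > 0)
      beta <- local({
        g <- rng$rgamma(K + 1, c(m_k + 1e-6, gamma_conc), rate = 1)
        g / sum(g)
      })
      if (it > half) {
        keep[[length(keep) + 1L]] <- list(K = K, q_kc = q_kc, n_pk = n_pk)
      }
    }
    keep
  }
  chains <- lapply(seq_len(n_chains), run_chain)
  # effective K per sample: dishes holding at least 2% of all events (tiny
  # transient dishes are a normal feature of the sampler, not signatures)
  k_eff <- function(s) sum(rowSums(s$q_kc) >= max(2, 0.02 * N))
  ks <- lapply(chains, function(ch) vapply(ch, k_eff, integer(1)))
  k_all <- unlist(ks)
  k_mode <- as.integer(names(sort(table(k_all), decreasing = TRUE))[1])
  # split-Rhat on K
  rhat <- {
    mlist <- unlist(lapply(ks, function(v) {
      h <- floor(length(v) / 2)
      list(v[seq_len(h)], v[h + seq_len(h)])
    }), recursive = FALSE)
    means <- vapply(mlist, mean, numeric(1))
    vars <- vapply(mlist, stats::var, numeric(1))
    W <- mean(vars)
    B <- stats::var(means) * length(mlist[[1]])
    if (is.na(W) || W == 0) 1 else sqrt((W * (1 - 1 / length(mlist[[1]])) +
                                           B / length(mlist[[1]])) / W)
  }
  # aggregate samples at the modal effective K (top dishes by usage),
  # matched to a reference by cosine
  samples <- Filter(function(s) k_eff(s) == k_mode,
                    unlist(chains, recursive = FALSE))
  if (length(samples) == 0) stop("no posterior samples at the modal K")
  spec_of <- function(s) {
    ord <- order(-rowSums(s$q_kc))[seq_len(k_mode)]
    H <- (s$q_kc[ord, , drop = FALSE] + eta) /
      (rowSums(s$q_kc[ord, , drop = FALSE]) + ncol(s$q_kc) * eta)
    list(H = H, ord = ord)
  }
  ref <- spec_of(samples[[length(samples)]])$H
  arr <- array(NA_real_, c(length(samples), k_mode, C))
  expo <- array(0, c(length(samples), n_pat, k_mode))
  for (si in seq_along(samples)) {
    sp <- spec_of(samples[[si]])
    mt <- match_signatures(ref, sp$H)
    arr[si, , ] <- sp$H[mt$perm, , drop = FALSE]
    npk <- samples[[si]]$n_pk[, sp$ord, drop = FALSE]
    expo[si, , ] <- npk[, mt$perm, drop = FALSE]
  }
  H_mean <- apply(arr, c(2, 3), mean)
  H_mean <- H_mean / rowSums(H_mean)
  ci_lo <- apply(arr, c(2, 3), stats::quantile, 0.025)
  ci_hi <- apply(arr, c(2, 3), stats::quantile, 0.975)
  W_mean <- apply(expo, c(2, 3), mean)
  rownames(H_mean) <- paste0("S", seq_len(k_mode))
  colnames(H_mean) <- colnames(V)
  structure(list(signatures = H_mean, exposures = W_mean, k = k_mode,
                 ci = list(lower = ci_lo, upper = ci_hi),
                 rhat = rhat, rhat_flag = !is.na(rhat) && rhat > 1.2,
                 method = "hdp-gibbs", seed = seed),
            class = "signature_set")
}

#' Split-half signature stability
#'
#' Randomly splits the cohort into two halves, extracts signatures in each,
#' and reports the cosines of Hungarian-matched signature pairs.
#'
#' @param counts Patients x categories count matrix (>= 20 patients).
#' @param extractor Extraction function (default [extract_signatures_nmf()]).
#' @param seed Integer seed.
#' @param ... Passed to the extractor.
#' @return Data frame of matched signature pairs and cosines.
#' @export
split_half_stability <- function(counts, extractor = extract_signatures_nmf,
                                 seed = 1, ...) {
  n <- nrow(counts)
  if (n < 20) stop("split-half stability needs >= 20 patients")
  rng <- local_rng(seed)
  half <- rng$sample_int(n, floor(n / 2))
  s1 <- extractor(counts[half, , drop = FALSE], seed = derive_seed(seed, 1), ...)
  s2 <- extractor(counts[-half, , drop = FALSE], seed = derive_seed(seed, 2), ...)
  k <- min(nrow(s1$signatures), nrow(s2$signatures))
  A <- s1$signatures[seq_len(k), , drop = FALSE]
  B <- s2$signatures[seq_len(k), , drop = FALSE]
  mt <- match_signatures(A, B)
  data.frame(half1 = rownames(A), half2 = rownames(B)[mt$perm],
             cosine = mt$cosines, stringsAsFactors = FALSE)
}

#' Associate driver-gene status with signature exposures
#'
#' Per (gene group, signature): a linear model of exposure on gene status
#' with histology indicators as covariates; two-sided test on the gene
#' coefficient, Benjamini-Hochberg correction across all pairs. Gene groups
#' pool related genes (mutated = any member mutated).
#'
#' @param exposures Patients x signatures matrix.
#' @param gene_status Patients x genes binary matrix (same row order).
#' @param histology Factor/character vector of histology labels per patient.
#' @param gene_groups Optional named list: group -> member genes.
#' @param min_mutated Genes mutated in fewer patients are skipped (default 3).
#' @return Data frame: gene, signature, effect, p, q, n_mutated.
#' @export
associate_drivers <- function(exposures, gene_status, histology,
                              gene_groups = NULL, min_mutated = 3) {
  gene_status <- as.matrix(gene_status)
  stopifnot(nrow(gene_status) == nrow(exposures),
            length(histology) == nrow(exposures))
  groups <- if (is.null(gene_groups))
    stats::setNames(as.list(colnames(gene_status)), colnames(gene_status))
  else gene_groups
  hist_f <- factor(histology)
  rows <- list()
  for (g in names(groups)) {
    members <- intersect(groups[[g]], colnames(gene_status))
    if (length(members) == 0) next
    status <- as.integer(rowSums(gene_status[, members, drop = FALSE]) > 0)
    if (sum(status) < min_mutated) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, signature = NA_character_, effect = NA_real_, p = NA_real_,
        n_mutated = sum(status), note = "skipped: too few mutated patients",
        stringsAsFactors = FALSE)
      next
    }
    for (s in colnames(exposures)) {
      dat <- data.frame(y = exposures[, s], gene = status, hist = hist_f)
      fit <- if (nlevels(hist_f) >= 2) stats::lm(y ~ gene + hist, data = dat)
             else stats::lm(y ~ gene, data = dat)
      co <- summary(fit)$coefficients
      if (!"gene" %in% rownames(co)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, signature = s, effect = co["gene", "Estimate"],
        p = co["gene", "Pr(>|t|)"], n_mutated = sum(status), note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out
}
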