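# Independent brute-force oracles. These deliberately share no code with the
# package implementations: texture matrices are enumerated voxel by voxel,
# AUC by pair counting, the Cox partial likelihood by direct maximization.

all_offsets_26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (!(dx == 0 && dy == 0 && dz == 0))
      out[[length(out) + 1L]] <- c(dx, dy, dz)
  out
}

# GLCM pair counts: every ordered voxel pair at Chebyshev distance 1 with
# both ends in the ROI.
bf_glcm_counts <- function(lev, Ng) {
  d <- dim(lev)
  counts <- matrix(0, Ng, Ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (o in all_offsets_26()) {
      xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
        next
      b <- lev[xx, yy, zz]
      if (!is.na(b)) counts[a, b] <- counts[a, b] + 1
    }
  }
  counts
}

# Run counts per direction: walk every maximal line, splitting at level
# changes and ROI gaps.
bf_glrlm_direction <- function(lev, Ng, o) {
  d <- dim(lev)
  counts <- matrix(0, Ng, 0)
  add_run <- function(counts, level, len) {
    if (len > ncol(counts))
      counts <- cbind(counts, matrix(0, Ng, len - ncol(counts)))
    counts[level, len] <- counts[level, len] + 1
    counts
  }
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    prev <- p - o
    if (inb(prev)) next   # not a line start
    run_lev <- NA; run_len <- 0L
    while (inb(p)) {
      v <- lev[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(run_lev) && v == run_lev) {
        run_len <- run_len + 1L
      } else {
        if (!is.na(run_lev)) counts <- add_run(counts, run_lev, run_len)
        run_lev <- v; run_len <- 1L
      }
      p <- p + o
    }
    if (!is.na(run_lev)) counts <- add_run(counts, run_lev, run_len)
  }
  counts
}

# Zone sizes by iterative label propagation (26-connectivity) to a fixpoint —
# a different algorithm from the package's flood fill.
bf_zone_sizes <- function(lev) {
  d <- dim(lev)
  lab <- array(seq_len(prod(d)), dim = d)
  lab[is.na(lev)] <- NA
  repeat {
    changed <- FALSE
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (is.na(lab[x, y, z])) next
      for (o in all_offsets_26()) {
        xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
          next
        if (is.na(lab[xx, yy, zz])) next
        if (lev[xx, yy, zz] == lev[x, y, z] &&
            lab[xx, yy, zz] < lab[x, y, z]) {
          lab[x, y, z] <- lab[xx, yy, zz]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids <- lab[!is.na(lab)]
  lv <- lev[!is.na(lev)]
  t <- table(ids)
  data.frame(level = as.integer(tapply(lv, ids, function(v) v[1])),
             size = as.integer(t))
}

bf_auc <- function(x, y) {
  pos <- x[y == 1]; neg <- x[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Cox partial likelihood for a single binary covariate with untied event
# times (Efron = Breslow there), maximized by grid/golden search.
bf_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

bf_cox_mle <- function(time, event, x, lower = -8, upper = 8) {
  stats::optimize(function(b) bf_cox_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE)$maximum
}

# Two-group log-rank statistic by explicit observed/expected summation.
bf_logrank_chisq <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Random small discretized ROI for matrix-equivalence sweeps.
random_small_roi <- function(seed, max_dim = 5L, Ng = 4L) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  lev <- array(sample.int(Ng, prod(d), replace = TRUE), dim = d)
  keep <- array(runif(prod(d)) < 0.8, dim = d)
  if (!any(keep)) keep[1, 1, 1] <- TRUE
  lev[!keep] <- NA
  structure(list(levels = lev, Ng = Ng,
                 bin_edges = seq(0, 1, length.out = Ng + 1)),
            class = "discretized_roi")
}

make_grid_mask <- function(values, mask_arr, spacing = c(1, 1, 1)) {
  g <- voxel_grid(values, spacing_mm = spacing)
  list(grid = g, mask = roi_mask(mask_arr, g))
}

sphere_mask <- function(r, pad = 3L, spacing = 1) {
  n <- 2L * (r + pad) + 1L
  c0 <- (n + 1) / 2
  x <- seq_len(n) - c0
  d2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  make_grid_mask(array(0, c(n, n, n)), d2 <= r^2, rep(spacing, 3))$mask
}

cube_mask <- function(a, pad = 3L) {
  n <- a + 2L * pad
  arr <- array(FALSE, c(n, n, n))
  arr[pad + seq_len(a), pad + seq_len(a), pad + seq_len(a)] <- TRUE
  make_grid_mask(array(0, c(n, n, n)), arr)$mask
}
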