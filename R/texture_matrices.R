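# Texture matrices on a discretized ROI. All three matrices use 1-based gray
# levels i = 1..Ng so inverse-square terms (1/i^2) are always defined.

#' The 13 unique 3D texture directions
#'
#' One representative per +/- offset pair at Chebyshev distance 1. The union
#' with the negated set is closed under 90-degree axis-aligned rotations,
#' which makes direction-aggregated texture features rotation-robust.
#'
#' @return a 13 x 3 integer matrix of voxel offsets.
#' @export
offsets_13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Co-occurrences of gray-level pairs at distance 1, accumulated over the 13
#' unique 3D directions in both orderings (symmetric), with pairs excluded
#' when either voxel lies outside the ROI. Matrices are summed over
#' directions and then normalized to total mass 1, yielding a single merged
#' `p(i, j)` from which the co-occurrence features are computed.
#'
#' @param disc a [discretize()]d ROI.
#' @param mask the paired [roi_mask] (the discretized levels already carry
#'   the mask; accepted for interface symmetry).
#' @return an object of class `glcm`: list with `matrix` (Ng x Ng, sums to
#'   1), `counts` (raw symmetric pair counts) and `n_pairs`.
#' @export
compute_glcm <- function(disc, mask = NULL) {
  stopifnot(inherits(disc, "discretized_roi"))
  lev <- disc$levels
  Ng <- disc$Ng
  d <- dim(lev)
  counts <- numeric(Ng * Ng)
  for (k in seq_len(nrow(offsets_13()))) {
    o <- offsets_13()[k, ]
    lo <- pmax(1L, 1L - o)
    hi <- pmin(d, d - o)
    if (any(lo > hi)) next
    xs <- seq.int(lo[1], hi[1])
    ys <- seq.int(lo[2], hi[2])
    zs <- seq.int(lo[3], hi[3])
    A <- lev[xs, ys, zs, drop = FALSE]
    B <- lev[xs + o[1], ys + o[2], zs + o[3], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    a <- A[ok]; b <- B[ok]
    counts <- counts + tabulate((b - 1L) * Ng + a, Ng * Ng) +
      tabulate((a - 1L) * Ng + b, Ng * Ng)
  }
  n_pairs <- sum(counts)
  if (n_pairs == 0)
    stop("no co-occurrences: ROI has no voxel pairs at distance 1")
  structure(list(matrix = matrix(counts / n_pairs, Ng, Ng),
                 counts = matrix(counts, Ng, Ng), n_pairs = n_pairs),
            class = "glcm")
}

#' Co-occurrence features
#'
#' Cluster prominence is the fourth central co-occurrence moment
#' `sum_{i,j} (i + j - mu_i - mu_j)^4 p(i,j)` (large for ROIs whose gray
#' levels cluster asymmetrically far from the mean); difference entropy is
#' the Shannon entropy (base 2) of the gray-level difference distribution
#' `p_{x-y}`; inverse difference normalized is
#' `sum_{i,j} p(i,j) / (1 + |i-j|/Ng)`, a homogeneity measure in (0, 1].
#'
#' @param g a [compute_glcm()] result.
#' @return a single numeric value.
#' @export
cluster_prominence <- function(g) {
  p <- g$matrix
  Ng <- nrow(p)
  i <- seq_len(Ng)
  mu_i <- sum(i * rowSums(p))
  mu_j <- sum(i * colSums(p))
  dev <- outer(i, i, "+") - mu_i - mu_j
  sum(dev^4 * p)
}

#' @rdname cluster_prominence
#' @export
difference_entropy <- function(g) {
  p <- g$matrix
  Ng <- nrow(p)
  k <- abs(outer(seq_len(Ng), seq_len(Ng), "-"))
  pxy <- vapply(0:(Ng - 1L), function(d) sum(p[k == d]), numeric(1))
  pxy <- pxy[pxy > 0]
  -sum(pxy * log2(pxy))
}

#' @rdname cluster_prominence
#' @export
inverse_difference_normalized <- function(g) {
  p <- g$matrix
  Ng <- nrow(p)
  k <- abs(outer(seq_len(Ng), seq_len(Ng), "-"))
  sum(p / (1 + k / Ng))
}

#' Gray-level run-length matrix (GLRLM)
#'
#' Maximal runs of equal gray level are counted along each of the 13 unique
#' 3D directions; runs break at ROI boundaries. Per-direction matrices
#' `r(i, j)` (level i, run length j) are summed by default; the
#' per-direction matrices are retained for the alternative
#' feature-averaging policy and for conservation checks
#' (`sum_j j * r(i, j)` equals the ROI voxel count in every direction).
#'
#' @inheritParams compute_glcm
#' @param aggregate `"sum"` (default) to pool run counts over directions
#'   before computing features, or `"mean"` to average per-direction feature
#'   values.
#' @return an object of class `glrlm`: list with `matrix` (summed Ng x Nr
#'   counts), `per_direction` (list of 13 matrices), `n_runs`, `aggregate`.
#' @export
compute_glrlm <- function(disc, mask = NULL, aggregate = c("sum", "mean")) {
  stopifnot(inherits(disc, "discretized_roi"))
  aggregate <- match.arg(aggregate)
  lev <- disc$levels
  Ng <- disc$Ng
  inside <- which(!is.na(lev))
  if (!length(inside)) stop("empty ROI: no runs to count")
  d <- dim(lev)
  co <- arrayInd(inside, d)
  lv <- lev[inside]
  per_dir <- vector("list", 13L)
  max_len <- 1L
  runs_all <- vector("list", 13L)
  for (k in seq_len(13L)) {
    o <- offsets_13()[k, ]
    t <- co[, 1] * o[1] + co[, 2] * o[2] + co[, 3] * o[3]
    # cross product of position with direction: constant exactly on one line
    k1 <- co[, 2] * o[3] - co[, 3] * o[2]
    k2 <- co[, 3] * o[1] - co[, 1] * o[3]
    k3 <- co[, 1] * o[2] - co[, 2] * o[1]
    ord <- order(k1, k2, k3, t)
    step <- sum(o^2)
    same <- c(FALSE,
              diff(k1[ord]) == 0 & diff(k2[ord]) == 0 & diff(k3[ord]) == 0 &
                diff(t[ord]) == step & diff(lv[ord]) == 0)
    run_id <- cumsum(!same)
    len <- tabulate(run_id)
    run_lev <- lv[ord][!same]
    runs_all[[k]] <- cbind(level = run_lev, length = len)
    max_len <- max(max_len, len)
  }
  Nr <- max_len
  total <- matrix(0, Ng, Nr)
  for (k in seq_len(13L)) {
    r <- runs_all[[k]]
    m <- matrix(tabulate((r[, 2] - 1L) * Ng + r[, 1], Ng * Nr), Ng, Nr)
    per_dir[[k]] <- m
    total <- total + m
  }
  structure(list(matrix = total, per_direction = per_dir,
                 n_runs = sum(total), aggregate = aggregate),
            class = "glrlm")
}

#' Run-length features
#'
#' Run-length non-uniformity `sum_j (sum_i r(i,j))^2 / N_r` grows when runs
#' concentrate on few lengths; short-run low gray-level emphasis
#' `(1/N_r) sum_{i,j} r(i,j) / (i^2 j^2)` weights short runs of dark voxels.
#' Under the `"mean"` policy the feature is averaged over the 13
#' per-direction matrices instead of computed on their sum.
#'
#' @param r a [compute_glrlm()] result.
#' @return a single numeric value.
#' @export
run_length_nonuniformity <- function(r) {
  glrlm_feature(r, function(m) {
    sum(colSums(m)^2) / sum(m)
  })
}

#' @rdname run_length_nonuniformity
#' @export
short_run_low_gray_emphasis <- function(r) {
  glrlm_feature(r, function(m) {
    i2 <- seq_len(nrow(m))^2
    j2 <- seq_len(ncol(m))^2
    sum(sweep(sweep(m, 1, i2, "/"), 2, j2, "/")) / sum(m)
  })
}

glrlm_feature <- function(r, f) {
  if (identical(r$aggregate, "mean")) {
    vals <- vapply(r$per_direction, function(m) if (sum(m) > 0) f(m) else NA_real_,
                   numeric(1))
    mean(vals, na.rm = TRUE)
  } else {
    f(r$matrix)
  }
}

#' Gray-level size-zone matrix (GLSZM)
#'
#' Zones are 26-connected components of equal gray level; the matrix
#' `s(i, j)` counts zones of level i and size j. Direction-free by
#' construction; `sum_j j * s(i, j)` equals the ROI voxel count.
#'
#' @inheritParams compute_glcm
#' @return an object of class `glszm`: list with `matrix` (Ng x Nz counts)
#'   and `n_zones`.
#' @export
compute_glszm <- function(disc, mask = NULL) {
  stopifnot(inherits(disc, "discretized_roi"))
  lev <- disc$levels
  if (!any(!is.na(lev))) stop("empty ROI: no zones to count")
  zs <- .zone_sizes_26(as.integer(lev), dim(lev))
  Ng <- disc$Ng
  Nz <- max(zs[, "size"])
  m <- matrix(tabulate((zs[, "size"] - 1L) * Ng + zs[, "level"], Ng * Nz),
              Ng, Nz)
  structure(list(matrix = m, n_zones = nrow(zs)), class = "glszm")
}

#' Size-zone features
#'
#' With `s(i, j)` the zone counts and `N_z` the total zone count:
#' high-intensity large area emphasis `(1/N_z) sum s(i,j) i^2 j^2`,
#' low-intensity large area emphasis `(1/N_z) sum s(i,j) j^2 / i^2`, and
#' low-intensity small area emphasis `(1/N_z) sum s(i,j) / (i^2 j^2)`.
#'
#' @param s a [compute_glszm()] result.
#' @return a single numeric value.
#' @export
high_intensity_large_area_emphasis <- function(s) {
  szm_weighted(s, function(i2, j2) outer(i2, j2))
}

#' @rdname high_intensity_large_area_emphasis
#' @export
low_intensity_large_area_emphasis <- function(s) {
  szm_weighted(s, function(i2, j2) outer(1 / i2, j2))
}

#' @rdname high_intensity_large_area_emphasis
#' @export
low_intensity_small_area_emphasis <- function(s) {
  szm_weighted(s, function(i2, j2) outer(1 / i2, 1 / j2))
}

szm_weighted <- function(s, wfun) {
  m <- s$matrix
  i2 <- seq_len(nrow(m))^2
  j2 <- seq_len(ncol(m))^2
  sum(m * wfun(i2, j2)) / sum(m)
}
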