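test_that("GLCM matches brute-force pair enumeration on random small ROIs", {
  for (seed in 1:60) {
    disc <- random_small_roi(seed)
    n_in <- sum(!is.na(disc$levels))
    bf <- bf_glcm_counts(disc$levels, disc$Ng)
    if (sum(bf) == 0) {
      expect_error(compute_glcm(disc), "no co-occurrences")
      next
    }
    g <- compute_glcm(disc)
    expect_equal(unname(g$counts), unname(bf))
    expect_equal(sum(g$matrix), 1, tolerance = 1e-9)
    expect_identical(g$matrix, t(g$matrix))
  }
})

test_that("GLCM on a hand-enumerable 2x2x1 ROI and a constant ROI", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  disc <- structure(list(levels = lev, Ng = 2L, bin_edges = 0:2),
                    class = "discretized_roi")
  g <- compute_glcm(disc)
  # pairs: 2 horizontal (1,1) and (2,2); 4 vertical/diagonal (1,2) —
  # doubled for symmetry: counts (1,1)=2,(2,2)=2,(1,2)=(2,1)=4, total 12
  expect_identical(g$counts, matrix(c(2, 4, 4, 2), 2, 2))
  expect_equal(g$matrix, matrix(c(2, 4, 4, 2) / 12, 2, 2))

  cst <- structure(list(levels = array(1L, c(3, 3, 3)), Ng = 32L,
                        bin_edges = seq(0, 1, length.out = 33)),
                   class = "discretized_roi")
  gc <- compute_glcm(cst)
  expect_equal(gc$matrix[1, 1], 1)
  expect_equal(sum(gc$matrix[-1, ]), 0)

  single <- structure(list(levels = array(1L, c(1, 1, 1)), Ng = 2L,
                           bin_edges = 0:2), class = "discretized_roi")
  expect_error(compute_glcm(single), "no co-occurrences")
})

test_that("co-occurrence features match hand-evaluated formulas", {
  two_cell <- function(p11, p22) {
    m <- matrix(0, 4, 4); m[1, 1] <- p11; m[2, 2] <- p22
    structure(list(matrix = m, counts = m, n_pairs = 1), class = "glcm")
  }
  g <- two_cell(0.5, 0.5)
  # mu_i = mu_j = 1.5; CP = 0.5*(2-3)^4 + 0.5*(4-3)^4 = 1
  expect_equal(cluster_prominence(g), 1)
  # p_{x-y} puts all mass at k=0 -> difference entropy 0; a fair split over
  # two k-values gives exactly 1 bit
  expect_equal(difference_entropy(g), 0)
  m <- matrix(0, 4, 4); m[1, 1] <- 0.5; m[1, 2] <- 0.25; m[2, 1] <- 0.25
  gb <- structure(list(matrix = m, counts = m, n_pairs = 1), class = "glcm")
  expect_equal(difference_entropy(gb), 1)
  # diagonal GLCM -> IDN 1; all mass at (1, Ng) -> 1/(1 + (Ng-1)/Ng)
  expect_equal(inverse_difference_normalized(g), 1)
  m2 <- matrix(0, 32, 32); m2[1, 32] <- 1
  g2 <- structure(list(matrix = m2, counts = m2, n_pairs = 1), class = "glcm")
  expect_equal(inverse_difference_normalized(g2), 32 / 63)
})

test_that("cluster prominence is invariant to a simultaneous level shift", {
  set.seed(71)
  disc <- random_small_roi(101, max_dim = 5, Ng = 4)
  g <- compute_glcm(disc)
  shifted <- disc
  shifted$levels <- disc$levels + 3L
  shifted$Ng <- disc$Ng + 3L
  gs <- compute_glcm(shifted)
  expect_equal(cluster_prominence(gs), cluster_prominence(g),
               tolerance = 1e-12)
})

test_that("difference entropy equals independent re-summation on random GLCMs", {
  set.seed(81)
  for (rep in 1:20) {
    disc <- random_small_roi(200 + rep, Ng = 5)
    if (sum(bf_glcm_counts(disc$levels, disc$Ng)) == 0) next
    g <- compute_glcm(disc)
    p <- g$matrix
    de <- 0
    for (k in 0:(disc$Ng - 1)) {
      pk <- 0
      for (i in seq_len(disc$Ng)) for (j in seq_len(disc$Ng))
        if (abs(i - j) == k) pk <- pk + p[i, j]
      if (pk > 0) de <- de - pk * log2(pk)
    }
    expect_equal(difference_entropy(g), de, tolerance = 1e-12)
  }
})

test_that("GLRLM matches brute-force line walking in every direction", {
  for (seed in 1:40) {
    disc <- random_small_roi(seed + 500)
    r <- compute_glrlm(disc)
    n_in <- sum(!is.na(disc$levels))
    for (k in seq_len(13)) {
      o <- meningrisk::offsets_13()[k, ]
      bf <- bf_glrlm_direction(disc$levels, disc$Ng, o)
      got <- r$per_direction[[k]]
      nc <- max(ncol(bf), ncol(got))
      pad <- function(m) cbind(m, matrix(0, nrow(m), nc - ncol(m)))
      expect_equal(unname(pad(got)) * 1.0, unname(pad(bf)) * 1.0)
      # per-direction voxel conservation
      expect_equal(sum(sweep(got, 2, seq_len(ncol(got)), "*")), n_in)
    }
  }
})

test_that("run-length features match hand enumeration on a 1D ROI", {
  # levels [1,1,2] along x: runs {(1, len 2), (2, len 1)} in the x direction
  lev <- array(c(1L, 1L, 2L), c(3, 1, 1))
  disc <- structure(list(levels = lev, Ng = 2L, bin_edges = 0:2),
                    class = "discretized_roi")
  r <- compute_glrlm(disc)
  rx <- r$per_direction[[1]]
  expect_equal(rx[1, 2], 1)
  expect_equal(rx[2, 1], 1)
  expect_equal(sum(rx), 2)
  one_dir <- structure(list(matrix = rx, per_direction = list(rx),
                            n_runs = sum(rx), aggregate = "sum"),
                       class = "glrlm")
  expect_equal(run_length_nonuniformity(one_dir), 1)   # (1^2+1^2)/2
  expect_equal(short_run_low_gray_emphasis(one_dir), 0.25)

  # constant 3x3x3 ROI: each axis direction has 9 runs of length 3
  cst <- structure(list(levels = array(1L, c(3, 3, 3)), Ng = 2L,
                        bin_edges = 0:2), class = "discretized_roi")
  rc <- compute_glrlm(cst)
  expect_equal(rc$per_direction[[1]][1, 3], 9)
})

test_that("GLSZM matches brute-force labeling and conserves voxel counts", {
  for (seed in 1:40) {
    disc <- random_small_roi(seed + 900)
    s <- compute_glszm(disc)
    bf <- bf_zone_sizes(disc$levels)
    bf_m <- matrix(0, disc$Ng, max(bf$size))
    for (i in seq_len(nrow(bf)))
      bf_m[bf$level[i], bf$size[i]] <- bf_m[bf$level[i], bf$size[i]] + 1
    nc <- max(ncol(bf_m), ncol(s$matrix))
    pad <- function(m) cbind(m, matrix(0, nrow(m), nc - ncol(m)))
    expect_equal(unname(pad(s$matrix)) * 1.0, unname(pad(bf_m)) * 1.0)
    expect_equal(sum(sweep(s$matrix, 2, seq_len(ncol(s$matrix)), "*")),
                 sum(!is.na(disc$levels)))
  }
})

test_that("size-zone features match hand evaluation on degenerate ROIs", {
  cst <- structure(list(levels = array(1L, c(2, 2, 2)), Ng = 2L,
                        bin_edges = 0:2), class = "discretized_roi")
  s <- compute_glszm(cst)
  expect_equal(s$n_zones, 1)
  expect_equal(high_intensity_large_area_emphasis(s), 64)   # 1^2 * 8^2
  expect_equal(low_intensity_small_area_emphasis(s), 1 / 64)
  expect_equal(low_intensity_large_area_emphasis(s), 64)    # 8^2 / 1^2

  # all-distinct levels: n zones of size 1
  lev <- array(1:8, c(2, 2, 2))
  dd <- structure(list(levels = lev, Ng = 8L, bin_edges = 0:8),
                  class = "discretized_roi")
  sd_ <- compute_glszm(dd)
  expect_equal(sd_$n_zones, 8)
  expect_true(all(sd_$matrix[, 1] == 1))
})

test_that("direction-aggregated GLCM features are invariant to 90-degree rotations", {
  set.seed(91)
  vals <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
  keep <- array(runif(9^3) < 0.7, c(9, 9, 9))
  gm <- make_grid_mask(vals, keep)
  disc <- discretize(gm$grid, gm$mask, 8)
  feats <- function(d) {
    g <- compute_glcm(d)
    c(cluster_prominence(g), difference_entropy(g),
      inverse_difference_normalized(g))
  }
  base <- feats(disc)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  disc_r <- disc
  disc_r$levels <- rot(disc$levels)
  expect_equal(feats(disc_r), base, tolerance = 1e-9)
})
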