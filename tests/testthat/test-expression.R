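tps <- c(1, 2, 3, 4, 5, 6, 8, 12, 24)

test_that("polynomial smoothing represents polynomials exactly and reduces noise", {
  # an exact 5th-order polynomial over 10 points is recovered
  t10 <- 1:10
  y <- 2 + 0.5 * t10 - 0.02 * t10^3 + 1e-4 * t10^5
  expect_equal(smooth_polynomial(y, t10, order = 5), y, tolerance = 1e-8)

  # constant series stays constant
  expect_equal(smooth_polynomial(rep(3, 9), tps), rep(3, 9))

  # on average the fit is closer to the truth than the noisy input
  set.seed(10)
  wins <- 0
  for (i in 1:100) {
    truth <- 3 * sin(tps / 8) + 0.1 * tps
    noisy <- truth + rnorm(length(tps), sd = 0.1)
    sm <- smooth_polynomial(noisy, tps)
    wins <- wins + (sqrt(mean((sm - truth)^2)) < sqrt(mean((noisy - truth)^2)))
  }
  expect_gt(wins, 50)

  expect_error(smooth_polynomial(1:4, 1:4, order = 5), "timepoints")
})

test_that("top-regulation filter requires two same-sign consecutive exceedances", {
  m <- rbind(up2 = c(0, 2.0, 2.1, 0, 0),
             spike = c(0, 3.0, 0, 0, 0),
             flip = c(0, 2.0, -2.0, 0, 0),
             down2 = c(0, -1.8, -1.9, 0, 0),
             weak = c(1.6, 1.6, 1.6, 1.6, 1.6))
  sel <- select_top_regulated(m, fc_threshold = 1.7)
  expect_setequal(sel, c("up2", "down2"))

  # monotone: raising the threshold never adds genes
  for (thr in c(1.0, 1.7, 1.9, 2.05)) {
    s_lo <- select_top_regulated(m, fc_threshold = thr)
    s_hi <- select_top_regulated(m, fc_threshold = thr + 0.1)
    expect_true(all(s_hi %in% s_lo))
  }
})

test_that("CAST groups identical profiles and recovers planted structure", {
  # ten identical profiles form a single cluster
  m1 <- matrix(rep(sin(tps / 4), 10), nrow = 10, byrow = TRUE,
               dimnames = list(paste0("g", 1:10), tps))
  cl1 <- cast_cluster(m1)
  expect_length(cl1$clusters, 1)
  expect_length(cl1$clusters[[1]], 10)

  # sign-flipped sine groups separate perfectly
  set.seed(6)
  prof <- sin(seq(0, 2 * pi, length.out = length(tps)))
  m2 <- rbind(t(replicate(12, prof + rnorm(length(tps), sd = 0.05))),
              t(replicate(12, -prof + rnorm(length(tps), sd = 0.05))))
  rownames(m2) <- paste0("g", 1:24)
  lab <- rep(1:2, each = 12)
  cl2 <- cast_cluster(m2)
  expect_length(cl2$clusters, 2)
  expect_equal(mclust::adjustedRandIndex(cl2$assignment[rownames(m2)], lab), 1.0)

  # output partitions the non-degenerate genes
  expect_setequal(unlist(cl2$clusters), rownames(m2))
  expect_false(any(duplicated(unlist(cl2$clusters))))

  # constant series are excluded with a warning
  m3 <- rbind(m1, flat = rep(1, length(tps)))
  expect_warning(cl3 <- cast_cluster(m3), "constant")
  expect_false("flat" %in% unlist(cl3$clusters))

  # raising t never decreases the cluster count on the same input
  m4 <- planted_cluster_matrix(3, 8, noise_sd = 0.3, seed = 12)
  ks <- sapply(c(0.6, 0.8, 0.9, 0.97), function(t)
    length(cast_cluster(m4, affinity_threshold = t)$clusters))
  expect_true(all(diff(ks) >= 0))
})

test_that("anti-correlation detection follows the slope/sign/r2 rule", {
  t <- 1:10
  expect_true(detect_anticorrelated(2 * t, -2 * t, t))
  expect_false(detect_anticorrelated(2 * t, 3 * t, t))       # same sign
  # boundary behaviour: r2 must be strictly above the threshold
  set.seed(3)
  noisy_down <- -2 * t + rnorm(10, sd = 3)
  r2 <- summary(lm(noisy_down ~ t))$r.squared
  # setting the threshold exactly at the achieved r2 fails the strict rule ...
  expect_false(detect_anticorrelated(2 * t, noisy_down, t, r2_threshold = r2))
  # ... while any threshold below it passes (slopes are significant and opposite)
  expect_true(detect_anticorrelated(2 * t, noisy_down, t,
                                    r2_threshold = r2 - 1e-6))
})

test_that("HiT-MDS embeds symmetric configurations and recovers planar data", {
  # equilateral triangle up to rigid motion
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  e3 <- hitmds_embed(D3, iterations = 500, seed = 1)
  d3 <- as.vector(dist(e3$points))
  expect_lt(max(abs(d3 - mean(d3))), 1e-6)

  # planar self-recovery
  set.seed(5)
  X <- matrix(rnorm(80), 40, 2)
  D <- as.matrix(dist(X))
  emb <- hitmds_embed(D, iterations = 1500, seed = 2)
  expect_gte(1 - emb$stress, 0.999)

  # reported stress trace is non-increasing
  expect_true(all(diff(emb$stress_trace) <= 1e-12))

  # stress is invariant under relabeling of the genes
  perm <- sample(40)
  emb_p <- hitmds_embed(D[perm, perm], iterations = 1500, seed = 2)
  expect_equal(emb_p$stress, emb$stress, tolerance = 5e-3)

  expect_error(hitmds_embed(matrix(0, 4, 4)), "degenerate")
})

test_that("skew-Gaussian uniqueness p-values flag density outliers", {
  set.seed(2)
  pts <- matrix(rnorm(1000), 500, 2)
  pts[1, ] <- c(10, 10)   # a 10-sd outlier
  p <- uniqueness_pvalue(pts, seed = 9)
  expect_equal(unname(which.min(p)), 1L)
  expect_lt(p[1], 0.01)
  expect_true(all(p > 0 & p <= 1))

  # coincident points are a degenerate cloud
  expect_error(fit_skew_gaussian(matrix(1, 20, 2)), "degenerate")

  # planted outliers at >= 6 sd are recovered with sensitivity >= 0.9
  set.seed(4)
  n <- 400; n_out <- 20
  cloud <- matrix(rnorm(2 * n), n, 2)
  ang <- runif(n_out, 0, 2 * pi)
  r <- runif(n_out, 6, 9)
  cloud[1:n_out, ] <- cbind(r * cos(ang), r * sin(ang))
  pv <- uniqueness_pvalue(cloud, seed = 5)
  expect_gte(mean(pv[1:n_out] < 0.01), 0.9)

  # p-values are invariant under rigid rotation of the embedding
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pv_rot <- uniqueness_pvalue(cloud %*% R, seed = 5)
  expect_equal(mean(pv_rot[1:n_out] < 0.01), mean(pv[1:n_out] < 0.01),
               tolerance = 0.1)
})

test_that("expression TSV I/O round-trips a matrix", {
  m <- planted_cluster_matrix(2, 3, noise_sd = 0.1, seed = 8)
  f <- tempfile(fileext = ".tsv")
  write_expression_tsv(m, f)
  back <- read_expression_tsv(f)
  expect_equal(unname(back), unname(m[, ]), tolerance = 1e-8)
  expect_equal(rownames(back), rownames(m))
})
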