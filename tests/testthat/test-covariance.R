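test_that("normalization limits: identical series give 1, negated series give -1", {
  d <- sinusoid_series(100)
  same <- two_bead_traj(d, d)
  anti <- two_bead_traj(d, -d)
  c_same <- normalize_covariance(compute_covariance(same, superpose = FALSE))
  c_anti <- normalize_covariance(compute_covariance(anti, superpose = FALSE))
  expect_equal(unname(c_same$values[1, 1]), 1)
  expect_equal(unname(c_anti$values[1, 1]), -1)
})

test_that("raw covariance: identical series give 3v, a stationary atom gives 0", {
  d <- sinusoid_series(64)
  d3 <- cbind(d[, 1], 0.5 * d[, 1], -0.25 * d[, 1])   # per-axis variance known
  raw <- compute_covariance(two_bead_traj(d3, d3), superpose = FALSE)
  v <- colMeans(d3^2)                                  # biased per-axis variance
  expect_equal(unname(raw$values[1, 1]), sum(v))

  still <- two_bead_traj(d3, 0 * d3)
  raw0 <- compute_covariance(still, superpose = FALSE)
  expect_equal(unname(raw0$values[1, 1]), 0)
  expect_error(compute_covariance(two_bead_traj(d3[1, , drop = FALSE],
                                                d3[1, , drop = FALSE]),
                                  superpose = FALSE), "2 frames")
})

test_that("biased vs unbiased estimator differ by n/(n-1)", {
  d <- sinusoid_series(50)
  tr <- two_bead_traj(d, 0.7 * d)
  b <- compute_covariance(tr, superpose = FALSE)$values
  u <- compute_covariance(tr, superpose = FALSE, unbiased = TRUE)$values
  expect_equal(u, b * 50 / 49, tolerance = 1e-12)
})

test_that("Gaussian generator covariance matches trace of the planted cross-covariance", {
  rho <- 0.6; sigma <- 0.5; n <- 10000
  spec <- coupling_spec(1, 1, data.frame(i = 1, j = 1, rho = rho,
                                         equilibrium_distance_A = 9),
                        sigma_A = sigma, n_frames = n, seed = 21)
  traj <- generate_coupled_trajectory(spec)
  raw <- compute_covariance(traj, superpose = FALSE)

  # independent oracle: per-frame displacement dot products + batch-means SE
  mu <- colMeans(traj$xyz)
  X <- sweep(traj$xyz, 2, mu)
  dots <- rowSums(X[, 1:3] * X[, 4:6])
  expect_equal(unname(raw$values[1, 1]), mean(dots), tolerance = 1e-12)
  batches <- colMeans(matrix(dots, nrow = 100))        # 100 batches of 100
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(raw$values[1, 1] - 3 * rho * sigma^2), 3 * se)
})

test_that("degenerate normalization: frozen residue gives 0 with a warning", {
  d <- sinusoid_series(30)
  raw <- compute_covariance(two_bead_traj(d, 0 * d), superpose = FALSE)
  expect_warning(ncov <- normalize_covariance(raw), "frozen")
  expect_equal(unname(ncov$values[1, 1]), 0)
  expect_error(normalize_covariance(raw, auto_cov1 = -1, auto_cov2 = 1),
               "integrity")
  expect_error(
    normalize_covariance(normalize_covariance(
      compute_covariance(two_bead_traj(d, d), superpose = FALSE))),
    "already normalized")
})

test_that("prefilter mask equals a brute-force all-pairs distance scan", {
  traj <- random_bead_traj(20, 20, n_frames = 10, seed = 31, spread = 3)
  avg <- compute_average_structure(traj, superpose = FALSE)
  mask <- build_prefilter_mask(avg, 13)
  d <- residue_distance_matrix(avg)
  oracle <- matrix(FALSE, 20, 20)
  m1 <- avg$mean_coords[1:20, ]; m2 <- avg$mean_coords[21:40, ]
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- sqrt(sum((m1[i, ] - m2[j, ])^2)) <= 13
  expect_equal(unname(mask$keep), oracle)
  expect_error(build_prefilter_mask(avg, -1), "cutoff")
})

test_that("prefilter boundary: 10 A kept at cutoff 13, 13.01 A excluded", {
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(5, 13.01, 0))
  atoms <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                      residue_id = c(1L, 2L, 1L, 2L),
                      chain_id = c("A", "A", "B", "B"),
                      protein_tag = rep(c("protein1", "protein2"), each = 2),
                      stringsAsFactors = FALSE)
  avg <- structure(list(mean_coords = base, source_n_frames = 2L,
                        atoms = atoms), class = "cc_avg_structure")
  mask <- build_prefilter_mask(avg, 13)
  expect_true(mask$keep["A:1:ALA", "B:1:ALA"])     # 10.0 A
  expect_false(mask$keep["A:2:ALA", "B:2:ALA"])    # 13.01 A
})

test_that("masked covariance equals the unmasked values on kept pairs, 0 elsewhere", {
  traj <- random_bead_traj(12, 15, n_frames = 60, seed = 8, spread = 3)
  avg <- compute_average_structure(traj, superpose = FALSE)
  mask <- build_prefilter_mask(avg, 15)
  full <- compute_covariance(traj, superpose = FALSE)
  part <- compute_covariance(traj, mask = mask, superpose = FALSE)
  expect_true(any(mask$keep) && !all(mask$keep))
  expect_equal(part$values[mask$keep], full$values[mask$keep],
               tolerance = 1e-12)
  expect_true(all(part$values[!mask$keep] == 0))
})

test_that("count_significant_elements uses strict asymmetric thresholds", {
  d <- sinusoid_series(20)
  ncov <- normalize_covariance(compute_covariance(two_bead_traj(d, d),
                                                  superpose = FALSE))
  probe <- function(vals) {
    x <- ncov
    x$values <- matrix(vals, 1)
    x
  }
  expect_equal(count_significant_elements(probe(0)), 0L)
  expect_equal(count_significant_elements(probe(0.5)), 1L)
  expect_equal(count_significant_elements(probe(c(-0.08, 0.1))), 0L)
  expect_equal(count_significant_elements(probe(c(-0.081, 0.101))), 2L)
  raw <- compute_covariance(two_bead_traj(d, d), superpose = FALSE)
  expect_error(count_significant_elements(raw), "normalized")
})

test_that("normalized elements stay in [-1, 1] on random trajectories", {
  for (s in 1:40) {
    traj <- random_bead_traj(3, 3, n_frames = 8, seed = 100 + s, spread = 2)
    ncov <- normalize_covariance(compute_covariance(traj, superpose = FALSE))
    expect_true(all(ncov$values >= -1 & ncov$values <= 1))
  }
})

test_that("interprotein block agrees with bio3d's cross-correlation matrix", {
  traj <- random_bead_traj(4, 5, n_frames = 50, seed = 77, spread = 3)
  ours <- normalize_covariance(compute_covariance(traj, superpose = FALSE))
  ref <- bio3d::dccm.xyz(traj$xyz, ncore = 1)
  expect_equal(unname(ours$values), unname(ref[1:4, 5:9]), tolerance = 1e-8)
})

test_that("planted correlation signs are recovered and error shrinks with frames", {
  pairs <- data.frame(i = 1:6, j = 1:6, rho = rep(c(0.5, -0.5), 3),
                      equilibrium_distance_A = 9)
  err_at <- function(n, seed) {
    spec <- coupling_spec(6, 6, pairs, n_frames = n, seed = seed)
    traj <- generate_coupled_trajectory(spec)
    ncov <- normalize_covariance(compute_covariance(traj, superpose = FALSE))
    est <- diag(ncov$values)
    expect_true(all(sign(est) == sign(pairs$rho)))
    mean(abs(est - pairs$rho))
  }
  errs <- c(err_at(500, 3), err_at(2000, 3), err_at(8000, 3))
  expect_true(errs[2] < errs[1] && errs[3] < errs[2])
})
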