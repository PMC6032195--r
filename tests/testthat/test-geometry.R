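## Brute-force oracle: best-fit RMSD by scanning rotations (coarse Euler
## grid + Nelder-Mead refinement), never touching the Kabsch path.
grid_fit_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  rot3 <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(a) sqrt(mean(rowSums((mc %*% rot3(a) - rc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_a <- c(0, 0, 0)
  for (ax in grid) for (ay in seq(-pi / 2, pi / 2, length.out = 7))
    for (az in grid) {
      v <- obj(c(ax, ay, az))
      if (v < best) { best <- v; best_a <- c(ax, ay, az) }
    }
  opt <- optim(best_a, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

test_that("superposition recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(24, sd = 5), ncol = 3)
  sp <- superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  rot_z90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ref <- sweep(P %*% rot_z90, 2, c(1, 2, 3), "+")
  sp <- superpose(P, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, rot_z90, tolerance = 1e-8)
  expect_equal(apply_transform(P, sp), ref, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
})

test_that("superposition matches a rotation-grid oracle on fixed point sets", {
  mob <- matrix(c(0, 0, 0, 4, 0, 0, 0, 3, 0, 1, 1, 2), ncol = 3,
                byrow = TRUE)
  ref <- matrix(c(0.2, -0.1, 0, 3.7, 0.4, 0.2, 0.5, 3.1, -0.3, 1.4, 0.8,
                  1.7), ncol = 3, byrow = TRUE)
  expect_equal(superpose(mob, ref)$rmsd, grid_fit_rmsd(mob, ref),
               tolerance = 1e-3)
  set.seed(42)
  mob2 <- matrix(rnorm(12, sd = 3), ncol = 3)
  ref2 <- matrix(rnorm(12, sd = 3), ncol = 3)
  expect_equal(superpose(mob2, ref2)$rmsd, grid_fit_rmsd(mob2, ref2),
               tolerance = 1e-3)
})

test_that("superposition rejects degenerate input", {
  expect_error(superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "mismatch")
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 0.0), "collinear")
})

test_that("rmsd_series is zero for static or rigidly moved frames", {
  set.seed(2)
  base <- matrix(rnorm(30, sd = 4), ncol = 3)
  topo <- toy_structure(base)
  frames <- list(base, base, sweep(base, 2, c(5, -2, 1), "+"),
                 base %*% rand_rotation())
  tr <- frames_trajectory(frames, topo)
  ser <- rmsd_series(tr, 1:10)
  expect_equal(ser$values, rep(0, 4), tolerance = 1e-8)
  expect_error(rmsd_series(tr, 1:10, reference_frame = 9), "out of range")
})

test_that("rmsd_series equals an independent per-frame refit (bio3d)", {
  set.seed(3)
  base <- matrix(rnorm(45, sd = 4), ncol = 3)
  frames <- lapply(1:6, function(i) base + matrix(rnorm(45, sd = 0.5),
                                                  ncol = 3))
  tr <- frames_trajectory(frames, toy_structure(base))
  ser <- rmsd_series(tr, 1:15, reference_frame = 1)
  oracle <- vapply(frames, function(f)
    bio3d::rmsd(as.vector(t(frames[[1]])), as.vector(t(f)),
                fit = TRUE), numeric(1))
  expect_equal(ser$values, oracle, tolerance = 2e-3)  # bio3d prints 3 dp
  ## plateau near the analytic two-sample level sigma * sqrt(6) (both the
  ## reference and each frame carry sigma = 0.5 noise), slightly reduced
  ## by the 6 fitted rigid-body degrees of freedom
  level <- 0.5 * sqrt(6) * sqrt(1 - 6 / 45)
  expect_equal(mean(ser$values[-1]), level, tolerance = 0.15)
})

test_that("rmsf is zero for a static trajectory and sees sigma*sqrt(3) jitter", {
  base <- atom_xyz(build_groove(groove_sim_spec(
    n_res_alpha = 11, n_res_beta = 11, peptide_len = 0)))
  topo <- toy_structure(base, resid = seq_len(nrow(base)))
  static <- frames_trajectory(list(base, base, base), topo)
  expect_equal(rmsf_profile(static, seq_len(nrow(base)))$values,
               rep(0, nrow(base)), tolerance = 1e-10)
  expect_error(rmsf_profile(frames_trajectory(list(base), topo), 1:5),
               "2 frames")

  sigma <- 0.3
  spec <- groove_sim_spec(n_res_alpha = 33, n_res_beta = 2, peptide_len = 0,
                          n_frames = 2000, residue_jitter = sigma, seed = 9)
  tr <- simulate_trajectory(spec)
  sel <- select_calpha(tr$topology, "A", c(46, 78))
  prof <- rmsf_profile(tr, sel)
  expect_equal(mean(prof$values), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsf localizes an amplified residue and survives rigid motion", {
  n_prot <- 12 + 12 + 0
  jit <- rep(0.2, n_prot); jit[7] <- 0.6
  spec <- groove_sim_spec(n_res_alpha = 12, n_res_beta = 12,
                          peptide_len = 0, n_frames = 300,
                          residue_jitter = jit, seed = 21)
  tr <- simulate_trajectory(spec)
  sel <- select_calpha(tr$topology, "A", c(46, 57))
  prof <- rmsf_profile(tr, sel)
  expect_equal(prof$resids[which.max(prof$values)], 46 + 6)

  ## global rigid motion of every frame leaves the profile unchanged
  R <- rand_rotation()
  xyz2 <- t(apply(tr$xyz, 1, function(v) {
    as.vector(t(sweep(matrix(v, ncol = 3, byrow = TRUE) %*% R, 2,
                      c(10, -4, 2), "+")))
  }))
  tr2 <- groove_trajectory(tr$topology, xyz2, dt = tr$dt)
  expect_equal(rmsf_profile(tr2, sel)$values, prof$values,
               tolerance = 1e-6)
})

test_that("representative_frame is the brute-force medoid", {
  ## 3-frame toy: frames differ by stretching one atom (rigid differences
  ## would vanish under superposition); the oracle enumerates the full
  ## pairwise fitted-RMSD matrix with bio3d and takes the argmin by hand.
  base <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 3, 3, 1), ncol = 3,
                 byrow = TRUE)
  topo <- toy_structure(base)
  mk <- function(d) { f <- base; f[4, 3] <- f[4, 3] + d; f }
  frames <- list(mk(0), mk(1), mk(5))
  tr <- frames_trajectory(frames, topo)
  pair <- function(i, j)
    bio3d::rmsd(as.vector(t(frames[[i]])), as.vector(t(frames[[j]])),
                fit = TRUE)
  m <- outer(1:3, 1:3, Vectorize(pair))
  means <- rowSums(m) / 2
  expect_equal(representative_frame(tr, 1:4, window = 3),
               which.min(means))

  ## identical frames: tie broken to the first frame of the window
  tie <- frames_trajectory(list(base, base, base, base), topo)
  expect_equal(representative_frame(tie, 1:4, window = 3), 2)

  ## random 50-frame window equals the exhaustive argmin
  set.seed(5)
  frames50 <- lapply(1:50, function(i) base + matrix(rnorm(12, sd = 0.4),
                                                     ncol = 3))
  tr50 <- frames_trajectory(frames50, topo)
  m50 <- outer(1:50, 1:50, Vectorize(function(i, j)
    if (i == j) 0 else
      bio3d::rmsd(as.vector(t(frames50[[i]])), as.vector(t(frames50[[j]])),
                  fit = TRUE)))
  expect_equal(representative_frame(tr50, 1:4, window = 50),
               which.min(rowMeans(m50) * 50 / 49))
  expect_error(representative_frame(tr50, 1:4, window = 1), "at least 2")
})
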