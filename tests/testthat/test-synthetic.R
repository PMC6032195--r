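test_that("build_groove hits the requested separation and layout", {
  spec <- groove_sim_spec(d0 = 13.0)
  s <- build_groove(spec)
  g <- groove_of(s)
  expect_equal(inter_helical_distance(s, g), 13.0, tolerance = 0.1)
  ## in fact the calibration makes it exact
  expect_equal(inter_helical_distance(s, g), 13.0, tolerance = 1e-7)
  ## chain layout: 33 + 38 helix residues, 13-mer peptide on chain C
  expect_equal(sum(s$atom$chain == "A"), 33)
  expect_equal(sum(s$atom$chain == "B"), 38)
  expect_equal(sum(s$atom$chain == "C"), 13)
  expect_equal(s$atom$resname[s$atom$chain == "C"][1:3],
               c("PRO", "ARG", "TYR"))  # HA 306-318
  ## ligand pseudo-molecule when enabled
  sl <- build_groove(groove_sim_spec(ligand = TRUE))
  expect_equal(sum(sl$atom$resname == "NVP"), 3)
  expect_true(all(sl$atom$type[sl$atom$resname == "NVP"] == "HETATM"))
})

test_that("generation is fully deterministic under a fixed seed", {
  spec <- groove_sim_spec(n_res_alpha = 8, n_res_beta = 9, peptide_len = 4,
                          n_frames = 6, sigma_d = 0.3,
                          residue_jitter = 0.25, ligand = TRUE,
                          ligand_presence = 0.5, ligand_jitter = 0.1,
                          seed = 123)
  t1 <- simulate_trajectory(spec)
  t2 <- simulate_trajectory(spec)
  expect_identical(t1$xyz, t2$xyz)
  ## byte-identical multi-model PDB output
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(t1, f1); write_trajectory(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## a different seed changes coordinates
  spec2 <- groove_sim_spec(n_res_alpha = 8, n_res_beta = 9, peptide_len = 4,
                           n_frames = 6, sigma_d = 0.3,
                           residue_jitter = 0.25, ligand = TRUE,
                           ligand_presence = 0.5, ligand_jitter = 0.1,
                           seed = 124)
  expect_false(identical(simulate_trajectory(spec2)$xyz, t1$xyz))
})

test_that("noiseless trajectories realize the drift exactly", {
  spec <- groove_sim_spec(n_res_alpha = 12, n_res_beta = 14,
                          peptide_len = 0, d0 = 13.0, slope = -0.14,
                          sigma_d = 0, n_frames = 40, dt = 0.125)
  tr <- simulate_trajectory(spec)
  sm <- summarize_series(groove_distance_series(tr, groove_of(tr$topology)))
  expect_equal(sm$slope, -0.14, tolerance = 1e-6)
  ## constant case
  spec0 <- groove_sim_spec(n_res_alpha = 12, n_res_beta = 14,
                           peptide_len = 0, d0 = 13.0, n_frames = 10)
  ser0 <- groove_distance_series(simulate_trajectory(spec0),
                                 groove_of(build_groove(spec0)))
  expect_equal(diff(range(ser0$values)), 0, tolerance = 1e-9)
})

test_that("the pipeline mean matches the analytic mean d0 + slope*T/2", {
  spec <- groove_sim_spec(d0 = 13.45, slope = -0.14, sigma_d = 0.4,
                          n_frames = 1250, seed = 42)
  sm <- summarize_series(groove_distance_series(simulate_trajectory(spec),
                                                groove_of(build_groove(spec))))
  analytic <- 13.45 - 0.14 * (1250 - 1) * 0.004 / 2
  expect_equal(sm$mean, analytic, tolerance = 0.1 / analytic)
  expect_equal(d0_for_mean(analytic, -0.14, 1250, 0.004), 13.45,
               tolerance = 1e-12)
})

test_that("ligand occupancy matches its closed-form expectation", {
  ## always present, no jitter: occupancy 1 in each home voxel
  spec1 <- groove_sim_spec(n_res_alpha = 6, n_res_beta = 6, peptide_len = 0,
                           n_frames = 20, ligand = TRUE,
                           ligand_presence = 1, seed = 31)
  tr1 <- simulate_trajectory(spec1)
  lig <- atom_select(tr1$topology, chain = "L")
  g1 <- occupancy_grid(tr1, lig, spacing = 1)
  truth1 <- ligand_occupancy_truth(spec1, g1)
  expect_equal(truth1$expected, rep(1, 3))
  for (r in 1:3)
    expect_equal(g1$values[truth1$i[r], truth1$j[r], truth1$k[r]], 1)

  ## present half the time: observed within a binomial interval of 0.5
  spec2 <- groove_sim_spec(n_res_alpha = 6, n_res_beta = 6, peptide_len = 0,
                           n_frames = 2000, ligand = TRUE,
                           ligand_presence = 0.5, seed = 32)
  tr2 <- simulate_trajectory(spec2)
  g2 <- occupancy_grid(tr2, atom_select(tr2$topology, chain = "L"),
                       spacing = 1)
  truth2 <- ligand_occupancy_truth(spec2, g2)
  ci <- 3 * sqrt(0.5 * 0.5 / 2000)
  for (r in 1:3) {
    obs <- g2$values[truth2$i[r], truth2$j[r], truth2$k[r]]
    expect_lt(abs(obs - truth2$expected[r]), ci)
  }

  ## jittered ligand: per-voxel expectation from the normal-interval product
  spec3 <- groove_sim_spec(n_res_alpha = 6, n_res_beta = 6, peptide_len = 0,
                           n_frames = 4000, ligand = TRUE,
                           ligand_presence = 1, ligand_jitter = 0.15,
                           seed = 33)
  tr3 <- simulate_trajectory(spec3)
  g3 <- occupancy_grid(tr3, atom_select(tr3$topology, chain = "L"),
                       spacing = 1)
  truth3 <- ligand_occupancy_truth(spec3, g3)
  for (r in 1:3) {
    obs <- g3$values[truth3$i[r], truth3$j[r], truth3$k[r]]
    tol <- 3 * sqrt(truth3$expected[r] * (1 - truth3$expected[r]) / 4000) +
      0.01
    expect_lt(abs(obs - truth3$expected[r]), tol)
  }
  expect_error(ligand_occupancy_truth(groove_sim_spec(), g3), "ligand")
})

test_that("recovered means and slopes bracket the truth across seeds", {
  d0 <- 13.3; slope <- -0.12; sig <- 0.4; nf <- 200; dt <- 0.004
  cover_mean <- 0L; cover_slope <- 0L
  tt <- (0:(nf - 1)) * dt
  for (sd_i in 1:20) {
    spec <- groove_sim_spec(n_res_alpha = 10, n_res_beta = 12,
                            peptide_len = 0, d0 = d0, slope = slope,
                            sigma_d = sig, n_frames = nf, seed = 500 + sd_i)
    ser <- groove_distance_series(simulate_trajectory(spec),
                                  groove_of(build_groove(spec)))
    fit <- lm(ser$values ~ ser$times)
    ci <- confint(fit)
    truth_mean <- d0 + slope * mean(tt)
    m_est <- mean(ser$values)
    se_m <- sd(ser$values - fitted(fit)) / sqrt(nf)
    if (abs(m_est - truth_mean) < qt(0.975, nf - 1) * se_m)
      cover_mean <- cover_mean + 1L
    if (ci[2, 1] < slope && slope < ci[2, 2])
      cover_slope <- cover_slope + 1L
  }
  expect_gte(cover_mean, 18)   # >= 90% coverage at nominal 95%
  expect_gte(cover_slope, 18)
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(groove_sim_spec(n_frames = 0))
  expect_error(groove_sim_spec(dt = 0))
  expect_error(groove_sim_spec(sigma_d = -1))
  expect_error(groove_sim_spec(residue_jitter = c(0.1, 0.2)),
               "residue_jitter")
  expect_error(groove_sim_spec(ligand_presence = 1.5))
})
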