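test_that("all generators are bit-reproducible under a fixed seed", {
  a <- gen_fd_traces(3, seed = 101)
  b <- gen_fd_traces(3, seed = 101)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traces[[2]]$force_pN, b$traces[[2]]$force_pN)

  U <- function(z) 0.5 * 10 * (z - 3)^2
  u1 <- gen_umbrella_samples(U, window_centers_nm = c(2.6, 3, 3.4),
                             n_samples_per_window = 500, seed = 7)
  u2 <- gen_umbrella_samples(U, window_centers_nm = c(2.6, 3, 3.4),
                             n_samples_per_window = 500, seed = 7)
  expect_identical(u1$windows[[2]]$samples_nm, u2$windows[[2]]$samples_nm)

  c1 <- gen_collapse_trajectories(n_traj = 4, target_tau_ns = 3, seed = 5,
                                  t_max_ns = 10)
  c2 <- gen_collapse_trajectories(n_traj = 4, target_tau_ns = 3, seed = 5,
                                  t_max_ns = 10)
  expect_identical(c1$truth, c2$truth)

  p1 <- gen_amide1_spectra(seed = 9, n_carriers = 1, n_wells = 2)
  p2 <- gen_amide1_spectra(seed = 9, n_carriers = 1, n_wells = 2)
  expect_identical(p1$plate, p2$plate)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  r1 <- runif(1)
  set.seed(1234)
  invisible(gen_fd_traces(1, seed = 9))
  invisible(gen_amide1_spectra(seed = 9, n_carriers = 1, n_wells = 1))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("trace generator validates fractions and emits ground truth", {
  expect_error(gen_fd_traces(2, specific_fraction = 1.2), "\\[0, 1\\]")
  expect_error(gen_fd_traces(2, noise_sd_pN = -1), "non-negative")
  sim <- gen_fd_traces(10, seed = 3, specific_fraction = 0.5)
  expect_identical(nrow(sim$truth), 10L)
  expect_true(all(sim$truth$lc_nm > 20, na.rm = TRUE))
  expect_setequal(unique(sim$truth$specific), c(TRUE, FALSE))
})

test_that("zero specific fraction yields no accepted traces downstream", {
  sim <- gen_fd_traces(20, seed = 19, specific_fraction = 0)
  res <- analyze_afm_cohort(sim$traces)
  expect_lte(sum(res$accepted), 1L)  # detector specificity >= 99 %
})

test_that("a flat potential gives the harmonic-window spread sqrt(kBT/k)", {
  sim <- gen_umbrella_samples(function(z) 0 * z, window_centers_nm = 3,
                              n_samples_per_window = 10000, seed = 3)
  expect_equal(sd(sim$windows[[1]]$samples_nm), sqrt(0.0083145 * 300 / 500),
               tolerance = 0.03)
  expect_equal(mean(sim$windows[[1]]$samples_nm), 3, tolerance = 0.005)
})

test_that("umbrella generator rejects a vanishing biased density", {
  U <- function(z) rep(Inf, length(z))
  expect_error(gen_umbrella_samples(U, window_centers_nm = 3,
                                    n_samples_per_window = 10, seed = 1),
               "numerically zero")
})

test_that("noise-free drift crosses the threshold at the analytic time", {
  pot <- list(U = function(z) 5 * z, dU = function(z) rep(5, length(z)))
  kBT <- 0.0083145 * 300
  mob <- 0.5 / kBT
  sim <- gen_collapse_trajectories(n_traj = 2, z_start_nm = 7,
                                   potential = pot, diffusion_nm2_ns = 0,
                                   mobility_nm2_kJ_mol_ns = mob,
                                   dt_ns = 1e-3, t_max_ns = 30, seed = 1)
  fpt <- first_passage_times(sim$trajectories)
  expect_equal(fpt$time_ns, rep((7 - 1.5) / (mob * 5), 2), tolerance = 0.01)
})

test_that("a strong trap above the threshold censors every trajectory", {
  pot <- list(U = function(z) 0.5 * 200 * (z - 5)^2,
              dU = function(z) 200 * (z - 5))
  sim <- gen_collapse_trajectories(n_traj = 5, z_start_nm = 5,
                                   potential = pot, diffusion_nm2_ns = 0.5,
                                   dt_ns = 1e-4, t_max_ns = 2, seed = 2)
  fpt <- first_passage_times(sim$trajectories)
  expect_true(all(fpt$censored))
})

test_that("oversized integration steps are rejected", {
  pot <- list(U = function(z) 0.5 * 500 * (z - 5)^2,
              dU = function(z) 500 * (z - 5))
  expect_error(gen_collapse_trajectories(n_traj = 1, z_start_nm = 6,
                                         potential = pot, dt_ns = 0.05,
                                         t_max_ns = 1, seed = 1),
               "too large")
})

test_that("calibrated collapse dynamics reproduce the target lifetime", {
  pot <- calibrate_collapse_potential(5)
  expect_equal(collapse_mfpt(pot, 2), 5, tolerance = 1e-6)
  sim <- gen_collapse_trajectories(n_traj = 200, target_tau_ns = 5, seed = 8)
  fpt <- first_passage_times(sim$trajectories)
  fit <- fit_lifetime(fpt, n_boot = 100, boot_seed = 1)
  expect_equal(fit$tau_ns, 5, tolerance = 0.2)
})

test_that("noiseless plates round-trip through preprocessing and fitting", {
  sim <- gen_amide1_spectra(noise_sd = 0, seed = 4, n_carriers = 1,
                            n_wells = 1)
  pre <- preprocess_spectra(sim$spectra)
  fit <- fit_gaussian_mixture(pre[[1]], 3, seed = 6)
  expect_equal(sort(fit$components$center_cm1), sim$truth$center_cm1,
               tolerance = 1e-3)
  expect_equal(sort(fit$components$fwhm_cm1), sort(sim$truth$fwhm_cm1),
               tolerance = 1e-2)
  expect_equal(fit$components$area_fraction, sim$truth$area,
               tolerance = 1e-3)
  expect_error(gen_amide1_spectra(
    components = data.frame(center_cm1 = 1500, fwhm_cm1 = 10, area = 1)),
    "within the region")
})
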