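test_that("single unbiased window reduces to direct Boltzmann inversion", {
  set.seed(2)
  samp <- rnorm(20000, 3, 0.5)
  pmf <- wham(list(umbrella_window(3, 1e-9, samp)), bin_width_nm = 0.1)
  expect_true(pmf$converged)
  h <- rowSums(pmf$counts)
  p <- h / sum(h)
  kBT <- 0.0083145 * 300
  G_dir <- ifelse(p > 0, -kBT * log(p), NA)
  G_dir <- G_dir - min(G_dir, na.rm = TRUE)
  well <- h >= 100
  expect_lt(max(abs(pmf$free_energy_kJ_mol[well] - G_dir[well])), 0.05)
  # and the empirical inversion tracks the known Gaussian free energy
  # (statistical error ~ kBT/sqrt(count) per bin)
  G_true <- kBT * (pmf$grid_nm - 3)^2 / (2 * 0.5^2)
  strong <- h >= 1000
  off <- mean((pmf$free_energy_kJ_mol - G_true)[strong])
  expect_lt(max(abs((pmf$free_energy_kJ_mol - G_true - off)[strong])), 0.3)
})

test_that("wham recovers a quadratic PMF under the study window layout", {
  U <- function(z) 0.5 * 10 * (z - 3)^2
  sim <- gen_umbrella_samples(U, n_samples_per_window = 5000, seed = 5)
  pmf <- wham(sim$windows, max_iter = 500000)
  expect_true(pmf$converged)
  sel <- rowSums(pmf$counts) >= 50 & is.finite(pmf$free_energy_kJ_mol)
  fit <- lm(G ~ poly(z, 2, raw = TRUE),
            data = data.frame(z = pmf$grid_nm[sel],
                              G = pmf$free_energy_kJ_mol[sel]))
  curv <- 2 * coef(fit)[[3]]
  expect_equal(curv, 10, tolerance = 0.05)
  expect_equal(min(pmf$free_energy_kJ_mol, na.rm = TRUE), 0)
})

test_that("wham is bit-identical under window permutation", {
  U <- function(z) 0.5 * 8 * (z - 2)^2
  sim <- gen_umbrella_samples(U, window_centers_nm = seq(0.8, 3.2, 0.4),
                              n_samples_per_window = 1000, seed = 9)
  p1 <- wham(sim$windows)
  p2 <- wham(rev(sim$windows))
  expect_identical(p1$free_energy_kJ_mol, p2$free_energy_kJ_mol)
  expect_identical(p1$n_iterations, p2$n_iterations)
})

test_that("non-overlapping windows raise a connectivity error naming the gap", {
  w1 <- umbrella_window(1, 100, rnorm(200, 1, 0.05))
  w2 <- umbrella_window(5, 100, rnorm(200, 5, 0.05))
  expect_error(wham(list(w1, w2)), "do not overlap")
  expect_error(wham(list(w1, w2)), "1 and 5")
})

test_that("wham enforces its sampling preconditions", {
  w <- umbrella_window(1, 100, rnorm(50, 1, 0.05))
  expect_error(wham(list(w)), "at least 100 samples")
  w2 <- umbrella_window(1, 100, rnorm(200, 1, 0.05))
  expect_error(wham(list(w2), grid_nm = seq(0.9, 1.1, 0.01)),
               "outside the supplied grid")
})

test_that("mean force converts PMF slopes to pN at 1.6606 pN per kJ/mol/nm", {
  z <- seq(0, 2, 0.1)
  flat <- mean_force_profile(list(grid_nm = z,
                                  free_energy_kJ_mol = rep(1, length(z))))
  expect_equal(flat$force_pN, rep(0, nrow(flat)))
  quad <- mean_force_profile(list(grid_nm = z,
                                  free_energy_kJ_mol = 0.5 * 10 * z^2))
  expect_equal(quad$force_pN[quad$z_nm == 1], 16.606, tolerance = 1e-6)
  expect_error(mean_force_profile(list(grid_nm = c(0, 1),
                                       free_energy_kJ_mol = c(0, 1))),
               "at least 3")
})

test_that("mean force round-trips an integrated WLC force curve", {
  p <- wlc_params(0.66, 7.0)
  z <- seq(0.05, 6.5, by = 0.05)
  U <- wlc_pmf_fun(0.66, 7.0)
  mf <- mean_force_profile(list(grid_nm = z, free_energy_kJ_mol = U(z)))
  tru <- wlc_force(p, mf$z_nm)
  sel <- tru > 0.5
  expect_lt(max(abs(mf$force_pN[sel] - tru[sel]) / tru[sel]), 0.02)
})

test_that("refusing to differentiate an unconverged PMF", {
  U <- function(z) 0.5 * 8 * (z - 2)^2
  sim <- gen_umbrella_samples(U, window_centers_nm = seq(1.2, 2.8, 0.4),
                              n_samples_per_window = 500, seed = 3)
  pmf <- wham(sim$windows, max_iter = 3L)
  expect_false(pmf$converged)
  expect_error(mean_force_profile(pmf), "did not converge")
})

test_that("window files and manifests parse, skipping xvg comments", {
  dir <- withr::local_tempdir()
  set.seed(4)
  for (i in 1:2) {
    z <- rnorm(300, i, 0.07)
    writeLines(c("@ title \"umbrella\"", sprintf("#center_nm %g", i),
                 "#spring_constant_kJ_mol_nm2 500",
                 sprintf("%.4f %.5f", seq_along(z) * 0.01, z)),
               file.path(dir, sprintf("win%d.xvg", i)))
  }
  wins <- read_umbrella_windows(dir)
  expect_length(wins, 2L)
  expect_equal(wins[[2]]$center_nm, 2)
  expect_equal(wins[[1]]$spring_constant_kJ_mol_nm2, 500)
  expect_length(wins[[1]]$samples_nm, 300L)
  # manifest route overrides headers
  writeLines(c("file\tcenter_nm\tspring_constant_kJ_mol_nm2",
               "win1.xvg\t1\t400", "win2.xvg\t2\t400"),
             file.path(dir, "manifest.tsv"))
  wins2 <- read_umbrella_windows(dir, file.path(dir, "manifest.tsv"))
  expect_equal(wins2[[1]]$spring_constant_kJ_mol_nm2, 400)
})

test_that("pipeline recovery: WLC persistence length from WHAM mean forces", {
  lp <- 0.89
  sim <- gen_umbrella_samples(wlc_pmf_fun(lp, 7.5),
                              n_samples_per_window = 5000, seed = 31)
  pmf <- wham(sim$windows, max_iter = 500000)
  rng <- pmf_supported_range(pmf)
  mf <- mean_force_profile(pmf)
  sel <- mf$z_nm >= max(rng[1], 0.4) & mf$z_nm <= rng[2]
  fit <- fit_wlc(mf[sel, ], fixed = list(contour_length_nm = 7.5))
  expect_equal(fit$params$persistence_length_nm, lp, tolerance = 0.05)
})
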