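test_that("first-passage detection interpolates the threshold crossing", {
  # linear descent z(t) = 7 - t crosses 1.5 nm at t = 5.5
  t <- seq(0, 7, by = 0.1)
  tr <- end_to_end_trajectory(t, pmax(7 - t, 0.01), "lin")
  fpt <- first_passage_times(list(tr))
  expect_false(fpt$censored)
  expect_equal(fpt$time_ns, 5.5, tolerance = 0.05)
  # already collapsed at the first frame
  tr0 <- end_to_end_trajectory(c(0, 1), c(1.2, 1.1), "low")
  expect_equal(first_passage_times(list(tr0))$time_ns, 0)
  # never collapsing: censored at the final time
  trc <- end_to_end_trajectory(t, rep(6, length(t)), "flat")
  fptc <- first_passage_times(list(trc))
  expect_true(fptc$censored)
  expect_equal(fptc$time_ns, 7)
})

test_that("cumulative event curves count passages and respect censoring", {
  times <- data.frame(trajectory_id = c("a", "b", "c"),
                      time_ns = c(1, 2, 3), censored = FALSE)
  cc <- cumulative_events(times, c(0, 2.5, 5))
  expect_equal(cc$count, c(0, 2, 3))
  allc <- data.frame(trajectory_id = "a", time_ns = 5, censored = TRUE)
  expect_equal(cumulative_events(allc, c(1, 10))$count, c(0, 0))
  # curve equals the empirical CDF scaled by the cohort size
  set.seed(6)
  ev <- data.frame(trajectory_id = paste0("t", 1:20),
                   time_ns = rexp(20, 1 / 4), censored = FALSE)
  grid <- seq(0.1, 30, length.out = 50)
  expect_equal(cumulative_events(ev, grid)$count,
               ecdf(ev$time_ns)(grid) * 20)
  # monotone, plateauing at the number of events
  expect_true(all(diff(cumulative_events(ev, grid)$count) >= 0))
  expect_equal(max(cumulative_events(ev, grid)$count), 20)
})

test_that("the noiseless cumulative-exponential curve is recovered exactly", {
  grid <- seq(0.1, 40, length.out = 150)
  counts <- 20 * (1 - exp(-grid / 5.7))
  fit <- fit_cumulative_exponential(grid, counts, 20)
  expect_equal(fit$tau_ns, 5.7, tolerance = 1e-6)
  expect_false(fit$at_bounds)
})

test_that("lifetime fitting is scale-equivariant and validates its input", {
  set.seed(12)
  times <- data.frame(trajectory_id = paste0("t", 1:20),
                      time_ns = rexp(20, 1 / 5), censored = FALSE)
  f1 <- fit_lifetime(times, n_boot = 50, boot_seed = 2)
  times2 <- times
  times2$time_ns <- times$time_ns * 3
  f2 <- fit_lifetime(times2, n_boot = 50, boot_seed = 2)
  expect_equal(f2$tau_ns, 3 * f1$tau_ns, tolerance = 1e-3)
  expect_identical(f1$n_events + f1$n_censored, f1$n_total)
  few <- times[1:2, ]
  expect_error(fit_lifetime(few), "at least 3")
})

test_that("free-plateau fitting matches the constrained fit on clean data", {
  grid <- seq(0.1, 40, length.out = 120)
  counts <- 20 * (1 - exp(-grid / 5.7))
  fit <- fit_cumulative_exponential(grid, counts, 20, free_plateau = TRUE)
  expect_equal(fit$tau_ns, 5.7, tolerance = 1e-4)
  expect_equal(fit$plateau, 20, tolerance = 1e-4)
})

test_that("lifetime estimator bias is small at the study cohort size", {
  set.seed(77)
  tau <- 5.7
  est <- replicate(400, {
    times <- data.frame(trajectory_id = "x", time_ns = rexp(20, 1 / tau),
                        censored = FALSE)
    grid <- seq(0, max(times$time_ns), length.out = 200)[-1]
    fit_cumulative_exponential(grid, cumulative_events(times, grid)$count,
                               20)$tau_ns
  })
  expect_lt(abs(mean(est) - tau), 0.1 * tau)
})

test_that("ppii fraction counts residues inside the dihedral window", {
  dih <- data.frame(frame = rep(1:2, each = 4),
                    residue = rep(1:4, 2),
                    phi_deg = c(rep(-75, 4), rep(c(-75, -60), 2)),
                    psi_deg = c(rep(145, 4), rep(c(145, -45), 2)))
  pf <- ppii_fraction(dih)
  expect_equal(pf$ppii_fraction, c(1, 0.5))
  helix <- data.frame(frame = 1, residue = 1:3, phi_deg = -60, psi_deg = -45)
  expect_equal(ppii_fraction(helix)$ppii_fraction, 0)
  # invariant under residue reordering
  sh <- dih[sample(nrow(dih)), ]
  expect_equal(ppii_fraction(sh), pf)
  bad <- data.frame(frame = 1, residue = 1, phi_deg = -181, psi_deg = 0)
  expect_error(ppii_fraction(bad), "-180")
  expect_error(ppii_fraction(dih[0, ]), "empty")
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  sim <- gen_collapse_trajectories(n_traj = 20, target_tau_ns = 5.7, seed = 3)
  fpt <- first_passage_times(sim$trajectories)
  fit <- fit_lifetime(fpt, n_boot = 200, boot_seed = 4)
  expect_gt(fit$tau_ns, 0)
  expect_lt(fit$tau_ci_ns[1], fit$tau_ns)
  expect_gt(fit$tau_ci_ns[2], fit$tau_ns)
  expect_identical(fit$n_total, 20L)
})
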