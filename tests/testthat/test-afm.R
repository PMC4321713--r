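test_that("trace files round-trip through read_traces with metadata", {
  dir <- withr::local_tempdir()
  d <- seq(0, 99.9, by = 0.1)
  writeLines(c("#pulling_speed_nm_s 800",
               sprintf("%.3f\t%.3f", d, sin(d))),
             file.path(dir, "t1.tsv"))
  traces <- read_traces(file.path(dir, "t1.tsv"))
  expect_length(traces, 1L)
  expect_length(traces[[1]]$distance_nm, 1000L)
  expect_equal(traces[[1]]$pulling_speed_nm_s, 800)
  expect_equal(traces[[1]]$trace_id, "t1")
})

test_that("malformed trace files raise parse errors naming the line", {
  dir <- withr::local_tempdir()
  writeLines(c("0\t1", "1\t2\t3", "2\t4"), file.path(dir, "bad.tsv"))
  expect_error(read_traces(file.path(dir, "bad.tsv")), "line 2")
  writeLines(c("0\t1", "1\tx"), file.path(dir, "bad2.tsv"))
  expect_error(read_traces(file.path(dir, "bad2.tsv")), "line 2")
})

test_that("write_traces/read_traces is an identity on generated cohorts", {
  dir <- withr::local_tempdir()
  sim <- gen_fd_traces(3, seed = 5, noise_sd_pN = 2)
  write_traces(sim$traces, dir)
  back <- read_traces(dir)
  expect_equal(vapply(back, `[[`, character(1), "trace_id"),
               vapply(sim$traces, `[[`, character(1), "trace_id"))
  expect_equal(back[[2]]$force_pN, sim$traces[[2]]$force_pN,
               tolerance = 1e-5)
})

test_that("baseline correction removes offsets and finds the contact point", {
  sim <- gen_fd_traces(1, seed = 3, noise_sd_pN = 0.5, contact_nm = 13,
                       baseline_offset_pN = 10)
  tr <- correct_baseline(sim$traces[[1]])
  n <- length(tr$force_pN)
  tail_f <- tr$force_pN[(n - n %/% 10):n]
  expect_lt(abs(median(tail_f)), 0.2)
  expect_equal(attr(tr, "contact_shift_nm"), 13, tolerance = 0.5)
  # idempotence: a corrected trace passes through unchanged
  tr2 <- correct_baseline(tr)
  expect_equal(tr2$distance_nm, tr$distance_nm, tolerance = 1e-9)
  expect_equal(tr2$force_pN, tr$force_pN, tolerance = 1e-9)
})

test_that("baseline correction rejects short or still-attached traces", {
  expect_error(correct_baseline(fd_trace("x", 1:10, rnorm(10))),
               "at least 50")
  # molecule still attached at the end: tail is a steep WLC rise
  p <- wlc_params(0.4, 60)
  d <- seq(0, 55, by = 0.25)
  expect_error(correct_baseline(fd_trace("y", d, wlc_force(p, d))),
               "baseline segment")
})

test_that("contour-length transform inverts WLC branches exactly", {
  p <- wlc_params(0.4, 100)
  x <- seq(30, 95, by = 0.5)
  tr <- fd_trace("t", x, wlc_force(p, x))
  lt <- contour_length_transform(tr, 0.4, min_force_pN = 10)
  expect_false(lt$empty)
  expect_equal(lt$lc_nm, rep(100, length(lt$lc_nm)), tolerance = 1e-6)
})

test_that("two-branch traces give a bimodal contour-length density", {
  p1 <- wlc_params(0.4, 90)
  p2 <- wlc_params(0.4, 98)
  x1 <- seq(40, wlc_extension(p1, 200), by = 0.2)
  x2 <- seq(max(x1) + 0.2, wlc_extension(p2, 200), by = 0.2)
  tr <- fd_trace("t", c(x1, x2), c(wlc_force(p1, x1), wlc_force(p2, x2)))
  lt <- contour_length_transform(tr, 0.4, min_force_pN = 10)
  modes <- sort(unique(round(lt$lc_nm, 1)))
  expect_equal(range(lt$lc_nm), c(90, 98), tolerance = 0.5)
  expect_gt(sum(abs(lt$lc_nm - 90) < 0.5), 10)
  expect_gt(sum(abs(lt$lc_nm - 98) < 0.5), 10)
})

test_that("all-noise traces below threshold give an empty transform", {
  set.seed(8)
  tr <- fd_trace("n", seq(0, 50, by = 0.1), rnorm(501, 0, 2))
  lt <- contour_length_transform(tr, 0.4, min_force_pN = 10)
  expect_true(lt$empty)
  expect_identical(lt$n_points, 0L)
})

test_that("specific double ruptures are detected at the 8 nm separation", {
  sim <- gen_fd_traces(1, seed = 17, noise_sd_pN = 3, specific_fraction = 1)
  tr <- correct_baseline(sim$traces[[1]])
  ev <- detect_specific_event(tr)
  expect_true(ev$specific)
  expect_equal(ev$delta_Lc_nm, 8, tolerance = 1.5)
  expect_lt(ev$first_peak_index, ev$second_peak_index)
})

test_that("single ruptures and wide separations are rejected with reasons", {
  sim <- gen_fd_traces(6, seed = 23, specific_fraction = 0, noise_sd_pN = 3)
  kinds <- sim$truth$kind
  i <- which(kinds == "single")[1]
  tr <- correct_baseline(sim$traces[[i]])
  ev <- detect_specific_event(tr)
  expect_false(ev$specific)
  expect_match(ev$reason, "single peak|no peaks")
  # 16 nm separation falls outside the 8 +/- 2 nm window
  sim2 <- gen_fd_traces(1, seed = 29, specific_fraction = 1,
                        separation_nm = 16, noise_sd_pN = 3)
  tr2 <- correct_baseline(sim2$traces[[1]])
  ev2 <- detect_specific_event(tr2)
  expect_false(ev2$specific)
  expect_equal(ev2$reason, "separation outside window")
  expect_equal(ev2$delta_Lc_nm, 16, tolerance = 2)
})

test_that("detector accuracy exceeds 99 % on strong-peak cohorts", {
  sim_s <- gen_fd_traces(100, seed = 31, specific_fraction = 1)
  sim_n <- gen_fd_traces(100, seed = 37, specific_fraction = 0)
  flag <- function(sim) vapply(sim$traces, function(t) {
    tr <- try(correct_baseline(t), silent = TRUE)
    if (inherits(tr, "try-error")) return(FALSE)
    isTRUE(detect_specific_event(tr)$specific)
  }, logical(1))
  acc <- (sum(flag(sim_s)) + sum(!flag(sim_n))) / 200
  expect_gte(acc, 0.99)
})

test_that("analyze_trace recovers parameters and rejects non-specific events", {
  # noiseless: exact recovery
  sim0 <- gen_fd_traces(1, seed = 41, noise_sd_pN = 1e-3)
  tr0 <- correct_baseline(sim0$traces[[1]])
  ev0 <- detect_specific_event(tr0)
  fit0 <- analyze_trace(tr0, ev0)
  expect_equal(fit0$params$contour_length_nm, sim0$truth$lc_nm[1],
               tolerance = 1e-3)
  expect_equal(fit0$params$persistence_length_nm, 0.37, tolerance = 1e-3)
  expect_equal(fit0$fit_window[2], ev0$first_peak_index)
  # at instrument noise the zero-force uncertainty dominates: typical
  # (median) per-trace errors stay within 5 % on Lc and 30 % on Lp
  sim <- gen_fd_traces(40, seed = 43, noise_sd_pN = 5)
  lc_err <- lp_err <- numeric(0)
  for (i in seq_along(sim$traces)) {
    tr <- correct_baseline(sim$traces[[i]])
    ev <- detect_specific_event(tr)
    if (!isTRUE(ev$specific)) next
    fit <- analyze_trace(tr, ev)
    lc_err <- c(lc_err, abs(fit$params$contour_length_nm /
                              sim$truth$lc_nm[i] - 1))
    lp_err <- c(lp_err, abs(fit$params$persistence_length_nm / 0.37 - 1))
  }
  expect_gte(length(lc_err), 30)
  expect_lt(median(lc_err), 0.05)
  expect_lt(median(lp_err), 0.3)
  bad <- structure(list(specific = FALSE, reason = "single peak"),
                   class = "stretch_event")
  expect_error(analyze_trace(tr0, bad), "rejected")
})

test_that("population summary reproduces hand arithmetic and histogram mass", {
  mk <- function(lp, lc) structure(list(
    params = wlc_params(lp, lc),
    param_uncertainties = c(persistence_length_nm = NA, contour_length_nm = NA),
    residual_norm = 0, n_points = 10, fit_window = c(1, 10),
    fixed_mask = c(persistence_length_nm = FALSE, contour_length_nm = FALSE)),
    class = "wlc_fit")
  fits <- list(mk(0.2, 80), mk(0.4, 90), mk(0.6, 100))
  s <- summarize_population(fits)
  expect_equal(s$persistence_mean_nm, 0.4)
  expect_equal(s$persistence_sd_nm, 0.1633, tolerance = 1e-3)
  expect_equal(sum(s$lc_histogram$counts), s$n_accepted)
  expect_equal(sum(s$lp_histogram$counts), s$n_accepted)
  s1 <- summarize_population(fits[1])
  expect_identical(s1$contour_sd_nm, 0)
  expect_error(summarize_population(list()), "no fits")
})
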