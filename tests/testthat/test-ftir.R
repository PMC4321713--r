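test_that("preprocessing yields unit-norm, trend-free spectra and is idempotent", {
  sim <- gen_amide1_spectra(seed = 7, n_carriers = 1, n_wells = 2)
  pre <- preprocess_spectra(sim$spectra)
  for (sp in pre) {
    expect_equal(sqrt(sum(sp$absorbance^2)), 1, tolerance = 1e-12)
    expect_lt(abs(mean(sp$absorbance)), 1e-12)
  }
  again <- preprocess_spectra(pre)
  expect_equal(again[[1]]$absorbance, pre[[1]]$absorbance, tolerance = 1e-9)
})

test_that("preprocessing rejects non-covering and degenerate spectra", {
  x <- seq(1620, 1700, 1)
  expect_error(preprocess_spectra(ir_spectrum(x, exp(-x / 100))),
               "does not cover")
  x2 <- seq(1590, 1725, 1)
  expect_error(preprocess_spectra(ir_spectrum(x2, 2 + 0.01 * x2)),
               "degenerate")
})

test_that("baseline removal preserves the band shape", {
  x <- seq(1590, 1725, 1)
  clean <- gauss_curve(x, 1650, 20, 0.3)
  sp <- ir_spectrum(x, clean + 0.1 + 0.002 * (x - 1600))
  pp <- preprocess_spectra(sp)
  keep <- x >= 1600 & x <= 1715
  g <- clean[keep]
  xc <- pp$wavenumber_cm1 - mean(pp$wavenumber_cm1)
  g_detr <- g - mean(g) - xc * sum(xc * g) / sum(xc^2)
  expect_gt(cor(pp$absorbance, g_detr), 0.999)
  expect_gt(cor(pp$absorbance, g), 0.99)
})

test_that("median spectrum is robust to a corrupted replicate", {
  x <- seq(1600, 1715, 1)
  clean <- gauss_curve(x, 1650, 18, 0.2)
  set.seed(3)
  reps <- lapply(1:9, function(i)
    ir_spectrum(x, clean + rnorm(length(x), 0, 0.002)))
  spike <- clean
  spike[40:45] <- spike[40:45] + 1
  reps[[5]] <- ir_spectrum(x, spike)
  med <- median_spectrum(reps)
  expect_lt(max(abs(med$absorbance - clean)), 0.01)
  # identical replicates: the median is the common spectrum
  same <- lapply(1:3, function(i) ir_spectrum(x, clean))
  expect_equal(median_spectrum(same)$absorbance, clean)
  # mismatched grids are rejected
  off <- ir_spectrum(x + 0.5, clean)
  expect_error(median_spectrum(list(reps[[1]], off)), "common wavenumber")
})

test_that("a noiseless single Gaussian is recovered to 1e-4", {
  x <- seq(1600, 1715, 1)
  sp <- ir_spectrum(x, gauss_curve(x, 1650, 20, 0.3))
  fit <- fit_gaussian_mixture(sp, 1, seed = 3)
  expect_equal(fit$components$center_cm1, 1650, tolerance = 1e-4)
  expect_equal(fit$components$fwhm_cm1, 20, tolerance = 1e-4)
  expect_equal(fit$components$amplitude, 0.3, tolerance = 1e-4)
  expect_equal(fit$components$area_fraction, 1)
})

test_that("mixture fitting is deterministic given the seed", {
  sim <- gen_amide1_spectra(seed = 11, n_carriers = 1, n_wells = 1)
  sp <- sim$spectra[[1]]
  f1 <- fit_gaussian_mixture(sp, 3, seed = 42)
  f2 <- fit_gaussian_mixture(sp, 3, seed = 42)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$rss, f2$rss)
})

test_that("over-parameterised fits are refused", {
  x <- seq(1600, 1715, 4)  # 29 points
  sp <- ir_spectrum(x, gauss_curve(x, 1650, 20, 0.3))
  expect_error(fit_gaussian_mixture(sp, 13), "cannot constrain")
  expect_error(fit_gaussian_mixture(sp, 0), "between 1 and 13")
})

test_that("Akaike weights follow the printed formula", {
  # construct fits whose AICc values differ by exactly {0, 2}
  n <- 116L
  mk <- function(k, rss) structure(
    list(components = data.frame(center_cm1 = rep(1650, k),
                                 fwhm_cm1 = rep(10, k),
                                 amplitude = rep(1, k),
                                 area_fraction = rep(1 / k, k)),
         rss = rss, n_points = n, n_params = 3L * k, k = k, aicc = NA),
    class = "mixture_fit")
  aicc <- function(k, rss) {
    p <- 3 * k + 1
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  }
  # choose rss5 so that AICc(5) - AICc(3) = 2
  rss3 <- 1e-4
  rss5 <- exp((aicc(3, rss3) + 2 - 2 * 16 - 2 * 16 * 17 / (n - 17)) / n) * n
  sel <- select_component_count(list(mk(3, rss3), mk(5, rss5)))
  expect_equal(sel$table$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  # equal AICc: symmetric weights, mean midway
  rss5eq <- exp((aicc(3, rss3) - 2 * 16 - 2 * 16 * 17 / (n - 17)) / n) * n
  sel2 <- select_component_count(list(mk(3, rss3), mk(5, rss5eq)))
  expect_equal(sel2$table$weight, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sel2$weighted_mean_k, 4, tolerance = 1e-9)
  # single fit: all the weight, zero spread
  sel1 <- select_component_count(list(mk(3, rss3)))
  expect_identical(sel1$table$weight, 1)
  expect_identical(sel1$weighted_sd_k, 0)
  expect_error(select_component_count(list(mk(3, 1), mk(3, 2))), "distinct")
})

test_that("weights are invariant to a constant shift of all AICc values", {
  n <- 116L
  mk <- function(k, rss) structure(
    list(rss = rss, n_points = n, n_params = 3L * k, k = k),
    class = "mixture_fit")
  s1 <- select_component_count(list(mk(2, 1e-4), mk(4, 8e-5), mk(6, 7e-5)))
  # scaling every rss by c shifts every AICc by n log(c)
  s2 <- select_component_count(list(mk(2, 2e-4), mk(4, 1.6e-4), mk(6, 1.4e-4)))
  expect_equal(s1$table$weight, s2$table$weight, tolerance = 1e-12)
})

test_that("peak width analysis flags the broad disorder band", {
  mkfit <- function(widths, centers, areas) structure(
    list(components = data.frame(center_cm1 = centers, fwhm_cm1 = widths,
                                 amplitude = areas,
                                 area_fraction = areas / sum(areas)),
         rss = 1e-4, n_points = 116L, n_params = 3L * length(widths),
         k = length(widths)),
    class = "mixture_fit")
  # target band at 1645 twice as broad as its neighbours, 4 replicates
  fits <- lapply(1:4, function(i)
    mkfit(c(12, 30 + 0.2 * i, 12), c(1625, 1645, 1678), c(1, 1.5, 1)))
  rep_w <- peak_width_analysis(fits)
  expect_equal(rep_w$mean_fwhm_cm1, mean(30 + 0.2 * (1:4)))
  expect_lt(rep_w$p_value, 0.05)
  expect_equal(rep_w$mean_sd_width_cm1,
               rep_w$mean_fwhm_cm1 / (2 * sqrt(2 * log(2))))
  # all-equal widths: no significance
  fits0 <- lapply(1:4, function(i)
    mkfit(c(15, 15, 15), c(1625, 1645, 1678), c(1, 1, 1)))
  expect_gt(peak_width_analysis(fits0)$p_value, 0.9)
  # sub-1 % components are dropped before the search
  f <- mkfit(c(12, 40, 12), c(1625, 1645, 1678), c(1, 0.005, 1))
  ws <- capture_warnings(out <- peak_width_analysis(list(f, f)))
  expect_length(ws, 2L)
  expect_match(ws, "excluded", all = TRUE)
  expect_identical(out$excluded, c(1L, 2L))
  # a single replicate cannot support the test
  one <- peak_width_analysis(fits[1])
  expect_true(is.na(one$p_value))
  expect_match(one$test_note, "fewer than 2 replicates")
})

test_that("plate IO round-trips through long-format CSV", {
  dir <- withr::local_tempdir()
  sim <- gen_amide1_spectra(seed = 13, n_carriers = 2, n_wells = 3)
  path <- file.path(dir, "plate.csv")
  write.csv(sim$plate, path, row.names = FALSE)
  spectra <- read_plate_csv(path)
  expect_length(spectra, 6L)
  ids <- vapply(spectra, function(s) paste(s$carrier_id, s$well_id),
                character(1))
  expect_setequal(ids, unique(paste(sim$plate$carrier_id, sim$plate$well_id)))
})

test_that("component count is recovered from synthetic plates", {
  # a single carrier is a noisy estimate of the component count (the
  # replicated-carrier average is exercised in the acceptance suite)
  sim <- gen_amide1_spectra(seed = 1, n_carriers = 1)
  res <- analyze_amide1_carrier(sim$spectra, k_max = 8, n_starts = 10,
                                seed = 2)
  expect_gte(res$selection$weighted_mean_k, 2.5)
  expect_lte(res$selection$weighted_mean_k, 4.5)
  expect_equal(sum(res$selection$table$weight), 1, tolerance = 1e-12)
  # the dominant model's components sit at the generated band positions
  comp <- res$best_fit$components
  comp <- comp[comp$area_fraction > 0.05, ]
  expect_equal(sort(comp$center_cm1), c(1625, 1645, 1678), tolerance = 1)
})
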