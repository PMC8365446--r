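test_that("turnover arithmetic from product formation", {
  expect_equal(activity_from_product(31, 2, 5), 3.1)
  expect_equal(activity_from_product(0, 2, 5), 0)
  expect_equal(activity_from_product(31, 2, 10),
               activity_from_product(31, 2, 5) / 2)
  expect_error(activity_from_product(31, 0, 5), "enzyme")
  expect_error(activity_from_product(31, 2, -1), "time")
})

test_that("rate laws: half-saturation, nesting limit, inhibition maximum", {
  expect_equal(mm_rate(0.30, 47.6, 0.30), 23.8)
  S <- c(0.05, 0.3, 1, 5, 20)
  expect_equal(si_rate(S, 47.6, 0.3, 1e9), mm_rate(S, 47.6, 0.3),
               tolerance = 1e-6)
  # d v_SI / dS = 0 at S = sqrt(Km * Ki)
  km <- 0.8; ki <- 12; peak <- sqrt(km * ki)
  grid <- seq(0.05, 30, by = 0.005)
  v <- si_rate(grid, 10, km, ki)
  expect_equal(grid[which.max(v)], peak, tolerance = 0.01)
})

test_that("noiseless Michaelis-Menten data is recovered to >= 4 significant digits", {
  d1 <- simulate_assay(assay_spec(true_kcat = 47.6, true_km = 0.30, noise_cv = 0))
  f1 <- fit_model(d1, "MM")
  expect_true(f1$converged)
  expect_equal(f1$kcat, 47.6, tolerance = 1e-5)
  expect_equal(f1$km, 0.30, tolerance = 1e-5)

  d2 <- simulate_assay(assay_spec(true_kcat = 3.8, true_km = 6.85, noise_cv = 0,
                                  substrate_grid = c(0.5, 1, 2, 4, 6, 8, 10)))
  f2 <- fit_model(d2, "MM")
  expect_equal(f2$kcat, 3.8, tolerance = 1e-5)
  expect_equal(f2$km, 6.85, tolerance = 1e-5)
})

test_that("the substrate-inhibition model is recovered and nests MM", {
  spec <- assay_spec(true_kcat = 20, true_km = 1.5, true_ki = 8, noise_cv = 0,
                     substrate_grid = c(0.2, 0.5, 1, 2, 3.5, 5, 8, 12, 20))
  f <- fit_model(simulate_assay(spec), "MM_SI")
  expect_true(f$converged)
  expect_equal(f$kcat, 20, tolerance = 1e-4)
  expect_equal(f$km, 1.5, tolerance = 1e-4)
  expect_equal(f$ki, 8, tolerance = 1e-4)

  # on MM-generated data, the best achievable RSS at fixed ki decreases
  # monotonically toward the MM optimum as ki -> Inf
  dmm <- simulate_assay(assay_spec(noise_cv = 0.05, seed = 4))
  mm <- fit_model(dmm, "MM")
  rss_prof <- sapply(c(2, 10, 100, 1e4, 1e6), function(ki_fixed) {
    obj <- function(par) sum((dmm$rate_per_min -
      si_rate(dmm$substrate_mM, par[1], par[2], ki_fixed))^2)
    optim(c(mm$kcat, mm$km), obj, method = "L-BFGS-B",
          lower = c(1e-6, 1e-6))$value
  })
  # strongly inhibited fits are strictly worse; the profile approaches the
  # MM optimum as ki grows and, nesting MM, never ends up above it
  expect_true(all(diff(rss_prof[1:4]) <= 1e-6))
  expect_lte(rss_prof[4], mm$rss + 1e-6)
  expect_equal(rss_prof[5], mm$rss, tolerance = 1e-3)
})

test_that("MM on strongly inhibited wide-range data surfaces its failure", {
  spec <- assay_spec(true_kcat = 30, true_km = 8, true_ki = 1.5,
                     noise_cv = 0.05,
                     substrate_grid = c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 15, 20),
                     seed = 2)
  f <- fit_model(simulate_assay(spec), "MM")
  km_se <- if (!is.null(f$se)) f$se[["km"]] else NA
  expect_true(!f$converged || is.na(km_se) || km_se > abs(f$km) ||
                f$km < 1e-6)
})

test_that("insufficient substrate levels are rejected", {
  d <- data.frame(substrate_mM = c(1, 2, 3), rate_per_min = c(1, 2, 3))
  expect_error(fit_model(d, "MM"), ">= 4")
  d5 <- data.frame(substrate_mM = 1:4, rate_per_min = mm_rate(1:4, 5, 2))
  expect_error(fit_model(d5, "MM_SI"), ">= 5")
})

test_that("apparent fit truncates the range and flags the Km caveat", {
  spec <- assay_spec(true_kcat = 3.8, true_km = 6.85, true_ki = 30,
                     noise_cv = 0,
                     substrate_grid = c(0.5, 1, 2, 3, 4, 6, 8, 10, 14, 20),
                     replicates = 1)
  d <- simulate_assay(spec)
  full <- fit_model(d, "MM")
  app <- apparent_fit(d, s_max = 6)
  expect_true(app$apparent)
  # truncating below sqrt(Km*Ki) hides the inhibition: apparent Km
  # underestimates the generating Km (lower bound behaviour)
  expect_lt(app$km, 6.85)
  expect_error(apparent_fit(d, s_max = 1.5), "fewer than 4")
  # s_max = Inf reproduces the plain fit
  app_inf <- apparent_fit(d)
  expect_equal(app_inf$km, full$km)
  expect_equal(app_inf$kcat, full$kcat)
})

test_that("apparent estimates move smoothly when dropping top points", {
  d <- simulate_assay(assay_spec(noise_cv = 0.02, seed = 9))
  full <- fit_model(d, "MM")
  drop2 <- apparent_fit(d, s_max = sort(unique(d$substrate_mM),
                                        decreasing = TRUE)[3])
  expect_lt(abs(drop2$km - full$km) / full$km, 0.10)
  expect_lt(abs(drop2$kcat - full$kcat) / full$kcat, 0.10)
})

test_that("fit is invariant to replicate order and equivariant to rate scaling", {
  d <- simulate_assay(assay_spec(noise_cv = 0.05, seed = 21))
  f1 <- fit_model(d, "MM")
  shuffled <- d[sample(nrow(d)), ]
  f2 <- fit_model(shuffled, "MM")
  expect_equal(f1$kcat, f2$kcat, tolerance = 1e-8)
  expect_equal(f1$km, f2$km, tolerance = 1e-8)
  scaled <- transform(d, rate_per_min = rate_per_min * 3)
  f3 <- fit_model(scaled, "MM")
  expect_equal(f3$kcat, 3 * f1$kcat, tolerance = 1e-6)
  expect_equal(f3$km, f1$km, tolerance = 1e-6)
})

test_that("competition ratios report fold product excess", {
  expect_equal(competition_ratio(c(dGDP = 5.5, dGTP = 1.0)), 5.5)
  expect_equal(competition_ratio(c(dGDP = 2, dGTP = 2)), 1.0)
  expect_equal(competition_ratio(c(dGDP = 23, dGTP = 1)), 23)
  expect_error(competition_ratio(c(dGDP = 1)), ">= 2")
  expect_error(competition_ratio(c(dGDP = 1, dGTP = 0)), "> 0")
})
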