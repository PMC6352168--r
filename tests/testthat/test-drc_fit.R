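test_that("noiseless curves are recovered at the zero-residual optimum", {
  obs <- make_logistic_obs(y0 = 100, a = 2, s = 5)
  fit <- fit_loglogistic(obs)
  expect_true(fit$converged)
  expect_equal(fit$y0, 100, tolerance = 1e-6)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, -5, tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-8)

  # generating forms on the most acidic reference soil: hand-computed a
  soils <- load_reference_soils()
  params <- species_params("tomato")
  sim <- simulate_bioassay(soils, params, noise_spec(cv = 0, seed = 1),
                           treatments = "unleached")
  f2 <- fit_loglogistic(sim[sim$site_id == "Haikou", ])
  a_hand <- 0.63 + 0.21 * 4.93 + 0.54 * log10(1.5) + 0.28 * log10(8.75)
  expect_equal(f2$a, a_hand, tolerance = 1e-6)
  expect_equal(f2$y0, params$y0, tolerance = 1e-5)
})

test_that("the multistart optimizer matches an independent Levenberg-Marquardt fit", {
  soils <- load_reference_soils()
  sim <- simulate_bioassay(soils[1, , drop = FALSE],
                           species_params("tomato"),
                           noise_spec(cv = 0.08, seed = 13),
                           treatments = "unleached")
  f <- fit_loglogistic(sim)
  expect_true(f$converged)
  df <- data.frame(x = log10(sim$edta_cu), y = sim$relative_growth)
  nls_fit <- minpack.lm::nlsLM(y ~ y0 / (1 + exp(s * (x - a))), data = df,
                               start = list(y0 = 100, a = 2, s = 5),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200, ftol = 1e-12))
  co <- coef(nls_fit)
  expect_equal(f$y0, co[["y0"]], tolerance = 1e-4)
  expect_equal(f$a, co[["a"]], tolerance = 1e-4)
  expect_equal(-f$b, co[["s"]], tolerance = 1e-4)
  expect_lte(f$ssr, sum(residuals(nls_fit)^2) + 1e-6)
})

test_that("degenerate inputs are reported as fit failures, not estimates", {
  obs <- make_logistic_obs()
  flat <- obs; flat$relative_growth <- 100
  f <- fit_loglogistic(flat)
  expect_false(f$converged)
  expect_match(f$failure_reason, "no dose effect")

  few <- obs[obs$edta_cu %in% unique(obs$edta_cu)[1:3], ]
  expect_false(fit_loglogistic(few)$converged)

  # an EC50 far outside the tested window is not trusted
  shallow <- make_logistic_obs(a = 8, s = 1.2,
                               edta = 10^seq(0.5, 2, length.out = 8))
  f3 <- fit_loglogistic(shallow)
  expect_false(f3$converged)
})

test_that("ECx thresholds follow the closed forms of the fitted curve", {
  fit <- make_fit_stub("S1", a = 2.0443, b = -6.04)
  expect_equal(ec_x(fit, 50)$value, 10^2.0443, tolerance = 1e-12)
  ec10 <- ec_x(fit, 10)$value
  expect_equal(ec10, 10^(2.0443 - log(9) / 6.04), tolerance = 1e-9)
  expect_equal(ec10, 47.9, tolerance = 1e-3)
  expect_equal(ec_x(fit, 50)$value, 110.7, tolerance = 1e-3)
  expect_equal(ec_x(fit, 50)$value / ec10, 2.31, tolerance = 1e-2)
  expect_error(ec_x(fit, 0), "x_percent")
  expect_error(ec_x(fit, 100), "x_percent")
  expect_error(ec_x(make_fit_stub("S1", 2, 3), 10), "negative")
  # strictly increasing in inhibition level
  grid <- vapply(seq(5, 95, by = 5), function(x) ec_x(fit, x)$value,
                 numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("closed-form EC50/EC10 ratio matches the slope identity", {
  expect_equal(ec_ratio_closed_form(-log(9)), 10, tolerance = 1e-12)
  expect_equal(ec_ratio_closed_form(-6.04), 2.31, tolerance = 1e-2)
  expect_equal(ec_ratio_closed_form(-1e6), 1, tolerance = 1e-5)
  expect_error(ec_ratio_closed_form(0.5), "negative")
  # internal consistency with ec_x on fitted curves
  soils <- load_reference_soils()
  sim <- simulate_bioassay(soils, species_params("tomato"),
                           noise_spec(cv = 0.1, seed = 5),
                           treatments = "unleached")
  fits <- Filter(function(f) isTRUE(f$converged), fit_bioassay(sim))
  expect_gte(length(fits), 15)
  for (f in fits) {
    expect_equal(ec_x(f, 50)$value / ec_x(f, 10)$value,
                 ec_ratio_closed_form(f$b), tolerance = 1e-9)
  }
})

test_that("bootstrap intervals are reproducible and collapse without noise", {
  soils <- load_reference_soils()
  sim <- simulate_bioassay(soils[1:2, ], species_params("tomato"),
                           noise_spec(cv = 0, seed = 1),
                           treatments = "unleached")
  g <- sim[sim$site_id == soils$site_id[1], ]
  ci0 <- bootstrap_ci(g, 10, B = 50, seed = 11)
  expect_equal(ci0$ci_low, ci0$value, tolerance = 1e-6)
  expect_equal(ci0$ci_high, ci0$value, tolerance = 1e-6)

  simn <- simulate_bioassay(soils[1:2, ], species_params("tomato"),
                            noise_spec(cv = 0.1, seed = 2),
                            treatments = "unleached")
  gn <- simn[simn$site_id == soils$site_id[1], ]
  c1 <- bootstrap_ci(gn, 10, B = 200, seed = 7)
  c2 <- bootstrap_ci(gn, 10, B = 200, seed = 7)
  expect_identical(c1, c2)
  expect_true(c1$ci_low <= c1$value && c1$value <= c1$ci_high)
})

test_that("leaching factors summarize paired threshold ratios", {
  soils <- load_reference_soils()[1:5, ]
  shift <- log10(1.5)
  params <- species_params("tomato", leach_a_shift = shift)
  sim <- simulate_bioassay(soils, params, noise_spec(cv = 0, seed = 1),
                           treatments = c("unleached", "leached"))
  fits <- fit_bioassay(sim)
  ul <- Filter(function(f) f$treatment == "unleached", fits)
  le <- Filter(function(f) f$treatment == "leached", fits)
  lf <- leaching_factor(ul, le, 10)
  expect_equal(lf$mean, 1.5, tolerance = 1e-4)
  expect_lt(lf$sd, 1e-3)
  expect_equal(lf$n, 5)
  # identical fits on both sides -> factor exactly 1
  lf1 <- leaching_factor(ul, ul, 50)
  expect_equal(lf1$mean, 1)
  expect_equal(lf1$sd, 0)
  expect_error(leaching_factor(ul[1], le[2], 10), "2 soils")
})

test_that("threshold summaries report range, fold-variation and exclusions", {
  s <- summarize_thresholds(c(32.4, 608.8))
  expect_equal(signif(s$fold_variation, 3), 18.8)
  expect_equal(s$range, c(32.4, 608.8))
  expect_equal(signif(summarize_thresholds(c(4.5, 148.5))$fold_variation,
                      3), 33.0)
  expect_equal(summarize_thresholds(42)$fold_variation, 1)
  fits <- list(make_fit_stub("A", 2, -5), make_fit_stub("B", 2.5, -5),
               structure(list(site_id = "C", treatment = "unleached",
                              species = "tomato", converged = FALSE,
                              failure_reason = "x"),
                         class = "cu_drc_fit"))
  s2 <- summarize_thresholds(fits, 50)
  expect_equal(s2$n_used, 2)
  expect_equal(s2$fold_variation, 10^0.5, tolerance = 1e-12)
  expect_match(s2$excluded, "^C/")
})
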