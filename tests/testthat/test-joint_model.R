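test_that("covariate screening ranks perfect and degenerate relationships correctly", {
  soils <- load_reference_soils()
  fits <- lapply(seq_len(nrow(soils)), function(i) {
    make_fit_stub(soils$site_id[i], a = 2, b = 0.9 * soils$pH[i] - 12)
  })
  sc <- screen_b_covariates(fits, soils)
  expect_equal(sc$covariate[1], "pH")
  expect_equal(abs(sc$r_b[1]), 1, tolerance = 1e-12)
  expect_true(sc$significant_b[1])

  const <- lapply(seq_len(nrow(soils)), function(i) {
    make_fit_stub(soils$site_id[i], a = 2, b = -5)
  })
  sc0 <- screen_b_covariates(const, soils)
  expect_true(all(is.na(sc0$r_b)))
  expect_false(any(sc0$significant_b))

  expect_error(screen_b_covariates(fits[1:4], soils), "5 converged")
})

test_that("screening recovers the generating b-structure from synthetic fits", {
  soils <- load_reference_soils()
  sim <- simulate_bioassay(soils, species_params("tomato"),
                           noise_spec(cv = 0.05, seed = 21),
                           treatments = "unleached")
  sc <- screen_b_covariates(fit_bioassay(sim), soils)
  expect_true("pH" %in% sc$covariate[1:2])
  # OX-Mn (log scale in the pool) correlates with pH on this panel, so it
  # should appear among the top-ranked covariates as well
  expect_true(sc$significant_b[sc$covariate == "pH"])
})

test_that("the joint model recovers its generating parameters without noise", {
  soils <- load_reference_soils()
  params <- species_params("tomato")
  sim <- simulate_bioassay(soils, params, noise_spec(cv = 0, seed = 1),
                           treatments = "unleached")
  jf <- fit_joint(sim, soils, b_covariates = c("pH", "ox_mn"))
  expect_true(jf$converged)
  expect_equal(jf$y0, params$y0, tolerance = 1e-4)
  expect_equal(unname(jf$a_coefs), unname(params$a_coefs),
               tolerance = 1e-4)
  expect_equal(unname(jf$b_coefs),
               unname(params$b_coefs[c("intercept", "pH", "ox_mn")]),
               tolerance = 1e-4)
  expect_lt(jf$ssr, 1e-6)
  expect_lt(jf$p_model, 1e-10)
})

test_that("joint fitting guards identifiability and pooling preconditions", {
  soils <- load_reference_soils()
  sim <- simulate_bioassay(soils, species_params("tomato"),
                           noise_spec(cv = 0, seed = 1),
                           treatments = "unleached")
  expect_error(fit_joint(sim[sim$site_id == "Haikou", ], soils),
               "insufficient soil diversity")
  both <- simulate_bioassay(soils[1:6, ], species_params("tomato"),
                            noise_spec(cv = 0, seed = 1),
                            treatments = c("unleached", "leached"))
  expect_error(fit_joint(both, soils), "one species x treatment")
})

test_that("joint SSR is bounded below by the per-soil fits and r2 degrades with noise", {
  soils <- load_reference_soils()
  sim <- simulate_bioassay(soils, species_params("tomato"),
                           noise_spec(cv = 0.1, seed = 31),
                           treatments = "unleached")
  jf <- fit_joint(sim, soils)
  per <- fit_bioassay(sim)
  ssr_sum <- sum(vapply(per, function(f)
    if (isTRUE(f$converged)) f$ssr else 0, numeric(1)))
  # the joint model constrains per-soil parameters to the linear forms
  expect_gte(jf$ssr, ssr_sum - 1e-6)

  r2 <- vapply(c(0.05, 0.2), function(cv) {
    s <- simulate_bioassay(soils, species_params("tomato"),
                           noise_spec(cv = cv, seed = 31),
                           treatments = "unleached")
    fit_joint(s, soils)$r2
  }, numeric(1))
  expect_gt(r2[1], r2[2])
})

test_that("the optimizer is not beaten by an exhaustive grid around truth", {
  soils <- load_reference_soils()
  params <- species_params("tomato")
  truth <- c(y0 = params$y0, K1 = 0.63, K2 = 0.21, K3 = 0.54, K4 = 0.28,
             b_intercept = -9.59, b_pH = 0.63, b_ox_mn = 0.002)
  sim <- simulate_bioassay(soils[1:6, ], params,
                           noise_spec(cv = 0, seed = 2),
                           treatments = "unleached")
  g <- grid_oracle_fit(sim, soils, c("pH", "ox_mn"),
                       grid = list(K2 = seq(0.15, 0.27, by = 0.03),
                                   b_pH = seq(0.5, 0.76, by = 0.065)),
                       pin = truth)
  # noiseless data, truth inside the grid -> the argmin is the truth
  best <- g$grid[which.min(g$grid$ssr), ]
  expect_equal(best$K2, 0.21, tolerance = 1e-12)
  expect_equal(best$b_pH, 0.63, tolerance = 1e-12)
  expect_lt(g$best_ssr, 1e-12)
  jf <- fit_joint(sim, soils, c("pH", "ox_mn"))
  expect_lte(jf$ssr, g$best_ssr + 1e-6)

  # one-dimensional profile over K2 dips at the truth
  prof <- grid_oracle_fit(sim, soils, c("pH", "ox_mn"),
                          grid = list(K2 = seq(0.11, 0.31, by = 0.02)),
                          pin = truth)$grid
  expect_equal(prof$K2[which.min(prof$ssr)], 0.21, tolerance = 1e-12)
  expect_true(all(diff(prof$ssr[prof$K2 <= 0.211]) <= 0))
  expect_true(all(diff(prof$ssr[prof$K2 >= 0.209]) >= 0))

  expect_error(grid_oracle_fit(sim, soils, c("pH", "ox_mn"),
                               grid = list(K1 = 1:300, K2 = 1:300,
                                           K3 = 1:300),
                               pin = truth),
               "grid too large")
})
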