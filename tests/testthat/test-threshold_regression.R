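test_that("ols_fit reproduces exact lines and the r2/correlation identity", {
  x <- seq(1, 10)
  m <- suppressWarnings(ols_fit(2 * x + 1, data.frame(x = x)))
  expect_equal(unname(m$coefs), c(1, 2), tolerance = 1e-12)
  expect_equal(m$r2, 1)

  set.seed(3)
  y <- rnorm(20); z <- rnorm(20)
  m2 <- ols_fit(y, data.frame(z = z))
  expect_equal(m2$r2, cor(y, z)^2, tolerance = 1e-12)
})

test_that("ols_fit matches the normal-equations oracle on random designs", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- rnorm(n)
    m <- ols_fit(y, as.data.frame(X))
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)  # normal equations
    expect_equal(unname(m$coefs), unname(drop(beta)), tolerance = 1e-8)
    res <- y - Xd %*% beta
    expect_equal(m$r2, 1 - sum(res^2) / sum((y - mean(y))^2),
                 tolerance = 1e-8)
  }
})

test_that("ols_fit rejects rank-deficient and undersized designs", {
  x <- rnorm(10)
  expect_error(ols_fit(rnorm(10), data.frame(a = x, b = x)),
               "collinear.*b")
  expect_error(ols_fit(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3))),
               "observations")
  expect_error(ols_fit(c(rnorm(9), NA), data.frame(a = rnorm(10))),
               "missing")
})

test_that("forward selection finds the generating predictor and respects ties", {
  set.seed(11)
  n <- 60
  cands <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 3 * cands$b + rnorm(n, sd = 0.1)
  m <- forward_select(y, cands)
  expect_equal(m$predictors[1], "b")

  # duplicated candidate columns: first by order wins, no crash
  dup <- data.frame(b = cands$b, b2 = cands$b)
  m2 <- forward_select(y, dup)
  expect_equal(m2$predictors, "b")

  # no candidate significant -> best single model flagged
  noise <- data.frame(a = rnorm(n), b = rnorm(n))
  m3 <- forward_select(rnorm(n), noise)
  expect_true(m3$nonsignificant)
  expect_equal(length(m3$predictors), 1)
})

test_that("forward selection is deterministic and permutation-invariant on real covariates", {
  covs <- log_transform_properties(load_reference_soils())
  cands <- covs[, c("pH", "logOC", "logCEC", "CaCO3", "logOXMn",
                    "logCDMn", "logCDFe")]
  set.seed(1)
  y <- 3.305 - 0.990 * cands$logCDMn + 0.971 * cands$logCEC +
    0.057 * cands$CaCO3 + rnorm(17, sd = 0.05)
  m <- forward_select(y, cands)
  expect_lte(length(m$predictors), 3)
  expect_true(all(m$p_coefs[m$predictors] <= 0.05))
  # deterministic: same inputs, same selection
  expect_identical(forward_select(y, cands)$predictors, m$predictors)
  # invariant to permutation of (untied) candidates
  perm <- cands[, c(6, 3, 1, 4, 2, 7, 5)]
  m_perm <- forward_select(y, perm)
  expect_setequal(m_perm$predictors, m$predictors)
  expect_equal(sort(unname(m_perm$coefs)), sort(unname(m$coefs)),
               tolerance = 1e-10)
})

test_that("nested OLS never loses r2 when a predictor is added", {
  set.seed(5)
  n <- 25
  cands <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(cands) <- letters[1:4]
  y <- rnorm(n)
  r2 <- vapply(1:4, function(k) ols_fit(y, cands[, 1:k, drop = FALSE])$r2,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("threshold prediction evaluates the fitted power-law form", {
  soils <- load_reference_soils()
  haikou <- soils[soils$site_id == "Haikou", ]
  m <- structure(list(response = "logEC10", predictors = "logCDMn",
                      coefs = c("(Intercept)" = 3.588, logCDMn = -0.607),
                      r2 = 0.51, p_model = 0.036,
                      p_coefs = c(0.01, 0.036), n = 17,
                      nonsignificant = FALSE),
                 class = "cu_threshold_lm")
  expect_equal(predict_threshold(m, haikou),
               10^(3.588 - 0.607 * log10(574)), tolerance = 1e-12)
  expect_equal(predict_threshold(m, haikou), 81.9, tolerance = 1e-3)

  m_oc <- structure(list(response = "logEC10", predictors = "logOC",
                         coefs = c("(Intercept)" = 1.286, logOC = 1.377),
                         r2 = 0.8, p_model = 1e-4, p_coefs = c(0, 0),
                         n = 17, nonsignificant = FALSE),
                    class = "cu_threshold_lm")
  oc1 <- make_soil_table(1); oc1$oc <- 1
  expect_equal(predict_threshold(m_oc, oc1), 10^1.286, tolerance = 1e-12)
  expect_equal(signif(predict_threshold(m_oc, oc1), 3), 19.3)

  m0 <- m; m0$predictors <- character(0)
  m0$coefs <- c("(Intercept)" = 2)
  expect_equal(predict_threshold(m0, haikou), 100)

  m_clay <- m; m_clay$predictors <- "clay"
  expect_error(predict_threshold(m_clay, haikou), "clay")
})
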