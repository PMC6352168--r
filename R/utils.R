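# Internal helpers shared across modules.

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# stream afterwards so simulation calls do not perturb user code.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  }, add = TRUE)
  force(expr)
}

# a(soil) = K1 + K2 pH + K3 log10(OC) + K4 log10(CEC)
.eval_a <- function(soils, a_coefs) {
  stopifnot(length(a_coefs) == 4L)
  a_coefs[[1L]] + a_coefs[[2L]] * soils$pH +
    a_coefs[[3L]] * log10(soils$oc) + a_coefs[[4L]] * log10(soils$cec)
}

# b(soil) = intercept + sum of named raw-covariate terms (pH, ox_mn, clay,
# caco3, ...). Covariates enter untransformed.
.eval_b <- function(soils, b_coefs) {
  nm <- names(b_coefs)
  if (is.null(nm) || !"intercept" %in% nm) {
    stop("b_coefs must be a named vector including an 'intercept' term",
         call. = FALSE)
  }
  b <- rep(b_coefs[["intercept"]], nrow(soils))
  for (term in setdiff(nm, "intercept")) {
    if (!term %in% names(soils)) {
      stop("soil table has no column '", term,
           "' required by the slope (b) covariates", call. = FALSE)
    }
    v <- soils[[term]]
    if (any(is.na(v))) {
      stop("covariate '", term, "' is missing (NA) for soil(s): ",
           paste(soils$site_id[is.na(v)], collapse = ", "), call. = FALSE)
    }
    b <- b + b_coefs[[term]] * v
  }
  b
}

# Numerically safe logistic response in the toxic-direction convention:
# Y = y0 / (1 + exp(-b * (X - a))) with b < 0 for toxicity.
.logistic_response <- function(y0, a, b, x) {
  z <- pmin(pmax(-b * (x - a), -700), 700)
  y0 / (1 + exp(z))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
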