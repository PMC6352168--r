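# Per-group log-logistic dose-response fitting and ECx threshold
# estimation on the EDTA-extractable Cu scale.
#
# Sign convention: the response is fitted as Y = y0 / (1 + exp(s (X - a)))
# with an internal slope s > 0 (Y decreasing in X). The reported slope is
# b = -s, so that toxicity curves carry a negative b and the closed-form
# EC ratio EC50/EC10 = 10^(-ln 9 / b) holds.

#' Options controlling the dose-response optimizer
#'
#' @param n_starts multistart count (moment-based start plus jittered
#'   copies).
#' @param maxit iteration cap per local search.
#' @param reltol relative SSR convergence tolerance.
#' @param s_min smallest slope magnitude accepted as a real dose effect.
#' @param ec50_window converged EC50 must lie within
#'   \[min(edta_cu)/w, max(edta_cu) x w\].
#' @param seed seed of the (deterministic) multistart jitter stream.
#' @return list of class `cu_drc_options`.
#' @export
drc_options <- function(n_starts = 5L, maxit = 10000L, reltol = 1e-10,
                        s_min = 0.05, ec50_window = 10, seed = 0L) {
  structure(list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 reltol = reltol, s_min = s_min, ec50_window = ec50_window,
                 seed = as.integer(seed)),
            class = "cu_drc_options")
}

# SSR of the logistic curve; theta = (y0, a, log_s).
.drc_ssr <- function(theta, x, y) {
  s <- exp(theta[3L])
  z <- pmin(pmax(s * (x - theta[2L]), -700), 700)
  sum((y - theta[1L] / (1 + exp(z)))^2)
}

# Moment-based starting point: y0 from the top of the curve, a from
# interpolating the half-maximal response, s from the steepest observed
# log-slope (logistic derivative at midpoint is -y0 s / 4).
.drc_init <- function(x, y) {
  lev <- sort(unique(x))
  ybar <- vapply(lev, function(v) mean(y[x == v]), numeric(1))
  y0 <- max(mean(ybar[seq_len(min(2L, length(ybar)))]), max(ybar), 1e-6)
  half <- y0 / 2
  a <- NA_real_
  for (i in seq_len(length(lev) - 1L)) {
    if ((ybar[i] - half) * (ybar[i + 1L] - half) <= 0) {
      w <- (ybar[i] - half) / (ybar[i] - ybar[i + 1L])
      if (!is.finite(w)) w <- 0.5
      a <- lev[i] + w * (lev[i + 1L] - lev[i])
      break
    }
  }
  if (!is.finite(a)) a <- stats::median(lev)
  slopes <- -diff(ybar) / diff(lev)
  s <- 4 * max(slopes, 0) / y0
  s <- .clip(ifelse(is.finite(s) & s > 0, s, 2), 0.3, 25)
  c(y0, a, log(s))
}

.drc_optimize <- function(x, y, options) {
  init <- .drc_init(x, y)
  starts <- list(init)
  if (options$n_starts > 1L) {
    jit <- .with_seed(options$seed, {
      lapply(seq_len(options$n_starts - 1L), function(i) {
        init + c(0, stats::runif(1, -0.4, 0.4), stats::runif(1, -0.7, 0.7))
      })
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, .drc_ssr, x = x, y = y,
                            method = "Nelder-Mead",
                            control = list(maxit = options$maxit,
                                           reltol = options$reltol)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    polish <- try(stats::optim(fit$par, .drc_ssr, x = x, y = y,
                               method = "BFGS",
                               control = list(maxit = options$maxit,
                                              reltol = options$reltol)),
                  silent = TRUE)
    if (!inherits(polish, "try-error") && polish$value <= fit$value) {
      fit <- polish
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Fit a log-logistic dose-response curve to one bioassay group
#'
#' Minimizes the sum of squared residuals of relative growth against
#' Y = y0 / (1 + exp(-b (X - a))), X = log10(EDTA-extractable Cu), over
#' y0 > 0, a, and slope b < 0, by multistart derivative-free search with a
#' quasi-Newton polish. `a` is log10 EC50.
#'
#' A fit is reported as non-converged (with a `failure_reason`) when the
#' optimizer fails, the slope magnitude falls below `s_min` (no dose
#' effect), or the implied EC50 falls outside the tested concentration
#' window — the situations in which no appropriate dose-response model can
#' be derived for a soil.
#'
#' @param obs observations of one soil x treatment x species group, with
#'   columns `edta_cu` and `relative_growth` (see
#'   [normalize_relative_growth()]).
#' @param options [drc_options()].
#' @return object of class `cu_drc_fit` with elements y0, a, b
#'   (negative slope), ssr, r2, n, converged, failure_reason and the group
#'   key.
#' @export
fit_loglogistic <- function(obs, options = drc_options()) {
  stopifnot(is.data.frame(obs),
            all(c("edta_cu", "relative_growth") %in% names(obs)))
  obs <- obs[is.finite(obs$edta_cu) & is.finite(obs$relative_growth), ,
             drop = FALSE]
  x <- log10(obs$edta_cu)
  y <- obs$relative_growth
  key <- list(
    site_id = if ("site_id" %in% names(obs))
      as.character(unique(obs$site_id)) else NA_character_,
    treatment = if ("treatment" %in% names(obs))
      as.character(unique(obs$treatment)) else NA_character_,
    species = if ("species" %in% names(obs))
      as.character(unique(obs$species)) else NA_character_
  )
  for (k in key) if (length(k) > 1L) {
    stop("fit_loglogistic expects a single soil x treatment x species ",
         "group; split the table first (see fit_bioassay)", call. = FALSE)
  }
  fail <- function(reason) {
    structure(c(key, list(y0 = NA_real_, a = NA_real_, b = NA_real_,
                          ssr = NA_real_, r2 = NA_real_, n = length(y),
                          converged = FALSE, failure_reason = reason,
                          x_range = range(x))),
              class = "cu_drc_fit")
  }
  if (length(unique(x)) < 4L) {
    return(fail("fewer than 4 distinct dose levels"))
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= .Machine$double.eps * length(y)) {
    return(fail("no dose effect (constant response)"))
  }
  best <- .drc_optimize(x, y, options)
  if (is.null(best)) return(fail("optimizer failed"))
  y0 <- best$par[1L]; a <- best$par[2L]; s <- exp(best$par[3L])
  if (!all(is.finite(best$par)) || y0 <= 0) {
    return(fail("optimizer returned invalid parameters"))
  }
  if (s < options$s_min) return(fail("no dose effect (slope below s_min)"))
  w <- options$ec50_window
  if (10^a < min(obs$edta_cu) / w || 10^a > max(obs$edta_cu) * w) {
    return(fail("EC50 outside the tested concentration window"))
  }
  structure(c(key, list(y0 = y0, a = a, b = -s, ssr = best$value,
                        r2 = 1 - best$value / sst, n = length(y),
                        converged = TRUE, failure_reason = NA_character_,
                        x_range = range(x))),
            class = "cu_drc_fit")
}

#' @export
print.cu_drc_fit <- function(x, ...) {
  cat(sprintf("<cu_drc_fit> %s / %s / %s\n",
              x$site_id, x$treatment, x$species))
  if (isTRUE(x$converged)) {
    cat(sprintf("  y0 = %.2f %%, a = %.4f (EC50 = %.1f mg/kg), b = %.3f\n",
                x$y0, x$a, 10^x$a, x$b))
    cat(sprintf("  SSR = %.4g, R2 = %.4f, n = %d\n", x$ssr, x$r2, x$n))
  } else {
    cat("  not converged:", x$failure_reason, "\n")
  }
  invisible(x)
}

#' Fit every soil x treatment x species group of a bioassay table
#'
#' @param obs bioassay observation table with `relative_growth` populated.
#' @param options [drc_options()].
#' @return list of `cu_drc_fit` (class `cu_drc_fit_list`); coerce to a flat
#'   table with [as.data.frame()].
#' @export
fit_bioassay <- function(obs, options = drc_options()) {
  validate_bioassay_table(obs)
  if (!"relative_growth" %in% names(obs) ||
      any(!is.finite(obs$relative_growth))) {
    obs <- normalize_relative_growth(obs)
  }
  key <- interaction(obs$site_id, obs$treatment, obs$species, drop = TRUE)
  fits <- lapply(levels(key), function(g) {
    fit_loglogistic(obs[key == g, , drop = FALSE], options = options)
  })
  structure(fits, class = "cu_drc_fit_list")
}

#' @export
as.data.frame.cu_drc_fit_list <- function(x, ...) {
  do.call(rbind, lapply(x, function(f) {
    data.frame(site_id = f$site_id, treatment = f$treatment,
               species = f$species, y0 = f$y0, a = f$a, b = f$b,
               ec10 = if (isTRUE(f$converged)) ec_x(f, 10)$value else NA_real_,
               ec50 = if (isTRUE(f$converged)) ec_x(f, 50)$value else NA_real_,
               ssr = f$ssr, r2 = f$r2, n = f$n, converged = f$converged,
               failure_reason = f$failure_reason, stringsAsFactors = FALSE)
  }))
}

#' ECx threshold from a fitted curve
#'
#' The concentration inhibiting x\% of growth:
#' log10 ECx = a + ln(q / (1 - q)) / (-b), q = x/100. EC50 is 10^a exactly.
#'
#' @param fit converged `cu_drc_fit` (or any list with elements `a` and
#'   `b`).
#' @param x_percent inhibition level in (0, 100).
#' @return object of class `cu_ecx` with the point `value` (mg/kg).
#' @export
ec_x <- function(fit, x_percent) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    stop("cannot compute ECx from a non-converged fit", call. = FALSE)
  }
  if (!is.finite(x_percent) || x_percent <= 0 || x_percent >= 100) {
    stop("x_percent must lie strictly between 0 and 100", call. = FALSE)
  }
  if (!is.finite(fit$b) || fit$b >= 0) {
    stop("ECx requires a negative slope (toxicity direction)",
         call. = FALSE)
  }
  q <- x_percent / 100
  logec <- fit$a + log(q / (1 - q)) / (-fit$b)
  structure(list(x_percent = x_percent, value = 10^logec,
                 ci_low = NA_real_, ci_high = NA_real_, method = "point"),
            class = "cu_ecx")
}

#' @export
print.cu_ecx <- function(x, ...) {
  cat(sprintf("EC%g = %.4g mg/kg (EDTA-extractable Cu)", x$x_percent,
              x$value))
  if (is.finite(x$ci_low)) {
    cat(sprintf(", 95%% CI [%.4g, %.4g] (%s)", x$ci_low, x$ci_high,
                x$method))
  }
  cat("\n")
  invisible(x)
}

#' Closed-form EC50/EC10 ratio from the slope
#'
#' For the log-logistic curve the threshold ratio depends only on the
#' slope: EC50/EC10 = 10^(-ln 9 / b), always > 1 for b < 0. Steep curves
#' (large |b|) pack EC10 and EC50 close together.
#'
#' @param b negative slope of a fitted curve.
#' @return the EC50/EC10 ratio.
#' @export
ec_ratio_closed_form <- function(b) {
  if (any(!is.finite(b) | b >= 0)) {
    stop("b must be negative (toxicity direction)", call. = FALSE)
  }
  10^(-log(9) / b)
}

#' Percentile bootstrap confidence interval for an ECx threshold
#'
#' Nonparametric case resampling of replicates within each dose level,
#' refitting the curve for each resample (single-start, warm-started at the
#' original estimate), and taking the 2.5/97.5 percentiles of the resampled
#' ECx values. Resamples whose refit does not converge are dropped and
#' counted; more than 50\% failures aborts with an "unstable fit" error.
#'
#' @param obs observations of one group (as [fit_loglogistic()]).
#' @param x_percent inhibition level.
#' @param B bootstrap resamples.
#' @param seed RNG seed (results are reproducible given `seed`).
#' @param options [drc_options()] for the initial fit.
#' @return `cu_ecx` with `ci_low`/`ci_high` filled, plus attributes
#'   `n_failed` and `B`.
#' @export
bootstrap_ci <- function(obs, x_percent = 10, B = 1000L, seed = 1L,
                         options = drc_options()) {
  fit0 <- fit_loglogistic(obs, options = options)
  if (!isTRUE(fit0$converged)) {
    stop("group cannot be fitted: ", fit0$failure_reason, call. = FALSE)
  }
  est <- ec_x(fit0, x_percent)
  dose_key <- if ("added_cu" %in% names(obs)) obs$added_cu else obs$edta_cu
  idx_by_dose <- split(seq_len(nrow(obs)), dose_key)
  theta0 <- c(fit0$y0, fit0$a, log(-fit0$b))
  w <- options$ec50_window
  boot_vals <- .with_seed(seed, {
    vapply(seq_len(B), function(i) {
      take <- unlist(lapply(idx_by_dose, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      xb <- log10(obs$edta_cu[take])
      yb <- obs$relative_growth[take]
      fb <- try(stats::optim(theta0, .drc_ssr, x = xb, y = yb,
                             method = "BFGS",
                             control = list(maxit = options$maxit,
                                            reltol = options$reltol)),
                silent = TRUE)
      if (inherits(fb, "try-error")) return(NA_real_)
      y0b <- fb$par[1L]; ab <- fb$par[2L]; sb <- exp(fb$par[3L])
      if (!all(is.finite(fb$par)) || y0b <= 0 || sb < options$s_min ||
          10^ab < min(obs$edta_cu) / w || 10^ab > max(obs$edta_cu) * w) {
        return(NA_real_)
      }
      q <- x_percent / 100
      10^(ab + log(q / (1 - q)) / sb)
    }, numeric(1))
  })
  n_failed <- sum(is.na(boot_vals))
  if (n_failed > B / 2) {
    stop("unstable fit: ", n_failed, " of ", B,
         " bootstrap resamples failed to fit", call. = FALSE)
  }
  qs <- stats::quantile(boot_vals, c(0.025, 0.975), na.rm = TRUE,
                        names = FALSE)
  out <- structure(list(x_percent = x_percent, value = est$value,
                        ci_low = qs[1L], ci_high = qs[2L],
                        method = "percentile bootstrap"),
                   class = "cu_ecx")
  attr(out, "n_failed") <- n_failed
  attr(out, "B") <- B
  out
}

#' Leaching factors from paired fits
#'
#' The leaching factor of a soil is ECx(leached) / ECx(unleached); values
#' above 1 mean leaching (removal of soluble salts) alleviates toxicity.
#' Factors are computed per soil over the converged pairs and summarized by
#' their mean with the standard error of the mean as the headline spread
#' (the SD is also returned).
#'
#' @param unleached_fits,leached_fits `cu_drc_fit_list` or lists of fits of
#'   the same species under the two treatments.
#' @param x_percent inhibition level of the threshold.
#' @return list with mean, se, sd, n and the per-soil ratio table.
#' @export
leaching_factor <- function(unleached_fits, leached_fits, x_percent = 10) {
  pick <- function(fits) {
    fits <- Filter(function(f) isTRUE(f$converged), fits)
    stats::setNames(fits, vapply(fits, function(f) f$site_id, character(1)))
  }
  ul <- pick(unleached_fits)
  le <- pick(leached_fits)
  common <- intersect(names(ul), names(le))
  if (length(common) < 2L) {
    stop("need converged unleached/leached fit pairs for at least 2 soils",
         call. = FALSE)
  }
  ratio <- vapply(common, function(s) {
    ec_x(le[[s]], x_percent)$value / ec_x(ul[[s]], x_percent)$value
  }, numeric(1))
  list(x_percent = x_percent,
       mean = mean(ratio),
       se = stats::sd(ratio) / sqrt(length(ratio)),
       sd = stats::sd(ratio),
       n = length(ratio),
       per_soil = data.frame(site_id = common, ratio = unname(ratio),
                             stringsAsFactors = FALSE))
}

#' Threshold summary across soils
#'
#' Range, median, mean and fold-variation (max/min) of ECx thresholds over
#' the converged fits of a panel; non-converged fits are excluded and
#' reported.
#'
#' @param fits `cu_drc_fit_list` (or list of fits), or directly a numeric
#'   vector of threshold values, mg/kg.
#' @param x_percent inhibition level (ignored for a numeric vector).
#' @return list with range, median, mean, fold_variation, n_used and the
#'   excluded site ids.
#' @export
summarize_thresholds <- function(fits, x_percent = 10) {
  if (is.numeric(fits)) {
    values <- fits[is.finite(fits)]
    excluded <- character(0)
  } else {
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    excluded <- vapply(fits[!conv], function(f)
      paste(f$site_id, f$treatment, f$species, sep = "/"), character(1))
    values <- vapply(fits[conv], function(f) ec_x(f, x_percent)$value,
                     numeric(1))
  }
  if (length(values) == 0L) stop("no converged fits to summarize",
                                 call. = FALSE)
  list(x_percent = x_percent,
       range = range(values),
       median = stats::median(values),
       mean = mean(values),
       fold_variation = max(values) / min(values),
       n_used = length(values),
       excluded = excluded)
}
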