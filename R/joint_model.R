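# Joint covariate-parameterized dose-response model: one logistic curve
# family fitted across all soils of a species x treatment, with
#   a = K1 + K2 pH + K3 log10(OC) + K4 log10(CEC)
#   b = intercept + linear form in configurable raw covariates
# and free undisturbed growth level y0. All parameters are estimated at
# once by minimizing the pooled sum of squared residuals.

#' Options controlling the joint optimizer
#'
#' @param n_starts multistart count (warm start from per-soil fits plus
#'   jittered copies).
#' @param maxit iteration cap per local search.
#' @param reltol relative SSR convergence tolerance.
#' @param seed seed of the deterministic multistart jitter stream.
#' @return list of class `cu_joint_options`.
#' @export
joint_options <- function(n_starts = 3L, maxit = 20000L, reltol = 1e-12,
                          seed = 0L) {
  structure(list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 reltol = reltol, seed = as.integer(seed)),
            class = "cu_joint_options")
}

# Precompute the per-observation design of the joint SSR: response, log10
# dose, and the a- and b-form covariate matrices (one row per observation).
.joint_data <- function(obs, soils, b_covariates) {
  validate_soil_table(soils)
  idx <- match(obs$site_id, soils$site_id)
  if (anyNA(idx)) {
    stop("bioassay references soil(s) absent from the soil table: ",
         paste(unique(obs$site_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  A <- cbind(1, soils$pH, log10(soils$oc), log10(soils$cec))[idx, ,
                                                            drop = FALSE]
  Bs <- matrix(1, nrow(soils), 1L)
  for (cv in b_covariates) {
    if (!cv %in% names(soils)) {
      stop("soil table has no column '", cv,
           "' requested as a slope (b) covariate", call. = FALSE)
    }
    if (anyNA(soils[[cv]])) {
      stop("slope covariate '", cv, "' has missing values", call. = FALSE)
    }
    Bs <- cbind(Bs, soils[[cv]])
  }
  list(x = log10(obs$edta_cu), y = obs$relative_growth,
       A = A, B = Bs[idx, , drop = FALSE], soil_index = idx,
       B_soil = Bs, n_soils = length(unique(idx)),
       b_covariates = b_covariates)
}

# theta = (y0, K1..K4, b_intercept, b_<cov>...)
.joint_theta_names <- function(b_covariates) {
  c("y0", "K1", "K2", "K3", "K4", "b_intercept",
    if (length(b_covariates)) paste0("b_", b_covariates))
}

.joint_ssr <- function(theta, jd) {
  a <- drop(jd$A %*% theta[2:5])
  b <- drop(jd$B %*% theta[6:length(theta)])
  z <- pmin(pmax(-b * (jd$x - a), -700), 700)
  sum((jd$y - theta[1L] / (1 + exp(z)))^2)
}

#' Screen soil covariates for the slope and location parameters
#'
#' Pearson correlation of the per-soil fitted slope b (and location a)
#' against each candidate covariate, ranked by |r| on b, with p <= 0.05
#' flagged. This is the screening that motivates which covariates enter
#' the joint model's b-form.
#'
#' @param fits list of per-soil `cu_drc_fit` (>= 5 converged).
#' @param soils soil table.
#' @param covariates candidate covariate names among the columns of
#'   [log_transform_properties()] output.
#' @return data.frame with covariate, r_b, p_b, r_a, p_a, significant_b,
#'   ranked by |r_b|.
#' @export
screen_b_covariates <- function(fits, soils,
                                covariates = .default_candidates) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) < 5L) {
    stop("need at least 5 converged per-soil fits to screen covariates",
         call. = FALSE)
  }
  covs <- log_transform_properties(soils)
  sites <- vapply(conv, function(f) f$site_id, character(1))
  idx <- match(sites, covs$site_id)
  if (anyNA(idx)) stop("fit references unknown soil(s)", call. = FALSE)
  b <- vapply(conv, function(f) f$b, numeric(1))
  a <- vapply(conv, function(f) f$a, numeric(1))
  rows <- lapply(covariates, function(nm) {
    v <- covs[[nm]][idx]
    safe_cor <- function(u) {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) {
        return(list(r = NA_real_, p = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(u, v))
      list(r = unname(ct$estimate), p = ct$p.value)
    }
    cb <- safe_cor(b); ca <- safe_cor(a)
    data.frame(covariate = nm, r_b = cb$r, p_b = cb$p,
               r_a = ca$r, p_a = ca$p,
               significant_b = is.finite(cb$p) && cb$p <= 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$r_b), na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the joint covariate-parameterized dose-response model
#'
#' Pools every observation of one species x treatment across soils and
#' minimizes the total SSR of relative growth against
#' Y = y0 / (1 + exp(-b(soil) (X - a(soil)))) over y0, the four
#' a-form coefficients K1-K4, and the b-form coefficients. The a-form is
#' fixed to (1, pH, logOC, logCEC); only the b covariates are selectable.
#'
#' The optimizer is warm-started from per-soil fits: per-soil a is
#' regressed on (1, pH, logOC, logCEC) and per-soil b on the chosen
#' covariates by OLS, then refined by multistart Nelder-Mead with BFGS
#' polish. R2 is 1 - SSR/SST about the grand mean of the pooled response,
#' and the overall p-value is an F-test against the constant model.
#'
#' @param obs bioassay table of a single species x treatment, spanning at
#'   least 5 soils with at least 4 dose levels each.
#' @param soils soil table providing the covariates.
#' @param b_covariates raw soil columns entering the slope form (default
#'   pH and ox_mn, the shape appropriate for tomato; use "pH" alone for
#'   bok choy).
#' @param options [joint_options()].
#' @param drc_opts [drc_options()] for the warm-start per-soil fits.
#' @return object of class `cu_joint_fit`.
#' @export
fit_joint <- function(obs, soils, b_covariates = c("pH", "ox_mn"),
                      options = joint_options(),
                      drc_opts = drc_options()) {
  validate_bioassay_table(obs)
  if (length(unique(obs$species)) > 1L ||
      length(unique(obs$treatment)) > 1L) {
    stop("fit_joint pools one species x treatment; split the table first",
         call. = FALSE)
  }
  if (!"relative_growth" %in% names(obs) ||
      any(!is.finite(obs$relative_growth))) {
    obs <- normalize_relative_growth(obs)
  }
  n_doses <- vapply(split(obs$edta_cu, obs$site_id),
                    function(v) length(unique(v)), integer(1))
  if (sum(n_doses >= 4L) < 5L) {
    stop("insufficient soil diversity: need >= 5 soils with >= 4 dose ",
         "levels each to identify the covariate forms", call. = FALSE)
  }
  jd <- .joint_data(obs, soils, b_covariates)
  theta_names <- .joint_theta_names(b_covariates)

  # warm start from per-soil fits
  per_soil <- fit_bioassay(obs, options = drc_opts)
  conv <- Filter(function(f) isTRUE(f$converged), per_soil)
  screening <- tryCatch(screen_b_covariates(per_soil, soils),
                        error = function(e) NULL)
  init <- rep(0, length(theta_names))
  names(init) <- theta_names
  if (length(conv) >= 5L) {
    sites <- vapply(conv, function(f) f$site_id, character(1))
    si <- match(sites, soils$site_id)
    a_i <- vapply(conv, function(f) f$a, numeric(1))
    b_i <- vapply(conv, function(f) f$b, numeric(1))
    Xa <- cbind(1, soils$pH, log10(soils$oc), log10(soils$cec))[si, ,
                                                               drop = FALSE]
    init[2:5] <- stats::coef(stats::lm.fit(Xa, a_i))
    Xb <- jd$B_soil[si, , drop = FALSE]
    init[6:length(init)] <- stats::coef(stats::lm.fit(Xb, b_i))
    init[1L] <- mean(vapply(conv, function(f) f$y0, numeric(1)))
  } else {
    init[1L] <- max(mean(jd$y), 100)
    init[2L] <- mean(jd$x)
    init[6L] <- -2
  }
  init[!is.finite(init)] <- 0

  starts <- list(init)
  if (options$n_starts > 1L) {
    jit <- .with_seed(options$seed, {
      lapply(seq_len(options$n_starts - 1L), function(i) {
        init * (1 + stats::runif(length(init), -0.15, 0.15)) +
          stats::runif(length(init), -0.05, 0.05)
      })
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, .joint_ssr, jd = jd,
                            method = "Nelder-Mead",
                            control = list(maxit = options$maxit,
                                           reltol = options$reltol)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    polish <- try(stats::optim(fit$par, .joint_ssr, jd = jd,
                               method = "BFGS",
                               control = list(maxit = options$maxit,
                                              reltol = options$reltol)),
                  silent = TRUE)
    if (!inherits(polish, "try-error") && polish$value <= fit$value) {
      fit <- polish
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  sst <- sum((jd$y - mean(jd$y))^2)
  n_obs <- length(jd$y)
  make <- function(theta, ssr, converged, reason) {
    a_coefs <- stats::setNames(theta[2:5],
                               c("intercept", "pH", "logOC", "logCEC"))
    b_coefs <- stats::setNames(theta[6:length(theta)],
                               c("intercept", b_covariates))
    p <- length(theta)
    r2 <- 1 - ssr / sst
    fstat <- ((sst - ssr) / (p - 1)) / (ssr / (n_obs - p))
    structure(list(
      species = unique(obs$species), treatment = unique(obs$treatment),
      y0 = unname(theta[1L]), a_coefs = a_coefs, b_coefs = b_coefs,
      b_covariates = b_covariates, ssr = ssr, r2 = r2,
      p_model = stats::pf(fstat, p - 1, n_obs - p, lower.tail = FALSE),
      n_obs = n_obs, n_soils = jd$n_soils, converged = converged,
      failure_reason = reason, screening_report = screening
    ), class = "cu_joint_fit")
  }
  if (is.null(best) || !all(is.finite(best$par))) {
    return(make(init, .joint_ssr(init, jd), FALSE, "optimizer failed"))
  }
  b_eval <- drop(jd$B_soil %*% best$par[6:length(best$par)])
  used <- sort(unique(jd$soil_index))
  if (any(b_eval[used] >= 0)) {
    return(make(best$par, best$value, FALSE,
                paste0("fitted slope non-negative for soil(s): ",
                       paste(soils$site_id[used][b_eval[used] >= 0],
                             collapse = ", "))))
  }
  if (best$par[1L] <= 0) {
    return(make(best$par, best$value, FALSE, "fitted y0 not positive"))
  }
  make(best$par, best$value, TRUE, NA_character_)
}

#' @export
print.cu_joint_fit <- function(x, ...) {
  cat(sprintf("<cu_joint_fit> %s, %s (%d soils, %d obs)\n",
              x$species, x$treatment, x$n_soils, x$n_obs))
  if (isTRUE(x$converged)) {
    cat(sprintf("  y0 = %.2f %%\n", x$y0))
    cat(sprintf("  a = %.3f + %.3f pH + %.3f logOC + %.3f logCEC\n",
                x$a_coefs[[1L]], x$a_coefs[[2L]], x$a_coefs[[3L]],
                x$a_coefs[[4L]]))
    bterms <- paste(sprintf("%+.4g %s", x$b_coefs[-1L],
                            names(x$b_coefs)[-1L]), collapse = " ")
    cat(sprintf("  b = %.3f %s\n", x$b_coefs[[1L]], bterms))
    cat(sprintf("  R2 = %.4f, p = %.3g, SSR = %.4g\n", x$r2, x$p_model,
                x$ssr))
  } else {
    cat("  not converged:", x$failure_reason, "\n")
  }
  invisible(x)
}

#' Exhaustive grid oracle for the joint optimizer
#'
#' Evaluates the joint SSR on a full grid over at most 3 named parameters,
#' the remaining parameters pinned at `pin`. Used to verify that the
#' optimizer is never beaten by brute force by more than tolerance on
#' small instances.
#'
#' @param obs,soils,b_covariates as [fit_joint()].
#' @param grid named list (<= 3 entries) of value vectors; names from
#'   y0, K1-K4, b_intercept, b_<covariate>.
#' @param pin named full parameter vector supplying the pinned values.
#' @return list with best_ssr, best_par and the evaluated grid
#'   (data.frame with an `ssr` column).
#' @export
grid_oracle_fit <- function(obs, soils, b_covariates, grid, pin) {
  stopifnot(is.list(grid), length(grid) >= 1L, length(grid) <= 3L)
  theta_names <- .joint_theta_names(b_covariates)
  if (!all(names(grid) %in% theta_names) ||
      !all(theta_names %in% names(pin))) {
    stop("grid/pin names must match the joint parameter names: ",
         paste(theta_names, collapse = ", "), call. = FALSE)
  }
  n_pts <- prod(vapply(grid, length, integer(1)))
  if (n_pts > 1e7) {
    stop("grid too large (", n_pts, " points > 1e7); refine it",
         call. = FALSE)
  }
  if (!"relative_growth" %in% names(obs) ||
      any(!is.finite(obs$relative_growth))) {
    obs <- normalize_relative_growth(obs)
  }
  jd <- .joint_data(obs, soils, b_covariates)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  theta <- pin[theta_names]
  ssr <- vapply(seq_len(nrow(pts)), function(i) {
    th <- theta
    th[names(grid)] <- as.numeric(pts[i, ])
    .joint_ssr(th, jd)
  }, numeric(1))
  pts$ssr <- ssr
  best <- which.min(ssr)
  th <- theta
  th[names(grid)] <- as.numeric(pts[best, names(grid)])
  list(best_ssr = ssr[best], best_par = th, grid = pts)
}
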