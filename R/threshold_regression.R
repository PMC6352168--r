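# Linear regression of log10 phytotoxicity thresholds on soil properties,
# with greedy forward predictor selection.

.default_candidates <- c("pH", "logOC", "logCEC", "CaCO3", "logOXMn",
                         "logCDMn", "logCDFe")

#' Ordinary least squares of log-thresholds on soil covariates
#'
#' Closed-form least squares (via [stats::lm()]) with the usual
#' normal-error inference: overall F-test p-value and per-coefficient
#' t-test p-values.
#'
#' @param y response vector (typically log10 ECx per soil).
#' @param predictors data.frame of covariate columns (already transformed,
#'   see [log_transform_properties()]).
#' @param response label carried on the model (e.g. "logEC10 tomato
#'   unleached").
#' @return object of class `cu_threshold_lm` with coefs, r2, p_model,
#'   p_coefs, n.
#' @export
ols_fit <- function(y, predictors, response = "log threshold") {
  stopifnot(is.numeric(y), is.data.frame(predictors),
            nrow(predictors) == length(y))
  if (anyNA(y) || anyNA(predictors)) {
    stop("missing values in response or covariates", call. = FALSE)
  }
  p <- ncol(predictors)
  n <- length(y)
  if (n <= p + 1L) {
    stop("need more observations (", n, ") than coefficients (", p + 1L,
         ")", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.y = y, predictors, check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", names(predictors)), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_model <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  coefs <- stats::coef(fit)
  names(coefs) <- gsub("`", "", names(coefs))
  p_coefs <- sm$coefficients[, "Pr(>|t|)"]
  names(p_coefs) <- names(coefs)
  structure(list(response = response, predictors = names(predictors),
                 coefs = coefs, r2 = sm$r.squared,
                 p_model = unname(p_model), p_coefs = p_coefs,
                 n = n, sigma = sm$sigma, nonsignificant = FALSE),
            class = "cu_threshold_lm")
}

#' @export
print.cu_threshold_lm <- function(x, digits = 3, ...) {
  cat(sprintf("<cu_threshold_lm> %s (n = %d)\n", x$response, x$n))
  cat("  ", equation_string(x), "\n", sep = "")
  cat(sprintf("  R2 = %.3f, model p = %.3g%s\n", x$r2, x$p_model,
              if (isTRUE(x$nonsignificant))
                "  [no predictor significant]" else ""))
  invisible(x)
}

#' Human-readable equation of a fitted threshold regression
#'
#' @param model `cu_threshold_lm`.
#' @return character scalar like "2.139 + 0.725 logOC".
#' @export
equation_string <- function(model) {
  co <- model$coefs
  out <- sprintf("%.3f", co[[1L]])
  for (nm in names(co)[-1L]) {
    out <- paste0(out, sprintf(" %s %.3f %s",
                               ifelse(co[[nm]] < 0, "-", "+"),
                               abs(co[[nm]]), nm))
  }
  out
}

#' Greedy forward selection of threshold predictors
#'
#' Starts from the single candidate with the highest R2; at each step adds
#' the candidate that maximizes R2 among those keeping every predictor
#' coefficient significant at `alpha`; stops at `max_terms` predictors or
#' when no admissible addition remains. Ties are broken by candidate order,
#' then name; candidates that make the design rank-deficient (duplicated
#' columns) are skipped. If even the best single predictor is not
#' significant the model is returned flagged `nonsignificant`.
#'
#' @param y response (log10 thresholds).
#' @param candidates data.frame of candidate covariates.
#' @param alpha significance level for entering coefficients.
#' @param max_terms maximum number of predictors.
#' @param response model label.
#' @return `cu_threshold_lm` of the selected model.
#' @export
forward_select <- function(y, candidates, alpha = 0.05, max_terms = 3L,
                           response = "log threshold") {
  stopifnot(is.data.frame(candidates), ncol(candidates) >= 2L)
  cand_names <- names(candidates)
  single_r2 <- vapply(cand_names, function(nm) {
    tryCatch(ols_fit(y, candidates[nm], response)$r2,
             error = function(e) -Inf)
  }, numeric(1))
  ord <- order(-single_r2, seq_along(cand_names))
  best_name <- cand_names[ord[1L]]
  current <- ols_fit(y, candidates[best_name], response)
  if (current$p_coefs[[best_name]] > alpha) {
    current$nonsignificant <- TRUE
    return(current)
  }
  selected <- best_name
  while (length(selected) < max_terms) {
    remaining <- setdiff(seq_along(cand_names),
                         match(selected, cand_names))
    best_add <- NULL
    best_r2 <- -Inf
    for (j in remaining) {
      nm <- cand_names[j]
      trial <- tryCatch(
        ols_fit(y, candidates[c(selected, nm)], response),
        error = function(e) NULL)
      if (is.null(trial)) next
      if (all(trial$p_coefs[trial$predictors] <= alpha) &&
          trial$r2 > best_r2 + 1e-12) {
        best_add <- trial
        best_r2 <- trial$r2
      }
    }
    if (is.null(best_add)) break
    current <- best_add
    selected <- current$predictors
  }
  current
}

#' Predict an ECx threshold for a soil from a fitted regression
#'
#' Evaluates 10^(intercept + sum of coefficient x covariate) on the soil's
#' transformed covariates.
#'
#' @param model `cu_threshold_lm`.
#' @param profile one-row soil table.
#' @return predicted threshold, mg/kg EDTA-extractable Cu.
#' @export
predict_threshold <- function(model, profile) {
  stopifnot(inherits(model, "cu_threshold_lm"), nrow(profile) == 1L)
  covs <- log_transform_properties(profile)
  missing <- setdiff(model$predictors, names(covs))
  if (length(missing) > 0L) {
    stop("soil profile lacks covariate(s) required by the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- model$coefs[[1L]]
  for (nm in model$predictors) {
    v <- covs[[nm]][1L]
    if (is.na(v)) stop("covariate '", nm, "' is NA for this soil",
                       call. = FALSE)
    lp <- lp + model$coefs[[nm]] * v
  }
  10^lp
}

#' Forward-selected regressions for every group of a fitted panel
#'
#' Convenience wrapper used by the pipeline: for each species x treatment x
#' inhibition level, regresses log10 of the converged ECx point estimates
#' on the default candidate covariates.
#'
#' @param fits_df data.frame as from
#'   `as.data.frame(fit_bioassay(...))`.
#' @param soils soil table.
#' @param ec_levels inhibition levels to model (default 10 and 50).
#' @param alpha,max_terms passed to [forward_select()].
#' @param candidates candidate covariate names (columns of
#'   [log_transform_properties()] output).
#' @return list of `cu_threshold_lm` keyed by "species/treatment/ECx".
#' @export
threshold_regressions <- function(fits_df, soils, ec_levels = c(10, 50),
                                  alpha = 0.05, max_terms = 3L,
                                  candidates = .default_candidates) {
  covs <- log_transform_properties(soils)
  out <- list()
  for (sp in unique(fits_df$species)) {
    for (tr in unique(fits_df$treatment)) {
      sub <- fits_df[fits_df$species == sp & fits_df$treatment == tr &
                       fits_df$converged, , drop = FALSE]
      if (nrow(sub) < 5L) next
      idx <- match(sub$site_id, covs$site_id)
      cand_df <- covs[idx, intersect(candidates, names(covs)),
                      drop = FALSE]
      for (x in ec_levels) {
        q <- x / 100
        y <- sub$a + log(q / (1 - q)) / (-sub$b)
        label <- sprintf("logEC%d-EDTA %s %s", x, sp, tr)
        out[[sprintf("%s/%s/EC%d", sp, tr, x)]] <-
          forward_select(y, cand_df, alpha = alpha, max_terms = max_terms,
                         response = label)
      }
    }
  }
  out
}
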