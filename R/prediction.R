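# Forward prediction from a joint model: response curves, inverse
# limit-concentration calculation, and species sensitivity comparison.

#' Hypothetical scenario soil from raw covariate values
#'
#' Builds a one-row covariate table for what-if predictions (e.g. "pH 5,
#' OC 1\%, CEC 20 cmol+/kg, OX-Mn 200 mg/kg") without requiring the full
#' measured profile of a real soil. Only positivity is enforced.
#'
#' @param pH soil pH.
#' @param oc organic carbon, \% mass.
#' @param cec cation exchange capacity, cmol+/kg.
#' @param ox_mn oxalate-extractable Mn, mg/kg (optional; required by
#'   models whose slope uses it).
#' @param clay clay content, \% (optional).
#' @return one-row data.frame usable by the predict functions.
#' @export
scenario_soil <- function(pH, oc, cec, ox_mn = NA_real_,
                          clay = NA_real_) {
  stopifnot(pH > 0, oc > 0, cec > 0, is.na(ox_mn) || ox_mn > 0,
            is.na(clay) || clay > 0)
  data.frame(site_id = "scenario", pH = pH, oc = oc, cec = cec,
             ox_mn = ox_mn, clay = clay, stringsAsFactors = FALSE)
}

# a, b, y0 of a model (cu_joint_fit or cu_species_params) on one profile.
.model_params_on <- function(model, profile) {
  stopifnot(nrow(profile) == 1L)
  if (!all(c("pH", "oc", "cec") %in% names(profile))) {
    stop("profile must provide pH, oc and cec", call. = FALSE)
  }
  a_coefs <- model$a_coefs
  b_coefs <- model$b_coefs
  if (is.null(a_coefs) || is.null(b_coefs) || is.null(model$y0)) {
    stop("model must carry y0, a_coefs and b_coefs (a cu_joint_fit or ",
         "cu_species_params object)", call. = FALSE)
  }
  a <- .eval_a(profile, a_coefs)
  b <- .eval_b(profile, b_coefs)
  if (!is.finite(b) || b >= 0) {
    stop("model outside valid domain for this soil: evaluated slope b = ",
         signif(b, 4), " is not negative", call. = FALSE)
  }
  list(y0 = model$y0, a = a, b = b)
}

#' Predicted relative growth at a given EDTA-extractable Cu concentration
#'
#' Evaluates the soil-specific curve of a joint model:
#' Y = y0 / (1 + exp(-b(soil) (X - a(soil)))), X = log10(edta_cu).
#'
#' @param model `cu_joint_fit` (or [species_params()] parameterization).
#' @param profile one-row soil table or [scenario_soil()].
#' @param edta_cu concentration(s), mg/kg, > 0.
#' @return predicted relative growth, \% (vectorized over `edta_cu`).
#' @export
predict_response <- function(model, profile, edta_cu) {
  stopifnot(all(is.finite(edta_cu)), all(edta_cu > 0))
  p <- .model_params_on(model, profile)
  .logistic_response(p$y0, p$a, p$b, log10(edta_cu))
}

#' Limiting concentration producing a target response
#'
#' The inverse of [predict_response()]: the EDTA-extractable Cu
#' concentration at which predicted relative growth equals `y_target`,
#' from X = a + ln((y0 - Y)/Y) / (-b) evaluated on the soil's parameters.
#' At `y_target = y0/2` the log terms cancel and the result is EC50 =
#' 10^a exactly.
#'
#' @param model `cu_joint_fit` or parameterization.
#' @param profile one-row soil table or scenario.
#' @param y_target target relative growth, \%, in (0, y0).
#' @return concentration, mg/kg (vectorized over `y_target`).
#' @export
predict_limit_concentration <- function(model, profile, y_target) {
  p <- .model_params_on(model, profile)
  if (any(!is.finite(y_target) | y_target <= 0 | y_target >= p$y0)) {
    stop("y_target must lie strictly between 0 and y0 = ",
         signif(p$y0, 5), call. = FALSE)
  }
  x <- p$a + (log(p$y0 - y_target) - log(y_target)) / (-p$b)
  10^x
}

#' Dose-toxicity curve table for plotting
#'
#' Evaluates the predicted response of a scenario soil over a
#' concentration grid.
#'
#' @param model `cu_joint_fit` or parameterization.
#' @param scenario one-row soil/scenario table.
#' @param edta_cu concentration grid, mg/kg; defaults to 100 log-spaced
#'   points from 1 to 3000 mg/kg.
#' @return data.frame with columns edta_cu and response.
#' @export
curve_table <- function(model, scenario,
                        edta_cu = 10^seq(0, log10(3000),
                                         length.out = 100)) {
  stopifnot(all(edta_cu > 0))
  data.frame(edta_cu = edta_cu,
             response = predict_response(model, scenario, edta_cu))
}

#' Compare the sensitivity of two models on one soil
#'
#' Evaluates both models at a concentration and reports which is more
#' inhibited relative to its own undisturbed level. When both responses
#' remain above 90\% of their y0 the comparison is flagged sub-threshold:
#' the dose sits below both EC10s, so the ordering carries little
#' toxicological meaning.
#'
#' @param model_a,model_b models to compare (e.g. tomato vs bok choy).
#' @param scenario one-row soil/scenario table.
#' @param edta_cu single concentration, mg/kg.
#' @return list with the two responses (\% of y0), the label of the more
#'   inhibited model ("tie" when equal) and a `sub_threshold` flag.
#' @export
compare_sensitivity <- function(model_a, model_b, scenario, edta_cu) {
  stopifnot(length(edta_cu) == 1L, edta_cu > 0)
  lab <- function(m, fallback) {
    if (!is.null(m$species)) {
      paste(m$species, m$treatment %||% "", sep = " ")
    } else fallback
  }
  ya <- predict_response(model_a, scenario, edta_cu)
  yb <- predict_response(model_b, scenario, edta_cu)
  fa <- ya / model_a$y0
  fb <- yb / model_b$y0
  more <- if (abs(fa - fb) < 1e-9) "tie" else if (fa < fb)
    trimws(lab(model_a, "model_a")) else trimws(lab(model_b, "model_b"))
  list(response_a = ya, response_b = yb,
       fraction_a = fa, fraction_b = fb,
       more_inhibited = more,
       sub_threshold = fa > 0.9 && fb > 0.9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
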