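# Synthetic bioassay generator: emulates a pH-stratified Cu spiking design
# (7 doubling doses + control per soil, leached/unleached pairs, replicated
# pots) with a logistic toxicity response whose parameters are linear in
# soil covariates. Generated datasets carry their generating truth as an
# attribute, so downstream fits can be validated by parameter recovery.

#' Species-level dose-response parameterization
#'
#' Bundles the generating parameters of one species x treatment: undisturbed
#' growth level `y0` (\%), the four coefficients of the curve-location form
#' a = K1 + K2 pH + K3 logOC + K4 logCEC, the named coefficients of the
#' slope form b (intercept plus raw covariates such as pH and ox_mn), and
#' the additive shift of `a` (log10 units) that represents leaching.
#'
#' The defaults are the package's reference parameterizations for tomato and
#' bok choy, calibrated so that the generator reproduces realistic Cu
#' dose-toxicity behaviour over the 17 reference Chinese soils: tomato
#' unleached y0 = 100.82, a = 0.63 + 0.21 pH + 0.54 logOC + 0.28 logCEC,
#' b = 0.63 pH + 0.002 OX-Mn - 9.59, and analogous forms for the other
#' three combinations. The evaluated slope b is negative (toxicity) for all
#' reference soils.
#'
#' @param species "tomato" or "bok_choy".
#' @param treatment the treatment the parameterization describes,
#'   "unleached" or "leached".
#' @param y0,a_coefs,b_coefs,leach_a_shift overrides of the defaults.
#' @return object of class `cu_species_params`.
#' @export
species_params <- function(species = c("tomato", "bok_choy"),
                           treatment = c("unleached", "leached"),
                           y0 = NULL, a_coefs = NULL, b_coefs = NULL,
                           leach_a_shift = NULL) {
  species <- match.arg(species)
  treatment <- match.arg(treatment)
  defaults <- list(
    tomato = list(
      unleached = list(y0 = 100.82,
                       a_coefs = c(intercept = 0.63, pH = 0.21,
                                   logOC = 0.54, logCEC = 0.28),
                       b_coefs = c(intercept = -9.59, pH = 0.63,
                                   ox_mn = 0.002)),
      leached = list(y0 = 106.30,
                     a_coefs = c(intercept = 0.72, pH = 0.20,
                                 logOC = 0.71, logCEC = 0.33),
                     b_coefs = c(intercept = -6.21, pH = 0.43,
                                 ox_mn = 0.007)),
      leach_a_shift = 0.18
    ),
    bok_choy = list(
      unleached = list(y0 = 99.93,
                       a_coefs = c(intercept = 1.43, pH = 0.07,
                                   logOC = 0.99, logCEC = -0.02),
                       b_coefs = c(intercept = -12.61, pH = 1.13)),
      leached = list(y0 = 101.09,
                     a_coefs = c(intercept = 1.61, pH = 0.05,
                                 logOC = 0.77, logCEC = 0.05),
                     b_coefs = c(intercept = -11.75, pH = 0.98)),
      leach_a_shift = 0.03
    )
  )
  base <- defaults[[species]][[treatment]]
  out <- structure(list(
    species = species,
    treatment = treatment,
    y0 = if (is.null(y0)) base$y0 else y0,
    a_coefs = if (is.null(a_coefs)) base$a_coefs else a_coefs,
    b_coefs = if (is.null(b_coefs)) base$b_coefs else b_coefs,
    leach_a_shift = if (is.null(leach_a_shift))
      defaults[[species]]$leach_a_shift else leach_a_shift
  ), class = "cu_species_params")
  if (length(out$a_coefs) != 4L) {
    stop("a_coefs must have 4 elements (intercept, pH, logOC, logCEC)",
         call. = FALSE)
  }
  out
}

#' @export
print.cu_species_params <- function(x, ...) {
  cat(sprintf("<cu_species_params> %s, %s\n", x$species, x$treatment))
  cat(sprintf("  y0 = %.2f %%\n", x$y0))
  cat("  a coefs:", paste(sprintf("%s=%.3g", names(x$a_coefs), x$a_coefs),
                          collapse = ", "), "\n")
  cat("  b coefs:", paste(sprintf("%s=%.3g", names(x$b_coefs), x$b_coefs),
                          collapse = ", "), "\n")
  cat(sprintf("  leach_a_shift = %+.2f log10 units\n", x$leach_a_shift))
  invisible(x)
}

#' Noise and replication settings for the generator
#'
#' @param cv coefficient of variation of the multiplicative Gaussian biomass
#'   noise (0.10 default; 0 gives noiseless curves).
#' @param replicates pots per soil x treatment x dose.
#' @param hormesis_peak low-dose stimulation factor >= 1; 1 disables
#'   hormesis. When > 1 a smooth unimodal multiplier with this maximum is
#'   applied, peaking one doubling step below EC50.
#' @param seed integer seed of the generator's pseudo-random stream.
#' @return object of class `cu_noise_spec`.
#' @export
noise_spec <- function(cv = 0.10, replicates = 3L, hormesis_peak = 1,
                       seed = 1L) {
  stopifnot(cv >= 0, replicates >= 1, hormesis_peak >= 1)
  structure(list(cv = cv, replicates = as.integer(replicates),
                 hormesis_peak = hormesis_peak, seed = as.integer(seed)),
            class = "cu_noise_spec")
}

#' pH-stratified Cu dose series
#'
#' Returns the control (0) plus seven doubling added-Cu doses, chosen by the
#' soil's pH stratum: 12.5-800 mg/kg below pH 5, 25-1600 mg/kg for pH in
#' [5, 7], and 37.5-2400 mg/kg above pH 7. Alkaline soils bind Cu more
#' strongly, so higher spikes are needed to span the response range.
#'
#' @param soil_pH soil pH in (2, 12).
#' @return numeric vector of 8 added-Cu doses, mg/kg, ascending.
#' @export
design_dose_series <- function(soil_pH) {
  stopifnot(length(soil_pH) == 1L, is.finite(soil_pH),
            soil_pH > 2, soil_pH < 12)
  base <- if (soil_pH < 5) 12.5 else if (soil_pH <= 7) 25 else 37.5
  c(0, base * 2^(0:6))
}

#' Simulated EDTA-extractability of added Cu
#'
#' A simple mass-balance stand-in for measured extraction: EDTA-extractable
#' Cu is a soil-specific background plus a recovery fraction of the added
#' dose, r = clip(0.95 - 0.02 CaCO3 - 0.05 (log10 CD-Fe - 3.5), 0.3, 0.95),
#' so recovery falls with carbonate content and with reactive Fe oxides, the
#' pools that occlude Cu from chelation. The background is log-normal
#' (median 5 mg/kg, sdlog 0.5) unless supplied.
#'
#' @param profile one-row soil table.
#' @param added_cu added Cu dose(s), mg/kg, >= 0.
#' @param background optional fixed background, mg/kg; when NULL one value
#'   is drawn from the current RNG stream.
#' @return EDTA-extractable Cu, mg/kg, same length as `added_cu`.
#' @export
simulate_extractability <- function(profile, added_cu, background = NULL) {
  stopifnot(all(added_cu >= 0))
  if (is.null(background)) background <- stats::rlnorm(1, log(5), 0.5)
  stopifnot(background > 0)
  r <- .clip(0.95 - 0.02 * profile$caco3 -
               0.05 * (log10(profile$cd_fe) - 3.5), 0.3, 0.95)
  background + r * added_cu
}

#' Simulate a Cu phytotoxicity bioassay over a soil panel
#'
#' For every soil x treatment x dose x replicate the generator computes the
#' soil's curve parameters a and b from the species' linear forms (a shifted
#' by `leach_a_shift` when the simulated treatment differs from the
#' parameterization's base treatment), converts the added dose to
#' EDTA-extractable Cu, evaluates the logistic mean response
#' Y = y0 / (1 + exp(-b (X - a))) at X = log10(EDTA-Cu), optionally applies
#' a hormesis multiplier, and adds multiplicative Gaussian noise truncated
#' at zero. Biomass is Y/100 x `control_mass`; `relative_growth` carries the
#' simulated response directly (re-deriving it from noisy controls is what
#' [normalize_relative_growth()] is for).
#'
#' @param soils soil table (the covariates of the generating forms).
#' @param params [species_params()] object.
#' @param noise [noise_spec()] object.
#' @param treatments treatments to simulate; defaults to the
#'   parameterization's own treatment.
#' @param control_mass nominal uninhibited shoot dry mass, g/pot.
#' @return bioassay observation data.frame with attribute `"truth"` holding
#'   the generating parameters (per-soil a and b, y0, backgrounds).
#' @export
simulate_bioassay <- function(soils, params = species_params(),
                              noise = noise_spec(),
                              treatments = params$treatment,
                              control_mass = 2) {
  validate_soil_table(soils)
  stopifnot(inherits(params, "cu_species_params"),
            inherits(noise, "cu_noise_spec"),
            all(treatments %in% c("unleached", "leached")))
  b_soil <- .eval_b(soils, params$b_coefs)
  if (any(b_soil >= 0)) {
    stop("generating slope b is non-negative for soil(s): ",
         paste(soils$site_id[b_soil >= 0], collapse = ", "),
         "; refusing a parameter set that reverses the toxicity direction",
         call. = FALSE)
  }
  a_base <- .eval_a(soils, params$a_coefs)

  .with_seed(noise$seed, {
    rows <- vector("list", length(treatments) * nrow(soils))
    truth_soils <- vector("list", length(rows))
    k <- 0L
    for (tr in treatments) {
      shift <- params$leach_a_shift *
        ((tr == "leached") - (params$treatment == "leached"))
      for (i in seq_len(nrow(soils))) {
        k <- k + 1L
        a_i <- a_base[i] + shift
        b_i <- b_soil[i]
        doses <- design_dose_series(soils$pH[i])
        background <- stats::rlnorm(1, log(5), 0.5)
        edta <- simulate_extractability(soils[i, , drop = FALSE], doses,
                                        background = background)
        x <- log10(edta)
        y_mean <- .logistic_response(params$y0, a_i, b_i, x)
        if (noise$hormesis_peak > 1) {
          h <- 1 + (noise$hormesis_peak - 1) *
            exp(-0.5 * ((x - (a_i - log10(2))) / 0.25)^2)
          y_mean <- y_mean * h
        }
        nrep <- noise$replicates
        y_obs <- rep(y_mean, each = nrep) *
          pmax(0, 1 + noise$cv * stats::rnorm(length(doses) * nrep))
        rows[[k]] <- data.frame(
          site_id = soils$site_id[i],
          treatment = tr,
          species = params$species,
          added_cu = rep(doses, each = nrep),
          edta_cu = rep(edta, each = nrep),
          replicate = rep(seq_len(nrep), times = length(doses)),
          biomass = y_obs / 100 * control_mass,
          relative_growth = y_obs,
          stringsAsFactors = FALSE
        )
        truth_soils[[k]] <- data.frame(
          site_id = soils$site_id[i], treatment = tr,
          a = a_i, b = b_i, background = background,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(
      params = params, noise = noise, control_mass = control_mass,
      per_soil = do.call(rbind, truth_soils)
    )
    out
  })
}
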