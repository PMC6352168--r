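# Shared fixtures: small soil tables and noiseless logistic datasets
# built in code.

make_soil_table <- function(n = 3) {
  data.frame(
    site_id = paste0("S", seq_len(n)),
    pH = seq(5, 8, length.out = n),
    ec = rep(100, n),
    cec = seq(8, 25, length.out = n),
    oc = seq(0.8, 3, length.out = n),
    caco3 = seq(0, 4, length.out = n),
    ox_mn = seq(50, 400, length.out = n),
    cd_mn = seq(60, 500, length.out = n),
    cd_fe = seq(4000, 60000, length.out = n),
    stringsAsFactors = FALSE
  )
}

# Noiseless observations on an explicit logistic curve
# Y = y0 / (1 + exp(s (X - a))), X = log10(edta_cu).
make_logistic_obs <- function(y0 = 100, a = 2, s = 5,
                              edta = 10^seq(0.5, 3, length.out = 8),
                              replicates = 3) {
  x <- rep(log10(edta), each = replicates)
  y <- y0 / (1 + exp(s * (x - a)))
  data.frame(site_id = "S1", treatment = "unleached", species = "tomato",
             added_cu = rep(seq_along(edta) - 1, each = replicates),
             edta_cu = 10^x,
             replicate = rep(seq_len(replicates), times = length(edta)),
             biomass = y / 100 * 2, relative_growth = y,
             stringsAsFactors = FALSE)
}

# Independent evaluation of the curve-location form on one profile.
.eval_a_for_test <- function(model, profile) {
  k <- model$a_coefs
  k[[1]] + k[[2]] * profile$pH + k[[3]] * log10(profile$oc) +
    k[[4]] * log10(profile$cec)
}

# A minimal converged-fit stub for functions that only read (a, b).
make_fit_stub <- function(site_id, a, b, y0 = 100) {
  structure(list(site_id = site_id, treatment = "unleached",
                 species = "tomato", y0 = y0, a = a, b = b,
                 ssr = 0, r2 = 1, n = 24, converged = TRUE,
                 failure_reason = NA_character_),
            class = "cu_drc_fit")
}
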