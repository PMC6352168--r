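# End-to-end pipeline: simulate (or load) a bioassay, fit per-soil curves,
# regress thresholds on soil properties, fit joint models, and emit
# prediction tables plus a summary report. All randomness flows from the
# single configured seed, so a rerun with the same configuration is
# byte-identical.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one nested list: panel and noise
#' settings of the generator, inhibition levels, selection parameters, and
#' the b-form covariates per species. Override fields via `...` (top-level
#' names replace the defaults wholesale).
#'
#' @param ... top-level overrides, e.g. `seed = 7`,
#'   `noise = list(cv = 0, replicates = 3, hormesis_peak = 1)`.
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    soils_csv = NULL,            # NULL = packaged 17-soil reference panel
    bioassay_csv = NULL,         # NULL = simulate
    species = c("tomato", "bok_choy"),
    treatments = c("unleached", "leached"),
    noise = list(cv = 0.10, replicates = 3L, hormesis_peak = 1),
    control_mass = 2,
    ec_levels = c(10, 50),
    bootstrap_B = 0L,            # per-group ECx bootstrap off by default
    alpha = 0.05,
    max_terms = 3L,
    b_covariates = list(tomato = c("pH", "ox_mn"), bok_choy = "pH"),
    scenario = list(pH = c(5, 8), oc = 1, cec = 20, ox_mn = 200)
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return configuration list (missing fields filled with defaults).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(paste(format(Sys.time(), "%H:%M:%S"), msg),
                                con)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load) the bioassay; fit every soil x
#' treatment x species group (`fits.csv`); summarize thresholds and
#' leaching factors; forward-selected threshold regressions
#' (`regressions.csv`); joint model per species x treatment
#' (`joint_model.json`); scenario curve tables and measured-vs-predicted
#' pairs (`predictions.csv`, `measured_vs_predicted.csv`); and a
#' `report.json` stamped with the configuration hash and seed.
#'
#' @param config [pipeline_config()] list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return the report list, invisibly; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config), !missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  hash <- .config_hash(config)
  .log_line(logf, "pipeline start; seed=", config$seed,
            " config_hash=", hash)

  soils <- if (is.null(config$soils_csv)) {
    load_reference_soils()
  } else {
    read_soil_table(config$soils_csv)
  }
  .log_line(logf, "soil panel: ", nrow(soils), " soils")

  # --- stage: simulate or load ---------------------------------------
  truth <- NULL
  if (is.null(config$bioassay_csv)) {
    parts <- list()
    truth <- list()
    for (i in seq_along(config$species)) {
      sp <- config$species[i]
      ns <- noise_spec(cv = config$noise$cv,
                       replicates = config$noise$replicates,
                       hormesis_peak = config$noise$hormesis_peak,
                       seed = config$seed + (i - 1L) * 1000L)
      sim <- simulate_bioassay(soils, species_params(sp), ns,
                               treatments = config$treatments,
                               control_mass = config$control_mass)
      tr <- attr(sim, "truth")
      truth[[sp]] <- list(y0 = tr$params$y0,
                          a_coefs = as.list(tr$params$a_coefs),
                          b_coefs = as.list(tr$params$b_coefs),
                          leach_a_shift = tr$params$leach_a_shift,
                          seed = ns$seed)
      parts[[sp]] <- sim
    }
    obs <- do.call(rbind, parts)
    rownames(obs) <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log_line(logf, "simulated ", nrow(obs), " observations")
  } else {
    obs <- read_bioassay_table(config$bioassay_csv)
    if (!"relative_growth" %in% names(obs)) {
      obs <- normalize_relative_growth(obs)
    }
    .log_line(logf, "loaded ", nrow(obs), " observations")
  }
  write_bioassay_table(obs, file.path(out_dir, "bioassay.csv"))

  # --- stage: per-group fits ------------------------------------------
  fits <- fit_bioassay(obs)
  fits_df <- as.data.frame(fits)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!isTRUE(f$converged)) {
      .log_line(logf, "fit failure ", f$site_id, "/", f$treatment, "/",
                f$species, ": ", f$failure_reason)
    }
  }
  if (config$bootstrap_B > 0L) {
    key <- interaction(obs$site_id, obs$treatment, obs$species,
                       drop = TRUE)
    for (x in config$ec_levels) {
      lo <- hi <- rep(NA_real_, nrow(fits_df))
      for (i in seq_len(nrow(fits_df))) {
        if (!fits_df$converged[i]) next
        g <- obs[obs$site_id == fits_df$site_id[i] &
                   obs$treatment == fits_df$treatment[i] &
                   obs$species == fits_df$species[i], , drop = FALSE]
        ci <- try(bootstrap_ci(g, x, B = config$bootstrap_B,
                               seed = config$seed + i), silent = TRUE)
        if (!inherits(ci, "try-error")) {
          lo[i] <- ci$ci_low; hi[i] <- ci$ci_high
        }
      }
      fits_df[[sprintf("ec%d_lo", x)]] <- lo
      fits_df[[sprintf("ec%d_hi", x)]] <- hi
    }
  }
  utils::write.csv(fits_df, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  .log_line(logf, "fitted ", nrow(fits_df), " groups (",
            sum(fits_df$converged), " converged)")

  # --- stage: threshold summaries and leaching factors ----------------
  summaries <- list()
  for (sp in config$species) {
    for (tr in unique(fits_df$treatment)) {
      sub <- Filter(function(f) f$species == sp && f$treatment == tr, fits)
      for (x in config$ec_levels) {
        s <- try(summarize_thresholds(sub, x), silent = TRUE)
        if (!inherits(s, "try-error")) {
          summaries[[sprintf("%s_%s_ec%d", sp, tr, x)]] <-
            s[c("range", "median", "mean", "fold_variation", "n_used")]
        }
      }
    }
    if (all(c("unleached", "leached") %in% fits_df$treatment)) {
      ul <- Filter(function(f) f$species == sp &&
                     f$treatment == "unleached", fits)
      le <- Filter(function(f) f$species == sp &&
                     f$treatment == "leached", fits)
      for (x in config$ec_levels) {
        lf <- try(leaching_factor(ul, le, x), silent = TRUE)
        if (!inherits(lf, "try-error")) {
          summaries[[sprintf("%s_leaching_ec%d", sp, x)]] <-
            lf[c("mean", "se", "sd", "n")]
        }
      }
    }
  }

  # --- stage: threshold regressions -----------------------------------
  regs <- threshold_regressions(fits_df, soils,
                                ec_levels = config$ec_levels,
                                alpha = config$alpha,
                                max_terms = config$max_terms)
  reg_df <- do.call(rbind, lapply(names(regs), function(nm) {
    m <- regs[[nm]]
    data.frame(model = nm, response = m$response,
               equation = equation_string(m), r2 = m$r2,
               p_model = m$p_model, n = m$n,
               nonsignificant = m$nonsignificant,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(reg_df, file.path(out_dir, "regressions.csv"),
                   row.names = FALSE)
  .log_line(logf, "threshold regressions: ", nrow(reg_df), " models")

  # --- stage: joint models --------------------------------------------
  joint <- list()
  for (sp in config$species) {
    bcov <- config$b_covariates[[sp]]
    for (tr in unique(obs$treatment[obs$species == sp])) {
      sub <- obs[obs$species == sp & obs$treatment == tr, , drop = FALSE]
      jf <- fit_joint(sub, soils, b_covariates = bcov)
      joint[[sprintf("%s_%s", sp, tr)]] <- jf
      .log_line(logf, "joint fit ", sp, "/", tr, ": R2=",
                round(jf$r2, 4),
                if (!isTRUE(jf$converged))
                  paste0(" NOT CONVERGED: ", jf$failure_reason) else "")
    }
  }
  jsonlite::write_json(
    lapply(joint, function(j) {
      list(species = j$species, treatment = j$treatment, y0 = j$y0,
           a_coefs = as.list(j$a_coefs), b_coefs = as.list(j$b_coefs),
           ssr = j$ssr, r2 = j$r2, p_model = j$p_model, n_obs = j$n_obs,
           n_soils = j$n_soils, converged = j$converged,
           screening = j$screening_report)
    }),
    file.path(out_dir, "joint_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage: predictions ---------------------------------------------
  sc <- config$scenario
  curves <- list()
  for (ph in sc$pH) {
    scen <- scenario_soil(pH = ph, oc = sc$oc, cec = sc$cec,
                          ox_mn = sc$ox_mn)
    for (nm in names(joint)) {
      jf <- joint[[nm]]
      if (!isTRUE(jf$converged)) next
      ct <- curve_table(jf, scen)
      ct$model <- nm
      ct$scenario_pH <- ph
      curves[[paste(nm, ph)]] <- ct
    }
  }
  pred_df <- do.call(rbind, curves)
  rownames(pred_df) <- NULL
  utils::write.csv(pred_df, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  mvp <- obs[, c("site_id", "treatment", "species", "edta_cu",
                 "relative_growth")]
  mvp$predicted <- NA_real_
  for (nm in names(joint)) {
    jf <- joint[[nm]]
    if (!isTRUE(jf$converged)) next
    sel <- which(mvp$species == jf$species & mvp$treatment == jf$treatment)
    for (s in unique(mvp$site_id[sel])) {
      rows <- sel[mvp$site_id[sel] == s]
      prof <- soils[soils$site_id == s, , drop = FALSE]
      mvp$predicted[rows] <- predict_response(jf, prof,
                                              mvp$edta_cu[rows])
    }
  }
  utils::write.csv(mvp, file.path(out_dir, "measured_vs_predicted.csv"),
                   row.names = FALSE)

  report <- list(
    config_hash = hash,
    seed = config$seed,
    n_soils = nrow(soils),
    n_obs = nrow(obs),
    n_groups = nrow(fits_df),
    n_converged = sum(fits_df$converged),
    threshold_summaries = summaries,
    joint_r2 = lapply(joint, function(j) j$r2),
    joint_converged = lapply(joint, function(j) j$converged)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(logf, "pipeline done: ", length(joint), " joint models")
  invisible(c(report, list(fits = fits, regressions = regs,
                           joint = joint)))
}
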