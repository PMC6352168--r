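# Soil property tables and bioassay observation handling.

.soil_required_cols <- c("site_id", "pH", "ec", "cec", "oc", "caco3",
                         "ox_mn", "cd_mn", "cd_fe")
.soil_optional_cols <- "clay"

.bioassay_required_cols <- c("site_id", "treatment", "species", "added_cu",
                             "edta_cu", "replicate", "biomass")

#' Validate a soil property table
#'
#' Checks the invariants every model in the package relies on: pH within
#' (2, 12); cec, oc, ox_mn, cd_mn and cd_fe strictly positive; caco3
#' non-negative; site_id unique.
#'
#' @param soils data.frame with columns site_id, pH, ec, cec, oc, caco3,
#'   ox_mn, cd_mn, cd_fe and optionally clay.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_soil_table <- function(soils) {
  stopifnot(is.data.frame(soils))
  missing <- setdiff(.soil_required_cols, names(soils))
  if (length(missing) > 0L) {
    stop("soil table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(soils$site_id)) {
    stop("duplicate site_id in soil table: ",
         paste(unique(soils$site_id[duplicated(soils$site_id)]),
               collapse = ", "), call. = FALSE)
  }
  check_row <- function(cond, what) {
    bad <- which(!cond)
    if (length(bad) > 0L) {
      stop(sprintf("soil table row %d (site '%s'): %s", bad[1L],
                   soils$site_id[bad[1L]], what), call. = FALSE)
    }
  }
  num_cols <- setdiff(.soil_required_cols, "site_id")
  for (cl in num_cols) {
    check_row(is.finite(soils[[cl]]), paste0(cl, " must be a finite number"))
  }
  check_row(soils$pH > 2 & soils$pH < 12, "pH must lie in (2, 12)")
  for (cl in c("cec", "oc", "ox_mn", "cd_mn", "cd_fe")) {
    check_row(soils[[cl]] > 0, paste0(cl, " must be strictly positive"))
  }
  check_row(soils$caco3 >= 0, "caco3 must be non-negative")
  if ("clay" %in% names(soils)) {
    check_row(is.na(soils$clay) | soils$clay > 0,
              "clay, when present, must be strictly positive")
  }
  invisible(soils)
}

#' Read a soil property table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header naming (case
#' insensitively) site_id, pH, ec, cec, oc, caco3, ox_mn, cd_mn, cd_fe and
#' optionally clay. Rows are validated with [validate_soil_table()] and
#' returned in file order.
#'
#' @param path path to the CSV file.
#' @return data.frame, one row per soil.
#' @export
read_soil_table <- function(path) {
  if (!file.exists(path)) stop("soil table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  canon <- c(.soil_required_cols, .soil_optional_cols)
  idx <- match(tolower(names(raw)), tolower(canon))
  names(raw)[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  missing <- setdiff(.soil_required_cols, names(raw))
  if (length(missing) > 0L) {
    stop("soil table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, intersect(canon, names(raw)), drop = FALSE]
  if (nrow(raw) == 0L) return(raw)
  raw$site_id <- as.character(raw$site_id)
  validate_soil_table(raw)
  raw
}

#' Write a soil property table to CSV
#'
#' @param soils validated soil table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_soil_table <- function(soils, path) {
  validate_soil_table(soils)
  utils::write.csv(soils, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The 17 reference Chinese agricultural soils
#'
#' Soil properties of 17 sites spanning the major Chinese agricultural soil
#' types: pH 4.93-8.90, CEC 6.36-33.6 cmol+/kg, OC 0.6-4.3\%, plus CaCO3 and
#' oxide-bound Mn/Fe pools. CaCO3 values below the 0.5\% detection limit are
#' stored as 0.25 (half the limit), the usual convention for left-censored
#' soil assays. These soils are the default covariate table of the synthetic
#' bioassay generator.
#'
#' @return data.frame with 17 rows and columns site_id, pH, ec, cec, oc,
#'   caco3, ox_mn, cd_mn, cd_fe.
#' @export
load_reference_soils <- function() {
  path <- system.file("extdata", "chinese_reference_soils.csv",
                      package = "cuphytox", mustWork = TRUE)
  read_soil_table(path)
}

#' Log10-transform soil covariates for regression and joint modelling
#'
#' OC, CEC, OX-Mn, CD-Mn and CD-Fe enter all models as log10; pH and CaCO3
#' (and clay, when present) enter untransformed.
#'
#' @param soils soil table (one or more rows).
#' @return data.frame with columns site_id, pH, logOC, logCEC, logOXMn,
#'   logCDMn, logCDFe, CaCO3 and clay when available.
#' @export
log_transform_properties <- function(soils) {
  validate_soil_table(soils)
  for (cl in c("oc", "cec", "ox_mn", "cd_mn", "cd_fe")) {
    if (any(soils[[cl]] <= 0)) {
      stop("cannot log10-transform non-positive ", cl, call. = FALSE)
    }
  }
  out <- data.frame(
    site_id = soils$site_id,
    pH      = soils$pH,
    logOC   = log10(soils$oc),
    logCEC  = log10(soils$cec),
    logOXMn = log10(soils$ox_mn),
    logCDMn = log10(soils$cd_mn),
    logCDFe = log10(soils$cd_fe),
    CaCO3   = soils$caco3,
    stringsAsFactors = FALSE
  )
  if ("clay" %in% names(soils)) out$clay <- soils$clay
  out
}

#' Validate a bioassay observation table
#'
#' @param obs data.frame with columns site_id, treatment, species, added_cu,
#'   edta_cu, replicate, biomass and optionally relative_growth.
#' @return the table, invisibly.
#' @export
validate_bioassay_table <- function(obs) {
  stopifnot(is.data.frame(obs))
  missing <- setdiff(.bioassay_required_cols, names(obs))
  if (length(missing) > 0L) {
    stop("bioassay table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_tr <- setdiff(unique(obs$treatment), c("unleached", "leached"))
  if (length(bad_tr) > 0L) {
    stop("unknown treatment level(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(obs$edta_cu) | obs$edta_cu <= 0)) {
    stop("edta_cu must be strictly positive for every observation",
         call. = FALSE)
  }
  if (any(!is.finite(obs$biomass) | obs$biomass < 0)) {
    stop("biomass must be non-negative for every observation", call. = FALSE)
  }
  if (any(obs$added_cu < 0)) {
    stop("added_cu must be non-negative", call. = FALSE)
  }
  invisible(obs)
}

#' Read / write a bioassay observation table
#'
#' @param path CSV path.
#' @return data.frame of observations.
#' @export
read_bioassay_table <- function(path) {
  if (!file.exists(path)) stop("bioassay table not found: ", path,
                               call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  names(obs) <- tolower(names(obs))
  validate_bioassay_table(obs)
  obs
}

#' @rdname read_bioassay_table
#' @param obs bioassay table.
#' @export
write_bioassay_table <- function(obs, path) {
  validate_bioassay_table(obs)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize biomass to relative growth (\% of control)
#'
#' Within each soil x treatment x species group, relative growth is 100 x
#' biomass / mean control biomass, so the controls of every group average
#' exactly 100. Each soil is its own reference: undisturbed growth differs
#' between soils and treatments, so a global control would confound soil
#' fertility with toxicity.
#'
#' @param obs bioassay table; each group must contain at least one control
#'   (added_cu = 0) observation.
#' @return the table with `relative_growth` (re)computed.
#' @export
normalize_relative_growth <- function(obs) {
  validate_bioassay_table(obs)
  key <- interaction(obs$site_id, obs$treatment, obs$species, drop = TRUE)
  out <- obs
  out$relative_growth <- NA_real_
  for (g in levels(key)) {
    rows <- which(key == g)
    ctrl <- rows[obs$added_cu[rows] == 0]
    if (length(ctrl) == 0L) {
      stop("no control (added_cu = 0) observation in group ", g,
           call. = FALSE)
    }
    m <- mean(obs$biomass[ctrl])
    if (m <= 0) stop("control biomass mean is not positive in group ", g,
                     call. = FALSE)
    out$relative_growth[rows] <- 100 * obs$biomass[rows] / m
  }
  out
}
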