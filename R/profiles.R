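#' Species presets with default body weights
#'
#' Reference body weights used throughout single-species scaling:
#' rat 0.25 kg, monkey 3.5 kg, human 70 kg.
#'
#' @format Named numeric vector of body weights in kg.
#' @export
species_presets <- c(rat = 0.25, monkey = 3.5, human = 70)

.analyte_levels <- c("total", "conjugated", "unconjugated", "payload")

#' Construct a concentration-time profile
#'
#' The universal currency of the package: one analyte's mean
#' concentration-time series in one species after an IV bolus dose,
#' together with the dose and body-weight metadata that the scaling
#' methods and noncompartmental analysis need.
#'
#' Units are fixed package-wide: time in days, concentration in ug/mL
#' (equivalently mg/L), body weight in kg, dose in mg (total) or mg/kg
#' (per-kg). At least one of `dose_per_kg` and `dose_total` must be given;
#' the other is derived via `body_weight`. When both are given they must
#' agree to 1e-9 relative.
#'
#' Concentrations below `lloq` (when given) are dropped with a message --
#' never stored as zero, since these are mean curves, not individual data.
#'
#' @param time Numeric vector of sampling times (days), strictly increasing,
#'   nonnegative.
#' @param conc Numeric vector of concentrations (ug/mL), all positive.
#' @param species Species label; one of the preset names (`rat`, `monkey`,
#'   `human`) or any identifier string when `body_weight` is supplied.
#' @param body_weight Body weight in kg. Defaults to the preset weight when
#'   `species` is a preset name.
#' @param dose_per_kg Dose in mg/kg (optional if `dose_total` given).
#' @param dose_total Total dose in mg (optional; derived when absent).
#' @param analyte One of `"total"`, `"conjugated"`, `"unconjugated"`,
#'   `"payload"`.
#' @param lloq Optional lower limit of quantification (ug/mL).
#' @param matrix Optional free-text tag for the sampled matrix
#'   (e.g. `"serum"`, `"plasma"`); carried without semantics.
#'
#' @return An object of class `conc_profile`.
#' @examples
#' p <- conc_profile(c(1, 7, 14), c(100, 50, 10),
#'                   species = "monkey", dose_per_kg = 1)
#' p$dose_total # 3.5 mg
#' @export
conc_profile <- function(time, conc, species, body_weight = NULL,
                         dose_per_kg = NULL, dose_total = NULL,
                         analyte = "total", lloq = NULL, matrix = NULL) {
  if (length(time) != length(conc))
    stop("`time` and `conc` must have equal length", call. = FALSE)
  if (length(time) == 0L)
    stop("profile has no data points", call. = FALSE)
  time <- as.numeric(time)
  conc <- as.numeric(conc)
  if (anyNA(time) || anyNA(conc))
    stop("`time`/`conc` must not contain missing values", call. = FALSE)
  if (any(time < 0))
    stop("times must be nonnegative", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing (row %d)", bad),
         call. = FALSE)
  }
  if (any(conc <= 0)) {
    bad <- which(conc <= 0)[1L]
    stop(sprintf("concentrations must be positive (row %d); drop below-LLOQ rows, do not store 0",
                 bad), call. = FALSE)
  }
  analyte <- match.arg(analyte, .analyte_levels)

  species <- as.character(species)
  if (is.null(body_weight)) {
    if (!species %in% names(species_presets))
      stop(sprintf("missing required metadata: body_weight_kg (no preset for species '%s')",
                   species), call. = FALSE)
    body_weight <- unname(species_presets[[species]])
  }
  body_weight <- as.numeric(body_weight)
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a positive number (kg)", call. = FALSE)

  if (is.null(dose_per_kg) && is.null(dose_total))
    stop("missing required metadata: dose (dose_per_kg or dose_total)",
         call. = FALSE)
  if (is.null(dose_total)) dose_total <- dose_per_kg * body_weight
  if (is.null(dose_per_kg)) dose_per_kg <- dose_total / body_weight
  dose_total <- as.numeric(dose_total)
  dose_per_kg <- as.numeric(dose_per_kg)
  if (dose_total <= 0 || dose_per_kg <= 0)
    stop("doses must be positive", call. = FALSE)
  if (abs(dose_total - dose_per_kg * body_weight) >
      1e-9 * max(dose_total, dose_per_kg * body_weight))
    stop("dose_total and dose_per_kg * body_weight disagree", call. = FALSE)

  if (!is.null(lloq)) {
    lloq <- as.numeric(lloq)
    if (!is.finite(lloq) || lloq <= 0)
      stop("lloq must be a positive number (ug/mL)", call. = FALSE)
    keep <- conc >= lloq
    if (!any(keep))
      stop("all concentrations are below the LLOQ", call. = FALSE)
    if (!all(keep))
      message(sprintf("dropped %d point(s) below LLOQ (%g ug/mL)",
                      sum(!keep), lloq))
    time <- time[keep]
    conc <- conc[keep]
  }

  structure(
    list(species = species, body_weight = body_weight,
         dose_per_kg = dose_per_kg, dose_total = dose_total,
         analyte = analyte, time = time, conc = conc,
         lloq = lloq, matrix = matrix),
    class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s (%g kg), analyte %s, dose %g mg (%g mg/kg)\n",
              x$species, x$body_weight, x$analyte, x$dose_total, x$dose_per_kg))
  if (!is.null(x$lloq)) cat(sprintf("  LLOQ: %g ug/mL\n", x$lloq))
  cat(sprintf("  %d points over %g-%g days; Cmax %g, Clast %g ug/mL\n",
              length(x$time), min(x$time), max(x$time),
              max(x$conc), x$conc[length(x$conc)]))
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(time_days = x$time, conc_ug_ml = x$conc)
}

#' @export
length.conc_profile <- function(x) length(x$time)

# ---- CSV serialization ------------------------------------------------------

# Dialect: UTF-8 CSV, '#key=value' metadata lines before the header,
# then columns time_days,conc_ug_ml.

.meta_keys <- c("species", "body_weight_kg", "dose_mg_per_kg", "dose_mg",
                "analyte", "lloq_ug_ml", "matrix")

#' Read a concentration-time profile from CSV
#'
#' Expects a comma-separated file whose data section has the header
#' `time_days,conc_ug_ml`, preceded by `#key=value` metadata lines.
#' Recognised keys: `species`, `body_weight_kg`, `dose_mg_per_kg`,
#' `dose_mg`, `analyte`, `lloq_ug_ml`, `matrix`. A dose may also be given
#' as `dose=<x> mg/kg` or `dose=<x> mg`. `species` plus either an explicit
#' body weight or a preset name, one dose field, and `analyte` are
#' required (defaults may be injected through `overrides`).
#'
#' Rows with concentration below the LLOQ (when one is given) are dropped
#' and the count reported via a message.
#'
#' @param path Path to the CSV file.
#' @param overrides Optional named list of metadata overriding (or
#'   supplying) file metadata; names as above.
#' @return A validated [conc_profile()].
#' @export
read_profile <- function(path, overrides = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  body_start <- match(FALSE, is_meta)
  if (is.na(body_start))
    stop("no data section found (only metadata lines)", call. = FALSE)

  meta <- list()
  for (ln in lines[seq_len(body_start - 1L)]) {
    ln <- sub("^#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    meta[[key]] <- val
  }
  if (!is.null(overrides)) meta[names(overrides)] <- overrides

  # 'dose=1 mg/kg' / 'dose=3.5 mg' shorthand
  if (!is.null(meta[["dose"]])) {
    d <- meta[["dose"]]
    if (grepl("mg\\s*/\\s*kg", d)) {
      meta[["dose_mg_per_kg"]] <- sub("mg\\s*/\\s*kg.*$", "", d)
    } else if (grepl("mg", d)) {
      meta[["dose_mg"]] <- sub("mg.*$", "", d)
    } else {
      stop("dose metadata needs a unit suffix ('mg/kg' or 'mg')",
           call. = FALSE)
    }
  }
  if (is.null(meta[["species"]]))
    stop("missing required metadata: species", call. = FALSE)
  if (is.null(meta[["dose_mg_per_kg"]]) && is.null(meta[["dose_mg"]]))
    stop("missing required metadata: dose (dose_mg_per_kg or dose_mg)",
         call. = FALSE)
  if (is.null(meta[["analyte"]]))
    stop("missing required metadata: analyte", call. = FALSE)

  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L || !grepl("^\\s*time_days\\s*,\\s*conc_ug_ml", body[1L]))
    stop("data section must start with header 'time_days,conc_ug_ml'",
         call. = FALSE)
  if (length(body) < 2L)
    stop("data section is empty", call. = FALSE)
  dat <- utils::read.csv(text = body, header = TRUE,
                         colClasses = c("numeric", "numeric"))

  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  conc_profile(
    time = dat$time_days, conc = dat$conc_ug_ml,
    species = meta[["species"]],
    body_weight = num_or_null(meta[["body_weight_kg"]]),
    dose_per_kg = num_or_null(meta[["dose_mg_per_kg"]]),
    dose_total = num_or_null(meta[["dose_mg"]]),
    analyte = if (is.null(meta[["analyte"]])) "total" else meta[["analyte"]],
    lloq = num_or_null(meta[["lloq_ug_ml"]]),
    matrix = meta[["matrix"]])
}

#' Write a concentration-time profile to CSV
#'
#' Inverse of [read_profile()]: writes the `#key=value` metadata block
#' (both dose fields populated) followed by the `time_days,conc_ug_ml`
#' data section. Numbers are serialized with 15 significant digits so that
#' `read_profile(write_profile(p))` reproduces `p` field-for-field.
#'
#' @param profile A [conc_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "conc_profile"))
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  meta <- c(
    sprintf("#species=%s", profile$species),
    sprintf("#body_weight_kg=%s", fmt(profile$body_weight)),
    sprintf("#dose_mg_per_kg=%s", fmt(profile$dose_per_kg)),
    sprintf("#dose_mg=%s", fmt(profile$dose_total)),
    sprintf("#analyte=%s", profile$analyte))
  if (!is.null(profile$lloq))
    meta <- c(meta, sprintf("#lloq_ug_ml=%s", fmt(profile$lloq)))
  if (!is.null(profile$matrix))
    meta <- c(meta, sprintf("#matrix=%s", profile$matrix))
  rows <- paste(fmt(profile$time), fmt(profile$conc), sep = ",")
  out <- c(meta, "time_days,conc_ug_ml", rows)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop(sprintf("cannot write to %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
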