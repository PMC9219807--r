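#' Define a concentration-time scaling method
#'
#' A scaling method maps each animal concentration to a predicted human
#' concentration through
#' \deqn{C_h(t) = C_a(t) \times (D_h/D_a)^{d} \times (W_a/W_h)^{b(t)}}
#' where \eqn{D} are total doses (mg), \eqn{W} body weights (kg), \eqn{d}
#' the dose exponent (1.0, or 0.85 when clearance scaling is folded into
#' the dose ratio) and \eqn{b(t)} the volume-of-distribution exponent,
#' optionally switching to a smaller value at `switch_time` to lift the
#' terminal phase.
#'
#' @param volume_exponent_early Exponent `b` before the switch (in (0, 1.5]).
#' @param volume_exponent_late Optional exponent at/after `switch_time`.
#' @param dose_exponent Exponent on the total-dose ratio; default 1.0.
#' @param switch_time Optional switch time in days (the late exponent
#'   applies for `t >= switch_time`, i.e. the boundary is inclusive).
#' @param method_id Label for printing; presets use Roman numerals I-VIII.
#' @return An object of class `scaling_method`.
#' @seealso [method_preset()] for the eight standard methods.
#' @export
scaling_method <- function(volume_exponent_early,
                           volume_exponent_late = NULL,
                           dose_exponent = 1.0,
                           switch_time = NULL,
                           method_id = "custom") {
  stopifnot(is.numeric(volume_exponent_early),
            length(volume_exponent_early) == 1L)
  if (volume_exponent_early <= 0 || volume_exponent_early > 1.5)
    stop("volume_exponent_early must lie in (0, 1.5]", call. = FALSE)
  if (xor(is.null(volume_exponent_late), is.null(switch_time)))
    stop("volume_exponent_late and switch_time must be given together",
         call. = FALSE)
  if (!is.null(switch_time) && switch_time < 0)
    stop("switch_time must be nonnegative", call. = FALSE)
  if (!is.null(volume_exponent_late) &&
      (volume_exponent_late <= 0 || volume_exponent_late > 1.5))
    stop("volume_exponent_late must lie in (0, 1.5]", call. = FALSE)
  if (dose_exponent <= 0)
    stop("dose_exponent must be positive", call. = FALSE)
  structure(
    list(method_id = method_id,
         volume_exponent_early = volume_exponent_early,
         volume_exponent_late = volume_exponent_late,
         dose_exponent = dose_exponent,
         switch_time = switch_time),
    class = "scaling_method")
}

.method_table <- list(
  I    = list(b = 1.0, d = 1.0,  mnemonic = "v1.0"),
  II   = list(b = 0.9, d = 1.0,  mnemonic = "v0.9"),
  III  = list(b = 0.8, d = 1.0,  mnemonic = "v0.8"),
  IV   = list(b = 1.0, d = 0.85, mnemonic = "cl0.85-v1.0"),
  V    = list(b = 0.9, d = 0.85, mnemonic = "cl0.85-v0.9"),
  VI   = list(b = 0.8, d = 0.85, mnemonic = "cl0.85-v0.8"),
  VII  = list(b = 1.0, d = 1.0,  late = 0.8, switch = 14, mnemonic = "v1.0+0.8"),
  VIII = list(b = 0.9, d = 1.0,  late = 0.8, switch = 14, mnemonic = "v0.9+0.8"))

#' The eight standard projection methods
#'
#' Presets I-III use a single volume exponent (1.0, 0.9, 0.8) on the
#' weight ratio with dose exponent 1.0; IV-VI add the clearance exponent
#' 0.85 on the dose ratio; VII and VIII switch the volume exponent to 0.8
#' from day 14 onwards (early exponent 1.0 and 0.9 respectively) to
#' improve the terminal phase.
#'
#' @param id Roman numeral `"I"`..`"VIII"` or the mnemonic name
#'   (`"v1.0"`, `"v0.9"`, `"v0.8"`, `"cl0.85-v1.0"`, `"cl0.85-v0.9"`,
#'   `"cl0.85-v0.8"`, `"v1.0+0.8"`, `"v0.9+0.8"`).
#' @return A [scaling_method()].
#' @examples
#' method_preset("VIII")
#' method_preset("v0.9+0.8")
#' @export
method_preset <- function(id) {
  id <- as.character(id)
  roman <- names(.method_table)
  mnems <- vapply(.method_table, `[[`, "", "mnemonic")
  key <- if (id %in% roman) id else roman[match(id, mnems)]
  if (is.na(key))
    stop(sprintf("unknown method '%s'; valid presets: %s", id,
                 paste(paste0(roman, " (", mnems, ")"), collapse = ", ")),
         call. = FALSE)
  m <- .method_table[[key]]
  scaling_method(volume_exponent_early = m$b,
                 volume_exponent_late = m$late,
                 dose_exponent = m$d,
                 switch_time = m$switch,
                 method_id = key)
}

#' All preset method ids
#' @return Character vector `c("I", ..., "VIII")`.
#' @export
method_ids <- function() names(.method_table)

#' @export
print.scaling_method <- function(x, ...) {
  cat(sprintf("<scaling_method %s> dose exponent %g; volume exponent %g",
              x$method_id, x$dose_exponent, x$volume_exponent_early))
  if (!is.null(x$switch_time))
    cat(sprintf(" (t < %g d), %g (t >= %g d)",
                x$switch_time, x$volume_exponent_late, x$switch_time))
  cat("\n")
  invisible(x)
}

#' Volume exponent in effect at a given time
#'
#' For switching methods (VII, VIII) returns the early exponent for
#' `t < switch_time` and the late exponent for `t >= switch_time`
#' (the switch day itself uses the late exponent); single-exponent
#' methods are time-invariant.
#'
#' @param method A [scaling_method()].
#' @param t Time(s) in days, nonnegative; vectorized.
#' @return Numeric vector of exponents, one per element of `t`.
#' @export
select_exponent <- function(method, t) {
  stopifnot(inherits(method, "scaling_method"), all(t >= 0))
  if (is.null(method$switch_time))
    return(rep_len(method$volume_exponent_early, length(t)))
  ifelse(t >= method$switch_time,
         method$volume_exponent_late,
         method$volume_exponent_early)
}

#' Dose- and weight-ratio scaling factor
#'
#' The multiplier applied to an animal concentration at time `t`:
#' `(D_h/D_a)^dose_exponent * (W_a/W_h)^b(t)`, evaluated in log space.
#' Doses are total amounts in mg -- with dose exponent 1 and equal mg/kg
#' doses this makes the factor reduce to `(W_h/W_a)^(1-b)`, so an animal
#' profile maps onto itself when weights are equal.
#'
#' @param method A [scaling_method()].
#' @param animal_dose_total,human_dose_total Total doses in mg.
#' @param animal_weight,human_weight Body weights in kg.
#' @param t Time(s) in days (selects the exponent for switching methods).
#' @return Positive scaling factor(s), one per element of `t`.
#' @examples
#' scaling_factor(method_preset("I"), 3.5, 350, 3.5, 70, 7) # 5
#' @export
scaling_factor <- function(method, animal_dose_total, human_dose_total,
                           animal_weight, human_weight, t) {
  vals <- c(animal_dose_total, human_dose_total, animal_weight, human_weight)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("doses and weights must be positive and finite", call. = FALSE)
  b <- select_exponent(method, t)
  exp(method$dose_exponent * (log(human_dose_total) - log(animal_dose_total)) +
        b * (log(animal_weight) - log(human_weight)))
}

#' Project an animal profile to a predicted human profile
#'
#' Applies [scaling_factor()] pointwise. Time values are carried over
#' unchanged (no species-invariant-time rescaling of the abscissa), so the
#' predicted profile has exactly the animal profile's sampling times.
#'
#' @param animal A [conc_profile()] in the source species.
#' @param human_dose_per_kg Intended human dose in mg/kg.
#' @param human_weight Human body weight in kg; default 70.
#' @param method A [scaling_method()] or a preset id accepted by
#'   [method_preset()].
#' @return A `predicted_profile`: a [conc_profile()] with species label
#'   `"human-predicted"` plus the method and source-species attributes.
#' @examples
#' mk <- conc_profile(c(1, 7, 14), c(100, 50, 10),
#'                    species = "monkey", dose_per_kg = 1)
#' predict_profile(mk, human_dose_per_kg = 5, method = "I")
#' @export
predict_profile <- function(animal, human_dose_per_kg, human_weight = 70,
                            method) {
  stopifnot(inherits(animal, "conc_profile"))
  if (is.character(method)) method <- method_preset(method)
  stopifnot(inherits(method, "scaling_method"))
  if (!is.finite(human_dose_per_kg) || human_dose_per_kg <= 0)
    stop("human_dose_per_kg must be positive", call. = FALSE)
  if (!is.finite(human_weight) || human_weight <= 0)
    stop("human_weight must be positive", call. = FALSE)
  human_dose_total <- human_dose_per_kg * human_weight
  f <- scaling_factor(method, animal$dose_total, human_dose_total,
                      animal$body_weight, human_weight, animal$time)
  out <- conc_profile(time = animal$time, conc = animal$conc * f,
                      species = "human-predicted",
                      body_weight = human_weight,
                      dose_per_kg = human_dose_per_kg,
                      dose_total = human_dose_total,
                      analyte = animal$analyte,
                      matrix = animal$matrix)
  class(out) <- c("predicted_profile", class(out))
  attr(out, "method") <- method
  attr(out, "source_species") <- animal$species
  out
}

#' @export
print.predicted_profile <- function(x, ...) {
  m <- attr(x, "method")
  cat(sprintf("<predicted_profile> method %s from %s\n",
              m$method_id, attr(x, "source_species")))
  NextMethod()
}
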