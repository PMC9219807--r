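#' Fixed-exponent PK scaling specification
#'
#' Exponents for single-species scaling of clearance and half-life.
#' Defaults: clearance exponent 0.85 (the consensus value for
#' macromolecules) and half-life exponent 0.15 = 1 - 0.85, the
#' volume-minus-clearance difference under a volume exponent of 1.0.
#' The half-life exponent is stored independently rather than derived so
#' it can be varied on its own (fixed 0.15 is not always accurate).
#'
#' @param cl_exponent Clearance exponent; default 0.85.
#' @param halflife_exponent Half-life exponent; default `1 - cl_exponent`.
#' @param human_weight Target human body weight in kg; default 70.
#' @return An object of class `pk_scaling_spec`.
#' @export
pk_scaling_spec <- function(cl_exponent = 0.85,
                            halflife_exponent = 1 - cl_exponent,
                            human_weight = 70) {
  stopifnot(is.numeric(cl_exponent), is.numeric(halflife_exponent),
            human_weight > 0)
  structure(list(cl_exponent = cl_exponent,
                 halflife_exponent = halflife_exponent,
                 human_weight = human_weight),
            class = "pk_scaling_spec")
}

#' @export
print.pk_scaling_spec <- function(x, ...) {
  cat(sprintf("<pk_scaling_spec> CL exponent %g, half-life exponent %g, human %g kg\n",
              x$cl_exponent, x$halflife_exponent, x$human_weight))
  invisible(x)
}

#' Predict human clearance from one animal species
#'
#' `CL_human = CL_animal * (W_human / W_animal) ^ cl_exponent`, with
#' clearance in absolute units (L/day) -- the weight-ratio power is only
#' valid for absolute, not per-kg, clearance.
#'
#' @param cl_animal Animal clearance, L/day; positive.
#' @param animal_weight Animal body weight, kg; positive.
#' @param spec A [pk_scaling_spec()].
#' @return Predicted human clearance, L/day.
#' @examples
#' predict_human_clearance(0.010, 3.5) # monkey -> 0.1276 L/day
#' @export
predict_human_clearance <- function(cl_animal, animal_weight,
                                    spec = pk_scaling_spec()) {
  stopifnot(inherits(spec, "pk_scaling_spec"))
  if (any(!is.finite(c(cl_animal, animal_weight))) ||
      any(c(cl_animal, animal_weight) <= 0))
    stop("cl_animal and animal_weight must be positive", call. = FALSE)
  cl_animal * exp(spec$cl_exponent *
                    (log(spec$human_weight) - log(animal_weight)))
}

#' Predict human half-life from one animal species
#'
#' `t_half_human = t_half_animal * (W_human / W_animal) ^ halflife_exponent`.
#'
#' @param thalf_animal Animal half-life, days; positive.
#' @param animal_weight Animal body weight, kg; positive.
#' @param spec A [pk_scaling_spec()].
#' @return Predicted human half-life, days.
#' @examples
#' predict_human_half_life(5, 3.5) # monkey -> 7.84 days
#' @export
predict_human_half_life <- function(thalf_animal, animal_weight,
                                    spec = pk_scaling_spec()) {
  stopifnot(inherits(spec, "pk_scaling_spec"))
  if (any(!is.finite(c(thalf_animal, animal_weight))) ||
      any(c(thalf_animal, animal_weight) <= 0))
    stop("thalf_animal and animal_weight must be positive", call. = FALSE)
  thalf_animal * exp(spec$halflife_exponent *
                       (log(spec$human_weight) - log(animal_weight)))
}

#' Species-invariant-time equivalence factor
#'
#' How many days of human time correspond to one day of animal time under
#' a Dedrick-style time transformation:
#' `(W_human / W_animal) ^ (v_exponent - cl_exponent)`.
#' With clearance exponent 0.79 and volume exponent 1.0, one monkey day is
#' about 1.88 human days and one rat day about 3.27 human days.
#'
#' This is a diagnostic only: the projection pipeline deliberately keeps
#' the animal time axis unchanged and never rescales time.
#'
#' @param animal_weight,human_weight Body weights in kg; positive.
#' @param cl_exponent Clearance exponent; default 0.79.
#' @param v_exponent Volume exponent; default 1.0.
#' @return Positive scalar, human days per animal day.
#' @examples
#' equivalent_time_factor(3.5, 70)   # ~1.88, rounds to 2
#' equivalent_time_factor(0.25, 70)  # ~3.27, rounds to 3
#' @export
equivalent_time_factor <- function(animal_weight, human_weight = 70,
                                   cl_exponent = 0.79, v_exponent = 1.0) {
  if (any(!is.finite(c(animal_weight, human_weight))) ||
      any(c(animal_weight, human_weight) <= 0))
    stop("weights must be positive", call. = FALSE)
  exp((v_exponent - cl_exponent) *
        (log(human_weight) - log(animal_weight)))
}
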