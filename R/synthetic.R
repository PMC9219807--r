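#' Define a synthetic allometric PK scenario
#'
#' Ground truth for a paired animal/human IV-bolus simulation from a
#' two-compartment disposition model. The reference (animal) parameters
#' are scaled to the human by `r = target_weight / ref_weight`:
#' clearances (CL, Q) by `r^e_cl`, volumes (V1, V2) by `r^e_v` -- flows
#' scale like clearances and volumes like volumes.
#'
#' Defaults describe a monkey-like reference with mAb-scale disposition
#' (CL 10 mL/day/kg, V1 40 mL/kg, i.e. roughly plasma volume) and the
#' sampling grid typical of ADC studies (0.25-42 days).
#'
#' @param ref_weight Animal body weight, kg (default monkey 3.5).
#' @param target_weight Human body weight, kg (default 70).
#' @param cl_ref,v1_ref,q_ref,v2_ref Reference clearance (L/day), central
#'   volume (L), inter-compartmental clearance (L/day), peripheral volume
#'   (L). `q_ref = 0` degenerates to a one-compartment model.
#' @param e_cl Allometric exponent for CL and Q; default 0.85.
#' @param e_v Allometric exponent for V1 and V2; default 0.9.
#' @param dose_animal_per_kg,dose_human_per_kg Doses in mg/kg.
#' @param sampling_times Strictly increasing sampling times, days.
#' @param noise_cv Lognormal residual coefficient of variation (0 = none).
#' @param lloq Optional LLOQ in ug/mL; simulated values below it are
#'   dropped.
#' @param seed Integer seed for the residual-noise generator.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(ref_weight = 3.5, target_weight = 70,
                         cl_ref = 0.035, v1_ref = 0.14,
                         q_ref = 0.025, v2_ref = 0.105,
                         e_cl = 0.85, e_v = 0.9,
                         dose_animal_per_kg = 1,
                         dose_human_per_kg = 5,
                         sampling_times = c(0.25, 1, 3, 7, 10, 14,
                                            21, 28, 35, 42),
                         noise_cv = 0, lloq = NULL, seed = 1L) {
  stopifnot(ref_weight > 0, target_weight > 0,
            cl_ref > 0, v1_ref > 0, q_ref >= 0, v2_ref > 0,
            dose_animal_per_kg > 0, dose_human_per_kg > 0,
            noise_cv >= 0)
  if (e_cl <= 0 || e_cl > 1.5 || e_v <= 0 || e_v > 1.5)
    stop("allometric exponents must lie in (0, 1.5]", call. = FALSE)
  if (length(sampling_times) < 2L ||
      is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling_times must be strictly increasing", call. = FALSE)
  structure(
    list(ref_weight = ref_weight, target_weight = target_weight,
         cl_ref = cl_ref, v1_ref = v1_ref, q_ref = q_ref, v2_ref = v2_ref,
         e_cl = e_cl, e_v = e_v,
         dose_animal_per_kg = dose_animal_per_kg,
         dose_human_per_kg = dose_human_per_kg,
         sampling_times = sampling_times,
         noise_cv = noise_cv, lloq = lloq, seed = as.integer(seed)),
    class = "sim_scenario")
}

#' Macro constants of the two-compartment IV-bolus model
#'
#' Closed-form hybrid constants for `C(t) = A exp(-alpha t) + B exp(-beta t)`
#' from micro rate constants `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`:
#' alpha and beta are the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21 = 0` (alpha > beta), and
#' `A = C0 (alpha - k21)/(alpha - beta)`, `B = C0 (k21 - beta)/(alpha - beta)`
#' with `C0 = dose/V1`. The smaller root is computed from the product
#' identity `beta = k10 k21 / alpha` to avoid cancellation.
#'
#' `q = 0` degenerates gracefully to the one-compartment limit
#' (`alpha = k10`, `B = 0`).
#'
#' @param cl Clearance, L/day.
#' @param v1 Central volume, L.
#' @param q Inter-compartmental clearance, L/day (may be 0).
#' @param v2 Peripheral volume, L.
#' @param dose_total Dose, mg.
#' @return List with `A`, `B` (ug/mL), `alpha`, `beta` (1/day).
#' @export
macro_constants <- function(cl, v1, q, v2, dose_total) {
  stopifnot(cl > 0, v1 > 0, q >= 0, v2 > 0, dose_total > 0)
  c0 <- dose_total / v1
  k10 <- cl / v1
  if (q == 0)
    return(list(A = c0, B = 0, alpha = k10, beta = 0))
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  beta <- k10 * k21 / alpha
  list(A = c0 * (alpha - k21) / (alpha - beta),
       B = c0 * (k21 - beta) / (alpha - beta),
       alpha = alpha, beta = beta)
}

.conc_curve <- function(mc, t) {
  mc$A * exp(-mc$alpha * t) + mc$B * exp(-mc$beta * t)
}

#' Simulate a paired animal/human concentration-time study
#'
#' Evaluates the two-compartment closed form in the reference animal and
#' in the allometrically scaled human on the scenario's sampling grid,
#' applies independent multiplicative lognormal noise per point
#' (`sdlog = sqrt(log(1 + cv^2))`, median-unbiased), drops values below
#' the LLOQ, and returns both profiles plus the exact scaled parameters.
#'
#' The same seed always yields identical output; animal and human noise
#' streams are drawn from one seeded generator in a fixed order.
#'
#' @param scenario A [sim_scenario()].
#' @return List with elements `animal` and `human` ([conc_profile()]s) and
#'   `truth`: the exact human parameters (`cl`, `v1`, `q`, `v2`, `vss`,
#'   `thalf_terminal`, macro constants) and their animal counterparts.
#' @examples
#' sim <- simulate_pair(sim_scenario(noise_cv = 0))
#' sim$truth$human$thalf_terminal
#' @export
simulate_pair <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  r <- sc$target_weight / sc$ref_weight

  par_animal <- list(cl = sc$cl_ref, v1 = sc$v1_ref,
                     q = sc$q_ref, v2 = sc$v2_ref)
  par_human <- list(cl = sc$cl_ref * r^sc$e_cl,
                    v1 = sc$v1_ref * r^sc$e_v,
                    q = sc$q_ref * r^sc$e_cl,
                    v2 = sc$v2_ref * r^sc$e_v)

  dose_animal <- sc$dose_animal_per_kg * sc$ref_weight
  dose_human <- sc$dose_human_per_kg * sc$target_weight
  mc_animal <- macro_constants(par_animal$cl, par_animal$v1, par_animal$q,
                               par_animal$v2, dose_animal)
  mc_human <- macro_constants(par_human$cl, par_human$v1, par_human$q,
                              par_human$v2, dose_human)

  t <- sc$sampling_times
  conc_a <- .conc_curve(mc_animal, t)
  conc_h <- .conc_curve(mc_human, t)

  if (sc$noise_cv > 0) {
    sdlog <- sqrt(log(1 + sc$noise_cv^2))
    # local RNG scope: do not disturb the caller's random stream
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(sc$seed)
    conc_a <- conc_a * exp(stats::rnorm(length(t), 0, sdlog))
    conc_h <- conc_h * exp(stats::rnorm(length(t), 0, sdlog))
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, .GlobalEnv)
    }
  }

  keep_a <- if (is.null(sc$lloq)) rep(TRUE, length(t)) else conc_a >= sc$lloq
  keep_h <- if (is.null(sc$lloq)) rep(TRUE, length(t)) else conc_h >= sc$lloq
  if (!any(keep_a) || !any(keep_h))
    stop("all simulated points censored by the LLOQ", call. = FALSE)

  animal <- conc_profile(t[keep_a], conc_a[keep_a],
                         species = "animal-sim",
                         body_weight = sc$ref_weight,
                         dose_per_kg = sc$dose_animal_per_kg,
                         analyte = "total")
  human <- conc_profile(t[keep_h], conc_h[keep_h],
                        species = "human-sim",
                        body_weight = sc$target_weight,
                        dose_per_kg = sc$dose_human_per_kg,
                        analyte = "total")

  thalf_of <- function(mc) {
    rate <- if (mc$B > 0) mc$beta else mc$alpha
    log(2) / rate
  }
  truth <- list(
    animal = c(par_animal,
               list(vss = par_animal$v1 + par_animal$v2,
                    thalf_terminal = thalf_of(mc_animal),
                    macro = mc_animal)),
    human = c(par_human,
              list(vss = par_human$v1 + par_human$v2,
                   thalf_terminal = thalf_of(mc_human),
                   macro = mc_human)),
    weight_ratio = r)
  list(animal = animal, human = human, truth = truth)
}
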