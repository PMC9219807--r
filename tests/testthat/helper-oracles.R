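`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent oracles used across the suite. These never call the code
# paths they check.

# Fixed-step RK4 integration of the two-compartment IV-bolus system
#   dA1/dt = -(k10 + k12) A1 + k21 A2,  dA2/dt = k12 A1 - k21 A2
# returning central concentration A1/V1 at the requested times.
ode_two_cpt <- function(cl, v1, q, v2, dose, times, dt = 1e-3) {
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  deriv <- function(a) c(-(k10 + k12) * a[1] + k21 * a[2],
                         k12 * a[1] - k21 * a[2])
  t_end <- max(times)
  n_steps <- ceiling(t_end / dt)
  grid <- seq(0, by = dt, length.out = n_steps + 1L)
  a <- c(dose, 0)
  out <- matrix(NA_real_, n_steps + 1L, 2L)
  out[1L, ] <- a
  for (i in seq_len(n_steps)) {
    k1 <- deriv(a)
    k2 <- deriv(a + dt / 2 * k1)
    k3 <- deriv(a + dt / 2 * k2)
    k4 <- deriv(a + dt * k3)
    a <- a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- a
  }
  # linear interpolation of the fine grid at the requested times
  stats::approx(grid, out[, 1L], xout = times)$y / v1
}

# Naive power evaluation of the projection factor (the implementation
# works in log space).
naive_factor <- function(d_a, d_h, w_a, w_h, b, d_exp = 1) {
  (d_h / d_a)^d_exp * (w_a / w_h)^b
}

# A valid random profile for round-trip and property tests.
random_profile <- function(n = 8L, species = "monkey") {
  time <- sort(round(stats::runif(n, 0.1, 60), 3))
  while (anyDuplicated(time)) time <- sort(round(stats::runif(n, 0.1, 60), 3))
  conc <- exp(stats::rnorm(n, log(10), 1))
  conc_profile(time, conc, species = species,
               dose_per_kg = round(stats::runif(1, 0.5, 30), 2),
               analyte = sample(c("total", "conjugated"), 1L))
}

# Mono-exponential profile with exact parameters.
mono_profile <- function(dose = 10, v = 0.1, k = 0.1,
                         times = seq(0, 60, by = 0.5),
                         species = "human", weight = 70) {
  conc_profile(times, (dose / v) * exp(-k * times), species = species,
               body_weight = weight, dose_total = dose)
}
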