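test_that("macro constants satisfy the Vieta and initial-value identities", {
  set.seed(21)
  for (i in 1:50) {
    cl <- exp(runif(1, -4, 1)); v1 <- exp(runif(1, -3, 2))
    q <- exp(runif(1, -4, 1)); v2 <- exp(runif(1, -3, 2))
    dose <- exp(runif(1, 0, 6))
    mc <- macro_constants(cl, v1, q, v2, dose)
    k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
    expect_gt(mc$alpha, mc$beta)
    expect_gt(mc$beta, 0)
    expect_equal(mc$alpha + mc$beta, k10 + k12 + k21, tolerance = 1e-10)
    expect_equal(mc$alpha * mc$beta, k10 * k21, tolerance = 1e-10)
    expect_equal(mc$A + mc$B, dose / v1, tolerance = 1e-9)
  }
})

test_that("q = 0 degenerates to the one-compartment limit", {
  mc <- macro_constants(cl = 0.01, v1 = 0.1, q = 0, v2 = 1, dose_total = 10)
  expect_equal(mc$A, 100)
  expect_equal(mc$B, 0)
  expect_equal(mc$alpha, 0.1)
})

test_that("the closed form matches an RK4 ODE integration oracle", {
  cl <- 0.4; v1 <- 3; q <- 0.6; v2 <- 2; dose <- 350
  times <- seq(0.5, 40, length.out = 20)
  mc <- macro_constants(cl, v1, q, v2, dose)
  closed <- mc$A * exp(-mc$alpha * times) + mc$B * exp(-mc$beta * times)
  ode <- ode_two_cpt(cl, v1, q, v2, dose, times)
  expect_equal(closed, ode, tolerance = 1e-6)
})

test_that("simulate_pair scales parameters allometrically and is seeded", {
  sc <- sim_scenario(e_cl = 0.85, e_v = 0.9, noise_cv = 0.25, seed = 42L)
  sim <- simulate_pair(sc)
  r <- 70 / 3.5
  expect_equal(sim$truth$human$cl, sc$cl_ref * r^0.85)
  expect_equal(sim$truth$human$v1, sc$v1_ref * r^0.9)
  expect_equal(sim$truth$human$q, sc$q_ref * r^0.85)
  expect_equal(sim$truth$human$v2, sc$v2_ref * r^0.9)
  # determinism: same seed, bit-identical output
  sim2 <- simulate_pair(sc)
  expect_identical(sim$animal$conc, sim2$animal$conc)
  expect_identical(sim$human$conc, sim2$human$conc)
  # different seed, different noise
  sim3 <- simulate_pair(sim_scenario(noise_cv = 0.25, seed = 43L))
  expect_false(identical(sim$animal$conc, sim3$animal$conc))
  # noise does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_pair(sc)); after <- runif(1)
  expect_identical(before, after)
})

test_that("LLOQ censoring drops points and can empty a profile", {
  sc <- sim_scenario(noise_cv = 0, lloq = 0.5)
  sim <- simulate_pair(sc)
  expect_true(all(sim$animal$conc >= 0.5))
  expect_lt(length(sim$animal), length(sc$sampling_times))
  expect_error(simulate_pair(sim_scenario(noise_cv = 0, lloq = 1e6)),
               "censored")
})

test_that("matching exponent reproduces the human profile exactly", {
  # when e_cl == e_v == b the rate constants are weight-invariant and the
  # total-dose factor with exponent b superimposes the curves
  for (b in c(0.8, 0.9, 1.0)) {
    sc <- sim_scenario(e_cl = b, e_v = b, noise_cv = 0,
                       dose_animal_per_kg = 1, dose_human_per_kg = 5)
    sim <- simulate_pair(sc)
    m <- scaling_method(b)
    pred <- predict_profile(sim$animal, sc$dose_human_per_kg, 70, m)
    rep <- evaluate_profiles(pred, sim$human)
    expect_equal(rep$afe, 1.0, tolerance = 1e-9)
    expect_equal(pred$conc, sim$human$conc, tolerance = 1e-9)
  }
})

test_that("non-matching exponents miss in the direction b-monotonicity predicts", {
  sc <- sim_scenario(e_cl = 0.9, e_v = 0.9, noise_cv = 0)
  sim <- simulate_pair(sc)
  afe_of <- function(b) {
    pred <- predict_profile(sim$animal, sc$dose_human_per_kg, 70,
                            scaling_method(b))
    evaluate_profiles(pred, sim$human)$afe
  }
  expect_lt(afe_of(1.0), 1)  # larger b underpredicts (W_a < W_h)
  expect_gt(afe_of(0.8), 1)  # smaller b overpredicts
})

test_that("NCA on noiseless simulations recovers the truth record", {
  # grid from 0 covering > 5 terminal half-lives in both species
  sc <- sim_scenario(e_cl = 0.85, e_v = 1.0, noise_cv = 0,
                     sampling_times = c(0, 0.25, 0.5, 1, 2, 3, 5, 7, 10,
                                        14, 21, 28, 35, 42, 56, 70, 84))
  sim <- simulate_pair(sc)
  for (side in c("animal", "human")) {
    res <- nca_summary(sim[[side]])
    truth <- sim$truth[[side]]
    expect_lt(abs(res$clearance - truth$cl) / truth$cl, 0.02)
    expect_lt(abs(res$thalf - truth$thalf_terminal) / truth$thalf_terminal,
              0.02)
  }
})

test_that("fixed-exponent PK scaling closes the loop at (0.85, 1.0)", {
  sc <- sim_scenario(e_cl = 0.85, e_v = 1.0, noise_cv = 0,
                     sampling_times = c(0, 0.25, 0.5, 1, 2, 3, 5, 7, 10,
                                        14, 21, 28, 35, 42, 56, 70, 84))
  sim <- simulate_pair(sc)
  nca_a <- nca_summary(sim$animal)
  nca_h <- nca_summary(sim$human)
  expect_lt(abs(predict_human_clearance(nca_a$clearance, sc$ref_weight) -
                  nca_h$clearance) / nca_h$clearance, 0.05)
  expect_lt(abs(predict_human_half_life(nca_a$thalf, sc$ref_weight) -
                  nca_h$thalf) / nca_h$thalf, 0.05)
})

test_that("scenario validation rejects impossible worlds", {
  expect_error(sim_scenario(e_v = 1.6), "exponents")
  expect_error(sim_scenario(sampling_times = c(3, 1, 2)), "increasing")
  expect_error(sim_scenario(cl_ref = -1))
})
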