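test_that("presets encode the eight methods", {
  expect_equal(method_ids(), c("I", "II", "III", "IV", "V", "VI",
                               "VII", "VIII"))
  spec <- list(
    I    = c(1.0, NA,  1.0,  NA), II  = c(0.9, NA,  1.0,  NA),
    III  = c(0.8, NA,  1.0,  NA), IV  = c(1.0, NA,  0.85, NA),
    V    = c(0.9, NA,  0.85, NA), VI  = c(0.8, NA,  0.85, NA),
    VII  = c(1.0, 0.8, 1.0,  14), VIII = c(0.9, 0.8, 1.0,  14))
  for (id in names(spec)) {
    m <- method_preset(id)
    expect_equal(m$volume_exponent_early, spec[[id]][1], info = id)
    expect_equal(m$volume_exponent_late %||% NA_real_, spec[[id]][2],
                 info = id)
    expect_equal(m$dose_exponent, spec[[id]][3], info = id)
    expect_equal(m$switch_time %||% NA_real_, spec[[id]][4], info = id)
  }
  # mnemonics resolve to the same presets
  expect_equal(method_preset("v0.9+0.8")$method_id, "VIII")
  expect_equal(method_preset("cl0.85-v0.8")$method_id, "VI")
  expect_error(method_preset("IX"), "valid presets")
})

test_that("select_exponent switches at day 14 inclusively", {
  m8 <- method_preset("VIII")
  expect_equal(select_exponent(m8, 7), 0.9)
  expect_equal(select_exponent(m8, 13.999), 0.9)
  expect_equal(select_exponent(m8, 14), 0.8)
  expect_equal(select_exponent(m8, c(0, 14, 42)), c(0.9, 0.8, 0.8))
  expect_equal(select_exponent(method_preset("II"), c(1, 100)), c(0.9, 0.9))
})

test_that("scaling_factor matches hand-derived values", {
  args <- list(animal_dose_total = 3.5, human_dose_total = 350,
               animal_weight = 3.5, human_weight = 70, t = 1)
  expect_equal(do.call(scaling_factor, c(list(method_preset("I")), args)),
               5.0, tolerance = 1e-12)
  expect_equal(do.call(scaling_factor, c(list(method_preset("II")), args)),
               100 * 0.05^0.9, tolerance = 1e-12)   # 6.746414
  expect_equal(do.call(scaling_factor, c(list(method_preset("IV")), args)),
               100^0.85 * 0.05, tolerance = 1e-12)  # 2.505936
  # identity when doses and weights are equal
  expect_equal(scaling_factor(method_preset("V"), 2, 2, 70, 70, 5), 1.0)
  expect_error(scaling_factor(method_preset("I"), -1, 1, 1, 1, 0),
               "positive")
})

test_that("log-space factor agrees with naive powers on random inputs", {
  set.seed(7)
  for (i in 1:100) {
    d_a <- exp(runif(1, -3, 5)); d_h <- exp(runif(1, -3, 7))
    w_a <- exp(runif(1, -2, 2)); w_h <- exp(runif(1, 2, 5))
    b <- runif(1, 0.1, 1.5); de <- runif(1, 0.5, 1)
    m <- scaling_method(b, dose_exponent = de)
    expect_equal(scaling_factor(m, d_a, d_h, w_a, w_h, 1),
                 naive_factor(d_a, d_h, w_a, w_h, b, de),
                 tolerance = 1e-12)
  }
})

test_that("factor is strictly decreasing in b, so III >= II >= I pointwise", {
  mk <- conc_profile(c(1, 7, 14, 21), c(100, 50, 20, 10),
                     species = "monkey", dose_per_kg = 1)
  p1 <- predict_profile(mk, 5, 70, "I")
  p2 <- predict_profile(mk, 5, 70, "II")
  p3 <- predict_profile(mk, 5, 70, "III")
  expect_true(all(p3$conc > p2$conc))
  expect_true(all(p2$conc > p1$conc))
  # switching methods equal method III at and after the switch day
  p7 <- predict_profile(mk, 5, 70, "VII")
  late <- mk$time >= 14
  expect_equal(p7$conc[late], p3$conc[late])
  expect_equal(p7$conc[!late], p1$conc[!late])
})

test_that("predict_profile maps points and preserves the time grid", {
  mk <- conc_profile(c(7, 21), c(10, 10), species = "monkey",
                     dose_per_kg = 1)
  pred <- predict_profile(mk, human_dose_per_kg = 5, method = "I")
  expect_equal(pred$time, mk$time)
  expect_equal(pred$conc[1], 50.0, tolerance = 1e-12)
  expect_equal(pred$species, "human-predicted")
  expect_equal(pred$dose_total, 350)
  expect_s3_class(pred, "predicted_profile")
  expect_equal(attr(pred, "source_species"), "monkey")

  # method VIII at t = 21 uses the late exponent 0.8
  pred8 <- predict_profile(mk, 5, 70, "VIII")
  expect_equal(pred8$conc[2], 10 * 100 * 0.05^0.8, tolerance = 1e-12)

  # projecting onto the same species/dose is the identity
  self <- predict_profile(mk, human_dose_per_kg = 1, human_weight = 3.5,
                          method = "II")
  expect_equal(self$conc, mk$conc)
})

test_that("prediction commutes with concatenation and preserves count", {
  set.seed(11)
  p <- random_profile(n = 10L)
  m <- method_preset("VII")
  whole <- predict_profile(p, 5, 70, m)
  head_p <- conc_profile(p$time[1:4], p$conc[1:4], species = p$species,
                         dose_per_kg = p$dose_per_kg)
  tail_p <- conc_profile(p$time[5:10], p$conc[5:10], species = p$species,
                         dose_per_kg = p$dose_per_kg)
  expect_length(whole, 10L)
  expect_equal(c(predict_profile(head_p, 5, 70, m)$conc,
                 predict_profile(tail_p, 5, 70, m)$conc),
               whole$conc)
})

test_that("spec constructor rejects inconsistent switch definitions", {
  expect_error(scaling_method(0.9, volume_exponent_late = 0.8),
               "together")
  expect_error(scaling_method(0.9, switch_time = 14), "together")
  expect_error(scaling_method(0), "0, 1.5")
  expect_error(scaling_method(1.6), "0, 1.5")
})
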