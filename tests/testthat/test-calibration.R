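# Calibration of muscle-tendon parameters against inverse-dynamics moments.

# Build a processed-trial stub whose m_id is produced by the model itself,
# so a perfect model has exactly zero objective.
model_consistent_ptrial <- function(model, li_level, u_ext, u_flex = 0.05,
                                    n = 101) {
  theta <- seq(0.15, 1.3, length.out = n)
  theta <- c(theta, rev(theta))
  n2 <- length(theta)
  exc <- cbind(longissimus_l = rep(u_ext, n2), longissimus_r = rep(u_ext, n2),
               iliocostalis_l = rep(0.8 * u_ext, n2),
               iliocostalis_r = rep(0.8 * u_ext, n2),
               rectus_abdominis_l = rep(u_flex, n2),
               rectus_abdominis_r = rep(u_flex, n2))
  est <- emg_driven_moment(model, exc, theta)
  structure(list(subject_id = "T", li_level = li_level, repetition = 1,
                 excitations = exc, theta = theta,
                 theta_dot = rep(0, n2), theta_ddot = rep(0, n2),
                 load_force = rep(0, n2), m_id = est$moment,
                 rom = diff(range(theta))),
            class = "processed_trial")
}

test_that("objective is zero iff moments match, with closed-form offsets", {
  model <- trunk_model(subject(75))
  p1 <- model_consistent_ptrial(model, 1, u_ext = 0.3)
  p3 <- model_consistent_ptrial(model, 3, u_ext = 0.6)
  expect_equal(calibration_objective(model, list(p1, p3)), 0)

  # constant offset delta on m_id of peak P gives objective delta / P
  delta <- 5
  p_off <- p1
  p_off$m_id <- p_off$m_id - delta
  P <- max(abs(p_off$m_id))
  expect_equal(calibration_objective(model, list(p_off)), delta / P,
               tolerance = 1e-9)

  # invariant to trial ordering
  expect_equal(calibration_objective(model, list(p1, p3)),
               calibration_objective(model, list(p3, p1)))

  p_flat <- p1
  p_flat$m_id <- rep(0, length(p_flat$m_id))
  expect_error(calibration_objective(model, list(p_flat)), "degenerate")
})

test_that("zero iteration budget returns the initial parameters", {
  model <- trunk_model(subject(75))
  ptr <- list(model_consistent_ptrial(model, 1, 0.3),
              model_consistent_ptrial(model, 3, 0.6))
  res <- calibrate(model, ptr, calibration_config(maxit = 0))
  expect_false(res$converged)
  expect_equal(res$iterations, 0)
  expect_equal(res$objective, res$initial_objective)
  expect_true(all(res$params$value == c(1, 1, 1, -1.5, -1.5, -1.5, 1)))
})

test_that("calibration requires trials from each calibration level", {
  model <- trunk_model(subject(75))
  only1 <- list(model_consistent_ptrial(model, 1, 0.3))
  expect_error(calibrate(model, only1, calibration_config()), "level 3")
})

test_that("same seed gives identical results; params stay in bounds", {
  truth <- trunk_model(subject(75))
  for (side in c("_l", "_r"))
    truth$groups[[paste0("longissimus", side)]]$params$f_max <- 5000 * 1.2
  ptr <- list(model_consistent_ptrial(truth, 1, 0.25),
              model_consistent_ptrial(truth, 3, 0.55))
  start <- trunk_model(subject(75))
  cfg <- calibration_config(adjustable = "f_max", restarts = 3, seed = 99,
                            maxit = 40)
  r1 <- calibrate(start, ptr, cfg)
  r2 <- calibrate(start, ptr, cfg)
  expect_identical(r1$params$value, r2$params$value)
  expect_identical(r1$objective, r2$objective)
  expect_true(all(r1$params$value >= r1$params$lower - 1e-12))
  expect_true(all(r1$params$value <= r1$params$upper + 1e-12))
  expect_lte(r1$objective, r1$initial_objective)
})

test_that("noiseless force scales are recovered and truth is optimal", {
  # trials generated by a known-truth model; objective at the truth is zero,
  # so no optimized start may do better (up to optimizer tolerance), and the
  # recovered force scales must land on the truth
  truth <- trunk_model(subject(78))
  true_scales <- c(longissimus = 1.25, iliocostalis = 0.9,
                   rectus_abdominis = 1.1)
  for (b in names(true_scales))
    for (side in c("_l", "_r")) {
      g <- paste0(b, side)
      truth$groups[[g]]$params$f_max <-
        truth$groups[[g]]$params$f_max * true_scales[[b]]
    }
  ptr <- list(model_consistent_ptrial(truth, 1, 0.25, u_flex = 0.08),
              model_consistent_ptrial(truth, 2, 0.4, u_flex = 0.11),
              model_consistent_ptrial(truth, 3, 0.55, u_flex = 0.14))
  res <- calibrate(trunk_model(subject(78)), ptr[c(1, 3)],
                   calibration_config(adjustable = "f_max", restarts = 3,
                                      seed = 5, maxit = 80))
  # the truth attains exactly zero, so no optimized start may beat it
  expect_equal(calibration_objective(truth, ptr[c(1, 3)]), 0)
  expect_gte(res$objective, -1e-6)
  # and the optimizer gets within a fraction of a percent of it
  expect_lte(res$objective, 0.005)
  got <- setNames(res$params$value, res$params$group)
  for (b in names(true_scales))
    expect_equal(unname(got[b]), unname(true_scales[[b]]), tolerance = 0.1)

  # held-out middle-risk trial generalizes
  val <- validate_calibration(res, ptr[2])
  expect_equal(nrow(val), 1)
  expect_lt(val$normalized, 0.10)

  # validating on a calibration trial reproduces its calibration-time RMSE
  val13 <- validate_calibration(res, ptr[c(1, 3)])
  expect_equal(val13$normalized, res$trial_rmse$normalized)
  expect_equal(validate_calibration(res, list())$normalized, numeric(0))
})

test_that("recovery also holds through the full synthetic pipeline", {
  ds <- clean_dataset(seed = 7)
  ptr <- process_all(ds)
  res <- calibrate(trunk_model(ds$subjects[[1]]), ptr,
                   calibration_config(adjustable = "f_max", restarts = 3,
                                      seed = 11, maxit = 60))
  got <- setNames(res$params$value, res$params$group)
  truth <- ds$true_params[[1]]$f_max
  for (b in names(truth))
    expect_equal(unname(got[b]), unname(truth[[b]]), tolerance = 0.1)
  held_out <- Filter(function(p) p$li_level == 2, ptr)
  val <- validate_calibration(res, held_out)
  expect_equal(nrow(val), length(held_out))
  expect_true(all(val$normalized <= 0.10))
  # calibrating on levels 1 and 3 generalizes: held-out error within twice
  # the calibration error (plus interpolation slack)
  expect_lt(mean(val$normalized), 2 * max(mean(res$trial_rmse$normalized),
                                          0.01))
})
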