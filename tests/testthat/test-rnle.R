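# Revised NIOSH Lifting Equation: multipliers, RWL, LI, inverse design.

test_that("neutral task gives unit multipliers and the 23 kg load constant", {
  res <- rnle_assess(neutral_task())
  expect_equal(res$LC, 23)
  for (m in c("HM", "VM", "DM", "AM", "FM", "CM")) expect_equal(res[[m]], 1)
  expect_equal(res$RWL, 23)
  expect_equal(res$LI, 1)
  expect_identical(res$risk_level, "low")
})

test_that("individual multiplier formulas match their closed forms", {
  expect_equal(rnle_multipliers(lifting_task(10, 50, 75, 25))$HM, 0.5)
  expect_equal(rnle_rwl(lifting_task(10, 50, 75, 25))$RWL, 11.5)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 100, 25))$VM,
               1 - 0.003 * 25)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 75, 100))$DM,
               0.82 + 4.5 / 100)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 75, 25, A = 45))$AM,
               1 - 0.0032 * 45)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 75, 25, A = 0))$AM, 1)
  # frequency and coupling lookups
  expect_equal(rnle_multipliers(lifting_task(10, 25, 50, 25, F = 9,
                                             duration_class = "8h"))$FM, 0)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 80, 25, F = 9,
                                             duration_class = "8h"))$FM,
               0.15)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 50, 25,
                                             coupling = "fair"))$CM, 0.95)
  expect_equal(rnle_multipliers(lifting_task(10, 25, 100, 25,
                                             coupling = "fair"))$CM, 1)
  # intermediate frequency uses the next-higher tabulated row
  expect_equal(rnle_multipliers(lifting_task(10, 25, 75, 25, F = 1.5))$FM,
               0.91)
})

test_that("out-of-range variables clamp or zero multipliers with flags", {
  low_h <- rnle_multipliers(lifting_task(10, 10, 75, 25))
  expect_equal(low_h$HM, 1)
  expect_true("H_clamped_low" %in% low_h$flags)
  far <- rnle_rwl(lifting_task(10, 80, 75, 25))
  expect_equal(far$HM, 0)
  expect_equal(far$RWL, 0)
  expect_true(all(c("H_out_of_range", "LI_undefined") %in% far$flags))
  expect_error(rnle_assess(lifting_task(10, 80, 75, 25)), "degenerate")
  expect_equal(rnle_multipliers(lifting_task(10, 25, 200, 25))$VM, 0)
  expect_error(lifting_task(10, Inf, 75, 25), "finite")
  expect_error(lifting_task(-1, 25, 75, 25), "load_mass")
})

test_that("lifting index and risk bands follow the LI ratio", {
  task <- lifting_task(21, 40, 50, 60)
  res <- rnle_assess(task)
  expect_equal(res$LI, 21 / res$RWL)
  task2 <- task; task2$load_mass <- 2 * res$RWL
  expect_equal(rnle_assess(task2)$LI, 2)
  expect_identical(rnle_risk_band(1), "low")
  expect_identical(rnle_risk_band(1.5), "medium")
  expect_identical(rnle_risk_band(2.5), "high")
  expect_identical(rnle_risk_band(3.5), "very_high")
})

test_that("RWL is bounded by 23 kg and monotone in H, |V-75| and A", {
  # property sweep over a grid of admissible tasks
  grid <- expand.grid(H = c(25, 30, 40, 55, 63), V = c(0, 30, 75, 120, 175),
                      D = c(25, 60, 175), A = c(0, 45, 135))
  rwl <- apply(grid, 1, function(g)
    rnle_rwl(lifting_task(10, g["H"], g["V"], g["D"], g["A"]))$RWL)
  expect_true(all(rwl <= 23 + 1e-12))
  expect_true(all(rwl >= 0))

  rwl_h <- vapply(seq(25, 63, by = 2), function(h)
    rnle_rwl(lifting_task(10, h, 75, 25))$RWL, numeric(1))
  expect_true(all(diff(rwl_h) <= 1e-12))
  rwl_v <- vapply(seq(75, 175, by = 10), function(v)
    rnle_rwl(lifting_task(10, 25, v, 25))$RWL, numeric(1))
  expect_true(all(diff(rwl_v) <= 1e-12))
  rwl_vd <- vapply(seq(75, 0, by = -15), function(v)
    rnle_rwl(lifting_task(10, 25, v, 25))$RWL, numeric(1))
  expect_true(all(diff(rwl_vd) <= 1e-12))
  rwl_a <- vapply(seq(0, 135, by = 15), function(a)
    rnle_rwl(lifting_task(10, 25, 75, 25, A = a))$RWL, numeric(1))
  expect_true(all(diff(rwl_a) <= 1e-12))
})

test_that("inverse task design reaches the target LI within 1 percent", {
  # the three study conditions
  t1 <- design_task_for_li(1, 21)
  expect_equal(rnle_assess(t1)$RWL, 21, tolerance = 0.01)
  t3 <- design_task_for_li(3, 20)
  expect_equal(rnle_assess(t3)$RWL, 20 / 3, tolerance = 0.01)

  # feasible round trips across the LI x load grid; infeasible targets must
  # raise the infeasible-design error (RWL cannot exceed 23 kg nor drop
  # below the multiplier floor)
  floor_prod <- (25 / 63) * (1 - 0.003 * 75) * (0.82 + 4.5 / 175)
  for (x in c(0.5, 1, 2, 3)) {
    for (m in seq(5, 23, by = 3)) {
      feasible <- (m / x) <= 23 && (m / x) >= 23 * floor_prod
      if (feasible) {
        task <- design_task_for_li(x, m)
        expect_equal(rnle_assess(task)$LI, x, tolerance = 0.01)
      } else {
        expect_error(design_task_for_li(x, m), "infeasible")
      }
    }
  }
})

test_that("inverse design keeps AM, FM, CM fixed and is a fixed point", {
  tmpl <- lifting_task(15, 30, 60, 40, A = 20, F = 2, coupling = "fair")
  designed <- design_task_for_li(2, 15, free = c("H", "V", "D"),
                                 template = tmpl)
  m0 <- rnle_multipliers(tmpl)
  m1 <- rnle_multipliers(designed)
  expect_equal(m1$AM, m0$AM)
  expect_equal(m1$FM, m0$FM)
  expect_equal(m1$CM, m0$CM)
  # requesting the template's own LI returns it unchanged
  li0 <- rnle_assess(tmpl)$LI
  expect_identical(design_task_for_li(li0, 15, template = tmpl), tmpl)
})
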