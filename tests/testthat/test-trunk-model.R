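# Planar trunk model: inverse dynamics, Hill curves, geometry, joint loads.

test_that("static stoop moment matches hand statics", {
  s <- stoop_subject()
  ang <- lift_ts(rep(pi / 2, 400), 340)
  load <- lift_ts(rep(20 * 9.81, 400), 340)
  M <- ts_channel(inverse_dynamics_moment(ang, s, load))[200]
  expect_equal(M, 35 * 9.81 * 0.25 + 20 * 9.81 * 0.45, tolerance = 1e-9)
  expect_equal(M, 174.1, tolerance = 1e-3)

  # upright static, zero load: zero lever under the sin(theta) convention
  M0 <- ts_channel(inverse_dynamics_moment(lift_ts(rep(0, 400), 340), s))
  expect_equal(max(abs(M0)), 0, tolerance = 1e-9)

  # doubling the load adds exactly the load term again
  load2 <- lift_ts(rep(40 * 9.81, 400), 340)
  M2 <- ts_channel(inverse_dynamics_moment(ang, s, load2))[200]
  expect_equal(M2 - M, 20 * 9.81 * 0.45, tolerance = 1e-9)

  expect_error(inverse_dynamics_moment(ang, s, lift_ts(rep(1, 100), 340)),
               "alignment")
})

test_that("moment arm is consistent with the length derivative", {
  # signed identity: s * r(theta) = dl/dtheta, checked against finite
  # differences for every default group across the angle range
  thetas <- seq(-0.19, 1.59, length.out = 200)
  h <- 1e-6
  for (g in default_mtu_groups()) {
    geo <- mtu_geometry(thetas, g)
    dl <- (mtu_geometry(thetas + h, g)$l_mt -
             mtu_geometry(thetas - h, g)$l_mt) / (2 * h)
    expect_lt(max(abs(g$sign * geo$r - dl)), 1e-4)
  }
})

test_that("constant moment arm integrates to a linear length", {
  g <- mtu_group("toy", "ch", "extensor", 1L, mtu_params(100, 0.2, 0.1),
                 moment_arm_coeffs = 0.04, l_ref = 0.5)
  geo <- mtu_geometry(c(0, 0.5, 1), g)
  expect_equal(geo$l_mt, 0.5 + 0.04 * c(0, 0.5, 1))
  expect_equal(mtu_geometry(0, g)$l_mt, 0.5)  # reference posture
  gf <- mtu_group("toyf", "ch", "flexor", 1L, mtu_params(100, 0.2, 0.1),
                  moment_arm_coeffs = 0.04, l_ref = 0.5)
  expect_equal(mtu_geometry(1, gf)$l_mt, 0.5 - 0.04)
  expect_warning(mtu_geometry(2, g), "range")
})

test_that("activation nonlinearity anchors, limits and shape value", {
  expect_equal(activation(0, -2), 0)
  expect_equal(activation(1, -2), 1)
  expect_equal(activation(0.5, 0), 0.5)  # linear limit
  u <- seq(0, 1, by = 0.05)
  expect_equal(activation(u, -1e-9), u, tolerance = 1e-6)
  expect_equal(activation(0.5, -3), (exp(-1.5) - 1) / (exp(-3) - 1))
  expect_equal(activation(0.5, -3), 0.818, tolerance = 1e-3)
  expect_true(all(diff(activation(u, -2.5)) > 0))
  expect_equal(activation(c(-1, 2), -2), c(0, 1))  # clipping
})

test_that("Hill force reproduces its curve anchors", {
  p <- mtu_params(f_max = 1200, l_opt = 0.2, l_ts = 0.1)
  # optimal isometric
  expect_equal(mtu_force(1, l_mt = 0.3, v_mt = 0, p), 1200)
  # passive-free below optimal at zero activation
  expect_equal(mtu_force(0, l_mt = 0.28, v_mt = 0, p), 0)
  # stretched isometric: Gaussian active + exponential passive
  l_norm <- 1.2
  expected <- 1200 * (exp(-((l_norm - 1) / 0.45)^2) +
                        (exp(10 * 0.2) - 1) / (exp(5) - 1))
  expect_equal(mtu_force(1, l_mt = 0.1 + 0.24, v_mt = 0, p), expected)
  expect_error(mtu_force(1, l_mt = 0.05, v_mt = 0, p), "slack")
  # force-velocity: concentric reduces, eccentric amplifies toward 1.4
  f_con <- mtu_force(1, 0.3, v_mt = -0.5, p)
  f_ecc <- mtu_force(1, 0.3, v_mt = 0.5, p)
  expect_lt(f_con, 1200)
  expect_gt(f_ecc, 1200)
  expect_lt(f_ecc, 1.4 * 1200)
})

test_that("EMG-driven moment sums signed moment-arm-weighted forces", {
  m <- toy_pair_model()
  n <- 10
  theta <- rep(0, n)
  exc <- cbind(ext_ch = rep(0.5, n), flx_ch = rep(0, n))
  out <- emg_driven_moment(m, exc, theta)
  a <- activation(0.5, -1.5)
  f <- mtu_force(a, 0.3, 0, m$groups$ext$params)
  expect_equal(out$moment, rep(0.05 * f, n))
  # zero excitation, slack-free below-optimal fibres: zero moment
  out0 <- emg_driven_moment(m, cbind(ext_ch = rep(0, n), flx_ch = rep(0, n)),
                            theta)
  expect_equal(out0$moment, rep(0, n))
  # equal antagonist excitation cancels the net moment entirely here
  outc <- emg_driven_moment(m, cbind(ext_ch = rep(0.5, n),
                                     flx_ch = rep(0.5, n)), theta)
  expect_equal(outc$moment, rep(0, n), tolerance = 1e-9)
  expect_error(emg_driven_moment(m, cbind(ext_ch = rep(0.5, n)), theta),
               "mapping")
})

test_that("joint reaction balances the static free body", {
  m <- trunk_model(subject(75), groups = list())
  # upright static, no muscle: compression = supported weight, no shear
  jr <- joint_reaction(m, theta = 0, load_force = 20 * 9.81)
  s <- m$subject
  w_above <- (s$trunk_mass + s$armhead_mass) * 9.81 + 20 * 9.81
  expect_equal(jr$compression, w_above, tolerance = 1e-9)
  expect_equal(jr$shear, 0, tolerance = 1e-9)
  # force balance: intersegmental force equals minus the sum of gravity and
  # load on the free body (static, so segment accelerations vanish)
  expect_lt(abs(jr$inter_z - w_above), 1e-6)
  expect_lt(abs(jr$inter_x), 1e-6)
  # flexed static: axial and shear components split by the trunk tilt
  th <- 0.7
  jr2 <- joint_reaction(m, theta = th, load_force = 0)
  w <- (s$trunk_mass + s$armhead_mass) * 9.81
  expect_equal(jr2$compression, w * cos(th), tolerance = 1e-9)
  expect_equal(jr2$shear, w * sin(th), tolerance = 1e-9)
  # zero gravity, zero motion, zero muscle: zero loads
  mg0 <- trunk_model(subject(75), groups = list(), gravity = 0)
  jr0 <- joint_reaction(mg0, theta = 0.3)
  expect_equal(jr0$compression, 0)
  expect_equal(jr0$shear, 0)
})

test_that("muscle forces along the trunk axis add directly to compression", {
  m <- toy_pair_model()
  forces <- matrix(c(400, 400), 1, 2, dimnames = list(NULL, c("ext", "flx")))
  jr_no <- joint_reaction(m, theta = 0.2)
  jr_with <- joint_reaction(m, theta = 0.2, muscle_forces = forces)
  expect_equal(jr_with$compression - jr_no$compression, 800)
  expect_equal(jr_with$shear, jr_no$shear)
})

test_that("co-activation raises compression at constant net moment", {
  m <- toy_pair_model()
  M0 <- 50  # target extension moment, N m
  r <- 0.05
  comp <- vapply(seq(0, 600, by = 100), function(f_flex) {
    f_ext <- (M0 + r * f_flex) / r
    forces <- matrix(c(f_ext, f_flex), 1, 2,
                     dimnames = list(NULL, c("ext", "flx")))
    moment <- r * f_ext - r * f_flex
    expect_equal(moment, M0, tolerance = 1e-9)
    joint_reaction(m, theta = 0.5, muscle_forces = forces)$compression
  }, numeric(1))
  expect_true(all(diff(comp) > 0))
})

test_that("channel-to-MTU mapping metadata totals 238 units in 11 rows", {
  tab <- mtu_mapping_table()
  expect_equal(nrow(tab), 11)
  expect_equal(sum(tab$n_units), 238)
  groups <- default_mtu_groups()
  expect_equal(sum(vapply(groups, `[[`, integer(1), "n_units")), 238)
  # lumped group counts agree with the mapping rows they carry
  by_group <- tapply(tab$n_units, tab$group, sum)
  expect_equal(unname(by_group[["passive"]]), groups$passive$n_units)
  expect_equal(unname(by_group[["longissimus"]]),
               groups$longissimus_l$n_units + groups$longissimus_r$n_units)
})

test_that("load normalization and exceedance flagging", {
  s <- subject(80)
  loads <- joint_load_series(t = 0:2 / 2, moment = c(100, 174.1, 120),
                             compression = c(3000, 6600, 800),
                             shear = c(100, 300, -50))
  n <- normalize_loads(loads, s)
  expect_equal(n$moment_norm, n$moment / 80)
  expect_equal(n$moment_norm[2], 174.1 / 80, tolerance = 1e-9)
  expect_equal(n$compression_bw, n$compression / (80 * 9.81))
  const_high <- joint_load_series(0:9, rep(100, 10), rep(6600, 10),
                                  rep(0, 10))
  expect_equal(flag_exceedance(const_high)$fraction, 1)
  const_low <- joint_load_series(0:9, rep(100, 10), rep(1000, 10),
                                 rep(0, 10))
  expect_equal(flag_exceedance(const_low)$fraction, 0)
  expect_equal(flag_exceedance(const_low, limit = 500)$fraction, 1)
  # a compression equal to body weight normalizes to exactly 1 BW
  one_bw <- joint_load_series(0, 0, s$body_weight, 0)
  expect_equal(normalize_loads(one_bw, s)$compression_bw, 1)
})
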