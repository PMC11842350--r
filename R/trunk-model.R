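# Planar lumbosacral trunk model.
#
# Two rigid bodies (pelvis fixed, trunk + arms/head rotating about L5-S1 in
# the sagittal plane) plus a hand-held load. Six lumped active Hill-type
# muscle-tendon groups (bilateral longissimus, iliocostalis, rectus
# abdominis) and one lumped passive group actuate the joint. The model
# supports inverse-dynamics moments, EMG-driven moments, and L5-S1
# compression/shear via a planar free-body joint-reaction balance.
#
# Conventions: theta is lumbosacral flexion, radians, positive forward;
# moments are extension-positive; compression acts along the trunk
# longitudinal axis; shear is anteroposterior, positive when the upper body
# tends to slide anteriorly on the sacrum.

GRAVITY <- 9.81

#' Subject anthropometry for the planar trunk model
#'
#' Segment parameters default to fixed anthropometric fractions of body mass
#' and stature (trunk 43 percent of mass with its centre of mass 45 percent
#' up the trunk; arms plus head lumped at 16 percent of mass) but every
#' derived quantity can be overridden, e.g. for worked static examples.
#'
#' @param body_mass Body mass, kg.
#' @param height Stature, m (default 1.75).
#' @param trunk_mass Trunk segment mass, kg.
#' @param trunk_length L5-S1 to shoulder distance, m.
#' @param trunk_com_distance Trunk centre of mass distance from L5-S1, m.
#' @param trunk_inertia Trunk moment of inertia about L5-S1, kg m^2.
#' @param armhead_mass Lumped arms + head mass, kg.
#' @param armhead_lever Its lever arm from L5-S1, m.
#' @param load_lever Hand (knuckle) distance from L5-S1, m.
#' @return A `subject` object; `body_weight` is `body_mass * 9.81`.
#' @examples
#' subject(75)
#' @export
subject <- function(body_mass, height = 1.75,
                    trunk_mass = 0.43 * body_mass,
                    trunk_length = 0.30 * height,
                    trunk_com_distance = 0.45 * trunk_length,
                    trunk_inertia = trunk_mass * (0.5 * trunk_length)^2,
                    armhead_mass = 0.16 * body_mass,
                    armhead_lever = 0.66 * trunk_length,
                    load_lever = 0.95 * trunk_length) {
  if (!is.finite(body_mass) || body_mass <= 0)
    stop("`body_mass` must be > 0", call. = FALSE)
  if (trunk_mass <= 0 || trunk_mass >= body_mass)
    stop("`trunk_mass` must be positive and below body mass", call. = FALSE)
  if (armhead_mass < 0) stop("`armhead_mass` must be >= 0", call. = FALSE)
  structure(list(body_mass = body_mass, height = height,
                 body_weight = body_mass * GRAVITY,
                 trunk_mass = trunk_mass, trunk_length = trunk_length,
                 trunk_com_distance = trunk_com_distance,
                 trunk_inertia = trunk_inertia,
                 armhead_mass = armhead_mass, armhead_lever = armhead_lever,
                 load_lever = load_lever),
            class = "subject")
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf(
    "<subject> %.1f kg, %.2f m | trunk %.1f kg @ %.3f m | arms+head %.1f kg @ %.3f m | hands %.3f m\n",
    x$body_mass, x$height, x$trunk_mass, x$trunk_com_distance,
    x$armhead_mass, x$armhead_lever, x$load_lever))
  invisible(x)
}

#' Hill-type muscle-tendon parameters
#'
#' @param f_max Maximal isometric force, N.
#' @param l_opt Optimal fibre length, m.
#' @param l_ts Tendon slack length, m (rigid tendon).
#' @param shape_A Activation nonlinearity shape factor in `[-3, 0]`
#'   (0 = linear limit).
#' @return An `mtu_params` object.
#' @export
mtu_params <- function(f_max, l_opt, l_ts, shape_A = -1.5) {
  if (any(c(f_max, l_opt, l_ts) <= 0))
    stop("f_max, l_opt and l_ts must be > 0", call. = FALSE)
  if (shape_A < -3 || shape_A > 0)
    stop("`shape_A` must lie in [-3, 0]", call. = FALSE)
  structure(list(f_max = f_max, l_opt = l_opt, l_ts = l_ts,
                 shape_A = shape_A), class = "mtu_params")
}

#' Lumped muscle-tendon group
#'
#' @param name Group name.
#' @param emg_channel Driving EMG channel name, or `"passive"`.
#' @param role `"extensor"` or `"flexor"`.
#' @param n_units Number of anatomical muscle-tendon units lumped into this
#'   group (metadata; see [mtu_mapping_table()]).
#' @param params An [mtu_params()].
#' @param moment_arm_coeffs Polynomial coefficients (ascending powers of the
#'   flexion angle in rad) of the moment-arm magnitude, m.
#' @param l_ref Muscle-tendon length at the upright reference posture, m.
#' @param constant_excitation Fixed excitation for groups without an EMG
#'   channel (the lumped passive group), or `NA`.
#' @return An `mtu_group` object.
#' @export
mtu_group <- function(name, emg_channel, role, n_units, params,
                      moment_arm_coeffs, l_ref,
                      constant_excitation = NA_real_) {
  role <- match.arg(role, c("extensor", "flexor"))
  if (n_units <= 0) stop("`n_units` must be > 0", call. = FALSE)
  structure(list(name = name, emg_channel = emg_channel, role = role,
                 n_units = as.integer(n_units), params = params,
                 moment_arm_coeffs = as.numeric(moment_arm_coeffs),
                 l_ref = l_ref, constant_excitation = constant_excitation,
                 sign = if (role == "extensor") 1 else -1),
            class = "mtu_group")
}

#' Mapping between sEMG channels and the anatomical muscle-tendon units
#'
#' Metadata reproducing the channel-to-MTU bookkeeping of the full-resolution
#' lifting model (238 units over 11 rows) that the lumped planar groups stand
#' in for. The `group` column names the lumped group each row feeds.
#'
#' @return A data.frame with columns `emg_channel`, `mtu_name`, `n_units`,
#'   `group`.
#' @export
mtu_mapping_table <- function() {
  data.frame(
    emg_channel = c(rep("erector_spinae_longissimus", 2),
                    rep("erector_spinae_iliocostalis", 2),
                    rep("rectus_abdominis", 3),
                    rep("passive", 4)),
    mtu_name = c("longissimus_thoracis_pars_lumborum",
                 "longissimus_thoracis_pars_thoracis",
                 "iliocostalis_lumborum_pars_lumborum",
                 "iliocostalis_lumborum_pars_thoracis",
                 "rectus_abdominis", "external_oblique", "internal_oblique",
                 "quadratus_lumborum", "psoas_major", "multifidus",
                 "latissimus_dorsi"),
    n_units = c(10L, 8L, 42L, 16L, 2L, 12L, 12L, 36L, 22L, 50L, 28L),
    group = c(rep("longissimus", 2), rep("iliocostalis", 2),
              rep("rectus_abdominis", 3), rep("passive", 4)),
    stringsAsFactors = FALSE
  )
}

#' Default lumped muscle-tendon groups of the planar trunk model
#'
#' Six bilateral active groups (longissimus, iliocostalis, rectus abdominis;
#' extensors/flexor) plus one lumped passive group carrying the unmeasured
#' muscles at a constant minimal excitation of 0.01. Unit counts per lumped
#' group follow [mtu_mapping_table()] and total 238.
#'
#' @return Named list of [mtu_group()] objects.
#' @export
default_mtu_groups <- function() {
  bilateral <- function(base, channel_base, role, n_units, params, coeffs,
                        l_ref) {
    sides <- c("l", "r")
    setNames(lapply(sides, function(s)
      mtu_group(paste0(base, "_", s), paste0(channel_base, "_", s), role,
                n_units, params, coeffs, l_ref)),
      paste0(base, "_", sides))
  }
  # extensor moment arms shrink with flexion (as erector spinae arms do),
  # so force per unit moment grows in deep flexion
  c(
    bilateral("longissimus", "longissimus", "extensor", 9L,
              mtu_params(5000, 0.25, 0.15), c(0.060, -0.008), 0.3875),
    bilateral("iliocostalis", "iliocostalis", "extensor", 29L,
              mtu_params(4500, 0.22, 0.12), c(0.055, -0.012), 0.318),
    bilateral("rectus_abdominis", "rectus_abdominis", "flexor", 13L,
              mtu_params(1500, 0.30, 0.10), c(0.075, 0.005), 0.40),
    list(passive = mtu_group("passive", "passive", "extensor", 136L,
                             mtu_params(2500, 0.20, 0.10), 0.05, 0.296,
                             constant_excitation = 0.01))
  )
}

#' Assemble a planar trunk model
#'
#' @param subj A [subject()].
#' @param groups List of [mtu_group()]s (default [default_mtu_groups()]).
#' @param gravity Gravitational acceleration, m/s^2.
#' @return A `trunk_model` object.
#' @export
trunk_model <- function(subj, groups = default_mtu_groups(),
                        gravity = GRAVITY) {
  if (!inherits(subj, "subject")) stop("`subj` must be a subject",
                                       call. = FALSE)
  structure(list(subject = subj, groups = groups, gravity = gravity),
            class = "trunk_model")
}

#' @export
print.trunk_model <- function(x, ...) {
  cat(sprintf("<trunk_model> subject %.1f kg, %d MTU groups (%d units), g = %g\n",
              x$subject$body_mass, length(x$groups),
              sum(vapply(x$groups, `[[`, integer(1), "n_units")), x$gravity))
  invisible(x)
}

polyval_asc <- function(coeffs, x) {
  out <- 0
  for (k in rev(seq_along(coeffs))) out <- out * x + coeffs[k]
  out
}

#' Muscle-tendon geometry at a lumbosacral angle
#'
#' Moment-arm magnitude from the group's polynomial and the consistent
#' muscle-tendon length `l_mt(theta) = l_ref + s * integral(r dtheta)` with
#' `s = +1` for extensors (which lengthen with flexion) and `-1` for flexors,
#' so the signed moment arm equals `dl/dtheta`.
#'
#' @param theta Flexion angle(s), rad. Values outside `[-0.2, 1.6]` trigger
#'   an extrapolation warning.
#' @param group An [mtu_group()].
#' @return List with `l_mt` and `r` (both m, vectorized over `theta`).
#' @export
mtu_geometry <- function(theta, group) {
  if (any(theta < -0.2 - 1e-9) || any(theta > 1.6 + 1e-9))
    warning("flexion angle outside the modelled range [-0.2, 1.6] rad; extrapolating")
  r <- polyval_asc(group$moment_arm_coeffs, theta)
  # antiderivative of the moment-arm polynomial, zero at theta = 0
  anti <- c(0, group$moment_arm_coeffs / seq_along(group$moment_arm_coeffs))
  l_mt <- group$l_ref + group$sign * polyval_asc(anti, theta)
  list(l_mt = l_mt, r = r)
}

#' Activation nonlinearity
#'
#' `a(u) = (exp(A u) - 1) / (exp(A) - 1)` with shape factor `A in [-3, 0]`;
#' `A = 0` is the linear limit. Excitation is clipped to `[0, 1]`.
#'
#' @param excitation Neural excitation, dimensionless.
#' @param shape_A Shape factor.
#' @return Activation in `[0, 1]`.
#' @examples
#' activation(0.5, -3)  # about 0.818
#' @export
activation <- function(excitation, shape_A) {
  u <- pmin(pmax(excitation, 0), 1)
  if (abs(shape_A) < 1e-8) return(u)
  (exp(shape_A * u) - 1) / (exp(shape_A) - 1)
}

force_length_active <- function(l_norm) exp(-((l_norm - 1) / 0.45)^2)

force_length_passive <- function(l_norm) {
  pmin((exp(10 * pmax(l_norm - 1, 0)) - 1) / (exp(5) - 1), 1)
}

force_velocity <- function(v_norm) {
  # concentric branch is 1 at v >= 0, eccentric branch is 1 at v <= 0,
  # so their product selects the right branch without branching
  vneg <- pmin(v_norm, 0)
  vpos <- pmax(v_norm, 0)
  pmax(0, (1 + vneg) / (1 - vneg / 0.25)) *
    (1 + 1.4 * vpos / 0.25) / (1 + vpos / 0.25)
}

#' Hill-type muscle-tendon force (rigid tendon)
#'
#' `F = f_max * (a * f_l(l) * f_v(v) + f_p(l))`, with a Gaussian active
#' force-length curve (width 0.45), a hyperbolic force-velocity curve
#' (eccentric plateau 1.4, maximal shortening velocity 10 optimal fibre
#' lengths per second) and an exponential passive curve (capped at 1).
#'
#' @param a Activation in `[0, 1]`.
#' @param l_mt Muscle-tendon length, m.
#' @param v_mt Muscle-tendon lengthening velocity, m/s (positive =
#'   lengthening).
#' @param params An [mtu_params()].
#' @return Force in N (vectorized).
#' @export
mtu_force <- function(a, l_mt, v_mt, params) {
  l_fib <- l_mt - params$l_ts
  if (any(l_fib <= 0))
    stop("slack configuration: fibre length <= 0", call. = FALSE)
  l_norm <- l_fib / params$l_opt
  v_norm <- v_mt / (10 * params$l_opt)
  f <- params$f_max * (a * force_length_active(l_norm) * force_velocity(v_norm) +
                         force_length_passive(l_norm))
  pmax(f, 0)
}

#' Inverse-dynamics sagittal lumbosacral moment
#'
#' `M(t) = I theta'' + (m_t d_t + m_ah d_ah) g sin(theta) + F_load d_load
#' sin(theta)` with angular derivatives by central differences on the
#' (pre-filtered) angle.
#'
#' @param angle `lift_ts` of lumbosacral flexion angle, rad (low-pass
#'   filtered by the caller).
#' @param subj A [subject()].
#' @param load_force `lift_ts` of the vertical hand force carried, N
#'   (downward positive, e.g. load mass times `g + box acceleration`), or
#'   `NULL` for no load.
#' @param gravity m/s^2.
#' @return `lift_ts` of extension-positive moment, N m.
#' @export
inverse_dynamics_moment <- function(angle, subj, load_force = NULL,
                                    gravity = GRAVITY) {
  stopifnot_ts(angle, "angle")
  theta <- ts_channel(angle)
  f_load <- if (is.null(load_force)) rep(0, length(theta)) else {
    stopifnot_ts(load_force, "load_force")
    if (n_samples(load_force) != length(theta) ||
        abs(load_force$fs - angle$fs) > 1e-9)
      stop("alignment error: load force and angle series differ",
           call. = FALSE)
    ts_channel(load_force)
  }
  theta_dd <- ts_channel(ts_derivative(ts_derivative(angle)))
  M <- subj$trunk_inertia * theta_dd +
    (subj$trunk_mass * subj$trunk_com_distance +
       subj$armhead_mass * subj$armhead_lever) * gravity * sin(theta) +
    f_load * subj$load_lever * sin(theta)
  lift_ts(M, angle$fs, angle$t0, "moment")
}

resolve_excitation <- function(group, excitations, n) {
  if (!is.na(group$constant_excitation))
    return(rep(group$constant_excitation, n))
  if (!(group$emg_channel %in% colnames(excitations)))
    stop(sprintf("mapping error: no EMG channel '%s' for group '%s'",
                 group$emg_channel, group$name), call. = FALSE)
  excitations[, group$emg_channel]
}

#' EMG-driven lumbosacral moment and muscle forces
#'
#' Converts per-channel excitations to activations, evaluates each group's
#' Hill force along the trunk motion, and sums signed moment contributions
#' (`M = sum(s_i r_i(theta) F_i)`, extensors positive).
#'
#' @param model A [trunk_model()].
#' @param excitations Matrix (samples x channels, named columns) of
#'   dimensionless excitations, e.g. iMVC-normalized envelopes.
#' @param theta Flexion angle vector, rad (same length).
#' @param theta_dot Angular velocity, rad/s (default 0 = isometric).
#' @return List with `moment` (N m), `forces` (samples x groups, N) and
#'   `activations`.
#' @export
emg_driven_moment <- function(model, excitations, theta, theta_dot = NULL) {
  if (is.null(dim(excitations)))
    excitations <- matrix(excitations, ncol = 1L)
  n <- length(theta)
  if (nrow(excitations) != n)
    stop("excitations and theta must share the time base", call. = FALSE)
  if (is.null(theta_dot)) theta_dot <- rep(0, n)
  forces <- matrix(0, n, length(model$groups),
                   dimnames = list(NULL, names(model$groups)))
  moment <- rep(0, n)
  for (g in names(model$groups)) {
    grp <- model$groups[[g]]
    u <- resolve_excitation(grp, excitations, n)
    a <- activation(u, grp$params$shape_A)
    geo <- mtu_geometry(theta, grp)
    v_mt <- grp$sign * geo$r * theta_dot
    f <- mtu_force(a, geo$l_mt, v_mt, grp$params)
    forces[, g] <- f
    moment <- moment + grp$sign * geo$r * f
  }
  list(moment = moment, forces = forces,
       activations = NULL)
}

#' L5-S1 joint reaction: compression and shear
#'
#' Planar Newton-Euler balance of the trunk + arms/head free body: the
#' intersegmental force is what the pelvis must exert to account for segment
#' accelerations, gravity and the hand-held load; muscle forces crossing the
#' joint (lines of action taken along the trunk longitudinal axis) add
#' directly to compression. Shear is the anteroposterior component, positive
#' anterior.
#'
#' @param model A [trunk_model()].
#' @param theta,theta_dot,theta_ddot Flexion angle (rad) and derivatives.
#' @param load_force Vertical hand force, N (downward positive); scalar or
#'   vector.
#' @param muscle_forces Samples x groups matrix of muscle forces, N (or
#'   `NULL` for none).
#' @return List with `compression`, `shear` (N) and the intersegmental force
#'   components `inter_x`, `inter_z` (N, anterior/up positive, force of
#'   pelvis on trunk).
#' @export
joint_reaction <- function(model, theta, theta_dot = 0, theta_ddot = 0,
                           load_force = 0, muscle_forces = NULL) {
  s <- model$subject
  g <- model$gravity
  n <- length(theta)
  theta_dot <- rep_len(theta_dot, n)
  theta_ddot <- rep_len(theta_ddot, n)
  load_force <- rep_len(load_force, n)

  com_acc <- function(d) {
    list(x = d * (theta_ddot * cos(theta) - theta_dot^2 * sin(theta)),
         z = -d * (theta_ddot * sin(theta) + theta_dot^2 * cos(theta)))
  }
  at <- com_acc(s$trunk_com_distance)
  ah <- com_acc(s$armhead_lever)

  inter_x <- s$trunk_mass * at$x + s$armhead_mass * ah$x
  inter_z <- s$trunk_mass * at$z + s$armhead_mass * ah$z +
    (s$trunk_mass + s$armhead_mass) * g + load_force

  axial <- inter_x * sin(theta) + inter_z * cos(theta)
  shear <- -(inter_x * cos(theta) - inter_z * sin(theta))
  fm <- if (is.null(muscle_forces)) 0 else rowSums(muscle_forces)
  list(compression = axial + fm, shear = shear,
       inter_x = inter_x, inter_z = inter_z)
}

#' Joint load series container
#'
#' @param t Time or cycle-fraction axis.
#' @param moment Sagittal lumbosacral moment, N m (extension positive).
#' @param compression,shear L5-S1 forces, N.
#' @return A `joint_load_series` object.
#' @export
joint_load_series <- function(t, moment, compression, shear) {
  n <- length(t)
  if (length(moment) != n || length(compression) != n || length(shear) != n)
    stop("all load components must share the time base", call. = FALSE)
  structure(list(t = t, moment = moment, compression = compression,
                 shear = shear, moment_norm = NULL, compression_bw = NULL,
                 shear_bw = NULL), class = "joint_load_series")
}

#' @export
print.joint_load_series <- function(x, ...) {
  cat(sprintf(
    "<joint_load_series> %d samples | peak moment %.1f N m | peak compression %.0f N | peak |shear| %.0f N\n",
    length(x$t), max(x$moment), max(x$compression), max(abs(x$shear))))
  if (!is.null(x$compression_bw))
    cat(sprintf("  normalized: %.2f N m/kg, %.2f BW compression, %.2f BW shear\n",
                max(x$moment_norm), max(x$compression_bw),
                max(abs(x$shear_bw))))
  invisible(x)
}

#' Body-normalized joint loads
#'
#' Moments are divided by body mass (N m/kg); compression and shear by body
#' weight (dimensionless multiples of BW).
#'
#' @param loads A [joint_load_series()].
#' @param subj A [subject()].
#' @return The series with `moment_norm`, `compression_bw`, `shear_bw`
#'   populated.
#' @export
normalize_loads <- function(loads, subj) {
  loads$moment_norm <- loads$moment / subj$body_mass
  loads$compression_bw <- loads$compression / subj$body_weight
  loads$shear_bw <- loads$shear / subj$body_weight
  loads
}

#' Flag samples exceeding a compression limit
#'
#' @param loads A [joint_load_series()].
#' @param limit Compression limit in N (default 3400, the action limit used
#'   in ergonomic guidance).
#' @return List with logical `above` per sample and the `fraction` of the
#'   cycle above the limit.
#' @export
flag_exceedance <- function(loads, limit = 3400) {
  above <- loads$compression > limit
  list(above = above, fraction = mean(above), limit = limit)
}

#' EMG-driven joint loads over a lift cycle
#'
#' Convenience wrapper: EMG-driven moment + joint reaction, packed into a
#' [joint_load_series()].
#'
#' @inheritParams emg_driven_moment
#' @param theta_ddot Angular acceleration, rad/s^2.
#' @param load_force Vertical hand force, N.
#' @param t Time axis for the result (defaults to cycle fraction).
#' @return A [joint_load_series()].
#' @export
estimate_joint_loads <- function(model, excitations, theta,
                                 theta_dot = NULL, theta_ddot = NULL,
                                 load_force = 0, t = NULL) {
  n <- length(theta)
  if (is.null(theta_dot)) theta_dot <- rep(0, n)
  if (is.null(theta_ddot)) theta_ddot <- rep(0, n)
  if (is.null(t)) t <- seq(0, 1, length.out = n)
  emg <- emg_driven_moment(model, excitations, theta, theta_dot)
  jr <- joint_reaction(model, theta, theta_dot, theta_ddot, load_force,
                       emg$forces)
  joint_load_series(t, emg$moment, jr$compression, jr$shear)
}
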