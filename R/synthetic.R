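# Seeded synthetic lifting datasets.
#
# The generator emulates the statistical structure the analysis assumes:
# 7 subjects x 3 risk conditions (lifting index 1, 2, 3 with 21/21/20 kg
# loads) x 3 repetitions; minimum-jerk box motion with a clean
# velocity-threshold crossing; lumbosacral flexion whose range of motion
# grows with risk level; antagonist co-activation growing with risk level;
# and raw-like sEMG synthesized as amplitude-modulated band-limited noise
# whose envelope tracks the intended excitation. Every trial carries its
# ground truth (true parameters, moments and joint loads) for recovery
# tests.

#' Generator settings for synthetic lifting datasets
#'
#' @param n_subjects Number of subjects (default 7).
#' @param repetitions Repetitions per condition (default 3).
#' @param li_targets Lifting-index targets of the three conditions.
#' @param loads Load masses (kg) per condition.
#' @param fs_motion,fs_emg Sampling frequencies, Hz.
#' @param lift_duration Duration of the box rise, s.
#' @param lead_in Seconds of stooping before lift-off.
#' @param settle Seconds of settling tail after the lift.
#' @param peak_flexion_deg Peak lumbosacral flexion per risk level, degrees.
#' @param subject_flexion_jitter_deg Subject-level jitter on peak flexion.
#' @param coactivation_base,coactivation_slope Antagonist excitation =
#'   base + slope * risk level.
#' @param emg_mode `"carrier"` synthesizes raw EMG (amplitude-modulated
#'   20-400 Hz noise); `"clean"` stores noiseless envelopes directly, for
#'   parameter-recovery studies.
#' @param noise_floor Baseline (additive) noise level of the synthesized
#'   EMG, expressed as the fraction of the iMVC envelope amplitude it
#'   contributes; default 0.02 (a 2 percent-of-MVC baseline, typical of
#'   surface EMG).
#' @param vary_shape Draw subject-specific activation shape factors as part
#'   of the ground truth (`FALSE` keeps the defaults, isolating force-scale
#'   recovery).
#' @param seed Master seed; all randomness derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 7L, repetitions = 3L,
                             li_targets = c(1, 2, 3),
                             loads = c(21, 21, 20),
                             fs_motion = 340, fs_emg = 1000,
                             lift_duration = 1.5, lead_in = 0.8,
                             settle = 1.0,
                             peak_flexion_deg = c(45, 65, 85),
                             subject_flexion_jitter_deg = 5,
                             coactivation_base = 0.05,
                             coactivation_slope = 0.03,
                             emg_mode = c("carrier", "clean"),
                             noise_floor = 0.02, vary_shape = TRUE,
                             seed = 1L) {
  emg_mode <- match.arg(emg_mode)
  stopifnot(n_subjects > 0, repetitions > 0, all(loads > 0),
            length(li_targets) == length(loads))
  list(n_subjects = as.integer(n_subjects),
       repetitions = as.integer(repetitions),
       li_targets = li_targets, loads = loads,
       fs_motion = fs_motion, fs_emg = fs_emg,
       lift_duration = lift_duration, lead_in = lead_in, settle = settle,
       peak_flexion_deg = peak_flexion_deg,
       subject_flexion_jitter_deg = subject_flexion_jitter_deg,
       coactivation_base = coactivation_base,
       coactivation_slope = coactivation_slope,
       emg_mode = emg_mode, noise_floor = noise_floor,
       vary_shape = isTRUE(vary_shape), seed = as.integer(seed))
}

#' Draw a synthetic subject
#'
#' Body mass index ~ Normal(24.70, 1.80) and stature ~ Normal(1.75, 0.06);
#' mass = BMI * height^2, redrawn until within [55, 100] kg. Segment
#' parameters follow the fixed anthropometric fractions of [subject()].
#'
#' @param seed Seed making the draw deterministic.
#' @return A [subject()].
#' @export
make_subject <- function(seed) {
  with_seed(seed, {
    repeat {
      bmi <- rnorm(1, 24.70, 1.80)
      height <- rnorm(1, 1.75, 0.06)
      mass <- bmi * height^2
      if (mass >= 55 && mass <= 100) break
    }
    subject(mass, height)
  })
}

#' Build the three risk conditions
#'
#' Solves task geometry via [design_task_for_li()] so the computed lifting
#' indices hit the targets; asymmetry, frequency and coupling multipliers are
#' identical across conditions by construction.
#'
#' @param cfg A [generator_config()].
#' @return List of [lifting_task()]s, one per condition.
#' @export
make_conditions <- function(cfg = generator_config()) {
  mapply(function(li, load) design_task_for_li(li, load),
         cfg$li_targets, cfg$loads, SIMPLIFY = FALSE)
}

min_jerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
min_jerk_vel <- function(tau, d, T) 30 * d / T * (tau^2 - 2 * tau^3 + tau^4)
min_jerk_acc <- function(tau, d, T) 60 * d / T^2 *
  (tau - 3 * tau^2 + 2 * tau^3)

#' Minimum-jerk box trajectory for a lifting task
#'
#' Box rises from the task's V to V + D (cm converted to m) along a
#' minimum-jerk profile, preceded by a stationary lead-in and followed by a
#' settling tail of sub-threshold positional noise. Peak velocity is
#' `1.875 * D / duration`.
#'
#' @param task A [lifting_task()] (must have D > 0).
#' @param duration Rise duration, s.
#' @param fs Sampling frequency, Hz.
#' @param lead_in,settle Stationary padding, s.
#' @param noise_sd Positional noise in the settling tail, m.
#' @param seed Seed for the tail noise.
#' @return `lift_ts` with channels `box_height` (m), `box_velocity` (m/s,
#'   analytic) and `box_acc` (m/s^2).
#' @export
make_trajectory <- function(task, duration = 1.5, fs = 340, lead_in = 0.8,
                            settle = 1.0, noise_sd = 2e-5, seed = 1L) {
  if (task$D <= 0) stop("degenerate lift: task has zero travel distance",
                        call. = FALSE)
  v0 <- task$V / 100
  d <- task$D / 100
  tt <- seq(0, lead_in + duration + settle, by = 1 / fs)
  tau <- pmin(pmax((tt - lead_in) / duration, 0), 1)
  h <- v0 + d * min_jerk_pos(tau)
  v <- ifelse(tt >= lead_in & tt <= lead_in + duration,
              min_jerk_vel(tau, d, duration), 0)
  a <- ifelse(tt >= lead_in & tt <= lead_in + duration,
              min_jerk_acc(tau, d, duration), 0)
  tail_idx <- tt > lead_in + duration
  h[tail_idx] <- h[tail_idx] +
    with_seed(seed, rnorm(sum(tail_idx), 0, noise_sd))
  lift_ts(cbind(box_height = h, box_velocity = v, box_acc = a), fs)
}

#' Lumbosacral flexion profile for a risk level
#'
#' Starts near upright, flexes to a risk-dependent peak during the stoop,
#' extends back during the lift and settles near upright; range of motion is
#' strictly increasing in risk level by construction.
#'
#' @param cfg A [generator_config()].
#' @param risk_level 1, 2 or 3.
#' @param subject_jitter_deg Per-subject offset on the flexion peak, deg.
#' @param rep_jitter_deg Per-repetition offset, deg.
#' @param fs Sampling frequency, Hz.
#' @return `lift_ts` with one channel `angle` (rad).
#' @export
make_angle_profile <- function(cfg, risk_level, subject_jitter_deg = 0,
                               rep_jitter_deg = 0, fs = cfg$fs_motion) {
  stopifnot(risk_level %in% seq_along(cfg$peak_flexion_deg))
  # jitter stays inside the trunk model's validated flexion range
  peak_deg <- min(max(cfg$peak_flexion_deg[risk_level] + subject_jitter_deg +
                        rep_jitter_deg, 15), 90)
  th0 <- 5 * pi / 180
  th_end <- 8 * pi / 180
  peak <- peak_deg * pi / 180
  tt <- seq(0, cfg$lead_in + cfg$lift_duration + cfg$settle, by = 1 / fs)
  th <- numeric(length(tt))
  seg1 <- tt <= cfg$lead_in
  th[seg1] <- th0 + (peak - th0) * min_jerk_pos(tt[seg1] / cfg$lead_in)
  seg2 <- tt > cfg$lead_in & tt <= cfg$lead_in + cfg$lift_duration
  th[seg2] <- peak + (th_end - peak) *
    min_jerk_pos((tt[seg2] - cfg$lead_in) / cfg$lift_duration)
  th[tt > cfg$lead_in + cfg$lift_duration] <- th_end
  lift_ts(th, fs, channels = "angle")
}

emg_channel_names <- function() {
  c("longissimus_l", "longissimus_r", "iliocostalis_l", "iliocostalis_r",
    "rectus_abdominis_l", "rectus_abdominis_r")
}

# Invert the activation nonlinearity.
excitation_for_activation <- function(a, shape_A) {
  a <- pmin(pmax(a, 0), 1)
  if (abs(shape_A) < 1e-8) return(a)
  log(1 + a * (exp(shape_A) - 1)) / shape_A
}

# Distribute the inverse-dynamics moment over the muscle groups so that the
# EMG-driven moment of the ground-truth model reproduces it exactly:
# passive group and baseline antagonist co-activation are computed first,
# the remaining extensor demand is split by fixed synergy weights, and where
# the demand falls below the extensors' passive floor the antagonist picks
# up the surplus instead.
solve_excitations <- function(model, m_id, theta, theta_dot, co_activation) {
  n <- length(theta)
  groups <- model$groups
  geo <- lapply(groups, function(g) mtu_geometry(theta, g))
  v_mt <- lapply(names(groups), function(g)
    groups[[g]]$sign * geo[[g]]$r * theta_dot)
  names(v_mt) <- names(groups)

  curves <- lapply(names(groups), function(g) {
    p <- groups[[g]]$params
    l_norm <- (geo[[g]]$l_mt - p$l_ts) / p$l_opt
    list(fl = force_length_active(l_norm),
         fp = force_length_passive(l_norm),
         fv = force_velocity(v_mt[[g]] / (10 * p$l_opt)))
  })
  names(curves) <- names(groups)

  grp_force <- function(g, a) {
    p <- groups[[g]]$params
    pmax(p$f_max * (a * curves[[g]]$fl * curves[[g]]$fv + curves[[g]]$fp), 0)
  }
  grp_moment <- function(g, a) groups[[g]]$sign * geo[[g]]$r * grp_force(g, a)

  m_passive <- grp_moment("passive",
                          activation(groups$passive$constant_excitation,
                                     groups$passive$params$shape_A))

  flex <- c("rectus_abdominis_l", "rectus_abdominis_r")
  ext <- c("longissimus_l", "longissimus_r", "iliocostalis_l",
           "iliocostalis_r")
  a_co <- activation(co_activation, groups[[flex[1L]]]$params$shape_A)
  m_flex_base <- grp_moment(flex[1L], a_co) + grp_moment(flex[2L], a_co)

  # extensor passive floor (zero activation)
  m_ext_floor <- Reduce(`+`, lapply(ext, grp_moment, a = 0))

  demand <- m_id - m_passive - m_flex_base   # m_flex_base is negative
  u <- matrix(0, n, length(flex) + length(ext),
              dimnames = list(NULL, c(ext, flex)))
  u[, flex] <- co_activation

  deficit <- m_ext_floor - demand
  short <- deficit > 0
  if (any(short)) {
    # raise the antagonists so total demand meets the passive floor
    extra <- ifelse(short, deficit, 0)
    for (f in flex) {
      g <- groups[[f]]
      need_f <- grp_force(f, a_co) + extra / (2 * geo[[f]]$r)
      a_f <- (need_f / g$params$f_max - curves[[f]]$fp) /
        (curves[[f]]$fl * curves[[f]]$fv)
      if (any(a_f > 1 + 1e-9))
        stop("capacity error: antagonist demand exceeds f_max; raise f_max",
             call. = FALSE)
      u[, f] <- excitation_for_activation(pmin(pmax(a_f, 0), 1),
                                          g$params$shape_A)
    }
  }

  active_demand <- pmax(demand - m_ext_floor, 0)
  # posture-dependent synergy: the longissimus share grows with flexion, so
  # the two extensors' moment contributions are not proportional in time
  # (keeps their force scales separately identifiable)
  w_long <- pmin(pmax(0.45 + 0.15 * theta, 0.3), 0.75)
  weights <- list(longissimus_l = w_long / 2, longissimus_r = w_long / 2,
                  iliocostalis_l = (1 - w_long) / 2,
                  iliocostalis_r = (1 - w_long) / 2)
  for (e in ext) {
    g <- groups[[e]]
    f_active <- weights[[e]] * active_demand / geo[[e]]$r
    a_e <- f_active / (g$params$f_max * curves[[e]]$fl * curves[[e]]$fv)
    if (any(a_e > 1 + 1e-9))
      stop("capacity error: required extensor moment exceeds muscle capacity; raise f_max",
           call. = FALSE)
    u[, e] <- excitation_for_activation(pmin(a_e, 1), g$params$shape_A)
  }
  u
}

synthesize_emg <- function(u_emg, gains, fs_emg, noise_floor, seed) {
  n <- nrow(u_emg)
  raw <- matrix(0, n, ncol(u_emg), dimnames = dimnames(u_emg))
  bp <- butter_coefs(4L, c(20, 400), fs_emg, "pass")
  lp <- butter_coefs(4L, 5, fs_emg, "low")
  with_seed(seed, {
    for (j in seq_len(ncol(u_emg))) {
      carrier <- filtfilt_vec(bp$b, bp$a, rnorm(n))
      carrier <- carrier / sd(carrier)
      # flatten the carrier's own linear envelope so the synthesized
      # signal's envelope tracks the excitation by construction
      env_c <- filtfilt_vec(lp$b, lp$a, abs(carrier))
      env_c <- pmax(env_c, 0.2 * mean(env_c))
      carrier <- carrier / env_c
      noise <- filtfilt_vec(bp$b, bp$a, rnorm(n))
      noise <- noise / sd(noise) * gains[j] * noise_floor / sqrt(2 / pi)
      # independent noise adds to the linear envelope in quadrature, so
      # pre-compensate the modulation depth: the resulting envelope tracks
      # the excitation target instead of riding above it
      depth <- sqrt(pmax(u_emg[, j]^2 - noise_floor^2, 0))
      raw[, j] <- gains[j] * depth * carrier + noise
    }
  })
  raw
}

#' Forward-simulate one lifting trial
#'
#' Builds box and trunk kinematics for the condition, computes the
#' inverse-dynamics moment, solves muscle excitations so the ground-truth
#' model reproduces it exactly, synthesizes raw-like EMG (or clean
#' envelopes), and stores the true moment and joint loads alongside.
#'
#' @param model The subject's ground-truth [trunk_model()].
#' @param task The condition's [lifting_task()].
#' @param li_level Risk level 1, 2 or 3.
#' @param cfg A [generator_config()].
#' @param subject_id Identifier stored with the trial.
#' @param repetition Repetition index.
#' @param seed Trial seed.
#' @param subject_jitter_deg Passed to [make_angle_profile()].
#' @return A `lift_trial` with motion channels, EMG, iMVC peaks and a
#'   `ground_truth` list (excitations, moment, compression, shear).
#' @export
forward_simulate <- function(model, task, li_level, cfg = generator_config(),
                             subject_id = 1L, repetition = 1L, seed = 1L,
                             subject_jitter_deg = 0) {
  rep_jit <- with_seed(seed, runif(1, -2, 2))
  traj <- make_trajectory(task, cfg$lift_duration, cfg$fs_motion,
                          cfg$lead_in, cfg$settle, seed = seed + 1L)
  ang <- make_angle_profile(cfg, li_level, subject_jitter_deg, rep_jit,
                            cfg$fs_motion)
  n <- min(n_samples(traj), n_samples(ang))
  theta <- ts_channel(ang)[1:n]
  tt <- ts_time(ang)[1:n]

  # vertical hand force: smooth grab ramp just before lift-off, then the
  # load's weight plus its vertical inertia
  grab_t0 <- cfg$lead_in - 0.15
  ramp <- pmin(pmax((tt - grab_t0) / 0.15, 0), 1)
  ramp <- ramp^2 * (3 - 2 * ramp)
  box_acc <- ts_channel(traj, "box_acc")[1:n]
  f_load <- ramp * task$load_mass * (model$gravity + box_acc)

  angle_ts <- lift_ts(theta, cfg$fs_motion, channels = "angle")
  load_ts <- lift_ts(f_load, cfg$fs_motion, channels = "load_force")
  m_id <- ts_channel(inverse_dynamics_moment(angle_ts, model$subject,
                                             load_ts, model$gravity))
  theta_dot <- ts_channel(ts_derivative(angle_ts))

  co_act <- cfg$coactivation_base + cfg$coactivation_slope * li_level
  u <- solve_excitations(model, m_id, theta, theta_dot, co_act)

  # true joint loads from the ground-truth model
  est <- emg_driven_moment(model, u, theta, theta_dot)
  theta_ddot <- ts_channel(ts_derivative(ts_derivative(angle_ts)))
  jr <- joint_reaction(model, theta, theta_dot, theta_ddot, f_load,
                       est$forces)

  channels <- emg_channel_names()
  gains <- with_seed(seed + 2L, runif(length(channels), 4e-4, 6e-4))
  names(gains) <- channels
  imvc_peaks <- lapply(channels, function(ch)
    gains[[ch]] * c(0.95, 1, 1.05))
  names(imvc_peaks) <- channels

  t_emg <- seq(0, tt[n], by = 1 / cfg$fs_emg)
  u_emg <- vapply(channels, function(ch)
    approx(tt, u[, ch], xout = t_emg, rule = 2)$y,
    numeric(length(t_emg)))

  if (cfg$emg_mode == "clean") {
    emg <- lift_ts(sweep(u_emg, 2, gains, `*`), cfg$fs_emg,
                   channels = channels)
    emg_is_envelope <- TRUE
  } else {
    emg <- lift_ts(synthesize_emg(u_emg, gains, cfg$fs_emg,
                                  cfg$noise_floor, seed + 3L),
                   cfg$fs_emg, channels = channels)
    emg_is_envelope <- FALSE
  }

  motion <- lift_ts(cbind(box_height = ts_channel(traj, "box_height")[1:n],
                          box_velocity = ts_channel(traj, "box_velocity")[1:n],
                          angle = theta, load_force = f_load),
                    cfg$fs_motion)
  structure(list(
    subject_id = subject_id, li_level = li_level, repetition = repetition,
    task = task, load_mass = task$load_mass,
    fs_motion = cfg$fs_motion, fs_emg = cfg$fs_emg,
    motion = motion, emg = emg, emg_is_envelope = emg_is_envelope,
    imvc_peaks = imvc_peaks,
    ground_truth = list(excitations = u, moment = m_id,
                        compression = jr$compression, shear = jr$shear,
                        excitation_targets_emg = u_emg)),
    class = "lift_trial")
}

#' @export
print.lift_trial <- function(x, ...) {
  cat(sprintf(
    "<lift_trial> subject %s, risk level %d, rep %d | %.1f kg | %.1f s motion @ %g Hz, EMG @ %g Hz%s\n",
    x$subject_id, x$li_level, x$repetition, x$load_mass,
    n_samples(x$motion) / x$fs_motion, x$fs_motion, x$fs_emg,
    if (x$emg_is_envelope) " (clean envelopes)" else ""))
  invisible(x)
}

#' Generate a full synthetic lifting dataset
#'
#' Draws subjects (each with ground-truth muscle parameters: force scales in
#' U(0.8, 1.3) and shape factors in U(-2.5, -0.8) per merged muscle), builds
#' the three conditions, and forward-simulates every trial.
#'
#' @param cfg A [generator_config()].
#' @return A `lift_dataset`: list with `subjects`, `models` (ground-truth
#'   per subject), `true_params`, `conditions`, `trials` and `cfg`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  conditions <- make_conditions(cfg)
  subjects <- list()
  models <- list()
  true_params <- list()
  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    subj <- make_subject(cfg$seed * 1000L + s)
    scales <- with_seed(cfg$seed * 1000L + 500L + s, list(
      f_max = setNames(runif(3, 0.8, 1.3),
                       c("longissimus", "iliocostalis", "rectus_abdominis")),
      shape_A = setNames(if (cfg$vary_shape) runif(3, -2.5, -0.8)
                         else rep(-1.5, 3),
                         c("longissimus", "iliocostalis", "rectus_abdominis"))))
    groups <- default_mtu_groups()
    for (b in names(scales$f_max)) {
      for (side in c("_l", "_r")) {
        g <- paste0(b, side)
        groups[[g]] <- within_group_update(groups[[g]], "f_max",
                                           scales$f_max[[b]])
        groups[[g]] <- within_group_update(groups[[g]], "shape_A",
                                           scales$shape_A[[b]])
      }
    }
    model <- trunk_model(subj, groups)
    jit <- with_seed(cfg$seed * 1000L + 800L + s,
                     runif(1, -cfg$subject_flexion_jitter_deg,
                           cfg$subject_flexion_jitter_deg))
    subjects[[sid]] <- subj
    models[[sid]] <- model
    true_params[[sid]] <- scales
    for (li in seq_along(conditions)) {
      for (r in seq_len(cfg$repetitions)) {
        trial_seed <- cfg$seed * 100000L + s * 100L + li * 10L + r
        trials[[length(trials) + 1L]] <-
          forward_simulate(model, conditions[[li]], li, cfg, sid, r,
                           trial_seed, jit)
      }
    }
  }
  structure(list(subjects = subjects, models = models,
                 true_params = true_params, conditions = conditions,
                 trials = trials, cfg = cfg),
            class = "lift_dataset")
}

#' @export
print.lift_dataset <- function(x, ...) {
  cat(sprintf("<lift_dataset> %d subjects x %d trials each (%d total), seed %d\n",
              length(x$subjects),
              length(x$trials) / max(length(x$subjects), 1L),
              length(x$trials), x$cfg$seed))
  invisible(x)
}
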