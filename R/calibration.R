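# Per-subject calibration of the lumped muscle-tendon parameters.
#
# The EMG-driven moment is matched to the inverse-dynamics moment over
# designated calibration trials (low- and high-risk conditions by default) by
# bounded multi-start optimization of a small parameter vector: per muscle
# (left/right homologues share parameters) a maximal-isometric-force scale
# and the activation shape factor, plus one global optimal-fibre-length
# scale. The objective is the mean over calibration trials of the moment
# RMSE normalized by each trial's peak inverse-dynamics moment, so trials of
# different magnitude weigh equally.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Calibration settings
#'
#' @param adjustable Which parameter families to calibrate: any of
#'   `"f_max"` (force scale per muscle), `"shape_A"` (activation shape per
#'   muscle), `"l_opt"` (one global fibre-length scale).
#' @param calibration_levels Risk levels whose trials are used for
#'   calibration (default low and high, `c(1, 3)`).
#' @param seed Seed for the multi-start draws.
#' @param restarts Number of optimization starts (first start = initial
#'   parameters).
#' @param maxit Iteration budget per start; 0 returns the initial parameters
#'   unchanged.
#' @return A `calibration_config` list.
#' @export
calibration_config <- function(adjustable = c("f_max", "shape_A", "l_opt"),
                               calibration_levels = c(1L, 3L),
                               seed = 42L, restarts = 5L, maxit = 60L) {
  adjustable <- match.arg(adjustable, c("f_max", "shape_A", "l_opt"),
                          several.ok = TRUE)
  if (length(calibration_levels) == 0L)
    stop("`calibration_levels` must be non-empty", call. = FALSE)
  list(adjustable = adjustable, calibration_levels = calibration_levels,
       seed = as.integer(seed), restarts = as.integer(restarts),
       maxit = as.integer(maxit))
}

merged_group_bases <- function(model) {
  nm <- names(model$groups)
  active <- nm[vapply(model$groups,
                      function(g) is.na(g$constant_excitation), logical(1))]
  unique(sub("_[lr]$", "", active))
}

# Parameter vector layout for the optimizer: one entry per (kind, base).
calibration_param_spec <- function(model, cfg) {
  bases <- merged_group_bases(model)
  spec <- list()
  if ("f_max" %in% cfg$adjustable)
    for (b in bases)
      spec[[length(spec) + 1L]] <- list(kind = "f_max", base = b,
                                        lower = 0.5, upper = 2.5, init = 1)
  if ("shape_A" %in% cfg$adjustable)
    for (b in bases) {
      g0 <- model$groups[[paste0(b, "_l")]]
      init <- if (!is.null(g0)) g0$params$shape_A else -1.5
      spec[[length(spec) + 1L]] <- list(kind = "shape_A", base = b,
                                        lower = -3, upper = -0.001,
                                        init = min(max(init, -3), -0.001))
    }
  if ("l_opt" %in% cfg$adjustable)
    spec[[length(spec) + 1L]] <- list(kind = "l_opt", base = "_global",
                                      lower = 0.5, upper = 1.5, init = 1)
  spec
}

apply_calibration_params <- function(model, spec, par) {
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    targets <- if (s$base == "_global")
      names(model$groups)[vapply(model$groups, function(g)
        is.na(g$constant_excitation), logical(1))]
    else grep(paste0("^", s$base, "(_[lr])?$"), names(model$groups),
              value = TRUE)
    for (g in targets)
      model$groups[[g]] <- within_group_update(model$groups[[g]], s$kind,
                                               par[i])
  }
  model
}

within_group_update <- function(group, kind, value) {
  p <- group$params
  if (kind == "f_max") {
    if (is.null(p$base_f_max)) p$base_f_max <- p$f_max
    p$f_max <- p$base_f_max * value
  } else if (kind == "shape_A") {
    p$shape_A <- value
  } else if (kind == "l_opt") {
    if (is.null(p$base_l_opt)) p$base_l_opt <- p$l_opt
    p$l_opt <- p$base_l_opt * value
  }
  group$params <- p
  group
}

trial_moment_rmse <- function(model, ptrial) {
  peak <- max(abs(ptrial$m_id))
  if (peak < 1e-9)
    stop("degenerate trial: inverse-dynamics moment has no variation",
         call. = FALSE)
  est <- emg_driven_moment(model, ptrial$excitations, ptrial$theta,
                           ptrial$theta_dot)
  rmse <- sqrt(mean((est$moment - ptrial$m_id)^2))
  c(rmse = rmse, normalized = rmse / peak)
}

#' Calibration objective: normalized moment-tracking error
#'
#' Mean over trials of `RMSE(M_emg - M_id) / max|M_id|`.
#'
#' @param model A [trunk_model()].
#' @param ptrials List of processed trials (see [process_trial()]).
#' @return Dimensionless non-negative scalar.
#' @export
calibration_objective <- function(model, ptrials) {
  mean(vapply(ptrials, function(p) trial_moment_rmse(model, p)["normalized"],
              numeric(1)))
}

# Precompute everything that does not depend on the calibrated parameters:
# per trial and group the moment arm, muscle-tendon length, velocity and
# resolved excitation. The fast objective below is algebraically identical
# to calibration_objective() but avoids rebuilding model objects per
# evaluation (it is cross-checked against the reference in the test suite).
calibration_statics <- function(model, ptrials) {
  lapply(ptrials, function(p) {
    n <- length(p$theta)
    peak <- max(abs(p$m_id))
    if (peak < 1e-9)
      stop("degenerate trial: inverse-dynamics moment has no variation",
           call. = FALSE)
    groups <- lapply(model$groups, function(g) {
      geo <- mtu_geometry(p$theta, g)
      list(sign = g$sign, r = geo$r, l_mt = geo$l_mt,
           v_mt = g$sign * geo$r * p$theta_dot,
           u = resolve_excitation(g, p$excitations, n),
           f_max = g$params$base_f_max %||% g$params$f_max,
           l_opt = g$params$base_l_opt %||% g$params$l_opt,
           l_ts = g$params$l_ts, shape_A = g$params$shape_A,
           passive = !is.na(g$constant_excitation))
    })
    list(groups = groups, m_id = p$m_id, peak = peak)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fast_objective <- function(statics, spec, par, group_names) {
  # materialize per-group multipliers from the parameter vector
  f_scale <- setNames(rep(1, length(group_names)), group_names)
  l_scale <- setNames(rep(1, length(group_names)), group_names)
  shape <- setNames(rep(NA_real_, length(group_names)), group_names)
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    targets <- if (s$base == "_global") group_names else
      grep(paste0("^", s$base, "(_[lr])?$"), group_names, value = TRUE)
    if (s$kind == "f_max") f_scale[targets] <- par[i]
    else if (s$kind == "l_opt") l_scale[targets] <- par[i]
    else if (s$kind == "shape_A") shape[targets] <- par[i]
  }
  errs <- vapply(statics, function(st) {
    moment <- 0
    for (g in names(st$groups)) {
      gr <- st$groups[[g]]
      sA <- if (gr$passive || is.na(shape[g])) gr$shape_A else shape[g]
      lsc <- if (gr$passive) 1 else l_scale[g]
      fsc <- if (gr$passive) 1 else f_scale[g]
      a <- activation(gr$u, sA)
      l_opt <- gr$l_opt * lsc
      l_norm <- (gr$l_mt - gr$l_ts) / l_opt
      f <- fsc * gr$f_max *
        (a * force_length_active(l_norm) *
           force_velocity(gr$v_mt / (10 * l_opt)) +
           force_length_passive(l_norm))
      moment <- moment + gr$sign * gr$r * pmax(f, 0)
    }
    sqrt(mean((moment - st$m_id)^2)) / st$peak
  }, numeric(1))
  mean(errs)
}

#' Calibrate muscle-tendon parameters against inverse-dynamics moments
#'
#' Bounded multi-start local optimization (L-BFGS-B with numerical
#' gradients), deterministic for a given seed. Only trials whose risk level
#' is in `cfg$calibration_levels` are used.
#'
#' @param model The subject's [trunk_model()] with initial (generic)
#'   parameters.
#' @param ptrials List of processed trials for this subject.
#' @param cfg A [calibration_config()].
#' @return A `calibration_result` with the calibrated `model`, a `params`
#'   table, `objective`, `initial_objective`, per-trial RMSE, `converged`,
#'   and `iterations`.
#' @export
calibrate <- function(model, ptrials, cfg = calibration_config()) {
  levels_present <- vapply(ptrials, `[[`, numeric(1), "li_level")
  use <- ptrials[levels_present %in% cfg$calibration_levels]
  for (lev in cfg$calibration_levels)
    if (!any(levels_present == lev))
      stop(sprintf("calibration needs at least one trial at level %s", lev),
           call. = FALSE)

  spec <- calibration_param_spec(model, cfg)
  lower <- vapply(spec, `[[`, numeric(1), "lower")
  upper <- vapply(spec, `[[`, numeric(1), "upper")
  init <- vapply(spec, `[[`, numeric(1), "init")

  statics <- calibration_statics(model, use)
  fn <- function(par) fast_objective(statics, spec, par,
                                     names(model$groups))

  initial_objective <- fn(init)
  if (cfg$maxit == 0L) {
    return(finish_calibration(model, spec, init, initial_objective,
                              initial_objective, use, converged = FALSE,
                              iterations = 0L, cfg = cfg))
  }

  starts <- with_seed(cfg$seed, {
    s <- list(init)
    for (i in seq_len(max(cfg$restarts - 1L, 0L)))
      s[[i + 1L]] <- runif(length(spec), lower, upper)
    s
  })

  best <- NULL
  iterations <- 0L
  any_ok <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = cfg$maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- TRUE
    iterations <- iterations + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_ok)
    stop("calibration failed: no optimizer start converged; best-so-far objective ",
         signif(initial_objective, 4), call. = FALSE)
  if (best$value > initial_objective) {
    best$par <- init
    best$value <- initial_objective
  }
  finish_calibration(model, spec, best$par, best$value, initial_objective,
                     use, converged = TRUE, iterations = iterations,
                     cfg = cfg)
}

finish_calibration <- function(model, spec, par, objective,
                               initial_objective, use, converged, iterations,
                               cfg) {
  calibrated <- apply_calibration_params(model, spec, par)
  params <- data.frame(
    kind = vapply(spec, `[[`, character(1), "kind"),
    group = vapply(spec, `[[`, character(1), "base"),
    value = par,
    lower = vapply(spec, `[[`, numeric(1), "lower"),
    upper = vapply(spec, `[[`, numeric(1), "upper"))
  rmse <- t(vapply(use, function(p) trial_moment_rmse(calibrated, p),
                   numeric(2)))
  structure(list(model = calibrated, params = params, objective = objective,
                 initial_objective = initial_objective,
                 trial_rmse = data.frame(
                   li_level = vapply(use, `[[`, numeric(1), "li_level"),
                   rmse = rmse[, 1L], normalized = rmse[, 2L]),
                 converged = converged, iterations = iterations,
                 seed = cfg$seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> objective %.4f (initial %.4f), %s after %d evaluations\n",
    x$objective, x$initial_objective,
    if (x$converged) "converged" else "initial parameters kept",
    x$iterations))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Validate a calibrated model on held-out trials
#'
#' Computes the normalized moment RMSE per held-out trial; no parameters are
#' updated.
#'
#' @param result A `calibration_result`.
#' @param ptrials Held-out processed trials.
#' @return Data frame with one row per trial (`li_level`, `rmse`,
#'   `normalized`).
#' @export
validate_calibration <- function(result, ptrials) {
  rmse <- t(vapply(ptrials, function(p) trial_moment_rmse(result$model, p),
                   numeric(2)))
  data.frame(li_level = vapply(ptrials, `[[`, numeric(1), "li_level"),
             rmse = rmse[, 1L], normalized = rmse[, 2L])
}
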