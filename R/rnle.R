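# Revised NIOSH Lifting Equation (RNLE).
#
# RWL = LC * HM * VM * DM * AM * FM * CM, with LC = 23 kg, and
# LI = load mass / RWL. Multiplier formulas follow the metric Applications
# Manual: HM = 25/H, VM = 1 - 0.003|V - 75|, DM = 0.82 + 4.5/D,
# AM = 1 - 0.0032 A; FM and CM come from the published lookup tables shipped
# under inst/extdata. Task variables beyond the applicability limits zero the
# corresponding multiplier (task not recommended).

RNLE_LC <- 23

.rnle_tables <- new.env(parent = emptyenv())

rnle_table <- function(which = c("fm", "cm")) {
  which <- match.arg(which)
  key <- paste0(which, "_table")
  if (is.null(.rnle_tables[[key]])) {
    path <- system.file("extdata", paste0(key, ".csv"), package = "liftload")
    .rnle_tables[[key]] <- read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE)
  }
  .rnle_tables[[key]]
}

#' Define a lifting task for the Revised NIOSH Lifting Equation
#'
#' @param load_mass Mass of the lifted object, kg (> 0).
#' @param H Horizontal location of the hands from the ankle midpoint, cm.
#' @param V Vertical location of the hands at lift origin, cm.
#' @param D Vertical travel distance, cm.
#' @param A Asymmetry angle, degrees (0 = sagittal lifting).
#' @param F Lifting frequency, lifts/min.
#' @param duration_class Work duration class: `"1h"`, `"2h"` or `"8h"`
#'   (`"<=1h"` etc. are accepted).
#' @param coupling Hand-to-object coupling quality: `"good"`, `"fair"`,
#'   `"poor"`.
#' @return A `lifting_task` object.
#' @examples
#' neutral <- lifting_task(23, H = 25, V = 75, D = 25)
#' rnle_assess(neutral)
#' @export
lifting_task <- function(load_mass, H, V, D, A = 0, F = 0.2,
                         duration_class = "1h", coupling = "good") {
  load_mass <- unname(as.numeric(load_mass))[1L]
  H <- unname(as.numeric(H))[1L]; V <- unname(as.numeric(V))[1L]
  D <- unname(as.numeric(D))[1L]; A <- unname(as.numeric(A))[1L]
  F <- unname(as.numeric(F))[1L]
  num <- c(load_mass = load_mass, H = H, V = V, D = D, A = A, F = F)
  if (any(!is.finite(num)))
    stop("task variables must be finite numbers", call. = FALSE)
  if (load_mass <= 0) stop("`load_mass` must be > 0", call. = FALSE)
  if (any(num[c("H", "V", "D", "A", "F")] < 0))
    stop("H, V, D, A and F must be non-negative", call. = FALSE)
  duration_class <- sub("^<=", "", duration_class)
  duration_class <- match.arg(duration_class, c("1h", "2h", "8h"))
  coupling <- match.arg(coupling, c("good", "fair", "poor"))
  structure(list(load_mass = load_mass, H = H, V = V, D = D, A = A, F = F,
                 duration_class = duration_class, coupling = coupling),
            class = "lifting_task")
}

#' @export
print.lifting_task <- function(x, ...) {
  cat(sprintf(
    "<lifting_task> load %.1f kg | H %.1f V %.1f D %.1f cm | A %.1f deg | F %.2f/min (%s, %s coupling)\n",
    x$load_mass, x$H, x$V, x$D, x$A, x$F, x$duration_class, x$coupling))
  invisible(x)
}

frequency_multiplier <- function(F, V, duration_class) {
  tab <- rnle_table("fm")
  F <- max(F, min(tab$frequency))
  if (F > max(tab$frequency)) return(0)
  # conservative: use the next-higher tabulated frequency
  row <- tab[which(tab$frequency >= F - 1e-9)[1L], ]
  col <- paste0("dur", duration_class, if (V < 75) "_vlow" else "_vhigh")
  as.numeric(row[[col]])
}

coupling_multiplier <- function(coupling, V) {
  tab <- rnle_table("cm")
  as.numeric(tab[tab$coupling == coupling, if (V < 75) "v_low" else "v_high"])
}

#' Compute RNLE multipliers, recommended weight limit and lifting index
#'
#' `rnle_multipliers()` evaluates the six multipliers for a task (recording
#' which variables were clamped or out of range), `rnle_rwl()` adds the
#' recommended weight limit `RWL = 23 * HM*VM*DM*AM*FM*CM`, and
#' `rnle_assess()` additionally computes the lifting index
#' `LI = load_mass / RWL` with its risk band (low for LI <= 1, medium for
#' LI <= 2, high for LI <= 3, very_high above).
#'
#' @param task A [lifting_task()].
#' @return An `rnle_result` list with elements `LC`, `HM`, `VM`, `DM`, `AM`,
#'   `FM`, `CM`, `RWL`, and for `rnle_assess()` also `LI` and `risk_level`;
#'   `flags` records clamped/zeroed variables.
#' @examples
#' task <- lifting_task(21, H = 40, V = 50, D = 60)
#' rnle_assess(task)
#' @export
rnle_multipliers <- function(task) {
  if (!inherits(task, "lifting_task"))
    stop("`task` must be a lifting_task", call. = FALSE)
  flags <- character(0)

  H <- task$H
  if (H < 25) { H <- 25; flags <- c(flags, "H_clamped_low") }
  HM <- if (H > 63) { flags <- c(flags, "H_out_of_range"); 0 } else 25 / H

  VM <- if (task$V > 175) { flags <- c(flags, "V_out_of_range"); 0 } else
    1 - 0.003 * abs(task$V - 75)

  D <- task$D
  if (D < 25) { D <- 25; flags <- c(flags, "D_clamped_low") }
  DM <- if (D > 175) { flags <- c(flags, "D_out_of_range"); 0 } else
    0.82 + 4.5 / D

  AM <- if (task$A > 135) { flags <- c(flags, "A_out_of_range"); 0 } else
    1 - 0.0032 * task$A

  FM <- frequency_multiplier(task$F, task$V, task$duration_class)
  if (FM == 0) flags <- c(flags, "F_out_of_range")
  CM <- coupling_multiplier(task$coupling, task$V)

  structure(list(LC = RNLE_LC, HM = HM, VM = VM, DM = DM, AM = AM,
                 FM = FM, CM = CM, RWL = NA_real_, LI = NA_real_,
                 risk_level = NA_character_, flags = flags,
                 task = task),
            class = "rnle_result")
}

#' @rdname rnle_multipliers
#' @export
rnle_rwl <- function(task) {
  res <- rnle_multipliers(task)
  res$RWL <- res$LC * res$HM * res$VM * res$DM * res$AM * res$FM * res$CM
  if (res$RWL == 0) res$flags <- c(res$flags, "LI_undefined")
  res
}

#' @rdname rnle_multipliers
#' @export
rnle_assess <- function(task) {
  res <- rnle_rwl(task)
  if (res$RWL <= 0)
    stop("degenerate task: RWL is zero, lifting index undefined",
         call. = FALSE)
  res$LI <- task$load_mass / res$RWL
  res$risk_level <- rnle_risk_band(res$LI)
  res
}

#' @rdname rnle_multipliers
#' @param li A lifting-index value.
#' @export
rnle_risk_band <- function(li) {
  cut(li, breaks = c(0, 1, 2, 3, Inf),
      labels = c("low", "medium", "high", "very_high"),
      include.lowest = TRUE, right = TRUE) |> as.character()
}

#' @export
print.rnle_result <- function(x, ...) {
  cat("<rnle_result>\n")
  cat(sprintf("  multipliers: HM %.3f VM %.3f DM %.3f AM %.3f FM %.2f CM %.2f\n",
              x$HM, x$VM, x$DM, x$AM, x$FM, x$CM))
  if (!is.na(x$RWL)) cat(sprintf("  RWL: %.2f kg (LC %g kg)\n", x$RWL, x$LC))
  if (!is.na(x$LI))
    cat(sprintf("  LI: %.3f (load %.1f kg) -> risk %s\n",
                x$LI, x$task$load_mass, x$risk_level))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Achievable multiplier range for each invertible geometry variable,
# restricting V to the below-knuckle side (lifting from low shelves).
.design_ranges <- list(
  H = c(25 / 63, 1),
  V = c(1 - 0.003 * 75, 1),
  D = c(0.82 + 4.5 / 175, 1)
)

multiplier_to_variable <- function(var, m) {
  switch(var,
    H = min(max(25 / m, 25), 63),
    V = min(max(75 - (1 - m) / 0.003, 0), 175),
    D = if (m >= 1) 25 else min(max(4.5 / (m - 0.82), 25), 175)
  )
}

#' Design task geometry for a target lifting index
#'
#' Inverts the RNLE: given a target LI and load mass, solves for the free
#' geometry variables (subset of H, V, D) so that the task's computed LI
#' matches the target, keeping AM, FM and CM fixed at the template's values.
#' The required multiplier product is spread across the free variables as
#' evenly as their admissible ranges allow.
#'
#' @param target_li Target lifting index (> 0).
#' @param load_mass Load mass in kg.
#' @param free Character vector naming the free variables, subset of
#'   `c("H", "V", "D")`.
#' @param template A [lifting_task()] supplying all fixed variables.
#' @return A `lifting_task` whose computed LI equals `target_li` (well within
#'   1 percent).
#' @examples
#' t1 <- design_task_for_li(1, 21)
#' rnle_assess(t1)$LI
#' @export
design_task_for_li <- function(target_li, load_mass,
                               free = c("H", "V", "D"),
                               template = lifting_task(load_mass, 25, 75, 25)) {
  if (!is.finite(target_li) || target_li <= 0)
    stop("`target_li` must be a positive number", call. = FALSE)
  free <- match.arg(free, c("H", "V", "D"), several.ok = TRUE)
  template$load_mass <- load_mass

  cur <- rnle_rwl(template)
  if (cur$RWL > 0 &&
      abs(load_mass / cur$RWL - target_li) <= 1e-9 * target_li)
    return(template)

  mult <- rnle_multipliers(template)
  fixed_prod <- mult$AM * mult$FM * mult$CM
  for (v in setdiff(c("H", "V", "D"), free))
    fixed_prod <- fixed_prod * mult[[paste0(v, "M")]]
  if (fixed_prod <= 0)
    stop("infeasible design: a fixed multiplier is zero", call. = FALSE)

  needed <- (load_mass / target_li) / (RNLE_LC * fixed_prod)
  lo <- vapply(.design_ranges[free], `[`, numeric(1), 1L)
  if (needed > 1 + 1e-9 || needed < prod(lo) - 1e-9)
    stop(sprintf(
      "infeasible design: required multiplier product %.3f outside [%.3f, 1]",
      needed, prod(lo)), call. = FALSE)

  k <- length(free)
  R <- min(needed, 1)
  ms <- numeric(k)
  for (i in seq_len(k)) {
    rest_lo <- if (i < k) prod(lo[(i + 1):k]) else 1
    lower <- max(lo[i], R)
    upper <- min(1, R / rest_lo)
    ms[i] <- min(max(R^(1 / (k - i + 1)), lower), upper)
    R <- R / ms[i]
  }

  task <- template
  for (i in seq_len(k))
    task[[free[i]]] <- multiplier_to_variable(free[i], ms[i])

  achieved <- rnle_assess(task)$LI
  if (abs(achieved - target_li) > 0.01 * target_li)
    stop("infeasible design: could not reach the target lifting index",
         call. = FALSE)
  task
}
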