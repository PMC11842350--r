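# Serialization of the trunk model and time-series export.

#' Write and read a trunk model definition as JSON
#'
#' The document carries the subject's segment parameters, every muscle
#' group's Hill parameters, moment-arm coefficients and channel mapping, and
#' gravity. `read_model_json()` validates the schema (required fields,
#' positive parameters) before rebuilding the model.
#'
#' @param model A [trunk_model()].
#' @param path Output/input file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a [trunk_model()].
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    schema = "liftload-trunk-model/1",
    gravity = model$gravity,
    subject = unclass(model$subject),
    groups = lapply(model$groups, function(g)
      list(name = g$name, emg_channel = g$emg_channel, role = g$role,
           n_units = g$n_units,
           params = unclass(g$params)[c("f_max", "l_opt", "l_ts",
                                        "shape_A")],
           moment_arm_coeffs = g$moment_arm_coeffs, l_ref = g$l_ref,
           constant_excitation = g$constant_excitation)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$schema, "liftload-trunk-model/1"))
    stop("not a liftload trunk-model document", call. = FALSE)
  for (f in c("gravity", "subject", "groups"))
    if (is.null(doc[[f]])) stop("model document missing field: ", f,
                                call. = FALSE)
  s <- doc$subject
  subj <- subject(s$body_mass, s$height, trunk_mass = s$trunk_mass,
                  trunk_length = s$trunk_length,
                  trunk_com_distance = s$trunk_com_distance,
                  trunk_inertia = s$trunk_inertia,
                  armhead_mass = s$armhead_mass,
                  armhead_lever = s$armhead_lever,
                  load_lever = s$load_lever)
  groups <- lapply(doc$groups, function(g) {
    for (f in c("name", "emg_channel", "role", "n_units", "params",
                "moment_arm_coeffs", "l_ref"))
      if (is.null(g[[f]])) stop("group missing field: ", f, call. = FALSE)
    mtu_group(g$name, g$emg_channel, g$role, g$n_units,
              mtu_params(g$params$f_max, g$params$l_opt, g$params$l_ts,
                         g$params$shape_A),
              unlist(g$moment_arm_coeffs), g$l_ref,
              constant_excitation = g$constant_excitation %||% NA_real_)
  })
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  trunk_model(subj, groups, gravity = doc$gravity)
}

#' Export a time series as motion-storage tabular text
#'
#' Writes the header-plus-tab-separated-rows layout used by musculoskeletal
#' tools for motion data: a small header with the series dimensions, then a
#' `time` column and one column per channel.
#'
#' @param series A [lift_ts()].
#' @param path Output file.
#' @param name Dataset name written into the header.
#' @return `path`, invisibly.
#' @export
write_motion_text <- function(series, path, name = "liftload") {
  stopifnot_ts(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", n_samples(series)),
               sprintf("nColumns=%d", ncol(series$values) + 1L),
               "endheader",
               paste(c("time", colnames(series$values)), collapse = "\t")),
             con)
  tab <- cbind(ts_time(series), series$values)
  write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
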