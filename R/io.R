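pose_csv_cols <- c("frame_id", "timestamp", "tag_id", pose_channels,
                   "detected")

#' Read / write marker-pose CSV files
#'
#' The on-disk pose format has one row per (frame, tag) with columns
#' `frame_id, timestamp, tag_id, x, y, z, yaw, pitch, roll, detected`
#' (positions in meters, angles in radians, both in the camera reference
#' frame). A (frame, tag) pair absent from the file becomes a
#' `detected = FALSE` entry with `NA` pose, so all markers share the frame
#' axis. Round-trip through [write_pose_csv()] is lossless for detected
#' samples.
#'
#' @param path File path.
#' @return `read_pose_csv()` returns a pose tibble (see
#'   [simulate_forearm()]); `write_pose_csv()` returns `path` invisibly.
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("pose file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  unknown <- setdiff(names(df), pose_csv_cols)
  if (length(unknown) > 0) {
    abort(sprintf("unknown pose column(s): %s", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(setdiff(pose_csv_cols, "detected"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing pose column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"detected" %in% names(df)) df$detected <- TRUE
  df$detected <- as.logical(df$detected)
  dup <- duplicated(df[, c("frame_id", "tag_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate (frame_id, tag_id) at row %d: (%s, %s)",
                  i, df$frame_id[i], df$tag_id[i]))
  }
  bad <- df |>
    group_by(.data$tag_id) |>
    summarise(mono = all(diff(.data$frame_id) > 0), .groups = "drop")
  if (any(!bad$mono)) {
    abort(sprintf("frame_id not strictly increasing for tag %s",
                  bad$tag_id[!bad$mono][1]))
  }
  frames <- tibble(frame_id = sort(unique(df$frame_id)))
  stamps <- distinct(df[, c("frame_id", "timestamp")])
  stamps <- stamps[!duplicated(stamps$frame_id), ]
  ids <- sort(unique(df$tag_id))
  full <- tidyr::expand_grid(frame_id = frames$frame_id, tag_id = ids)
  out <- left_join(full, select(df, -"timestamp"),
                   by = c("frame_id", "tag_id"))
  out <- left_join(out, stamps, by = "frame_id")
  out$detected[is.na(out$detected)] <- FALSE
  for (ch in pose_channels) out[[ch]][!out$detected] <- NA_real_
  out <- select(out, all_of(pose_csv_cols))
  out <- arrange(out, .data$frame_id, .data$tag_id)
  ts <- sort(unique(out$timestamp))
  fps <- if (length(ts) > 1) 1 / stats::median(diff(ts)) else NA_real_
  new_poses(out, ids, fps)
}

#' @rdname read_pose_csv
#' @param poses A pose tibble.
#' @export
write_pose_csv <- function(poses, path) {
  readr::write_csv(poses[, pose_csv_cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write stimulus CSV files
#'
#' The stimulus format has columns `frame_id`, `timestamp` and one activation
#' column per degree of freedom; every activation must lie in `[0, 1]`
#' (out-of-range values are rejected, naming the offending row, rather than
#' clipped). Column order defines DOF order.
#'
#' @param path File path.
#' @return `read_stimulus_csv()` returns a stimulus tibble (see
#'   [generate_stimulus()]); `write_stimulus_csv()` returns `path` invisibly.
#' @export
read_stimulus_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("stimulus file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame_id", "timestamp")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing stimulus column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dofs <- setdiff(names(df), need)
  if (length(dofs) == 0) abort("stimulus file has no DOF columns.")
  for (d in dofs) {
    v <- df[[d]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(sprintf("stimulus column `%s` must be numeric without NA.", d))
    }
    bad <- which(v < 0 | v > 1)
    if (length(bad) > 0) {
      abort(sprintf("stimulus value %g outside [0, 1] at row %d, column `%s`",
                    v[bad[1]], bad[1], d))
    }
  }
  if (is.unsorted(df$frame_id, strictly = TRUE)) {
    abort("stimulus frame_id must be strictly increasing.")
  }
  fps <- if (nrow(df) > 1) 1 / stats::median(diff(df$timestamp)) else NA_real_
  new_stimulus(df, dofs, fps)
}

#' @rdname read_stimulus_csv
#' @param stimulus A stimulus tibble.
#' @export
write_stimulus_csv <- function(stimulus, path) {
  readr::write_csv(as_tibble(stimulus), path, progress = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes weights and hyperparameters; for RFF models the random feature
#' frequencies and phases are regenerated from the stored `(sigma, D, seed)`
#' on read, so the file stays small and the round-trip is exact.
#'
#' @param model An `omg_rr` or `omg_rrff` model.
#' @param path Output path.
#' @return `path`, invisibly; `read_model_json()` returns the model.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "omg_rrff")) {
    list(type = "rrff", w = model$w, lambda = model$lambda,
         sigma = model$sigma, D = model$D, seed = model$seed,
         p = model$p, features = model$features,
         intercept = model$intercept)
  } else {
    list(type = "rr", w = model$w, lambda = model$lambda,
         features = model$features, intercept = model$intercept)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "rrff")) {
    draw <- rff_draw(obj$p, obj$D, obj$sigma, obj$seed)
    structure(list(w = obj$w, lambda = obj$lambda, sigma = obj$sigma,
                   D = as.integer(obj$D), seed = as.integer(obj$seed),
                   p = as.integer(obj$p), omega = draw$omega,
                   beta = draw$beta, features = obj$features,
                   intercept = isTRUE(obj$intercept)),
              class = "omg_rrff")
  } else {
    structure(list(w = obj$w, lambda = obj$lambda, features = obj$features,
                   intercept = isTRUE(obj$intercept)),
              class = "omg_rr")
  }
}
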