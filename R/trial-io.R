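#' Write a trial to the standard CSV layout
#'
#' Writes the delimited trial file used across the package: columns
#' `time_s`, one `emg_<muscle>` column per channel (lower-case muscle
#' names), and `torque_Nm` when a torque series is present. A JSON sidecar
#' (`<path>.json`) stores the per-sample segment labels and the seed so
#' that windowed metrics survive the round trip.
#'
#' @param trial A `synth_trial` (see [generate_reference_trial()]) or a
#'   list with fields `emg` (named list of [uniform_series()]), optionally
#'   `torque`, `labels`, `seed`.
#' @param path Output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(is.list(trial$emg), length(trial$emg) >= 1L)
  first <- trial$emg[[1]]
  df <- data.frame(time_s = time_points(first))
  for (nm in names(trial$emg)) {
    check_same_time_base(first, trial$emg[[nm]], "EMG channels")
    df[[paste0("emg_", tolower(nm))]] <- trial$emg[[nm]]$values
  }
  if (!is.null(trial$torque)) {
    check_same_time_base(first, trial$torque, "EMG and torque")
    df$torque_Nm <- trial$torque$values
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    seed = trial$seed,
    forward_model = trial$forward_model,
    labels = trial$labels
  )
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trial from the standard CSV layout
#'
#' Reads a trial written by [write_trial()] (or hand-made in the same
#' layout: header row with `time_s`, `emg_*` columns, optional
#' `torque_Nm`). The sampling step is taken from the median time
#' difference; the time stamps must be uniform.
#'
#' @param path CSV path.
#' @return List with `emg` (named list of [uniform_series()], upper-case
#'   muscle names), `torque` ([uniform_series()] or `NULL`), `labels`
#'   (character or `NULL`), `seed`.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("trial file needs a 'time_s' column")
  tt <- df$time_s
  if (length(tt) < 2L) stop("trial file needs at least two samples")
  dt <- stats::median(diff(tt))
  if (max(abs(diff(tt) - dt)) > 1e-6) {
    stop("'time_s' is not uniformly sampled")
  }
  emg_cols <- grep("^emg_", names(df), value = TRUE)
  if (length(emg_cols) == 0L) stop("trial file has no 'emg_*' columns")
  emg <- lapply(emg_cols, function(cl) {
    uniform_series(df[[cl]], dt = dt, t0 = tt[1])
  })
  names(emg) <- toupper(sub("^emg_", "", emg_cols))
  torque <- if ("torque_Nm" %in% names(df)) {
    uniform_series(df$torque_Nm, dt = dt, t0 = tt[1])
  }
  labels <- NULL
  seed <- NULL
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    labels <- sidecar$labels
    seed <- sidecar$seed
  }
  list(emg = emg, torque = torque, labels = labels, seed = seed)
}
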