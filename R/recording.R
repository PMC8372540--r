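#' Construct a synchronized EEG/EMG/torque recording
#'
#' Bundles the raw signals of one subject x condition together with montage
#' and task metadata. All signal matrices are channels x samples and share
#' the sample axis. Torque has two rows: shoulder-abduction (SABD) and
#' elbow-flexion (EF), in newton-metres. EEG is in microvolts, EMG in
#' millivolts.
#'
#' @param eeg numeric matrix [n_eeg_channels x n_samples]
#' @param emg numeric matrix [n_emg_channels x n_samples]
#' @param torque numeric matrix [2 x n_samples], rows SABD and EF
#' @param fs sampling rate in Hz
#' @param eeg_labels 10/20 channel names, one per EEG row
#' @param subject_id subject identifier
#' @param group "stroke" or "control"
#' @param condition "SABD20", "SABD40" or "MVT"
#' @param tested_arm "left" or "right"
#' @param lesioned_hemisphere "left", "right" or "none" (controls)
#' @param trial_boundaries list of c(start_sample, end_sample) per hold,
#'   1-based inclusive
#' @return object of class `bmc_recording`
#' @export
recording <- function(eeg, emg, torque, fs, eeg_labels,
                      subject_id, group, condition, tested_arm,
                      lesioned_hemisphere = "none",
                      trial_boundaries = list()) {
  rec <- structure(
    list(eeg = eeg, emg = emg, torque = torque, fs = fs,
         eeg_labels = eeg_labels, subject_id = subject_id, group = group,
         condition = condition, tested_arm = tested_arm,
         lesioned_hemisphere = lesioned_hemisphere,
         trial_boundaries = trial_boundaries),
    class = "bmc_recording"
  )
  validate_recording(rec)
}

#' Validate a recording's invariants
#'
#' Checks the shared sample axis, sampling rate, label validity, presence of
#' the 18 sensorimotor electrodes, and the group/lesion consistency rule
#' (lesioned_hemisphere is "none" if and only if the subject is a control).
#'
#' @param rec a `bmc_recording`
#' @return the recording, invisibly unchanged, or an error
#' @export
validate_recording <- function(rec) {
  for (f in c("eeg", "emg", "torque", "fs", "eeg_labels", "subject_id",
              "group", "condition", "tested_arm", "lesioned_hemisphere",
              "trial_boundaries")) {
    if (is.null(rec[[f]])) stop("recording is missing field '", f, "'")
  }
  if (!is.matrix(rec$eeg) || !is.matrix(rec$emg) || !is.matrix(rec$torque)) {
    stop("eeg, emg and torque must be matrices (channels x samples)")
  }
  ns <- ncol(rec$eeg)
  if (ncol(rec$emg) != ns || ncol(rec$torque) != ns) {
    stop("eeg, emg and torque must share n_samples (got ",
         ns, ", ", ncol(rec$emg), ", ", ncol(rec$torque), ")")
  }
  if (nrow(rec$torque) != 2L) stop("torque must have 2 rows (SABD, EF)")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    stop("fs must be a positive scalar")
  }
  if (length(rec$eeg_labels) != nrow(rec$eeg)) {
    stop("eeg_labels length must match the number of EEG rows")
  }
  bad <- rec$eeg_labels[!valid_1020_label(rec$eeg_labels)]
  if (length(bad) > 0L) {
    stop("invalid 10/20 labels: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(sensorimotor_labels("both"), rec$eeg_labels)
  if (length(missing) > 0L) {
    stop("recording lacks sensorimotor channels required for index ",
         "computation: ", paste(missing, collapse = ", "))
  }
  if (!rec$group %in% c("stroke", "control")) {
    stop("group must be 'stroke' or 'control'")
  }
  if (!rec$condition %in% c("SABD20", "SABD40", "MVT")) {
    stop("condition must be 'SABD20', 'SABD40' or 'MVT'")
  }
  if ((rec$lesioned_hemisphere == "none") != (rec$group == "control")) {
    stop("lesioned_hemisphere must be 'none' iff group is 'control'")
  }
  for (tb in rec$trial_boundaries) {
    if (length(tb) != 2L || tb[1] < 1L || tb[2] > ns || tb[1] > tb[2]) {
      stop("trial boundary out of range: [", tb[1], ", ", tb[2], "]")
    }
  }
  invisible(rec)
}

# current on-disk container layout version
.container_format <- "bmconn-recording-v1"

#' Write a recording container
#'
#' Serializes the recording as a self-describing hierarchical container
#' (R native serialization, version 3, uncompressed payload under gzip
#' container defaults off for byte stability). Lossless for double
#' precision; [read_recording()] reproduces the object bit-exactly.
#'
#' @param rec a validated `bmc_recording`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  payload <- unclass(rec)
  payload$.format <- .container_format
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  saveRDS(payload, con, version = 3)
  invisible(path)
}

#' Read a recording container
#'
#' @param path file written by [write_recording()]
#' @return a validated `bmc_recording`; raw sample values unchanged
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("'", path, "' is not a readable recording container: ",
         conditionMessage(e))
  })
  if (!is.list(payload) || !identical(payload$.format, .container_format)) {
    stop("'", path, "' is not a ", .container_format, " container")
  }
  payload$.format <- NULL
  rec <- structure(payload, class = "bmc_recording")
  validate_recording(rec)
  rec
}

#' @export
print.bmc_recording <- function(x, ...) {
  cat("<bmc_recording> ", x$subject_id, " [", x$group, ", ", x$condition,
      ", ", x$tested_arm, " arm]\n", sep = "")
  cat("  ", nrow(x$eeg), " EEG + ", nrow(x$emg), " EMG channels, ",
      ncol(x$eeg), " samples @ ", x$fs, " Hz, ",
      length(x$trial_boundaries), " trials\n", sep = "")
  invisible(x)
}
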