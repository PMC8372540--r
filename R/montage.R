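#' Sensorimotor electrode sets of the 10/20 montage
#'
#' The laterality and N-L indices are computed over nine sensorimotor
#' electrodes per hemisphere: FC1, FC3, FC5, C1, C3, C5, CP1, CP3, CP5 on
#' the left and FC2, FC4, FC6, C2, C4, C6, CP2, CP4, CP6 on the right.
#' By 10/20 convention odd-numbered labels lie over the left hemisphere and
#' even-numbered labels over the right.
#'
#' @param side one of "left", "right", "both"
#' @return character vector of electrode labels
#' @export
sensorimotor_labels <- function(side = c("both", "left", "right")) {
  side <- match.arg(side)
  left  <- c("FC1", "FC3", "FC5", "C1", "C3", "C5", "CP1", "CP3", "CP5")
  right <- c("FC2", "FC4", "FC6", "C2", "C4", "C6", "CP2", "CP4", "CP6")
  switch(side, left = left, right = right, both = c(left, right))
}

#' Default 32-channel montage used by the simulator
#'
#' The 18 sensorimotor electrodes plus 14 standard 10/20 sites, 32 labels in
#' total, so that every simulated recording carries the full electrode set
#' the indices require.
#'
#' @return character vector of 32 10/20 labels
#' @export
default_montage <- function() {
  c(sensorimotor_labels("both"),
    "Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "Cz",
    "Pz", "P3", "P4", "O1", "O2", "Oz")
}

# known 10/20 label stems accepted as valid channel names
valid_1020_label <- function(x) {
  grepl("^(Fp|AF|F|FT|FC|T|C|TP|CP|P|PO|O|I)(z|[0-9]|10)$", x)
}

# hemisphere from a 10/20 label: odd digit = left, even = right, z = midline
label_hemisphere <- function(labels) {
  digit <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  out <- rep("midline", length(labels))
  out[!is.na(digit) & digit %% 2L == 1L] <- "left"
  out[!is.na(digit) & digit %% 2L == 0L] <- "right"
  out
}

#' Assign contralateral/ipsilesional electrode roles
#'
#' Partitions the 18 sensorimotor electrodes into the CS set
#' (contralateral to the tested arm for controls; ipsilesional for stroke)
#' and the IS set (the opposite hemisphere). For stroke participants the
#' tested arm is the paretic arm, which is contralateral to the lesion, so
#' both rules place the CS set on the hemisphere opposite the tested arm;
#' a stroke subject whose lesion is ipsilateral to the tested arm is
#' rejected as inconsistent.
#'
#' @param eeg_labels channel labels available in the recording
#' @param tested_arm "left" or "right"
#' @param lesioned_hemisphere "left", "right" or "none"
#' @param group "stroke" or "control"
#' @return object of class `bmc_roles`: list with `cs_set` and `is_set`
#' @export
assign_laterality <- function(eeg_labels, tested_arm,
                              lesioned_hemisphere = "none",
                              group = c("control", "stroke")) {
  group <- match.arg(group)
  tested_arm <- match.arg(tested_arm, c("left", "right"))
  lesioned_hemisphere <- match.arg(lesioned_hemisphere,
                                   c("left", "right", "none"))
  need <- sensorimotor_labels("both")
  missing <- setdiff(need, eeg_labels)
  if (length(missing) > 0L) {
    stop("missing sensorimotor channels: ", paste(missing, collapse = ", "))
  }
  if (group == "control" && lesioned_hemisphere != "none") {
    stop("control subjects must have lesioned_hemisphere = 'none'")
  }
  if (group == "stroke") {
    if (lesioned_hemisphere == "none") {
      stop("stroke subjects require a lesioned hemisphere")
    }
    if (lesioned_hemisphere == tested_arm) {
      stop("inconsistent laterality: the paretic (tested) arm is ",
           "contralateral to the lesion, but tested_arm and ",
           "lesioned_hemisphere are both '", tested_arm, "'")
    }
    cs_side <- lesioned_hemisphere           # ipsilesional
  } else {
    cs_side <- if (tested_arm == "right") "left" else "right"  # contralateral
  }
  is_side <- if (cs_side == "left") "right" else "left"
  structure(
    list(cs_set = sensorimotor_labels(cs_side),
         is_set = sensorimotor_labels(is_side)),
    class = "bmc_roles"
  )
}

#' @export
print.bmc_roles <- function(x, ...) {
  cat("Laterality roles\n")
  cat("  CS (contralateral/ipsilesional):",
      paste(x$cs_set, collapse = " "), "\n")
  cat("  IS (ipsilateral/contralesional):",
      paste(x$is_set, collapse = " "), "\n")
  invisible(x)
}
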