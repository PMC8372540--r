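#' Per-channel signal power as epoch-averaged RMS
#'
#' Estimates the task-related signal power of each channel as the average
#' over epochs of the epoch root-mean-square amplitude.
#'
#' @param e a `bmc_epochs` object with at least one epoch
#' @return named numeric vector, one value per channel
#' @export
channel_power <- function(e) {
  stopifnot(inherits(e, "bmc_epochs"))
  if (dim(e$data)[1] < 1L) stop("channel_power requires at least one epoch")
  rms <- sqrt(apply(e$data^2, c(1L, 2L), mean))   # epochs x channels
  out <- colMeans(rms)
  names(out) <- e$labels
  out
}

#' Laterality Index of EEG power
#'
#' LI = (CS - IS) / (CS + IS), where CS is the summed channel power over
#' the contralateral/ipsilesional sensorimotor electrodes and IS the sum
#' over the ipsilateral/contralesional set. LI > 0 indicates
#' contralateral/ipsilesional dominance, LI < 0 the reverse.
#'
#' @param power named per-channel power vector from [channel_power()]
#' @param roles a `bmc_roles` object from [assign_laterality()]
#' @return scalar in [-1, 1]
#' @export
laterality_index <- function(power, roles) {
  stopifnot(inherits(roles, "bmc_roles"))
  need <- c(roles$cs_set, roles$is_set)
  missing <- setdiff(need, names(power))
  if (length(missing) > 0L) {
    stop("power is missing channels: ", paste(missing, collapse = ", "))
  }
  cs <- sum(power[roles$cs_set])
  is_ <- sum(power[roles$is_set])
  if (cs + is_ <= 0) stop("total sensorimotor power must be positive")
  (cs - is_) / (cs + is_)
}

#' Nonlinear-over-linear (N-L) index
#'
#' N-L = (SN - SL) / (SN + SL), contrasting aggregated nonlinear against
#' linear cross-spectral connectivity over sensorimotor electrodes;
#' positive values indicate nonlinear dominance. In the literal mode
#' (default) SL aggregates linear-pair connectivity over the
#' contralateral/ipsilesional electrode set and SN nonlinear-pair
#' connectivity over the ipsilateral/contralesional set; the pooled mode
#' aggregates both over all 18 sensorimotor electrodes, removing the
#' hemisphere split for sensitivity analysis. Aggregation is "sum" (as the
#' index is defined) or "mean" (per channel x pair average), the latter
#' controlling the size imbalance between the large nonlinear and small
#' linear pair sets.
#'
#' @param cmap a `bmc_cmap` covering the 18 sensorimotor channels
#' @param roles a `bmc_roles` object
#' @param mode "literal" or "pooled"
#' @param aggregation "sum" or "mean"
#' @return scalar in [-1, 1], or NA when SN + SL = 0
#' @export
nl_index <- function(cmap, roles, mode = c("literal", "pooled"),
                     aggregation = c("sum", "mean")) {
  stopifnot(inherits(cmap, "bmc_cmap"), inherits(roles, "bmc_roles"))
  mode <- match.arg(mode)
  aggregation <- match.arg(aggregation)
  all_sm <- c(roles$cs_set, roles$is_set)
  missing <- setdiff(all_sm, cmap$labels)
  if (length(missing) > 0L) {
    stop("connectivity map is missing channels: ",
         paste(missing, collapse = ", "))
  }
  agg <- if (aggregation == "sum") {
    function(v) sum(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  lin <- cmap$pairs$kind == "linear"
  nl <- cmap$pairs$kind == "nonlinear"
  rows_l <- match(if (mode == "literal") roles$cs_set else all_sm,
                  cmap$labels)
  rows_n <- match(if (mode == "literal") roles$is_set else all_sm,
                  cmap$labels)
  sl <- agg(cmap$values[rows_l, lin])
  sn <- agg(cmap$values[rows_n, nl])
  if (!is.finite(sl) || !is.finite(sn) || sn + sl == 0) return(NA_real_)
  (sn - sl) / (sn + sl)
}

#' Maximum voluntary torque with the consistency rule
#'
#' The MVT is the mean of three continuous maximal trials, accepted only if
#' their spread (max - min) does not exceed 10% of the mean. An
#' inconsistent triplet signals that the trials must be repeated; it is
#' returned as NA with a warning.
#'
#' @param peaks numeric vector of exactly three positive peak torques, N*m
#' @return the mean torque, or NA (with a warning) when inconsistent
#' @export
mvt <- function(peaks) {
  if (length(peaks) != 3L) stop("mvt requires exactly 3 trial peaks")
  if (any(!is.finite(peaks)) || any(peaks <= 0)) {
    stop("trial peak torques must be positive")
  }
  m <- mean(peaks)
  if (max(peaks) - min(peaks) > 0.10 * m) {
    warning("inconsistent MVT trials (spread ",
            signif(max(peaks) - min(peaks), 4), " > 10% of mean ",
            signif(m, 4), "); repeat the trials")
    return(NA_real_)
  }
  m
}

#' MVT estimates from a maximum-effort recording
#'
#' Extracts the per-trial peak torque of each axis over the recording's
#' three maximal holds and applies the [mvt()] consistency rule.
#'
#' @param rec the MVT-condition `bmc_recording`
#' @return list with `sabd` and `ef` MVT values (N*m) and the per-trial
#'   peak vectors `sabd_peaks`, `ef_peaks`
#' @export
mvt_from_recording <- function(rec) {
  validate_recording(rec)
  if (length(rec$trial_boundaries) != 3L) {
    stop("MVT estimation expects exactly 3 maximal trials, got ",
         length(rec$trial_boundaries))
  }
  peaks <- function(row) {
    vapply(rec$trial_boundaries,
           function(tb) max(rec$torque[row, tb[1]:tb[2]]), numeric(1))
  }
  sp <- peaks(1L)
  ep <- peaks(2L)
  list(sabd = mvt(sp), ef = mvt(ep), sabd_peaks = sp, ef_peaks = ep)
}

#' Flexion-synergy ratio
#'
#' Quantifies the involuntary synergic elbow-flexion torque generated
#' during the shoulder-abduction holds, normalized to the elbow-flexion
#' MVT: the mean EF torque over all hold windows divided by `ef_mvt`.
#'
#' @param ef_trace elbow-flexion torque trace, N*m
#' @param trial_boundaries list of c(start, end) sample indices per hold
#' @param ef_mvt elbow-flexion maximum voluntary torque, N*m (> 0)
#' @return non-negative scalar (fraction of EF MVT)
#' @export
flexion_synergy <- function(ef_trace, trial_boundaries, ef_mvt) {
  if (!is.numeric(ef_mvt) || length(ef_mvt) != 1L || !is.finite(ef_mvt) ||
      ef_mvt <= 0) {
    stop("ef_mvt must be a positive scalar")
  }
  if (length(trial_boundaries) == 0L) stop("no hold windows defined")
  idx <- unlist(lapply(trial_boundaries, function(tb) tb[1]:tb[2]))
  mean(ef_trace[idx]) / ef_mvt
}
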