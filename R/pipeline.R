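#' Restrict an epoch set to a subset of channels
#'
#' @param e a `bmc_epochs`
#' @param labels channel labels to keep, in the order given
#' @return a `bmc_epochs` over the selected channels
#' @export
select_channels <- function(e, labels) {
  stopifnot(inherits(e, "bmc_epochs"))
  idx <- match(labels, e$labels)
  if (anyNA(idx)) {
    stop("unknown channels: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  e$data <- e$data[, idx, , drop = FALSE]
  e$labels <- e$labels[idx]
  e
}

#' Run the full analysis for one subject
#'
#' From the subject's MVT and task recordings: estimates the SABD and EF
#' maximum voluntary torques and the peak-EMG normalization reference from
#' the MVT recording, preprocesses each task recording, computes channel
#' power, the Laterality Index, the CSC connectivity map over the 18
#' sensorimotor electrodes, the N-L index, and the flexion-synergy ratio.
#'
#' @param recs list with elements `MVT`, `SABD20`, `SABD40`
#'   (`bmc_recording`s of one subject)
#' @param cfg a [pipeline_config()]
#' @param keep_cmaps keep the per-condition connectivity maps in the
#'   result (needed for the long-format connectivity table)
#' @return list with `indices` (one row per task condition: subject,
#'   group, condition, li, nl, fs_ratio, n_epochs), `mvt`, `roles`, and
#'   optionally `cmaps`
#' @export
run_subject <- function(recs, cfg = pipeline_config(), keep_cmaps = FALSE) {
  stopifnot(all(c("MVT", "SABD20", "SABD40") %in% names(recs)))
  peak <- emg_peak_from_mvt(recs$MVT, cfg)
  mvts <- mvt_from_recording(recs$MVT)
  if (is.na(mvts$ef)) stop("inconsistent EF MVT trials for subject ",
                           recs$MVT$subject_id)
  ref <- recs$SABD20
  roles <- assign_laterality(ref$eeg_labels, ref$tested_arm,
                             ref$lesioned_hemisphere, ref$group)
  pairs <- enumerate_pairs(cfg$eeg_freq_range, cfg$emg_freq_range)
  rows <- list()
  cmaps <- list()
  for (cond in c("SABD20", "SABD40")) {
    rec <- recs[[cond]]
    pp <- preprocess_recording(rec, peak, cfg)
    power <- channel_power(pp$eeg)
    li <- laterality_index(power, roles)
    sm <- select_channels(pp$eeg, sensorimotor_labels("both"))
    sx <- fourier_coefficients(sm, cfg$taper)
    sy <- fourier_coefficients(pp$emg, cfg$taper)
    cmap <- csc_map(sx, sy, pairs)
    nl <- nl_index(cmap, roles, cfg$nl_index_mode, cfg$nl_aggregation)
    fs_ratio <- flexion_synergy(rec$torque[2L, ], rec$trial_boundaries,
                                mvts$ef)
    rows[[cond]] <- data.frame(
      subject = rec$subject_id, group = rec$group, condition = cond,
      li = li, nl = nl, fs_ratio = fs_ratio,
      n_epochs = dim(pp$eeg$data)[1]
    )
    if (keep_cmaps) cmaps[[cond]] <- cmap
  }
  out <- list(indices = do.call(rbind, c(rows, make.row.names = FALSE)),
              mvt = mvts, roles = roles)
  if (keep_cmaps) out$cmaps <- cmaps
  out
}

#' Run the full analysis over a simulated or loaded cohort
#'
#' @param subjects nested list as produced by [simulate_cohort()]
#' @param cfg a [pipeline_config()]
#' @param verbose print one line per subject
#' @return list with `indices` (cohort index table) and `stats` (the group
#'   comparison table from [cohort_stats()])
#' @export
run_cohort <- function(subjects, cfg = pipeline_config(), verbose = FALSE) {
  tabs <- lapply(subjects, function(s) {
    if (verbose) message("processing ", s$id, " (", s$group, ")")
    run_subject(s$recordings, cfg)$indices
  })
  indices <- do.call(rbind, c(tabs, make.row.names = FALSE))
  list(indices = indices, stats = cohort_stats(indices, cfg$alpha))
}

# one tidy row per test report
report_row <- function(measure, comparison, r) {
  data.frame(measure = measure, comparison = comparison, test = r$test,
             statistic = r$statistic, df = r$df, p = r$p, tail = r$tail,
             paired = r$paired, significant = r$decision)
}

#' Group-comparison stage over the cohort index table
#'
#' Reproduces the statistical design of the study: within-group paired
#' comparisons of the 40% versus 20% load (one-tailed for stroke, with the
#' hypothesized directions nl up, li down, flexion synergy up; two-tailed
#' for controls) and one-tailed two-sample comparisons of stroke versus
#' control at each load (nl and flexion synergy higher in stroke, li
#' lower). No multiple-testing correction is applied.
#'
#' @param indices cohort index table from [run_cohort()]
#' @param alpha significance level
#' @return list with `table` (tidy data.frame of all tests) and `reports`
#'   (named list of `bmc_test` objects)
#' @export
cohort_stats <- function(indices, alpha = 0.05) {
  grab <- function(group, condition, measure) {
    sub <- indices[indices$group == group & indices$condition == condition, ]
    sub <- sub[order(sub$subject), ]
    sub[[measure]]
  }
  directions <- c(nl = "greater", li = "less", fs_ratio = "greater")
  reports <- list()
  rows <- list()
  for (measure in names(directions)) {
    for (group in c("stroke", "control")) {
      r <- compare_conditions(grab(group, "SABD20", measure),
                              grab(group, "SABD40", measure),
                              group = group,
                              direction = directions[[measure]],
                              alpha = alpha)
      key <- paste(measure, group, "40v20", sep = "_")
      reports[[key]] <- r
      rows[[key]] <- report_row(measure, paste0(group, ": SABD40 vs SABD20"),
                                r)
    }
    for (condition in c("SABD20", "SABD40")) {
      r <- compare_groups(grab("stroke", condition, measure),
                          grab("control", condition, measure),
                          direction = directions[[measure]],
                          tail = "one", alpha = alpha)
      key <- paste(measure, "stroke_v_control", condition, sep = "_")
      reports[[key]] <- r
      rows[[key]] <- report_row(measure,
                                paste0("stroke vs control @ ", condition), r)
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       reports = reports)
}

#' Long-format connectivity table
#'
#' Flattens a connectivity map into the long TSV layout used by the
#' analysis scripts: one row per channel x frequency pair.
#'
#' @param cmap a `bmc_cmap`
#' @param subject,group,condition metadata columns
#' @return data.frame with columns subject, group, condition, channel,
#'   f_x, f_y, n, m, kind, csc
#' @export
connectivity_table <- function(cmap, subject, group, condition) {
  stopifnot(inherits(cmap, "bmc_cmap"))
  n_ch <- length(cmap$labels)
  n_pr <- nrow(cmap$pairs)
  data.frame(
    subject = subject, group = group, condition = condition,
    channel = rep(cmap$labels, times = n_pr),
    f_x = rep(cmap$pairs$f_x, each = n_ch),
    f_y = rep(cmap$pairs$f_y, each = n_ch),
    n = rep(cmap$pairs$n, each = n_ch),
    m = rep(cmap$pairs$m, each = n_ch),
    kind = rep(cmap$pairs$kind, each = n_ch),
    csc = as.vector(cmap$values)
  )
}

#' Write cohort outputs
#'
#' Writes the index table as TSV and the statistics stage as both TSV and
#' JSON under `dir`.
#'
#' @param result list from [run_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_cohort_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    indices = file.path(dir, "indices.tsv"),
    stats_tsv = file.path(dir, "stats.tsv"),
    stats_json = file.path(dir, "stats.json")
  )
  utils::write.table(result$indices, paths["indices"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$stats$table, paths["stats_tsv"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(result$stats$reports, function(r) {
      r <- unclass(r)
      r[c("test", "statistic", "df", "p", "tail", "paired", "decision")]
    }),
    paths["stats_json"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
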