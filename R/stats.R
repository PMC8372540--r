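#' Assumption gate: normality and homoscedasticity
#'
#' Runs Shapiro-Wilk on each sample and, for two or more samples, Levene's
#' F-test for homoscedasticity, and routes the downstream comparison:
#' parametric (pooled t) when the variance gate passes, Welch otherwise.
#' Constant samples are flagged degenerate (the gates are undefined on
#' them) and routed parametric.
#'
#' @param samples list of numeric vectors, each of length >= 3
#' @param alpha gate significance level
#' @return list with `normality_p` (per sample), `levene_p`,
#'   `homoscedastic`, `normal`, `degenerate`, `route`
#'   ("parametric"/"welch")
#' @export
assumption_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  if (any(vapply(samples, length, integer(1)) < 3L)) {
    stop("each sample must have at least 3 observations")
  }
  degenerate <- any(vapply(samples, function(s) stats::sd(s) == 0,
                           logical(1)))
  normality_p <- vapply(samples, function(s) {
    if (stats::sd(s) == 0) NA_real_ else stats::shapiro.test(s)$p.value
  }, numeric(1))
  levene_p <- NA_real_
  if (length(samples) >= 2L && !degenerate) {
    y <- unlist(samples)
    g <- factor(rep(seq_along(samples), lengths(samples)))
    levene_p <- car::leveneTest(y, g)[1, "Pr(>F)"]
  }
  homoscedastic <- is.na(levene_p) || levene_p >= alpha
  normal <- all(is.na(normality_p) | normality_p >= alpha)
  list(normality_p = normality_p, levene_p = levene_p,
       homoscedastic = homoscedastic, normal = normal,
       degenerate = degenerate,
       route = if (homoscedastic) "parametric" else "welch")
}

# assemble the standard report structure shared by both comparisons
test_report <- function(test, statistic, df, p, tail, paired, alpha,
                        gate) {
  structure(
    list(test = test, statistic = unname(statistic), df = unname(df),
         p = unname(p), tail = tail, paired = paired, alpha = alpha,
         normality_p = gate$normality_p, levene_p = gate$levene_p,
         decision = is.finite(p) && p < alpha),
    class = "bmc_test"
  )
}

#' @export
print.bmc_test <- function(x, ...) {
  cat("<bmc_test> ", x$test, ": t = ", signif(x$statistic, 4),
      ", df = ", signif(x$df, 4), ", ", x$tail, "-tailed p = ",
      signif(x$p, 4), if (x$decision) " *" else "", "\n", sep = "")
  invisible(x)
}

# paired t on differences with explicit handling of zero-variance
# differences so degenerate certainty never yields NaN
paired_t <- function(d, alternative) {
  n <- length(d)
  if (stats::sd(d) == 0) {
    md <- mean(d)
    p <- if (md == 0) {
      if (alternative == "two.sided") 1 else 0.5
    } else if (alternative == "two.sided") {
      0
    } else if ((alternative == "greater") == (md > 0)) 0 else 1
    return(list(statistic = if (md == 0) 0 else sign(md) * Inf,
                df = n - 1, p = p))
  }
  tt <- stats::t.test(d, alternative = alternative)
  list(statistic = tt$statistic, df = tt$parameter, p = tt$p.value)
}

#' Compare task loads within a group (paired)
#'
#' Paired t-test of the 40% versus 20% load conditions. For the stroke
#' group the hypothesis is directional (one-tailed, direction given by
#' `direction` for x40 relative to x20); for controls the test is
#' two-tailed. Homoscedasticity is not required for a paired t; if the
#' gate nevertheless fails, a warning is logged and the paired test
#' proceeds.
#'
#' @param x20,x40 paired samples (same subjects, equal length >= 3)
#' @param group "stroke" or "control"
#' @param direction "greater" or "less": hypothesized direction of x40
#'   relative to x20 (used for the stroke one-tailed test)
#' @param alpha significance level
#' @return a `bmc_test` report
#' @export
compare_conditions <- function(x20, x40, group = c("stroke", "control"),
                               direction = c("greater", "less"),
                               alpha = 0.05) {
  group <- match.arg(group)
  direction <- match.arg(direction)
  if (length(x20) != length(x40)) stop("paired samples must have equal length")
  if (length(x20) < 3L) stop("paired comparison requires n >= 3")
  gate <- assumption_gate(list(x20, x40), alpha)
  if (!gate$homoscedastic) {
    warning("heteroscedastic paired samples (Levene p = ",
            signif(gate$levene_p, 3),
            "); the paired t-test does not require homoscedasticity")
  }
  tail <- if (group == "stroke") "one" else "two"
  alternative <- if (tail == "one") direction else "two.sided"
  res <- paired_t(x40 - x20, alternative)
  test_report(paste0("paired t (", group, ", ", tail, "-tailed)"),
              res$statistic, res$df, res$p, tail, paired = TRUE, alpha,
              gate)
}

#' Compare stroke versus control groups (two-sample)
#'
#' One-tailed two-sample t-test of the stroke group against controls,
#' pooled-variance when the Levene gate passes and Welch otherwise.
#'
#' @param stroke,control independent samples, each n >= 3
#' @param direction "greater" or "less": hypothesized direction of stroke
#'   relative to control
#' @param tail "one" or "two"
#' @param alpha significance level
#' @return a `bmc_test` report
#' @export
compare_groups <- function(stroke, control,
                           direction = c("greater", "less"),
                           tail = c("one", "two"), alpha = 0.05) {
  direction <- match.arg(direction)
  tail <- match.arg(tail)
  if (length(stroke) < 3L || length(control) < 3L) {
    stop("each group requires n >= 3")
  }
  gate <- assumption_gate(list(stroke, control), alpha)
  alternative <- if (tail == "one") direction else "two.sided"
  if (gate$degenerate && stats::sd(stroke) == 0 &&
      stats::sd(control) == 0) {
    md <- mean(stroke) - mean(control)
    p <- if (md == 0) {
      if (alternative == "two.sided") 1 else 0.5
    } else if (alternative == "two.sided") {
      0
    } else if ((alternative == "greater") == (md > 0)) 0 else 1
    return(test_report("two-sample t (degenerate)",
                       if (md == 0) 0 else sign(md) * Inf,
                       length(stroke) + length(control) - 2, p, tail,
                       paired = FALSE, alpha, gate))
  }
  tt <- stats::t.test(stroke, control, alternative = alternative,
                      var.equal = gate$route == "parametric")
  name <- if (gate$route == "welch") "Welch two-sample t" else
    "pooled two-sample t"
  test_report(paste0(name, " (", tail, "-tailed)"), tt$statistic,
              tt$parameter, tt$p.value, tail, paired = FALSE, alpha, gate)
}
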