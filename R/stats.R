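# Statistical layer for the sweep: one-way ANOVA across weight conditions
# per metric, with Tukey post-hoc comparisons against the control condition.

#' One-way ANOVA across conditions
#'
#' Classical k-group between/within decomposition (`F = MSB/MSW`, df
#' `k - 1` and `N - k`), computed through [stats::aov()]. Also reports the
#' per-group means and standard errors of the mean used for plotting
#' mean +/- s.e.m. profiles.
#'
#' @param values numeric metric values.
#' @param groups condition labels, same length as `values`; at least two
#'   groups with at least two values each.
#' @return List of class `"anova_result"`: `F`, `df` (numerator,
#'   denominator), `p`, `means`, `sem`, `n`, and `degenerate` (`TRUE` when
#'   every group has zero within-variance, in which case `F`/`p` are not
#'   meaningful and a warning is issued).
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  n <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n < 2)) stop("every group needs at least 2 values", call. = FALSE)
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  within_var <- tapply(values, groups, stats::var)
  degenerate <- all(within_var == 0)
  if (degenerate)
    warning("zero within-group variance in every group; F is degenerate",
            call. = FALSE)
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  structure(list(
    F = tab["groups", "F value"],
    df = c(tab["groups", "Df"], tab["Residuals", "Df"]),
    p = tab["groups", "Pr(>F)"],
    means = means, sem = sds / sqrt(as.numeric(n)), n = as.numeric(n),
    degenerate = degenerate, fit = fit
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p,
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  tab <- data.frame(mean = as.numeric(x$means), sem = as.numeric(x$sem),
                    n = x$n, row.names = names(x$means))
  print(tab)
  invisible(x)
}

#' Tukey HSD comparisons against the control condition
#'
#' Tukey's honestly-significant-difference post-hoc test (Tukey-Kramer for
#' unbalanced groups, via [stats::TukeyHSD()]), reduced to the pairwise
#' comparisons of every condition against the control. Significance is
#' flagged at adjusted p < `alpha`.
#'
#' @param values numeric metric values.
#' @param groups condition labels.
#' @param control the control group label; must be present in `groups`.
#' @param alpha significance level (default 0.05).
#' @return data.frame `group, diff, lwr, upr, p_adj, significant` with one
#'   row per non-control group; `diff` is group mean minus control mean.
#' @export
tukey_hsd <- function(values, groups, control, alpha = 0.05) {
  groups <- factor(groups)
  if (!control %in% levels(groups))
    stop("control label '", control, "' not present in groups", call. = FALSE)
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  cmp <- rownames(tk)
  parts <- strsplit(cmp, "-", fixed = TRUE)
  keep <- vapply(parts, function(x) control %in% x, TRUE)
  tk <- tk[keep, , drop = FALSE]
  parts <- parts[keep]
  other <- vapply(parts, function(x) setdiff(x, control)[1], "")
  # TukeyHSD reports "b-a": flip sign when control is the first element
  sign_flip <- vapply(parts, function(x) x[1] == control, TRUE)
  est <- ifelse(sign_flip, -tk[, "diff"], tk[, "diff"])
  lwr <- ifelse(sign_flip, -tk[, "upr"], tk[, "lwr"])
  upr <- ifelse(sign_flip, -tk[, "lwr"], tk[, "upr"])
  data.frame(group = other, diff = est, lwr = lwr, upr = upr,
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' ANOVA + Tukey summary for one metric of a sweep
#'
#' Convenience wrapper running [one_way_anova()] across the scale conditions
#' of one pathway in a [run_sweep()] result, plus [tukey_hsd()] against the
#' control scale.
#'
#' @param sweep data.frame from [run_sweep()] / [run_condition()].
#' @param metric name of the metric column (e.g. `"pct_REM"`).
#' @param pathway pathway to condition on.
#' @param control_scale the control scale factor (default 1).
#' @return List with elements `anova` and `tukey`.
#' @export
sweep_stats <- function(sweep, metric, pathway, control_scale = 1) {
  d <- sweep[sweep$pathway == pathway & is.finite(sweep[[metric]]), ]
  if (nrow(d) == 0) stop("no finite values for this pathway/metric", call. = FALSE)
  grp <- factor(d$scale)
  list(anova = one_way_anova(d[[metric]], grp),
       tukey = tukey_hsd(d[[metric]], grp, control = as.character(control_scale)))
}
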