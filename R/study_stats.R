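#' Classify subjects into low- and high-BAT groups
#'
#' Applies the study's responder rule to per-subject percent changes in
#' total heat output under stimulation: the cutoff is the cohort mean plus
#' one standard error of the mean (sample SD with n-1 denominator over
#' sqrt(n)), and a subject is high-BAT iff their percent change is strictly
#' greater than the cutoff.
#'
#' @param pct_changes numeric vector of percent changes (n >= 2, finite).
#' @return object of class `group_assignment`: list with `cutoff_pct`,
#'   `labels` (factor, levels `low-BAT`, `high-BAT`), `mean_pct`, `se_pct`,
#'   `n_high`, `n_low`.
#' @export
classify_groups <- function(pct_changes) {
  pct_changes <- as.numeric(pct_changes)
  if (length(pct_changes) < 2L)
    stop("need at least 2 subjects (SE undefined otherwise)", call. = FALSE)
  if (!all(is.finite(pct_changes)))
    stop("percent changes must be finite", call. = FALSE)
  m <- mean(pct_changes)
  se <- stats::sd(pct_changes) / sqrt(length(pct_changes))
  cutoff <- m + se
  labels <- factor(ifelse(pct_changes > cutoff, "high-BAT", "low-BAT"),
                   levels = c("low-BAT", "high-BAT"))
  structure(list(cutoff_pct = cutoff, labels = labels, mean_pct = m,
                 se_pct = se, n_high = sum(labels == "high-BAT"),
                 n_low = sum(labels == "low-BAT")),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> cutoff %.2f%% (mean %.2f + SE %.2f): %d high-BAT, %d low-BAT\n",
              x$cutoff_pct, x$mean_pct, x$se_pct, x$n_high, x$n_low))
  invisible(x)
}

#' Paired (or unpaired) t test on heat-output measurements
#'
#' Thin wrapper over [stats::t.test()] adding the degenerate-input contract:
#' all-zero-variance differences (e.g. identical paired lists) raise an
#' error rather than returning an undefined statistic.
#'
#' @param a,b numeric vectors; equal length required when `paired`.
#' @param paired logical (default TRUE).
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t_test <- function(a, b, paired = TRUE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired vectors must match in length", call. = FALSE)
    if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
    d <- a - b
    if (stats::sd(d) == 0)
      stop("differences have zero variance; t statistic undefined", call. = FALSE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("both samples have zero variance; t statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_diff = if (paired) mean(a - b) else mean(a) - mean(b))
}

#' Pearson correlation between a covariate and heat output
#'
#' Thin wrapper over [stats::cor.test()] (Pearson, two-sided) with explicit
#' zero-variance and length guards, as used for the fasting-glucose and
#' basal-metabolic-rate associations.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must match in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Study-level summary of a subject table
#'
#' Applies the responder rule to a per-subject table of baseline and
#' stimulated total heat outputs and summarises both groups
#' (mean +/- SE of baseline, stimulated, and percent change). When the
#' table lacks a `pct_change` column it is derived via
#' [percent_change_heat()].
#'
#' @param table data.frame with columns `subject`, `baseline_w`,
#'   `stimulated_w` and optionally `pct_change`.
#' @return list with `assignment` (a [classify_groups()] result), `groups`
#'   (data.frame of per-group n, mean and SE), `table` (input plus
#'   `pct_change` and `group` columns).
#' @export
study_summary <- function(table) {
  need <- c("subject", "baseline_w", "stimulated_w")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!"pct_change" %in% names(table))
    table$pct_change <- mapply(percent_change_heat,
                               table$baseline_w, table$stimulated_w)
  asg <- classify_groups(table$pct_change)
  table$group <- asg$labels
  se <- function(v) stats::sd(v) / sqrt(length(v))
  groups <- do.call(rbind, lapply(levels(asg$labels), function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(sub),
               baseline_mean_w = mean(sub$baseline_w),
               baseline_se_w = if (nrow(sub) > 1L) se(sub$baseline_w) else NA_real_,
               stimulated_mean_w = mean(sub$stimulated_w),
               stimulated_se_w = if (nrow(sub) > 1L) se(sub$stimulated_w) else NA_real_,
               pct_change_mean = mean(sub$pct_change),
               pct_change_se = if (nrow(sub) > 1L) se(sub$pct_change) else NA_real_)
  }))
  list(assignment = asg, groups = groups, table = table)
}

#' Per-timepoint baseline-adjusted paired contrasts
#'
#' For longitudinal two-condition data (e.g. active compound vs placebo
#' measured at several timepoints in the same subjects), computes at each
#' timepoint the paired t test of the baseline-adjusted changes
#' `(value - baseline)` between conditions. A transparent per-timepoint
#' alternative to a fitted longitudinal structural model, which is outside
#' this package's scope.
#'
#' @param long data.frame with columns `subject`, `condition` (two levels),
#'   `time`, `value`, `baseline`.
#' @return data.frame with one row per timepoint: `time`, `n`, `mean_diff`
#'   (condition 2 minus condition 1 of baseline-adjusted changes), `t`,
#'   `df`, `p_value`.
#' @export
timepoint_contrasts <- function(long) {
  need <- c("subject", "condition", "time", "value", "baseline")
  if (!all(need %in% names(long)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  conds <- sort(unique(as.character(long$condition)))
  if (length(conds) != 2L) stop("exactly two conditions required", call. = FALSE)
  long$adj <- long$value - long$baseline
  out <- lapply(sort(unique(long$time)), function(tp) {
    sub <- long[long$time == tp, , drop = FALSE]
    a <- sub[sub$condition == conds[1L], c("subject", "adj")]
    b <- sub[sub$condition == conds[2L], c("subject", "adj")]
    common <- intersect(a$subject, b$subject)
    if (length(common) < 2L) return(NULL)
    av <- a$adj[match(common, a$subject)]
    bv <- b$adj[match(common, b$subject)]
    tt <- paired_t_test(bv, av)
    data.frame(time = tp, n = length(common), mean_diff = tt$mean_diff,
               t = tt$t, df = tt$df, p_value = tt$p_value)
  })
  do.call(rbind, out)
}
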