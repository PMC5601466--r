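# Z-rule comparison of rupture-force sets and tilt-based ROC
# classification of unfolding pathways.

#' Z-rule comparison of two rupture-force samples
#'
#' Two systems differ significantly when the difference in means is at
#' least twice the combined standard error, 2 sqrt(e1^2 + e2^2), with
#' e1, e2 the standard errors of the mean (sample sd, n-1 denominator).
#'
#' @param a,b numeric force samples (pN), each of length >= 2.
#' @param labels length-2 character labels.
#' @return A `mean_comparison`: `means`, `se`, `z_margin` (pN),
#'   `difference` (mean(a) - mean(b)) and the `significant` verdict.
#' @export
z_compare <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 values")
  se <- c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b)))
  means <- c(mean(a), mean(b))
  margin <- 2 * sqrt(sum(se^2))
  structure(list(labels = labels, means = means, se = se,
                 z_margin = margin, difference = means[1] - means[2],
                 significant = abs(means[1] - means[2]) >= margin),
            class = "mean_comparison")
}

#' @export
print.mean_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %.1f +/- %.1f pN vs %s: %.1f +/- %.1f pN; |diff| %.1f %s margin %.1f -> %s\n",
    x$labels[1], x$means[1], x$se[1], x$labels[2], x$means[2], x$se[2],
    abs(x$difference), if (x$significant) ">=" else "<", x$z_margin,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Multi-velocity Z-rule verdict
#'
#' Two systems are called significantly different only when the per-velocity
#' Z-rule holds at every one of the requested velocities (the fastest three
#' in the original design, where 10 replicas per system are available).
#'
#' @param table_a,table_b rupture tables with `F_r_pN` and
#'   `v_pull_nm_per_ns` columns.
#' @param velocities velocities (nm/ns) at which the rule must hold.
#' @param labels system labels.
#' @return List with `per_velocity` (list of `mean_comparison`) and
#'   overall `significant`.
#' @export
z_compare_velocities <- function(table_a, table_b, velocities,
                                 labels = c("a", "b")) {
  per <- lapply(velocities, function(v) {
    z_compare(table_a$F_r_pN[table_a$v_pull_nm_per_ns == v],
              table_b$F_r_pN[table_b$v_pull_nm_per_ns == v],
              labels = labels)
  })
  names(per) <- as.character(velocities)
  list(per_velocity = per,
       significant = all(vapply(per, `[[`, logical(1), "significant")))
}

#' ROC curve of a score against a binary label
#'
#' Threshold sweep over the unique scores (plus sentinels), recording the
#' true- and false-positive rates of the rule score >= threshold. AUC by
#' the trapezoid rule, which equals the Mann-Whitney U statistic scaled to
#' [0, 1] with ties counted one half.
#'
#' @param scores numeric scores (here: maximum tilt angle in degrees).
#' @param labels logical or 0/1; `TRUE`/1 is the positive class (here: low
#'   second-peak rupture force, predicted by high tilt).
#' @return A `roc_curve`: `fpr`, `tpr` (per threshold, sorted), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(threshold = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.3f\n",
              length(x$threshold), x$auc))
  invisible(x)
}

#' Label trajectories as high- or low-force unfolders by peak count
#'
#' A force profile featuring at least three distinct peaks (by the
#' prominence rule of [count_peaks()]) unfolds at high force in the second
#' peak; a profile lacking the middle peak unfolds at low force.
#'
#' @param smoothed_traces list of `smoothed_trace` objects, smoothed
#'   consistently.
#' @param prominence,min_separation passed to [count_peaks()].
#' @return Character vector `"high"`/`"low"`, one per trace.
#' @export
label_high_low <- function(smoothed_traces, prominence = 100,
                           min_separation = 5) {
  vapply(smoothed_traces, function(st) {
    if (count_peaks(st, prominence, min_separation)$n >= 3L) "high" else "low"
  }, character(1))
}
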