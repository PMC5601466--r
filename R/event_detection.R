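# Unfolding-event detection from contact-area series, using IQR-based
# equilibrium baselines.

#' Equilibrium contact-area baseline
#'
#' Computes the lower outlier fence of the equilibrium contact-area
#' distribution, CA_low = Q1 - 1.5 (Q3 - Q1), with Q1/Q3 the first and
#' third quartiles over equilibrium frames (type-7 linear-interpolation
#' quantiles).
#'
#' @param equilibrium_ca numeric vector of contact areas (nm^2) from the
#'   equilibrium segment; at least 4 samples.
#' @param pair label carried through to the baseline object.
#' @return An `equilibrium_baseline` with `q1`, `q3`, `ca_low` (nm^2).
#' @export
baseline <- function(equilibrium_ca, pair = "") {
  x <- as.numeric(equilibrium_ca)
  if (length(x) < 4L) stop("need >= 4 equilibrium samples, got ", length(x))
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(pair = pair, q1 = q[1], q3 = q[2],
                 ca_low = q[1] - 1.5 * (q[2] - q[1])),
            class = "equilibrium_baseline")
}

#' @export
print.equilibrium_baseline <- function(x, ...) {
  cat(sprintf("baseline '%s': Q1 = %.3f, Q3 = %.3f, CA_low = %.3f nm^2\n",
              x$pair, x$q1, x$q3, x$ca_low))
  invisible(x)
}

# End threshold: the numerical accuracy floor of the contact-area analysis.
CA_END_NM2 <- 0.002

#' Detect an unfolding event in a contact-area series
#'
#' The event starts at the elongation of the first frame where the contact
#' area drops strictly below CA_low / 2 and ends at the first subsequent
#' frame where it drops below 0.002 nm^2 (the numerical accuracy floor).
#' First-crossing semantics, no re-arming: at most one event per feature.
#' If the start threshold would be non-positive (very wide equilibrium IQR)
#' it is clamped to the 0.002 nm^2 floor with a warning, keeping the
#' detector total.
#'
#' @param series a `contact_area_series` with non-decreasing elongation.
#' @param base an [baseline()] result for the same feature.
#' @param traj_id trajectory identifier for the event row.
#' @return An `unfolding_event` (fields `start`, `end`, `open_ended`) or
#'   `NULL` when the start threshold is never crossed. An event whose end
#'   threshold is never reached is open-ended: `end` is the last elongation
#'   and `open_ended` is `TRUE`.
#' @export
detect_event <- function(series, base, traj_id = "") {
  stopifnot(inherits(series, "contact_area_series"),
            inherits(base, "equilibrium_baseline"))
  x <- series$elongation
  if (any(diff(x) < 0)) stop("elongation must be monotone non-decreasing")
  thr_start <- base$ca_low / 2
  if (thr_start <= 0) {
    warning("CA_low/2 <= 0 for '", series$pair,
            "'; clamping start threshold to ", CA_END_NM2, " nm^2")
    thr_start <- CA_END_NM2
  }
  i_start <- which(series$ca < thr_start)
  if (length(i_start) == 0L) return(NULL)
  i_start <- i_start[1]
  i_end <- which(series$ca < CA_END_NM2 & seq_along(x) >= i_start)
  open <- length(i_end) == 0L
  i_end <- if (open) length(x) else i_end[1]
  structure(list(traj_id = traj_id, feature = series$pair,
                 start = x[i_start], end = x[i_end], open_ended = open),
            class = "unfolding_event")
}

#' Widen an event window for display
#'
#' Event boxes narrower than `min_width` are widened symmetrically about
#' their centre to that width (2 nm by default) and clamped at elongation 0.
#'
#' @param ev an `unfolding_event`.
#' @param min_width minimum display width in nm.
#' @return The event with `disp_start`/`disp_end` fields set.
#' @export
widen_for_display <- function(ev, min_width = 2) {
  stopifnot(inherits(ev, "unfolding_event"))
  if (ev$end - ev$start >= min_width) {
    ev$disp_start <- ev$start
    ev$disp_end <- ev$end
  } else {
    mid <- (ev$start + ev$end) / 2
    lo <- mid - min_width / 2
    if (lo < 0) lo <- 0
    ev$disp_start <- lo
    ev$disp_end <- lo + min_width
  }
  ev
}

event_row <- function(ev) {
  data.frame(traj_id = ev$traj_id, feature = ev$feature,
             start_nm = ev$start, end_nm = ev$end,
             disp_start_nm = ev$disp_start, disp_end_nm = ev$disp_end,
             open_ended = ev$open_ended, stringsAsFactors = FALSE)
}

empty_event_table <- function() {
  data.frame(traj_id = character(), feature = character(),
             start_nm = numeric(), end_nm = numeric(),
             disp_start_nm = numeric(), disp_end_nm = numeric(),
             open_ended = logical(), stringsAsFactors = FALSE)
}

#' Catalogue unfolding events over several features
#'
#' Runs [detect_event()] for each feature's contact-area series against its
#' equilibrium baseline and returns one row per detected event, ordered by
#' start elongation, with display windows attached.
#'
#' @param series_list named list of `contact_area_series`, one per feature.
#' @param baselines named list of `equilibrium_baseline` matching
#'   `series_list` names.
#' @param traj_id trajectory identifier.
#' @param min_width display-widening floor passed to [widen_for_display()].
#' @return Event table data.frame (possibly zero rows) with columns
#'   `traj_id`, `feature`, `start_nm`, `end_nm`, `disp_start_nm`,
#'   `disp_end_nm`, `open_ended`.
#' @export
event_catalog <- function(series_list, baselines, traj_id = "",
                          min_width = 2) {
  stopifnot(length(series_list) == length(baselines))
  rows <- list()
  for (nm in names(series_list)) {
    base <- baselines[[nm]]
    if (is.null(base)) stop("no baseline for feature '", nm, "'")
    ev <- detect_event(series_list[[nm]], base, traj_id = traj_id)
    if (!is.null(ev)) rows[[nm]] <- event_row(widen_for_display(ev, min_width))
  }
  if (length(rows) == 0L) return(empty_event_table())
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$start_nm), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
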