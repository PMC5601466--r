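# Bell-model fit of rupture forces against the loading rate.

#' Fit the Bell model across a pulling-velocity ladder
#'
#' Dynamic force spectroscopy model: the rupture force grows
#' logarithmically with the loading rate r = k_spring * v,
#' F_r = (kT / x_b) ln(r x_b / (kT k_off)) = A ln(k v / B),
#' with x_b the distance to the transition state and k_off the zero-force
#' unfolding rate. An unweighted least-squares fit of all individual
#' records of F_r against ln(k_spring * v) gives A (slope) and B
#' (intercept transform); then x_b = kT / A and k_off = B / A.
#'
#' @param records rupture-record data.frame (rows from [rupture_force()],
#'   or any table with `F_r_pN` and `v_pull_nm_per_ns`); at least two
#'   distinct velocities.
#' @param k_spring spring constant in pN/nm shared by all records.
#' @param T_K temperature in K (default 300).
#' @return A `bell_fit`: `A` (pN), `B` (pN/ns), `x_b` (nm), `k_off`
#'   (1/ns), `kT` (pN nm), residuals, and `flagged` when the fitted slope
#'   is non-positive (anti-Bell trend: forces decreasing with loading
#'   rate), in which case x_b and k_off are NA.
#' @export
fit_bell <- function(records, k_spring, T_K = 300) {
  stopifnot(is.data.frame(records),
            all(c("F_r_pN", "v_pull_nm_per_ns") %in% names(records)))
  v <- records$v_pull_nm_per_ns
  if (length(unique(v)) < 2L)
    stop("Bell fit needs >= 2 distinct pulling velocities (rank-deficient)")
  log_r <- log(k_spring * v)
  fit <- stats::lm(records$F_r_pN ~ log_r)
  A <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  kT_val <- kT(T_K, "pN.nm")
  flagged <- !is.finite(A) || A <= 0
  B <- if (flagged) NA_real_ else exp(-intercept / A)
  structure(list(
    A = A, B = B,
    x_b = if (flagged) NA_real_ else kT_val / A,
    k_off = if (flagged) NA_real_ else B / A,
    kT = kT_val, T_K = T_K, k_spring = k_spring,
    velocities = sort(unique(v)),
    residuals = unname(stats::residuals(fit)),
    flagged = flagged),
    class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  if (x$flagged) {
    cat("bell_fit: FLAGGED (non-positive slope, anti-Bell trend)\n")
  } else {
    cat(sprintf(
      "bell_fit: A = %.4g pN, B = %.4g pN/ns, x_b = %.4g nm, k_off = %.4g /ns\n",
      x$A, x$B, x$x_b, x$k_off))
    cat(sprintf("  slope %.1f pN per decade of velocity, %d velocities\n",
                slope_per_decade(x), length(x$velocities)))
  }
  invisible(x)
}

#' Rupture-force slope per decade of pulling velocity
#'
#' @param fit a `bell_fit`.
#' @return A * ln(10), in pN per order of magnitude in velocity.
#' @export
slope_per_decade <- function(fit) {
  stopifnot(inherits(fit, "bell_fit"))
  fit$A * log(10)
}

#' Zero-force unfolding rate extrapolated from a Bell fit
#'
#' Returns the fitted k_off, i.e. the unfolding rate at zero force under
#' the Bell model. This is an extrapolation across many orders of
#' magnitude below the probed loading rates; a warning to that effect is
#' always attached.
#'
#' @param fit a `bell_fit`; must not be flagged.
#' @return k_off in 1/ns.
#' @export
extrapolate_k0 <- function(fit) {
  stopifnot(inherits(fit, "bell_fit"))
  if (fit$flagged) stop("cannot extrapolate from a flagged (anti-Bell) fit")
  warning("k_off is an extrapolation far below the probed loading rates; ",
          "interpret with caution")
  fit$k_off
}
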