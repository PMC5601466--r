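# Seeded generators for every input the pipeline consumes: force traces
# with sawtooth rupture peaks, Bell first-passage rupture forces,
# contact-area series with planted loss events, toy structures with
# analytically known geometry, and binomial unfolding-order counts.

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# state. Every generator routes its randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a synthetic two-channel pull-force trace
#'
#' The underlying force is a sawtooth: linear loading at slope `k_eff` in
#' elongation, with instantaneous partial drops at the planted rupture
#' elongations (each drop removes `drop_frac` of the current force). The
#' two recorded channels are f1 = +F + noise and f2 = -F + noise,
#' mimicking the antisymmetric spring forces.
#'
#' @param v_pull pulling velocity, nm/ns.
#' @param k_eff loading slope in pN per nm of elongation.
#' @param events data.frame with columns `elong` (nm, increasing) and
#'   `drop_frac` in (0, 1]; may have zero rows.
#' @param noise_sd per-channel Gaussian noise sd in pN.
#' @param duration trace length in ns.
#' @param dt sample spacing in ns (default 0.05, the pull-force output
#'   interval).
#' @param k_spring spring constant metadata, pN/nm.
#' @param seed RNG seed; identical seeds give identical traces.
#' @param label trace label.
#' @return A [force_trace].
#' @export
gen_force_trace <- function(v_pull, k_eff, events = NULL, noise_sd = 0,
                            duration = 30, dt = 0.05, k_spring = 830,
                            seed = NULL, label = "synthetic") {
  if (is.null(events))
    events <- data.frame(elong = numeric(), drop_frac = numeric())
  stopifnot(all(diff(events$elong) > 0),
            all(events$drop_frac > 0 & events$drop_frac <= 1))
  with_seed(seed, {
    time <- seq(0, duration, by = dt)
    x <- v_pull * time
    F <- numeric(length(x))
    next_ev <- 1L
    for (i in seq_along(x)[-1]) {
      F[i] <- F[i - 1] + k_eff * (x[i] - x[i - 1])
      # the ramp attains the event elongation before the drop applies, so
      # a drop planted on the sample grid leaves its peak value recorded
      while (next_ev <= nrow(events) && x[i] > events$elong[next_ev]) {
        F[i] <- F[i] * (1 - events$drop_frac[next_ev])
        next_ev <- next_ev + 1L
      }
    }
    f1 <- F + stats::rnorm(length(F), 0, noise_sd)
    f2 <- -F + stats::rnorm(length(F), 0, noise_sd)
    force_trace(time, f1, f2, v_pull, k_spring, label = label)
  })
}

#' Sample rupture forces from the Bell first-passage law
#'
#' For a force ramp at loading rate r = k_spring * v and an escape rate
#' k(F) = k_off exp(F x_b / kT), the survival function is
#' S(F) = exp(-(k_off kT)/(r x_b) (exp(F x_b / kT) - 1)); forces are drawn
#' by inverse-CDF sampling. The modal force approaches the Bell-model
#' prediction (kT/x_b) ln(r x_b / (kT k_off)) at high reduced loading
#' rates.
#'
#' @param x_b distance to the transition state, nm.
#' @param k_off zero-force unfolding rate, 1/ns.
#' @param k_spring spring constant, pN/nm.
#' @param velocities pulling velocities, nm/ns.
#' @param replicas rupture samples per velocity.
#' @param T_K temperature, K.
#' @param seed RNG seed.
#' @param system label prefix for `traj_id`.
#' @return Rupture-record data.frame (`traj_id`, `v_pull_nm_per_ns`,
#'   `F_r_pN`, `peak_x_nm` = NA, `window_nm` = NA, `truncated` = FALSE).
#' @export
gen_bell_ruptures <- function(x_b, k_off, k_spring,
                              velocities = c(1, 1/3, 1/10, 1/30),
                              replicas = 10, T_K = 300, seed = NULL,
                              system = "synthetic") {
  stopifnot(x_b > 0, k_off > 0, k_spring > 0, all(velocities > 0),
            replicas >= 1)
  kT_val <- kT(T_K, "pN.nm")
  with_seed(seed, {
    rows <- lapply(velocities, function(v) {
      r <- k_spring * v
      u <- stats::runif(replicas)
      F <- (kT_val / x_b) * log1p(-(r * x_b) / (k_off * kT_val) * log(u))
      data.frame(
        traj_id = sprintf("%s_v%g_r%d", system, v, seq_len(replicas)),
        v_pull_nm_per_ns = v, F_r_pN = F, peak_x_nm = NA_real_,
        window_nm = NA_real_, truncated = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Bell-model modal rupture force (generator-side closed form)
#'
#' @inheritParams gen_bell_ruptures
#' @param v pulling velocity, nm/ns.
#' @return Modal force (kT/x_b) ln(r x_b / (kT k_off)) in pN.
#' @export
bell_modal_force <- function(x_b, k_off, k_spring, v, T_K = 300) {
  kT_val <- kT(T_K, "pN.nm")
  (kT_val / x_b) * log(k_spring * v * x_b / (kT_val * k_off))
}

#' Generate a contact-area series with planted loss events
#'
#' An equilibrium AR(1) segment around `eq_mean` (for baseline estimation)
#' followed by a pulled segment in which the contact area decays to zero
#' through logistic (sigmoidal) loss events; values clamped at 0.
#'
#' @param eq_mean equilibrium mean contact area, nm^2.
#' @param ar_coef AR(1) coefficient in [0, 1).
#' @param innov_sd AR(1) innovation sd, nm^2.
#' @param events data.frame with `center` (elongation nm of the sigmoid
#'   midpoint) and `width` (nm); products of several sigmoids are taken.
#' @param n_eq equilibrium samples.
#' @param x_max pulled-segment elongation span, nm.
#' @param dx elongation sampling step, nm.
#' @param pull_noise_sd Gaussian noise on the pulled segment, nm^2.
#' @param seed RNG seed.
#' @param pair feature label.
#' @return List with `equilibrium` (numeric vector) and `series`
#'   (a `contact_area_series` over the pulled segment).
#' @export
gen_ca_series <- function(eq_mean = 3, ar_coef = 0.8, innov_sd = 0.15,
                          events = data.frame(center = 40, width = 1),
                          n_eq = 500, x_max = 80, dx = 0.05,
                          pull_noise_sd = 0, seed = NULL, pair = "synthetic") {
  stopifnot(ar_coef >= 0, ar_coef < 1, all(events$width > 0))
  with_seed(seed, {
    eq <- numeric(n_eq)
    sd_stat <- innov_sd / sqrt(1 - ar_coef^2)
    eq[1] <- eq_mean + stats::rnorm(1, 0, sd_stat)
    for (i in seq_len(n_eq - 1)) {
      eq[i + 1] <- eq_mean + ar_coef * (eq[i] - eq_mean) +
        stats::rnorm(1, 0, innov_sd)
    }
    eq <- pmax(eq, 0)
    x <- seq(0, x_max, by = dx)
    # logistic decay: multiply by 1/(1+exp((x-center)/width)) per event
    ca <- rep(eq_mean, length(x))
    for (j in seq_len(nrow(events)))
      ca <- ca * stats::plogis(-(x - events$center[j]) / events$width[j])
    if (pull_noise_sd > 0)
      ca <- ca + stats::rnorm(length(ca), 0, pull_noise_sd)
    ca <- pmax(ca, 0)
    list(equilibrium = eq,
         series = ca_series(pair, seq_along(x) - 1L, x, ca))
  })
}

#' Generate toy structures with analytically known geometry
#'
#' Fixtures for the geometry layer:
#' \describe{
#'   \item{sphere_pair}{two carbon atoms on the x-axis at
#'     `params$separation` nm (chains A, B; the isolated/two-sphere SASA
#'     oracles).}
#'   \item{helix_pair}{two parallel straight C-alpha rods of
#'     `params$n_res` residues at spacing `params$rise` (default 0.15 nm)
#'     along x, `params$gap` nm apart in y (chains A, B); with
#'     `params$offsets`, a list of frames where chain B is translated by
#'     each offset in y (a contact-loss fixture).}
#'   \item{tilted_rod}{one chain of `params$n_res` C-alphas along a
#'     direction at `params$angle_deg` to the x-axis in the xy-plane
#'     (tilt-angle oracle).}
#' }
#'
#' @param kind `"sphere_pair"`, `"helix_pair"` or `"tilted_rod"`.
#' @param params list of kind-specific parameters (see above).
#' @return A [structure_model], or a list of frames when
#'   `params$offsets` is given for `helix_pair`.
#' @export
gen_toy_structure <- function(kind = c("sphere_pair", "helix_pair",
                                       "tilted_rod"),
                              params = list()) {
  kind <- match.arg(kind)
  if (kind == "sphere_pair") {
    sep <- params$separation %||% 1
    at <- data.frame(
      name = c("C1", "C1"), element = c("C", "C"),
      resid = c(1L, 1L), resname = c("TOY", "TOY"), chain = c("A", "B"),
      x = c(0, sep), y = 0, z = 0, stringsAsFactors = FALSE)
    return(structure_model(at))
  }
  if (kind == "tilted_rod") {
    n_res <- params$n_res %||% 10L
    ang <- (params$angle_deg %||% 30) * pi / 180
    rise <- params$rise %||% 0.15
    s <- (seq_len(n_res) - 1) * rise
    at <- data.frame(
      name = "CA", element = "C", resid = seq_len(n_res), resname = "GLY",
      chain = "A", x = s * cos(ang), y = s * sin(ang), z = 0,
      stringsAsFactors = FALSE)
    return(structure_model(at))
  }
  # helix_pair
  n_res <- params$n_res %||% 12L
  rise <- params$rise %||% 0.15
  gap <- params$gap %||% 0.5
  rod <- function(chain, y_off) data.frame(
    name = "CA", element = "C", resid = seq_len(n_res), resname = "GLY",
    chain = chain, x = (seq_len(n_res) - 1) * rise, y = y_off, z = 0,
    stringsAsFactors = FALSE)
  build <- function(extra, frame) structure_model(
    rbind(rod("A", 0), rod("B", gap + extra)), frame = frame)
  offsets <- params$offsets
  if (is.null(offsets)) return(build(0, 0L))
  lapply(seq_along(offsets), function(i) build(offsets[i], i - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw binomial unfolding-order counts at a known barrier difference
#'
#' k ~ Binomial(n, p) with p = 1 / (1 + exp(ddg / kT)): the
#' generator-side counterpart of the logistic link used by the posterior.
#'
#' @param ddg true barrier difference, kcal/mol (may be `Inf`/`-Inf`).
#' @param n number of trajectories.
#' @param T_K temperature, K.
#' @param seed RNG seed.
#' @return An [order_counts()].
#' @export
gen_order_counts <- function(ddg, n, T_K = 300, seed = NULL) {
  stopifnot(n >= 1)
  p <- p_from_ddg(ddg, T_K)
  with_seed(seed, order_counts(stats::rbinom(1, n, p), n, T_K = T_K))
}
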