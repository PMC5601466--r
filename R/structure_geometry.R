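# Solvent-accessible surface areas (Shrake-Rupley), inter-region contact
# areas, and helix tilt angles.

# Van der Waals radii in nm (Bondi-style), overridable per call.
default_vdw_radii <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120)

# Deterministic quasi-uniform points on the unit sphere (golden-angle
# generalized spiral). Same point set for every atom, so SASA is exactly
# reproducible for fixed n.
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

atom_radii <- function(elements, radii) {
  r <- radii[elements]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "),
         " (supply a radii override)")
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals spheres of the selected atoms
#' using a deterministic golden-angle point set: for each atom, the fraction
#' of `n_points` test points on its expanded sphere (radius r_i + probe) not
#' buried inside any neighbour's expanded sphere, times 4*pi*(r_i+probe)^2.
#'
#' @param model a [structure_model].
#' @param atoms integer row indices into `model$atoms` (default: all atoms).
#'   Only these atoms are present: excluded atoms are replaced by solvent.
#' @param probe probe radius in nm (default 0.14, a water molecule).
#' @param n_points test points per atom (default 960; >= 32).
#' @param radii named per-element radii in nm overriding the built-in
#'   Bondi-style table.
#' @return Total SASA in nm^2.
#' @export
#' @examples
#' m <- gen_toy_structure("sphere_pair", list(separation = 2))
#' sasa(m, atoms = 1L)  # isolated sphere: ~4*pi*(0.17+0.14)^2
sasa <- function(model, atoms = NULL, probe = 0.14, n_points = 960L,
                 radii = default_vdw_radii) {
  stopifnot(inherits(model, "structure_model"), probe >= 0, n_points >= 32L)
  at <- model$atoms
  if (is.null(atoms)) atoms <- seq_len(nrow(at))
  if (length(atoms) == 0L) stop("empty atom selection")
  xyz <- as.matrix(at[atoms, c("x", "y", "z")])
  r_ext <- atom_radii(at$element[atoms], radii) + probe
  pts <- sphere_points(as.integer(n_points))
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r_ext + r_ext[i])^2 & seq_len(n) != i)
    area_i <- 4 * pi * r_ext[i]^2
    if (length(nb) == 0L) { total <- total + area_i; next }
    surf <- pts * r_ext[i]
    surf <- sweep(surf, 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj <- sweep(surf, 2, xyz[j, ])
      buried <- buried | (rowSums(dj^2) < r_ext[j]^2)
      if (all(buried)) break
    }
    total <- total + area_i * mean(!buried)
  }
  total
}

#' Define a residue-range region of a structure
#'
#' @param label region name.
#' @param ranges data.frame with columns `chain`, `first`, `last` (residue
#'   numbers, inclusive).
#' @param trim residues dropped at each end of every range. Interface
#'   selections between consecutive fragments use `trim = 2` so the contact
#'   area can reach zero; intra-domain helix pairs use `trim = 0`.
#' @return Object of class `region_selection`.
#' @export
region_selection <- function(label, ranges, trim = 0L) {
  stopifnot(is.data.frame(ranges),
            all(c("chain", "first", "last") %in% names(ranges)))
  trim <- as.integer(trim)
  if (any(ranges$first + trim > ranges$last - trim))
    stop("region '", label, "': a range is empty after trimming ", trim,
         " residues at each end")
  structure(list(label = label, ranges = ranges, trim = trim),
            class = "region_selection")
}

# Row indices of model atoms belonging to the (trimmed) selection.
resolve_selection <- function(model, sel) {
  at <- model$atoms
  idx <- integer(0)
  for (i in seq_len(nrow(sel$ranges))) {
    rr <- sel$ranges[i, ]
    lo <- rr$first + sel$trim
    hi <- rr$last - sel$trim
    idx <- c(idx, which(at$chain == rr$chain & at$resid >= lo & at$resid <= hi))
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L)
    stop("region '", sel$label, "' selects no atoms in frame ", model$frame)
  idx
}

#' Contact area between two regions
#'
#' CA = (SASA_A + SASA_B - SASA_{A+B}) / 2: half the surface buried by
#' bringing the two regions together. SASA_A and SASA_B are evaluated with
#' only that region's atoms present (solvent replacing the partner), so the
#' contact area decays to zero as the regions separate.
#'
#' @param model a [structure_model].
#' @param a,b [region_selection] objects; must be disjoint after trimming.
#' @inheritParams sasa
#' @return Contact area in nm^2 (>= 0 up to quadrature noise).
#' @export
contact_area <- function(model, a, b, probe = 0.14, n_points = 960L,
                         radii = default_vdw_radii) {
  ia <- resolve_selection(model, a)
  ib <- resolve_selection(model, b)
  if (length(intersect(ia, ib)) > 0L)
    stop("regions '", a$label, "' and '", b$label,
         "' overlap after trimming")
  s_a  <- sasa(model, ia, probe, n_points, radii)
  s_b  <- sasa(model, ib, probe, n_points, radii)
  s_ab <- sasa(model, c(ia, ib), probe, n_points, radii)
  (s_a + s_b - s_ab) / 2
}

#' Per-frame contact-area series along a pulling trajectory
#'
#' @param frames list of [structure_model].
#' @param a,b region selections.
#' @param elongation numeric vector, one pulling-coordinate value (nm) per
#'   frame; typically `v_pull * t`.
#' @inheritParams sasa
#' @return A `contact_area_series`: data.frame-backed object with `frame`,
#'   `elongation` (nm) and `ca` (nm^2), plus the pair label.
#' @export
contact_area_series <- function(frames, a, b, elongation,
                                probe = 0.14, n_points = 960L,
                                radii = default_vdw_radii) {
  if (length(frames) == 0L) stop("empty frame list")
  if (length(elongation) != length(frames))
    stop("elongation must have one value per frame")
  ca <- vapply(frames, function(f)
    contact_area(f, a, b, probe, n_points, radii), numeric(1))
  ca_series(sprintf("%s|%s", a$label, b$label),
            frame = vapply(frames, function(f) f$frame, integer(1)),
            elongation = elongation, ca = ca)
}

# Lightweight constructor shared with the synthetic generator.
ca_series <- function(pair, frame, elongation, ca) {
  stopifnot(length(frame) == length(ca), length(elongation) == length(ca))
  if (any(ca < -1e-6)) stop("contact area below -1e-6 nm^2")
  structure(list(pair = pair, frame = as.integer(frame),
                 elongation = as.numeric(elongation), ca = as.numeric(ca)),
            class = "contact_area_series")
}

#' @export
print.contact_area_series <- function(x, ...) {
  cat(sprintf("contact_area_series '%s': %d frames, CA = [%.3f, %.3f] nm^2\n",
              x$pair, length(x$ca), min(x$ca), max(x$ca)))
  invisible(x)
}

ca_of <- function(model, chain, resid, name = "CA") {
  at <- model$atoms
  i <- which(at$chain == chain & at$resid == resid & at$name == name)
  if (length(i) != 1L)
    stop(sprintf("frame %d: expected exactly one %s atom for %s:%d, found %d",
                 model$frame, name, chain, resid, length(i)))
  unlist(at[i, c("x", "y", "z")], use.names = FALSE)
}

angle_deg <- function(v, axis) {
  nv <- sqrt(sum(v^2)); na <- sqrt(sum(axis^2))
  if (nv == 0 || na == 0) stop("zero-length vector in angle computation")
  # clip to guard rounding at 0 and 180 degrees
  acos(min(1, max(-1, sum(v * axis) / (nv * na)))) * 180 / pi
}

#' Helix tilt angles along a trajectory
#'
#' For each frame measures the angles between the pulling axis and the two
#' vectors from a mid-anchor C-alpha to an N-side and a C-side anchor
#' C-alpha. Large tilt marks the 'tearing' (unzipping) unfolding topology;
#' small tilt the 'shearing' one. Shipped anchor presets:
#' [tilt_anchor_presets].
#'
#' @param frames list of [structure_model].
#' @param anchor_mid,anchor_n,anchor_c length-2 vectors `c(chain, resid)`
#'   naming the mid, N-side and C-side anchor residues.
#' @param axis pulling-axis direction (length-3, need not be unit).
#' @param traj_id identifier stored with the series.
#' @return A `tilt_series` with per-frame `alpha1`, `alpha2` in degrees.
#' @export
tilt_angles <- function(frames, anchor_mid, anchor_n, anchor_c,
                        axis = c(1, 0, 0), traj_id = "") {
  if (length(frames) == 0L) stop("empty frame list")
  a1 <- a2 <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    p_mid <- ca_of(f, anchor_mid[1], as.integer(anchor_mid[2]))
    p_n   <- ca_of(f, anchor_n[1],   as.integer(anchor_n[2]))
    p_c   <- ca_of(f, anchor_c[1],   as.integer(anchor_c[2]))
    a1[i] <- angle_deg(p_n - p_mid, axis)
    a2[i] <- angle_deg(p_c - p_mid, axis)
  }
  structure(list(traj_id = traj_id, alpha1 = a1, alpha2 = a2),
            class = "tilt_series")
}

#' Anchor residues for the two studied plakin domains
#'
#' Mid/N-side/C-side C-alpha anchors used for the tilt angles:
#' desmoplakin N375, P342, Y403; plectin N858, P825, Y886.
#' @export
tilt_anchor_presets <- list(
  desmoplakin = list(mid = c("A", 375), n = c("A", 342), c = c("A", 403)),
  plectin     = list(mid = c("A", 858), n = c("A", 825), c = c("A", 886))
)

#' Maximum tilt angle of a trajectory
#'
#' The classifier score: the largest of the two per-frame tilt angles,
#' maximised over frames.
#'
#' @param series a `tilt_series` from [tilt_angles()].
#' @return Maximum angle in degrees.
#' @export
max_tilt <- function(series) {
  stopifnot(inherits(series, "tilt_series"))
  if (length(series$alpha1) == 0L) stop("empty tilt series")
  max(pmax(series$alpha1, series$alpha2))
}
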