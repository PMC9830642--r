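#' Reaction dipole vector
#'
#' The vector difference between the transition-state and local-minimum
#' dipole moments, both expressed in the same aligned Cartesian frame. Its
#' direction is the "reaction axis": the direction of electron-density flow
#' during the transformation, and hence the field orientation to which the
#' barrier is most susceptible.
#'
#' @param mu_int Local-minimum (intermediate) dipole, length-3, Debye.
#' @param mu_ts Transition-state dipole, length-3, Debye.
#' @return Length-3 reaction dipole (Debye): `mu_ts - mu_int`.
#' @examples
#' reaction_dipole(c(0.2481, -1.8900, -0.0889), c(0.3813, 1.2430, 0.6952))
#' @export
reaction_dipole <- function(mu_int, mu_ts) {
  mu_int <- as.numeric(mu_int); mu_ts <- as.numeric(mu_ts)
  stopifnot(length(mu_int) == 3L, length(mu_ts) == 3L,
            all(is.finite(mu_int)), all(is.finite(mu_ts)))
  mu_ts - mu_int
}

#' Normalize the reaction dipole into a reaction axis
#'
#' @param mu_rxn Length-3 reaction dipole (Debye).
#' @param threshold Degeneracy threshold (Debye, default 1e-3): below it the
#'   optimal field orientation is numerically meaningless and construction
#'   fails.
#' @return List with `norm` (Debye) and `unit` (the reaction axis, unit norm).
#' @export
normalize_axis <- function(mu_rxn, threshold = 1e-3) {
  mu_rxn <- as.numeric(mu_rxn)
  stopifnot(length(mu_rxn) == 3L, all(is.finite(mu_rxn)))
  nrm <- sqrt(sum(mu_rxn^2))
  if (nrm < threshold) {
    stop("degenerate axis: ||mu_rxn|| = ", format(nrm),
         " D is below the threshold of ", threshold,
         " D; no well-defined reaction axis")
  }
  list(norm = nrm, unit = mu_rxn / nrm)
}

#' Map a unit axis into a structure's Z-matrix frame
#'
#' Dipole directions are frame-direction objects: only the rotation part of a
#' [frame_rotation] applies (no translation). The output is unit-norm because
#' rotations are isometries.
#'
#' @param unit Length-3 unit vector (norm within 1e-9 of 1).
#' @param frame A [frame_rotation].
#' @return The rotated unit vector.
#' @export
map_axis_to_frame <- function(unit, frame) {
  unit <- as.numeric(unit)
  stopifnot(length(unit) == 3L, inherits(frame, "frame_rotation"))
  if (abs(sqrt(sum(unit^2)) - 1) > 1e-9) {
    stop("map_axis_to_frame expects a unit vector (||x|| - 1 <= 1e-9); ",
         "normalize first via normalize_axis()")
  }
  as.numeric(frame$rotation %*% unit)
}

#' Reaction axis for an aligned structure pair
#'
#' Bundles the reaction dipole, its norm, the unit reaction axis, and its
#' images in each structure's Z-matrix frame.
#'
#' @param mu_int,mu_ts Same-frame dipoles (Debye).
#' @param frame_sm,frame_ts Optional [frame_rotation]s for the local-minimum
#'   and transition-state structures; when supplied, the mapped axes
#'   `mapped_sm` / `mapped_ts` are populated.
#' @param threshold Degeneracy threshold in Debye (see [normalize_axis]).
#' @return Object of class `reaction_axis` with fields `mu_int`, `mu_ts`,
#'   `mu_rxn`, `norm`, `unit`, `mapped_sm`, `mapped_ts`.
#' @export
reaction_axis <- function(mu_int, mu_ts, frame_sm = NULL, frame_ts = NULL,
                          threshold = 1e-3) {
  mu_rxn <- reaction_dipole(mu_int, mu_ts)
  nx <- normalize_axis(mu_rxn, threshold)
  mapped_sm <- if (!is.null(frame_sm)) map_axis_to_frame(nx$unit, frame_sm)
  mapped_ts <- if (!is.null(frame_ts)) map_axis_to_frame(nx$unit, frame_ts)
  structure(list(mu_int = as.numeric(mu_int), mu_ts = as.numeric(mu_ts),
                 mu_rxn = mu_rxn, norm = nx$norm, unit = nx$unit,
                 mapped_sm = mapped_sm, mapped_ts = mapped_ts),
            class = "reaction_axis")
}

#' @export
print.reaction_axis <- function(x, ...) {
  cat(sprintf("reaction axis: mu_rxn = [%s] D, ||mu_rxn|| = %.4f D\n",
              paste(sprintf("%.4f", x$mu_rxn), collapse = ", "), x$norm))
  cat(sprintf("  unit: [%s]\n", paste(sprintf("%.4f", x$unit), collapse = ", ")))
  invisible(x)
}

#' Field vector along a mapped axis
#'
#' Builds the applied-field vector at a given magnitude. Under the physics
#' sign convention the interaction energy is `-mu . F`, so a field along the
#' +axis direction is the stabilizing choice when the axis is the reaction
#' dipole direction. Quantum-chemistry input decks that define the positive
#' field direction opposite to physics convention (the `gaussian` convention)
#' get the exact negation.
#'
#' @param axis Length-3 unit vector (a mapped reaction axis).
#' @param magnitude Field magnitude, atomic units, `>= 0` (the direction sign
#'   lives in the convention and the axis, never in the magnitude).
#' @param convention `"physics"` (default) or `"gaussian"`.
#' @return Object of class `field_vector`: `components` (a.u.), `magnitude`,
#'   `convention`.
#' @export
field_vector <- function(axis, magnitude,
                         convention = c("physics", "gaussian")) {
  convention <- match.arg(convention)
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3L, is.numeric(magnitude), length(magnitude) == 1L)
  if (magnitude < 0) {
    stop("magnitude must be >= 0; express direction through the axis or ",
         "the sign convention")
  }
  if (magnitude > 0 && abs(sqrt(sum(axis^2)) - 1) > 1e-9) {
    stop("axis must be unit-norm")
  }
  comp <- magnitude * axis
  if (convention == "gaussian") comp <- -comp
  structure(list(components = comp, magnitude = magnitude,
                 convention = convention),
            class = "field_vector")
}

#' @rdname field_vector
#' @param field A `field_vector`.
#' @export
flip_convention <- function(field) {
  stopifnot(inherits(field, "field_vector"))
  field$components <- -field$components
  field$convention <- if (field$convention == "physics") "gaussian" else "physics"
  field
}

#' First-order barrier change under an optimally aligned field
#'
#' To first order in the field, the interaction energy is `-mu . F`, so the
#' change in activation barrier induced by a field of magnitude `F` applied
#' along the reaction axis is `-||mu_rxn|| * F` — the scalar form for the
#' optimally aligned case. Curvature from the polarizability contributes only
#' at second order.
#'
#' @param mu_rxn_norm Reaction-dipole magnitude, Debye.
#' @param magnitude Field magnitude, atomic units.
#' @return Barrier change in kcal/mol (negative = barrier lowering).
#' @examples
#' first_order_barrier_change(3.2324, 2.5e-3)  # about -2.0 kcal/mol
#' @export
first_order_barrier_change <- function(mu_rxn_norm, magnitude) {
  stopifnot(is.numeric(mu_rxn_norm), is.numeric(magnitude))
  k <- oef_constants()
  -(mu_rxn_norm * k$debye_to_au) * magnitude * k$hartree_to_kcal
}
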