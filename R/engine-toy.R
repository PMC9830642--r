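#' Analytic harmonic point-charge engine
#'
#' A fully analytic model chemistry for end-to-end testing of the field-ramp
#' workflow without any quantum-chemistry code. Atoms carry fixed point
#' charges `q` (e) and are tethered harmonically (force constant `k`,
#' Hartree/bohr^2) to a reference geometry `r0`. In atomic units the energy
#' under a field `F` is
#'
#'   `E(r, F) = E0 + k/2 * sum_i ||r_i - r0_i||^2 - mu(r) . F - F' alpha F / 2`
#'
#' with `mu(r) = sum_i q_i r_i` and a geometry-independent polarizability
#' `alpha`. The model is deliberately minimal but reproduces the physics the
#' workflow relies on: a field-dependent dipole, a quadratic (polarizability)
#' curvature of the barrier, and a closed-form optimum
#' `r_i* = r0_i + (q_i / k) F` so that every pipeline result can be checked
#' against exact arithmetic. Because the tether is expressed in a fixed
#' frame, the reference geometry pins the orientation in the same way a
#' Z-matrix does.
#'
#' @param r0 Reference geometry: an [xyz_structure] (Angstrom).
#' @param q Per-atom point charges (e), length N.
#' @param k Restoring force constant, Hartree/bohr^2, > 0.
#' @param E0 Base electronic energy at `r0` and zero field, Hartree.
#' @param alpha 3 x 3 symmetric positive-semidefinite polarizability (a.u.).
#' @param ts_axis Optional unit vector: when set, the analytic Hessian has
#'   one negated direction, so results report one imaginary mode (a
#'   transition state); otherwise zero (a local minimum).
#' @param g_offset Optional thermal correction added to `E` to report a free
#'   energy (Hartree); `NULL` suppresses free energies.
#' @return Engine object of class `toy_engine` usable with
#'   [engine_evaluate], [engine_optimize], [engine_permute],
#'   [engine_transform].
#' @export
toy_engine <- function(r0, q, k, E0 = 0, alpha = matrix(0, 3, 3),
                       ts_axis = NULL, g_offset = NULL) {
  stopifnot(inherits(r0, "xyz_structure"))
  q <- as.numeric(q)
  alpha <- as.matrix(alpha)
  if (length(q) != n_atoms(r0)) stop("length(q) must match the atom count")
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be > 0")
  if (any(dim(alpha) != c(3L, 3L)) || max(abs(alpha - t(alpha))) > 1e-12) {
    stop("alpha must be a symmetric 3 x 3 matrix")
  }
  if (min(eigen(alpha, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("alpha must be positive semidefinite")
  }
  if (!is.null(ts_axis)) {
    ts_axis <- as.numeric(ts_axis)
    stopifnot(length(ts_axis) == 3L)
    ts_axis <- ts_axis / sqrt(sum(ts_axis^2))
  }
  structure(list(r0 = r0, q = q, k = k, E0 = E0, alpha = alpha,
                 ts_axis = ts_axis, g_offset = g_offset),
            class = "toy_engine")
}

#' @export
print.toy_engine <- function(x, ...) {
  cat(sprintf("toy_engine: %d atoms, k = %g Ha/bohr^2, %s\n",
              n_atoms(x$r0), x$k,
              if (is.null(x$ts_axis)) "minimum (0 imaginary)"
              else "transition state (1 imaginary)"))
  invisible(x)
}

.toy_mu_au <- function(engine, coords_bohr) {
  as.numeric(colSums(engine$q * coords_bohr))
}

#' @export
engine_evaluate.toy_engine <- function(engine, structure, field = NULL) {
  stopifnot(inherits(structure, "xyz_structure"))
  if (n_atoms(structure) != n_atoms(engine$r0)) {
    stop("structure atom count (", n_atoms(structure),
         ") does not match engine parameters (", n_atoms(engine$r0), ")")
  }
  kk <- oef_constants()
  f <- .field_components(field)
  r <- structure$coords * kk$angstrom_to_bohr
  r0 <- engine$r0$coords * kk$angstrom_to_bohr
  mu <- .toy_mu_au(engine, r)
  e <- engine$E0 + 0.5 * engine$k * sum((r - r0)^2) - sum(mu * f) -
    0.5 * as.numeric(t(f) %*% engine$alpha %*% f)
  engine_result(
    energy = e,
    dipole = mu / kk$debye_to_au,
    geometry = structure,
    free_energy = if (!is.null(engine$g_offset)) e + engine$g_offset,
    n_imaginary = if (is.null(engine$ts_axis)) 0L else 1L,
    converged = TRUE
  )
}

#' @export
engine_optimize.toy_engine <- function(engine, structure, field = NULL) {
  stopifnot(inherits(structure, "xyz_structure"))
  if (n_atoms(structure) != n_atoms(engine$r0)) {
    stop("structure atom count does not match engine parameters")
  }
  kk <- oef_constants()
  f <- .field_components(field)
  r0 <- engine$r0$coords * kk$angstrom_to_bohr
  # closed-form optimum of the convex model (start geometry only seeds it)
  ropt <- r0 + outer(engine$q / engine$k, f)
  mu0 <- .toy_mu_au(engine, r0)
  sq2 <- sum(engine$q^2)
  e <- engine$E0 - sum(mu0 * f) - (sq2 / (2 * engine$k)) * sum(f^2) -
    0.5 * as.numeric(t(f) %*% engine$alpha %*% f)
  # the optimum is returned in the engine's own frame: all alignment and
  # Z-matrix orientation bookkeeping lives in the workflow, which transforms
  # the engine alongside every rigid motion it applies
  geom <- xyz_structure(engine$r0$symbols, ropt * kk$bohr_to_angstrom,
                        comment = sprintf("toy optimum, |F| = %g a.u.",
                                          sqrt(sum(f^2))))
  engine_result(
    energy = e,
    dipole = .toy_mu_au(engine, ropt) / kk$debye_to_au,
    geometry = geom,
    free_energy = if (!is.null(engine$g_offset)) e + engine$g_offset,
    n_imaginary = if (is.null(engine$ts_axis)) 0L else 1L,
    converged = TRUE
  )
}

#' @export
engine_permute.toy_engine <- function(engine, perm) {
  perm <- as.integer(perm)
  n <- n_atoms(engine$r0)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("perm must be a permutation of 1..", n)
  }
  engine$r0$symbols <- engine$r0$symbols[perm]
  engine$r0$coords <- engine$r0$coords[perm, , drop = FALSE]
  engine$q <- engine$q[perm]
  engine
}

#' @export
engine_transform.toy_engine <- function(engine, frame) {
  stopifnot(inherits(frame, "frame_rotation"))
  engine$r0 <- apply_frame(frame, engine$r0)
  r <- frame$rotation
  engine$alpha <- r %*% engine$alpha %*% t(r)
  if (!is.null(engine$ts_axis)) {
    engine$ts_axis <- as.numeric(r %*% engine$ts_axis)
  }
  engine
}
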