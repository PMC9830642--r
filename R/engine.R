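#' Result of an energy-engine evaluation or optimization
#'
#' The common currency between energy engines and the workflow: a single
#' electronic-structure result.
#'
#' @param energy Electronic energy, Hartree.
#' @param dipole Length-3 dipole moment, Debye.
#' @param geometry [xyz_structure] the result refers to.
#' @param free_energy Optional thermally corrected free energy, Hartree.
#' @param n_imaginary Number of imaginary vibrational modes (0 for a local
#'   minimum, 1 for a transition state) or `NA` when no frequency data exist.
#' @param converged Logical convergence / normal-termination flag.
#' @return Object of class `engine_result`.
#' @export
engine_result <- function(energy, dipole, geometry, free_energy = NULL,
                          n_imaginary = NA_integer_, converged = TRUE) {
  if (isTRUE(converged)) {
    stopifnot(is.finite(energy), inherits(geometry, "xyz_structure"))
  }
  if (!is.na(n_imaginary) && n_imaginary < 0) stop("n_imaginary must be >= 0")
  structure(list(energy = energy, free_energy = free_energy,
                 dipole = as.numeric(dipole), geometry = geometry,
                 n_imaginary = as.integer(n_imaginary),
                 converged = isTRUE(converged)),
            class = "engine_result")
}

#' @export
print.engine_result <- function(x, ...) {
  cat(sprintf("engine_result: E = %.6f Ha, |mu| = %.4f D, %s\n",
              x$energy, sqrt(sum(x$dipole^2)),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Energy-engine contract
#'
#' An engine is any object for which these generics are defined:
#'
#' * `engine_evaluate(engine, structure, field)` — single-point energy and
#'   dipole at a fixed geometry under an applied field.
#' * `engine_optimize(engine, structure, field)` — geometry optimization
#'   under the field, seeded at `structure`. The optimized geometry is
#'   returned in the engine's own coordinate frame; the workflow owns all
#'   rigid-motion bookkeeping (alignment, Z-matrix orientation) and keeps
#'   engines consistent through `engine_transform`.
#' * `engine_permute(engine, perm)` — an engine consistent with atoms
#'   reordered by `perm` (identity for engines that carry no per-atom state).
#' * `engine_transform(engine, frame)` — an engine consistent with the
#'   molecule rigidly moved by a [frame_rotation] (identity by default).
#'
#' `field` is a [field_vector] in the physics convention (interaction energy
#' `-mu . F`); engines that speak another dialect convert internally.
#'
#' @param engine An engine object.
#' @param structure [xyz_structure] (Angstrom).
#' @param field A [field_vector], or `NULL` for zero field.
#' @param perm Integer permutation vector.
#' @param frame A [frame_rotation].
#' @return `engine_evaluate` / `engine_optimize` return an [engine_result];
#'   `engine_permute` / `engine_transform` return a modified engine.
#' @name engine-contract
NULL

#' @rdname engine-contract
#' @export
engine_evaluate <- function(engine, structure, field = NULL) {
  UseMethod("engine_evaluate")
}

#' @rdname engine-contract
#' @export
engine_optimize <- function(engine, structure, field = NULL) {
  UseMethod("engine_optimize")
}

#' @rdname engine-contract
#' @export
engine_permute <- function(engine, perm) UseMethod("engine_permute")

#' @rdname engine-contract
#' @export
engine_transform <- function(engine, frame) UseMethod("engine_transform")

#' @export
engine_permute.default <- function(engine, perm) engine

#' @export
engine_transform.default <- function(engine, frame) engine

.field_components <- function(field) {
  if (is.null(field)) return(c(0, 0, 0))
  stopifnot(inherits(field, "field_vector"))
  f <- field$components
  if (field$convention == "gaussian") f <- -f  # internal convention: physics
  f
}
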