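#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` by the proper rigid motion (rotation
#' plus translation, no reflection) minimizing the RMSD over corresponding
#' atoms. Correspondence is positional: atom i of `mobile` matches atom i of
#' `reference`.
#'
#' The rotation is obtained from the SVD of the cross-covariance of the
#' centered coordinate sets, with the usual determinant-sign correction so
#' that a reflection is never returned, even for degenerate (rank-deficient)
#' configurations.
#'
#' @param mobile,reference [xyz_structure] objects with equal atom counts.
#' @return List with `alignment` (class `alignment_result`: `rotation`,
#'   `translation`, `rmsd` in Angstrom) and `structure` (the moved copy of
#'   `mobile`, `rotation %*% x + translation`).
#' @examples
#' s <- xyz_structure(c("O", "H", "H"),
#'                    rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' fit <- kabsch_superpose(s, s)
#' fit$alignment$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  stopifnot(inherits(mobile, "xyz_structure"),
            inherits(reference, "xyz_structure"))
  n <- n_atoms(mobile)
  if (n != n_atoms(reference)) {
    stop("atom-count mismatch: mobile has ", n, ", reference has ",
         n_atoms(reference), "; correspondence is positional")
  }
  pm <- mobile$coords
  pr <- reference$coords
  cm <- colMeans(pm)
  cr <- colMeans(pr)
  if (n < 3L) {
    warning("fewer than 3 atoms: rotation is underdetermined; ",
            "translation-only fit returned")
    rot <- diag(3)
  } else {
    h <- crossprod(sweep(pm, 2, cm), sweep(pr, 2, cr))
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1  # rank-deficient tie: break toward det +1
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  trans <- as.numeric(cr - rot %*% cm)
  moved <- mobile
  moved$coords <- sweep(pm %*% t(rot), 2, -trans)
  res <- structure(list(rotation = rot, translation = trans,
                        rmsd = rmsd(moved, reference)),
                   class = "alignment_result")
  list(alignment = res, structure = moved)
}

#' Root-mean-square deviation of corresponding atoms
#'
#' Computed without re-superposition: the two structures are assumed to share
#' a coordinate frame (as they do by construction throughout the field ramp,
#' where every geometry lives in its structure's Z-matrix frame).
#'
#' @param a,b [xyz_structure] objects with equal atom counts.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  stopifnot(inherits(a, "xyz_structure"), inherits(b, "xyz_structure"))
  if (n_atoms(a) != n_atoms(b)) {
    stop("atom-count mismatch: ", n_atoms(a), " vs ", n_atoms(b))
  }
  sqrt(mean(rowSums((a$coords - b$coords)^2)))
}

#' Normalize an RMSD by molecular size
#'
#' Expresses a deviation as a percentage of the reference structure's
#' unweighted radius of gyration, making the >10% structural-distortion
#' warning scale-free across molecule sizes. The raw Angstrom value should
#' always be reported alongside.
#'
#' @param deviation RMSD in Angstrom.
#' @param reference [xyz_structure] with at least 2 atoms.
#' @return Percentage (100 * deviation / radius of gyration).
#' @export
rmsd_percent <- function(deviation, reference) {
  stopifnot(inherits(reference, "xyz_structure"), deviation >= 0)
  if (n_atoms(reference) < 2L) stop("reference needs at least 2 atoms")
  rg <- radius_of_gyration(reference)
  if (rg < 1e-12) stop("degenerate reference: all atoms coincident")
  100 * deviation / rg
}

#' @rdname rmsd_percent
#' @export
radius_of_gyration <- function(reference) {
  stopifnot(inherits(reference, "xyz_structure"))
  centered <- sweep(reference$coords, 2, colMeans(reference$coords))
  sqrt(mean(rowSums(centered^2)))
}
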