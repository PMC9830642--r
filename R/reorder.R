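#' Reorder atoms so the leading atoms form a stable Z-matrix frame
#'
#' The first atoms of a Z-matrix define its orientation frame; a poor choice
#' (collinear, floppy, or reacting atoms up front) makes the field direction
#' drift or the optimization fail. Three reordering methods are provided:
#'
#' * **Method 0** — no reordering (identity permutation).
#' * **Method 1** — the four atoms nearest the unweighted Cartesian center of
#'   the *transition* structure are moved to positions 1-4 in ascending
#'   distance order; these core atoms are expected to displace least under a
#'   field. All other atoms keep their relative order.
#' * **Method 2** — the atom farthest from the transformation-site centroid
#'   becomes atom 1; that atom and all atoms following it in the original
#'   order move as a contiguous block to the top (internal order preserved),
#'   the remaining atoms follow in original order. This keeps connectivity
#'   implied by atom order intact while anchoring the frame on a spectator
#'   atom remote from the reacting center.
#'
#' The same permutation is applied to both structures so positional atom
#' correspondence is preserved. All distance ties break toward the lower
#' original index.
#'
#' @param method Integer 0, 1 or 2.
#' @param minimum,ts Aligned [xyz_structure] pair with equal atom counts.
#' @param reacting_atoms Integer indices of the atoms at the site of
#'   transformation (required by method 2; if `NULL`, inferred via
#'   [infer_reacting_atoms]).
#' @param threshold Distance-change threshold (Angstrom) for the inference
#'   fallback.
#' @return List with `permutation` (class `atom_permutation`: fields `perm`,
#'   an integer vector where new position i holds original index `perm[i]`,
#'   and `method`), `minimum` and `ts` (the reordered structures).
#' @export
reorder_structures <- function(method, minimum, ts, reacting_atoms = NULL,
                               threshold = 0.3) {
  stopifnot(inherits(minimum, "xyz_structure"), inherits(ts, "xyz_structure"))
  n <- n_atoms(minimum)
  if (n != n_atoms(ts)) stop("atom-count mismatch between minimum and ts")
  if (!method %in% c(0L, 1L, 2L)) stop("method must be 0, 1 or 2")
  method <- as.integer(method)

  perm <- switch(as.character(method),
    "0" = seq_len(n),
    "1" = {
      center <- colMeans(ts$coords)
      d <- sqrt(rowSums(sweep(ts$coords, 2, center)^2))
      ord <- order(d, seq_len(n))  # ties -> lower original index
      lead <- ord[seq_len(min(4L, n))]
      c(lead, setdiff(seq_len(n), lead))
    },
    "2" = {
      if (is.null(reacting_atoms)) {
        reacting_atoms <- infer_reacting_atoms(minimum, ts, threshold)
      }
      reacting_atoms <- as.integer(reacting_atoms)
      if (!length(reacting_atoms) || any(reacting_atoms < 1L) ||
          any(reacting_atoms > n)) {
        stop("configuration error: method 2 needs valid reacting_atoms ",
             "indices (supply them explicitly or lower the inference ",
             "threshold)")
      }
      site <- colMeans(ts$coords[reacting_atoms, , drop = FALSE])
      d <- sqrt(rowSums(sweep(ts$coords, 2, site)^2))
      far <- order(-d, seq_len(n))[1]  # ties -> lower original index
      c(far:n, seq_len(far - 1L)[seq_len(far - 1L) > 0])
    })
  perm <- as.integer(perm)

  out_min <- minimum; out_ts <- ts
  out_min$symbols <- minimum$symbols[perm]
  out_min$coords <- minimum$coords[perm, , drop = FALSE]
  out_ts$symbols <- ts$symbols[perm]
  out_ts$coords <- ts$coords[perm, , drop = FALSE]
  list(permutation = structure(list(perm = perm, method = method),
                               class = "atom_permutation"),
       minimum = out_min, ts = out_ts)
}

#' @export
print.atom_permutation <- function(x, ...) {
  cat(sprintf("atom_permutation (method %d): %s\n", x$method,
              paste(x$perm, collapse = " ")))
  invisible(x)
}

#' Infer the atoms at the site of transformation
#'
#' An atom is considered part of the reacting site when its interatomic
#' distance to some partner changes by more than `threshold` between the
#' local-minimum and transition-state structures. This is the fallback used
#' by reorder method 2 when the user does not name the reacting atoms.
#'
#' @param minimum,ts Aligned [xyz_structure] pair.
#' @param threshold Minimum absolute distance change (Angstrom, default 0.3).
#' @return Integer vector of atom indices (ascending).
#' @export
infer_reacting_atoms <- function(minimum, ts, threshold = 0.3) {
  stopifnot(inherits(minimum, "xyz_structure"), inherits(ts, "xyz_structure"))
  n <- n_atoms(minimum)
  if (n != n_atoms(ts)) stop("atom-count mismatch")
  dmin <- as.matrix(stats::dist(minimum$coords))
  dts <- as.matrix(stats::dist(ts$coords))
  change <- abs(dts - dmin)
  diag(change) <- 0
  hit <- which(apply(change, 1, max) > threshold)
  if (!length(hit)) {
    stop("no atom pair changes distance by more than ", threshold,
         " Angstrom between the two structures; supply reacting_atoms ",
         "explicitly")
  }
  as.integer(hit)
}

#' Check the quality of the orientation atoms
#'
#' Report-only diagnostic on a (reordered) structure: flags near-collinear
#' atoms 1-3 (angle within `collinear_tol` degrees of 0 or 180) and
#' near-coincident atoms among positions 1-4 (pairwise distance below
#' `proximity_tol` Angstrom). Either condition degrades the Z-matrix frame.
#'
#' @param x [xyz_structure] (at least 3 atoms for the collinearity check).
#' @param collinear_tol Degrees (default 5).
#' @param proximity_tol Angstrom (default 0.5).
#' @return List of class `orientation_report` with `collinear` (flag),
#'   `angle_123` (degrees), `close_pairs` (two-column matrix of flagged index
#'   pairs) and `clean` (overall flag).
#' @export
validate_orientation_atoms <- function(x, collinear_tol = 5,
                                       proximity_tol = 0.5) {
  stopifnot(inherits(x, "xyz_structure"))
  n <- n_atoms(x)
  angle <- NA_real_
  collinear <- FALSE
  if (n >= 3L) {
    angle <- .vector_angle(x$coords[2, ] - x$coords[1, ],
                           x$coords[3, ] - x$coords[1, ])
    collinear <- min(angle, 180 - angle) < collinear_tol
  }
  k <- min(4L, n)
  close_pairs <- matrix(integer(0), 0, 2)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (sqrt(sum((x$coords[i, ] - x$coords[j, ])^2)) < proximity_tol) {
          close_pairs <- rbind(close_pairs, c(i, j))
        }
      }
    }
  }
  structure(list(collinear = collinear, angle_123 = angle,
                 close_pairs = close_pairs,
                 clean = !collinear && nrow(close_pairs) == 0L),
            class = "orientation_report")
}

#' @export
print.orientation_report <- function(x, ...) {
  cat("orientation atoms:", if (x$clean) "clean" else "flagged", "\n")
  if (x$collinear) {
    cat(sprintf("  collinear atoms 1-3 (angle %.2f deg)\n", x$angle_123))
  }
  if (nrow(x$close_pairs)) {
    cat("  near-coincident pairs:",
        paste(apply(x$close_pairs, 1, paste, collapse = "-"), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a permutation map file
#'
#' Two-column plain-text map (new position, original index) recording how
#' atoms were reordered, so external tools can track correspondence.
#'
#' @param permutation An `atom_permutation` from [reorder_structures].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_permutation_map <- function(permutation, path) {
  stopifnot(inherits(permutation, "atom_permutation"))
  df <- data.frame(new = seq_along(permutation$perm),
                   original = permutation$perm)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
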