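#' Molecular structure container
#'
#' An ordered collection of atoms with Cartesian coordinates in Angstrom.
#' Atom order is significant throughout the package: alignment, reordering
#' and the Z-matrix frame all operate on positional correspondence.
#'
#' @param symbols Character vector of element symbols (e.g. `"C"`, `"O"`).
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param comment Free-text comment carried on the XYZ comment line.
#' @return An object of class `xyz_structure` with fields `symbols`, `coords`
#'   and `comment`.
#' @examples
#' h2 <- xyz_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' n_atoms(h2)
#' @export
xyz_structure <- function(symbols, coords, comment = "") {
  symbols <- as.character(symbols)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(symbols) < 1L) stop("a structure needs at least one atom")
  if (!is.matrix(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(symbols)) {
    stop("coords must be an N x 3 matrix matching length(symbols)")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  element_number(symbols)  # errors on unknown element
  dimnames(coords) <- NULL
  structure(list(symbols = symbols, coords = coords,
                 comment = as.character(comment)[1]),
            class = "xyz_structure")
}

#' @rdname xyz_structure
#' @param x An `xyz_structure`.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "xyz_structure"))
  length(x$symbols)
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("xyz_structure: %d atoms (%s)\n", n_atoms(x),
              paste(utils::head(x$symbols, 8), collapse = " ")))
  invisible(x)
}

#' Read a structure from an XYZ file
#'
#' Standard XYZ convention: an integer atom-count line, a comment line, then
#' one `symbol x y z` record per atom. Atom order is preserved.
#'
#' @param path Path to an existing `.xyz` file.
#' @return An [xyz_structure].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 3L) stop("XYZ format error in ", path,
                               ": fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ format error in ", path, ": count line 1 is not a positive ",
         "integer: '", lines[1], "'")
  }
  if (length(lines) < n + 2L) {
    stop("XYZ format error in ", path, ": count line declares ", n,
         " atoms but only ", length(lines) - 2L, " atom lines follow")
  }
  body <- lines[3:(n + 2L)]
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L) {
      stop("XYZ format error in ", path, ": line ", i + 2L,
           " ('", body[i], "') does not have 4 fields")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ format error in ", path, ": non-numeric coordinate on line ",
           i + 2L)
    }
    symbols[i] <- tok[1]
    coords[i, ] <- xyz
  }
  xyz_structure(symbols, coords, comment = lines[2])
}

#' Write a structure to an XYZ file
#'
#' @param x An [xyz_structure].
#' @param path Output path.
#' @param digits Decimal places for coordinates (at least 6).
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "xyz_structure"))
  digits <- max(6L, as.integer(digits))
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6L, digits, digits + 6L, digits, digits + 6L, digits)
  body <- sprintf(fmt, x$symbols, x$coords[, 1], x$coords[, 2], x$coords[, 3])
  out <- c(as.character(n_atoms(x)), x$comment, body)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Rigid frame rotation
#'
#' A proper rotation plus translation taking a structure from one Cartesian
#' orientation to another (here: from its aligned orientation into its
#' Z-matrix orientation). Directions such as dipole vectors are mapped with
#' the rotation alone.
#'
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1).
#' @param translation Length-3 translation vector (Angstrom).
#' @return Object of class `frame_rotation`.
#' @export
frame_rotation <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10) {
    stop("rotation is not orthogonal within 1e-10")
  }
  if (abs(det(rotation) - 1) > 1e-10) {
    stop("rotation must be proper (determinant +1); got det = ",
         format(det(rotation)))
  }
  structure(list(rotation = rotation, translation = translation),
            class = "frame_rotation")
}

#' @rdname frame_rotation
#' @param frame A `frame_rotation`.
#' @param x An [xyz_structure] or an N x 3 coordinate matrix.
#' @export
apply_frame <- function(frame, x) {
  stopifnot(inherits(frame, "frame_rotation"))
  if (inherits(x, "xyz_structure")) {
    x$coords <- apply_frame(frame, x$coords)
    return(x)
  }
  sweep(as.matrix(x) %*% t(frame$rotation), 2, -frame$translation)
}

# Rodrigues rotation taking unit vector `from` onto unit vector `to`.
.rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    ref <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(from[2] * ref[3] - from[3] * ref[2],
            from[3] * ref[1] - from[1] * ref[3],
            from[1] * ref[2] - from[2] * ref[1])
    ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

.rotation_about_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Orient a structure into its Z-matrix frame
#'
#' Applies the rigid motion placing atom 1 at the origin, atom 2 on the +z
#' axis, and atom 3 in the xz half-plane with x >= 0. This is the standard
#' Z-matrix orientation: it removes all translational and rotational freedom
#' with three atoms, so a field vector expressed in this frame keeps a fixed
#' direction relative to the molecule during a constrained optimization.
#'
#' @param x An [xyz_structure] with at least 3 atoms; atoms 1-3 must not be
#'   collinear (use a reorder method if they are).
#' @param collinear_tol Degrees from 0/180 below which atoms 1-3 are treated
#'   as collinear.
#' @return List with `structure` (the oriented copy) and `frame` (the
#'   [frame_rotation] mapping input coordinates to oriented coordinates).
#' @export
orient_to_zmatrix_frame <- function(x, collinear_tol = 1e-6) {
  stopifnot(inherits(x, "xyz_structure"))
  if (n_atoms(x) < 3L) stop("orientation requires at least 3 atoms")
  p <- x$coords
  v12 <- p[2, ] - p[1, ]
  v13 <- p[3, ] - p[1, ]
  ang <- .vector_angle(v12, v13)
  if (min(ang, 180 - ang) < collinear_tol) {
    stop("atoms 1-3 are collinear (angle ", format(ang, digits = 6),
         " deg): the Z-matrix frame is degenerate; reorder the atoms ",
         "(see reorder_structures) so the first three are not collinear")
  }
  r1 <- .rotation_between(v12, c(0, 0, 1))
  q3 <- as.numeric(r1 %*% v13)
  r2 <- .rotation_about_z(-atan2(q3[2], q3[1]))
  rot <- r2 %*% r1
  trans <- as.numeric(-rot %*% p[1, ])
  frame <- frame_rotation(rot, trans)
  oriented <- x
  oriented$coords <- sweep(p %*% t(rot), 2, -trans)
  list(structure = oriented, frame = frame)
}

.vector_angle <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stop("zero-length vector in angle computation")
  cosang <- max(-1, min(1, sum(u * v) / (cu * cv)))
  acos(cosang) * 180 / pi
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build a simple-chain Z-matrix
#'
#' Internal-coordinate representation where entry i is defined relative to
#' atoms i-1 (bond length), i-2 (angle) and i-3 (dihedral). The chain
#' convention is deterministic; choosing an atom order that makes the chain
#' chemically sensible is the job of the reorder methods.
#'
#' @param x An oriented [xyz_structure] (see [orient_to_zmatrix_frame]).
#' @param angle_tol Degrees from 0/180 within which a reference angle is
#'   flagged as a Z-matrix quality problem (warning, not fatal).
#' @return Object of class `zmatrix`: `symbols`, per-entry `refs` (up to
#'   three back-references), `lengths` (Angstrom), `angles` and `dihedrals`
#'   (degrees), and `quality_warnings`.
#' @export
build_zmatrix <- function(x, angle_tol = 1e-3) {
  stopifnot(inherits(x, "xyz_structure"))
  n <- n_atoms(x)
  p <- x$coords
  lengths <- rep(NA_real_, n); angles <- rep(NA_real_, n)
  dihedrals <- rep(NA_real_, n)
  refs <- matrix(NA_integer_, n, 3)
  warns <- character(0)
  for (i in seq_len(n)) {
    if (i >= 2L) {
      refs[i, 1] <- i - 1L
      lengths[i] <- sqrt(sum((p[i, ] - p[i - 1L, ])^2))
      if (lengths[i] <= 0) stop("coincident atoms ", i - 1L, " and ", i)
    }
    if (i >= 3L) {
      refs[i, 2] <- i - 2L
      angles[i] <- .vector_angle(p[i, ] - p[i - 1L, ], p[i - 2L, ] - p[i - 1L, ])
      if (min(angles[i], 180 - angles[i]) < angle_tol) {
        warns <- c(warns, sprintf(
          "entry %d: reference angle %.6f deg is nearly linear; Z-matrix quality is poor",
          i, angles[i]))
      }
    }
    if (i >= 4L) {
      refs[i, 3] <- i - 3L
      dihedrals[i] <- .dihedral_angle(p[i, ], p[i - 1L, ], p[i - 2L, ], p[i - 3L, ])
    }
  }
  if (length(warns)) warning(paste(warns, collapse = "; "), call. = FALSE)
  structure(list(symbols = x$symbols, refs = refs, lengths = lengths,
                 angles = angles, dihedrals = dihedrals,
                 quality_warnings = warns),
            class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(sprintf("zmatrix: %d entries, %d quality warning(s)\n",
              length(x$symbols), length(x$quality_warnings)))
  invisible(x)
}

#' Convert a Z-matrix back to Cartesian coordinates
#'
#' Reconstructs coordinates by sequential placement (natural extension
#' reference frame) and returns them in the standard Z-matrix orientation.
#'
#' @param zm A [build_zmatrix] result.
#' @return An [xyz_structure] in the Z-matrix orientation.
#' @export
zmatrix_to_structure <- function(zm) {
  stopifnot(inherits(zm, "zmatrix"))
  n <- length(zm$symbols)
  p <- matrix(0, n, 3)
  if (n >= 2L) p[2, ] <- c(0, 0, zm$lengths[2])
  if (n >= 3L) {
    # atom 3 bonded to atom 2 with angle 3-2-1, placed in the xz half-plane
    a <- zm$angles[3] * pi / 180
    p[3, ] <- p[2, ] + zm$lengths[3] * c(sin(a), 0, -cos(a))
  }
  if (n >= 4L) {
    for (i in 4:n) {
      p[i, ] <- .place_atom(p[i - 1L, ], p[i - 2L, ], p[i - 3L, ],
                            zm$lengths[i], zm$angles[i], zm$dihedrals[i])
    }
  }
  out <- xyz_structure(zm$symbols, p, comment = "reconstructed from Z-matrix")
  if (n >= 3L) out <- orient_to_zmatrix_frame(out)$structure
  out
}

# Place atom at distance r from a, angle theta (deg) a-b, dihedral phi (deg)
# a-b-c, following the NERF construction.
.place_atom <- function(a, b, c_, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- a - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - c_
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), -r * sin(theta) * sin(phi))
  a + d[1] * bc + d[2] * m + d[3] * n
}

#' Export a Z-matrix as Gaussian-style text
#'
#' Produces the Z-matrix block in Gaussian layout with a named variables
#' section (`Bn`, `An`, `Dn`).
#'
#' @param zm A [zmatrix].
#' @return Character vector of lines (Z-matrix block, blank line, variables).
#' @export
format_gaussian_zmatrix <- function(zm) {
  stopifnot(inherits(zm, "zmatrix"))
  n <- length(zm$symbols)
  lines <- character(n)
  vars <- character(0)
  for (i in seq_len(n)) {
    parts <- zm$symbols[i]
    if (i >= 2L) {
      parts <- c(parts, zm$refs[i, 1], sprintf("B%d", i))
      vars <- c(vars, sprintf("B%d=%.8f", i, zm$lengths[i]))
    }
    if (i >= 3L) {
      parts <- c(parts, zm$refs[i, 2], sprintf("A%d", i))
      vars <- c(vars, sprintf("A%d=%.8f", i, zm$angles[i]))
    }
    if (i >= 4L) {
      parts <- c(parts, zm$refs[i, 3], sprintf("D%d", i))
      vars <- c(vars, sprintf("D%d=%.8f", i, zm$dihedrals[i]))
    }
    lines[i] <- paste(parts, collapse = " ")
  }
  c(lines, "", vars)
}
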