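#' Representative reference values for the demo reaction
#'
#' A bundled, fixed set of values on the scale produced by hybrid-DFT
#' calculations of a small pericyclic reaction in the gas phase: dipole
#' moments of the two stationary points (Debye), zero-field electronic and
#' free energies (Hartree). These seed the demo fixtures so that toy-engine
#' pipelines exercise realistic magnitudes (a reaction dipole of a few Debye,
#' a barrier of a few tens of kcal/mol).
#'
#' @return Named list: `mu_int`, `mu_ts` (Debye), `e_int`, `e_ts`, `g_int`,
#'   `g_ts` (Hartree).
#' @export
demo_reaction_values <- function() {
  list(mu_int = c(0.2481, -1.8900, -0.0889),
       mu_ts = c(0.3813, 1.2430, 0.6952),
       e_int = -210.2570, e_ts = -210.1791,
       g_int = -210.2011, g_ts = -210.1282)
}

#' Solve point charges reproducing a target dipole
#'
#' Finds the minimum-norm per-atom charge vector with zero net charge whose
#' point-charge dipole `sum(q_i r_i)` equals the target exactly. Used by the
#' fixture generator to give the toy engine any desired dipole on a fixed
#' geometry.
#'
#' @param structure An [xyz_structure]; needs N >= 4 atoms spanning three
#'   dimensions (a planar or linear geometry cannot realize every dipole
#'   direction with zero net charge).
#' @param mu_debye Target dipole, Debye.
#' @return Numeric charge vector (e), length N.
#' @export
solve_charges_for_dipole <- function(structure, mu_debye) {
  stopifnot(inherits(structure, "xyz_structure"), length(mu_debye) == 3L)
  k <- oef_constants()
  r <- structure$coords * k$angstrom_to_bohr
  m <- rbind(t(r), rep(1, nrow(r)))       # 4 x N: dipole rows + neutrality
  gram <- m %*% t(m)
  if (rcond(gram) < 1e-12) {
    stop("degenerate geometry: cannot realize an arbitrary dipole ",
         "with zero net charge")
  }
  b <- c(as.numeric(mu_debye) * k$debye_to_au, 0)
  as.numeric(t(m) %*% solve(gram, b))
}

# fixed non-degenerate 6-atom skeleton used by the demo fixtures (Angstrom)
.fixture_coords <- function() {
  rbind(c(0.000, 0.000, 0.000),
        c(1.480, 0.000, 0.000),
        c(2.120, 1.150, 0.300),
        c(1.300, 2.250, 0.650),
        c(-0.550, 0.920, 0.180),
        c(-0.600, -0.850, -0.420))
}

#' Toy molecules for testing
#'
#' `fixture_water()` is a fixed water geometry; `fixture_molecule()` is a
#' reproducible random cloud of carbon atoms with a guaranteed
#' non-degenerate orientation frame (useful for property-style tests).
#'
#' @return An [xyz_structure].
#' @export
fixture_water <- function() {
  xyz_structure(c("O", "H", "H"),
                rbind(c(0.0000, 0.0000, 0.1173),
                      c(0.0000, 0.7572, -0.4692),
                      c(0.0000, -0.7572, -0.4692)),
                comment = "water fixture")
}

#' @rdname fixture_water
#' @param n Number of atoms (>= 4).
#' @param seed Integer seed for reproducibility.
#' @export
fixture_molecule <- function(n = 6L, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 4L)
  set.seed(seed)
  repeat {
    coords <- matrix(stats::runif(3L * n, -2, 2), n, 3)
    ok <- min(stats::dist(coords)) > 0.8
    ang <- .vector_angle(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ])
    if (ok && min(ang, 180 - ang) > 15) break
  }
  xyz_structure(rep("C", n), coords, comment = sprintf("random fixture %d", seed))
}

#' Demo reaction fixture: a matched toy-engine pair
#'
#' Builds a local-minimum / transition-state pair for the toy engine whose
#' zero-field dipoles and energies equal the bundled demo values
#' ([demo_reaction_values]) exactly. Both stationary points share the same
#' six-atom reference geometry and differ in their charge distributions (and
#' in the one negative-curvature mode carried by the transition-state
#' engine), so the reaction dipole comes out of the pipeline exactly as
#' seeded and every downstream quantity has a closed form.
#'
#' @param k Harmonic force constant, Hartree/bohr^2 (default 0.5, a typical
#'   bond-stretch stiffness; use a large value such as 1e6 for the rigid
#'   limit).
#' @param alpha_int,alpha_ts 3 x 3 polarizabilities (a.u.). Defaults are
#'   isotropic 65 and 70 a.u. — the scale of a small organic molecule, with
#'   the transition state slightly more polarizable so that barrier-vs-field
#'   curves show the expected slight curvature. Pass zero matrices for the
#'   polarizability-free limit.
#' @param values Reference values, as from [demo_reaction_values].
#' @return List: `minimum`, `ts` (identical [xyz_structure]s), `engine_min`,
#'   `engine_ts` ([toy_engine]s), and the seeded `values`.
#' @export
fixture_reaction <- function(k = 0.5,
                             alpha_int = diag(65, 3),
                             alpha_ts = diag(70, 3),
                             values = demo_reaction_values()) {
  coords <- .fixture_coords()
  sym <- c("C", "C", "O", "C", "H", "H")
  minimum <- xyz_structure(sym, coords, comment = "demo reaction minimum")
  ts <- xyz_structure(sym, coords, comment = "demo reaction transition state")
  q_int <- solve_charges_for_dipole(minimum, values$mu_int)
  q_ts <- solve_charges_for_dipole(ts, values$mu_ts)
  ts_axis <- coords[3, ] - coords[2, ]
  list(
    minimum = minimum, ts = ts,
    engine_min = toy_engine(minimum, q_int, k = k, E0 = values$e_int,
                            alpha = alpha_int,
                            g_offset = values$g_int - values$e_int),
    engine_ts = toy_engine(ts, q_ts, k = k, E0 = values$e_ts,
                           alpha = alpha_ts,
                           ts_axis = ts_axis / sqrt(sum(ts_axis^2)),
                           g_offset = values$g_ts - values$e_ts),
    values = values)
}

#' Synthetic log-file pair for parser testing
#'
#' Writes (or returns) two synthetic quantum-chemistry logs — one local
#' minimum, one transition state — carrying the bundled demo values, for
#' round-trip tests of [parse_gaussian_log] without any external code.
#'
#' @param dir Optional directory; when given, `minimum.log` and `ts.log` are
#'   written there.
#' @param values Reference values, as from [demo_reaction_values].
#' @return Named list of log texts (`minimum`, `ts`); paths are attached as
#'   attribute `paths` when `dir` is given.
#' @export
fixture_gaussian_logs <- function(dir = NULL, values = demo_reaction_values()) {
  fx <- fixture_reaction(values = values)
  log_min <- synthetic_gaussian_log(
    energy = values$e_int, dipole = values$mu_int, geometry = fx$minimum,
    frequencies = c(112.5, 345.8, 870.1, 1415.2, 1712.9, 3050.4),
    free_energy = values$g_int)
  log_ts <- synthetic_gaussian_log(
    energy = values$e_ts, dipole = values$mu_ts, geometry = fx$ts,
    frequencies = c(-612.7, 340.1, 865.3, 1400.8, 1705.2, 3041.6),
    free_energy = values$g_ts)
  out <- list(minimum = log_min, ts = log_ts)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(minimum = file.path(dir, "minimum.log"),
               ts = file.path(dir, "ts.log"))
    writeLines(log_min, paths["minimum"])
    writeLines(log_ts, paths["ts"])
    attr(out, "paths") <- paths
  }
  out
}
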