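#' Field-ramp configuration
#'
#' @param magnitudes Field magnitudes in atomic units, starting at 0 and
#'   strictly increasing. The default ramp (0, 2.5, 5.0, 7.5, 10.0 x 1e-3
#'   a.u.) spans the range where barrier response is near-linear for typical
#'   small organics.
#' @param reorder_method Atom-reordering method 0, 1 or 2 (see
#'   [reorder_structures]).
#' @param reacting_atoms Optional indices for reorder method 2.
#' @param freq Logical: engines are asked for (and the success check
#'   enforces) vibrational-mode counts — 0 imaginary for the minimum, 1 for
#'   the transition state.
#' @param direction `"stabilizing"` (default: field along the reaction axis
#'   in the physics convention, lowering the barrier) or `"destabilizing"`
#'   (negated, for sensitivity studies).
#' @param convention Sign convention fields are reported in: `"physics"` or
#'   `"gaussian"`.
#' @param r2_threshold Minimum R^2 of the barrier-vs-field line for a run to
#'   count as successful (default 0.95).
#' @param rmsd_warn_percent Structural-deviation warning threshold as a
#'   percentage of the reference radius of gyration (default 10).
#' @param rmsd_jump Maximum allowed step-to-step RMSD jump (Angstrom) before
#'   a discontinuity is flagged (default 0.05).
#' @param axis_threshold Reaction-axis degeneracy threshold, Debye.
#' @param seed Optional integer seed forwarded to any stochastic engine.
#' @return Object of class `ramp_config`.
#' @export
ramp_config <- function(magnitudes = c(0, 2.5e-3, 5.0e-3, 7.5e-3, 10.0e-3),
                        reorder_method = 0L, reacting_atoms = NULL,
                        freq = FALSE,
                        direction = c("stabilizing", "destabilizing"),
                        convention = c("physics", "gaussian"),
                        r2_threshold = 0.95, rmsd_warn_percent = 10,
                        rmsd_jump = 0.05, axis_threshold = 1e-3,
                        seed = NULL) {
  magnitudes <- as.numeric(magnitudes)
  if (length(magnitudes) < 1L || magnitudes[1] != 0 ||
      any(diff(magnitudes) <= 0)) {
    stop("magnitudes must start at 0 and strictly increase")
  }
  structure(list(magnitudes = magnitudes,
                 reorder_method = as.integer(reorder_method),
                 reacting_atoms = reacting_atoms, freq = isTRUE(freq),
                 direction = match.arg(direction),
                 convention = match.arg(convention),
                 r2_threshold = r2_threshold,
                 rmsd_warn_percent = rmsd_warn_percent,
                 rmsd_jump = rmsd_jump, axis_threshold = axis_threshold,
                 seed = seed),
            class = "ramp_config")
}

.as_structure <- function(x, what) {
  if (inherits(x, "xyz_structure")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_xyz(x))
  stop(what, " must be an xyz_structure or a path to an XYZ file")
}

# Shared front end of run_ramp and orientation_scan: zero-field optimization,
# alignment, reordering, orientation, dipoles, reaction axis. A degenerate
# (vanishing) reaction dipole aborts the ramp, which needs the axis, but is
# tolerated by the orientation scan, which explores all directions anyway.
.prepare_pair <- function(minimum, ts, engine_min, engine_ts, config,
                          degenerate_axis_ok = FALSE) {
  minimum <- .as_structure(minimum, "minimum")
  ts <- .as_structure(ts, "ts")
  if (!is.null(config$seed)) set.seed(config$seed)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  # (1) zero-field optimization of both stationary points
  opt_min <- engine_optimize(engine_min, minimum, NULL)
  opt_ts <- engine_optimize(engine_ts, ts, NULL)
  say("zero-field optimization: E_min = %.8f Ha, E_ts = %.8f Ha",
      opt_min$energy, opt_ts$energy)

  # (2) superpose the TS onto the minimum (positional correspondence)
  fit <- kabsch_superpose(opt_ts$geometry, opt_min$geometry)
  engine_ts <- engine_transform(
    engine_ts, frame_rotation(fit$alignment$rotation,
                              fit$alignment$translation))
  say("alignment: Kabsch RMSD = %.6f Angstrom", fit$alignment$rmsd)

  # (3) reorder atoms for a stable Z-matrix frame (same permutation both)
  ro <- reorder_structures(config$reorder_method, opt_min$geometry,
                           fit$structure, config$reacting_atoms)
  engine_min <- engine_permute(engine_min, ro$permutation$perm)
  engine_ts <- engine_permute(engine_ts, ro$permutation$perm)
  say("reorder method %d: permutation [%s]", config$reorder_method,
      paste(ro$permutation$perm, collapse = " "))
  quality <- list(minimum = validate_orientation_atoms(ro$minimum),
                  ts = validate_orientation_atoms(ro$ts))

  # (4) zero-field dipoles in the shared aligned frame
  sp_min <- engine_evaluate(engine_min, ro$minimum, NULL)
  sp_ts <- engine_evaluate(engine_ts, ro$ts, NULL)

  # (5) orient each structure into its own Z-matrix frame
  om <- orient_to_zmatrix_frame(ro$minimum)
  ot <- orient_to_zmatrix_frame(ro$ts)
  engine_min <- engine_transform(engine_min, om$frame)
  engine_ts <- engine_transform(engine_ts, ot$frame)

  # (6) reaction axis and its frame-mapped images
  axis <- tryCatch(
    reaction_axis(sp_min$dipole, sp_ts$dipole, om$frame, ot$frame,
                  threshold = config$axis_threshold),
    error = function(e) if (degenerate_axis_ok) NULL else stop(e))
  if (is.null(axis)) {
    say("reaction axis degenerate (||mu_rxn|| below threshold)")
  } else {
    say("reaction axis: ||mu_rxn|| = %.4f D, unit [%s]", axis$norm,
        paste(sprintf("%.4f", axis$unit), collapse = " "))
  }

  list(engine_min = engine_min, engine_ts = engine_ts,
       oriented_min = om$structure, oriented_ts = ot$structure,
       frame_min = om$frame, frame_ts = ot$frame,
       axis = axis, permutation = ro$permutation,
       alignment = fit$alignment, quality = quality, log = log)
}

#' Run the oriented-electric-field ramp
#'
#' The full pipeline: zero-field optimization of both stationary points,
#' least-squares superposition of the transition state onto the minimum,
#' atom reordering, per-structure Z-matrix orientation, reaction-axis
#' computation, and geometry optimization under fields of increasing
#' magnitude applied along the frame-mapped reaction axis. Each optimization
#' is seeded from the optimum at the preceding (weaker) field, which keeps
#' the geometric perturbation per step small.
#'
#' @param minimum,ts Local-minimum and transition-state structures
#'   ([xyz_structure] or paths to XYZ files) with consistent atom numbering.
#' @param engine_min,engine_ts Energy engines (see [engine-contract]);
#'   `engine_ts` defaults to `engine_min`.
#' @param config A [ramp_config].
#' @return Object of class `ramp_result`: `magnitudes` (completed), `results`
#'   (per-magnitude list with `minimum`/`ts` [engine_result]s and RMSDs
#'   relative to zero field in Angstrom and percent), `axis`
#'   ([reaction_axis]), `permutation`, `frames`, `alignment`, `config`,
#'   `truncated`/`truncation_reason`, and a structured `log`.
#' @export
run_ramp <- function(minimum, ts, engine_min, engine_ts = engine_min,
                     config = ramp_config()) {
  stopifnot(inherits(config, "ramp_config"))
  prep <- .prepare_pair(minimum, ts, engine_min, engine_ts, config)
  log <- prep$log
  sign_dir <- if (config$direction == "stabilizing") 1 else -1
  ax_min <- sign_dir * prep$axis$mapped_sm
  ax_ts <- sign_dir * prep$axis$mapped_ts

  results <- list()
  truncated <- FALSE
  reason <- NULL
  seed_min <- prep$oriented_min
  seed_ts <- prep$oriented_ts
  zero_min <- NULL
  zero_ts <- NULL
  for (m in config$magnitudes) {
    f_min <- if (m > 0) field_vector(ax_min, m) else NULL
    f_ts <- if (m > 0) field_vector(ax_ts, m) else NULL
    res <- tryCatch(
      list(minimum = engine_optimize(prep$engine_min, seed_min, f_min),
           ts = engine_optimize(prep$engine_ts, seed_ts, f_ts)),
      error = function(e) e)
    if (inherits(res, "error") || !res$minimum$converged ||
        !res$ts$converged) {
      truncated <- TRUE
      reason <- if (inherits(res, "error")) conditionMessage(res) else
        "engine did not converge"
      log <- c(log, sprintf(
        "ramp truncated at |F| = %g a.u.: %s", m, reason))
      break
    }
    if (m == 0) {
      zero_min <- res$minimum$geometry
      zero_ts <- res$ts$geometry
    }
    entry <- list(
      magnitude = m,
      minimum = res$minimum, ts = res$ts,
      rmsd_min = rmsd(res$minimum$geometry, zero_min),
      rmsd_ts = rmsd(res$ts$geometry, zero_ts))
    entry$rmsd_min_pct <- rmsd_percent(entry$rmsd_min, zero_min)
    entry$rmsd_ts_pct <- rmsd_percent(entry$rmsd_ts, zero_ts)
    results[[length(results) + 1L]] <- entry
    log <- c(log, sprintf(
      "|F| = %6.4g a.u.: E_min = %.8f, E_ts = %.8f, RMSD(min) = %.4f, RMSD(ts) = %.4f",
      m, res$minimum$energy, res$ts$energy, entry$rmsd_min, entry$rmsd_ts))
    seed_min <- res$minimum$geometry
    seed_ts <- res$ts$geometry
  }
  if (!length(results)) stop("ramp failed at zero field: ", reason)

  structure(list(
    magnitudes = vapply(results, `[[`, numeric(1), "magnitude"),
    results = results, axis = prep$axis, permutation = prep$permutation,
    frames = list(minimum = prep$frame_min, ts = prep$frame_ts),
    alignment = prep$alignment, quality = prep$quality, config = config,
    truncated = truncated, truncation_reason = reason, log = log),
    class = "ramp_result")
}

#' @export
print.ramp_result <- function(x, ...) {
  cat(sprintf("ramp_result: %d field strengths%s, ||mu_rxn|| = %.4f D\n",
              length(x$results),
              if (x$truncated) " (TRUNCATED)" else "", x$axis$norm))
  invisible(x)
}

.barrier_series <- function(ramp) {
  k <- oef_constants()
  data.frame(
    magnitude = ramp$magnitudes,
    dE = vapply(ramp$results, function(r)
      (r$ts$energy - r$minimum$energy) * k$hartree_to_kcal, numeric(1)),
    dG = vapply(ramp$results, function(r) {
      if (is.null(r$ts$free_energy) || is.null(r$minimum$free_energy))
        NA_real_
      else (r$ts$free_energy - r$minimum$free_energy) * k$hartree_to_kcal
    }, numeric(1)))
}

#' Diagnose whether a ramp was successful
#'
#' A successful run shows a near-linear reduction of the activation energy
#' with field magnitude (R^2 of the ordinary least-squares line above the
#' configured threshold, default 0.95; slight curvature from the
#' polarizability is expected), no discontinuous jumps in energy or geometry,
#' and — when frequency data are requested — zero imaginary modes for the
#' minimum and exactly one for the transition state at every field strength.
#'
#' A point is flagged as an energy discontinuity when its residual from the
#' fitted line exceeds 3x a robust residual scale (the median absolute
#' residual, floored at 0.01 kcal/mol); a geometry discontinuity is a
#' step-to-step RMSD jump above `config$rmsd_jump`.
#'
#' @param ramp A [run_ramp] result with at least 3 completed magnitudes.
#' @param config A [ramp_config]; defaults to the one stored in `ramp`.
#' @return Object of class `success_report`: `r2`, `slope` (kcal/mol per
#'   a.u.), `intercept`, `discontinuities` (integer indices),
#'   `rmsd_warnings`, `frequency_ok`, `pass`.
#' @export
evaluate_success <- function(ramp, config = ramp$config) {
  stopifnot(inherits(ramp, "ramp_result"))
  if (length(ramp$results) < 3L) {
    stop("insufficient data: need at least 3 completed field magnitudes, got ",
         length(ramp$results))
  }
  ser <- .barrier_series(ramp)
  fit <- stats::lm(dE ~ magnitude, data = ser)
  res <- stats::residuals(fit)
  ss_tot <- sum((ser$dE - mean(ser$dE))^2)
  r2 <- if (ss_tot < 1e-20) 1 else 1 - sum(res^2) / ss_tot
  scale <- max(stats::median(abs(res)), 0.01)
  disc_energy <- which(abs(res) > 3 * scale)
  dr_min <- abs(diff(vapply(ramp$results, `[[`, numeric(1), "rmsd_min")))
  dr_ts <- abs(diff(vapply(ramp$results, `[[`, numeric(1), "rmsd_ts")))
  disc_geom <- which(dr_min > config$rmsd_jump | dr_ts > config$rmsd_jump) + 1L
  discontinuities <- sort(unique(c(disc_energy, disc_geom)))

  rmsd_warnings <- character(0)
  for (r in ramp$results) {
    for (side in c("min", "ts")) {
      pct <- r[[paste0("rmsd_", side, "_pct")]]
      if (pct > config$rmsd_warn_percent) {
        rmsd_warnings <- c(rmsd_warnings, sprintf(
          "|F| = %g a.u.: %s RMSD is %.1f%% of the reference size (%.4f A)",
          r$magnitude, side, pct, r[[paste0("rmsd_", side)]]))
      }
    }
  }

  frequency_ok <- TRUE
  if (config$freq) {
    n_min <- vapply(ramp$results, function(r) r$minimum$n_imaginary,
                    integer(1))
    n_ts <- vapply(ramp$results, function(r) r$ts$n_imaginary, integer(1))
    frequency_ok <- !anyNA(c(n_min, n_ts)) && all(n_min == 0L) &&
      all(n_ts == 1L)
  }

  pass <- r2 >= config$r2_threshold && length(discontinuities) == 0L &&
    frequency_ok && !ramp$truncated
  structure(list(r2 = r2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 discontinuities = discontinuities,
                 rmsd_warnings = rmsd_warnings,
                 frequency_ok = frequency_ok,
                 truncated = ramp$truncated,
                 pass = pass),
            class = "success_report")
}

#' @export
print.success_report <- function(x, ...) {
  cat(sprintf("success_report: %s (R^2 = %.4f, slope = %.2f kcal/mol per a.u.)\n",
              if (x$pass) "PASS" else "FAIL", x$r2, x$slope))
  if (length(x$discontinuities)) {
    cat("  discontinuities at points:",
        paste(x$discontinuities, collapse = ", "), "\n")
  }
  if (length(x$rmsd_warnings)) {
    cat(paste0("  warning: ", x$rmsd_warnings, collapse = "\n"), "\n")
  }
  if (!x$frequency_ok) cat("  imaginary-frequency check failed\n")
  invisible(x)
}

#' Uniform direction sets on the unit sphere
#'
#' `dodecahedron_directions()` returns the 20 vertices of a regular
#' dodecahedron (normalized): a deterministic, antipodally symmetric,
#' isotropic direction set. `fibonacci_sphere_directions(n)` is the standard
#' Fibonacci-lattice fallback for other counts.
#'
#' @return An n x 3 matrix of unit vectors.
#' @export
dodecahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  s <- 1 / phi
  v <- rbind(
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    cbind(0, c(-s, -s, s, s), c(-phi, phi, -phi, phi)),
    cbind(c(-s, -s, s, s), c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-s, -s, s, s)))
  dimnames(v) <- NULL
  v / sqrt(rowSums(v^2))
}

#' @rdname dodecahedron_directions
#' @param n Number of directions (>= 4).
#' @export
fibonacci_sphere_directions <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 4L)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Scan barrier response over field orientations
#'
#' Applies a field of fixed magnitude along a set of directions distributed
#' over the unit sphere (the 20 dodecahedron vertices when `n_directions` is
#' 20, a Fibonacci lattice otherwise), optimizing both structures under each
#' field and recording the resulting barrier. Used to validate that the
#' barrier-minimizing orientation coincides with the reaction axis.
#'
#' Directions are expressed in the shared aligned Cartesian frame and mapped
#' into each structure's Z-matrix frame before the field is applied, exactly
#' as in [run_ramp].
#'
#' @inheritParams run_ramp
#' @param magnitude Field magnitude, a.u. (default 5.0e-3).
#' @param n_directions Number of directions (>= 4, default 20).
#' @return Object of class `orientation_scan`: a `table` data frame
#'   (direction components, barrier in kcal/mol, barrier change vs zero
#'   field, `ok` flag), the `axis` (`NULL` when the reaction dipole is
#'   degenerate — the scan itself does not need it), the zero-field barrier,
#'   and the indices of the extremal directions (`i_min`, `i_max`).
#' @export
orientation_scan <- function(minimum, ts, engine_min, engine_ts = engine_min,
                             magnitude = 5.0e-3, n_directions = 20L,
                             config = ramp_config()) {
  stopifnot(magnitude > 0)
  n_directions <- as.integer(n_directions)
  if (n_directions < 4L) stop("n_directions must be >= 4")
  prep <- .prepare_pair(minimum, ts, engine_min, engine_ts, config,
                        degenerate_axis_ok = TRUE)
  dirs <- if (n_directions == 20L) dodecahedron_directions() else
    fibonacci_sphere_directions(n_directions)
  k <- oef_constants()

  e0_min <- engine_optimize(prep$engine_min, prep$oriented_min, NULL)
  e0_ts <- engine_optimize(prep$engine_ts, prep$oriented_ts, NULL)
  barrier0 <- (e0_ts$energy - e0_min$energy) * k$hartree_to_kcal

  barrier <- rep(NA_real_, n_directions)
  ok <- rep(FALSE, n_directions)
  for (i in seq_len(n_directions)) {
    d <- dirs[i, ]
    f_min <- field_vector(map_axis_to_frame(d, prep$frame_min), magnitude)
    f_ts <- field_vector(map_axis_to_frame(d, prep$frame_ts), magnitude)
    res <- tryCatch(
      list(minimum = engine_optimize(prep$engine_min, prep$oriented_min,
                                     f_min),
           ts = engine_optimize(prep$engine_ts, prep$oriented_ts, f_ts)),
      error = function(e) e)
    if (inherits(res, "error") || !res$minimum$converged ||
        !res$ts$converged) next
    barrier[i] <- (res$ts$energy - res$minimum$energy) * k$hartree_to_kcal
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("orientation scan failed for every direction")
  tab <- data.frame(dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                    barrier = barrier, ddE = barrier - barrier0, ok = ok)
  structure(list(table = tab, axis = prep$axis, barrier0 = barrier0,
                 magnitude = magnitude,
                 i_min = which.min(replace(barrier, !ok, Inf)),
                 i_max = which.max(replace(barrier, !ok, -Inf))),
            class = "orientation_scan")
}

#' @export
print.orientation_scan <- function(x, ...) {
  cat(sprintf(
    "orientation_scan: %d directions at |F| = %g a.u.; barrier %.2f..%.2f kcal/mol\n",
    nrow(x$table), x$magnitude,
    min(x$table$barrier, na.rm = TRUE), max(x$table$barrier, na.rm = TRUE)))
  invisible(x)
}
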