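#' Field-ramp summary table
#'
#' The tabular product of a ramp: dipole block, per-magnitude electronic
#' (and, when present, free) energies for both stationary points, activation
#' energies, field-induced barrier changes relative to zero field, and RMSD
#' rows. All arithmetic is carried at full precision; rounding happens only
#' when the table is serialized.
#'
#' @param magnitudes Field magnitudes (a.u.), first entry 0.
#' @param e_int,e_ts Electronic energies (Hartree) per magnitude.
#' @param g_int,g_ts Optional free energies (Hartree) per magnitude.
#' @param mu_int,mu_ts Optional zero-field dipoles (Debye) populating the
#'   dipole block.
#' @param rmsd_int,rmsd_ts Optional RMSD vs zero field (Angstrom).
#' @return Object of class `report_table` with the barrier columns `dE`,
#'   `ddE` (and `dG`, `ddG`) in kcal/mol.
#' @export
report_table <- function(magnitudes, e_int, e_ts, g_int = NULL, g_ts = NULL,
                         mu_int = NULL, mu_ts = NULL,
                         rmsd_int = NULL, rmsd_ts = NULL) {
  magnitudes <- as.numeric(magnitudes)
  n <- length(magnitudes)
  stopifnot(n >= 1L, length(e_int) == n, length(e_ts) == n)
  if (magnitudes[1] != 0) {
    stop("the zero-field pair must be present as the first magnitude")
  }
  k <- oef_constants()
  dE <- (e_ts - e_int) * k$hartree_to_kcal
  ddE <- dE - dE[1]
  dG <- ddG <- NULL
  if (!is.null(g_int) && !is.null(g_ts)) {
    stopifnot(length(g_int) == n, length(g_ts) == n)
    dG <- (g_ts - g_int) * k$hartree_to_kcal
    ddG <- dG - dG[1]
  }
  dipoles <- NULL
  if (!is.null(mu_int) && !is.null(mu_ts)) {
    mu_rxn <- reaction_dipole(mu_int, mu_ts)
    dipoles <- list(mu_int = as.numeric(mu_int), mu_ts = as.numeric(mu_ts),
                    mu_rxn = mu_rxn,
                    norm_int = sqrt(sum(mu_int^2)),
                    norm_ts = sqrt(sum(mu_ts^2)),
                    norm_rxn = sqrt(sum(mu_rxn^2)))
  }
  structure(list(magnitudes = magnitudes, e_int = e_int, e_ts = e_ts,
                 g_int = g_int, g_ts = g_ts, dE = dE, ddE = ddE,
                 dG = dG, ddG = ddG, dipoles = dipoles,
                 rmsd_int = rmsd_int, rmsd_ts = rmsd_ts),
            class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat("report_table:\n")
  df <- data.frame(F_au = x$magnitudes, dE_kcal = round(x$dE, 2),
                   ddE_kcal = round(x$ddE, 2))
  if (!is.null(x$dG)) {
    df$dG_kcal <- round(x$dG, 2)
    df$ddG_kcal <- round(x$ddG, 2)
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate activation energies from a ramp result
#'
#' @param ramp A [run_ramp] result containing the zero-field pair.
#' @return A [report_table].
#' @export
activation_energies <- function(ramp) {
  stopifnot(inherits(ramp, "ramp_result"))
  if (!length(ramp$results) || ramp$results[[1]]$magnitude != 0) {
    stop("ramp is missing the zero-field result pair")
  }
  gi <- vapply(ramp$results, function(r)
    if (is.null(r$minimum$free_energy)) NA_real_ else r$minimum$free_energy,
    numeric(1))
  gt <- vapply(ramp$results, function(r)
    if (is.null(r$ts$free_energy)) NA_real_ else r$ts$free_energy, numeric(1))
  has_g <- !anyNA(gi) && !anyNA(gt)
  report_table(
    magnitudes = ramp$magnitudes,
    e_int = vapply(ramp$results, function(r) r$minimum$energy, numeric(1)),
    e_ts = vapply(ramp$results, function(r) r$ts$energy, numeric(1)),
    g_int = if (has_g) gi, g_ts = if (has_g) gt,
    mu_int = ramp$axis$mu_int, mu_ts = ramp$axis$mu_ts,
    rmsd_int = vapply(ramp$results, `[[`, numeric(1), "rmsd_min"),
    rmsd_ts = vapply(ramp$results, `[[`, numeric(1), "rmsd_ts"))
}

.ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-20) 1 else
    1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = max(0, min(1, r2)))
}

#' Fit activation energy against field magnitude
#'
#' Ordinary least squares of the activation energy (electronic, and free
#' when present) against field magnitude, zero-field point included. The R^2
#' of this line is the run-success statistic: near-linearity is expected to
#' first order, with slight curvature from the polarizability.
#'
#' @param table A [report_table] with at least 3 magnitudes.
#' @return List with `electronic` and (optionally) `free`, each containing
#'   `slope` (kcal/mol per a.u.), `intercept` (kcal/mol) and `r2`. A constant
#'   series has no defined R^2 and is reported as `r2 = 1` with zero slope
#'   and a `note`.
#' @export
fit_barrier_vs_field <- function(table) {
  stopifnot(inherits(table, "report_table"))
  if (length(table$magnitudes) < 3L) {
    stop("insufficient data: need at least 3 magnitudes")
  }
  fit_one <- function(y) {
    if (max(y) - min(y) < 1e-12) {
      return(list(slope = 0, intercept = y[1], r2 = 1,
                  note = "constant series: R^2 undefined, reported as 1"))
    }
    .ols(table$magnitudes, y)
  }
  out <- list(electronic = fit_one(table$dE))
  if (!is.null(table$dG)) out$free <- fit_one(table$dG)
  out
}

#' Correlate barrier change with reaction-dipole magnitude
#'
#' Across a set of reactions, the field-induced barrier change at a fixed
#' field magnitude correlates linearly with the reaction-dipole magnitude
#' (the first-order law predicts slope = -F in converted units). This
#' utility fits that line for multi-reaction studies.
#'
#' @param mu_rxn_norm Reaction-dipole magnitudes, Debye (one per reaction).
#' @param ddE Barrier changes at the chosen field, kcal/mol (same length).
#' @return List with `slope` (kcal/mol per Debye), `intercept` and `r2`.
#' @export
dipole_barrier_correlation <- function(mu_rxn_norm, ddE) {
  mu_rxn_norm <- as.numeric(mu_rxn_norm)
  ddE <- as.numeric(ddE)
  if (length(mu_rxn_norm) != length(ddE)) stop("length mismatch")
  if (length(ddE) < 3L) {
    stop("insufficient data: need at least 3 (||mu_rxn||, ddE) records")
  }
  .ols(mu_rxn_norm, ddE)
}

.fmt <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the ramp report files
#'
#' Serializes a [report_table] (plus optional fits and success report) into a
#' results directory:
#'
#' * `report.csv` — dipole block and per-magnitude energy/barrier/RMSD rows
#'   (Hartree and Debye at 4 decimal places, kcal/mol at 2, RMSD at 4);
#' * `plot_data.csv` — full-precision (magnitude, dE, dG) for plotting;
#' * `summary.txt` — human-readable run summary.
#'
#' Re-export of the same inputs is byte-identical.
#'
#' @param table A [report_table].
#' @param directory Output directory (created if needed).
#' @param fits Optional [fit_barrier_vs_field] result.
#' @param success Optional [evaluate_success] report.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(table, directory, fits = NULL, success = NULL) {
  stopifnot(inherits(table, "report_table"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  rows <- character(0)
  add <- function(...) rows <<- c(rows, paste(c(...), collapse = ","))
  if (!is.null(table$dipoles)) {
    d <- table$dipoles
    add("quantity", "x", "y", "z", "norm")
    add("mu_Int_debye", .fmt(d$mu_int, 4), .fmt(d$norm_int, 4))
    add("mu_TS_debye", .fmt(d$mu_ts, 4), .fmt(d$norm_ts, 4))
    add("mu_rxn_debye", .fmt(d$mu_rxn, 4), .fmt(d$norm_rxn, 4))
    add("")
  }
  add("quantity", paste0("F=", format(table$magnitudes, trim = TRUE)))
  add("E_Int_hartree", .fmt(table$e_int, 4))
  add("E_TS_hartree", .fmt(table$e_ts, 4))
  add("dE_kcal_mol", .fmt(table$dE, 2))
  add("ddE_kcal_mol", .fmt(table$ddE, 2))
  if (!is.null(table$dG)) {
    add("G_Int_hartree", .fmt(table$g_int, 4))
    add("G_TS_hartree", .fmt(table$g_ts, 4))
    add("dG_kcal_mol", .fmt(table$dG, 2))
    add("ddG_kcal_mol", .fmt(table$ddG, 2))
  }
  if (!is.null(table$rmsd_int)) add("RMSD_Int_angstrom", .fmt(table$rmsd_int, 4))
  if (!is.null(table$rmsd_ts)) add("RMSD_TS_angstrom", .fmt(table$rmsd_ts, 4))
  report_path <- file.path(directory, "report.csv")
  writeLines(rows, report_path)

  plot_df <- data.frame(magnitude_au = table$magnitudes,
                        dE_kcal_mol = table$dE)
  if (!is.null(table$dG)) plot_df$dG_kcal_mol <- table$dG
  plot_path <- file.path(directory, "plot_data.csv")
  utils::write.table(plot_df, plot_path, sep = ",", row.names = FALSE,
                     quote = FALSE)

  sm <- c(sprintf("field magnitudes (a.u.): %s",
                  paste(format(table$magnitudes, trim = TRUE),
                        collapse = ", ")),
          sprintf("zero-field dE = %.2f kcal/mol", table$dE[1]))
  if (!is.null(fits)) {
    sm <- c(sm, sprintf(
      "electronic fit: slope = %.4f kcal/mol per a.u., R^2 = %.6f",
      fits$electronic$slope, fits$electronic$r2))
    if (!is.null(fits$free)) {
      sm <- c(sm, sprintf(
        "free-energy fit: slope = %.4f kcal/mol per a.u., R^2 = %.6f",
        fits$free$slope, fits$free$r2))
    }
  }
  if (!is.null(success)) {
    sm <- c(sm, sprintf("success: %s (R^2 = %.4f, %d discontinuity flag(s), %d RMSD warning(s))",
                        if (success$pass) "PASS" else "FAIL", success$r2,
                        length(success$discontinuities),
                        length(success$rmsd_warnings)),
            success$rmsd_warnings)
  }
  summary_path <- file.path(directory, "summary.txt")
  writeLines(sm, summary_path)
  invisible(c(report_path, plot_path, summary_path))
}

#' Write all run artifacts for a completed ramp
#'
#' Convenience wrapper writing the report files, the reaction-axis vectors
#' (Debye, plus the unit axis and its frame-mapped images) and the atom
#' permutation map into one results directory.
#'
#' @param ramp A [run_ramp] result.
#' @param directory Output directory.
#' @return Invisibly, the paths written.
#' @export
write_run_artifacts <- function(ramp, directory) {
  stopifnot(inherits(ramp, "ramp_result"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  table <- activation_energies(ramp)
  fits <- if (length(ramp$results) >= 3L) fit_barrier_vs_field(table)
  success <- if (length(ramp$results) >= 3L) evaluate_success(ramp)
  paths <- write_report(table, directory, fits = fits, success = success)

  ax <- ramp$axis
  axis_lines <- c(
    sprintf("mu_Int_debye: %s", paste(sprintf("%.6f", ax$mu_int), collapse = " ")),
    sprintf("mu_TS_debye: %s", paste(sprintf("%.6f", ax$mu_ts), collapse = " ")),
    sprintf("mu_rxn_debye: %s", paste(sprintf("%.6f", ax$mu_rxn), collapse = " ")),
    sprintf("norm_debye: %.6f", ax$norm),
    sprintf("unit_axis: %s", paste(sprintf("%.8f", ax$unit), collapse = " ")),
    sprintf("mapped_sm: %s", paste(sprintf("%.8f", ax$mapped_sm), collapse = " ")),
    sprintf("mapped_ts: %s", paste(sprintf("%.8f", ax$mapped_ts), collapse = " ")))
  axis_path <- file.path(directory, "reaction_axis.txt")
  writeLines(axis_lines, axis_path)

  perm_path <- file.path(directory, "permutation.tsv")
  write_permutation_map(ramp$permutation, perm_path)

  log_path <- file.path(directory, "run_log.txt")
  writeLines(ramp$log, log_path)
  invisible(c(paths, axis_path, perm_path, log_path))
}
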