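#' Gaussian-style job specification
#'
#' Describes one quantum-chemistry job for the file-format adapter. The
#' adapter writes input decks and parses log files; it never executes or
#' schedules jobs — running them is the user's infrastructure.
#'
#' @param route Level-of-theory string (e.g. `"B3LYP/def2TZVP"`); treated as
#'   opaque user input.
#' @param charge Integer total charge.
#' @param multiplicity Positive integer spin multiplicity; checked for
#'   consistency with the electron parity implied by the charge.
#' @param geometry A [zmatrix].
#' @param field Optional [field_vector]; written in the file's own (gaussian)
#'   sign convention regardless of the convention it is supplied in.
#' @param freq Logical: request a frequency analysis.
#' @param opt Logical: request a geometry optimization (in internal
#'   coordinates, so the Z-matrix frame is preserved).
#' @param title Job title line.
#' @return Object of class `gaussian_job`.
#' @export
gaussian_job <- function(route, charge, multiplicity, geometry, field = NULL,
                         freq = FALSE, opt = TRUE, title = "oefield job") {
  stopifnot(is.character(route), length(route) == 1L,
            inherits(geometry, "zmatrix"))
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L) {
    stop("multiplicity must be a positive integer")
  }
  n_elec <- sum(element_number(geometry$symbols)) - charge
  if (n_elec < 0) stop("charge exceeds available electrons")
  if ((n_elec + multiplicity) %% 2L == 0L) {
    stop("multiplicity ", multiplicity, " is inconsistent with ", n_elec,
         " electrons (parity mismatch)")
  }
  if (!is.null(field)) stopifnot(inherits(field, "field_vector"))
  structure(list(route = route, charge = charge, multiplicity = multiplicity,
                 geometry = geometry, field = field, freq = isTRUE(freq),
                 opt = isTRUE(opt), title = as.character(title)[1]),
            class = "gaussian_job")
}

#' Write a Gaussian-style input deck
#'
#' Deterministic, byte-stable text: route section, title, charge/multiplicity
#' line, Z-matrix block with a named variables section, and (when a field is
#' requested) the field specification. Two field dialects are supported:
#'
#' * `"read"` (default) — the route carries `Field=Read` and an explicit
#'   three-component field record (a.u.) follows the geometry; this expresses
#'   an arbitrary direction, which the mapped reaction axis generally is.
#' * `"axis"` — the single-axis `Field=X+N` token (N in 1e-4 a.u.); only
#'   valid when the field is exactly axis-aligned.
#'
#' The sign written to file follows the file format's own convention, which
#' is opposite to the physics convention: a supplied physics-convention field
#' is negated at this boundary.
#'
#' @param job A [gaussian_job].
#' @param dialect `"read"` or `"axis"`.
#' @return Character scalar: the full input text.
#' @export
write_gaussian_input <- function(job, dialect = c("read", "axis")) {
  stopifnot(inherits(job, "gaussian_job"))
  dialect <- match.arg(dialect)
  if (is.null(job$geometry)) stop("job has no geometry")
  route <- paste0("# ", job$route)
  if (job$opt) route <- paste0(route, " Opt=Z-Matrix")
  if (job$freq) route <- paste0(route, " Freq")

  field_tail <- character(0)
  f_gauss <- NULL
  if (!is.null(job$field) && job$field$magnitude > 0) {
    f_gauss <- if (job$field$convention == "gaussian") {
      job$field$components
    } else {
      -job$field$components
    }
    f_gauss <- f_gauss + 0  # normalize IEEE signed zeros for stable output
    if (dialect == "read") {
      route <- paste0(route, " Field=Read")
      field_tail <- c("", sprintf("%.10f %.10f %.10f",
                                  f_gauss[1], f_gauss[2], f_gauss[3]))
    } else {
      nz <- which(abs(f_gauss) > 1e-15)
      if (length(nz) != 1L) {
        stop("dialect 'axis' requires an axis-aligned field; use 'read'")
      }
      ax <- c("X", "Y", "Z")[nz]
      n <- f_gauss[nz] / 1e-4
      if (abs(n - round(n)) > 1e-9) {
        stop("dialect 'axis' requires the magnitude to be a multiple of ",
             "1e-4 a.u.")
      }
      route <- paste0(route, sprintf(" Field=%s%+d", ax, as.integer(round(n))))
    }
  }
  lines <- c(route, "", job$title, "",
             sprintf("%d %d", job$charge, job$multiplicity),
             format_gaussian_zmatrix(job$geometry),
             field_tail, "")
  paste(lines, collapse = "\n")
}

#' Parse a Gaussian-style log file
#'
#' Extracts the final SCF energy, the dipole vector (Debye), the final
#' geometry (last standard-orientation block), the count of imaginary
#' vibrational frequencies, the thermally corrected free energy when present,
#' and the normal-termination flag.
#'
#' @param x Path to a log file, or its text as a character vector of lines
#'   (a single string is split on newlines).
#' @return An [engine_result]. Abnormal termination yields
#'   `converged = FALSE` with whatever records were found; a log with no SCF
#'   energy record is a parse error.
#' @export
parse_gaussian_log <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(as.character(x), "\n", fixed = TRUE))
  }
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[EeDd][-+]?[0-9]+)?"

  scf <- grep("SCF Done:", lines, value = TRUE)
  if (!length(scf)) {
    stop("parse error: no 'SCF Done' energy record found in log")
  }
  energy <- .last_number(scf[length(scf)],
                         paste0("=\\s*(", num, ")"))

  dipole <- c(NA_real_, NA_real_, NA_real_)
  dip_at <- grep("Dipole moment", lines)
  if (length(dip_at)) {
    dl <- lines[dip_at[length(dip_at)] + 1L]
    m <- regmatches(dl, gregexpr(paste0("[XYZ]=\\s*(", num, ")"), dl,
                                 perl = TRUE))[[1]]
    if (length(m) >= 3L) {
      dipole <- as.numeric(sub("^[XYZ]=\\s*", "", m))[1:3]
    }
  }

  geometry <- .parse_orientation_block(lines, num)
  if (is.null(geometry)) {
    stop("parse error: no orientation (geometry) block found in log")
  }

  freq_lines <- grep("Frequencies --", lines, value = TRUE)
  n_imag <- if (length(freq_lines)) {
    stripped <- sub(".*--", "", freq_lines)
    vals <- as.numeric(unlist(regmatches(
      stripped, gregexpr(num, stripped, perl = TRUE))))
    sum(vals < 0)
  } else {
    NA_integer_
  }

  g_lines <- grep("Sum of electronic and thermal Free Energies", lines,
                  value = TRUE)
  free_energy <- if (length(g_lines)) {
    .last_number(g_lines[length(g_lines)], paste0("(", num, ")\\s*$"))
  }

  converged <- any(grepl("Normal termination", lines))
  engine_result(energy = energy, dipole = dipole, geometry = geometry,
                free_energy = free_energy, n_imaginary = n_imag,
                converged = converged)
}

.last_number <- function(line, pattern) {
  m <- regmatches(line, regexec(pattern, line, perl = TRUE))[[1]]
  if (length(m) < 2L) stop("parse error: malformed record: '", line, "'")
  as.numeric(gsub("[Dd]", "E", m[2]))
}

.parse_orientation_block <- function(lines, num) {
  starts <- grep("(Standard|Input) orientation:", lines)
  if (!length(starts)) return(NULL)
  i <- starts[length(starts)] + 5L  # skip 4 header/rule lines
  sym <- character(0); xyz <- NULL
  while (i <= length(lines) && !grepl("^\\s*-{5,}", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 6L) return(NULL)
    sym <- c(sym, element_symbol(as.integer(tok[2])))
    xyz <- rbind(xyz, as.numeric(tok[(length(tok) - 2L):length(tok)]))
    i <- i + 1L
  }
  if (!length(sym)) return(NULL)
  xyz_structure(sym, xyz, comment = "parsed from log")
}

#' Generate a synthetic Gaussian-style log (test fixture)
#'
#' Emits a minimal log with the records [parse_gaussian_log] consumes, for
#' round-trip testing of the parser without any quantum-chemistry code. The
#' content is synthetic: it is formatted like a Gaussian log but produced by
#' this function from the arguments alone.
#'
#' @param energy Final SCF energy, Hartree.
#' @param dipole Length-3 dipole, Debye.
#' @param geometry [xyz_structure].
#' @param frequencies Numeric vibrational frequencies (cm^-1); negative
#'   entries are imaginary modes. Omit for no frequency section.
#' @param free_energy Optional free energy, Hartree.
#' @param normal_termination Logical: end with the normal-termination line.
#' @return Character scalar: the synthetic log text.
#' @export
synthetic_gaussian_log <- function(energy, dipole, geometry,
                                   frequencies = numeric(0),
                                   free_energy = NULL,
                                   normal_termination = TRUE) {
  stopifnot(inherits(geometry, "xyz_structure"), length(dipole) == 3L)
  z <- element_number(geometry$symbols)
  geo <- c(
    "                         Standard orientation:",
    " ---------------------------------------------------------------------",
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    " ---------------------------------------------------------------------",
    sprintf(" %6d %10d %11d    %11.6f %11.6f %11.6f",
            seq_along(z), z, 0L,
            geometry$coords[, 1], geometry$coords[, 2], geometry$coords[, 3]),
    " ---------------------------------------------------------------------"
  )
  out <- c(
    " Entering Gaussian System",
    geo,
    sprintf(" SCF Done:  E(RTOY) =  %.8f     A.U. after    1 cycles", energy),
    " Dipole moment (field-independent basis, Debye):",
    sprintf("    X=    %10.4f    Y=    %10.4f    Z=    %10.4f  Tot=    %10.4f",
            dipole[1], dipole[2], dipole[3], sqrt(sum(dipole^2)))
  )
  if (length(frequencies)) {
    for (chunk in split(frequencies,
                        ceiling(seq_along(frequencies) / 3))) {
      out <- c(out, paste0(" Frequencies --  ",
                           paste(sprintf("%10.4f", chunk), collapse = " ")))
    }
  }
  if (!is.null(free_energy)) {
    out <- c(out, sprintf(
      " Sum of electronic and thermal Free Energies=        %.6f",
      free_energy))
  }
  if (normal_termination) {
    out <- c(out, " Normal termination of Gaussian 16.")
  }
  paste(out, collapse = "\n")
}

#' File-based engine stub for external quantum-chemistry workflows
#'
#' An engine-shaped object whose `optimize`/`evaluate` methods write the
#' corresponding input deck into `dir` and then stop with an informative
#' error: job execution is outside this package's scope. Use it to generate
#' the complete set of field-ramp input files for an external cluster; parse
#' the resulting logs with [parse_gaussian_log].
#'
#' @param route Level-of-theory string.
#' @param charge,multiplicity Integers (see [gaussian_job]).
#' @param dir Directory that receives the generated input decks.
#' @param freq Logical: request frequency analyses.
#' @return Object of class `gaussian_files_engine`.
#' @export
gaussian_files_engine <- function(route, charge, multiplicity, dir,
                                  freq = FALSE) {
  structure(list(route = route, charge = charge, multiplicity = multiplicity,
                 dir = dir, freq = freq, counter = 0L),
            class = "gaussian_files_engine")
}

.gaussian_files_emit <- function(engine, structure, field, tag) {
  if (!dir.exists(engine$dir)) dir.create(engine$dir, recursive = TRUE)
  zm <- build_zmatrix(orient_to_zmatrix_frame(structure)$structure)
  job <- gaussian_job(engine$route, engine$charge, engine$multiplicity, zm,
                      field = field, freq = engine$freq,
                      title = sprintf("oefield %s job", tag))
  mag <- if (is.null(field)) 0 else field$magnitude
  path <- file.path(engine$dir, sprintf("%s_F%07.4f.gjf", tag, mag * 1e3))
  writeLines(write_gaussian_input(job), path)
  path
}

#' @export
engine_optimize.gaussian_files_engine <- function(engine, structure,
                                                  field = NULL) {
  path <- .gaussian_files_emit(engine, structure, field, "opt")
  stop("gaussian_files_engine wrote '", path, "' but does not execute jobs; ",
       "run it externally and parse the log with parse_gaussian_log()",
       call. = FALSE)
}

#' @export
engine_evaluate.gaussian_files_engine <- function(engine, structure,
                                                  field = NULL) {
  path <- .gaussian_files_emit(engine, structure, field, "sp")
  stop("gaussian_files_engine wrote '", path, "' but does not execute jobs; ",
       "run it externally and parse the log with parse_gaussian_log()",
       call. = FALSE)
}
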