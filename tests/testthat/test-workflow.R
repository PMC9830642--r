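const <- oef_constants()

# a ramp_result skeleton for testing the success diagnostics in isolation
fake_ramp <- function(dE_kcal, magnitudes = seq(0, by = 2.5e-3,
                                                length.out = length(dE_kcal)),
                      rmsds = rep(0.002, length(dE_kcal)),
                      n_imag_ts = rep(1L, length(dE_kcal)),
                      freq = TRUE) {
  geo <- fixture_water()
  results <- lapply(seq_along(dE_kcal), function(i) {
    e_min <- -100
    list(magnitude = magnitudes[i],
         minimum = engine_result(e_min, c(0, 0, 0), geo, n_imaginary = 0L),
         ts = engine_result(e_min + dE_kcal[i] / const$hartree_to_kcal,
                            c(0, 0, 0), geo, n_imaginary = n_imag_ts[i]),
         rmsd_min = rmsds[i], rmsd_ts = rmsds[i],
         rmsd_min_pct = 1, rmsd_ts_pct = 1)
  })
  structure(list(magnitudes = magnitudes, results = results,
                 truncated = FALSE,
                 config = ramp_config(magnitudes = magnitudes, freq = freq)),
            class = "ramp_result")
}

test_that("a field-blind system gives flat barriers and zero RMSDs", {
  fx <- fixture_reaction()
  eng_min <- toy_engine(fx$minimum, q = rep(0, 6), k = 0.5, E0 = -10)
  eng_ts <- toy_engine(fx$ts, q = rep(0, 6), k = 0.5, E0 = -9.9,
                       ts_axis = c(1, 0, 0))
  # no charges means no dipole: the reaction axis is degenerate and the
  # ramp aborts ...
  expect_error(run_ramp(fx$minimum, fx$ts, eng_min, eng_ts), "degenerate")
  # ... but the orientation scan still runs and sees identical barriers
  sc <- orientation_scan(fx$minimum, fx$ts, eng_min, eng_ts)
  expect_true(all(sc$table$ok))
  expect_lt(max(sc$table$barrier) - min(sc$table$barrier), 1e-10)
  expect_lt(max(abs(sc$table$ddE)), 1e-10)
})

test_that("the ramp lowers the barrier monotonically along the reaction axis", {
  fx <- fixture_reaction()
  ramp <- run_ramp(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts,
                   ramp_config(freq = TRUE))
  expect_length(ramp$results, 5L)
  tab <- activation_energies(ramp)
  expect_true(all(diff(tab$dE) < 0))
  expect_true(all(tab$ddE[-1] < 0))
  # zero-field barrier equals the engines' independent zero-field energies
  expect_equal(tab$dE[1],
               (engine_optimize(fx$engine_ts, fx$ts, NULL)$energy -
                  engine_optimize(fx$engine_min, fx$minimum, NULL)$energy) *
                 const$hartree_to_kcal,
               tolerance = 1e-9)
  # RMSD rows: zero at zero field, growing but small under the ramp
  r_ts <- vapply(ramp$results, `[[`, numeric(1), "rmsd_ts")
  expect_equal(r_ts[1], 0)
  expect_true(all(diff(r_ts) > 0))
  expect_lt(max(r_ts), 0.1)

  success <- evaluate_success(ramp)
  expect_true(success$pass)
  expect_gte(success$r2, 0.95)
  expect_lt(success$slope, 0)
})

test_that("reruns are deterministic and destabilizing fields raise the barrier", {
  fx <- fixture_reaction()
  cfg <- ramp_config(freq = TRUE)
  t1 <- activation_energies(run_ramp(fx$minimum, fx$ts, fx$engine_min,
                                     fx$engine_ts, cfg))
  t2 <- activation_energies(run_ramp(fx$minimum, fx$ts, fx$engine_min,
                                     fx$engine_ts, cfg))
  expect_identical(t1$dE, t2$dE)
  expect_identical(t1$e_int, t2$e_int)

  up <- run_ramp(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts,
                 ramp_config(direction = "destabilizing"))
  expect_true(all(diff(activation_energies(up)$dE) > 0))
})

test_that("recursive seeding and cold starts reach identical optima", {
  fx <- fixture_reaction()
  ramp <- run_ramp(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts)
  cold <- run_ramp(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts,
                   ramp_config(magnitudes = c(0, 1e-2)))
  e_ramped <- ramp$results[[5]]$ts$energy
  e_cold <- cold$results[[2]]$ts$energy
  expect_equal(e_ramped, e_cold, tolerance = 1e-13)
  expect_lt(rmsd(ramp$results[[5]]$ts$geometry,
                 cold$results[[2]]$ts$geometry), 1e-9)
})

test_that("the fitted slope recovers the reaction-dipole magnitude", {
  # rigid, polarizability-free limit: slope -> -||mu_rxn|| in kcal/mol per a.u.
  fx <- fixture_reaction(k = 1e6, alpha_int = diag(0, 3),
                         alpha_ts = diag(0, 3))
  ramp <- run_ramp(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts)
  s <- evaluate_success(ramp)
  expected <- -ramp$axis$norm * const$debye_to_au * const$hartree_to_kcal
  expect_lt(abs(s$slope - expected) / abs(expected), 0.01)
  expect_gt(s$r2, 0.999)
})

test_that("reorder methods leave ramp energetics unchanged", {
  # the permutation relabels atoms; physics cannot depend on it
  fx <- fixture_reaction()
  t0 <- activation_energies(run_ramp(fx$minimum, fx$ts, fx$engine_min,
                                     fx$engine_ts,
                                     ramp_config(reorder_method = 0)))
  t1 <- activation_energies(run_ramp(fx$minimum, fx$ts, fx$engine_min,
                                     fx$engine_ts,
                                     ramp_config(reorder_method = 1)))
  t2 <- activation_energies(run_ramp(fx$minimum, fx$ts, fx$engine_min,
                                     fx$engine_ts,
                                     ramp_config(reorder_method = 2,
                                                 reacting_atoms = c(2, 3))))
  expect_equal(t1$dE, t0$dE, tolerance = 1e-9)
  expect_equal(t2$dE, t0$dE, tolerance = 1e-9)
})

test_that("success diagnostics detect jumps, bad fits and wrong mode counts", {
  linear <- 48 - 800 * seq(0, 1e-2, by = 2.5e-3)
  s <- evaluate_success(fake_ramp(linear))
  expect_true(s$pass)
  expect_equal(s$r2, 1, tolerance = 1e-9)

  jumped <- linear
  jumped[3] <- jumped[3] + 5
  s_jump <- evaluate_success(fake_ramp(jumped))
  expect_false(s_jump$pass)
  expect_true(3 %in% s_jump$discontinuities)

  geom_jump <- evaluate_success(fake_ramp(linear,
                                          rmsds = c(0, 0.001, 0.3, 0.3, 0.3)))
  expect_false(geom_jump$pass)

  wrong_modes <- evaluate_success(fake_ramp(linear,
                                            n_imag_ts = rep(0L, 5)))
  expect_false(wrong_modes$pass)
  expect_false(wrong_modes$frequency_ok)

  expect_error(evaluate_success(fake_ramp(linear[1:2])), "insufficient")
})

test_that("orientation scan is extremal along the reaction axis", {
  # rigid limit isolates the first-order (linear) response
  fx <- fixture_reaction(k = 1e6, alpha_int = diag(0, 3),
                         alpha_ts = diag(0, 3))
  sc <- orientation_scan(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts)
  expect_equal(nrow(sc$table), 20L)
  expect_true(all(sc$table$ok))
  dirs <- as.matrix(sc$table[, c("dx", "dy", "dz")])
  dots <- as.numeric(dirs %*% sc$axis$unit)
  # the minimum-barrier direction is the sampled direction best aligned
  # with the reaction axis; the maximum-barrier one is its antipode
  expect_equal(sc$i_min, which.max(dots))
  expect_equal(sc$i_max, which.min(dots))
  # antipodal direction pairs: equal and opposite first-order changes
  for (i in seq_len(20)) {
    j <- which.min(rowSums(sweep(dirs, 2, -dirs[i, ])^2))
    expect_lt(abs(sc$table$ddE[i] + sc$table$ddE[j]), 1e-7)
  }
})

test_that("the dodecahedral direction set is unit, antipodal and isotropic", {
  d <- dodecahedron_directions()
  expect_equal(dim(d), c(20L, 3L))
  expect_equal(rowSums(d^2), rep(1, 20), tolerance = 1e-12)
  expect_equal(colSums(d), c(0, 0, 0), tolerance = 1e-12)
  # every vertex has its antipode in the set
  for (i in 1:20) {
    expect_lt(min(rowSums(sweep(d, 2, -d[i, ])^2)), 1e-12)
  }
  f <- fibonacci_sphere_directions(35)
  expect_equal(rowSums(f^2), rep(1, 35), tolerance = 1e-12)
})

test_that("run artifacts serialize the complete provenance", {
  fx <- fixture_reaction()
  ramp <- run_ramp(fx$minimum, fx$ts, fx$engine_min, fx$engine_ts,
                   ramp_config(freq = TRUE))
  dir <- withr::local_tempdir()
  paths <- write_run_artifacts(ramp, dir)
  expect_true(all(file.exists(paths)))
  axis_txt <- readLines(file.path(dir, "reaction_axis.txt"))
  norm_written <- as.numeric(sub("norm_debye: ", "", axis_txt[4]))
  expect_equal(round(norm_written, 4), 3.2324)
  perm <- read.delim(file.path(dir, "permutation.tsv"))
  expect_identical(perm$original, seq_len(6L) + 0L)
})
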