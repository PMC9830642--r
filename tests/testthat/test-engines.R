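const <- oef_constants()

test_that("toy evaluation matches an independent term-by-term recomputation", {
  set.seed(77)
  r0 <- fixture_molecule(5, seed = 19)
  q <- c(0.3, -0.2, 0.1, -0.15, -0.05)
  alpha <- crossprod(matrix(rnorm(9), 3))  # symmetric PSD
  eng <- toy_engine(r0, q, k = 0.4, E0 = -12.5, alpha = alpha)

  # at the reference geometry, zero field: base energy and dipole sum(q r0)
  at0 <- engine_evaluate(eng, r0, NULL)
  expect_equal(at0$energy, -12.5, tolerance = 1e-12)
  mu0_au <- colSums(q * (r0$coords * const$angstrom_to_bohr))
  expect_equal(at0$dipole, mu0_au / const$debye_to_au, tolerance = 1e-12)

  # doubling all charges doubles the dipole
  eng2 <- toy_engine(r0, 2 * q, k = 0.4, E0 = -12.5, alpha = alpha)
  expect_equal(engine_evaluate(eng2, r0, NULL)$dipole, 2 * at0$dipole,
               tolerance = 1e-12)

  # random geometry and field vs independent arithmetic
  s <- r0
  s$coords <- s$coords + matrix(rnorm(15, sd = 0.1), ncol = 3)
  f <- field_vector(normalize_axis(rnorm(3))$unit, 7.3e-3)
  got <- engine_evaluate(eng, s, f)
  rb <- s$coords * const$angstrom_to_bohr
  rb0 <- r0$coords * const$angstrom_to_bohr
  e_harm <- 0.5 * 0.4 * sum((rb - rb0)^2)
  mu <- c(sum(q * rb[, 1]), sum(q * rb[, 2]), sum(q * rb[, 3]))
  e_field <- -sum(mu * f$components)
  e_pol <- -0.5 * sum(f$components * (alpha %*% f$components))
  expect_equal(got$energy, -12.5 + e_harm + e_field + e_pol,
               tolerance = 1e-12)
  expect_equal(got$dipole * const$debye_to_au, mu, tolerance = 1e-12)

  expect_error(engine_evaluate(eng, fixture_molecule(4), NULL),
               "does not match")
})

test_that("toy optimization has the closed-form optimum and energy", {
  r0 <- fixture_molecule(5, seed = 19)
  q <- c(0.3, -0.2, 0.1, -0.15, -0.05)
  eng <- toy_engine(r0, q, k = 0.4, E0 = -12.5)

  at0 <- engine_optimize(eng, r0, NULL)
  expect_equal(at0$energy, -12.5, tolerance = 1e-14)
  expect_structure_equal(at0$geometry, r0, tol = 1e-12)
  expect_equal(at0$n_imaginary, 0L)
  expect_true(at0$converged)

  # single atom: displacement q F / k along the field
  one <- xyz_structure("H", matrix(0, 1, 3))
  eng1 <- toy_engine(one, q = 0.1, k = 0.5, E0 = 0)
  f <- field_vector(c(0, 0, 1), 5e-3)
  opt <- engine_optimize(eng1, one, f)
  expect_equal(opt$geometry$coords[1, 3] * const$angstrom_to_bohr, 1e-3,
               tolerance = 1e-12)
  # cross-check the optimum against a numerical minimization
  num <- optim(c(0, 0, 0), function(r_bohr) {
    s <- one
    s$coords <- matrix(r_bohr * const$bohr_to_angstrom, 1)
    engine_evaluate(eng1, s, f)$energy
  }, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(opt$energy, num$value, tolerance = 1e-10)
  expect_equal(opt$geometry$coords[1, ] * const$angstrom_to_bohr, num$par,
               tolerance = 1e-5)

  # optimality: never above the single-point energy at the seed geometry
  eng5 <- toy_engine(r0, q, k = 0.4, E0 = -12.5, alpha = diag(3))
  seed_geo <- r0
  seed_geo$coords <- seed_geo$coords + 0.05
  f2 <- field_vector(c(0, 1, 0), 8e-3)
  expect_lte(engine_optimize(eng5, seed_geo, f2)$energy,
             engine_evaluate(eng5, seed_geo, f2)$energy)

  expect_error(toy_engine(r0, q, k = 0), "k must be > 0")
})

test_that("uncharged, unpolarizable systems are field-blind", {
  r0 <- fixture_molecule(6, seed = 31)
  eng <- toy_engine(r0, q = rep(0, 6), k = 0.7, E0 = 3.25)
  for (m in c(0, 2.5e-3, 1e-2)) {
    f <- if (m > 0) field_vector(c(0, 0, 1), m) else NULL
    expect_equal(engine_optimize(eng, r0, f)$energy, 3.25, tolerance = 1e-14)
    expect_equal(engine_evaluate(eng, r0, f)$energy, 3.25, tolerance = 1e-14)
  }
})

test_that("rigid-limit toy barrier change converges to the first-order law", {
  v <- demo_reaction_values()
  f_mag <- 5e-3
  dmu_au <- reaction_dipole(v$mu_int, v$mu_ts) * const$debye_to_au
  axis <- normalize_axis(reaction_dipole(v$mu_int, v$mu_ts))$unit
  f <- field_vector(axis, f_mag)
  exact <- -sum(dmu_au * f$components) * const$hartree_to_kcal
  prev_err <- Inf
  for (k in c(10, 1e3, 1e6)) {
    fx <- fixture_reaction(k = k, alpha_int = diag(0, 3),
                           alpha_ts = diag(0, 3))
    de <- (engine_optimize(fx$engine_ts, fx$ts, f)$energy -
             engine_optimize(fx$engine_min, fx$minimum, f)$energy -
             (v$e_ts - v$e_int)) * const$hartree_to_kcal
    err <- abs(de - exact)
    expect_lt(err, prev_err + 1e-15)  # O(1/k) convergence
    prev_err <- err
  }
  expect_lt(prev_err, 1e-8)
})

test_that("engine permutation and rigid transforms commute with evaluation", {
  r0 <- fixture_molecule(5, seed = 40)
  q <- c(0.25, -0.1, -0.05, 0.05, -0.15)
  eng <- toy_engine(r0, q, k = 0.5, E0 = 1.0, alpha = diag(2, 3))
  f <- field_vector(normalize_axis(c(1, 2, -1))$unit, 6e-3)

  perm <- c(3L, 1L, 5L, 2L, 4L)
  s_perm <- r0
  s_perm$symbols <- r0$symbols[perm]
  s_perm$coords <- r0$coords[perm, ]
  e1 <- engine_evaluate(eng, r0, f)
  e2 <- engine_evaluate(engine_permute(eng, perm), s_perm, f)
  expect_equal(e2$energy, e1$energy, tolerance = 1e-12)
  expect_equal(e2$dipole, e1$dipole, tolerance = 1e-12)

  fr <- random_rigid_motion(6)
  e3 <- engine_evaluate(engine_transform(eng, fr), apply_frame(fr, r0),
                        field_vector(map_axis_to_frame(f$components /
                                                         f$magnitude, fr),
                                     f$magnitude))
  expect_equal(e3$energy, e1$energy, tolerance = 1e-10)
})
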