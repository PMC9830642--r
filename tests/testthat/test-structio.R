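test_that("XYZ I/O round-trips losslessly and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen pair", "H 0 0 0", "H 0 0 0.74"), path)
  s <- read_xyz(path)
  expect_equal(n_atoms(s), 2L)
  expect_equal(s$coords[2, 3], 0.74)

  m <- fixture_molecule(6, seed = 7)
  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, out)
  back <- read_xyz(out)
  expect_identical(back$symbols, m$symbols)
  expect_lt(max(abs(back$coords - m$coords)), 1e-6)
  write_xyz(back, out)
  expect_structure_equal(read_xyz(out), back, tol = 1e-12)

  one <- xyz_structure("He", matrix(c(0.1, 0.2, 0.3), 1))
  write_xyz(one, out)
  expect_length(readLines(out), 3L)

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "count mismatch", "H 0 0 0", "H 0 0 0.74"), bad)
  expect_error(read_xyz(bad), "count line declares 3")
  writeLines(c("2", "bad element", "Qq 0 0 0", "H 0 0 0.74"), bad)
  expect_error(read_xyz(bad), "unrecognized element")
  writeLines(c("2", "bad field", "H 0 0", "H 0 0 0.74"), bad)
  expect_error(read_xyz(bad), "4 fields")
})

test_that("structure construction enforces its invariants", {
  expect_error(xyz_structure(character(0), matrix(0, 0, 3)), "at least one")
  expect_error(xyz_structure("H", matrix(c(1, 2, NA), 1)), "finite")
  expect_error(xyz_structure(c("H", "H"), matrix(0, 1, 3)), "N x 3")
  expect_error(xyz_structure("Xx", matrix(0, 1, 3)), "unrecognized")
})

test_that("Z-matrix frame orientation fixes the standard convention", {
  m <- fixture_molecule(6, seed = 11)
  o <- orient_to_zmatrix_frame(m)
  p <- o$structure$coords
  expect_lt(max(abs(p[1, ])), 1e-12)          # atom 1 at origin
  expect_lt(max(abs(p[2, 1:2])), 1e-12)       # atom 2 on z axis
  expect_gt(p[2, 3], 0)                       # ... the +z axis
  expect_lt(abs(p[3, 2]), 1e-12)              # atom 3 in xz plane
  expect_gte(p[3, 1], 0)                      # ... the x >= 0 half

  # rigid motion: all interatomic distances preserved
  expect_lt(max(abs(dist(p) - dist(m$coords))), 1e-9)

  # FrameRotation contract: applying it to the input gives the output
  expect_lt(max(abs(apply_frame(o$frame, m)$coords - p)), 1e-12)

  # idempotence: orienting the oriented structure changes nothing
  o2 <- orient_to_zmatrix_frame(o$structure)
  expect_lt(max(abs(o2$structure$coords - p)), 1e-9)
  expect_lt(max(abs(o2$frame$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(o2$frame$translation)), 1e-9)
})

test_that("orientation of a rigidly moved copy matches the original's", {
  m <- fixture_molecule(7, seed = 23)
  direct <- orient_to_zmatrix_frame(m)$structure
  for (seed in 1:5) {
    moved <- apply_frame(random_rigid_motion(seed), m)
    expect_lt(max(abs(orient_to_zmatrix_frame(moved)$structure$coords -
                        direct$coords)), 1e-9)
  }
})

test_that("collinear leading atoms give a degenerate-frame error", {
  lin <- xyz_structure(c("C", "C", "C"),
                       rbind(c(0, 0, 0), c(0, 0, 1.2), c(0, 0, 2.4)))
  expect_error(orient_to_zmatrix_frame(lin), "collinear.*reorder")
})

test_that("Z-matrix construction and reconstruction are mutually inverse", {
  w <- orient_to_zmatrix_frame(fixture_water())$structure
  zm <- build_zmatrix(w)
  expect_length(zm$symbols, 3L)
  # O-H bond length equals the distance in the fixture coordinates
  oh <- sqrt(sum((fixture_water()$coords[2, ] - fixture_water()$coords[1, ])^2))
  expect_equal(zm$lengths[2], oh, tolerance = 1e-9)

  for (seed in c(2, 9)) {
    o <- orient_to_zmatrix_frame(fixture_molecule(8, seed = seed))$structure
    zm1 <- build_zmatrix(o)
    rec <- zmatrix_to_structure(zm1)
    expect_lt(max(abs(rec$coords - o$coords)), 1e-6)
    zm2 <- build_zmatrix(rec)
    expect_lt(max(abs(zm2$lengths[-1] - zm1$lengths[-1])), 1e-6)
    expect_lt(max(abs(zm2$angles[-(1:2)] - zm1$angles[-(1:2)])), 1e-6)
  }
})

test_that("a nearly linear reference angle triggers a quality warning", {
  lin <- xyz_structure(c("O", "C", "O"),
                       rbind(c(0, 0, 0), c(0, 0, 1.16), c(0, 0, 2.32)))
  # build the Z-matrix on unoriented coordinates: the frame would reject them
  expect_warning(build_zmatrix(lin), "nearly linear")
})

test_that("Gaussian Z-matrix text has the chain layout and variables block", {
  o <- orient_to_zmatrix_frame(fixture_molecule(5, seed = 4))$structure
  txt <- format_gaussian_zmatrix(build_zmatrix(o))
  expect_match(txt[2], "^C 1 B2$")
  expect_match(txt[3], "^C 2 A3$|^C 2 B3 1 A3$")
  expect_true(any(grepl("^B2=", txt)))
  expect_true(any(grepl("^D5=", txt)))
})
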