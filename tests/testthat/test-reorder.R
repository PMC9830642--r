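make_pair <- function(n = 8, seed = 2, stretch = NULL) {
  minimum <- fixture_molecule(n, seed = seed)
  ts <- minimum
  if (!is.null(stretch)) {
    # move atom stretch[2] along its separation from stretch[1] by stretch[3]
    d <- ts$coords[stretch[2], ] - ts$coords[stretch[1], ]
    ts$coords[stretch[2], ] <- ts$coords[stretch[2], ] +
      stretch[3] * d / sqrt(sum(d^2))
  }
  list(minimum = minimum, ts = ts)
}

test_that("method 0 is the identity permutation", {
  p <- make_pair()
  ro <- reorder_structures(0, p$minimum, p$ts)
  expect_identical(ro$permutation$perm, seq_len(8L))
  expect_structure_equal(ro$minimum, p$minimum, tol = 1e-15)
  expect_structure_equal(ro$ts, p$ts, tol = 1e-15)
})

test_that("method 1 puts the four atoms nearest the TS centroid first", {
  p <- make_pair(n = 5, seed = 13)
  ro <- reorder_structures(1, p$minimum, p$ts)
  # brute-force oracle: full distance sort to the unweighted TS centroid
  center <- colMeans(p$ts$coords)
  d <- sqrt(rowSums(sweep(p$ts$coords, 2, center)^2))
  oracle <- order(d)
  expect_identical(ro$permutation$perm[1:4], as.integer(oracle[1:4]))
  # distances of the first four atoms are ascending
  d_new <- sqrt(rowSums(sweep(ro$ts$coords[1:4, ], 2, center)^2))
  expect_true(all(diff(d_new) >= 0))
  # remaining atoms keep their original relative order
  rest <- ro$permutation$perm[-(1:4)]
  expect_true(all(diff(rest) > 0))
})

test_that("method 2 block-moves from the atom farthest from the site", {
  # 8 atoms: reacting pair near the origin, atom 6 placed farthest
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(2, 1, 0.5),
                  c(-1, 0.5, 0.4), c(8, 8, 8), c(2.5, -1, 0.2), c(0, 2, 1))
  minimum <- xyz_structure(rep("C", 8), coords)
  ts <- minimum
  ro <- reorder_structures(2, minimum, ts, reacting_atoms = c(1, 2))
  expect_identical(ro$permutation$perm, c(6L, 7L, 8L, 1L, 2L, 3L, 4L, 5L))
  expect_identical(ro$minimum$coords[1, ], coords[6, ])
})

test_that("method 2 without reacting atoms falls back to inference", {
  p <- make_pair(n = 6, seed = 21, stretch = c(1, 2, -1.0))
  ro <- reorder_structures(2, p$minimum, p$ts)
  expect_s3_class(ro$permutation, "atom_permutation")
  # identical structures leave nothing to infer
  q <- make_pair(n = 6, seed = 21)
  expect_error(reorder_structures(2, q$minimum, q$ts), "reacting_atoms")
})

test_that("reordering preserves content and applies one permutation to both", {
  p <- make_pair(n = 7, seed = 17, stretch = c(2, 3, 0.8))
  for (method in 0:2) {
    ro <- reorder_structures(method, p$minimum, p$ts,
                             reacting_atoms = c(2, 3))
    for (pair in list(c("minimum", "minimum"), c("ts", "ts"))) {
      orig <- p[[pair[1]]]
      new <- ro[[pair[2]]]
      expect_setequal(
        paste(new$symbols, new$coords[, 1], new$coords[, 2], new$coords[, 3]),
        paste(orig$symbols, orig$coords[, 1], orig$coords[, 2],
              orig$coords[, 3]))
      expect_lt(max(abs(sort(dist(new$coords)) - sort(dist(orig$coords)))),
                1e-12)
    }
    # same permutation on both: correspondence intact
    expect_identical(ro$minimum$coords,
                     p$minimum$coords[ro$permutation$perm, ])
    expect_identical(ro$ts$coords, p$ts$coords[ro$permutation$perm, ])
  }
})

test_that("reacting atoms are inferred from interatomic distance changes", {
  p <- make_pair(n = 6, seed = 9, stretch = c(1, 4, -1.0))
  hit <- infer_reacting_atoms(p$minimum, p$ts, threshold = 0.3)
  expect_true(all(c(1L, 4L) %in% hit))
  expect_error(infer_reacting_atoms(p$minimum, p$ts, threshold = 50),
               "supply reacting_atoms")
  expect_error(infer_reacting_atoms(p$minimum, p$minimum), "supply")
})

test_that("orientation-atom validation flags collinearity and proximity", {
  good <- fixture_molecule(5, seed = 3)
  expect_true(validate_orientation_atoms(good)$clean)

  lin <- xyz_structure(rep("C", 4),
                       rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(1, 1, 1)))
  rep_lin <- validate_orientation_atoms(lin)
  expect_true(rep_lin$collinear)
  expect_false(rep_lin$clean)

  close <- xyz_structure(rep("C", 4),
                         rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 1.4, 0),
                               c(1.4, 0, 1)))
  rep_close <- validate_orientation_atoms(close)
  expect_true(nrow(rep_close$close_pairs) >= 1)
  expect_true(any(rep_close$close_pairs[, 1] == 1 &
                    rep_close$close_pairs[, 2] == 2))
})
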