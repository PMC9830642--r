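# shared helpers: random rigid motions and an independent superposition
# oracle, deliberately separate from the SVD (Kabsch) code path

quaternion_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  frame_rotation(quaternion_rotation(stats::rnorm(4)),
                 stats::runif(3, -3, 3))
}

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

# brute-force minimum RMSD over proper rigid motions: random rotation
# sampling followed by Nelder-Mead polish in axis-angle coordinates
brute_force_min_rmsd <- function(mobile, reference, n_samples = 3000,
                                 seed = 42) {
  p <- sweep(mobile$coords, 2, colMeans(mobile$coords))
  q <- sweep(reference$coords, 2, colMeans(reference$coords))
  obj_rot <- function(r) sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  set.seed(seed)
  best <- diag(3)
  best_val <- obj_rot(best)
  for (i in seq_len(n_samples)) {
    r <- quaternion_rotation(stats::rnorm(4))
    v <- obj_rot(r)
    if (v < best_val) {
      best <- r
      best_val <- v
    }
  }
  fit <- stats::optim(c(0, 0, 0),
                      function(w) obj_rot(rodrigues(w) %*% best),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 3000))
  min(best_val, fit$value)
}

expect_structure_equal <- function(a, b, tol = 1e-9) {
  expect_identical(a$symbols, b$symbols)
  expect_lt(max(abs(a$coords - b$coords)), tol)
}
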