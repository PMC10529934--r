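# Fixtures and independent oracles shared across the suite. All
# reference values here are computed with brute-force double loops or
# closed forms, never with the package's own vectorised paths.

K_C <- 14.3996      # V*A/e
K_D <- 4.80320      # D per e*A
K_E <- 4.8009       # kcal/mol per (D * V/A)
R_KCAL <- 1.98720425e-3

make_atoms <- function(x, y, z, charge, group = "G", name = NULL) {
  n <- length(x)
  tibble::tibble(
    index = seq_len(n) - 1L,
    name = name %||% sprintf("A%d", seq_len(n)),
    group = rep_len(group, n),
    x = x, y = y, z = z, charge = charge
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_atoms <- function(n, seed, box = 10, groups = c("G1", "G2")) {
  withr::with_seed(seed, make_atoms(
    x = runif(n, -box, box), y = runif(n, -box, box), z = runif(n, -box, box),
    charge = runif(n, -1, 1),
    group = sample(groups, n, replace = TRUE)
  ))
}

# Brute-force Coulomb field: explicit loop over atoms
brute_field <- function(atoms, point) {
  f <- c(0, 0, 0)
  for (i in seq_len(nrow(atoms))) {
    d <- point - c(atoms$x[i], atoms$y[i], atoms$z[i])
    r <- sqrt(sum(d^2))
    f <- f + K_C * atoms$charge[i] * d / r^3
  }
  f
}

# Brute-force distance-shell membership: double loop over pairs
brute_shell <- function(atoms, a_idx, b_idx, r) {
  keep <- integer()
  for (i in a_idx) {
    ai <- which(atoms$index == i)
    dmin <- Inf
    for (j in b_idx) {
      bj <- which(atoms$index == j)
      d <- sqrt((atoms$x[ai] - atoms$x[bj])^2 +
                  (atoms$y[ai] - atoms$y[bj])^2 +
                  (atoms$z[ai] - atoms$z[bj])^2)
      dmin <- min(dmin, d)
    }
    if (dmin <= r) keep <- c(keep, i)
  }
  sort(keep)
}

# Uniformly random proper rotation matrix
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_dec <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_dec)
    q <- q %*% diag(sign(diag(qr.R(qr_dec))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

rotate_atoms <- function(atoms, rot, shift = c(0, 0, 0)) {
  p <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- p[, 1] + shift[1]
  atoms$y <- p[, 2] + shift[2]
  atoms$z <- p[, 3] + shift[3]
  atoms
}

# A small jitter-free cage used in several field tests
tiny_cage <- function(seed = 7, n_frames = 3, sigma = 0.1) {
  gen_cage_system(cage_spec(
    n_periphery = 4, periphery_charge = 1, periphery_radius = 8,
    n_cage_dipoles = 6, shell_radius = 12, n_solvent = 10,
    solvent_shell = c(13, 15), feo_length = 1.65,
    positional_sigma = sigma, n_frames = n_frames, seed = seed
  ))
}
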