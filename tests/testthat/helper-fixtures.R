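# Hand-built minimal structures and independent oracles shared by the
# test files. Oracles here never call the implementation they check.

# Build a funcfix_structure directly from an atom table, bypassing the
# readers, so geometric expectations can be computed by hand.
hand_structure <- function(atoms, id = "hand") {
  defaults <- data.frame(record = "ATOM", chain = "A", res_name = "ALA",
                         auth_seq_id = 1L, ins = "", seq_index = 1L,
                         atom_name = "CA", element = "C", x = 0, y = 0, z = 0,
                         occ = 1, b = 0, is_hetero = FALSE,
                         stringsAsFactors = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  atoms <- atoms[, names(defaults)]
  structure(list(id = id, atoms = atoms), class = "funcfix_structure")
}

# One-CA-per-residue chain at given coordinates.
ca_chain <- function(xyz, chain = "A") {
  n <- nrow(xyz)
  hand_structure(data.frame(chain = chain, auth_seq_id = seq_len(n),
                            seq_index = seq_len(n),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# Brute-force rigid-superposition oracle: optimal translation is centroid
# alignment; the rotation is searched over Euler angles from a coarse
# deterministic grid, refined with Nelder-Mead. Independent of the SVD path.
oracle_rigid_rmsd <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  rotmat <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  f <- function(a) sqrt(mean(rowSums((pc - qc %*% t(rotmat(a)))^2)))
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 7)[-7],
                                a2 = seq(0, 2 * pi, length.out = 7)[-7],
                                a3 = seq(0, 2 * pi, length.out = 7)[-7]))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    r <- stats::optim(grid[i, ], f, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    if (r$value < best) best <- r$value
  }
  best
}

# A rate table evaluated straight from the Michaelis-Menten law, with no
# package code involved.
oracle_mm_rates <- function(kcat, km, e, s) kcat * e * s / (km + s)

# Closed-form OLS slope (textbook formula), used to check initial_rate.
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
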