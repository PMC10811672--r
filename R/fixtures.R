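## Synthetic-input generators with planted ground truth. Every analysis
## module has a generator here producing the same formats the analysis
## functions read, plus the planted truth, so the full pipeline is
## testable without any external download.

## run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## ideal-helix C-alpha trace: radius 2.3 A, rise 1.5 A, 100 deg/residue
helix_ca <- function(n_res) {
  i <- seq_len(n_res) - 1
  ang <- i * 100 * pi / 180
  cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
}

#' Synthetic ligand-bound structure with planted first-shell truth
#'
#' Builds an ideal-helix C-alpha chain (chain A, alanines) plus a
#' pseudo-ligand hetero group (`LIG`) whose atoms are placed radially
#' off chosen residues, so each targeted residue's minimum heavy-atom
#' distance to the ligand is controlled. The generator records the
#' realized per-residue minimum distances (plain coordinate arithmetic
#' on its own output), from which the true shell at any cutoff follows.
#'
#' @param n_res number of residues (>= 3).
#' @param ligand_offsets named or positional numeric vector: entry i (or
#'   names giving residue indices) is the radial distance (A) at which a
#'   ligand atom is planted off residue i. `NA` entries plant no atom.
#' @param seed integer; sets a global rigid orientation (distances are
#'   unaffected, bytes are deterministic per seed).
#' @return list with `structure` (`funcfix_structure`), `min_distances`
#'   (per-residue minimum heavy-atom distance to the ligand, `Inf` when
#'   there is no ligand atom) and `true_shell(cutoff)` (function
#'   returning the residue indices within the cutoff).
#' @export
make_toy_structure <- function(n_res, ligand_offsets = numeric(), seed = 1) {
  stopifnot(n_res >= 3)
  ca <- helix_ca(n_res)
  targets <- if (!is.null(names(ligand_offsets))) {
    as.integer(names(ligand_offsets))
  } else seq_along(ligand_offsets)
  offs <- as.numeric(ligand_offsets)
  keep <- is.finite(offs)
  targets <- targets[keep]; offs <- offs[keep]
  stopifnot(all(targets >= 1 & targets <= n_res), all(offs > 0))

  lig <- NULL
  if (length(targets)) {
    ang <- (targets - 1) * 100 * pi / 180
    u <- cbind(cos(ang), sin(ang), 0)             # radial unit vectors
    lig <- ca[targets, , drop = FALSE] + u * offs
  }

  ## seeded rigid reorientation of the whole assembly
  rot <- with_seed(seed, {
    m <- matrix(stats::rnorm(9), 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
  ca <- ca %*% rot
  if (!is.null(lig)) lig <- lig %*% rot

  atoms <- data.frame(
    record = "ATOM", chain = "A", res_name = "ALA",
    auth_seq_id = seq_len(n_res), ins = "", seq_index = seq_len(n_res),
    atom_name = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3], occ = 1, b = 0,
    is_hetero = FALSE, stringsAsFactors = FALSE)
  if (!is.null(lig)) {
    atoms <- rbind(atoms, data.frame(
      record = "HETATM", chain = "L", res_name = "LIG",
      auth_seq_id = 900L, ins = "", seq_index = NA_integer_,
      atom_name = paste0("C", seq_len(nrow(lig))), element = "C",
      x = lig[, 1], y = lig[, 2], z = lig[, 3], occ = 1, b = 0,
      is_hetero = TRUE, stringsAsFactors = FALSE))
  }
  st <- structure(list(id = sprintf("toy%d", n_res), atoms = atoms),
                  class = "funcfix_structure")

  mind <- rep(Inf, n_res)
  if (!is.null(lig)) {
    for (i in seq_len(n_res)) {
      mind[i] <- sqrt(min(rowSums(sweep(lig, 2, ca[i, ])^2)))
    }
  }
  list(structure = st, min_distances = mind,
       true_shell = function(cutoff) which(mind <= cutoff))
}

#' Synthetic MSA with exact per-column conservation
#'
#' Rows are allocated so that each column's parent-identity frequency
#' equals its target exactly: with `n_rows` rows a target must be a
#' multiple of `1/n_rows` in `[1/n_rows, 1]` (the parent row always
#' matches itself). Which non-parent rows match is drawn per column from
#' the seeded stream; mismatching rows get the alphabetically next
#' amino acid, so every column count is exact by construction.
#'
#' @param parent parent amino-acid sequence (ungapped).
#' @param n_rows number of alignment rows (>= 2), row 1 is the parent.
#' @param conservation per-column target frequency, length
#'   `nchar(parent)` (recycled if length 1).
#' @param seed integer.
#' @return list with `msa` (`funcfix_msa`) and `true_profile` (the
#'   exact per-column frequencies).
#' @export
make_toy_msa <- function(parent, n_rows, conservation, seed = 1) {
  stopifnot(n_rows >= 2)
  pv <- strsplit(toupper(parent), "")[[1]]
  L <- length(pv)
  target <- rep_len(conservation, L)
  m <- target * n_rows
  if (any(abs(m - round(m)) > 1e-9) || any(round(m) < 1) || any(round(m) > n_rows)) {
    stop("conservation target not attainable with ", n_rows,
         " rows (must be k/n_rows with k in 1..n_rows)", call. = FALSE)
  }
  m <- as.integer(round(m))
  rows <- matrix("", n_rows, L)
  rows[1, ] <- pv
  with_seed(seed, {
    for (j in seq_len(L)) {
      match_rows <- if (m[j] > 1) c(1L, sample(2:n_rows, m[j] - 1L)) else 1L
      sub <- AA20[AA20 != pv[j]][1]
      col <- rep(sub, n_rows)
      col[match_rows] <- pv[j]
      rows[, j] <- col
    }
  })
  msa <- structure(list(rows = rows,
                        ids = c("parent", sprintf("hom%03d", seq_len(n_rows - 1))),
                        parent_row = 1L),
                   class = "funcfix_msa")
  list(msa = msa, true_profile = m / n_rows)
}

#' Synthetic Michaelis-Menten rate table
#'
#' Rates follow v = kcat * E * S / (Km + S) with optional multiplicative
#' Gaussian noise of relative scale `noise_rel`.
#'
#' @param kcat turnover number (min^-1).
#' @param km Michaelis constant (uM, > 0).
#' @param enzyme_conc enzyme concentration (uM).
#' @param substrate_levels substrate concentrations (uM).
#' @param noise_rel relative noise scale (0 = noise-free).
#' @param seed integer.
#' @return data frame with `substrate_conc`, `rate`; attributes
#'   `enzyme_conc`, `true_kcat`, `true_km`.
#' @export
make_rate_table <- function(kcat, km, enzyme_conc = 0.5,
                            substrate_levels = km * c(0.2, 0.5, 1, 2, 3, 5, 8, 10),
                            noise_rel = 0, seed = 1) {
  stopifnot(km > 0, enzyme_conc > 0, all(substrate_levels > 0))
  s <- sort(unique(substrate_levels))
  v <- kcat * enzyme_conc * s / (km + s)
  if (noise_rel > 0) {
    v <- with_seed(seed, v * (1 + stats::rnorm(length(v), 0, noise_rel)))
  }
  out <- data.frame(substrate_conc = s, rate = v)
  attr(out, "enzyme_conc") <- enzyme_conc
  attr(out, "true_kcat") <- kcat
  attr(out, "true_km") <- km
  out
}

#' Synthetic thermal melt curve
#'
#' Two-state sigmoid with linear folded/unfolded baselines and seeded
#' Gaussian noise scaled to the transition amplitude. Setting
#' `unfolded` equal to `folded` produces a no-transition (fully folded)
#' curve.
#'
#' @param tm planted midpoint (degrees C), inside the temperature grid.
#' @param width transition width (degrees C).
#' @param folded,unfolded baseline `c(intercept, slope)` pairs for the
#'   folded and unfolded states (signal units, e.g. MRE).
#' @param noise relative noise (fraction of the amplitude; of the signal
#'   range for flat curves).
#' @param temperature scan grid (degrees C).
#' @param seed integer.
#' @return data frame with `temperature`, `signal`; attribute `true_tm`.
#' @export
make_melt_curve <- function(tm, width = 2.5, folded = c(-20, 0.02),
                            unfolded = c(-2, 0.01), noise = 0,
                            temperature = seq(20, 95, by = 0.5), seed = 1) {
  stopifnot(tm > min(temperature), tm < max(temperature), width > 0)
  tt <- temperature
  bf <- folded[1] + folded[2] * tt
  bu <- unfolded[1] + unfolded[2] * tt
  f <- 1 / (1 + exp((tm - tt) / width))
  y <- bf + (bu - bf) * f
  amp <- abs((unfolded[1] + unfolded[2] * tm) - (folded[1] + folded[2] * tm))
  scale <- if (amp > 0) amp else max(diff(range(y)), 1)
  if (noise > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise * scale))
  }
  out <- data.frame(temperature = tt, signal = y)
  attr(out, "true_tm") <- if (amp > 0) tm else NA_real_
  out
}

#' Synthetic conformational ensemble with planted fluctuations
#'
#' Frames are the base structure plus independent isotropic Gaussian
#' displacements with a per-residue standard deviation (per coordinate),
#' so the expected C-alpha RMSF of residue r over n frames is
#' sigma_r * sqrt(3) * sqrt((n-1)/n). Optionally a dyad atom pair
#' (hetero atoms `L:901:SG` and `L:902:NE2`) is planted whose per-frame
#' distance is drawn exactly from the stated modes with the stated
#' occupancies.
#'
#' @param base a `funcfix_structure` (e.g. from [make_toy_structure()]).
#' @param per_residue_sigma per-residue displacement sd (A), recycled
#'   over the polymer residues.
#' @param n_frames number of frames (>= 2).
#' @param dyad_modes optional `list(distances =, fractions =)`;
#'   `fractions` must sum to 1 and give whole frame counts.
#' @param seed integer.
#' @return list with `ensemble` (`funcfix_ensemble`), `truth` (list with
#'   `sigma`, and for a planted dyad `dyad_assignment` (mode index per
#'   frame), `dyad_distances`, `atom_a`, `atom_b`).
#' @export
make_ensemble <- function(base, per_residue_sigma, n_frames = 100,
                          dyad_modes = NULL, seed = 1) {
  stopifnot(n_frames >= 2)
  atoms <- base$atoms
  nres_idx <- atoms$seq_index
  pol <- !atoms$is_hetero
  res_ids <- sort(unique(nres_idx[pol]))
  sigma <- rep_len(per_residue_sigma, length(res_ids))
  stopifnot(all(sigma >= 0))
  sig_atom <- numeric(nrow(atoms))
  sig_atom[pol] <- sigma[match(nres_idx[pol], res_ids)]

  assignment <- NULL; dists <- NULL
  if (!is.null(dyad_modes)) {
    fr <- dyad_modes$fractions
    stopifnot(abs(sum(fr) - 1) < 1e-9,
              length(fr) == length(dyad_modes$distances))
    counts <- fr * n_frames
    if (any(abs(counts - round(counts)) > 1e-9)) {
      stop("dyad mode fractions must give whole frame counts", call. = FALSE)
    }
    assignment <- rep(seq_along(fr), as.integer(round(counts)))
    anchor <- unname(colMeans(as.matrix(atoms[pol, c("x", "y", "z")]))) + c(15, 0, 0)
    atoms <- rbind(atoms, data.frame(
      record = "HETATM", chain = "L",
      res_name = c("CYS", "HIS"), auth_seq_id = c(901L, 902L), ins = "",
      seq_index = NA_integer_, atom_name = c("SG", "NE2"),
      element = c("S", "N"),
      x = anchor[1], y = anchor[2], z = anchor[3], occ = 1, b = 0,
      is_hetero = TRUE, stringsAsFactors = FALSE))
  }

  base_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n_at <- nrow(base_xyz)
  sig_atom <- c(sig_atom, rep(0, n_at - length(sig_atom)))

  frames <- with_seed(seed, {
    if (!is.null(assignment)) assignment <- sample(assignment)
    lapply(seq_len(n_frames), function(f) {
      fr_xyz <- base_xyz + matrix(stats::rnorm(n_at * 3), n_at, 3) * sig_atom
      if (!is.null(assignment)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        d <- dyad_modes$distances[assignment[f]]
        fr_xyz[n_at, ] <- fr_xyz[n_at - 1, ] + u * d
      }
      fr_xyz
    })
  })
  ens <- new_ensemble(frames, atoms, source = "trajectory")
  truth <- list(sigma = sigma)
  if (!is.null(assignment)) {
    truth$dyad_assignment <- assignment
    truth$dyad_distances <- dyad_modes$distances[assignment]
    truth$atom_a <- "L:901:SG"
    truth$atom_b <- "L:902:NE2"
  }
  list(ensemble = ens, truth = truth)
}

#' Synthetic design candidates around a reference structure
#'
#' Each candidate's model is the reference C-alpha trace perturbed by
#' isotropic Gaussian noise of the stated per-coordinate sd, its pLDDT
#' is constant at the stated level, and its sequence is the reference
#' sequence with `n_mut` positions substituted. Useful for exercising
#' the triage filter end to end with known expected outcomes.
#'
#' @param reference a `funcfix_structure`.
#' @param spec data frame with columns `id`, `noise` (A, per
#'   coordinate), `plddt` (0-100) and optionally `n_mut`.
#' @param chain reference chain (default first polymer chain).
#' @param seed integer.
#' @return list of `funcfix_candidate`.
#' @export
make_candidates <- function(reference, spec, chain = NULL, seed = 1) {
  ref <- reference_ca(reference, chain)
  seq0 <- strsplit(extract_sequence(reference, chain), "")[[1]]
  n <- nrow(ref$xyz)
  with_seed(seed, {
    lapply(seq_len(nrow(spec)), function(i) {
      xyz <- ref$xyz + matrix(stats::rnorm(n * 3, 0, spec$noise[i]), n, 3)
      sq <- seq0
      nm <- if ("n_mut" %in% names(spec)) spec$n_mut[i] else 0L
      if (nm > 0) {
        at <- sample(n, nm)
        sq[at] <- vapply(sq[at], function(a) AA20[AA20 != a][1], "")
      }
      design_candidate(spec$id[i], paste(sq, collapse = ""), xyz,
                       rep(spec$plddt[i], n))
    })
  })
}
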