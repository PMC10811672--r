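## Conformational-ensemble statistics: superposition, per-residue RMSF,
## region rigidity, catalytic-dyad distance populations, pLDDT profiles.

## index of the Cα atom of every polymer residue, in (chain, seq_index) order
ca_indices <- function(atoms) {
  idx <- which(!atoms$is_hetero & atoms$atom_name == "CA")
  idx[order(atoms$chain[idx], atoms$seq_index[idx])]
}

#' Superpose all frames of an ensemble onto the first frame
#'
#' Rigid-fits (proper rotation + translation, via [kabsch_superpose()])
#' every frame onto frame 1 over the C-alpha atoms of `selection`
#' (default: all polymer residues). Fluctuation statistics are only
#' meaningful after this step removes global rigid-body motion.
#'
#' @param ensemble a `funcfix_ensemble`.
#' @param selection optional `funcfix_selection` naming the residues to
#'   fit on; the transform is applied to all atoms.
#' @return a superposed `funcfix_ensemble`.
#' @export
superpose_frames <- function(ensemble, selection = NULL) {
  stopifnot(length(ensemble$frames) >= 2)
  a <- ensemble$atoms
  fit_idx <- ca_indices(a)
  if (!is.null(selection)) {
    keep <- paste(a$chain[fit_idx], a$seq_index[fit_idx]) %in%
      paste(selection$positions$chain, selection$positions$seq_index)
    fit_idx <- fit_idx[keep]
  }
  if (length(fit_idx) < 3) stop("fit selection resolves to < 3 C-alpha atoms", call. = FALSE)
  ref <- ensemble$frames[[1]][fit_idx, , drop = FALSE]
  frames <- lapply(ensemble$frames, function(fr) {
    k <- kabsch_superpose(ref, fr[fit_idx, , drop = FALSE])
    sweep(fr %*% t(k$rotation), 2, k$translation, "+")
  })
  new_ensemble(frames, a, source = ensemble$source)
}

#' Per-residue root-mean-square fluctuation
#'
#' For each polymer residue, the RMS deviation of its C-alpha position
#' from its across-frame average. Low RMSF marks a rigid residue; loop
#' rigidification shows up as an RMSF drop across variants. Frames must
#' already be superposed ([superpose_frames()]).
#'
#' @param ensemble a superposed `funcfix_ensemble` with >= 2 frames.
#' @return data frame with `chain`, `seq_index`, `rmsf` (A).
#' @export
per_residue_rmsf <- function(ensemble) {
  if (length(ensemble$frames) < 2) stop("need >= 2 frames for RMSF", call. = FALSE)
  a <- ensemble$atoms
  idx <- ca_indices(a)
  coords <- vapply(ensemble$frames, function(fr) fr[idx, , drop = FALSE],
                   matrix(0, length(idx), 3))   # n_res x 3 x n_frames
  avg <- apply(coords, c(1, 2), mean)
  dev2 <- apply((coords - as.vector(avg))^2, c(1, 3), sum)  # n_res x n_frames
  data.frame(chain = a$chain[idx], seq_index = a$seq_index[idx],
             rmsf = sqrt(rowMeans(dev2)),
             stringsAsFactors = FALSE)
}

#' Mean RMSF over a residue span
#'
#' Unweighted mean of per-residue RMSF over a contiguous span, e.g. a
#' loop whose rigidity is compared across variants.
#'
#' @param rmsf data frame from [per_residue_rmsf()].
#' @param from,to inclusive `seq_index` bounds.
#' @param chain chain id (default: first chain present).
#' @return mean RMSF in Angstrom.
#' @export
region_rigidity <- function(rmsf, from, to, chain = NULL) {
  if (is.null(chain)) chain <- rmsf$chain[1]
  sel <- rmsf$chain == chain & rmsf$seq_index >= from & rmsf$seq_index <= to
  if (!any(sel)) stop("empty residue span ", chain, ":", from, "-", to, call. = FALSE)
  mean(rmsf$rmsf[sel])
}

## resolve "chain:auth_seq_id:atom_name" or list(chain=,resno=,atom=) to a row index
resolve_atom <- function(atoms, sel) {
  if (is.character(sel) && length(sel) == 1) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("atom selector must be 'chain:resnum:atomname'", call. = FALSE)
    sel <- list(chain = parts[1], resno = as.integer(parts[2]), atom = parts[3])
  }
  i <- which(atoms$chain == sel$chain & atoms$auth_seq_id == sel$resno &
             atoms$atom_name == sel$atom)
  if (length(i) != 1) {
    stop("atom ", sel$chain, ":", sel$resno, ":", sel$atom,
         if (length(i)) " matches multiple atoms" else " not found", call. = FALSE)
  }
  i
}

#' Inter-atom distance across ensemble frames
#'
#' Per-frame Euclidean distance between two named atoms — an internal
#' coordinate, so no superposition is needed. The classic use is the
#' catalytic Cys-His dyad distance (thiol S to His ring N) of a
#' protease, whose short-distance population marks catalytically
#' competent conformations.
#'
#' @param ensemble a `funcfix_ensemble`.
#' @param atom_a,atom_b selectors `"chain:resnum:atomname"` (author
#'   residue numbers) or lists `list(chain=, resno=, atom=)`.
#' @return numeric vector, one distance (A) per frame.
#' @export
dyad_distance_series <- function(ensemble, atom_a, atom_b) {
  ia <- resolve_atom(ensemble$atoms, atom_a)
  ib <- resolve_atom(ensemble$atoms, atom_b)
  vapply(ensemble$frames, function(fr) {
    sqrt(sum((fr[ia, ] - fr[ib, ])^2))
  }, 0)
}

#' Fraction of frames in the catalytically competent state
#'
#' Fraction of frames whose dyad distance is at or below the cutoff.
#' The competence cutoff is geometry the user must choose (4.0 A is a
#' common proton-transfer distance for a Cys-His pair); it is a required
#' argument rather than a silent default for that reason.
#'
#' @param distances per-frame distances (A), length >= 1.
#' @param cutoff competence distance (A, > 0).
#' @return fraction in \[0,1\].
#' @export
competent_fraction <- function(distances, cutoff) {
  stopifnot(length(distances) >= 1, cutoff > 0)
  mean(distances <= cutoff)
}

#' Per-residue pLDDT profile of a prediction ensemble
#'
#' Across a set of equal-length predicted models, the per-position mean
#' and spread (population standard deviation) of the per-residue
#' confidence. Consistently low-confidence, high-spread positions track
#' flexible regions.
#'
#' @param models list of `funcfix_candidate` of equal length.
#' @return data frame with `position`, `mean_plddt`, `sd_plddt`.
#' @export
ensemble_plddt_profile <- function(models) {
  stopifnot(length(models) >= 1)
  lens <- vapply(models, function(m) length(m$plddt), 1L)
  if (length(unique(lens)) != 1) {
    stop("models differ in length: ", paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(models, function(m) m$plddt))
  mu <- colMeans(mat)
  sdev <- sqrt(colMeans(sweep(mat, 2, mu)^2))  # population sd
  data.frame(position = seq_len(ncol(mat)), mean_plddt = mu, sd_plddt = sdev)
}

#' Write a per-residue RMSF profile as TSV
#' @param rmsf data frame from [per_residue_rmsf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsf_profile <- function(rmsf, path) {
  atomic_write(c(paste(names(rmsf), collapse = "\t"),
                 sprintf("%s\t%d\t%.4f", rmsf$chain, rmsf$seq_index, rmsf$rmsf)),
               path)
}

#' Summarise a dyad-distance population as JSON
#' @param distances per-frame distances.
#' @param cutoff competence cutoff (A).
#' @param path optional output file.
#' @return JSON string with `n_frames`, `cutoff`, `fraction`.
#' @export
dyad_summary <- function(distances, cutoff, path = NULL) {
  obj <- list(n_frames = length(distances), cutoff = cutoff,
              fraction = competent_fraction(distances, cutoff))
  json <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  if (!is.null(path)) { atomic_write(json, path); return(invisible(json)) }
  json
}
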