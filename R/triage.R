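## Candidate triage: Kabsch superposition, C-alpha RMSD to the parent
## structure, sequence identity, and confidence/RMSD filtering.

#' Optimal rigid superposition of two point sets
#'
#' Least-squares rigid-body superposition (Kabsch algorithm via SVD of
#' the cross-covariance matrix). Reflections are corrected by flipping
#' the sign of the smallest singular direction, so the returned rotation
#' is always proper.
#'
#' @param p,q n x 3 coordinate matrices in correspondence (n >= 3).
#' @return list with `rotation` (3x3, applied to centred `q`),
#'   `translation` (so that `q %*% t(rotation) + translation`
#'   superposes `q` onto `p`), `rmsd` (A) and `collinear` (TRUE when
#'   either set is degenerate within machine tolerance; the RMSD is
#'   still returned).
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q)) stop("point sets differ in length", call. = FALSE)
  if (nrow(p) < 3) stop("superposition under-determined: need >= 3 points", call. = FALSE)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- t(qc) %*% pc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  qr_ <- qc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((pc - qr_)^2)))
  collinear <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  list(rotation = rot, translation = cp - as.numeric(cq %*% t(rot)),
       rmsd = rmsd, collinear = collinear)
}

#' Create a design candidate
#'
#' A candidate couples a designed sequence with the C-alpha trace of its
#' predicted model and the predictor's per-residue confidence (pLDDT,
#' 0-100).
#'
#' @param id candidate name.
#' @param sequence amino-acid string.
#' @param model_ca n x 3 C-alpha coordinates (A), n = nchar(sequence).
#' @param plddt per-residue confidence, length n, values in \[0,100\].
#' @return object of class `funcfix_candidate` with `mean_plddt` the
#'   unweighted mean of the per-residue values.
#' @export
design_candidate <- function(id, sequence, model_ca, plddt) {
  model_ca <- as.matrix(model_ca)
  n <- nchar(sequence)
  if (nrow(model_ca) != n || length(plddt) != n) {
    stop("sequence, model_ca and plddt lengths disagree (",
         n, ", ", nrow(model_ca), ", ", length(plddt), ")", call. = FALSE)
  }
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT outside [0,100]", call. = FALSE)
  structure(list(id = id, sequence = sequence, model_ca = model_ca,
                 plddt = as.numeric(plddt), mean_plddt = mean(plddt)),
            class = "funcfix_candidate")
}

#' @export
print.funcfix_candidate <- function(x, ...) {
  cat("design candidate '", x$id, "': ", nchar(x$sequence),
      " residues, mean pLDDT ", sprintf("%.1f", x$mean_plddt), "\n", sep = "")
  invisible(x)
}

#' Read a predicted-model PDB as a design candidate
#'
#' Reads the C-alpha trace and the per-residue confidence from the
#' B-factor column (the convention of structure predictors, which store
#' pLDDT there) of the named chain.
#'
#' @param path model PDB file.
#' @param chain chain to read (default first polymer chain).
#' @param id candidate name (default: file basename).
#' @return a `funcfix_candidate`.
#' @export
read_candidate <- function(path, chain = NULL, id = NULL) {
  st <- read_structure(path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  a <- st$atoms
  if (is.null(chain)) chain <- a$chain[!a$is_hetero][1]
  ca <- a[!a$is_hetero & a$chain == chain & a$atom_name == "CA", , drop = FALSE]
  ca <- ca[order(ca$seq_index), , drop = FALSE]
  design_candidate(id, extract_sequence(st, chain),
                   as.matrix(ca[, c("x", "y", "z")]), ca$b)
}

## C-alpha coordinates of a structure chain, in seq_index order,
## optionally restricted to a residue selection
reference_ca <- function(reference, chain = NULL, selection = NULL) {
  a <- reference$atoms
  if (is.null(chain)) chain <- a$chain[!a$is_hetero][1]
  ca <- a[!a$is_hetero & a$chain == chain & a$atom_name == "CA", , drop = FALSE]
  ca <- ca[order(ca$seq_index), , drop = FALSE]
  if (!is.null(selection)) {
    keep <- ca$seq_index %in% selection$positions$seq_index[selection$positions$chain == chain]
    ca <- ca[keep, , drop = FALSE]
  }
  list(xyz = as.matrix(ca[, c("x", "y", "z")]), seq_index = ca$seq_index)
}

#' C-alpha RMSD of a candidate model to a reference structure
#'
#' Superposes the candidate C-alpha trace onto the reference with
#' [kabsch_superpose()] and returns the minimised RMSD. Superposition
#' and measurement use the same residue selection; region-wise numbers
#' (e.g. RMSD over a remodelled loop) are obtained by passing the
#' region as `selection`.
#'
#' @param candidate a `funcfix_candidate`.
#' @param reference a `funcfix_structure` (its design chain must have
#'   the same length as the candidate: designs are fixed-length
#'   sequence redesigns) or an n x 3 matrix of C-alpha coordinates.
#' @param selection optional `funcfix_selection` restricting the
#'   compared residues.
#' @param chain reference chain (default first polymer chain).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(candidate, reference, selection = NULL, chain = NULL) {
  if (inherits(reference, "funcfix_structure")) {
    ref <- reference_ca(reference, chain, selection = NULL)
    rxyz <- ref$xyz; ridx <- ref$seq_index
  } else {
    rxyz <- as.matrix(reference); ridx <- seq_len(nrow(rxyz))
  }
  cxyz <- candidate$model_ca
  if (nrow(rxyz) != nrow(cxyz)) {
    stop("cannot pair C-alpha sets: reference has ", nrow(rxyz),
         " residues, candidate has ", nrow(cxyz),
         " (fixed-length redesign expected; no silent truncation)", call. = FALSE)
  }
  if (!is.null(selection)) {
    ch <- if (is.null(chain)) unique(selection$positions$chain)[1] else chain
    keep <- ridx %in% selection$positions$seq_index[selection$positions$chain == ch]
    if (!any(keep)) stop("selection matches no reference residues", call. = FALSE)
    rxyz <- rxyz[keep, , drop = FALSE]
    cxyz <- cxyz[keep, , drop = FALSE]
  }
  kabsch_superpose(rxyz, cxyz)$rmsd
}

#' Positional sequence identity
#'
#' Percent of matching positions between two equal-length sequences.
#' Alignment-free: designs preserve length, so positional comparison is
#' exact. For sequences of different length use an external aligner
#' first.
#'
#' @param a,b amino-acid strings of equal length.
#' @return identity in percent, \[0,100\].
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b),
         "); align externally before comparing", call. = FALSE)
  }
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  100 * sum(va == vb) / length(va)
}

#' Filter design candidates by confidence and backbone agreement
#'
#' A candidate passes when `mean_plddt > plddt_min` AND
#' `ca_rmsd < rmsd_max` — strict inequalities, so a candidate exactly at
#' a threshold fails. Input order is preserved.
#'
#' @param candidates list of `funcfix_candidate`.
#' @param reference `funcfix_structure` or C-alpha matrix.
#' @param plddt_min minimum mean pLDDT (default 85.0).
#' @param rmsd_max maximum C-alpha RMSD in A (default 1.0).
#' @param parent_sequence optional parent sequence; when given,
#'   identity_to_parent is reported.
#' @param chain reference chain.
#' @return data frame of class `funcfix_triage`: one row per candidate
#'   with `id`, `mean_plddt`, `ca_rmsd`, `identity_to_parent`, `pass`,
#'   `reasons` (semicolon-joined failed criteria; empty iff pass).
#' @export
filter_candidates <- function(candidates, reference, plddt_min = 85.0,
                              rmsd_max = 1.0, parent_sequence = NULL,
                              chain = NULL) {
  stopifnot(is.finite(plddt_min), is.finite(rmsd_max))
  rows <- lapply(candidates, function(cand) {
    rmsd <- ca_rmsd(cand, reference, chain = chain)
    reasons <- character()
    if (!(cand$mean_plddt > plddt_min)) {
      reasons <- c(reasons, sprintf("mean_plddt %.2f <= %.2f", cand$mean_plddt, plddt_min))
    }
    if (!(rmsd < rmsd_max)) {
      reasons <- c(reasons, sprintf("ca_rmsd %.3f >= %.3f", rmsd, rmsd_max))
    }
    ident <- if (!is.null(parent_sequence)) {
      percent_identity(cand$sequence, parent_sequence)
    } else NA_real_
    data.frame(id = cand$id, mean_plddt = cand$mean_plddt, ca_rmsd = rmsd,
               identity_to_parent = ident,
               pass = length(reasons) == 0,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(), mean_plddt = numeric(), ca_rmsd = numeric(),
               identity_to_parent = numeric(), pass = logical(),
               reasons = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("funcfix_triage", "data.frame")
  out
}

#' Write a triage report as TSV
#'
#' Rows sorted by (pass desc, mean_plddt desc); a summary comment line
#' with the pass count heads the file.
#'
#' @param results a `funcfix_triage` data frame.
#' @param path output path.
#' @return the sorted data frame, invisibly.
#' @export
triage_report <- function(results, path = NULL) {
  ord <- order(-as.integer(results$pass), -results$mean_plddt)
  res <- results[ord, , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(path)) {
    hdr <- sprintf("# passed %d of %d", sum(res$pass), nrow(res))
    body <- if (nrow(res)) {
      do.call(paste, c(lapply(res, function(col) {
        if (is.numeric(col)) sprintf("%.4f", col) else as.character(col)
      }), sep = "\t"))
    } else character()
    atomic_write(c(hdr, paste(names(res), collapse = "\t"), body), path)
  }
  invisible(res)
}
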