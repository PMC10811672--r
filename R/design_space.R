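## Fixed-position design-space construction: ligand first-shell residues,
## MSA conservation ranking, mask assembly and ProteinMPNN-dialect output.

#' Create a residue selection
#'
#' A residue selection is a set of (chain, seq_index) positions plus a
#' provenance label recording why they were selected.
#'
#' @param chain chain identifier(s), recycled against `seq_index`.
#' @param seq_index 1-based sequential residue indices.
#' @param label provenance: `"shell"`, `"conserved"`, `"catalytic"` or
#'   `"manual"`.
#' @return object of class `funcfix_selection`.
#' @export
residue_selection <- function(chain, seq_index,
                              label = c("manual", "shell", "conserved", "catalytic")) {
  label <- match.arg(label)
  pos <- unique(data.frame(chain = as.character(chain),
                           seq_index = as.integer(seq_index),
                           stringsAsFactors = FALSE))
  pos <- pos[order(pos$chain, pos$seq_index), , drop = FALSE]
  rownames(pos) <- NULL
  structure(list(positions = pos, label = label), class = "funcfix_selection")
}

#' @export
print.funcfix_selection <- function(x, ...) {
  cat("residue selection [", x$label, "]: ", nrow(x$positions), " positions\n",
      sep = "")
  invisible(x)
}

#' First-shell residues around a bound ligand
#'
#' Selects every polymer residue having at least one heavy (non-hydrogen)
#' atom within `cutoff` of any heavy ligand atom. This is the contact
#' criterion used to fix substrate-binding residues during sequence
#' redesign; the default 7 A cutoff captures the first functional shell
#' of a bound ligand.
#'
#' @param structure a `funcfix_structure`.
#' @param ligand ligand selector: a hetero-group residue name (e.g.
#'   `"HEM"`), or a polymer chain id when the ligand is itself a peptide
#'   (e.g. a substrate chain). Waters and monoatomic ions are never
#'   matched by residue name unless `include_waters`/`include_ions`.
#' @param cutoff contact distance in Angstrom (> 0); default 7.
#' @param include_waters,include_ions widen hetero-group candidacy.
#' @return `funcfix_selection` labelled `"shell"`. Attribute
#'   `min_distances` holds the per-selected-residue minimum heavy-atom
#'   distance.
#' @export
ligand_shell <- function(structure, ligand, cutoff = 7.0,
                         include_waters = FALSE, include_ions = FALSE) {
  stopifnot(cutoff > 0)
  a <- structure$atoms
  heavy <- !(a$element %in% c("H", "D"))
  pol_chains <- unique(a$chain[!a$is_hetero])

  if (ligand %in% pol_chains) {
    lig <- heavy & !a$is_hetero & a$chain == ligand
    pol <- heavy & !a$is_hetero & a$chain != ligand
  } else {
    hg <- hetero_groups(structure, include_waters = include_waters,
                        include_ions = include_ions)
    if (!ligand %in% hg$res_name) {
      stop("ligand '", ligand, "' not found; available hetero groups: ",
           if (nrow(hg)) paste(unique(hg$res_name), collapse = ", ") else "(none)",
           "; polymer chains: ", paste(pol_chains, collapse = ", "),
           call. = FALSE)
    }
    lig <- heavy & a$is_hetero & a$res_name == ligand
    pol <- heavy & !a$is_hetero
  }
  if (!any(lig)) stop("ligand selection resolved to zero atoms", call. = FALSE)

  lxyz <- as.matrix(a[lig, c("x", "y", "z")])
  pxyz <- as.matrix(a[pol, c("x", "y", "z")])
  ## squared distance of every polymer heavy atom to its nearest ligand atom
  d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") - 2 * pxyz %*% t(lxyz)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))

  key <- paste(a$chain[pol], a$seq_index[pol], sep = "|")
  res_min <- tapply(mind, key, min)
  hit <- res_min <= cutoff
  if (!any(hit)) {
    sel <- residue_selection(character(), integer(), "shell")
    attr(sel, "min_distances") <- numeric(0)
    return(sel)
  }
  parts <- strsplit(names(res_min)[hit], "|", fixed = TRUE)
  sel <- residue_selection(vapply(parts, `[`, "", 1),
                           as.integer(vapply(parts, `[`, "", 2)),
                           "shell")
  ord <- order(sel$positions$chain, sel$positions$seq_index)
  attr(sel, "min_distances") <- as.numeric(res_min[hit])[ord]
  sel
}

#' Per-column conservation of the parent sequence
#'
#' For each ungapped parent column, the default metric is the fraction
#' of alignment rows carrying the parent's residue at that column. Gap
#' characters count in the denominator but never the numerator, so a
#' mostly-deleted column scores low: deletions across homologs are
#' evidence the position is not essential. An entropy-based alternative
#' (1 - normalised Shannon entropy over the 20 amino acids; gaps
#' counted as a 21st state) is available for comparison.
#'
#' @param msa a `funcfix_msa` with at least 2 rows.
#' @param metric `"parent_frequency"` (default) or `"entropy"`.
#' @return object of class `funcfix_conservation`: list with `scores`
#'   (one value in \[0,1\] per ungapped parent position), `parent_column`
#'   (alignment column backing each score), `n_effective` (non-gap rows
#'   per column) and `metric_name`.
#' @export
conservation_scores <- function(msa, metric = c("parent_frequency", "entropy")) {
  metric <- match.arg(metric)
  rows <- msa$rows
  if (nrow(rows) < 2) stop("need >= 2 alignment rows", call. = FALSE)
  parent <- rows[msa$parent_row, ]
  cols <- which(parent != "-")
  n <- nrow(rows)
  scores <- vapply(cols, function(j) {
    col <- rows[, j]
    if (metric == "parent_frequency") {
      sum(col == parent[j]) / n
    } else {
      p <- table(col) / n
      h <- -sum(p * log(p))
      1 - h / log(21)
    }
  }, 0)
  n_eff <- vapply(cols, function(j) sum(rows[, j] != "-"), 1L)
  structure(list(scores = scores, parent_column = cols,
                 n_effective = n_eff, metric_name = metric),
            class = "funcfix_conservation")
}

#' @export
print.funcfix_conservation <- function(x, ...) {
  cat("conservation profile (", x$metric_name, "): ", length(x$scores),
      " positions, scores ", sprintf("%.2f-%.2f", min(x$scores), max(x$scores)),
      "\n", sep = "")
  invisible(x)
}

#' Select the top conserved fraction of positions
#'
#' Returns the `ceiling(percent/100 * n)` highest-scoring parent
#' positions. Ties are broken by ascending position index, which makes
#' the output deterministic and the selections nested: the positions
#' fixed at 30% are a subset of those fixed at 50%, which are a subset
#' of those at 70%.
#'
#' @param profile a `funcfix_conservation`.
#' @param percent fraction of positions to fix, 0-100.
#' @param chain chain the profile positions refer to (default `"A"`).
#' @return `funcfix_selection` labelled `"conserved"`.
#' @export
top_conserved <- function(profile, percent, chain = "A") {
  stopifnot(percent >= 0, percent <= 100)
  n <- length(profile$scores)
  k <- ceiling(percent / 100 * n)
  if (k == 0) return(residue_selection(character(), integer(), "conserved"))
  ord <- order(-profile$scores, seq_len(n))
  residue_selection(chain, sort(ord[seq_len(k)]), "conserved")
}

#' Build a fixed/free design mask
#'
#' Unions the supplied selections into the fixed set; every other
#' polymer position of the design chains is free. Fixed and free always
#' partition the design chains. Per-position provenance records every
#' label that contributed a position.
#'
#' @param structure a `funcfix_structure`.
#' @param selections list of `funcfix_selection` (may be empty: fully
#'   free mask).
#' @param design_chains chains being redesigned; defaults to all polymer
#'   chains.
#' @return object of class `funcfix_mask`: list with `fixed`, `free`
#'   (data frames of chain/seq_index), `sources` (fixed positions with
#'   comma-joined provenance), `design_chains`.
#' @export
build_mask <- function(structure, selections = list(), design_chains = NULL) {
  if (inherits(selections, "funcfix_selection")) selections <- list(selections)
  a <- structure$atoms
  pol <- a[!a$is_hetero, , drop = FALSE]
  all_chains <- unique(pol$chain)
  if (is.null(design_chains)) design_chains <- all_chains
  if (!all(design_chains %in% all_chains)) {
    stop("design chain(s) not in structure: ",
         paste(setdiff(design_chains, all_chains), collapse = ", "), call. = FALSE)
  }
  univ <- unique(pol[pol$chain %in% design_chains, c("chain", "seq_index")])
  univ <- univ[order(univ$chain, univ$seq_index), , drop = FALSE]
  rownames(univ) <- NULL

  fixed_rows <- list(); labels <- list()
  for (s in selections) {
    stopifnot(inherits(s, "funcfix_selection"))
    p <- s$positions
    if (nrow(p) == 0) next
    bad <- !p$chain %in% design_chains
    if (any(bad)) {
      stop("selection [", s$label, "] references chain(s) outside design chains: ",
           paste(unique(p$chain[bad]), collapse = ", "), call. = FALSE)
    }
    miss <- !paste(p$chain, p$seq_index) %in% paste(univ$chain, univ$seq_index)
    if (any(miss)) {
      stop("selection [", s$label, "] references positions absent from structure: ",
           paste(paste0(p$chain[miss], ":", p$seq_index[miss]), collapse = ", "),
           call. = FALSE)
    }
    fixed_rows[[length(fixed_rows) + 1]] <- p
    labels[[length(labels) + 1]] <- rep(s$label, nrow(p))
  }
  if (length(fixed_rows)) {
    fx <- do.call(rbind, fixed_rows)
    lab <- unlist(labels)
    key <- paste(fx$chain, fx$seq_index)
    src <- tapply(lab, key, function(l) paste(sort(unique(l)), collapse = ","))
    fixed <- unique(fx)
    fixed <- fixed[order(fixed$chain, fixed$seq_index), , drop = FALSE]
    rownames(fixed) <- NULL
    sources <- data.frame(fixed,
                          provenance = as.character(src[paste(fixed$chain, fixed$seq_index)]),
                          stringsAsFactors = FALSE)
  } else {
    fixed <- univ[0, , drop = FALSE]
    sources <- data.frame(fixed, provenance = character(), stringsAsFactors = FALSE)
  }
  free <- univ[!paste(univ$chain, univ$seq_index) %in% paste(fixed$chain, fixed$seq_index), ,
               drop = FALSE]
  rownames(free) <- NULL
  structure(list(fixed = fixed, free = free, sources = sources,
                 design_chains = design_chains),
            class = "funcfix_mask")
}

#' @export
print.funcfix_mask <- function(x, ...) {
  n <- nrow(x$fixed) + nrow(x$free)
  cat("design mask: ", nrow(x$fixed), " fixed / ", nrow(x$free), " free (",
      sprintf("%.1f%%", 100 * nrow(x$fixed) / max(n, 1)), " fixed) on chain(s) ",
      paste(x$design_chains, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Emit a mask in the ProteinMPNN fixed-position dialect
#'
#' Produces `{"name": {"chain": [seq_index, ...]}}` JSON with sorted
#' chain keys and ascending position lists. Chains with no fixed
#' positions emit an empty list. Output is byte-stable across reruns so
#' fixed-position files are diffable.
#'
#' @param mask a `funcfix_mask`.
#' @param name design name used as the top-level JSON key.
#' @param path optional output file; when given, written atomically
#'   (write-then-rename).
#' @return the JSON string, invisibly when `path` is given.
#' @export
emit_fixed_positions <- function(mask, name, path = NULL) {
  chains <- sort(mask$design_chains)
  per_chain <- lapply(chains, function(ch) {
    idx <- sort(mask$fixed$seq_index[mask$fixed$chain == ch])
    as.integer(idx)
  })
  names(per_chain) <- chains
  obj <- list(per_chain)
  names(obj) <- name
  json <- as.character(jsonlite::toJSON(obj, digits = NA))
  if (!is.null(path)) {
    atomic_write(json, path)
    return(invisible(json))
  }
  json
}

## write-then-rename so consumers never see partial files
atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Tabulate a design mask against its structure
#'
#' One row per polymer position of the design chains: chain, sequential
#' index, author residue number, residue name, fixed/free status and
#' provenance. Summary counts are attached as attributes `n_fixed`,
#' `n_free` and `fraction_fixed`.
#'
#' @param mask a `funcfix_mask` built from `structure`.
#' @param structure the source `funcfix_structure`.
#' @return data frame; see Details.
#' @export
mask_report <- function(mask, structure) {
  a <- structure$atoms
  pol <- a[!a$is_hetero & a$chain %in% mask$design_chains, , drop = FALSE]
  res <- unique(pol[, c("chain", "seq_index", "auth_seq_id", "ins", "res_name")])
  res <- res[order(res$chain, res$seq_index), , drop = FALSE]
  key <- paste(res$chain, res$seq_index)
  fkey <- paste(mask$fixed$chain, mask$fixed$seq_index)
  skey <- paste(mask$sources$chain, mask$sources$seq_index)
  out <- data.frame(
    chain = res$chain, seq_index = res$seq_index,
    auth_seq_id = paste0(res$auth_seq_id, res$ins),
    res_name = res$res_name,
    status = ifelse(key %in% fkey, "fixed", "free"),
    provenance = ifelse(key %in% fkey,
                        mask$sources$provenance[match(key, skey)], ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_fixed") <- sum(out$status == "fixed")
  attr(out, "n_free") <- sum(out$status == "free")
  attr(out, "fraction_fixed") <- if (nrow(out)) sum(out$status == "fixed") / nrow(out) else 0
  out
}

#' Write a mask report as TSV
#' @param report output of [mask_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_report <- function(report, path) {
  hdr <- sprintf("# n_fixed=%d n_free=%d fraction_fixed=%.4f",
                 attr(report, "n_fixed"), attr(report, "n_free"),
                 attr(report, "fraction_fixed"))
  lines <- c(hdr, paste(names(report), collapse = "\t"),
             do.call(paste, c(report, sep = "\t")))
  atomic_write(lines, path)
}
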