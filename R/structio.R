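#' @importFrom stats coef lm sd deviance residuals predict median
#' @importFrom graphics lines abline
#' @importFrom utils head
NULL

WATER_CODES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Read a protein structure from PDB or mmCIF
#'
#' Parses a coordinate file into a uniform atom table. Polymer residues
#' (ATOM records) are assigned a 1-based sequential index (`seq_index`)
#' per chain in file order, the numbering convention consumed by
#' fixed-position design backends; author residue numbers are preserved
#' untouched in `auth_seq_id`. Hetero groups (HETATM) carry no
#' `seq_index`. When a file holds alternate conformations, only the
#' highest-occupancy conformer of each atom is kept. Multi-model files
#' yield the first model; use [read_ensemble()] for all models.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"cif"`.
#' @return An object of class `funcfix_structure`: a list with `id` and
#'   `atoms`, a data frame with one row per atom (columns `record`,
#'   `chain`, `res_name`, `auth_seq_id`, `ins`, `seq_index`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `occ`, `b`, `is_hetero`).
#'   The B-factor column doubles as per-residue pLDDT when the file is a
#'   predicted model.
#' @seealso [extract_sequence()], [hetero_groups()], [ligand_shell()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  st <- as_structure(pdb, id = sub("\\.(pdb|cif|ent)$", "", basename(path),
                                   ignore.case = TRUE))
  if (!any(!st$atoms$is_hetero)) {
    stop("no polymer (ATOM) residues in ", path, call. = FALSE)
  }
  st
}

## Convert a bio3d pdb object into the package's atom table, resolving
## altlocs to the highest-occupancy conformer and assigning seq_index.
as_structure <- function(pdb, id = "structure") {
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  ins <- if ("insert" %in% names(a)) ifelse(is.na(a$insert), "", a$insert) else ""
  elem <- if ("elesy" %in% names(a)) a$elesy else NA_character_
  elem <- ifelse(is.na(elem) | elem == "", guess_element(a$elety), toupper(elem))
  occ <- if ("o" %in% names(a)) ifelse(is.na(a$o), 1, a$o) else 1
  atoms <- data.frame(
    record = a$type, chain = chain, res_name = a$resid,
    auth_seq_id = a$resno, ins = ins, seq_index = NA_integer_,
    atom_name = a$elety, element = elem,
    x = a$x, y = a$y, z = a$z, occ = occ,
    b = ifelse(is.na(a$b), 0, a$b),
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)

  ## altloc: keep the highest-occupancy copy of each atom
  alt <- if ("alt" %in% names(a)) ifelse(is.na(a$alt), "", a$alt) else ""
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$auth_seq_id, atoms$ins, atoms$res_name,
                 atoms$atom_name, sep = "|")
    ord <- order(key, -atoms$occ, alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$auth_seq_id, atoms$ins,
                                     atoms$res_name, atoms$atom_name, sep = "|")), ,
                   drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }

  ## sequential polymer numbering, 1..n per chain in file order
  pol <- !atoms$is_hetero
  for (ch in unique(atoms$chain[pol])) {
    sel <- pol & atoms$chain == ch
    rkey <- paste(atoms$auth_seq_id[sel], atoms$ins[sel], sep = "|")
    atoms$seq_index[sel] <- match(rkey, unique(rkey))
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "funcfix_structure")
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "MG", "ZN", "MN", "CU", "NA", "CL", "BR", "SE", "CA"),
         two, one)
}

#' @export
print.funcfix_structure <- function(x, ...) {
  pol <- x$atoms[!x$atoms$is_hetero, ]
  chains <- unique(pol$chain)
  nres <- vapply(chains, function(ch) length(unique(pol$seq_index[pol$chain == ch])), 1L)
  cat("funcfix structure '", x$id, "'\n", sep = "")
  cat("  chains: ", paste0(chains, " (", nres, " res)", collapse = ", "), "\n", sep = "")
  hg <- hetero_groups(x)
  if (nrow(hg)) {
    cat("  hetero: ", paste0(hg$res_name, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' List hetero groups of a structure
#'
#' One row per hetero group (ligand, ion, water). Waters and monoatomic
#' ions are excluded by default because they are rarely meaningful
#' ligands for design-mask construction.
#'
#' @param structure a `funcfix_structure`.
#' @param include_waters keep water molecules.
#' @param include_ions keep monoatomic groups.
#' @return data frame with `chain`, `auth_seq_id`, `res_name`, `n_atoms`.
#' @export
hetero_groups <- function(structure, include_waters = FALSE, include_ions = FALSE) {
  a <- structure$atoms[structure$atoms$is_hetero, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(chain = character(), auth_seq_id = integer(),
                      res_name = character(), n_atoms = integer()))
  }
  key <- paste(a$chain, a$auth_seq_id, a$ins, a$res_name, sep = "|")
  sp <- split(seq_len(nrow(a)), key)
  sp <- sp[order(vapply(sp, min, 1L))]  # file order
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(chain = a$chain[i[1]], auth_seq_id = a$auth_seq_id[i[1]],
               res_name = a$res_name[i[1]], n_atoms = length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!include_waters) out <- out[!(out$res_name %in% WATER_CODES), , drop = FALSE]
  if (!include_ions) out <- out[out$n_atoms > 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the one-letter amino-acid sequence of a chain
#'
#' One letter per polymer residue in `seq_index` order; residues with no
#' one-letter mapping become `"X"`.
#'
#' @param structure a `funcfix_structure`.
#' @param chain chain identifier; defaults to the first polymer chain.
#' @return single character string.
#' @export
extract_sequence <- function(structure, chain = NULL) {
  pol <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  chains <- unique(pol$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  p <- pol[pol$chain == chain, , drop = FALSE]
  res3 <- p$res_name[!duplicated(p$seq_index)][order(unique(p$seq_index))]
  aa <- suppressWarnings(bio3d::aa321(res3))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  paste(aa, collapse = "")
}

#' Write a structure as a PDB file
#'
#' Emits ATOM/HETATM/TER/END records in fixed-width PDB format. Used by
#' the fixture generators so that synthetic inputs are valid input for
#' third-party tools as well.
#'
#' @param structure a `funcfix_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_atom_records(structure$atoms), con)
  writeLines("END", con)
  invisible(path)
}

format_atom_records <- function(atoms, serial_start = 1L) {
  n <- nrow(atoms)
  serial <- seq.int(serial_start, length.out = n)
  name4 <- ifelse(nchar(atoms$atom_name) >= 4, substr(atoms$atom_name, 1, 4),
                  sprintf(" %-3s", atoms$atom_name))
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, serial, name4, "", substr(atoms$res_name, 1, 3),
          atoms$chain, atoms$auth_seq_id, substr(paste0(atoms$ins, " "), 1, 1),
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b, atoms$element)
}

## ---------------------------------------------------------------- MSA ----

#' Read a multiple sequence alignment
#'
#' Aligned FASTA is read as-is. A3M is normalised first: lowercase
#' letters mark insertions relative to the query and are removed, so all
#' rows align to the query columns; `.` gap characters become `-`.
#'
#' @param path alignment file.
#' @param format `"auto"` (by extension: `.a3m` vs anything else),
#'   `"fasta"` or `"a3m"`.
#' @param parent_row index of the parent/query row (default 1, the usual
#'   position of the query in homology-search output).
#' @return object of class `funcfix_msa`: list with `rows` (character
#'   matrix, sequences x columns), `ids`, `parent_row`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m"), parent_row = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("MSA file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  }
  if (format == "fasta") {
    aln <- bio3d::read.fasta(path)
    rows <- toupper(aln$ali)
    ids <- rownames(aln$ali)
  } else {
    fa <- parse_fasta_lines(readLines(path))
    if (!length(fa$seq)) stop("empty alignment file: ", path, call. = FALSE)
    seqs <- vapply(fa$seq, function(s) gsub("[a-z]", "", chartr(".", "-", s)), "")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop("ragged alignment after a3m normalization: row lengths ",
           paste(unique(lens), collapse = ", "), call. = FALSE)
    }
    rows <- do.call(rbind, strsplit(toupper(seqs), ""))
    ids <- fa$id
  }
  if (is.null(dim(rows)) || nrow(rows) == 0 || ncol(rows) == 0) {
    stop("empty alignment: ", path, call. = FALSE)
  }
  rownames(rows) <- NULL
  if (parent_row < 1 || parent_row > nrow(rows)) {
    stop("parent_row out of range", call. = FALSE)
  }
  structure(list(rows = rows, ids = ids, parent_row = as.integer(parent_row)),
            class = "funcfix_msa")
}

## minimal FASTA tokenizer used only for a3m, whose ragged raw rows are
## not a valid aligned-FASTA matrix
parse_fasta_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(list(id = character(), seq = character()))
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  list(id = ids, seq = unname(seqs))
}

#' @export
print.funcfix_msa <- function(x, ...) {
  cat("funcfix MSA: ", nrow(x$rows), " sequences x ", ncol(x$rows),
      " columns (parent row ", x$parent_row, ")\n", sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#' @param msa a `funcfix_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  ids <- if (is.null(msa$ids)) paste0("seq", seq_len(nrow(msa$rows))) else msa$ids
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(msa$rows))) {
    writeLines(c(paste0(">", ids[i]), paste(msa$rows[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a multi-model PDB as a coordinate ensemble
#'
#' Every MODEL block becomes one frame; all frames must share the same
#' atom count and ordering. Binary trajectory formats are not parsed;
#' convert them to multi-model PDB upstream.
#'
#' @param path multi-model PDB file.
#' @return object of class `funcfix_ensemble`: list with `frames` (list
#'   of n_atoms x 3 matrices), `atoms` (the shared atom table of the
#'   first frame) and `source = "trajectory"`.
#' @export
read_ensemble <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  st <- as_structure(pdb, id = basename(path))
  xyz <- pdb$xyz
  nfr <- nrow(xyz)
  frames <- lapply(seq_len(nfr), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  new_ensemble(frames, st$atoms, source = "trajectory")
}

new_ensemble <- function(frames, atoms, source = "trajectory") {
  stopifnot(length(frames) >= 1)
  nat <- vapply(frames, nrow, 1L)
  if (length(unique(nat)) != 1) stop("frames differ in atom count", call. = FALSE)
  if (nat[1] != nrow(atoms)) stop("frame size does not match atom table", call. = FALSE)
  structure(list(frames = frames, atoms = atoms, source = source),
            class = "funcfix_ensemble")
}

#' @export
print.funcfix_ensemble <- function(x, ...) {
  cat("funcfix ensemble: ", length(x$frames), " frames x ",
      nrow(x$atoms), " atoms (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Write an ensemble as a multi-model PDB
#' @param ensemble a `funcfix_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  atoms <- ensemble$atoms
  for (i in seq_along(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    fr <- ensemble$frames[[i]]
    atoms$x <- fr[, 1]; atoms$y <- fr[, 2]; atoms$z <- fr[, 3]
    writeLines(format_atom_records(atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
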