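# Structure and alignment I/O. PDB parsing/writing is delegated to bio3d;
# this layer adds validation with line numbers, alt-loc resolution by
# occupancy, element inference, and the container classes used downstream.

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
WATER_RESID <- c("HOH", "WAT")

#' Construct a structure model
#'
#' A `structure_model` holds one conformation as an atom table: chain id,
#' author residue number, insertion code, residue name, atom name, element,
#' Cartesian coordinates (Angstrom), occupancy and a hetero flag.
#'
#' @param atom data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`, `o`, `hetero`.
#' @param model model index (>= 1).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atom, model = 1L) {
  required <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "o", "hetero")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atom) == 0L) stop("structure has zero atoms")
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atom coordinates")
  key <- atom_key(atom)
  if (anyDuplicated(key))
    stop("duplicate atom identity after alt-loc resolution: ",
         key[duplicated(key)][1L])
  rownames(atom) <- NULL
  structure(list(atom = atom, model = as.integer(model)),
            class = "structure_model")
}

atom_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
}

residue_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, sep = "|")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atom
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(residue_key(a[!a$hetero, , drop = FALSE]))),
      "protein residues,", sum(a$hetero), "hetero atoms\n")
  invisible(x)
}

#' Extract an n x 3 coordinate matrix
#'
#' @param x a `structure_model`.
#' @param sel optional logical/integer row selector on the atom table.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x, sel = NULL) {
  a <- x$atom
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Construct a trajectory container
#'
#' Ordered conformations sharing one atom roster, stored bio3d-style as a
#' frames x 3N coordinate matrix.
#'
#' @param atom shared atom roster (as in [structure_model()], coordinates
#'   ignored).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atom)` columns.
#' @param box optional per-frame box lengths (frames x 3, Angstrom).
#' @return object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(atom, xyz, box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atom))
    stop("xyz has ", ncol(xyz), " columns; roster implies ", 3L * nrow(atom))
  if (!all(is.finite(xyz))) stop("non-finite trajectory coordinates")
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 3L)
    if (nrow(box) == 1L) box <- box[rep(1L, nrow(xyz)), , drop = FALSE]
    if (nrow(box) != nrow(xyz)) stop("box rows must match frame count")
  }
  rownames(atom) <- NULL
  structure(list(atom = atom, xyz = xyz, box = box),
            class = "trajectory_frames")
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat("trajectory_frames:", nrow(x$xyz), "frames x", nrow(x$atom), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param frames a `trajectory_frames`.
#' @export
n_frames <- function(frames) nrow(frames$xyz)

#' Extract one frame as a structure model
#' @param frames a `trajectory_frames`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(frames, i) {
  if (i < 1L || i > n_frames(frames)) stop("frame index out of range")
  a <- frames$atom
  m <- matrix(frames$xyz[i, ], ncol = 3L, byrow = TRUE)
  a$x <- m[, 1L]; a$y <- m[, 2L]; a$z <- m[, 3L]
  structure_model(a, model = i)
}

infer_element <- function(elety, resid) {
  # strip leading digits ("1HB"), take leading alpha token
  nm <- toupper(gsub("^[0-9]+", "", trimws(elety)))
  two <- substr(nm, 1L, 2L)
  el <- substr(nm, 1L, 1L)
  ions <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA", "K")
  ifelse(two %in% c("CL", "BR") |
           (toupper(resid) %in% ions & two %in% ions), two, el)
}

resolve_altloc <- function(atom) {
  # keep, per atom identity, the highest-occupancy conformer;
  # ties broken by alphabetical alt-loc id
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- atom_key(atom)
  ord <- order(key, -occ, alt)
  keep_first <- !duplicated(key[ord])
  sort(ord[keep_first])
}

#' Read a PDB structure or multi-model trajectory
#'
#' ATOM/HETATM records are parsed with bio3d. Alternate locations are
#' resolved to the highest-occupancy conformer (ties: alphabetical alt-loc
#' id). Elements missing from the element column are inferred from the atom
#' name. Waters and other hetero groups are retained and flagged.
#'
#' @param path PDB file.
#' @param model_policy `"first"` returns a [structure_model()] from the
#'   first MODEL; `"all"` returns [trajectory_frames()] over all MODELs.
#' @return `structure_model` or `trajectory_frames`.
#' @export
read_structure <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'")
  for (ln in which(is_atom)) {
    txt <- lines[ln]
    if (nchar(txt) < 54L)
      stop("malformed ATOM/HETATM record at line ", ln, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(txt, 31, 38),
                                         substr(txt, 39, 46),
                                         substr(txt, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM/HETATM record at line ", ln,
           ": unreadable coordinates")
  }
  multi <- model_policy == "all"
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)))
  a <- pdb$atom
  atom <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = toupper(a$resid),
    elety = a$elety,
    element = ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                     infer_element(a$elety, a$resid), toupper(trimws(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    hetero = a$type == "HETATM",
    alt = a$alt,
    stringsAsFactors = FALSE)
  keep <- resolve_altloc(atom)
  atom <- atom[keep, setdiff(names(atom), "alt"), drop = FALSE]
  if (multi) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
    trajectory_frames(atom, xyz[, cols, drop = FALSE])
  } else {
    structure_model(atom)
  }
}

#' Write a structure or trajectory to PDB
#'
#' Hetero records are written as HETATM; multi-frame inputs produce a
#' MODEL/ENDMDL block per frame.
#'
#' @param x a `structure_model` or `trajectory_frames`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "structure_model")) {
    atom <- x$atom
    xyz <- as.vector(t(coords(x)))
  } else if (inherits(x, "trajectory_frames")) {
    atom <- x$atom
    xyz <- x$xyz
  } else stop("x must be a structure_model or trajectory_frames")
  ins <- atom$insert
  ins[ins == ""] <- NA_character_
  ch <- atom$chain
  ch[ch == ""] <- NA_character_
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(atom$hetero, "HETATM", "ATOM"),
                   resno = atom$resno, resid = atom$resid,
                   eleno = seq_len(nrow(atom)), elety = atom$elety,
                   chain = ch, insert = ins, o = atom$o,
                   b = rep(0, nrow(atom)), elesy = atom$element)
  invisible(path)
}

#' Read an aligned-FASTA multiple sequence alignment
#'
#' @param path aligned FASTA file; at least two records of equal length.
#' @return object of class `alignment_set`: list with `labels`, `seqs`
#'   (named uppercase strings over the amino-acid alphabet plus `-`) and
#'   `ncol`.
#' @export
read_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  seqs <- toupper(unlist(recs))
  alignment_set(seqs)
}

#' Construct an alignment set from named aligned sequences
#' @param seqs named character vector of equal-length aligned sequences.
#' @export
alignment_set <- function(seqs) {
  if (length(seqs) < 2L) stop("alignment needs at least 2 records")
  labels <- names(seqs)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("alignment records must carry unique non-empty labels")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "))
  structure(list(labels = labels, seqs = toupper(seqs),
                 ncol = unname(widths[1L])),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set:", length(x$labels), "records x", x$ncol, "columns\n")
  invisible(x)
}

#' Write an alignment set as aligned FASTA
#' @param aln an `alignment_set`.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$labels))
    writeLines(c(paste0(">", aln$labels[i]), aln$seqs[[i]]), con)
  invisible(path)
}
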