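# Binding-site residue selection and group-aware pairwise conservation
# scoring across receptors. Identical residues score 1.0, residues from the
# same physicochemical group 0.5, anything else (including gaps) 0.0; the
# percentage is taken relative to the maximally achievable score, i.e. the
# number of site residues.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default residue-group scheme
#'
#' Partition of the 20 standard amino acids into physicochemical classes
#' used for the 0.5 "same group" score. Any complete partition can be
#' supplied in its place.
#'
#' @return named list of single-letter amino-acid vectors.
#' @export
default_group_scheme <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "M"),
       aromatic    = c("F", "W", "Y"),
       polar       = c("S", "T", "N", "Q", "C", "G", "P"),
       positive    = c("K", "R", "H"),
       negative    = c("D", "E"))
}

validate_group_scheme <- function(scheme) {
  members <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, AA1))
    stop("group scheme must partition the 20 standard amino acids")
  invisible(scheme)
}

group_lookup <- function(scheme) {
  validate_group_scheme(scheme)
  g <- rep(names(scheme), lengths(scheme))
  names(g) <- unlist(scheme, use.names = FALSE)
  g
}

#' Score one aligned residue pair
#'
#' @param a,b single-letter amino acids (or `"-"` for a gap).
#' @param scheme residue-group partition, see [default_group_scheme()].
#' @return 1.0 (identical), 0.5 (same group), or 0.0 (different group or
#'   any gap).
#' @export
score_residue_pair <- function(a, b, scheme = default_group_scheme()) {
  g <- group_lookup(scheme)
  a <- toupper(a); b <- toupper(b)
  bad <- setdiff(c(a, b), c(AA1, "-"))
  if (length(bad)) stop("unknown residue letter: ", paste(bad, collapse = ", "))
  ifelse(a == "-" | b == "-", 0,
         ifelse(a == b, 1, ifelse(g[a] == g[b], 0.5, 0)))
}

#' Pairwise conservation percentage over site columns
#'
#' Sum of per-column pair scores over the given alignment columns, as a
#' percentage of the maximum achievable score (one per site residue).
#' Columns where either sequence carries a gap contribute 0 but stay in the
#' denominator.
#'
#' @param columns alignment column indices (1-based), one per site residue.
#' @param row_a,row_b aligned sequences (strings of equal length).
#' @param scheme residue-group partition.
#' @return percentage in \[0, 100\].
#' @export
conservation_percentage <- function(columns, row_a, row_b,
                                    scheme = default_group_scheme()) {
  if (length(columns) == 0L) stop("empty site column list")
  if (any(columns < 1L | columns > nchar(row_a) | columns > nchar(row_b)))
    stop("site column outside alignment bounds")
  ca <- substring(row_a, columns, columns)
  cb <- substring(row_b, columns, columns)
  100 * sum(score_residue_pair(ca, cb, scheme)) / length(columns)
}

parse_ligand_selector <- function(sel) {
  if (is.list(sel)) return(sel)
  parts <- strsplit(as.character(sel), ":", fixed = TRUE)[[1L]]
  if (length(parts) == 2L)
    list(chain = parts[1L], resno = as.integer(parts[2L]))
  else
    list(resid = toupper(parts[1L]))
}

#' Select binding-site residues around a cocrystallized ligand
#'
#' The allosteric site is the contact shell: every protein residue with at
#' least one heavy atom within `radius` of any ligand heavy atom.
#' Hydrogens are ignored on both sides.
#'
#' @param structure a [structure_model()].
#' @param ligand ligand selector: `"chain:resno"` string, a list with
#'   `chain`/`resno` (and optionally `insert`), or a list with `resid`
#'   naming a hetero residue.
#' @param radius contact radius, Angstrom (default 5.0).
#' @return data frame of residues (`chain`, `resno`, `insert`, `resid`),
#'   ordered by residue number.
#' @export
select_site_residues <- function(structure, ligand, radius = 5.0) {
  a <- structure$atom
  sel <- parse_ligand_selector(ligand)
  lig <- if (!is.null(sel$resid)) {
    a$resid == sel$resid
  } else {
    hit <- a$chain == sel$chain & a$resno == sel$resno
    if (!is.null(sel$insert)) hit & a$insert == sel$insert else hit
  }
  lig <- lig & a$element != "H"
  if (!any(lig)) stop("ligand selector matches no heavy atoms")
  prot <- !a$hetero & a$element != "H" & !lig
  if (!any(prot)) stop("no protein heavy atoms in structure")
  lp <- coords(structure, lig)
  pp <- coords(structure, prot)
  # squared distance of each protein atom to its nearest ligand atom
  d2 <- rowSums(pp^2) %*% t(rep(1, nrow(lp))) +
    rep(1, nrow(pp)) %*% t(rowSums(lp^2)) - 2 * pp %*% t(lp)
  near <- apply(d2, 1L, min) <= radius^2
  res <- a[prot, c("chain", "resno", "insert", "resid")][near, , drop = FALSE]
  res <- unique(res)
  res <- res[order(res$resno, res$insert, res$chain), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Site definition: residues plus their alignment columns
#'
#' @param label site label (e.g. `"AF2"` or `"BF3"`).
#' @param reference reference receptor label.
#' @param residues residue table from [select_site_residues()].
#' @param columns optional alignment columns, one per residue.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(label, reference, residues, columns = NULL) {
  if (nrow(residues) == 0L) stop("site residue list is empty")
  if (anyDuplicated(residue_key(residues))) stop("duplicate site residues")
  if (!is.null(columns) && length(columns) != nrow(residues))
    stop("alignment columns must map 1:1 to residues")
  structure(list(label = label, reference = reference,
                 residues = residues, columns = columns),
            class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("site_definition:", x$label, "on", x$reference, "-",
      nrow(x$residues), "residues",
      if (!is.null(x$columns)) "(mapped to alignment)" else "(unmapped)", "\n")
  invisible(x)
}

#' Map site residues onto alignment columns
#'
#' The reference receptor's ungapped aligned sequence must contain the
#' structure-derived sequence of the site's protein chain; each site
#' residue is assigned the alignment column that holds it.
#'
#' @param site a [site_definition()].
#' @param structure the reference [structure_model()] the site was
#'   selected on.
#' @param alignment an `alignment_set` containing the reference receptor.
#' @return the site with `columns` filled in.
#' @export
map_site_to_alignment <- function(site, structure, alignment) {
  if (!site$reference %in% alignment$labels)
    stop("reference receptor '", site$reference, "' absent from alignment")
  row <- alignment$seqs[[site$reference]]
  row_chars <- strsplit(row, "")[[1L]]
  nongap_cols <- which(row_chars != "-")
  ungapped <- paste(row_chars[nongap_cols], collapse = "")

  a <- structure$atom
  prot <- a[!a$hetero & a$resid %in% STANDARD_AA3, , drop = FALSE]
  rk <- residue_key(prot)
  first <- !duplicated(rk)
  res_tab <- prot[first, c("chain", "resno", "insert", "resid"), drop = FALSE]
  struct_seq <- paste(bio3d::aa321(res_tab$resid), collapse = "")
  off <- regexpr(struct_seq, ungapped, fixed = TRUE)
  if (off < 0L)
    stop("structure-derived sequence not found in the reference aligned row")
  pos <- match(residue_key(site$residues), residue_key(res_tab))
  if (anyNA(pos))
    stop("site residue not locatable in the reference structure sequence")
  cols <- nongap_cols[as.integer(off) - 1L + pos]
  expect <- bio3d::aa321(site$residues$resid)
  got <- row_chars[cols]
  if (any(got != expect))
    stop("aligned row letters disagree with site residues at columns ",
         paste(cols[got != expect], collapse = ", "))
  site$columns <- cols
  site
}

#' Full pairwise conservation matrix over a site
#'
#' @param alignment an `alignment_set`.
#' @param site a mapped [site_definition()] (columns filled), or an integer
#'   vector of alignment columns.
#' @param scheme residue-group partition.
#' @return symmetric percentage matrix (class `conservation_matrix`) with
#'   receptor labels, diagonal 100.
#' @export
build_conservation_matrix <- function(alignment, site,
                                      scheme = default_group_scheme()) {
  columns <- if (inherits(site, "site_definition")) site$columns else site
  if (is.null(columns)) stop("site has no alignment columns; map it first")
  labs <- alignment$labels
  n <- length(labs)
  m <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- conservation_percentage(
      columns, alignment$seqs[[labs[i]]], alignment$seqs[[labs[j]]], scheme)
  }
  class(m) <- c("conservation_matrix", class(m))
  m
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("conservation_matrix (% of maximally achievable score):\n")
  print(round(unclass(x), 1), ...)
  invisible(x)
}

#' Write a conservation matrix as CSV
#' @param m a `conservation_matrix`.
#' @param path output file.
#' @export
write_conservation_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
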