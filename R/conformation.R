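# Superposition and conformational-adaptation analysis: Kabsch rigid
# fitting, pairwise RMSD matrices, medoid representative selection (the
# mutual-similarity "jury" criterion under an RMSD similarity), per-residue
# heavy-atom RMSD between representatives, and backbone RMSD series.

BACKBONE_ELETY <- c("N", "CA", "C", "O")

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid transform mapping `mobile` onto `reference`;
#' reflections are excluded, so the rotation is always proper
#' (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, matched
#'   row-for-row.
#' @param weights optional non-negative per-point weights.
#' @return list of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom). The transform maps a
#'   mobile point p to `rotation %*% p + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- matrix(as.numeric(mobile), ncol = 3L)
  Q <- matrix(as.numeric(reference), ncol = 3L)
  if (nrow(P) != nrow(Q)) stop("point counts differ")
  if (nrow(P) < 3L) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(P)) else as.numeric(weights)
  if (length(w) != nrow(P) || any(w < 0) || sum(w) == 0)
    stop("invalid weights")
  w <- w / sum(w)
  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  for (M in list(Pc, Qc)) {
    s <- svd(M * sqrt(w))$d
    if (s[2L] < 1e-8 * max(s[1L], 1))
      stop("degenerate geometry: points are (near-)collinear")
  }
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = as.vector(cq - R %*% cp),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `superposition`.
#' @param xyz n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(matrix(as.numeric(xyz), ncol = 3L) %*% t(sup$rotation),
        2L, sup$translation, "+")
}

atom_selector <- function(atom, selector = c("heavy", "backbone", "all")) {
  selector <- match.arg(selector)
  switch(selector,
         all = rep(TRUE, nrow(atom)),
         heavy = atom$element != "H" & !atom$hetero,
         backbone = !atom$hetero & atom$element != "H" &
           atom$elety %in% BACKBONE_ELETY)
}

# matched coordinate pair for two structures, by atom identity key
matched_coords <- function(a, b, selector = "heavy") {
  sa <- atom_selector(a$atom, selector)
  sb <- atom_selector(b$atom, selector)
  ka <- atom_key(a$atom)[sa]
  kb <- atom_key(b$atom)[sb]
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no matchable atoms between structures")
  list(a = coords(a, sa)[match(shared, ka), , drop = FALSE],
       b = coords(b, sb)[match(shared, kb), , drop = FALSE],
       keys = shared)
}

as_structure_list <- function(structures) {
  if (inherits(structures, "trajectory_frames"))
    lapply(seq_len(n_frames(structures)), function(i)
      get_frame(structures, i))
  else structures
}

#' Pairwise post-superposition RMSD matrix
#'
#' @param structures a [trajectory_frames()] or list of
#'   [structure_model()]s sharing one atom roster.
#' @param selector `"backbone"` or `"heavy"`.
#' @return symmetric RMSD matrix (Angstrom) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(structures,
                                 selector = c("backbone", "heavy")) {
  selector <- match.arg(selector)
  xs <- as_structure_list(structures)
  n <- length(xs)
  keys <- lapply(xs, function(s)
    atom_key(s$atom)[atom_selector(s$atom, selector)])
  if (!all(vapply(keys[-1L], identical, logical(1L), keys[[1L]])))
    stop("structures do not share one atom roster")
  cs <- lapply(xs, function(s)
    coords(s, atom_selector(s$atom, selector)))
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- kabsch_superpose(cs[[i]], cs[[j]])$rmsd
  }
  m
}

#' Select the representative structure of an ensemble
#'
#' Mutual-similarity ("jury") ranking under an RMSD similarity reduces to
#' the medoid: the structure minimizing the summed pairwise RMSD to all
#' others. Ties break to the lowest index.
#'
#' @param structures ensemble, as in [pairwise_rmsd_matrix()].
#' @param selector atom selection for the RMSD.
#' @return index of the representative structure.
#' @export
select_representative <- function(structures,
                                  selector = c("backbone", "heavy")) {
  xs <- as_structure_list(structures)
  if (length(xs) == 1L) return(1L)
  m <- pairwise_rmsd_matrix(xs, match.arg(selector))
  which.min(rowSums(m))
}

#' Per-residue heavy-atom RMSD between two representatives
#'
#' Structures are superimposed once on their shared protein backbone; each
#' site residue's RMSD is then measured over matched heavy atoms in that
#' global frame (no per-residue refit), so both displacement and rotamer
#' change contribute. Residues missing from either structure are flagged
#' rather than scored.
#'
#' @param rep_a,rep_b [structure_model()]s (e.g. cosolvent vs pure-water
#'   representatives).
#' @param site a [site_definition()] or residue data frame with `chain`,
#'   `resno`, `insert`, `resid`.
#' @return data frame: residue identity, matched atom count, `rmsd`
#'   (Angstrom, NA when missing) and `missing` flag.
#' @export
per_residue_rmsd <- function(rep_a, rep_b, site) {
  residues <- if (inherits(site, "site_definition")) site$residues else site
  bb <- matched_coords(rep_a, rep_b, "backbone")
  sup <- kabsch_superpose(bb$b, bb$a)   # move B onto A
  hk_a <- atom_key(rep_a$atom)
  hk_b <- atom_key(rep_b$atom)
  heavy_a <- rep_a$atom$element != "H"
  heavy_b <- rep_b$atom$element != "H"
  rk_a <- residue_key(rep_a$atom)
  rk_b <- residue_key(rep_b$atom)
  out <- residues
  out$n_atoms <- 0L
  out$rmsd <- NA_real_
  out$missing <- FALSE
  for (r in seq_len(nrow(residues))) {
    key <- residue_key(residues)[r]
    ia <- which(rk_a == key & heavy_a)
    ib <- which(rk_b == key & heavy_b)
    if (!length(ia) || !length(ib)) {
      out$missing[r] <- TRUE
      next
    }
    shared <- intersect(hk_a[ia], hk_b[ib])
    if (!length(shared)) {
      out$missing[r] <- TRUE
      next
    }
    pa <- coords(rep_a)[match(shared, hk_a), , drop = FALSE]
    pb <- apply_superposition(sup,
                              coords(rep_b)[match(shared, hk_b), , drop = FALSE])
    out$n_atoms[r] <- length(shared)
    out$rmsd[r] <- sqrt(mean(rowSums((pa - pb)^2)))
  }
  out
}

#' Backbone RMSD of every frame against a reference
#'
#' Backbone atoms (N, CA, C, O) are matched by identity; each frame is
#' superimposed onto the reference before the RMSD is taken.
#'
#' @param frames a [trajectory_frames()].
#' @param reference a [structure_model()].
#' @return data frame with `frame` and `rmsd` (Angstrom).
#' @export
backbone_rmsd_series <- function(frames, reference) {
  sel <- atom_selector(frames$atom, "backbone")
  if (!any(sel)) stop("trajectory roster has no backbone atoms")
  kf <- atom_key(frames$atom)[sel]
  selr <- atom_selector(reference$atom, "backbone")
  kr <- atom_key(reference$atom)[selr]
  shared <- intersect(kf, kr)
  if (length(shared) < 3L) stop("fewer than 3 matchable backbone atoms")
  ref <- coords(reference, selr)[match(shared, kr), , drop = FALSE]
  idx <- which(sel)[match(shared, kf)]
  xi <- 3L * idx - 2L
  rmsd <- vapply(seq_len(n_frames(frames)), function(f) {
    mob <- cbind(frames$xyz[f, xi], frames$xyz[f, xi + 1L],
                 frames$xyz[f, xi + 2L])
    kabsch_superpose(mob, ref)$rmsd
  }, numeric(1L))
  data.frame(frame = seq_len(n_frames(frames)), rmsd = rmsd)
}
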