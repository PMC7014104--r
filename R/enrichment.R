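# Docking-score enrichment analysis. Scores are kcal/mol, lower = better
# (Glide-style convention); class labels are active / library / decoy.

#' Read a docking-score table
#'
#' @param path CSV with columns `ligand_id`, `receptor`, `site`, `score`,
#'   `class` and optionally `designed_for`.
#' @return data frame of docking records.
#' @export
read_scores <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ligand_id", "receptor", "site", "score", "class")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols))
    stop("score table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(rec$score))) stop("non-finite docking scores")
  bad <- setdiff(unique(rec$class), c("active", "library", "decoy"))
  if (length(bad)) stop("unknown record class: ", paste(bad, collapse = ", "))
  rec
}

#' Mean docking-score shift between actives and another group
#'
#' `mean(others) - mean(actives)`; with lower-is-better scores a positive
#' shift means the actives score better by that many kcal/mol.
#'
#' @param actives,others numeric score vectors, non-empty.
#' @return shift in kcal/mol.
#' @export
score_shift <- function(actives, others) {
  if (!length(actives) || !length(others)) stop("empty score group")
  mean(others) - mean(actives)
}

#' ROC AUC of actives against decoys
#'
#' Probability that a randomly chosen active outranks (scores lower than) a
#' randomly chosen decoy, ties counted half — the normalized Mann-Whitney
#' rank-sum statistic.
#'
#' @param actives,decoys numeric score vectors (kcal/mol, lower = better).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(actives, decoys) {
  na <- length(actives); nd <- length(decoys)
  if (!na || !nd) stop("empty score group")
  r <- rank(c(actives, decoys))
  # pairs where the active scores above (worse than) the decoy, ties half
  u_worse <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  1 - u_worse / (na * nd)
}

#' In-place heavy-atom pose RMSD
#'
#' RMSD between a docked pose and the native pose over atoms matched by
#' name, with no re-superposition (both poses live in the shared receptor
#' frame). For symmetric ligands, automorphic atom-name remappings can be
#' supplied; the reported RMSD is the minimum over the identity and all
#' supplied mappings.
#'
#' @param pose,native n x 3 coordinate matrices with atom names as row
#'   names, or data frames with `name`, `x`, `y`, `z`.
#' @param symmetry optional list of named character vectors; each maps
#'   pose atom names onto equivalent native atom names.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose, native, symmetry = NULL) {
  as_named <- function(p) {
    if (is.data.frame(p)) {
      m <- as.matrix(p[, c("x", "y", "z")])
      rownames(m) <- p$name
      m
    } else as.matrix(p)
  }
  p <- as_named(pose)
  q <- as_named(native)
  if (is.null(rownames(p)) || is.null(rownames(q)))
    stop("poses must carry atom names")
  if (!setequal(rownames(p), rownames(q)) || nrow(p) != nrow(q))
    stop("atom rosters differ between pose and native")
  rmsd_for <- function(map) {
    nm <- rownames(p)
    if (!is.null(map)) {
      remapped <- ifelse(nm %in% names(map), map[nm], nm)
      if (anyDuplicated(remapped) || !setequal(remapped, rownames(q)))
        stop("symmetry mapping is not a permutation of the atom roster")
      nm <- remapped
    }
    sqrt(mean(rowSums((p - q[nm, , drop = FALSE])^2)))
  }
  min(vapply(c(list(NULL), symmetry), rmsd_for, numeric(1L)))
}

#' Per-class score distribution summary
#'
#' Binned counts on shared breaks plus bin-free summaries per class, and
#' the pairwise histogram overlap coefficient
#' (sum of per-bin minimum proportions; 1 = identical distributions).
#'
#' @param scores numeric score vector.
#' @param class class label per score.
#' @param binwidth histogram bin width, kcal/mol (default 0.5).
#' @return list of class `score_distribution`: `summary` data frame,
#'   `breaks`, `counts` matrix (class x bin) and `overlap` matrix.
#' @export
distribution_summary <- function(scores, class, binwidth = 0.5) {
  if (!length(scores)) stop("no records")
  if (length(class) != length(scores)) stop("one class label per score")
  lo <- floor(min(scores) / binwidth) * binwidth
  hi <- ceiling(max(scores) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  classes <- sort(unique(class))
  counts <- t(vapply(classes, function(cl)
    graphics::hist(scores[class == cl], breaks = breaks, plot = FALSE)$counts,
    numeric(length(breaks) - 1L)))
  rownames(counts) <- classes
  summ <- do.call(rbind, lapply(classes, function(cl) {
    s <- scores[class == cl]
    data.frame(class = cl, n = length(s), mean = mean(s),
               median = stats::median(s), iqr = stats::IQR(s),
               sd = stats::sd(s))
  }))
  ov <- diag(1, length(classes))
  dimnames(ov) <- list(classes, classes)
  for (i in seq_along(classes)) for (j in seq_len(i - 1L)) {
    p <- counts[i, ] / sum(counts[i, ])
    q <- counts[j, ] / sum(counts[j, ])
    ov[i, j] <- ov[j, i] <- sum(pmin(p, q))
  }
  structure(list(summary = summ, breaks = breaks, counts = counts,
                 overlap = ov),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("score_distribution over", length(x$breaks) - 1L, "bins\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Enrichment report for one receptor/site group
#'
#' Computes the ROC AUC of actives against decoys and the mean score shift
#' of actives against the rest of the library for the selected records.
#'
#' @param records docking-record data frame (see [read_scores()]).
#' @param receptor,site optional filters on the record table.
#' @return list of class `enrichment_report`: `auc`, `shift`
#'   (kcal/mol, NA when a group is absent), class counts and the filters.
#' @export
enrichment_report <- function(records, receptor = NULL, site = NULL) {
  r <- records
  if (!is.null(receptor)) r <- r[r$receptor == receptor, , drop = FALSE]
  if (!is.null(site)) r <- r[r$site == site, , drop = FALSE]
  if (!nrow(r)) stop("no records after filtering")
  act <- r$score[r$class == "active"]
  dec <- r$score[r$class == "decoy"]
  lib <- r$score[r$class == "library"]
  structure(list(
    receptor = receptor, site = site,
    n_active = length(act), n_decoy = length(dec), n_library = length(lib),
    auc = if (length(act) && length(dec)) roc_auc(act, dec) else NA_real_,
    shift = if (length(act) && length(lib)) score_shift(act, lib)
            else NA_real_),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment_report [%s %s]: %d actives / %d library / %d decoys\n",
              x$receptor %||% "all", x$site %||% "sites",
              x$n_active, x$n_library, x$n_decoy))
  cat(sprintf("  ROC AUC vs decoys: %s\n",
              if (is.na(x$auc)) "n/a" else sprintf("%.3f", x$auc)))
  cat(sprintf("  mean score shift vs library: %s\n",
              if (is.na(x$shift)) "n/a"
              else sprintf("%+.2f kcal/mol", x$shift)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
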