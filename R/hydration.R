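# Hydration-site analysis: DBSCAN clustering of water-oxygen positions
# from MD snapshots or merged crystal structures, occupancy computation and
# conserved-site filtering, and a distance-threshold consensus between the
# MD and crystal predictions. The crystal protocol uses epsilon 0.9 A and
# min_pts 2 (neighbor count includes the query point, so "at least one
# other water within epsilon"); the consensus threshold is 1.4 A.

#' Water observation set
#'
#' @param points n x 3 matrix of water-oxygen positions (Angstrom).
#' @param source integer source id per point (frame index or structure
#'   index, 1-based).
#' @param n_sources total number of sources (frames/structures), including
#'   those contributing no waters.
#' @return object of class `water_observations`.
#' @export
water_observations <- function(points, source, n_sources) {
  points <- matrix(as.numeric(points), ncol = 3L)
  source <- as.integer(source)
  if (nrow(points) != length(source))
    stop("one source id is required per point")
  if (n_sources < 1L) stop("source count must be >= 1")
  if (length(source) && max(source) > n_sources)
    stop("point source id exceeds source count")
  structure(list(points = points, source = source,
                 n_sources = as.integer(n_sources)),
            class = "water_observations")
}

#' @export
print.water_observations <- function(x, ...) {
  cat("water_observations:", nrow(x$points), "points from",
      x$n_sources, "sources\n")
  invisible(x)
}

#' Extract crystallographic water oxygens from superimposed structures
#'
#' One point per water oxygen (residues named HOH/WAT); hydrogens are
#' ignored. Water residues lacking an oxygen atom are skipped with a
#' warning. Structures must already share one frame (superimpose first,
#' see [kabsch_superpose()]).
#'
#' @param structures list of [structure_model()]s.
#' @return a [water_observations()] with one source per structure.
#' @export
extract_crystal_waters <- function(structures) {
  if (inherits(structures, "structure_model")) structures <- list(structures)
  pts <- list()
  src <- list()
  n_missing <- 0L
  for (i in seq_along(structures)) {
    a <- structures[[i]]$atom
    wat <- a[a$hetero & a$resid %in% WATER_RESID, , drop = FALSE]
    if (!nrow(wat)) next
    ox <- wat[wat$element == "O", , drop = FALSE]
    n_missing <- n_missing +
      length(setdiff(unique(residue_key(wat)), unique(residue_key(ox))))
    if (nrow(ox)) {
      pts[[length(pts) + 1L]] <- cbind(ox$x, ox$y, ox$z)
      src[[length(src) + 1L]] <- rep(i, nrow(ox))
    }
  }
  if (n_missing > 0L)
    warning(n_missing, " water residue(s) lack an oxygen atom; skipped")
  water_observations(do.call(rbind, c(pts, list(matrix(0, 0, 3)))),
                     unlist(c(src, list(integer()))), length(structures))
}

#' Collect water oxygens from trajectory frames
#'
#' @param frames a [trajectory_frames()].
#' @return a [water_observations()] with one source per frame.
#' @export
extract_md_waters <- function(frames) {
  a <- frames$atom
  sel <- which(a$hetero & a$resid %in% WATER_RESID & a$element == "O")
  nf <- n_frames(frames)
  if (!length(sel))
    return(water_observations(matrix(0, 0, 3), integer(), nf))
  xi <- 3L * sel - 2L
  pts <- do.call(rbind, lapply(seq_len(nf), function(f)
    cbind(frames$xyz[f, xi], frames$xyz[f, xi + 1L], frames$xyz[f, xi + 2L])))
  water_observations(pts, rep(seq_len(nf), each = length(sel)), nf)
}

# neighbor lists within eps via cell binning (cells of edge eps, 27-cell probe)
eps_neighbors <- function(points, eps) {
  n <- nrow(points)
  cell <- floor(sweep(points, 2L, apply(points, 2L, min)) / eps)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  cellmap <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- unlist(cellmap[paste(cell[i, 1L] + offsets[, 1L],
                                 cell[i, 2L] + offsets[, 2L],
                                 cell[i, 3L] + offsets[, 3L])],
                   use.names = FALSE)
    d2 <- (points[cand, 1L] - points[i, 1L])^2 +
      (points[cand, 2L] - points[i, 2L])^2 +
      (points[cand, 3L] - points[i, 3L])^2
    sort(cand[d2 <= eps2])
  })
}

#' DBSCAN clustering of 3D points
#'
#' Classic DBSCAN over Euclidean distance. A point is a core point when at
#' least `min_pts` points (itself included) lie within `eps`; clusters are
#' the density-connected sets and everything else is noise. Border points
#' are assigned to the first core cluster that reaches them in input
#' order, so results are deterministic for a given point order.
#'
#' @param points n x 3 numeric matrix.
#' @param eps neighborhood radius, Angstrom (default 0.9).
#' @param min_pts minimum neighbor count including the point itself
#'   (default 2).
#' @return list with `cluster` (integer labels, 0 = noise) and `core`
#'   (logical).
#' @export
dbscan_cluster <- function(points, eps = 0.9, min_pts = 2L) {
  if (eps <= 0) stop("eps must be positive")
  if (min_pts < 1L) stop("min_pts must be >= 1")
  points <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(points)
  if (n == 0L)
    return(list(cluster = integer(), core = logical()))
  nb <- eps_neighbors(points, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) labels[k] <- cl
        if (!visited[k] && core[k]) {
          visited[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  list(cluster = labels, core = core)
}

#' Hydration site from one cluster
#'
#' Centroid is the unweighted mean of member coordinates; occupancy is the
#' number of distinct sources contributing members divided by the source
#' count.
#'
#' @param points member coordinates (m x 3).
#' @param source member source ids.
#' @param n_sources total source count.
#' @param provenance `"MD"`, `"crystal"` or `"consensus"`.
#' @return one-row hydration-site data frame.
#' @export
site_from_cluster <- function(points, source, n_sources,
                              provenance = "MD") {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) == 0L) stop("empty cluster")
  data.frame(provenance = provenance,
             x = mean(points[, 1L]), y = mean(points[, 2L]),
             z = mean(points[, 3L]),
             members = nrow(points),
             occupancy = length(unique(source)) / n_sources,
             dH = NA_real_, mTdS = NA_real_)
}

#' Cluster a water observation set into hydration sites
#'
#' Runs [dbscan_cluster()] and summarizes every cluster via
#' [site_from_cluster()]. Noise points are discarded.
#'
#' @param obs a [water_observations()].
#' @param eps,min_pts DBSCAN parameters.
#' @param provenance provenance label for the resulting sites.
#' @return hydration-site data frame, one row per cluster, ordered by
#'   decreasing occupancy then member count.
#' @export
find_hydration_sites <- function(obs, eps = 0.9, min_pts = 2L,
                                 provenance = "MD") {
  res <- dbscan_cluster(obs$points, eps, min_pts)
  ids <- setdiff(unique(res$cluster), 0L)
  if (!length(ids)) {
    return(data.frame(provenance = character(), x = numeric(), y = numeric(),
                      z = numeric(), members = integer(),
                      occupancy = numeric(), dH = numeric(),
                      mTdS = numeric()))
  }
  sites <- do.call(rbind, lapply(ids, function(k) {
    memb <- res$cluster == k
    site_from_cluster(obs$points[memb, , drop = FALSE],
                      obs$source[memb], obs$n_sources, provenance)
  }))
  sites <- sites[order(-sites$occupancy, -sites$members,
                       sites$x, sites$y, sites$z), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Default minimal-occupancy schedule for conserved waters
#'
#' Step schedule on the number of input sources: fewer sources demand a
#' stricter occupancy for a cluster to count as conserved.
#'
#' @return data frame with `min_sources` and `threshold`.
#' @export
default_occupancy_schedule <- function() {
  data.frame(min_sources = c(1L, 10L, 30L),
             threshold = c(0.5, 0.4, 0.3))
}

#' Filter hydration sites down to conserved ones
#'
#' @param sites hydration-site data frame.
#' @param n_sources number of input sources behind the sites.
#' @param min_occupancy explicit occupancy threshold; when `NULL`, looked
#'   up from `schedule`.
#' @param schedule step schedule, see [default_occupancy_schedule()].
#' @return the subset of `sites` with occupancy >= threshold.
#' @export
filter_conserved <- function(sites, n_sources, min_occupancy = NULL,
                             schedule = default_occupancy_schedule()) {
  if (is.null(min_occupancy)) {
    row <- max(which(n_sources >= schedule$min_sources))
    min_occupancy <- schedule$threshold[row]
  }
  if (min_occupancy <= 0 || min_occupancy > 1)
    stop("occupancy threshold must lie in (0, 1]")
  out <- sites[sites$occupancy >= min_occupancy, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus between MD and crystal hydration sites
#'
#' Greedy globally-closest matching: repeatedly pair the closest unmatched
#' (MD, crystal) site pair with distance <= threshold; each site is matched
#' at most once. The consensus centroid is the pair midpoint; occupancy is
#' the mean of the two, enthalpy annotations are carried from the MD site.
#'
#' @param md_sites,crystal_sites hydration-site data frames.
#' @param threshold matching distance, Angstrom (default 1.4).
#' @return list with `consensus` (site data frame), `pairs`
#'   (`md`, `crystal`, `distance` row indices) and the unmatched row
#'   indices of both inputs.
#' @export
consensus_match <- function(md_sites, crystal_sites, threshold = 1.4) {
  if (threshold <= 0) stop("threshold must be positive")
  na <- nrow(md_sites); nb <- nrow(crystal_sites)
  pairs <- data.frame(md = integer(), crystal = integer(),
                      distance = numeric())
  if (na > 0L && nb > 0L) {
    pa <- as.matrix(md_sites[, c("x", "y", "z")])
    pb <- as.matrix(crystal_sites[, c("x", "y", "z")])
    d <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                     2 * pa %*% t(pb), 0))
    repeat {
      m <- which(d == min(d), arr.ind = TRUE)
      if (!nrow(m) || d[m[1L, 1L], m[1L, 2L]] > threshold) break
      m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE][1L, ]
      pairs <- rbind(pairs, data.frame(md = m[[1L]], crystal = m[[2L]],
                                       distance = d[m[1L], m[2L]]))
      d[m[1L], ] <- Inf
      d[, m[2L]] <- Inf
      if (all(is.infinite(d))) break
    }
  }
  consensus <- if (nrow(pairs)) {
    a <- md_sites[pairs$md, , drop = FALSE]
    b <- crystal_sites[pairs$crystal, , drop = FALSE]
    data.frame(provenance = "consensus",
               x = (a$x + b$x) / 2, y = (a$y + b$y) / 2,
               z = (a$z + b$z) / 2,
               members = a$members + b$members,
               occupancy = (a$occupancy + b$occupancy) / 2,
               dH = a$dH, mTdS = a$mTdS)
  } else {
    md_sites[0L, , drop = FALSE]
  }
  rownames(consensus) <- NULL
  list(consensus = consensus, pairs = pairs,
       unmatched_md = setdiff(seq_len(na), pairs$md),
       unmatched_crystal = setdiff(seq_len(nb), pairs$crystal))
}

#' Flag enthalpically favorable hydration sites
#'
#' Adds a logical `favorable` column: `TRUE` iff the site carries an
#' enthalpy estimate below the cutoff (default -1.0 kcal/mol). Sites
#' without a dH value are left unflagged.
#'
#' @param sites hydration-site data frame.
#' @param cutoff kcal/mol.
#' @return `sites` with a `favorable` column.
#' @export
flag_favorable <- function(sites, cutoff = -1.0) {
  sites$favorable <- !is.na(sites$dH) & sites$dH < cutoff
  sites
}

#' Attach per-site energy estimates from an external table
#'
#' Enthalpy/entropy values estimated upstream (e.g. by a hydration-site
#' prediction tool) are matched to sites by nearest centroid.
#'
#' @param sites hydration-site data frame.
#' @param energies data frame with `x`, `y`, `z`, `dH` and optionally
#'   `mTdS`.
#' @param max_dist maximum centroid distance for a match, Angstrom.
#' @return `sites` with `dH`/`mTdS` filled where matched.
#' @export
attach_site_energies <- function(sites, energies, max_dist = 1.0) {
  if (!nrow(sites) || !nrow(energies)) return(sites)
  pa <- as.matrix(sites[, c("x", "y", "z")])
  pb <- as.matrix(energies[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                   2 * pa %*% t(pb), 0))
  j <- apply(d, 1L, which.min)
  hit <- d[cbind(seq_len(nrow(sites)), j)] <= max_dist
  sites$dH[hit] <- energies$dH[j[hit]]
  if ("mTdS" %in% names(energies)) sites$mTdS[hit] <- energies$mTdS[j[hit]]
  sites
}

#' Write hydration sites as CSV
#' @param sites hydration-site data frame.
#' @param path output file.
#' @export
write_hydration_sites <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' Read a hydration-site CSV
#' @param path file written by [write_hydration_sites()] or an external
#'   site/energy table with at least `x`, `y`, `z` columns.
#' @export
read_hydration_sites <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Convert hydration sites to pseudo-atoms for PDB export
#'
#' One water oxygen per site; occupancy carries the site occupancy.
#'
#' @param sites hydration-site data frame.
#' @return a [structure_model()] writable with [write_structure()].
#' @export
hydration_sites_to_structure <- function(sites) {
  if (!nrow(sites)) stop("no sites to convert")
  structure_model(data.frame(
    chain = "W", resno = seq_len(nrow(sites)), insert = "",
    resid = "HOH", elety = "O", element = "O",
    x = sites$x, y = sites$y, z = sites$z,
    o = pmin(pmax(sites$occupancy, 0), 1), hetero = TRUE))
}
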