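# Cosolvent-probe density mapping: bin probe heavy-atom positions from
# trajectory frames into a voxel grid, normalize by the bulk probe density
# so 1.0 means bulk, and extract face-connected hotspots above an isovalue
# (the study views maps at 12x bulk).

#' Bulk number density
#'
#' @param count number of probe entities in the box.
#' @param volume box volume, cubic Angstrom.
#' @return number density in 1/Angstrom^3.
#' @export
bulk_number_density <- function(count, volume) {
  if (!is.finite(volume) || volume <= 0) stop("box volume must be positive")
  if (count < 0) stop("probe count must be >= 0")
  count / volume
}

#' Compute a bulk-normalized probe density grid
#'
#' For every voxel, the mean per-frame count of selected probe atoms in the
#' voxel is divided by `voxel volume * bulk_density`, so a voxel sampled at
#' bulk density reads 1.0. Probe atoms outside the grid are ignored.
#'
#' @param frames a [trajectory_frames()].
#' @param probe residue name(s) selecting probe molecules.
#' @param origin,dims,spacing grid geometry (see [density_grid()]).
#' @param bulk_density bulk probe-atom number density (1/A^3). Default:
#'   selected-atom count divided by the mean frame box volume.
#' @param position `"atoms"` bins every probe heavy atom; `"com"` bins one
#'   point per probe molecule (unweighted heavy-atom centroid).
#' @return a [density_grid()].
#' @export
compute_density_grid <- function(frames, probe, origin, dims, spacing,
                                 bulk_density = NULL,
                                 position = c("atoms", "com")) {
  position <- match.arg(position)
  a <- frames$atom
  sel <- which(a$resid %in% toupper(probe) & a$element != "H")
  if (!length(sel)) stop("probe selector matches no heavy atoms")
  spacing <- rep_len(as.numeric(spacing), 3L)
  dims <- rep_len(as.integer(dims), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  nf <- n_frames(frames)
  if (nf < 1L) stop("trajectory has no frames")
  if (is.null(bulk_density)) {
    if (is.null(frames$box))
      stop("bulk_density not given and trajectory carries no box lengths")
    vols <- apply(frames$box, 1L, prod)
    bulk_density <- bulk_number_density(length(sel), mean(vols))
  }
  if (bulk_density <= 0) stop("bulk density must be positive")

  xi <- 3L * sel - 2L
  counts <- integer(prod(dims))
  for (f in seq_len(nf)) {
    px <- frames$xyz[f, xi]
    py <- frames$xyz[f, xi + 1L]
    pz <- frames$xyz[f, xi + 2L]
    if (position == "com") {
      mol <- a$resno[sel]
      px <- tapply(px, mol, mean)
      py <- tapply(py, mol, mean)
      pz <- tapply(pz, mol, mean)
    }
    ix <- floor((px - origin[1L]) / spacing[1L])
    iy <- floor((py - origin[2L]) / spacing[2L])
    iz <- floor((pz - origin[3L]) / spacing[3L])
    ok <- ix >= 0L & ix < dims[1L] & iy >= 0L & iy < dims[2L] &
      iz >= 0L & iz < dims[3L]
    if (!any(ok)) next
    lin <- 1L + ix[ok] + dims[1L] * (iy[ok] + dims[2L] * iz[ok])
    t <- tabulate(lin, nbins = prod(dims))
    counts <- counts + t
  }
  vals <- array(counts / (nf * prod(spacing) * bulk_density), dim = dims)
  density_grid(vals, origin, spacing,
               probe = paste(probe, collapse = "+"), n_frames = nf)
}

# union-find over supra-threshold voxels, 6-neighbor connectivity
face_components <- function(mask_idx, dims) {
  n <- length(mask_idx)
  pos <- match(seq_len(prod(dims)), mask_idx)  # voxel lin id -> member rank
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx0 <- mask_idx - 1L
  ix <- idx0 %% dims[1L]
  iy <- (idx0 %/% dims[1L]) %% dims[2L]
  iz <- idx0 %/% (dims[1L] * dims[2L])
  link <- function(keep, offset) {
    nb <- pos[mask_idx[keep] + offset]
    hit <- which(!is.na(nb))
    for (h in hit) {
      ra <- find(which(keep)[h]); rb <- find(nb[h])
      if (ra != rb) parent[ra] <<- rb
    }
  }
  link(ix > 0L, -1L)
  link(iy > 0L, -dims[1L])
  link(iz > 0L, -dims[1L] * dims[2L])
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

#' Extract isovalue hotspots from a density grid
#'
#' Face-connected (6-neighbor) components of voxels with value >= the
#' isovalue. Each hotspot reports its value-weighted centroid, volume,
#' peak and mean value. Hotspots are sorted by peak value (descending),
#' ties broken by lexicographic centroid order.
#'
#' @param grid a [density_grid()].
#' @param isovalue threshold in multiples of bulk density (default 12).
#' @param min_voxels drop components smaller than this many voxels.
#' @return data frame (class `hotspot_set`) with one row per hotspot and a
#'   `voxels` attribute listing member voxel linear indices.
#' @export
extract_hotspots <- function(grid, isovalue = 12, min_voxels = 1L) {
  if (isovalue <= 0) stop("isovalue must be positive")
  mask_idx <- which(as.vector(grid$values) >= isovalue)
  empty <- data.frame(hotspot = integer(), n_voxels = integer(),
                      volume = numeric(), peak = numeric(), mean = numeric(),
                      x = numeric(), y = numeric(), z = numeric())
  if (!length(mask_idx)) {
    attr(empty, "voxels") <- list()
    class(empty) <- c("hotspot_set", class(empty))
    return(empty)
  }
  comp <- face_components(mask_idx, grid$dims)
  v <- as.vector(grid$values)[mask_idx]
  idx3 <- arrayInd(mask_idx, grid$dims)
  centers <- voxel_centers(grid, idx3)
  rows <- lapply(split(seq_along(mask_idx), comp), function(memb) {
    w <- v[memb] / sum(v[memb])
    c(n = length(memb), peak = max(v[memb]), mean = mean(v[memb]),
      cx = sum(w * centers[memb, 1L]), cy = sum(w * centers[memb, 2L]),
      cz = sum(w * centers[memb, 3L]))
  })
  tab <- do.call(rbind, rows)
  keep <- tab[, "n"] >= min_voxels
  if (!any(keep)) {
    attr(empty, "voxels") <- list()
    class(empty) <- c("hotspot_set", class(empty))
    return(empty)
  }
  tab <- tab[keep, , drop = FALSE]
  members <- split(mask_idx, comp)[keep]
  ord <- order(-tab[, "peak"], tab[, "cx"], tab[, "cy"], tab[, "cz"])
  tab <- tab[ord, , drop = FALSE]
  out <- data.frame(hotspot = seq_len(nrow(tab)),
                    n_voxels = as.integer(tab[, "n"]),
                    volume = tab[, "n"] * voxel_volume(grid),
                    peak = tab[, "peak"], mean = tab[, "mean"],
                    x = tab[, "cx"], y = tab[, "cy"], z = tab[, "cz"])
  attr(out, "voxels") <- unname(members[ord])
  class(out) <- c("hotspot_set", class(out))
  out
}

#' Compare two congruent density maps at an isovalue
#'
#' Reports the Jaccard overlap of the supra-isovalue voxel sets, the
#' shared/unique map volumes, and nearest-centroid pairings between the
#' hotspots of the two maps.
#'
#' @param grid_a,grid_b congruent [density_grid()]s (same origin, dims,
#'   spacing; structures already superimposed).
#' @param isovalue threshold in multiples of bulk density.
#' @return list of class `density_overlap`.
#' @export
compare_density_maps <- function(grid_a, grid_b, isovalue = 12) {
  congruent <- isTRUE(all.equal(grid_a$origin, grid_b$origin)) &&
    identical(grid_a$dims, grid_b$dims) &&
    isTRUE(all.equal(grid_a$spacing, grid_b$spacing))
  if (!congruent) stop("grids are not congruent (origin/dims/spacing differ)")
  ma <- which(as.vector(grid_a$values) >= isovalue)
  mb <- which(as.vector(grid_b$values) >= isovalue)
  inter <- length(intersect(ma, mb))
  uni <- length(union(ma, mb))
  jac <- if (uni == 0L) 1 else inter / uni
  vv <- voxel_volume(grid_a)
  ha <- extract_hotspots(grid_a, isovalue)
  hb <- extract_hotspots(grid_b, isovalue)
  pairs <- if (nrow(ha) && nrow(hb)) {
    d2 <- outer(rowSums(ha[, c("x", "y", "z")]^2),
                rowSums(hb[, c("x", "y", "z")]^2), "+") -
      2 * as.matrix(ha[, c("x", "y", "z")]) %*%
      t(as.matrix(hb[, c("x", "y", "z")]))
    d <- sqrt(pmax(d2, 0))
    data.frame(hotspot_a = seq_len(nrow(ha)),
               nearest_b = apply(d, 1L, which.min),
               distance = apply(d, 1L, min))
  } else {
    data.frame(hotspot_a = integer(), nearest_b = integer(),
               distance = numeric())
  }
  structure(list(jaccard = jac, shared_volume = inter * vv,
                 unique_a_volume = (length(ma) - inter) * vv,
                 unique_b_volume = (length(mb) - inter) * vv,
                 pairings = pairs),
            class = "density_overlap")
}

#' @export
print.density_overlap <- function(x, ...) {
  cat(sprintf("density_overlap: Jaccard %.3f, shared %.1f A^3 (unique %.1f / %.1f)\n",
              x$jaccard, x$shared_volume, x$unique_a_volume, x$unique_b_volume))
  invisible(x)
}
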