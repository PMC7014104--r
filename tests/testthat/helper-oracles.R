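# Independent brute-force oracles. Each is written against the definition,
# not against the package implementation it checks.

# O(n^2) DBSCAN from the textbook definition: full distance matrix,
# region queries by row, recursive-free expansion via repeated sweeps.
brute_dbscan <- function(points, eps, min_pts) {
  n <- nrow(points)
  if (n == 0) return(list(cluster = integer(), core = logical()))
  d <- as.matrix(stats::dist(points))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    repeat {
      # density-connect: any unlabeled point within eps of a labeled core
      grew <- FALSE
      for (j in which(core & labels == cl)) {
        reach <- nbr[[j]]
        new <- reach[labels[reach] == 0L]
        if (length(new)) {
          labels[new] <- cl
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  }
  list(cluster = labels, core = core)
}

# compare two DBSCAN labelings as partitions (labels renumbered; noise and
# core flags must agree; border-point ownership may differ between valid
# DBSCAN runs, so border points are compared by reachability, not label)
same_dbscan_partition <- function(a, b, points, eps) {
  if (!identical(a$core, b$core)) return(FALSE)
  if (!identical(a$cluster == 0L, b$cluster == 0L)) return(FALSE)
  core <- a$core
  # core points determine clusters uniquely
  part <- function(lab) {
    sets <- split(which(core), lab$cluster[core])
    unname(lapply(sets, sort))
  }
  pa <- part(a); pb <- part(b)
  if (!identical(sort(vapply(pa, paste, "", collapse = ",")),
                 sort(vapply(pb, paste, "", collapse = ",")))) return(FALSE)
  # each border point must sit within eps of a core point of its cluster
  ok <- TRUE
  for (lab in list(a, b)) {
    for (i in which(!core & lab$cluster != 0L)) {
      same <- which(core & lab$cluster == lab$cluster[i])
      dmin <- min(sqrt(colSums((t(points[same, , drop = FALSE]) -
                                  points[i, ])^2)))
      if (dmin > eps) ok <- FALSE
    }
  }
  ok
}

# AUC by enumerating all (active, decoy) pairs
enum_auc <- function(actives, decoys) {
  wins <- outer(actives, decoys, "<") + 0.5 * outer(actives, decoys, "==")
  mean(wins)
}

# conservation percentage by explicit per-column loop
brute_conservation <- function(columns, row_a, row_b, scheme) {
  g <- rep(names(scheme), lengths(scheme))
  names(g) <- unlist(scheme)
  total <- 0
  for (cc in columns) {
    a <- substr(row_a, cc, cc)
    b <- substr(row_b, cc, cc)
    s <- if (a == "-" || b == "-") 0
    else if (a == b) 1
    else if (g[[a]] == g[[b]]) 0.5
    else 0
    total <- total + s
  }
  100 * total / length(columns)
}

# greedy globally-closest matching by explicit enumeration: at each step
# scan every remaining (a, b) pair for the minimum distance
enum_greedy_match <- function(pa, pb, threshold) {
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  pairs <- NULL
  repeat {
    best <- NULL; best_d <- Inf
    for (i in which(!used_a)) for (j in which(!used_b)) {
      dij <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      if (dij < best_d) {
        best_d <- dij; best <- c(i, j)
      }
    }
    if (is.null(best) || best_d > threshold) break
    used_a[best[1]] <- TRUE; used_b[best[2]] <- TRUE
    pairs <- rbind(pairs, c(best, best_d))
  }
  if (is.null(pairs)) matrix(numeric(), 0, 3) else pairs
}

# flood fill over supra-threshold voxels, 6-neighbor, recursive queue
flood_components <- function(values, iso) {
  dims <- dim(values)
  lab <- array(0L, dims)
  cl <- 0L
  idx <- which(values >= iso, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    cl <- cl + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- cl
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        nb <- q + step
        if (any(nb < 1) || any(nb > dims)) next
        if (values[nb[1], nb[2], nb[3]] >= iso &&
            lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cl
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# density grid by direct per-frame triple counting (no vectorized binning);
# spacing is the scalar voxel edge
brute_density <- function(frames, sel_idx, origin, dims, spacing, bulk) {
  counts <- array(0, dims)
  nf <- nrow(frames$xyz)
  for (f in seq_len(nf)) {
    for (i in sel_idx) {
      p <- frames$xyz[f, (3 * i - 2):(3 * i)]
      v <- floor((p - origin) / spacing) + 1
      if (all(v >= 1) && all(v <= dims))
        counts[v[1], v[2], v[3]] <- counts[v[1], v[2], v[3]] + 1
    }
  }
  counts / (nf * spacing^3 * bulk)
}

# rigid-fit RMSD by direct numerical minimization over 6 parameters
numeric_fit_rmsd <- function(mobile, reference) {
  obj <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cg <- cos(par[3]); sg <- sin(par[3])
    Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cg, sg, 0, -sg, cg), 3, 3)
    moved <- sweep(mobile %*% t(Rz %*% Ry %*% Rx), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    r <- stats::optim(stats::runif(6, -1, 1), obj,
                      method = "BFGS", control = list(maxit = 500))
    best <- min(best, r$value)
  }
  best
}
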