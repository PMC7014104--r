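# Seeded synthetic-data generators standing in for the MD and docking
# engines. Every generator is deterministic for a fixed seed and returns
# machine-readable ground truth next to the data, so downstream tests
# never re-derive the truth from generator internals.
#
# Defaults mirror the study conditions: probes at 5% by volume in a
# 40 A cubic box, water sites observed with positional jitter across many
# sources, an eight-receptor site alignment, and Gaussian score classes.

#' Nominal per-molecule probe volumes
#'
#' Used to convert a probe volume fraction into a molecule count
#' (molar volume from liquid density, in cubic Angstrom per molecule).
#'
#' @return named numeric vector (IPA = isopropanol, ACN = acetonitrile,
#'   PYR = pyrimidine).
#' @export
probe_molecule_volumes <- function() {
  c(IPA = 127.7, ACN = 86.8, PYR = 130.9)
}

#' Synthetic probe trajectory with planted enrichment hotspots
#'
#' Each frame holds `n_background` single-pseudo-atom probes placed
#' uniformly in the box (the bulk), plus, per hotspot, a fixed number of
#' extra probes drawn from an isotropic Gaussian at the hotspot center.
#' The extra count is chosen so the expected density at the blob center is
#' `factor` times bulk:
#' `n_extra = round((factor - 1) * bulk * (2 * pi * sigma^2)^(3/2))`.
#'
#' @param n_frames number of frames (>= 1).
#' @param box box lengths, Angstrom.
#' @param probe probe label (sets the default molecular volume).
#' @param volume_fraction probe volume fraction (default 0.05, i.e. 5% v/v).
#' @param n_probes override the background probe count directly (otherwise
#'   derived from `volume_fraction` and the probe molecular volume).
#' @param hotspots data frame with `x`, `y`, `z`, `sigma` (Angstrom) and
#'   `factor` (enrichment over bulk, >= 1); may be empty.
#' @param seed RNG seed.
#' @return list with `frames` (a [trajectory_frames()]) and `truth`
#'   (bulk density, background count, hotspot table with planted extras).
#' @export
gen_probe_trajectory <- function(n_frames = 100L, box = c(40, 40, 40),
                                 probe = "IPA", volume_fraction = 0.05,
                                 n_probes = NULL, hotspots = NULL,
                                 seed = 1L) {
  if (n_frames < 1L) stop("need at least one frame")
  box <- rep_len(as.numeric(box), 3L)
  vol <- prod(box)
  if (volume_fraction <= 0 || volume_fraction >= 1)
    stop("volume fraction must lie in (0, 1)")
  if (is.null(n_probes)) {
    vmol <- probe_molecule_volumes()[[probe]]
    n_probes <- max(1L, round(volume_fraction * vol / vmol))
  }
  bulk <- n_probes / vol
  if (is.null(hotspots))
    hotspots <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                           sigma = numeric(), factor = numeric())
  if (nrow(hotspots) && any(hotspots$factor < 1))
    stop("hotspot enrichment factors must be >= 1")
  n_extra <- if (nrow(hotspots))
    as.integer(round((hotspots$factor - 1) * bulk *
                       (2 * pi * hotspots$sigma^2)^1.5))
  else integer()
  n_atoms <- n_probes + sum(n_extra)
  atom <- data.frame(
    chain = "X", resno = seq_len(n_atoms), insert = "",
    resid = toupper(probe), elety = "C1", element = "C",
    x = 0, y = 0, z = 0, o = 1, hetero = TRUE)
  set.seed(seed)
  xyz <- matrix(0, n_frames, 3L * n_atoms)
  for (f in seq_len(n_frames)) {
    bg <- cbind(stats::runif(n_probes, 0, box[1L]),
                stats::runif(n_probes, 0, box[2L]),
                stats::runif(n_probes, 0, box[3L]))
    extra <- if (sum(n_extra)) do.call(rbind, lapply(which(n_extra > 0L),
      function(h) cbind(
        stats::rnorm(n_extra[h], hotspots$x[h], hotspots$sigma[h]),
        stats::rnorm(n_extra[h], hotspots$y[h], hotspots$sigma[h]),
        stats::rnorm(n_extra[h], hotspots$z[h], hotspots$sigma[h]))))
    else matrix(0, 0L, 3L)
    xyz[f, ] <- as.vector(t(rbind(bg, extra)))
  }
  truth <- list(bulk_density = bulk, n_background = n_probes,
                box = box,
                hotspots = cbind(hotspots, n_extra = n_extra))
  list(frames = trajectory_frames(atom, xyz,
                                  box = matrix(box, 1L)),
       truth = truth)
}

#' Synthetic water observations with planted conserved sites
#'
#' Every source (frame or structure) contributes, per planted site, one
#' jittered point with probability `occupancy`, plus `background` uniform
#' bulk waters to exercise noise rejection.
#'
#' @param n_sources number of sources.
#' @param sites data frame with `x`, `y`, `z`, `occupancy` in (0, 1\] and
#'   `jitter` (isotropic positional sd, Angstrom).
#' @param background uniform background waters per source (default 2).
#' @param box box lengths for the background, Angstrom.
#' @param seed RNG seed.
#' @return list with `obs` (a [water_observations()]) and `truth`
#'   (planted site table with realized member counts).
#' @export
gen_water_observations <- function(n_sources = 20L, sites,
                                   background = 2L, box = c(40, 40, 40),
                                   seed = 1L) {
  if (any(sites$occupancy <= 0 | sites$occupancy > 1))
    stop("site occupancies must lie in (0, 1]")
  box <- rep_len(as.numeric(box), 3L)
  set.seed(seed)
  pts <- list(); src <- list()
  realized <- integer(nrow(sites))
  for (s in seq_len(n_sources)) {
    present <- stats::runif(nrow(sites)) <= sites$occupancy
    realized <- realized + present
    if (any(present)) {
      k <- which(present)
      pts[[length(pts) + 1L]] <- cbind(
        stats::rnorm(length(k), sites$x[k], sites$jitter[k]),
        stats::rnorm(length(k), sites$y[k], sites$jitter[k]),
        stats::rnorm(length(k), sites$z[k], sites$jitter[k]))
      src[[length(src) + 1L]] <- rep(s, length(k))
    }
    if (background > 0L) {
      pts[[length(pts) + 1L]] <- cbind(stats::runif(background, 0, box[1L]),
                                       stats::runif(background, 0, box[2L]),
                                       stats::runif(background, 0, box[3L]))
      src[[length(src) + 1L]] <- rep(s, background)
    }
  }
  obs <- water_observations(do.call(rbind, c(pts, list(matrix(0, 0, 3)))),
                            unlist(c(src, list(integer()))), n_sources)
  list(obs = obs, truth = cbind(sites, members = realized))
}

#' Synthetic site alignment with planted pairwise conservation
#'
#' Row 1 is the reference. For every other receptor each site column is,
#' relative to the reference letter, identical, a different letter from
#' the same residue group, or a letter from another group. With
#' `exact = TRUE` the category counts are exact
#' (`round(frac * n_columns)`), so the planted conservation percentage
#' against the reference is exact; otherwise categories are sampled per
#' column.
#'
#' @param n_receptors number of rows (>= 2).
#' @param n_columns site length (e.g. 20 for AF-2, 23 for BF-3).
#' @param identical_frac,group_frac per-pair category fractions versus the
#'   reference (remainder: other-group).
#' @param scheme residue-group partition.
#' @param exact use exact category counts instead of per-column sampling.
#' @param seed RNG seed.
#' @return list with `alignment` (an `alignment_set`, labels `R1..Rn`) and
#'   `truth` (expected percentage of each row versus the reference).
#' @export
gen_alignment <- function(n_receptors = 8L, n_columns = 20L,
                          identical_frac = 0.5, group_frac = 0.5,
                          scheme = default_group_scheme(), exact = TRUE,
                          seed = 1L) {
  if (n_receptors < 2L) stop("need at least two receptors")
  other_frac <- 1 - identical_frac - group_frac
  if (other_frac < -1e-9) stop("category fractions exceed 1")
  g <- group_lookup(scheme)
  set.seed(seed)
  ref <- sample(AA1, n_columns, replace = TRUE)
  same_group_letter <- function(a) {
    pool <- setdiff(names(g)[g == g[[a]]], a)
    if (!length(pool)) stop("residue group of '", a, "' has a single member")
    pool[sample.int(length(pool), 1L)]
  }
  other_group_letter <- function(a) {
    pool <- names(g)[g != g[[a]]]
    pool[sample.int(length(pool), 1L)]
  }
  rows <- list(R1 = paste(ref, collapse = ""))
  expected <- c(R1 = 100)
  for (r in seq_len(n_receptors - 1L)) {
    if (exact) {
      n_id <- round(identical_frac * n_columns)
      n_gr <- round(group_frac * n_columns)
      if (n_id + n_gr > n_columns) stop("exact category counts exceed columns")
      cat_vec <- sample(rep(c("id", "gr", "ot"),
                            c(n_id, n_gr, n_columns - n_id - n_gr)))
    } else {
      cat_vec <- sample(c("id", "gr", "ot"), n_columns, replace = TRUE,
                        prob = c(identical_frac, group_frac,
                                 max(other_frac, 0)))
      n_id <- sum(cat_vec == "id"); n_gr <- sum(cat_vec == "gr")
    }
    letters_r <- vapply(seq_len(n_columns), function(cc)
      switch(cat_vec[cc],
             id = ref[cc],
             gr = same_group_letter(ref[cc]),
             ot = other_group_letter(ref[cc])),
      character(1L))
    lab <- paste0("R", r + 1L)
    rows[[lab]] <- paste(letters_r, collapse = "")
    expected[[lab]] <- 100 * (n_id + 0.5 * n_gr) / n_columns
  }
  list(alignment = alignment_set(unlist(rows)),
       truth = data.frame(receptor = names(expected),
                          expected_vs_reference = unname(expected)))
}

#' Synthetic docking-score table with known separation
#'
#' Gaussian scores per class. Ground truth includes the planted
#' active-vs-library shift and the analytic active-vs-decoy AUC
#' `pnorm((mean_decoy - mean_active) / sqrt(sd_active^2 + sd_decoy^2))`.
#'
#' @param classes data frame with `class` (active/library/decoy), `mean`,
#'   `sd` and `n`. Default: 50 actives at -7.0, 500 library and 500 decoys
#'   at -6.0, sd 1.0 (a planted 1.0 kcal/mol shift).
#' @param receptor,site labels stamped on the records.
#' @param seed RNG seed.
#' @return list with `records` (docking-record data frame) and `truth`
#'   (`shift`, `auc`).
#' @export
gen_score_table <- function(classes = NULL, receptor = "AR", site = "BF3",
                            seed = 1L) {
  if (is.null(classes))
    classes <- data.frame(class = c("active", "library", "decoy"),
                          mean = c(-7, -6, -6), sd = c(1, 1, 1),
                          n = c(50L, 500L, 500L))
  if (any(classes$sd <= 0) || any(classes$n < 1L))
    stop("class sds must be positive and counts >= 1")
  set.seed(seed)
  records <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i)
    data.frame(ligand_id = sprintf("%s%04d", toupper(substr(
                 classes$class[i], 1L, 1L)), seq_len(classes$n[i])),
               receptor = receptor, site = site,
               score = stats::rnorm(classes$n[i], classes$mean[i],
                                    classes$sd[i]),
               class = classes$class[i],
               designed_for = site)))
  rownames(records) <- NULL
  pick <- function(cl) {
    i <- which(classes$class == cl)
    if (length(i)) classes[i[1L], ] else NULL
  }
  ca <- pick("active"); cd <- pick("decoy"); cl <- pick("library")
  truth <- list(
    shift = if (!is.null(ca) && !is.null(cl)) cl$mean - ca$mean else NA_real_,
    auc = if (!is.null(ca) && !is.null(cd))
      stats::pnorm((cd$mean - ca$mean) / sqrt(ca$sd^2 + cd$sd^2))
    else NA_real_)
  list(records = records, truth = truth)
}
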