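test_that("DBSCAN basics: pairs cluster, isolated points are noise", {
  pts <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(5, 5, 5))
  r <- dbscan_cluster(pts, eps = 0.9, min_pts = 2)
  expect_equal(r$cluster[1:2], c(1L, 1L))
  expect_equal(r$cluster[3], 0L)
  expect_equal(r$core, c(TRUE, TRUE, FALSE))
  expect_equal(dbscan_cluster(matrix(0, 0, 3))$cluster, integer())
  expect_error(dbscan_cluster(pts, eps = 0), "positive")
})

test_that("DBSCAN agrees with the O(n^2) brute-force oracle", {
  set.seed(31)
  for (trial in 1:30) {
    n <- sample(20:60, 1)
    # mixture of tight clumps and scattered noise
    k <- sample(2:5, 1)
    centers <- matrix(stats::runif(3 * k, 0, 10), k, 3)
    pts <- do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(stats::rnorm(3 * 8, 0, 0.3), 8, 3), 2, centers[i, ], "+")))
    pts <- rbind(pts, matrix(stats::runif(3 * (n %/% 2), 0, 10), n %/% 2, 3))
    eps <- stats::runif(1, 0.5, 1.2)
    mine <- dbscan_cluster(pts, eps, 2)
    oracle <- brute_dbscan(pts, eps, 2)
    expect_true(same_dbscan_partition(mine, oracle, pts, eps))
  }
})

test_that("cluster summaries report centroid and per-source occupancy", {
  s <- site_from_cluster(rbind(c(0, 0, 0), c(1, 0, 0)), source = c(1, 2),
                         n_sources = 10)
  expect_equal(c(s$x, s$y, s$z), c(0.5, 0, 0))
  expect_equal(s$occupancy, 0.2)
  # many members from one source still count one source
  s2 <- site_from_cluster(matrix(stats::rnorm(30), 10, 3),
                          source = rep(1, 10), n_sources = 10)
  expect_equal(s2$occupancy, 0.1)
  expect_equal(s2$members, 10)
})

test_that("conserved-site filter honors threshold and source schedule", {
  sites <- data.frame(provenance = "crystal", x = 1:3, y = 0, z = 0,
                      members = c(8, 3, 5), occupancy = c(0.8, 0.3, 0.45),
                      dH = NA_real_, mTdS = NA_real_)
  kept <- filter_conserved(sites, n_sources = 5, min_occupancy = 0.5)
  expect_equal(kept$occupancy, 0.8)
  # schedule: < 10 sources -> 0.5; 10-29 -> 0.4; >= 30 -> 0.3
  expect_equal(nrow(filter_conserved(sites, n_sources = 5)), 1)
  expect_equal(nrow(filter_conserved(sites, n_sources = 12)), 2)
  expect_equal(nrow(filter_conserved(sites, n_sources = 40)), 3)
  # monotone in the threshold
  for (th in c(0.2, 0.4, 0.6, 0.9)) {
    expect_lte(nrow(filter_conserved(sites, 5, th + 0.1)),
               nrow(filter_conserved(sites, 5, th)))
  }
  expect_error(filter_conserved(sites, 5, 0), "threshold")
})

test_that("consensus matching pairs closest sites within 1.4 A, each at most once", {
  mk <- function(x) data.frame(provenance = "MD", x = x, y = 0, z = 0,
                               members = 1, occupancy = 1,
                               dH = NA_real_, mTdS = NA_real_)
  r <- consensus_match(mk(0), mk(1.0))
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$consensus$x, 0.5)
  expect_equal(nrow(consensus_match(mk(0), mk(1.5))$pairs), 0)

  # 3 MD vs 2 crystal sites on a line: compare to enumeration oracle
  md <- mk(c(0, 2.0, 4.0))
  cr <- mk(c(0.9, 2.2))
  got <- consensus_match(md, cr)
  oracle <- enum_greedy_match(as.matrix(md[, c("x", "y", "z")]),
                              as.matrix(cr[, c("x", "y", "z")]), 1.4)
  expect_equal(as.matrix(got$pairs[, 1:2]), oracle[, 1:2, drop = FALSE],
               ignore_attr = TRUE)
})

test_that("consensus matching is symmetric in its arguments", {
  set.seed(41)
  for (trial in 1:20) {
    a <- data.frame(provenance = "MD", x = stats::runif(4, 0, 4),
                    y = stats::runif(4, 0, 4), z = stats::runif(4, 0, 4),
                    members = 1, occupancy = 1, dH = NA_real_,
                    mTdS = NA_real_)
    b <- a[sample(1:4), ]
    b$x <- b$x + stats::rnorm(4, 0, 0.8)
    ab <- consensus_match(a, b)$pairs
    ba <- consensus_match(b, a)$pairs
    expect_equal(nrow(ab), nrow(ba))
    expect_setequal(paste(ab$md, ab$crystal), paste(ba$crystal, ba$md))
  }
})

test_that("favorable-enthalpy flag uses the -1.0 kcal/mol cutoff", {
  sites <- data.frame(provenance = "consensus", x = 0, y = 0, z = 0,
                      members = 1, occupancy = 1,
                      dH = c(-2.3, -0.5, NA), mTdS = NA_real_)
  f <- flag_favorable(sites)
  expect_equal(f$favorable, c(TRUE, FALSE, FALSE))
})

test_that("crystal water extraction takes one oxygen per water per structure", {
  wat <- function(n, offset) data.frame(
    elety = "O", resid = "HOH", chain = "W", resno = seq_len(n) + offset,
    x = seq_len(n) + offset, y = 0, z = 0, het = TRUE)
  prot <- data.frame(elety = "CA", resid = "GLY", chain = "A", resno = 1L,
                     x = -5, y = 0, z = 0, het = FALSE)
  s1 <- read_structure(write_toy_pdb(rbind(prot, wat(3, 0)),
                                     tempfile(fileext = ".pdb")))
  s2 <- read_structure(write_toy_pdb(rbind(prot, wat(4, 10)),
                                     tempfile(fileext = ".pdb")))
  obs <- extract_crystal_waters(list(s1, s2))
  expect_equal(nrow(obs$points), 7)
  expect_equal(obs$n_sources, 2)
  expect_equal(obs$source, c(1, 1, 1, 2, 2, 2, 2))

  # a water with only hydrogens is skipped with a warning
  badwat <- data.frame(elety = c("H1", "H2"), resid = "HOH", chain = "W",
                       resno = 99L, x = 8, y = 0, z = 0, het = TRUE)
  s3 <- read_structure(write_toy_pdb(rbind(prot, wat(1, 0), badwat),
                                     tempfile(fileext = ".pdb")))
  expect_warning(obs3 <- extract_crystal_waters(list(s3)), "oxygen")
  expect_equal(nrow(obs3$points), 1)
})

test_that("planted conserved waters are recovered; bulk noise is rejected", {
  planted <- data.frame(x = c(10, 20, 30), y = c(10, 25, 15),
                        z = c(12, 18, 30),
                        occupancy = c(0.9, 0.8, 0.7), jitter = 0.25)
  g <- gen_water_observations(n_sources = 40, sites = planted,
                              background = 2, box = c(40, 40, 40), seed = 8)
  sites <- find_hydration_sites(g$obs, eps = 0.9, min_pts = 2,
                                provenance = "crystal")
  conserved <- filter_conserved(sites, g$obs$n_sources)
  expect_equal(nrow(conserved), 3)
  d <- sqrt(outer(conserved$x, planted$x, "-")^2 +
              outer(conserved$y, planted$y, "-")^2 +
              outer(conserved$z, planted$z, "-")^2)
  expect_lt(max(apply(d, 2, min)), 0.3)
})
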