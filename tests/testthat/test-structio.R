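test_that("single- and multi-model PDB reading preserves atoms and frames", {
  df <- data.frame(elety = rep(c("N", "CA", "C", "O", "CB"), 2),
                   resid = rep(c("ALA", "LEU"), each = 5),
                   chain = "A", resno = rep(1:2, each = 5),
                   x = seq(0, 9) * 1.3, y = seq(0, 9) * 0.7, z = 0.5)
  p <- write_toy_pdb(df, tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_s3_class(s, "structure_model")
  expect_equal(nrow(s$atom), 10)
  expect_false(any(s$atom$hetero))

  p3 <- write_toy_pdb(df, tempfile(fileext = ".pdb"),
                      models = list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)))
  tr <- read_structure(p3, model_policy = "all")
  expect_s3_class(tr, "trajectory_frames")
  expect_equal(n_frames(tr), 3)
  expect_equal(nrow(tr$atom), 10)
  # frame offsets survive
  expect_equal(get_frame(tr, 2)$atom$x, df$x + 1, tolerance = 1e-6)
  expect_equal(get_frame(tr, 3)$atom$y, df$y + 2, tolerance = 1e-6)
})

test_that("alt-locs resolve to the highest-occupancy conformer, ties alphabetical", {
  base <- data.frame(elety = c("N", "N", "CA", "C"),
                     resid = "ALA", chain = "A", resno = 1L,
                     x = c(1.0, 2.0, 3.0, 4.0), y = 0, z = c(0, 0, 1, 2),
                     o = c(0.6, 0.4, 1, 1), alt = c("A", "B", " ", " "))
  p <- write_toy_pdb(base, tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_equal(nrow(s$atom), 3)
  expect_equal(s$atom$x[s$atom$elety == "N"], 1.0)  # conformer A (occ 0.6)

  base$o <- c(0.4, 0.6, 1, 1)
  p <- write_toy_pdb(base, tempfile(fileext = ".pdb"))
  expect_equal(read_structure(p)$atom$x[1], 2.0)    # conformer B wins now

  base$o <- c(0.5, 0.5, 1, 1)
  p <- write_toy_pdb(base, tempfile(fileext = ".pdb"))
  expect_equal(read_structure(p)$atom$x[1], 1.0)    # tie -> alt-loc "A"
})

test_that("malformed and empty PDB inputs raise informative errors", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
               "ATOM      2  CA  ALA A   1      bad.coord   0.0     0.0"),
             p)
  expect_error(read_structure(p), "line 2")

  writeLines(c("HEADER    NOTHING", "END"), tempfile(fileext = ".pdb")) -> ignored
  p2 <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), p2)
  expect_error(read_structure(p2), "no ATOM/HETATM")
})

test_that("parsing tolerates trailing whitespace and infers missing elements", {
  ln <- pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3)
  ln2 <- pdb_atom_line(2, "N", "ALA", "A", 1, 2, 2, 3)
  # blank the element columns (77-78) and append trailing spaces
  strip <- function(l) paste0(substr(l, 1, 76), "     ")
  p <- tempfile(fileext = ".pdb")
  writeLines(c(strip(ln), strip(ln2), "END"), p)
  s <- read_structure(p)
  expect_equal(s$atom$element, c("C", "N"))
})

test_that("structure round-trip preserves roster, coordinates and hetero flags", {
  df <- data.frame(elety = c("N", "CA", "C", "O", "O"),
                   resid = c(rep("GLY", 4), "HOH"),
                   chain = c(rep("A", 4), "W"),
                   resno = c(rep(7L, 4), 101L),
                   x = c(1.234, 2.345, 3.456, 4.567, 9.876),
                   y = c(0.111, 0.222, 0.333, 0.444, 5.555),
                   z = c(-1.1, -2.2, -3.3, -4.4, 0),
                   het = c(rep(FALSE, 4), TRUE))
  s <- read_structure(write_toy_pdb(df, tempfile(fileext = ".pdb")))
  out <- tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(s2$atom$elety, s$atom$elety)
  expect_equal(s2$atom$resno, s$atom$resno)
  expect_equal(s2$atom$hetero, s$atom$hetero)
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)

  tr <- read_structure(write_toy_pdb(df, tempfile(fileext = ".pdb"),
                                     models = list(c(0, 0, 0), c(0.5, 0, 0))),
                       model_policy = "all")
  out2 <- tempfile(fileext = ".pdb")
  write_structure(tr, out2)
  tr2 <- read_structure(out2, model_policy = "all")
  expect_equal(n_frames(tr2), 2)
  expect_equal(tr2$xyz, tr$xyz, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("aligned-FASTA reading enforces shape and labels", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "AC-D", ">r2", "ACED"), p)
  aln <- read_alignment(p)
  expect_s3_class(aln, "alignment_set")
  expect_equal(aln$ncol, 4)
  expect_equal(aln$labels, c("r1", "r2"))

  writeLines(c(">solo", "ACDE"), p)
  expect_error(read_alignment(p), "at least 2")

  writeLines(c(">r1", "ACD", ">r2", "ACDE"), p)
  expect_error(read_alignment(p), "ragged")

  g <- gen_alignment(n_receptors = 8, n_columns = 20, seed = 11)
  p8 <- tempfile(fileext = ".fasta")
  write_alignment(g$alignment, p8)
  rt <- read_alignment(p8)
  expect_equal(length(rt$labels), 8)
  expect_equal(rt$seqs, g$alignment$seqs, ignore_attr = TRUE)
})

test_that("grid round-trips through OpenDX and CNS dialects", {
  set.seed(5)
  vals <- array(stats::runif(2 * 3 * 4, 0, 0.9), dim = c(2, 3, 4))
  g <- density_grid(vals, origin = c(-1, 0.5, 2), spacing = c(0.5, 1, 0.25),
                    probe = "IPA", n_frames = 10)

  dx <- tempfile(fileext = ".dx")
  write_grid(g, dx, "opendx")
  g2 <- read_grid(dx)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_equal(g2$dims, g$dims)
  expect_equal(g2$values, g$values, tolerance = 1e-7)

  cns <- tempfile(fileext = ".cns")
  write_grid(g, cns, "cns")
  g3 <- read_grid(cns)
  expect_equal(g3$origin, g$origin)
  expect_equal(g3$spacing, g$spacing)
  expect_equal(g3$dims, g$dims)
  expect_equal(g3$values, g$values, tolerance = 1e-5)

  ones <- density_grid(array(1, c(2, 2, 2)), c(0, 0, 0), 1)
  dx1 <- tempfile(fileext = ".dx")
  write_grid(ones, dx1)
  expect_equal(read_grid(dx1)$values, ones$values)

  bad <- ones
  bad$values[1, 1, 1] <- NaN
  expect_error(write_grid(bad, tempfile()), "non-finite")
})
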