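# Fixture builders: hand-written PDB text (independent of the package's
# writer) and small toy structures.

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          o = 1, het = FALSE, alt = " ", insert = " ",
                          element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", elety), 1, 1)
  # left-justify short atom names in column 14 (PDB convention)
  name4 <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name4, alt, resid, chain,
          resno, insert, x, y, z, o, 0, element)
}

# df columns: elety, resid, chain, resno, x, y, z + optional o, het, alt,
# insert, element
write_toy_pdb <- function(df, path, models = NULL) {
  fill <- function(col, default) if (col %in% names(df)) df[[col]] else
    rep(default, nrow(df))
  mk_lines <- function(dx, dy, dz) {
    vapply(seq_len(nrow(df)), function(i)
      pdb_atom_line(i, df$elety[i], df$resid[i], df$chain[i], df$resno[i],
                    df$x[i] + dx, df$y[i] + dy, df$z[i] + dz,
                    o = fill("o", 1)[i], het = fill("het", FALSE)[i],
                    alt = fill("alt", " ")[i],
                    insert = fill("insert", " ")[i]),
      character(1))
  }
  if (is.null(models)) {
    writeLines(c(mk_lines(0, 0, 0), "END"), path)
  } else {
    # models: list of c(dx, dy, dz) offsets, one per MODEL
    out <- unlist(lapply(seq_along(models), function(m)
      c(sprintf("MODEL     %4d", m),
        mk_lines(models[[m]][1], models[[m]][2], models[[m]][3]),
        "ENDMDL")))
    writeLines(c(out, "END"), path)
  }
  path
}

# small two-residue protein + one hetero ligand atom at the origin
toy_site_structure <- function() {
  df <- data.frame(
    elety = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O", "C1"),
    resid = c(rep("ALA", 5), rep("GLY", 4), "LIG"),
    chain = c(rep("A", 9), "B"),
    resno = c(rep(1L, 5), rep(2L, 4), 101L),
    x = c(4.9, 5.5, 6.0, 6.5, 5.2, 5.1, 5.8, 6.3, 6.8, 0),
    y = 0, z = 0,
    het = c(rep(FALSE, 9), TRUE))
  p <- tempfile(fileext = ".pdb")
  write_toy_pdb(df, p)
  read_structure(p)
}

# toy peptide with full backbone + one side-chain atom per residue,
# usable for superposition tests (non-collinear)
toy_peptide <- function(n_res = 5, seed = 1) {
  set.seed(seed)
  base <- expand.grid(a = 1:4, r = seq_len(n_res))
  df <- data.frame(
    elety = rep(c("N", "CA", "C", "O"), n_res),
    resid = "ALA", chain = "A",
    resno = rep(seq_len(n_res), each = 4),
    x = base$r * 3.8 + stats::runif(nrow(base), -0.3, 0.3),
    y = rep(c(0, 1.2, 2.1, 3.0), n_res) + stats::runif(nrow(base), -0.3, 0.3),
    z = rep(c(0.5, -0.4, 0.6, -0.2), n_res) + stats::runif(nrow(base), -0.3, 0.3))
  p <- tempfile(fileext = ".pdb")
  write_toy_pdb(df, p)
  read_structure(p)
}

rotate_z_90 <- function() matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(R)
  s$atom$x <- xyz[, 1] + t[1]
  s$atom$y <- xyz[, 2] + t[2]
  s$atom$z <- xyz[, 3] + t[3]
  s
}

jitter_structure <- function(s, sd = 0.3) {
  n <- nrow(s$atom)
  s$atom$x <- s$atom$x + stats::rnorm(n, 0, sd)
  s$atom$y <- s$atom$y + stats::rnorm(n, 0, sd)
  s$atom$z <- s$atom$z + stats::rnorm(n, 0, sd)
  s
}
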