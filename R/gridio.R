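# Volumetric map container and OpenDX / CNS text formats. Values are
# dimensionless multiples of the bulk probe density (1.0 = bulk).

#' Construct a density grid
#'
#' Axis-aligned 3D scalar field. `origin` is the Cartesian position of the
#' lower corner of the first voxel; voxel centers sit at
#' `origin + (index - 0.5) * spacing`.
#'
#' @param values 3D numeric array (nx x ny x nz), non-negative.
#' @param origin length-3 numeric, Angstrom.
#' @param spacing voxel edge length per axis, Angstrom (scalar recycled).
#' @param probe probe label.
#' @param n_frames number of trajectory frames averaged into the grid.
#' @return object of class `density_grid`.
#' @export
density_grid <- function(values, origin, spacing, probe = "", n_frames = 1L) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("grid dims must be >= 1 per axis")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(values < 0, na.rm = TRUE)) stop("density values must be >= 0")
  structure(list(values = values, origin = origin, spacing = spacing,
                 dims = dim(values), probe = probe,
                 n_frames = as.integer(n_frames)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels, spacing %.3g A, max %.3g x bulk\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], max(x$values)))
  invisible(x)
}

voxel_volume <- function(grid) prod(grid$spacing)

#' Cartesian centers of all voxels (or a subset)
#' @param grid a `density_grid`.
#' @param idx optional matrix of 1-based voxel indices (n x 3).
#' @return n x 3 matrix of voxel-center coordinates.
#' @export
voxel_centers <- function(grid, idx = NULL) {
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(seq_len(grid$dims[1]), seq_len(grid$dims[2]),
                                 seq_len(grid$dims[3])))
  }
  sweep(sweep(idx - 0.5, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Write a density grid to OpenDX or CNS format
#'
#' OpenDX round-trips origin, spacing, dims and values exactly. The CNS
#' dialect (readable by PyMOL) quantizes the origin to integer grid units;
#' the exact origin and spacing are carried in a REMARKS line that
#' [read_grid()] prefers.
#'
#' @param grid a `density_grid`.
#' @param path output file.
#' @param dialect `"opendx"` or `"cns"`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, dialect = c("opendx", "cns")) {
  dialect <- match.arg(dialect)
  if (!all(is.finite(grid$values)))
    stop("grid contains non-finite values; refusing to write")
  if (dialect == "opendx") write_grid_dx(grid, path) else write_grid_cns(grid, path)
  invisible(path)
}

write_grid_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# probe %s over %d frames (values in multiples of bulk density)",
            grid$probe, grid$n_frames),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.9g %.9g %.9g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.9g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.9g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.9g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: last axis (z) varies fastest
  v <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))
  pad <- (-length(v)) %% 3L
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  rows <- apply(m, 1L, function(r)
    paste(sprintf("%.9g", r[!is.na(r)]), collapse = " "))
  writeLines(rows, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
}

write_grid_cns <- function(grid, path) {
  d <- grid$dims
  s <- grid$spacing
  amin <- round(grid$origin / s)
  cell <- d * s
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "       2 !NTITLE",
    sprintf(" REMARKS ALLOSITE ORIGIN %.9g %.9g %.9g SPACING %.9g %.9g %.9g",
            grid$origin[1], grid$origin[2], grid$origin[3], s[1], s[2], s[3]),
    sprintf(" REMARKS probe %s frames %d", grid$probe, grid$n_frames),
    sprintf("%8d%8d%8d%8d%8d%8d%8d%8d%8d",
            d[1], amin[1], amin[1] + d[1] - 1L,
            d[2], amin[2], amin[2] + d[2] - 1L,
            d[3], amin[3], amin[3] + d[3] - 1L),
    sprintf("%12.5E%12.5E%12.5E%12.5E%12.5E%12.5E",
            cell[1], cell[2], cell[3], 90, 90, 90),
    "ZYX"), con)
  nsec <- d[1] * d[2]
  for (k in seq_len(d[3])) {
    writeLines(sprintf("%8d", k - 1L), con)
    v <- as.vector(grid$values[, , k])   # x fastest within a section
    pad <- (-nsec) %% 6L
    if (pad) v <- c(v, rep(NA_real_, pad))
    m <- matrix(v, ncol = 6L, byrow = TRUE)
    rows <- apply(m, 1L, function(r)
      paste(sprintf("%12.5E", r[!is.na(r)]), collapse = ""))
    writeLines(rows, con)
  }
  writeLines(c(sprintf("%8d", -9999L),
               sprintf("%12.4E %12.4E", mean(grid$values),
                       stats::sd(as.vector(grid$values)))), con)
}

#' Read a density grid written by [write_grid()]
#'
#' @param path OpenDX or CNS map file; the dialect is auto-detected.
#' @return a `density_grid`.
#' @export
read_grid <- function(path) {
  head <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("gridpositions", head))) read_grid_dx(path) else read_grid_cns(path)
}

read_grid_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  counts_line <- grep("object 1 class gridpositions counts", lines,
                      fixed = TRUE, value = TRUE)[1L]
  d <- as.integer(strsplit(trimws(sub(".*counts", "", counts_line)),
                           "\\s+")[[1L]])
  origin <- as.numeric(strsplit(trimws(sub("^origin", "",
    grep("^origin", lines, value = TRUE)[1L])), "\\s+")[[1L]])
  deltas <- grep("^delta", lines, value = TRUE)
  dm <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1L]]),
    numeric(3L)))
  spacing <- diag(dm)
  start <- grep("data follows", lines)[1L] + 1L
  end <- grep('attribute "dep"', lines, fixed = TRUE)[1L] - 1L
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  stopifnot(length(v) == prod(d))
  vals <- aperm(array(v, dim = rev(d)), c(3L, 2L, 1L))
  density_grid(vals, origin, spacing)
}

read_grid_cns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  zyx <- grep("^ZYX", lines)[1L]
  hdr <- as.integer(substring(lines[zyx - 2L],
                              seq(1L, 65L, by = 8L), seq(8L, 72L, by = 8L)))
  d <- hdr[c(1L, 4L, 7L)]
  amin <- hdr[c(2L, 5L, 8L)]
  cell <- as.numeric(substring(lines[zyx - 1L],
                               seq(1L, 29L, by = 12L), seq(12L, 40L, by = 12L)))[1:3]
  spacing <- cell / d
  origin <- amin * spacing
  rem <- grep("REMARKS ALLOSITE ORIGIN", lines, value = TRUE)
  if (length(rem)) {
    tok <- as.numeric(strsplit(trimws(sub(".*ORIGIN", "", gsub("SPACING", "",
      rem[1L]))), "\\s+")[[1L]])
    origin <- tok[1:3]
    spacing <- tok[4:6]
  }
  vals <- array(0, dim = d)
  nsec <- d[1L] * d[2L]
  rows_per_sec <- ceiling(nsec / 6L)
  i <- zyx + 1L
  for (k in seq_len(d[3L])) {
    i <- i + 1L  # section-number line
    block <- lines[i:(i + rows_per_sec - 1L)]
    v <- as.numeric(unlist(lapply(block, function(l)
      substring(l, seq(1L, nchar(l), by = 12L),
                pmin(seq(12L, nchar(l) + 11L, by = 12L), nchar(l))))))
    v <- v[!is.na(v)]
    vals[, , k] <- v[seq_len(nsec)]
    i <- i + rows_per_sec
  }
  density_grid(vals, origin, spacing)
}
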