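# Gaussian cube volumetric densities: reader, a small writer (used to build
# test volumes), and a trilinear-interpolation density field.

#' Read a Gaussian cube file
#'
#' Standard layout: two comment lines; `natoms origin_x origin_y origin_z`;
#' three axis lines `n vx vy vz`; `natoms` atom lines `Z charge x y z`; then
#' the voxel values with z fastest. A negative atom count (the convention
#' signalling a DSET id line after the atom block) is handled and noted.
#' All lengths are bohr. Tiny negative voxel values (>= -1e-8) are clamped
#' to zero and counted.
#'
#' @param path File path.
#' @return An object of class `cube_density`: `origin`, `axes` (3 x 3, rows
#'   are voxel step vectors), `counts`, `values` (array nx x ny x nz),
#'   `atomic_numbers`, `positions`, `clamped` (count of clamped voxels),
#'   `voxel_integral` (sum of voxels times the voxel volume, a sanity
#'   number).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("truncated cube file ", path)
  toks <- function(i) as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
  hdr <- toks(3L)
  natoms <- as.integer(hdr[1])
  extra_dset <- natoms < 0L
  natoms <- abs(natoms)
  origin <- hdr[2:4]
  axes <- matrix(0, 3L, 3L)
  counts <- integer(3L)
  for (i in 1:3) {
    a <- toks(3L + i)
    counts[i] <- as.integer(a[1])
    axes[i, ] <- a[2:4]
  }
  if (any(counts < 1L)) stop("cube axis counts must be >= 1")
  if (det(axes) <= 0) stop("cube axes must span a right-handed volume")
  atom_rows <- lapply(seq_len(natoms), function(i) toks(6L + i))
  z <- vapply(atom_rows, function(r) as.integer(r[1]), integer(1))
  pos <- t(vapply(atom_rows, function(r) r[3:5], numeric(3)))
  first_val <- 7L + natoms + if (extra_dset) 1L else 0L
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[seq(first_val, length(lines))]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  nval <- prod(counts)
  if (length(vals) < nval) {
    stop("cube parse error: value block truncated (", length(vals), " of ",
         nval, " values)")
  }
  vals <- vals[seq_len(nval)]
  if (any(vals < -1e-8)) {
    stop("cube contains significantly negative densities (min ",
         signif(min(vals), 3), ")")
  }
  clamped <- sum(vals < 0)
  vals[vals < 0] <- 0
  # file order: x slowest, z fastest -> array indexed [ix, iy, iz]
  arr <- aperm(array(vals, dim = rev(counts)), c(3L, 2L, 1L))
  structure(
    list(origin = origin, axes = axes, counts = counts, values = arr,
         atomic_numbers = z, positions = pos, clamped = clamped,
         extra_dset = extra_dset,
         voxel_integral = sum(vals) * det(axes)),
    class = "cube_density"
  )
}

#' Write a Gaussian cube file
#'
#' Mainly a fixture builder for tests and round-trip checks.
#'
#' @param path Output path.
#' @param origin Length-3 origin, bohr.
#' @param axes 3 x 3 matrix of voxel step vectors (rows), bohr.
#' @param values Array nx x ny x nz of densities.
#' @param atomic_numbers,positions Atom records (positions in bohr).
#' @export
write_cube <- function(path, origin, axes, values, atomic_numbers, positions) {
  counts <- dim(values)
  positions <- as_point_matrix(positions)
  out <- c(
    "cube written by shpart",
    "electron density, all lengths in bohr",
    sprintf("%5d %12.6f %12.6f %12.6f", length(atomic_numbers),
            origin[1], origin[2], origin[3]),
    vapply(1:3, function(i) sprintf("%5d %12.6f %12.6f %12.6f", counts[i],
                                    axes[i, 1], axes[i, 2], axes[i, 3]),
           character(1)),
    vapply(seq_along(atomic_numbers), function(a) {
      sprintf("%5d %12.6f %12.6f %12.6f %12.6f", atomic_numbers[a],
              as.numeric(atomic_numbers[a]),
              positions[a, 1], positions[a, 2], positions[a, 3])
    }, character(1))
  )
  flat <- as.vector(aperm(values, c(3L, 2L, 1L)))  # z fastest
  rows <- split(flat, ceiling(seq_along(flat) / 6))
  # 17 significant digits so values survive the round trip bit for bit
  out <- c(out, vapply(rows, function(r) paste(sprintf("%.16e", r),
                                               collapse = " "), character(1)))
  writeLines(out, path)
  invisible(path)
}

#' @export
print.cube_density <- function(x, ...) {
  cat(sprintf(
    "<cube density: %d x %d x %d voxels, %d atom(s), voxel integral %.6g e%s>\n",
    x$counts[1], x$counts[2], x$counts[3], length(x$atomic_numbers),
    x$voxel_integral,
    if (x$clamped > 0) sprintf(", %d voxel(s) clamped to 0", x$clamped) else ""))
  invisible(x)
}

#' @export
eval_density.cube_density <- function(field, points) {
  points <- as_point_matrix(points)
  # fractional voxel coordinates: point = origin + t(axes) %*% frac
  rel <- sweep(points, 2L, field$origin)
  frac <- rel %*% solve(field$axes)  # axes rows are step vectors
  nx <- field$counts[1]; ny <- field$counts[2]; nz <- field$counts[3]
  i0 <- floor(frac[, 1]); j0 <- floor(frac[, 2]); k0 <- floor(frac[, 3])
  fx <- frac[, 1] - i0; fy <- frac[, 2] - j0; fz <- frac[, 3] - k0
  inside <- i0 >= 0 & i0 <= nx - 2 & j0 >= 0 & j0 <= ny - 2 &
    k0 >= 0 & k0 <= nz - 2
  out <- numeric(nrow(points))
  if (!any(inside)) return(out)
  i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  v <- field$values
  idx <- function(di, dj, dk) {
    v[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  }
  out[inside] <-
    idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    idx(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    idx(1, 1, 0) * fx * fy * (1 - fz) +
    idx(1, 0, 1) * fx * (1 - fy) * fz +
    idx(0, 1, 1) * (1 - fx) * fy * fz +
    idx(1, 1, 1) * fx * fy * fz
  out
}
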