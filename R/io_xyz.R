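# XYZ / extended-XYZ I/O. Coordinates are angstrom in files (the XYZ
# convention) and bohr everywhere inside the package; the conversion happens
# only here.

#' Read an (extended) XYZ geometry
#'
#' Parses a standard XYZ file: atom count, comment line, then one
#' `symbol x y z [extra columns...]` row per atom with coordinates in
#' angstrom. If the comment line carries an extended-XYZ
#' `Properties=species:S:1:pos:R:3:...` declaration, the trailing per-atom
#' columns are named accordingly and returned in `extra`.
#'
#' @param path File path.
#' @return List with `elements`, `atomic_numbers`, `positions` (bohr),
#'   `positions_angstrom`, `comment`, and `extra` (data frame of trailing
#'   columns, or `NULL`).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ header in ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("malformed XYZ header (line 1) in ", path)
  if (length(lines) < 2L + n) {
    stop("XYZ parse error: header declares ", n, " atoms but only ",
         max(0L, length(lines) - 2L), " rows follow (line ", length(lines) + 1L,
         ")")
  }
  comment <- lines[2]
  rows <- strsplit(trimws(lines[seq(3L, 2L + n)]), "\\s+")
  bad <- which(lengths(rows) < 4L)
  if (length(bad)) {
    stop("XYZ parse error: too few fields on line ", bad[1] + 2L)
  }
  symbols <- vapply(rows, `[`, character(1), 1L)
  z <- atomic_number(symbols)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(coords) || !all(is.finite(coords))) {
    stop("XYZ parse error: non-numeric coordinates in ", path)
  }
  n_extra <- min(lengths(rows)) - 4L
  extra <- NULL
  if (n_extra > 0L) {
    ex <- vapply(rows, function(r) {
      as.numeric(r[seq(5L, 4L + n_extra)])
    }, numeric(n_extra))
    ex <- if (n_extra == 1L) matrix(ex, ncol = 1L) else t(ex)
    extra <- as.data.frame(ex)
    names(extra) <- .extra_column_names(comment, n_extra)
  }
  list(elements = element_symbol(z), atomic_numbers = z,
       positions = coords * ANGSTROM_TO_BOHR,
       positions_angstrom = coords,
       comment = comment, extra = extra)
}

.extra_column_names <- function(comment, n_extra) {
  m <- regmatches(comment, regexpr("Properties=[^ ]+", comment))
  if (length(m)) {
    fields <- strsplit(sub("Properties=", "", m), ":")[[1]]
    if (length(fields) %% 3L == 0L) {
      names <- fields[seq(1L, length(fields), 3L)]
      counts <- as.integer(fields[seq(3L, length(fields), 3L)])
      cols <- character(0)
      for (i in seq_along(names)) {
        cols <- c(cols, if (counts[i] == 1L) names[i] else
          paste0(names[i], "_", seq_len(counts[i])))
      }
      cols <- cols[-seq_len(4L)]  # drop species + pos
      if (length(cols) >= n_extra) return(cols[seq_len(n_extra)])
    }
  }
  paste0("col", seq_len(n_extra) + 4L)
}

#' Write an extended XYZ file with per-atom charge columns
#'
#' Emits the `Properties=species:S:1:pos:R:3:...` dialect with one real
#' column per named charge scheme (e.g. `q_h`, `q_sh`), coordinates in
#' angstrom.
#'
#' @param path Output path.
#' @param elements Element symbols or atomic numbers.
#' @param positions m x 3 positions, bohr.
#' @param charges Named list of numeric vectors (one value per atom), or
#'   `NULL` for a plain XYZ.
#' @param comment Extra text appended to the properties line.
#' @export
write_extended_xyz <- function(path, elements, positions, charges = NULL,
                               comment = "") {
  z <- if (is.character(elements)) atomic_number(elements) else as.integer(elements)
  positions <- as_point_matrix(positions)
  ang <- positions * BOHR_TO_ANGSTROM
  n <- length(z)
  props <- "Properties=species:S:1:pos:R:3"
  if (!is.null(charges)) {
    stopifnot(is.list(charges), !is.null(names(charges)))
    for (nm in names(charges)) {
      if (length(charges[[nm]]) != n) stop("charge column ", nm, " length mismatch")
      props <- paste0(props, ":", nm, ":R:1")
    }
  }
  header <- paste(props, comment)
  rows <- vapply(seq_len(n), function(i) {
    extra <- if (is.null(charges)) "" else
      paste0(" ", paste(sprintf("%.10f", vapply(charges, `[`, numeric(1), i)),
                        collapse = " "))
    sprintf("%-2s %15.10f %15.10f %15.10f%s",
            element_symbol(z[i]), ang[i, 1], ang[i, 2], ang[i, 3], extra)
  }, character(1))
  writeLines(c(as.character(n), trimws(header, which = "right"), rows), path)
  invisible(path)
}
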