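#' Molecular snapshot container
#'
#' Lightweight carrier for the structural analyses: a set of atoms (name,
#' residue id/name, Cartesian position in nm) plus an orthorhombic box.
#'
#' @param atoms data frame with columns `residue_id` (integer),
#'   `residue_name`, `name` (character) and `x`, `y`, `z` (nm).
#' @param box box lengths, nm (length-3, all > 0).
#' @param title snapshot title.
#' @return Object of class `snapshot`.
#' @export
snapshot <- function(atoms, box, title = "snapshot") {
  req <- c("residue_id", "residue_name", "name", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop("'atoms' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!is.numeric(box) || length(box) != 3L || any(!is.finite(box)) ||
      any(box <= 0))
    stop("'box' must be three positive lengths (nm)", call. = FALSE)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(pos)))
    stop("all atom coordinates must be finite", call. = FALSE)
  structure(list(atoms = atoms, box = as.numeric(box),
                 title = as.character(title)[1]),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("Snapshot '%s': %d atoms, box %.3f x %.3f x %.3f nm\n",
              x$title, nrow(x$atoms), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Read a GRO coordinate file
#'
#' Parses the fixed-column GROMACS GRO layout: title line, atom count,
#' one record per atom (residue number, residue name, atom name, atom
#' number, x/y/z in nm with 3 decimals), and the box vector on the last
#' line. Velocity columns, if present, are ignored.
#'
#' @param path file path.
#' @return A [snapshot()].
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("truncated GRO file: fewer than 3 lines in ", path, call. = FALSE)
  title <- lines[1]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0L)
    stop("malformed atom count on line 2 of ", path, call. = FALSE)
  if (length(lines) < 2L + n + 1L)
    stop(sprintf("truncated GRO file: declared %d atoms but only %d lines",
                 n, length(lines)), call. = FALSE)
  recs <- lines[seq_len(n) + 2L]
  parse_field <- function(s, from, to) substr(s, from, to)
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (any(is.na(v)))
      stop(sprintf("malformed %s on line %d", what,
                   ln[which(is.na(v))[1]]), call. = FALSE)
    v
  }
  ln <- seq_len(n) + 2L
  residue_id <- as.integer(num(parse_field(recs, 1, 5), "residue number", ln))
  residue_name <- trimws(parse_field(recs, 6, 10))
  name <- trimws(parse_field(recs, 11, 15))
  x <- num(parse_field(recs, 21, 28), "x coordinate", ln)
  y <- num(parse_field(recs, 29, 36), "y coordinate", ln)
  z <- num(parse_field(recs, 37, 44), "z coordinate", ln)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3L]),
                                              "\\s+")[[1]]))
  if (length(box) < 3L || any(is.na(box[1:3])))
    stop("malformed box line in ", path, call. = FALSE)
  snapshot(data.frame(residue_id = residue_id, residue_name = residue_name,
                      name = name, x = x, y = y, z = z,
                      stringsAsFactors = FALSE),
           box[1:3], title = title)
}

#' Write a GRO coordinate file
#'
#' @param snap a [snapshot()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(snap, path) {
  stopifnot(inherits(snap, "snapshot"))
  a <- snap$atoms
  n <- nrow(a)
  recs <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  a$residue_id %% 100000L,
                  substr(a$residue_name, 1, 5), substr(a$name, 1, 5),
                  seq_len(n) %% 100000L, a$x, a$y, a$z)
  writeLines(c(snap$title, sprintf("%5d", n), recs,
               sprintf("%10.5f%10.5f%10.5f", snap$box[1], snap$box[2],
                       snap$box[3])),
             path)
  invisible(path)
}
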