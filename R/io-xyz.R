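#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then one `element x y z`
#' line per atom, repeated per frame. A comment containing `t=<ps>` sets the
#' frame time; otherwise times default to the frame index in ps.
#'
#' @param path Path to an XYZ file.
#' @return A [trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  i <- 1
  frame_no <- 0
  n_ref <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    if (i + 1 + n > length(lines))
      stop(sprintf("line %d: truncated frame (%d atom lines expected)", i, n))
    comment <- lines[i + 1]
    frame_no <- frame_no + 1
    tm <- regmatches(comment, regexec("t=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else frame_no - 1)
    el <- character(n)
    xyz <- matrix(NA_real_, n, 3)
    for (a in seq_len(n)) {
      ln <- i + 1 + a
      parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(parts) < 4)
        stop(sprintf("line %d: malformed atom line '%s'", ln, lines[ln]))
      el[a] <- parts[1]
      v <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(v)))
        stop(sprintf("line %d: non-numeric coordinates '%s'", ln, lines[ln]))
      xyz[a, ] <- v
    }
    if (is.null(n_ref)) n_ref <- n
    else if (n != n_ref)
      stop(sprintf("line %d: frame has %d atoms but previous frames have %d",
                   i, n, n_ref))
    frames[[frame_no]] <- configuration(xyz, elements = el, names = el)
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames found in XYZ file")
  trajectory(frames, times)
}

#' Write a trajectory (or single configuration) as multi-frame XYZ
#'
#' Coordinates are written with 6 decimals; the comment line carries
#' `t=<ps>` so that [read_xyz()] round-trips frame times.
#'
#' @param x A [trajectory()] or [configuration()].
#' @param path Output file path.
#' @param digits Decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, digits = 6) {
  if (inherits(x, "configuration")) x <- trajectory(list(x), times = 0)
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$frames)) {
    f <- x$frames[[i]]
    writeLines(as.character(nrow(f$coords)), con)
    writeLines(sprintf("t=%g", x$times[i]), con)
    writeLines(sprintf(fmt, f$elements, f$coords[, 1], f$coords[, 2],
                       f$coords[, 3]), con)
  }
  invisible(path)
}
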