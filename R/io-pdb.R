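#' Read a minimal PDB subset
#'
#' Parses ATOM/HETATM records (PDB v3.3 fixed columns: name, resName, chain,
#' resSeq, x, y, z, element). Everything else (CONECT, occupancy, altLoc,
#' MODEL semantics, insertion codes) is ignored. Groups are auto-populated:
#' one group per residue name, `backbone_ref` for CA atoms, and `water_O`
#' for water oxygens (residue HOH/WAT/SOL/TIP and element O, or atom name
#' OW).
#'
#' @param path Path to a PDB file.
#' @return A [configuration()] with `resid`/`resname` columns attached as
#'   fields.
#' @export
read_pdb_minimal <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no ATOM/HETATM records: empty structure")
  sub <- lines[keep]
  num <- function(s, lo, hi, what, ln) {
    v <- suppressWarnings(as.numeric(trimws(substr(s, lo, hi))))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("line %d: non-numeric %s field '%s'", ln[bad[1]], what,
                   trimws(substr(s[bad[1]], lo, hi))))
    v
  }
  name <- trimws(substr(sub, 13, 16))
  resname <- trimws(substr(sub, 18, 20))
  resseq <- suppressWarnings(as.integer(trimws(substr(sub, 23, 26))))
  x <- num(sub, 31, 38, "x", keep)
  y <- num(sub, 39, 46, "y", keep)
  z <- num(sub, 47, 54, "z", keep)
  element <- trimws(substr(sub, 77, 78))
  guess <- toupper(substr(name, 1, 1))
  element <- ifelse(nzchar(element), element, guess)

  groups <- lapply(split(seq_along(keep), resname), as.integer)
  ca <- which(name == "CA")
  if (length(ca)) groups$backbone_ref <- as.integer(ca)
  wat <- which((resname %in% c("HOH", "WAT", "SOL", "TIP", "TIP3") &
                  toupper(element) == "O") | name == "OW")
  if (length(wat)) groups$water_O <- as.integer(wat)

  conf <- configuration(cbind(x, y, z), elements = element, names = name,
                        groups = groups)
  conf$resname <- resname
  conf$resid <- resseq
  conf
}

#' Write a configuration as a minimal PDB file
#'
#' @param conf A [configuration()]; `resname`/`resid` fields are used when
#'   present, else every atom goes into residue `MOL 1`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_minimal <- function(conf, path) {
  n <- n_atoms(conf)
  resname <- if (is.null(conf$resname)) rep("MOL", n) else conf$resname
  resid <- if (is.null(conf$resid)) rep(1L, n) else conf$resid
  lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   seq_len(n), substr(conf$names, 1, 4),
                   substr(resname, 1, 3), resid,
                   conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
                   substr(conf$elements, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
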