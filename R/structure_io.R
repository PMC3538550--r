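# PDB export of all-atom models and import of coarse-grained point inputs.

# fixed-column PDB v3 ATOM line. Atom names of <= 3 characters start in
# column 14 per convention (none of the nucleotide names here use 4).
.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           occ = 1, bfac = 0, element = "") {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, occ, bfac, element)
}

.pdb_ter_line <- function(serial, resname, chain, resno) {
  sprintf("TER   %5d      %3s %s%4d", serial, resname, chain, resno)
}

# serial/residue counters wrap to stay inside their fixed-width columns
.wrap_serial <- function(i) ((i - 1L) %% 99999L) + 1L
.wrap_resno <- function(i) ((i - 1L) %% 9999L) + 1L

#' Export a DNA model as a PDB file
#'
#' Strand I is written as chain A in 5'-to-3' order (residues 1..N, following
#' the base-pair index), strand II as chain B in its own 5'-to-3' order
#' (reverse base-pair index, residues 1..N), with a TER record closing each
#' chain. Base pairs are instantiated lazily while writing, so arbitrarily
#' long strands export in bounded memory. Atom serials above 99999 (and
#' residue numbers above 9999) wrap around with a warning, preserving the
#' fixed-column format.
#'
#' @param model a `dna_model`.
#' @param file output path or connection.
#' @param chunk_bp base pairs instantiated per write (memory/speed knob).
#' @return `file`, invisibly.
#' @export
export_pdb <- function(model, file, chunk_bp = 2000L) {
  stopifnot(inherits(model, "dna_model"))
  tpl <- bp_templates()
  N <- model$n_bp
  per_pair <- vapply(tpl, nrow, 0L)
  total_atoms <- sum(per_pair[model$pairs])
  if (total_atoms > 99999L) {
    warning("model has ", total_atoms, " atoms; PDB serials wrap modulo 100000")
  }
  if (N > 9999L) warning("model has ", N, " residues per chain; residue numbers wrap modulo 10000")
  con <- if (inherits(file, "connection")) file else {
    fc <- base::file(file, open = "wt")
    on.exit(close(fc), add = TRUE)
    fc
  }
  serial <- 0L
  write_chain <- function(strand, chain, bp_order) {
    resno <- 0L
    last <- NULL
    for (start in seq(1L, length(bp_order), by = chunk_bp)) {
      idx <- bp_order[start:min(start + chunk_bp - 1L, length(bp_order))]
      lines <- character(0)
      for (i in idx) {
        at <- instantiate_base_pair(tpl[[model$pairs[i]]],
                                    frame_at(model$frames, i),
                                    model$schedule$angles[i])
        at <- at[at$strand == strand, , drop = FALSE]
        resno <- resno + 1L
        sers <- .wrap_serial(serial + seq_len(nrow(at)))
        serial <<- serial + nrow(at)
        lines <- c(lines, .pdb_atom_line(sers, at$name, at$resname[1], chain,
                                         .wrap_resno(resno), at$x, at$y, at$z,
                                         element = at$element))
        last <- list(resname = at$resname[1], resno = .wrap_resno(resno))
      }
      writeLines(lines, con)
    }
    serial <<- serial + 1L
    writeLines(.pdb_ter_line(.wrap_serial(serial), last$resname, chain, last$resno), con)
  }
  write_chain(1L, "A", seq_len(N))
  write_chain(2L, "B", rev(seq_len(N)))
  writeLines("END", con)
  invisible(file)
}

#' Read ATOM/HETATM records from a PDB file
#'
#' Minimal fixed-column reader used for round-trip checks and re-export; only
#' the fields this package writes are interpreted.
#'
#' @param file path to a PDB file.
#' @return data frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `occ`, `bfac`, `element`.
#' @export
read_pdb_atoms <- function(file) {
  if (!file.exists(file)) stop_input("PDB file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  sel <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  if (!length(sel)) stop_input("no ATOM/HETATM records in ", file)
  ln <- lines[sel]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (anyNA(v)) stop_input("malformed ", what, " field in ", file,
                             " at line ", sel[which(is.na(v))[1]])
    v
  }
  data.frame(serial = as.integer(num(7, 11, "serial")),
             name = trimws(substr(ln, 13, 16)),
             resname = trimws(substr(ln, 18, 20)),
             chain = substr(ln, 22, 22),
             resno = as.integer(num(23, 26, "residue number")),
             x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
             occ = num(55, 60, "occupancy"), bfac = num(61, 66, "B-factor"),
             element = trimws(substr(ln, 77, 78)),
             stringsAsFactors = FALSE)
}

#' Re-write parsed atom records as a PDB file
#'
#' Formatting a table read back by [read_pdb_atoms()] reproduces the original
#' ATOM records byte for byte (TER/END records are re-derived per chain).
#'
#' @param atoms a data frame as returned by [read_pdb_atoms()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, file) {
  lines <- .pdb_atom_line(atoms$serial, atoms$name, atoms$resname, atoms$chain,
                          atoms$resno, atoms$x, atoms$y, atoms$z,
                          atoms$occ, atoms$bfac, atoms$element)
  # TER after each chain
  out <- character(0)
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch
    i_last <- max(which(sel))
    out <- c(out, lines[sel],
             .pdb_ter_line(.wrap_serial(atoms$serial[i_last] + 1L),
                           atoms$resname[i_last], ch, atoms$resno[i_last]))
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}

#' Import a coarse-grained point sequence
#'
#' Reads one 3D point per bead, in file order: either whitespace-delimited
#' xyz text (three numbers per line; blank lines and `#` comments ignored)
#' or the coordinate fields of PDB ATOM/HETATM records (chain order
#' preserved). The resulting points are typically handed to
#' [interpolate_points()] to obtain a smooth helical axis.
#'
#' @param file input path.
#' @param format `"auto"` (detect ATOM/HETATM records), `"xyz"` or `"pdb"`.
#' @return an n x 3 matrix of points.
#' @export
import_points <- function(file, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(file)) stop_input("points file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  if (format == "auto") {
    format <- if (any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))) "pdb" else "xyz"
  }
  if (format == "pdb") {
    at <- read_pdb_atoms(file)
    return(unname(cbind(at$x, at$y, at$z)))
  }
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop_input("no points in ", file)
  pts <- matrix(0, length(keep), 3)
  for (j in seq_along(keep)) {
    toks <- strsplit(trimws(lines[keep[j]]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (length(v) != 3L || anyNA(v)) {
      stop_input("malformed xyz line ", keep[j], " in ", file, ": expected 3 numbers")
    }
    pts[j, ] <- v
  }
  pts
}
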