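#' Physical constants and unit conventions
#'
#' All quantities in the package use a single unit system: lengths in
#' angstrom (A), energies in kcal/mol, times in ps, charges in units of the
#' elementary charge e, temperatures in K.  The two constants below are
#' frozen literals so that results are reproducible bit-for-bit.
#'
#' * `kB` — Boltzmann constant, 1.9872041e-3 kcal/(mol K).
#' * `coulomb_k` — Coulomb prefactor, 332.0636 kcal A/(mol e^2), so that the
#'   potential of a point charge q at distance r in a uniform dielectric
#'   `eps` is `coulomb_k * q / (eps * r)` kcal/(mol e).
#'
#' The Z axis convention is +Z = extracellular side; Z = 0 is the position
#' of the reference bead (the analogue of the T381 C-alpha used to define
#' the permeation reaction coordinate).
#'
#' @return `groove_constants()` returns a list with elements `kB`,
#'   `coulomb_k` and `temperature` (the package default, 310 K).
#' @export
groove_constants <- function() {
  list(kB = 1.9872041e-3, coulomb_k = 332.0636, temperature = 310)
}

.KB <- 1.9872041e-3
.COULOMB_K <- 332.0636
.DEFAULT_TEMP <- 310

#' Thermal energy kT
#'
#' @param temperature temperature in K (default 310, the simulation
#'   temperature used throughout).
#' @return kB * T in kcal/mol.
#' @examples
#' kT(310) # 0.616 kcal/mol
#' @export
kT <- function(temperature = .DEFAULT_TEMP) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive finite number (K)",
         call. = FALSE)
  }
  .KB * temperature
}

#' Reaction coordinate of a permeating ion
#'
#' The reaction coordinate is the signed Z distance between the ion and the
#' reference bead: `value = ion_z - ref_z`, positive on the extracellular
#' side of the reference.
#'
#' @param ion_z Z coordinate of the ion, A.
#' @param ref_z Z coordinate of the reference bead, A.
#' @return object of class `reaction_coordinate`: list with `ion_z`,
#'   `ref_z`, `value` (A).
#' @export
reaction_coordinate <- function(ion_z, ref_z) {
  stopifnot(is.numeric(ion_z), is.numeric(ref_z), length(ion_z) == length(ref_z))
  structure(list(ion_z = ion_z, ref_z = ref_z, value = ion_z - ref_z),
            class = "reaction_coordinate")
}

#' Construct a bead
#'
#' Beads are the coarse structural unit of the synthetic system: the
#' permeating ion, the fixed reference bead that defines Z = 0, named
#' interaction partners (gate residue, in-groove lipid headgroup), and
#' scaffold beads lining the groove.
#'
#' @param id bead label (character).
#' @param kind one of `"ion"`, `"reference"`, `"partner"`, `"scaffold"`.
#' @param x,y,z coordinates, A.
#' @param radius bead radius, A (>= 0).
#' @param charge bead charge, e.
#' @return one-row data frame with columns id, kind, x, y, z, radius, charge.
#' @export
bead <- function(id, kind, x, y, z, radius = 0, charge = 0) {
  kind <- match.arg(kind, c("ion", "reference", "partner", "scaffold"))
  if (!is.numeric(radius) || radius < 0) {
    stop("bead radius must be >= 0", call. = FALSE)
  }
  data.frame(id = as.character(id), kind = kind,
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             radius = as.numeric(radius), charge = as.numeric(charge),
             stringsAsFactors = FALSE)
}

#' Construct a trajectory frame
#'
#' A frame holds a time stamp and a bead table containing exactly one ion
#' and one reference bead; the reaction coordinate is derived from their Z
#' positions.
#'
#' @param time time stamp, ps.
#' @param beads data frame of beads as produced by [bead()] (rows may be
#'   concatenated with `rbind`).
#' @return object of class `md_frame`: list with `time`, `beads`, `rc`
#'   (a [reaction_coordinate()]).
#' @export
md_frame <- function(time, beads) {
  stopifnot(is.data.frame(beads),
            all(c("id", "kind", "x", "y", "z", "radius", "charge") %in% names(beads)))
  n_ion <- sum(beads$kind == "ion")
  n_ref <- sum(beads$kind == "reference")
  if (n_ion != 1L || n_ref != 1L) {
    stop(sprintf("a frame needs exactly one ion and one reference bead (got %d / %d)",
                 n_ion, n_ref), call. = FALSE)
  }
  rc <- reaction_coordinate(beads$z[beads$kind == "ion"],
                            beads$z[beads$kind == "reference"])
  structure(list(time = as.numeric(time), beads = beads, rc = rc),
            class = "md_frame")
}

## ---- PDB-style bead serialization -------------------------------------
## Frames are written as HETATM records, one MODEL per frame; the occupancy
## column carries the bead radius and the B-factor column the bead charge.
## No pre-installed R package writes arbitrary pseudo-atom PDBs, so the
## fixed-width record is produced here.

.pdb_kind_chain <- c(ion = "I", reference = "R", partner = "P", scaffold = "S")

.format_pdb_atom <- function(serial, name, chain, resseq, x, y, z, occ, bfac) {
  sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, substr(name, 1, 4), "BEA", chain, resseq, x, y, z, occ, bfac)
}

#' Write bead frames to a PDB-format file
#'
#' Each frame becomes one MODEL; bead radius goes in the occupancy column
#' and bead charge in the B-factor column.  A sidecar CSV (same path with
#' `.csv` appended) records per-frame time, ion position and reaction
#' coordinate.  Units: A, ps, e (stated in the file headers).
#'
#' @param frames list of [md_frame()] objects.
#' @param path output PDB path.
#' @param sidecar write the sidecar CSV (default TRUE).
#' @return invisibly, the PDB path.
#' @export
write_bead_pdb <- function(frames, path, sidecar = TRUE) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("REMARK units: length A, time ps, charge e",
               "REMARK occupancy = bead radius (A); B-factor = bead charge (e)"),
             con)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    b <- fr$beads
    rec <- .format_pdb_atom(seq_len(nrow(b)), b$id,
                            .pdb_kind_chain[b$kind], seq_len(nrow(b)),
                            b$x, b$y, b$z, b$radius, b$charge)
    writeLines(rec, con)
    writeLines("ENDMDL", con)
  }
  if (sidecar) {
    side <- data.frame(
      time_ps = vapply(frames, function(f) f$time, numeric(1)),
      ion_x_A = vapply(frames, function(f) f$beads$x[f$beads$kind == "ion"], numeric(1)),
      ion_y_A = vapply(frames, function(f) f$beads$y[f$beads$kind == "ion"], numeric(1)),
      ion_z_A = vapply(frames, function(f) f$beads$z[f$beads$kind == "ion"], numeric(1)),
      rc_A = vapply(frames, function(f) f$rc$value, numeric(1)))
    utils::write.csv(side, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read bead frames written by [write_bead_pdb()]
#'
#' Tolerates files without the REMARK header and without a sidecar CSV; the
#' kind of each bead is recovered from the chain identifier.
#'
#' @param path PDB path.
#' @return list of [md_frame()] objects (times from the sidecar CSV if
#'   present, else 0, 1, 2, ... ps).
#' @export
read_bead_pdb <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_starts) == 0L) {  # single frame, bare records
    model_starts <- 1L
    model_ends <- length(lines)
  }
  kind_of <- stats::setNames(names(.pdb_kind_chain), .pdb_kind_chain)
  times <- seq_along(model_starts) - 1
  side_path <- paste0(path, ".csv")
  if (file.exists(side_path)) {
    side <- utils::read.csv(side_path)
    if ("time_ps" %in% names(side) && nrow(side) == length(model_starts)) {
      times <- side$time_ps
    }
  }
  frames <- vector("list", length(model_starts))
  for (i in seq_along(model_starts)) {
    rec <- lines[model_starts[i]:model_ends[i]]
    rec <- rec[grepl("^(HETATM|ATOM)", rec)]
    beads <- data.frame(
      id = trimws(substr(rec, 13, 16)),
      kind = unname(kind_of[substr(rec, 22, 22)]),
      x = as.numeric(substr(rec, 31, 38)),
      y = as.numeric(substr(rec, 39, 46)),
      z = as.numeric(substr(rec, 47, 54)),
      radius = as.numeric(substr(rec, 55, 60)),
      charge = as.numeric(substr(rec, 61, 66)),
      stringsAsFactors = FALSE)
    frames[[i]] <- md_frame(times[i], beads)
  }
  frames
}
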