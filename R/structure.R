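# Protein structure input: Calpha coordinates from PDB-format ATOM records.
#
# No installed R package parses PDB, so a minimal fixed-column parser for the
# supported dialect (ATOM records, Calpha atoms, no insertion codes) is
# implemented here. Bit-exactness on that dialect beats permissive parsing.

#' Construct a structure model from Calpha coordinates
#'
#' @param coords numeric matrix with 3 columns (x, y, z in Angstrom) and one
#'   row per residue; rownames are residue sequence numbers.
#' @param chain_id chain identifier.
#' @return an object of class `structure_model` with elements `chain_id`,
#'   `residues` (integer vector) and `coords`.
#' @export
structure_model <- function(coords, chain_id = "A") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) pev_stop("coords must have 3 columns (x, y, z)")
  if (is.null(rownames(coords))) {
    pev_stop("coords must have residue numbers as rownames")
  }
  residues <- as.integer(rownames(coords))
  if (anyNA(residues)) pev_stop("residue numbers must be integers")
  if (anyDuplicated(residues)) {
    pev_stop("duplicate residue numbers in structure model")
  }
  if (!all(is.finite(coords))) pev_stop("coordinates must be finite")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  structure(list(chain_id = chain_id,
                 residues = residues,
                 coords = coords),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: chain %s, %d Calpha residues (%d..%d)\n",
              x$chain_id, length(x$residues),
              min(x$residues), max(x$residues)))
  invisible(x)
}

#' Read Calpha coordinates from a PDB-format file
#'
#' Parses ATOM records of one chain and keeps one Calpha per residue, keyed
#' by the residue sequence number. Alternate locations are resolved by first
#' occurrence; HETATM records are ignored; insertion codes are not supported
#' and raise an error.
#'
#' @param path path to a PDB-format text file.
#' @param chain chain identifier to extract (default `"A"`).
#' @return a `structure_model`.
#' @export
read_ca_coordinates <- function(path, chain = "A") {
  if (!file.exists(path)) pev_stop("structure file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) > 0L) {
    atom_name <- trimws(substr(lines, 13L, 16L))
    chain_id <- substr(lines, 22L, 22L)
    lines <- lines[atom_name == "CA" & chain_id == chain]
  }
  if (length(lines) == 0L) {
    pev_stop("no Calpha atoms found for chain '%s' in %s", chain, path)
  }
  icode <- substr(lines, 27L, 27L)
  if (any(icode != " ")) {
    pev_stop("insertion codes are not supported (found '%s')",
             paste(unique(icode[icode != " "]), collapse = "', '"))
  }
  resseq <- as.integer(substr(lines, 23L, 26L))
  # first altloc wins; duplicates of the same residue number are dropped
  keep <- !duplicated(resseq)
  lines <- lines[keep]
  resseq <- resseq[keep]
  coords <- cbind(x = as.numeric(substr(lines, 31L, 38L)),
                  y = as.numeric(substr(lines, 39L, 46L)),
                  z = as.numeric(substr(lines, 47L, 54L)))
  if (anyNA(coords)) pev_stop("malformed coordinate fields in %s", path)
  rownames(coords) <- resseq
  structure_model(coords, chain_id = chain)
}

#' Write a structure model as PDB-format ATOM records
#'
#' Emits one Calpha ATOM record per residue (residue type written as ALA;
#' only the coordinates matter downstream).
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(model$residues), model$chain_id, model$residues,
    model$coords[, 1L], model$coords[, 2L], model$coords[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
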