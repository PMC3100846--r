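# Reading protein structures and bound ligands from PDB files.
#
# Polymer atoms come from ATOM records; ligands are grouped from HETATM
# records by residue (chain, residue number, residue name), waters excluded.
# Each atom carries a van der Waals radius from a fixed element table so
# that downstream surface generation is reproducible.

# vdW radii (Angstroms); unknown elements fall back to 1.7 with a warning.
.vdw_table <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
                SE = 1.9)
.fallback_radius <- 1.7

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

# ligand residue names mapped to the nine benchmark ligand types; the two
# steroids AND and EST share the STR label.
.ligand_type_map <- c(AMP = "AMP", ATP = "ATP", FAD = "FAD", FMN = "FMN",
                      GLC = "GLC", HEM = "HEM", NAD = "NAD", PO4 = "PO4",
                      AND = "STR", EST = "STR")

#' Known ligand type labels
#' @return character vector of the nine ligand classes plus OTHER.
#' @export
ligand_types <- function() {
  c("AMP", "ATP", "FAD", "FMN", "GLC", "HEM", "NAD", "PO4", "STR", "OTHER")
}

.element_radius <- function(elements) {
  key <- toupper(elements)
  r <- unname(.vdw_table[key])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            ": using fallback radius ", .fallback_radius, " A")
    r[unknown] <- .fallback_radius
  }
  r
}

.guess_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # derive from the atom name: strip digits, take the leading letter(s)
    nm <- gsub("[0-9']", "", toupper(trimws(elety[miss])))
    two <- substr(nm, 1, 2)
    el2 <- ifelse(two %in% names(.vdw_table), two, substr(nm, 1, 1))
    el[miss] <- el2
  }
  el
}

.make_atoms <- function(df) {
  el <- .guess_element(df$elesy, df$elety)
  data.frame(
    serial = df$eleno,
    element = el,
    x = df$x, y = df$y, z = df$z,
    radius = .element_radius(el),
    is_hetero = df$type == "HETATM",
    residue_name = trimws(df$resid),
    stringsAsFactors = FALSE
  )
}

#' Read a protein structure and its bound ligands from a PDB file
#'
#' Parses ATOM records into polymer atoms and groups non-water HETATM
#' records into ligand records by residue. Only the first model is used and
#' alternate locations other than 'A' or blank are dropped. Hydrogen-free
#' (heavy-atom) coordinates define each ligand's geometric center.
#'
#' @param path path to a PDB file.
#' @return list with `atoms` (data.frame: serial, element, x, y, z, radius,
#'   is_hetero, residue_name) and `ligands` (list of ligand records, each
#'   with `ligand_type`, `residue_name`, `atoms` data.frame and `center`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  poly <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0) stop("empty structure: no ATOM records in ", path)
  het <- at[at$type == "HETATM" &
              !(trimws(at$resid) %in% .water_resnames), , drop = FALSE]

  atoms <- .make_atoms(poly)
  ligands <- list()
  if (nrow(het) > 0) {
    grp <- paste(het$chain, het$resno, trimws(het$resid), sep = "_")
    for (g in unique(grp)) {
      sub <- .make_atoms(het[grp == g, , drop = FALSE])
      heavy <- sub[sub$element != "H", , drop = FALSE]
      if (nrow(heavy) == 0) next
      resname <- heavy$residue_name[1]
      ltype <- .ligand_type_map[resname]
      if (is.na(ltype)) ltype <- "OTHER"
      ligands[[length(ligands) + 1]] <- list(
        ligand_type = unname(ltype),
        residue_name = resname,
        id = g,
        atoms = heavy,
        center = ligand_center(list(atoms = heavy))
      )
    }
  }
  list(atoms = atoms, ligands = ligands)
}

#' Geometric center of a ligand
#'
#' Arithmetic mean of the heavy-atom coordinates; this point anchors the
#' ray-casting pocket extraction.
#'
#' @param ligand a ligand record (list with an `atoms` data.frame holding
#'   x, y, z), or a bare coordinate matrix.
#' @return numeric length-3 vector (Angstroms).
#' @export
ligand_center <- function(ligand) {
  xyz <- if (is.list(ligand) && !is.null(ligand$atoms)) {
    as.matrix(ligand$atoms[, c("x", "y", "z")])
  } else {
    as.matrix(ligand)
  }
  if (nrow(xyz) == 0) stop("ligand has no atoms")
  colMeans(xyz)
}

#' Coordinate matrix of an atom table
#' @param atoms atom data.frame from [read_structure()].
#' @return n x 3 numeric matrix.
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# Minimal PDB writer used by fixtures and round-trip tests.
.write_pdb_atoms <- function(atoms, path, het = atoms$is_hetero,
                             resname = atoms$residue_name) {
  fmt <- function(rec, serial, name, res, resno, x, y, z, el) {
    sprintf("%-6s%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, res, resno, x, y, z, el)
  }
  n <- nrow(atoms)
  rec <- ifelse(het, "HETATM", "ATOM")
  resno <- ifelse(het, 900L, 1L)
  name <- paste0(atoms$element, seq_len(n) %% 100)
  lines <- vapply(seq_len(n), function(i) {
    fmt(rec[i], atoms$serial[i], name[i], resname[i], resno[i],
        atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
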