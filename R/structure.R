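# Molecular structures: atom tables read from PDB files.
#
# A Structure is a light S3 container: a data.frame of heavy-atom records
# plus an id. One row per atom with columns
#   element, x, y, z, atom_name, res_index, res_name, chain, role
# where role is "protein" or "ligand". Hydrogens are skipped at read time;
# the whole pipeline (grids, flooding, clash checks) is heavy-atom only.

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.AA1TO3 <- setNames(names(.AA3TO1), .AA3TO1)
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `atom_name`, `res_index`, `res_name`, `chain`, `role`.
#' @param id Text label for the structure.
#' @return An object of class `vox_structure`.
#' @export
vox_structure <- function(atoms, id = "structure") {
  need <- c("element", "x", "y", "z", "atom_name", "res_index", "res_name",
            "chain", "role")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) vs_stop("atom table lacks column(s): %s",
                            paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) vs_stop("empty structure: no heavy atoms")
  if (!all(atoms$role %in% c("protein", "ligand")))
    vs_stop("role must be 'protein' or 'ligand'")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) vs_stop("non-finite atom coordinates")
  atoms$element <- normalize_element(atoms$element)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = as.character(id)),
            class = "vox_structure")
}

#' @export
print.vox_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<vox_structure '%s': %d heavy atoms (%d protein, %d ligand), %d residues>\n",
              x$id, nrow(a), sum(a$role == "protein"), sum(a$role == "ligand"),
              length(unique(paste(a$chain, a$res_index)[a$role == "protein"]))))
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

# 3 x N coordinate matrix (optionally restricted to one role).
struct_coords <- function(s, role = NULL) {
  a <- s$atoms
  if (!is.null(role)) a <- a[a$role == role, , drop = FALSE]
  t(as.matrix(a[, c("x", "y", "z")]))
}

#' Read a PDB file into a Structure
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 fixed columns). Hydrogens and
#' waters are skipped; for alternate locations only the highest-occupancy
#' conformer of each atom is kept. HETATM atoms are assigned
#' `role = "ligand"`, ATOM records `role = "protein"`. Coordinates are taken
#' verbatim from the file (Angstrom); no re-centering.
#'
#' @param path Path to a PDB file.
#' @param keep_hydrogens Keep H/D atoms (default `FALSE`).
#' @return A [vox_structure()].
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) vs_stop("cannot read PDB file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) vs_stop("empty structure: no ATOM/HETATM records in %s", path)
  f <- function(a, b) substr(lines, a, b)
  atom_name <- trimws(f(13, 16))
  altloc    <- f(17, 17)
  res_name  <- trimws(f(18, 20))
  chain     <- f(22, 22)
  res_index <- suppressWarnings(as.integer(trimws(f(23, 26))))
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(f(61, 66)))
  element <- trimws(f(77, 78))
  # fall back to the atom-name field when the element column is blank
  noel <- element == ""
  if (any(noel)) {
    nm <- gsub("[^A-Za-z].*$", "", atom_name[noel])
    two <- toupper(nm) %in% toupper(names(.ELEMENT_MASS)) & nchar(nm) == 2
    element[noel] <- ifelse(two, nm, substr(nm, 1, 1))
  }
  element <- normalize_element(element)
  role <- ifelse(substr(lines, 1, 6) == "HETATM", "ligand", "protein")

  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  ok <- ok & !(res_name %in% .WATER_NAMES)
  if (!keep_hydrogens) ok <- ok & !(element %in% c("H", "D"))
  a <- data.frame(element = element, x = x, y = y, z = z,
                  atom_name = atom_name, res_index = res_index,
                  res_name = res_name, chain = chain, role = role,
                  occupancy = occ, bfactor = bfac,
                  altloc = altloc, stringsAsFactors = FALSE)[ok, , drop = FALSE]
  if (nrow(a) == 0L) vs_stop("empty structure: no heavy atoms in %s", path)
  # alternate locations: keep highest occupancy per atom site
  if (any(a$altloc != " ")) {
    key <- paste(a$chain, a$res_index, a$res_name, a$atom_name)
    ord <- order(key, -a$occupancy)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$res_index, a$res_name, a$atom_name)), ,
           drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  a$altloc <- NULL
  vox_structure(a, id = sub("\\.(pdb|ent)$", "", basename(path)))
}

#' Write a Structure to a PDB file
#'
#' Inverse of [read_pdb()]: protein atoms become ATOM records, ligand atoms
#' HETATM. Coordinates are written at PDB precision (3 decimals).
#'
#' @param s A [vox_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  rec <- ifelse(a$role == "ligand", "HETATM", "ATOM  ")
  nm <- a$atom_name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                sprintf(" %-3s", nm))  # standard left-pad for short names
  lines <- sprintf("%s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), nm4, " ", a$res_name, a$chain,
                   a$res_index, a$x, a$y, a$z,
                   a$occupancy %||% 1, a$bfactor %||% 0,
                   toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Parse a residue specification string
#'
#' Accepts comma-separated tokens of one-letter amino-acid code plus residue
#' index, e.g. `"S91, R94, D114"`. Order is preserved; duplicates are an
#' error.
#'
#' @param text Character scalar.
#' @return data.frame with columns `aa` (1-letter code) and `res_index`.
#' @examples
#' parse_residue_spec("S91, R94")
#' @export
parse_residue_spec <- function(text) {
  tok <- trimws(strsplit(as.character(text), ",")[[1]])
  tok <- tok[tok != ""]
  if (!length(tok)) vs_stop("empty residue specification")
  ok <- grepl("^[A-Za-z][0-9]+$", tok)
  if (any(!ok)) vs_stop("malformed residue token(s): %s",
                        paste(tok[!ok], collapse = ", "))
  if (anyDuplicated(toupper(tok)))
    vs_stop("duplicate residue token(s): %s",
            paste(unique(tok[duplicated(toupper(tok))]), collapse = ", "))
  idx <- as.integer(sub("^[A-Za-z]", "", tok))
  if (any(idx < 1L)) vs_stop("residue index must be >= 1")
  data.frame(aa = toupper(substr(tok, 1, 1)), res_index = idx,
             stringsAsFactors = FALSE)
}

#' Format residue references back into a spec string
#'
#' Inverse of [parse_residue_spec()].
#'
#' @param refs data.frame with columns `aa`, `res_index`.
#' @return Character scalar like `"S91, R94"`.
#' @export
format_residue_spec <- function(refs) {
  paste(paste0(refs$aa, refs$res_index), collapse = ", ")
}

#' Default atom-type channel scheme
#'
#' Atoms are binned by element group (C, N, O, S, P, halogen, other) crossed
#' with role (protein, ligand): 14 channels. Protein channels come first.
#' The scheme is pluggable: pass a different `groups` vector to change the
#' element typing.
#'
#' @param groups Character vector of element groups; `"halogen"` matches
#'   F/Cl/Br/I and `"other"` is the fallback bin.
#' @return An object of class `channel_scheme`.
#' @export
channel_scheme <- function(groups = c("C", "N", "O", "S", "P", "halogen", "other")) {
  if (!"other" %in% groups) groups <- c(groups, "other")
  structure(list(groups = groups,
                 n_channels = 2L * length(groups),
                 roles = c("protein", "ligand")),
            class = "channel_scheme")
}

#' Map an atom to its featurization channel
#'
#' Deterministic and total: unknown elements fall into the `"other"` group.
#'
#' @param element Element symbol(s).
#' @param role `"protein"` or `"ligand"` (vectorized).
#' @param scheme A [channel_scheme()].
#' @return Integer channel index (1-based).
#' @examples
#' atom_channel("C", "protein")  # 1
#' atom_channel("Cl", "ligand")  # ligand-halogen channel
#' @export
atom_channel <- function(element, role, scheme = channel_scheme()) {
  stopifnot(inherits(scheme, "channel_scheme"))
  e <- normalize_element(element)
  grp <- ifelse(e %in% .HALOGENS, "halogen", e)
  gi <- match(grp, scheme$groups)
  gi[is.na(gi)] <- match("other", scheme$groups)
  ri <- match(role, scheme$roles)
  if (anyNA(ri)) vs_stop("role must be 'protein' or 'ligand'")
  as.integer((ri - 1L) * length(scheme$groups) + gi)
}
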