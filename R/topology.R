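# Standard atomic masses (amu) for the elements that occur in protein/ligand
# heavy-atom + hydrogen models.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904
)

#' Infer an element symbol from a PDB atom name
#'
#' Used when the PDB element column (columns 77-78) is blank: the first
#' alphabetic character of the atom name, after stripping leading digits,
#' is taken as the element (so `"CA"` -> C, `"OD1"` -> O, `"1HB"` -> H).
#'
#' @param atom_name character vector of PDB atom names.
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(atom_name) {
  stripped <- sub("^[0-9']+", "", trimws(atom_name))
  toupper(substr(stripped, 1L, 1L))
}

.mass_for_element <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    unknown <- unique(element[is.na(m)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; assigning carbon mass", call. = FALSE)
    m[is.na(m)] <- .element_masses[["C"]]
  }
  unname(m)
}

#' Construct a topology
#'
#' A topology is the static atom table shared by all frames of a trajectory:
#' atom names, residue names, author-numbered residue ids, elements and
#' masses, for a single chain. Residue ids follow the author (PDB) numbering
#' convention used throughout receptor structural biology (e.g. the androgen
#' receptor ligand-binding domain spans residues ~690-919 regardless of how
#' many are resolved), so they need not start at 1 nor be contiguous.
#'
#' @param atom_name,residue_name character vectors, one entry per atom.
#' @param residue_id integer vector of author-numbered residue ids.
#' @param element optional character vector; inferred from `atom_name` when
#'   `NULL`.
#' @param mass optional numeric vector (amu); default per-element masses are
#'   assigned when `NULL`.
#' @param chain_id single chain identifier.
#' @param record optional character vector of PDB record types
#'   (`"ATOM"`/`"HETATM"`); defaults to `"ATOM"`.
#' @return an object of class `"topology"`: a list with an `atoms` data frame
#'   (`atom_name`, `residue_name`, `residue_id`, `element`, `mass`, `record`),
#'   `chain_id` and `n_atoms`.
#' @export
topology <- function(atom_name, residue_name, residue_id, element = NULL,
                     mass = NULL, chain_id = "A", record = NULL) {
  n <- length(atom_name)
  if (n < 1L) stop("a topology needs at least one atom")
  stopifnot(length(residue_name) == n, length(residue_id) == n)
  if (is.null(element)) element <- infer_element(atom_name)
  if (is.null(mass)) mass <- .mass_for_element(element)
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("masses must be positive")
  if (is.null(record)) record <- rep("ATOM", n)
  key <- paste(residue_id, trimws(atom_name))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (residue_id, atom_name) pair within chain: ", d)
  }
  structure(
    list(
      atoms = data.frame(
        atom_name = trimws(atom_name),
        residue_name = trimws(residue_name),
        residue_id = as.integer(residue_id),
        element = element,
        mass = mass,
        record = record,
        stringsAsFactors = FALSE
      ),
      chain_id = chain_id,
      n_atoms = n
    ),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      length(unique(x$atoms$residue_id)), "residues, chain", x$chain_id, "\n")
  invisible(x)
}

# Parse the fixed-column fields of one ATOM/HETATM line.
.parse_pdb_atom_line <- function(line) {
  list(
    record = trimws(substr(line, 1L, 6L)),
    atom_name = trimws(substr(line, 13L, 16L)),
    residue_name = trimws(substr(line, 18L, 20L)),
    chain_id = substr(line, 22L, 22L),
    residue_id = suppressWarnings(as.integer(substr(line, 23L, 26L))),
    x = suppressWarnings(as.numeric(substr(line, 31L, 38L))),
    y = suppressWarnings(as.numeric(substr(line, 39L, 46L))),
    z = suppressWarnings(as.numeric(substr(line, 47L, 54L))),
    element = trimws(substr(line, 77L, 78L))
  )
}

#' Read a topology from a PDB file
#'
#' Reads ATOM/HETATM records (first MODEL only, for multi-model files) into a
#' [topology()]. Residue ids are taken verbatim from the PDB columns (author
#' numbering, no renumbering); the element is taken from columns 77-78 when
#' present, else inferred from the atom name; default masses are assigned per
#' element. Only single-chain files are accepted: the analyses here assume
#' one ligand-binding domain monomer.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is supported.
#' @return a [topology()]; the first model's coordinates are attached as
#'   attribute `"coords"` (n_atoms x 3 matrix, Angstrom).
#' @export
read_topology <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  # restrict to the first model when MODEL records are present
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    end1 <- grep("^ENDMDL", lines)[1L]
    if (is.na(end1)) stop("MODEL without ENDMDL in ", path)
    is_atom[-(model_starts[1L]:end1)] <- FALSE
  }
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM/HETATM records in ", path)

  fields <- lapply(lines[idx], .parse_pdb_atom_line)
  get <- function(f, mode) vapply(fields, `[[`, FUN.VALUE = vector(mode, 1L), f)

  chain <- get("chain_id", "character")
  chain[chain == " "] <- "A"
  if (length(unique(chain)) > 1L) {
    stop("multiple chains found (", paste(unique(chain), collapse = ", "),
         "); single-chain input required")
  }
  rid <- get("residue_id", "integer")
  if (anyNA(rid)) {
    bad <- idx[which(is.na(rid))[1L]]
    stop("unparseable residue id at line ", bad, " of ", path)
  }
  aname <- get("atom_name", "character")
  key <- paste(rid, aname)
  if (anyDuplicated(key)) {
    bad <- idx[which(duplicated(key))[1L]]
    stop("duplicate (residue_id, atom_name) pair at line ", bad, " of ", path,
         ": (", rid[duplicated(key)][1L], ", ", aname[duplicated(key)][1L], ")")
  }
  element <- get("element", "character")
  element[element == ""] <- infer_element(aname[element == ""])
  top <- topology(
    atom_name = aname,
    residue_name = get("residue_name", "character"),
    residue_id = rid,
    element = element,
    chain_id = unique(chain),
    record = get("record", "character")
  )
  xyz <- cbind(get("x", "double"), get("y", "double"), get("z", "double"))
  colnames(xyz) <- c("x", "y", "z")
  attr(top, "coords") <- xyz
  top
}

# Format one PDB ATOM/HETATM line.
.format_pdb_atom_line <- function(serial, record, atom_name, residue_name,
                                  chain_id, residue_id, xyz, element) {
  name_field <- if (nchar(atom_name) < 4L) sprintf(" %-3s", atom_name)
                else sprintf("%-4s", atom_name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, name_field, residue_name, chain_id,
          residue_id, xyz[1L], xyz[2L], xyz[3L], 1.0, 0.0, element)
}

#' Write a topology (with coordinates) as a single-model PDB file
#'
#' @param top a [topology()].
#' @param coords n_atoms x 3 coordinate matrix (Angstrom); defaults to the
#'   coordinates attached by [read_topology()] or [generate_topology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path, coords = attr(top, "coords")) {
  stopifnot(inherits(top, "topology"))
  if (is.null(coords)) stop("no coordinates supplied or attached")
  con <- file(path, "w")
  on.exit(close(con))
  .write_model_atoms(con, top, coords)
  writeLines("END", con)
  invisible(path)
}

.write_model_atoms <- function(con, top, coords) {
  a <- top$atoms
  lines <- vapply(seq_len(top$n_atoms), function(i) {
    .format_pdb_atom_line(i, a$record[i], a$atom_name[i], a$residue_name[i],
                          top$chain_id, a$residue_id[i], coords[i, ],
                          a$element[i])
  }, character(1L))
  writeLines(lines, con)
}
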