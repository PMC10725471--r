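# Multi-model PDB reading/writing and atom selection.
#
# Coordinates are stored in a flat atom table (one row per atom per model)
# so that downstream modules can address atoms by residue number, atom name
# and model index without caring how many models the file carried.

#' Parse a PDB-format string into a structure object
#'
#' Reads `ATOM`/`HETATM` records from the fixed PDB columns (serial 7-11,
#' atom name 13-16, altLoc 17, residue name 18-20, chain 22, residue number
#' 23-26, x/y/z 31-54, element 77-78; coordinates in Angstrom).
#' `MODEL`/`ENDMDL` blocks are counted; a file without `MODEL` records is a
#' single-model structure. Alternate locations other than blank or `"A"` are
#' dropped so every retained residue has a single conformer.
#'
#' @param text Character scalar (or vector of lines) holding PDB-format text.
#' @param source_id Identifier stored with the structure (defaults to
#'   `"text"`).
#' @return An object of class `"bax_structure"`: a list with `atoms` (a
#'   data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, `x`, `y`, `z`, `element`, `model_index`),
#'   `n_models` and `source_id`. Atom order within each model follows file
#'   order.
#' @seealso [read_pdb()] to read from a file, [write_pdb()] for the inverse.
#' @export
parse_pdb <- function(text, source_id = "text") {
  if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- as.character(text)
  }
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    startsWith(rec, "ATOM") & nchar(trimws(rec)) == 4L
  is_model <- startsWith(rec, "MODEL")

  n_models_seen <- 0L
  current_model <- 1L
  out <- vector("list", sum(is_atom))
  k <- 0L
  for (i in seq_along(lines)) {
    if (is_model[i]) {
      n_models_seen <- n_models_seen + 1L
      current_model <- n_models_seen
      next
    }
    if (!is_atom[i]) next
    ln <- lines[i]
    altloc <- substr(ln, 17L, 17L)
    if (!(altloc %in% c(" ", "", "A"))) next
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31L, 38L), substr(ln, 39L, 46L), substr(ln, 47L, 54L)
    )))
    if (anyNA(xyz) || any(!is.finite(xyz))) {
      stop("malformed coordinate field in PDB line ", i, ": ", trimws(ln))
    }
    resno <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
    if (is.na(resno)) {
      stop("malformed residue number in PDB line ", i, ": ", trimws(ln))
    }
    element <- trimws(substr(ln, 77L, 78L))
    atom_name <- trimws(substr(ln, 13L, 16L))
    if (element == "") {
      element <- substr(gsub("[0-9]", "", atom_name), 1L, 1L)
    }
    k <- k + 1L
    out[[k]] <- list(
      serial = suppressWarnings(as.integer(substr(ln, 7L, 11L))),
      atom_name = atom_name,
      residue_name = trimws(substr(ln, 18L, 20L)),
      residue_number = resno,
      chain_id = substr(ln, 22L, 22L),
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      element = element,
      model_index = current_model
    )
  }
  if (k == 0L) stop("no ATOM/HETATM records found: empty structure")
  out <- out[seq_len(k)]
  atoms <- data.frame(
    serial = vapply(out, `[[`, integer(1), "serial"),
    atom_name = vapply(out, `[[`, character(1), "atom_name"),
    residue_name = vapply(out, `[[`, character(1), "residue_name"),
    residue_number = vapply(out, `[[`, integer(1), "residue_number"),
    chain_id = vapply(out, `[[`, character(1), "chain_id"),
    x = vapply(out, `[[`, numeric(1), "x"),
    y = vapply(out, `[[`, numeric(1), "y"),
    z = vapply(out, `[[`, numeric(1), "z"),
    element = vapply(out, `[[`, character(1), "element"),
    model_index = vapply(out, `[[`, integer(1), "model_index"),
    stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms, n_models = max(1L, n_models_seen),
         source_id = source_id),
    class = "bax_structure"
  )
}

#' Read a PDB file
#'
#' @param file Path to a PDB file.
#' @return A `"bax_structure"`; see [parse_pdb()].
#' @export
read_pdb <- function(file) {
  parse_pdb(readLines(file, warn = FALSE), source_id = basename(file))
}

#' @export
print.bax_structure <- function(x, ...) {
  cat("<bax_structure> ", x$source_id, ": ",
      nrow(x$atoms), " atoms, ", x$n_models, " model(s), ",
      length(unique(x$atoms$residue_number[x$atoms$model_index == 1L])),
      " residues\n", sep = "")
  invisible(x)
}

# backbone + terminal oxygens; everything else heavy is sidechain
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

.is_hydrogen <- function(atom_name, element) {
  element == "H" | grepl("^[0-9]*H", atom_name)
}

#' Select atom coordinates from a structure
#'
#' Resolves a residue/atom selection in one model of a structure and returns
#' the coordinates in file order. `atom` may be a vector of PDB atom names
#' (e.g. `"CA"`, `c("OD1","OD2","CG")`) or the keyword `"sidechain"`, which
#' selects all heavy atoms outside the peptide backbone. Structures with a
#' single chain need no `chain_id`; multi-chain structures require one.
#'
#' @param structure A `"bax_structure"`.
#' @param residue_number Integer residue number.
#' @param atom Atom name(s) or `"sidechain"`.
#' @param chain_id Optional one-character chain identifier.
#' @param model Model index (1-based; defaults to 1, conventionally the
#'   lowest-energy member of an NMR ensemble).
#' @return Numeric matrix (n x 3) of coordinates in Angstrom, with atom
#'   names as row names.
#' @export
select_atoms <- function(structure, residue_number, atom = "CA",
                         chain_id = NULL, model = 1L) {
  stopifnot(inherits(structure, "bax_structure"))
  if (model < 1L || model > structure$n_models) {
    stop("model ", model, " out of range [1, ", structure$n_models, "]")
  }
  a <- structure$atoms[structure$atoms$model_index == model, , drop = FALSE]
  chains <- unique(a$chain_id)
  if (is.null(chain_id)) {
    if (length(chains) > 1L) {
      stop("structure has multiple chains (", paste(chains, collapse = ", "),
           "); supply chain_id")
    }
  } else {
    a <- a[a$chain_id == chain_id, , drop = FALSE]
  }
  a <- a[a$residue_number == residue_number, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("selection error: residue ", residue_number, " not found",
         if (!is.null(chain_id)) paste0(" in chain ", chain_id) else "")
  }
  if (identical(atom, "sidechain")) {
    keep <- !(a$atom_name %in% .backbone_atoms) &
      !.is_hydrogen(a$atom_name, a$element)
  } else {
    keep <- a$atom_name %in% atom
  }
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("selection error: residue ", residue_number, " has no atoms matching ",
         if (identical(atom, "sidechain")) "sidechain heavy atoms"
         else paste(atom, collapse = "/"))
  }
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$atom_name
  m
}

#' Write a structure as PDB-format text
#'
#' Emits `ATOM` records in the fixed PDB columns (coordinates `%8.3f`);
#' multi-model structures are wrapped in `MODEL`/`ENDMDL` blocks. A
#' coordinate that does not fit the 8.3 field is an error rather than a
#' silently corrupted file. Round-tripping through [parse_pdb()] preserves
#' atom metadata and coordinates to 3 decimals.
#'
#' @param structure A `"bax_structure"`.
#' @param file Optional path; if supplied, the text is also written there.
#' @return The PDB-format text, invisibly if `file` is given.
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "bax_structure"))
  a <- structure$atoms
  if (nrow(a) == 0L) stop("empty structure")
  bad <- a$x >= 10000 | a$x <= -1000 | a$y >= 10000 | a$y <= -1000 |
    a$z >= 10000 | a$z <= -1000
  if (any(bad)) {
    stop("coordinate overflow: value does not fit the PDB 8.3 field ",
         "(first offending atom serial ", a$serial[which(bad)[1L]], ")")
  }
  fmt_line <- function(r) {
    nm <- r$atom_name
    if (nchar(nm) < 4L) nm <- paste0(" ", nm)
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$serial, nm, " ", r$residue_name,
            ifelse(r$chain_id == "", " ", r$chain_id),
            r$residue_number, " ", r$x, r$y, r$z, 1, 0, r$element)
  }
  out <- character(0)
  multi <- structure$n_models > 1L
  for (m in seq_len(structure$n_models)) {
    am <- a[a$model_index == m, , drop = FALSE]
    if (multi) out <- c(out, sprintf("MODEL %8d", m))
    out <- c(out, vapply(seq_len(nrow(am)), function(i) fmt_line(am[i, ]),
                         character(1)))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(txt))
  }
  txt
}
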