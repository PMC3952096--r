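#' Read a protein structure from PDB text or file
#'
#' Parses `ATOM` records of a PDB file into an atom table grouped by residue
#' and chain. For multi-model (NMR) files only the model selected by
#' `model_index` is read. Alternate locations are resolved by keeping, per
#' atom, the highest-occupancy record (ties broken in favour of altloc `"A"`,
#' then alphabetically). `HETATM` groups and waters are dropped unless
#' `keep_hetatm = TRUE`.
#'
#' @param pdb Either a file path or a character scalar/vector of PDB text.
#' @param model_index Zero-based index of the model to read (default 0, the
#'   first model; files without `MODEL` records have a single model 0).
#' @param chain_filter Optional character vector of chain identifiers to keep.
#' @param keep_hetatm Keep non-water `HETATM` records (default `FALSE`).
#' @return An object of class `critres_structure`: a list with element
#'   `atoms`, a tibble with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `insert`, `resid`, `x`, `y`, `z`, `is_sidechain`, `is_cbeta`,
#'   `is_hydrogen`, plus `n_models` recording how many models the file held.
#' @export
read_structure <- function(pdb, model_index = 0, chain_filter = NULL,
                           keep_hetatm = FALSE) {
  lines <- .pdb_lines(pdb)
  lines <- .select_model(lines, model_index)

  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  atom_lines <- lines[keep]
  if (length(atom_lines) == 0) {
    stop("no ATOM records found in PDB input", call. = FALSE)
  }

  atoms <- tibble::tibble(
    record  = trimws(substr(atom_lines, 1, 6)),
    serial  = as.integer(substr(atom_lines, 7, 11)),
    name    = trimws(substr(atom_lines, 13, 16)),
    altloc  = substr(atom_lines, 17, 17),
    resid   = trimws(substr(atom_lines, 18, 20)),
    chain   = substr(atom_lines, 22, 22),
    resno   = as.integer(substr(atom_lines, 23, 26)),
    insert  = trimws(substr(atom_lines, 27, 27)),
    x       = as.numeric(substr(atom_lines, 31, 38)),
    y       = as.numeric(substr(atom_lines, 39, 46)),
    z       = as.numeric(substr(atom_lines, 47, 54)),
    occ     = suppressWarnings(as.numeric(substr(atom_lines, 55, 60))),
    element = trimws(substr(atom_lines, 77, 78))
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$element <- ifelse(atoms$element == "",
                          .element_from_name(atoms$name), atoms$element)
  atoms$element <- toupper(atoms$element)

  atoms <- dplyr::filter(atoms, !(.data$resid %in% c("HOH", "WAT", "DOD")))
  if (!is.null(chain_filter)) {
    atoms <- dplyr::filter(atoms, .data$chain %in% chain_filter)
  }
  if (nrow(atoms) == 0) {
    stop("no atoms left after filtering", call. = FALSE)
  }

  ## altloc resolution: per (chain, resno, insert, name) keep the
  ## highest-occupancy copy; ties -> altloc 'A', then alphabetical.
  atoms <- atoms |>
    dplyr::mutate(.alt_pref = ifelse(.data$altloc %in% c(" ", ""), "0",
                                     .data$altloc)) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$.alt_pref,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial)

  unknown <- setdiff(unique(atoms$resid[atoms$record == "ATOM"]),
                     .standard_aa)
  if (length(unknown) > 0) {
    warning("unknown residue name(s): ", paste(unknown, collapse = ", "),
            "; atoms kept with hydrophobicity class 'none'", call. = FALSE)
  }

  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in PDB input", call. = FALSE)
  }

  atoms <- atoms |>
    dplyr::mutate(
      is_hydrogen = .data$element %in% c("H", "D"),
      is_sidechain = !(.data$name %in% .backbone_names),
      is_cbeta = .data$name == "CB"
    ) |>
    dplyr::select("serial", "name", "element", "chain", "resno", "insert",
                  "resid", "x", "y", "z", "is_sidechain", "is_cbeta",
                  "is_hydrogen")

  structure(
    list(atoms = atoms, n_models = attr(lines, "n_models")),
    class = "critres_structure"
  )
}

#' @export
print.critres_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("<critres_structure> ", nrow(x$atoms), " atoms, ", nrow(res),
      " residues, ", length(unique(res$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param structure A `critres_structure`.
#' @return Tibble with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `n_atoms`, `hydrophobicity`.
#' @export
residue_table <- function(structure) {
  structure$atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::summarise(resid = dplyr::first(.data$resid),
                     n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(hydrophobicity = hydrophobicity_class(.data$resid)) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
}

#' Write a structure back out as PDB text
#'
#' @param structure A `critres_structure`.
#' @param path Optional file path; when `NULL` the text is returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_structure <- function(structure, path = NULL) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, .pdb_atom_field(a$name), a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, 1, 0, a$element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

## PDB columns 13-16: element right-justified in 13-14 for 1-2 letter names.
.pdb_atom_field <- function(name) {
  ifelse(nchar(name) >= 4, name, paste0(" ", formatC(name, width = -3)))
}

.pdb_lines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1) {
    strsplit(pdb, "\n", fixed = TRUE)[[1]]
  } else {
    pdb
  }
}

.select_model <- function(lines, model_index) {
  starts <- grep("^MODEL ", lines)
  if (length(starts) == 0) {
    attr(lines, "n_models") <- 1L
    if (model_index != 0) {
      stop("model_index ", model_index,
           " requested but file has a single model", call. = FALSE)
    }
    return(lines)
  }
  ends <- grep("^ENDMDL", lines)
  if (model_index + 1 > length(starts)) {
    stop("model_index ", model_index, " requested but file has only ",
         length(starts), " model(s)", call. = FALSE)
  }
  i <- model_index + 1
  end_i <- ends[ends > starts[i]][1]
  if (is.na(end_i)) end_i <- length(lines)
  out <- lines[(starts[i] + 1):(end_i - 1)]
  attr(out, "n_models") <- length(starts)
  out
}

.element_from_name <- function(name) {
  ## strip leading digits (e.g. "1HB"), take first char; two-letter elements
  ## in amino acids are only SE (selenomethionine), handled explicitly.
  core <- sub("^[0-9]+", "", name)
  ifelse(substr(core, 1, 2) == "SE" & nchar(core) == 2, "SE",
         substr(core, 1, 1))
}

## residue key as a stable string id "chain:resno:insert"
.residue_key <- function(chain, resno, insert) {
  paste(chain, resno, insert, sep = ":")
}
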