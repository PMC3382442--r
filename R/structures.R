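# Non-canonical residues with a standard canonical parent. Anything else
# among HETATM/modified residues is skipped with a warning.
.noncanonical_map <- c(
  MSE = "Met", SEC = "Cys", PYL = "Lys", HYP = "Pro",
  SEP = "Ser", TPO = "Thr", PTR = "Tyr", CSO = "Cys", MLY = "Lys"
)

.aa3_upper <- stats::setNames(amino_acids(), toupper(amino_acids()))

#' Protein structures as typed alpha-carbon point clouds
#'
#' A `protein_structure` is a tibble with one row per residue and columns
#' `chain` (chain identifier), `seq_index` (residue sequence number),
#' `icode` (insertion code, `""` when absent), `res_type` (canonical
#' three-letter code, see [amino_acids()]) and `x`, `y`, `z` (alpha-carbon
#' coordinates in Angstroms). The structure identifier is carried in the
#' `"id"` attribute.
#'
#' @param residues A data frame with columns `res_type`, `x`, `y`, `z` and
#'   optionally `chain`, `seq_index`, `icode`.
#' @param id Structure identifier string.
#' @return A tibble of class `protein_structure`.
#' @export
#' @examples
#' protein_structure(
#'   data.frame(res_type = c("Arg", "Gly"), x = c(0, 3.8), y = 0, z = 0),
#'   id = "toy"
#' )
protein_structure <- function(residues, id = "structure") {
  residues <- as_tibble(residues)
  if (!all(c("res_type", "x", "y", "z") %in% names(residues))) {
    abort("residues need columns res_type, x, y, z", class = "bh_error_config")
  }
  if (nrow(residues) == 0L) {
    abort("structure has no residues", class = "bh_error_empty_structure")
  }
  if (is.null(residues[["chain"]])) residues$chain <- "A"
  if (is.null(residues[["seq_index"]])) {
    residues$seq_index <- seq_len(nrow(residues))
  }
  if (is.null(residues[["icode"]])) residues$icode <- ""
  residues$icode[is.na(residues$icode)] <- ""
  residues <- residues[, c("chain", "seq_index", "icode", "res_type", "x", "y", "z")]
  bad <- setdiff(unique(residues$res_type), amino_acids())
  if (length(bad)) {
    abort(paste0("non-canonical residue types: ", paste(bad, collapse = ", ")),
          class = "bh_error_config")
  }
  coords <- as.matrix(residues[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("residue coordinates must be finite", class = "bh_error_config")
  }
  key <- paste(residues$chain, residues$seq_index, residues$icode)
  if (anyDuplicated(key)) {
    abort("duplicated (chain, seq_index, icode) residue identity",
          class = "bh_error_config")
  }
  structure(residues,
            id = as.character(id),
            class = c("protein_structure", class(residues)))
}

#' @rdname protein_structure
#' @param structure A `protein_structure`.
#' @export
structure_id <- function(structure) {
  attr(structure, "id") %||% "structure"
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("# protein_structure '", structure_id(x), "': ", nrow(x),
      " residues\n", sep = "")
  NextMethod()
}

# Coordinate matrix (n x 3) of the alpha carbons.
ca_coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Read a protein structure from a PDB file
#'
#' Extracts one residue per standard amino acid that has an alpha-carbon
#' atom. Only the first model of multi-model files is used; for alternate
#' locations the first conformer is kept; hetero and solvent records are
#' excluded except for modified residues with a standard canonical parent
#' (e.g. selenomethionine MSE -> Met), which are mapped; other non-standard
#' residues are skipped with a warning. All chains are pooled into one
#' residue list.
#'
#' @param path Path to the structure file.
#' @param format Input format; only `"pdb"` is supported.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, format = c("pdb"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path), class = "bh_error_parse")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    { # bio3d chats on the console about ALT records; keep stdout clean
      utils::capture.output(
        p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                              verbose = FALSE))
      )
      p
    },
    error = function(e) {
      abort(paste0("failed to parse PDB file '", path, "': ",
                   conditionMessage(e)),
            class = "bh_error_parse")
    }
  )
  at <- pdb$atom
  at <- at[at$elety == "CA", , drop = FALSE]
  # bio3d already keeps only altLoc A when ALT records are present; guard
  # anyway by keeping the first CA per residue identity.
  resid_up <- toupper(at$resid)
  canon <- .aa3_upper[resid_up]
  mapped <- .noncanonical_map[resid_up]
  canon[is.na(canon)] <- mapped[is.na(canon)]
  keep_std <- at$type == "ATOM" & !is.na(canon)
  keep_map <- !is.na(canon) & !is.na(mapped)
  unknown <- resid_up[is.na(canon) & at$type == "ATOM"]
  if (length(unknown)) {
    warn(paste0("skipping residues without a canonical mapping: ",
                paste(unique(unknown), collapse = ", ")))
  }
  at <- at[keep_std | keep_map, , drop = FALSE]
  canon <- canon[keep_std | keep_map]
  if (nrow(at) == 0L) {
    abort(paste0("no amino-acid residues with alpha-carbons in '", path, "'"),
          class = "bh_error_empty_structure")
  }
  icode <- at$insert
  icode[is.na(icode)] <- ""
  key <- paste(at$chain, at$resno, icode)
  first <- !duplicated(key)
  res <- tibble(
    chain = as.character(at$chain[first]),
    seq_index = as.integer(at$resno[first]),
    icode = icode[first],
    res_type = unname(canon[first]),
    x = at$x[first], y = at$y[first], z = at$z[first]
  )
  protein_structure(res, id = id)
}

#' Geometric center of a structure
#'
#' The unweighted arithmetic mean of all alpha-carbon coordinates.
#'
#' @param structure A [protein_structure()].
#' @return A named numeric vector `c(x, y, z)` in Angstroms.
#' @export
#' @examples
#' s <- protein_structure(data.frame(res_type = "Arg", x = 1, y = 2, z = 3))
#' geometric_center(s)
geometric_center <- function(structure) {
  if (nrow(structure) == 0L) {
    abort("structure has no residues", class = "bh_error_empty_structure")
  }
  colMeans(ca_coords(structure))
}

#' Write a structure as a minimal PDB file
#'
#' Emits one `ATOM` record per residue (alpha-carbon only). Coordinates are
#' written with three decimals, the precision of the PDB fixed-width format.
#'
#' @param structure A [protein_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(structure)),
    toupper(structure$res_type),
    substr(structure$chain, 1, 1),
    structure$seq_index,
    ifelse(nzchar(structure$icode), substr(structure$icode, 1, 1), " "),
    structure$x, structure$y, structure$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
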