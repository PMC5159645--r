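# Structure and sequence input adapters.

# Modified nucleotides mapped to their parent base; editable via the
# `modified_map` argument of read_rna_structure().
default_modified_map <- c(
  "1MA" = "A", "2MA" = "A", "6MA" = "A", "MIA" = "A", "A2M" = "A",
  "5MC" = "C", "OMC" = "C", "4OC" = "C",
  "1MG" = "G", "2MG" = "G", "7MG" = "G", "M2G" = "G", "OMG" = "G", "YG"  = "G",
  "5MU" = "U", "PSU" = "U", "H2U" = "U", "4SU" = "U", "OMU" = "U", "DHU" = "U"
)

#' Read one RNA chain from a PDB or mmCIF file
#'
#' Parses the structure with `bio3d`, keeps the requested chain's heavy
#' atoms, maps modified nucleotides to their parent base via a small editable
#' table, drops other HETATM records and hydrogens, and attaches van der
#' Waals radii.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chain Chain identifier to extract.
#' @param radii Named element -> radius vector; see [vdw_radii()].
#' @param modified_map Named vector residue-name -> parent base extending or
#'   replacing the built-in modified-nucleotide table.
#' @return Atom tibble: `atom_name`, `element`, `vdw_radius`, `x`, `y`, `z`,
#'   `residue_index` (0-based, in chain order), `residue_base`.
#' @export
read_rna_structure <- function(path, chain, radii = vdw_radii(),
                               modified_map = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("package 'bio3d' is required to read structure files", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path, call. = FALSE)

  map <- default_modified_map
  if (!is.null(modified_map)) map[names(modified_map)] <- modified_map
  base_of <- function(resid) {
    if (resid %in% c("A", "C", "G", "U")) return(resid)
    if (resid %in% names(map)) return(map[[resid]])
    NA_character_
  }
  bases <- vapply(at$resid, base_of, character(1), USE.NAMES = FALSE)
  keep <- !is.na(bases)                              # drops non-nucleotide HETATM
  at <- at[keep, , drop = FALSE]
  bases <- bases[keep]

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))
  heavy <- elem != "H" & elem != "D"
  at <- at[heavy, , drop = FALSE]
  bases <- bases[heavy]
  elem <- elem[heavy]

  rid <- paste(at$resno, at$insert %||% "", sep = "_")
  residue_index <- as.integer(factor(rid, levels = unique(rid))) - 1L

  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown) > 0) {
    warning("no van der Waals radius for element(s) ",
            paste(unknown, collapse = ", "), "; using 1.70", call. = FALSE)
  }
  r <- unname(radii[elem])
  r[is.na(r)] <- 1.70

  tibble::tibble(
    atom_name = trimws(at$elety),
    element = elem,
    vdw_radius = r,
    x = at$x, y = at$y, z = at$z,
    residue_index = residue_index,
    residue_base = bases
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-residue ASA table as TSV
#'
#' @param res Residue tibble from [chain_asa()].
#' @param path Output path.
#' @param chain Chain identifier recorded in the first column.
#' @return `res`, invisibly.
#' @export
write_asa_tsv <- function(res, path, chain = "A") {
  out <- tibble::tibble(
    chain = chain,
    residue_index = res$residue_index,
    base = res$base,
    asa_A2 = res$asa,
    asa_norm = res$asa_norm,
    valid = res$valid
  )
  readr::write_tsv(out, path)
  invisible(res)
}

#' Read sequences from FASTA
#'
#' Thin wrapper over `Biostrings`; T is mapped to U so DNA-alphabet inputs
#' are accepted.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("package 'Biostrings' is required to read FASTA", call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  gsub("T", "U", seqs, fixed = TRUE)
}
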