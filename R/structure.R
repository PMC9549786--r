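#' @importFrom stats setNames median cor sd
#' @importFrom utils write.table read.table head
NULL

# Canonical water component names; never reported as ligands.
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Residue keys
#'
#' A residue is identified by the triple (chain, author residue number,
#' insertion code), formatted as `"chain:resno:icode"`.  Author numbering is
#' kept verbatim from the coordinate file.
#'
#' @param chain,resno,icode vectors of equal length (icode may be `""`).
#' @return character vector of residue keys.
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  sprintf("%s:%s:%s", chain, as.integer(resno), icode)
}

#' Construct a structure object from an atom table
#'
#' The atom table is the single source of truth: one row per atom with
#' columns `chain`, `resno`, `icode`, `resname`, `atom` (atom name),
#' `element`, `x`, `y`, `z`, `occ` and `het` (HETATM flag).  Hydrogens are
#' retained but flagged; every distance computation in the package ignores
#' them.
#'
#' @param atoms data.frame as described above.
#' @param struct_id identifier string (e.g. PDB id plus chain selection).
#' @param source_format `"PDB"`, `"mmCIF"` or `"synthetic"`.
#' @return an object of class `ligsphere_structure`.
#' @export
new_structure <- function(atoms, struct_id = "struct", source_format = "synthetic") {
  needed <- c("chain", "resno", "icode", "resname", "atom", "element",
              "x", "y", "z", "occ", "het")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$element <- toupper(trimws(atoms$element))
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) == 0L) stop("empty-structure error: no atom coordinates")
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  atoms$hyd <- atoms$element %in% c("H", "D")
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL
  structure(
    list(struct_id = struct_id, atoms = atoms, source_format = source_format),
    class = "ligsphere_structure")
}

#' @export
print.ligsphere_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<ligsphere_structure> %s: %d atoms, %d residues (%d polymer), chains: %s\n",
              x$struct_id, nrow(x$atoms), nrow(rt), sum(!rt$het),
              paste(unique(rt$chain), collapse = ",")))
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param s a `ligsphere_structure`.
#' @return data.frame with one row per residue in file order: `key`, `chain`,
#'   `resno`, `icode`, `resname`, `het` (TRUE when every atom of the residue
#'   is a HETATM record).
#' @export
residue_table <- function(s) {
  a <- s$atoms
  first <- !duplicated(a$key)
  het <- tapply(a$het, a$key, all)
  out <- data.frame(key = a$key[first], chain = a$chain[first],
                    resno = a$resno[first], icode = a$icode[first],
                    resname = a$resname[first], stringsAsFactors = FALSE)
  out$het <- as.logical(het[out$key])
  rownames(out) <- NULL
  out
}

# Polymer (protein) residue keys: non-HETATM residues that are not waters.
polymer_keys <- function(s) {
  rt <- residue_table(s)
  rt$key[!rt$het & !(rt$resname %in% WATER_NAMES)]
}

# Heavy-atom coordinate matrix for a subset of residue keys (all atoms of the
# structure when keys is NULL), with the corresponding residue key per row.
heavy_atoms <- function(s, keys = NULL) {
  a <- s$atoms
  sel <- !a$hyd
  if (!is.null(keys)) sel <- sel & (a$key %in% keys)
  a[sel, , drop = FALSE]
}

# Representative point (CA, or CB with CA fallback) per polymer residue.
# Returns list(keys, xyz, resname, chain, resno) ordered as in the file.
rep_points <- function(s, unit = c("CA", "CB"), keys = NULL) {
  unit <- match.arg(unit)
  a <- s$atoms
  if (is.null(keys)) keys <- polymer_keys(s)
  a <- a[a$key %in% keys & !a$hyd, , drop = FALSE]
  pick <- function(df) {
    nm <- if (unit == "CB") c("CB", "CA") else "CA"
    for (n in nm) {
      i <- which(df$atom == n)
      if (length(i) > 0) return(df[i[1], , drop = FALSE])
    }
    NULL
  }
  rows <- do.call(rbind, lapply(split(a, factor(a$key, levels = unique(a$key))), pick))
  if (is.null(rows) || nrow(rows) == 0)
    return(list(keys = character(0), xyz = matrix(0, 0, 3),
                resname = character(0), chain = character(0), resno = integer(0)))
  # restore file order
  rows <- rows[order(match(rows$key, unique(a$key))), , drop = FALSE]
  list(keys = rows$key, xyz = as.matrix(rows[, c("x", "y", "z")]),
       resname = rows$resname, chain = rows$chain, resno = rows$resno)
}

# Subset a structure to the given residue keys (file order preserved).
subset_structure <- function(s, keys, struct_id = s$struct_id) {
  new_structure(s$atoms[s$atoms$key %in% keys, , drop = FALSE],
                struct_id = struct_id, source_format = s$source_format)
}

# One-letter sequence of the observed polymer residues of a chain set.
chain_sequence <- function(s, chains = NULL) {
  rt <- residue_table(s)
  rt <- rt[!rt$het & !(rt$resname %in% WATER_NAMES), , drop = FALSE]
  if (!is.null(chains)) rt <- rt[rt$chain %in% chains, , drop = FALSE]
  if (nrow(rt) == 0) return("")
  one <- suppressWarnings(bio3d::aa321(rt$resname))
  one[is.na(one) | one == ""] <- "X"
  paste(one, collapse = "")
}
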