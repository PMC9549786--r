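#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d} (`read.pdb` / `read.cif`); the result
#' is normalised into the package's atom-table representation.  Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' file order).  Hydrogens are kept but flagged and ignored by all distance
#' computations.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param struct_id identifier; defaults to the file base name.
#' @return a `ligsphere_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           struct_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  if (is.null(struct_id)) struct_id <- sub("\\.[^.]*$", "", basename(path))
  # keep alternate locations (rm.alt = FALSE): the package resolves them by
  # occupancy itself rather than taking bio3d's altloc-A default
  parse_fun <- function()
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  pdb <- tryCatch(
    parse_fun(),
    error = function(e) stop("format error: cannot parse ", basename(path),
                             " as ", format, " (", conditionMessage(e), ")"),
    warning = function(w) suppressWarnings(parse_fun()))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty-structure error: ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = a$resid,
    atom = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "", guess_element(a$elety), a$elesy),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  atoms <- resolve_altlocs(atoms)
  atoms$alt <- NULL
  new_structure(atoms, struct_id = struct_id,
                source_format = if (format == "cif") "mmCIF" else "PDB")
}

#' Parse a structure from in-memory file content
#'
#' @param raw character scalar (or vector of lines) with PDB or mmCIF text.
#' @param fmt `"pdb"` or `"cif"`.
#' @param struct_id identifier for the resulting structure.
#' @return a `ligsphere_structure`.
#' @export
parse_structure <- function(raw, fmt = c("pdb", "cif"), struct_id = "struct") {
  fmt <- match.arg(fmt)
  tf <- tempfile(fileext = paste0(".", fmt))
  on.exit(unlink(tf))
  writeLines(if (length(raw) == 1L) strsplit(raw, "\n", fixed = TRUE)[[1]] else raw, tf)
  read_structure(tf, format = fmt, struct_id = struct_id)
}

# Keep the highest-occupancy altloc per atom site; ties -> first in file.
resolve_altlocs <- function(atoms) {
  site <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname, atoms$atom)
  if (!anyDuplicated(site)) return(atoms)
  ord <- order(factor(site, levels = unique(site)), -atoms$occ,
               seq_len(nrow(atoms)))
  a2 <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(paste(a2$chain, a2$resno, a2$icode, a2$resname, a2$atom))
  a2 <- a2[keep, , drop = FALSE]
  a2[order(match(rownames(a2), rownames(atoms))), , drop = FALSE]
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  el <- toupper(substr(nm, 1, 1))
  known2 <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "CU", "NI", "CO", "SE")
  ifelse(two %in% known2 & nchar(atom_name) == 2 & atom_name == toupper(atom_name),
         two, el)
}

#' Write a structure as a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (coordinates to 3 decimals) so that
#' re-parsing preserves residue keys, atom names and coordinates.
#'
#' @param s a `ligsphere_structure`.
#' @param path output file path.
#' @param extra_atoms optional atom data.frame (same columns) appended as
#'   HETATM records, e.g. a transplanted ligand.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, extra_atoms = NULL) {
  a <- s$atoms
  if (!is.null(extra_atoms)) {
    extra_atoms$het <- TRUE
    keep <- intersect(names(a), names(extra_atoms))
    a <- rbind(a[, keep, drop = FALSE], extra_atoms[, keep, drop = FALSE])
  }
  lines <- pdb_records(a)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

pdb_records <- function(a) {
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  name <- vapply(a$atom, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  }, character(1))
  sprintf("%s%5d %4s %-3s%2s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(a)) %% 100000L, name, substr(a$resname, 1, 3),
          substr(paste0(" ", a$chain), nchar(a$chain), nchar(a$chain) + 1),
          a$resno, ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occ, 0, substr(a$element, 1, 2))
}

#' List ligand instances of a structure
#'
#' One instance is returned per non-water hetero compound, per metal/ion
#' (single-heavy-atom hetero group) and per polymer chain of at most 25
#' residues that is not itself the protein chain.  Waters (HOH/WAT/DOD) are
#' never reported.
#'
#' @param s a `ligsphere_structure`.
#' @param max_peptide_res longest polymer chain still treated as a peptide
#'   ligand (default 25 residues).
#' @return list of `ligand_instance` objects, each with `ligand_id`, `kind`
#'   (`"compound"`, `"peptide"` or `"metal_or_ion"`), `atoms`, `n_heavy` and
#'   `source_residues`.
#' @export
list_ligand_instances <- function(s, max_peptide_res = 25L) {
  a <- s$atoms
  rt <- residue_table(s)
  out <- list()

  # hetero groups: one instance per residue-level hetero group, waters excluded
  hets <- rt[rt$het & !(rt$resname %in% WATER_NAMES), , drop = FALSE]
  for (i in seq_len(nrow(hets))) {
    atoms_i <- a[a$key == hets$key[i], , drop = FALSE]
    nh <- sum(!atoms_i$hyd)
    if (nh == 0) next
    out[[length(out) + 1L]] <- new_ligand_instance(
      ligand_id = hets$resname[i],
      kind = if (nh == 1L) "metal_or_ion" else "compound",
      atoms = atoms_i, source_residues = hets$key[i], source_id = s$struct_id)
  }

  # short polymer chains bound to the protein chain(s)
  poly <- rt[!rt$het & !(rt$resname %in% WATER_NAMES), , drop = FALSE]
  if (nrow(poly) > 0) {
    nres <- table(poly$chain)
    protein_chains <- names(nres)[nres > max_peptide_res]
    if (length(protein_chains) == 0)  # everything short: longest chain is the protein
      protein_chains <- names(nres)[which.max(nres)]
    pep_chains <- setdiff(names(nres)[nres <= max_peptide_res], protein_chains)
    for (ch in pep_chains) {
      keys <- poly$key[poly$chain == ch]
      atoms_i <- a[a$key %in% keys, , drop = FALSE]
      if (sum(!atoms_i$hyd) == 0) next
      out[[length(out) + 1L]] <- new_ligand_instance(
        ligand_id = ch, kind = "peptide", atoms = atoms_i,
        source_residues = keys, source_id = s$struct_id)
    }
  }
  out
}

new_ligand_instance <- function(ligand_id, kind, atoms, source_residues,
                                source_id = "struct") {
  structure(list(ligand_id = ligand_id, kind = kind, atoms = atoms,
                 n_heavy = sum(!atoms$hyd), source_residues = source_residues,
                 source_id = source_id),
            class = "ligand_instance")
}

#' @export
print.ligand_instance <- function(x, ...) {
  cat(sprintf("<ligand_instance> %s (%s), %d heavy atoms, %d source residues [%s]\n",
              x$ligand_id, x$kind, x$n_heavy, length(x$source_residues),
              x$source_id))
  invisible(x)
}

# Heavy-atom coordinates of a ligand instance.
ligand_xyz <- function(lig) {
  at <- lig$atoms[!lig$atoms$hyd, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Extract the protein region around a ligand
#'
#' Keeps every polymer residue having at least one heavy atom within
#' `radius` of any ligand heavy atom (inclusive threshold), preserving
#' residue identity and file order; the ligand's own atoms are carried along
#' so the region can seed sphere construction.
#'
#' @param s a `ligsphere_structure`.
#' @param lig a `ligand_instance` belonging to `s`.
#' @param radius inclusion radius in Angstrom (default 16).
#' @param keep_ligand include the ligand atoms in the returned structure.
#' @return a `ligsphere_structure` restricted to the region.
#' @export
extract_region <- function(s, lig, radius = 16.0, keep_ligand = TRUE) {
  stopifnot(radius > 0)
  lxyz <- ligand_xyz(lig)
  if (nrow(lxyz) == 0) stop("invalid-ligand error: ligand has no heavy atoms")
  pk <- setdiff(polymer_keys(s), lig$source_residues)
  prot <- heavy_atoms(s, pk)
  dmin <- min_dist_per_residue(prot, lxyz)
  keep <- names(dmin)[dmin <= radius]
  keep_keys <- c(keep, if (keep_ligand) lig$source_residues)
  subset_structure(s, keep_keys,
                   struct_id = paste0(s$struct_id, "_region"))
}

#' Tabulate ligand instances as a data.frame
#'
#' @param ligs list of `ligand_instance` objects (or a structure, in which
#'   case its instances are listed first).
#' @return data.frame with columns `ligand_id`, `kind`, `n_heavy`,
#'   `source_id`, `chain`.
#' @export
ligand_inventory <- function(ligs) {
  if (inherits(ligs, "ligsphere_structure")) ligs <- list_ligand_instances(ligs)
  if (length(ligs) == 0)
    return(data.frame(ligand_id = character(0), kind = character(0),
                      n_heavy = integer(0), source_id = character(0),
                      chain = character(0)))
  do.call(rbind, lapply(ligs, function(l) data.frame(
    ligand_id = l$ligand_id, kind = l$kind, n_heavy = l$n_heavy,
    source_id = l$source_id, chain = l$atoms$chain[1],
    stringsAsFactors = FALSE)))
}
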