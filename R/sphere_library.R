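#' Build a sphere template around a ligand
#'
#' The sphere is the local protein environment of a bound ligand: every
#' polymer residue (waters excluded) with at least one heavy atom within
#' `shell_radius` of any ligand heavy atom.  Residues with an atom within
#' `interface_radius` of the ligand form the interface set.  Both thresholds
#' are inclusive and use heavy atoms only.
#'
#' @param s a `ligsphere_structure` containing the complex.
#' @param lig a `ligand_instance` belonging to `s`.
#' @param shell_radius sphere shell radius in Angstrom (default 12.0).
#' @param interface_radius interface radius in Angstrom (default 4.5).
#' @return a `sphere_template` with fields `sphere_id`
#'   (`"ligand_id.n_heavy.source_id"`), `structure` (the shell residues),
#'   `interface_keys`, `ligand`, `ns`, `source_sequence` and `kind`.
#' @export
build_sphere <- function(s, lig, shell_radius = 12.0, interface_radius = 4.5) {
  stopifnot(shell_radius >= interface_radius, interface_radius > 0)
  lxyz <- ligand_xyz(lig)
  if (nrow(lxyz) == 0) stop("invalid-ligand error: ligand has no heavy atoms")
  pk <- setdiff(polymer_keys(s), lig$source_residues)
  dmin <- min_dist_per_residue(heavy_atoms(s, pk), lxyz)
  shell_keys <- names(dmin)[dmin <= shell_radius]
  if (length(shell_keys) == 0)
    stop("degenerate-sphere error: no residue within ", shell_radius,
         " A of ligand ", lig$ligand_id)
  interface_keys <- names(dmin)[dmin <= interface_radius]
  shell <- subset_structure(s, shell_keys, struct_id = s$struct_id)
  structure(list(
    sphere_id = sprintf("%s.%d.%s", lig$ligand_id, lig$n_heavy, s$struct_id),
    structure = shell,
    interface_keys = interface_keys,
    ligand = lig,
    ns = length(shell_keys),
    source_sequence = chain_sequence(s),
    source_id = s$struct_id,
    kind = lig$kind), class = "sphere_template")
}

#' @export
print.sphere_template <- function(x, ...) {
  cat(sprintf("<sphere_template> %s: Ns=%d, interface=%d residues, ligand %s (%d heavy atoms)\n",
              x$sphere_id, x$ns, length(x$interface_keys),
              x$ligand$ligand_id, x$ligand$n_heavy))
  invisible(x)
}

sphere_keys <- function(sp) residue_table(sp$structure)$key

#' Build a sphere library from a set of complexes
#'
#' One template per (structure, ligand instance); ligand-free structures and
#' isolated ligands (degenerate spheres) contribute nothing, with a warning
#' for the latter.  Duplicate sphere ids are disambiguated with a numeric
#' suffix.
#'
#' @param complexes list of `ligsphere_structure` objects.
#' @param shell_radius,interface_radius passed to [build_sphere()].
#' @return a `sphere_library`: list with `entries` and an `index` data.frame
#'   (`sphere_id`, `ligand_id`, `n_heavy`, `ns`, `source_id`, `kind`).
#' @export
build_library <- function(complexes, shell_radius = 12.0, interface_radius = 4.5) {
  entries <- list()
  for (s in complexes) {
    for (lig in list_ligand_instances(s)) {
      sp <- tryCatch(build_sphere(s, lig, shell_radius, interface_radius),
                     error = function(e) {
                       warning("skipping degenerate sphere in ", s$struct_id,
                               ": ", conditionMessage(e), call. = FALSE)
                       NULL
                     })
      if (!is.null(sp)) entries[[length(entries) + 1L]] <- sp
    }
  }
  ids <- vapply(entries, function(e) e$sphere_id, "")
  dup <- duplicated(ids)
  if (any(dup)) {
    warning("duplicate sphere ids disambiguated: ",
            paste(unique(ids[dup]), collapse = ", "), call. = FALSE)
    for (i in which(duplicated(ids) | duplicated(ids, fromLast = TRUE))) {
      k <- sum(ids[seq_len(i)] == ids[i])
      if (k > 1) {
        entries[[i]]$sphere_id <- sprintf("%s_%d", ids[i], k)
      }
    }
  }
  new_sphere_library(entries)
}

new_sphere_library <- function(entries) {
  index <- if (length(entries) == 0)
    data.frame(sphere_id = character(0), ligand_id = character(0),
               n_heavy = integer(0), ns = integer(0),
               source_id = character(0), kind = character(0))
  else do.call(rbind, lapply(entries, function(e) data.frame(
    sphere_id = e$sphere_id, ligand_id = e$ligand$ligand_id,
    n_heavy = e$ligand$n_heavy, ns = e$ns, source_id = e$source_id,
    kind = e$kind, stringsAsFactors = FALSE)))
  rownames(index) <- NULL
  structure(list(entries = entries, index = index), class = "sphere_library")
}

#' @export
print.sphere_library <- function(x, ...) {
  cat(sprintf("<sphere_library> %d templates (%s)\n", length(x$entries),
              paste(sprintf("%s: %d", names(table(x$index$kind)),
                            table(x$index$kind)), collapse = ", ")))
  invisible(x)
}

#' Smith-Waterman local sequence identity
#'
#' Local alignment with BLOSUM62, affine gaps (open 11, extend 1); identity
#' is 100 x identical positions / aligned columns of the local alignment.
#' When no positive-scoring local alignment exists the identity is 0 and the
#' result carries attribute `empty_alignment = TRUE`.
#'
#' @param query_seq,target_seq one-letter amino-acid sequences (X allowed).
#' @param gap_open,gap_extend affine gap penalties.
#' @return percent identity in `[0, 100]`.
#' @export
sw_identity <- function(query_seq, target_seq, gap_open = 11, gap_extend = 1) {
  if (!nzchar(query_seq) || !nzchar(target_seq))
    stop("invalid-input error: empty sequence")
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    query_seq, target_seq, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aligned <- nchar(as.character(Biostrings::pattern(pa)))
  if (aligned == 0 || Biostrings::score(pa) <= 0) {
    out <- 0
    attr(out, "empty_alignment") <- TRUE
    return(out)
  }
  Biostrings::pid(pa, type = "PID1")
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Preselect a library subset
#'
#' Filters templates by ligand attributes and/or sequence identity of the
#' template's source chain(s) to a query sequence, mirroring restricted-
#' library search protocols (e.g. exclude templates above 90% identity).
#'
#' @param lib a `sphere_library`.
#' @param max_seq_id,min_seq_id percent-identity bounds (require `query_seq`).
#' @param ligand_ids keep only these ligand component ids.
#' @param n_heavy_range length-2 numeric `[min, max]` heavy-atom range.
#' @param query_seq one-letter query sequence for the identity bounds.
#' @return the filtered `sphere_library`.
#' @export
preselect <- function(lib, max_seq_id = NULL, min_seq_id = NULL,
                      ligand_ids = NULL, n_heavy_range = NULL,
                      query_seq = NULL) {
  keep <- rep(TRUE, length(lib$entries))
  if (!is.null(n_heavy_range)) {
    if (n_heavy_range[1] > n_heavy_range[2])
      stop("invalid-criteria error: n_heavy_range min > max")
    keep <- keep & lib$index$n_heavy >= n_heavy_range[1] &
      lib$index$n_heavy <= n_heavy_range[2]
  }
  if (!is.null(min_seq_id) && !is.null(max_seq_id) && min_seq_id > max_seq_id)
    stop("invalid-criteria error: min_seq_id > max_seq_id")
  if (!is.null(ligand_ids))
    keep <- keep & lib$index$ligand_id %in% ligand_ids
  if (!is.null(max_seq_id) || !is.null(min_seq_id)) {
    if (is.null(query_seq))
      stop("invalid-criteria error: sequence-identity bounds require query_seq")
    ids <- vapply(lib$entries, function(e)
      as.numeric(sw_identity(query_seq, e$source_sequence)), 0)
    if (!is.null(max_seq_id)) keep <- keep & ids <= max_seq_id
    if (!is.null(min_seq_id)) keep <- keep & ids >= min_seq_id
  }
  new_sphere_library(lib$entries[keep])
}

#' Persist / load a sphere library
#'
#' The library directory holds one PDB file per sphere (shell residues plus
#' the ligand as HETATM records) and a tab-separated `index.tsv` with the
#' template metadata and source sequences.
#'
#' @param lib a `sphere_library`.
#' @param dir library directory.
#' @return `dir` (write) or a `sphere_library` (read).
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- lib$index
  idx$file <- paste0(gsub("[^A-Za-z0-9._-]", "_", idx$sphere_id), ".pdb")
  idx$interface_keys <- vapply(lib$entries, function(e)
    paste(e$interface_keys, collapse = ","), "")
  idx$ligand_keys <- vapply(lib$entries, function(e)
    paste(e$ligand$source_residues, collapse = ","), "")
  idx$source_sequence <- vapply(lib$entries, function(e) e$source_sequence, "")
  for (i in seq_along(lib$entries)) {
    e <- lib$entries[[i]]
    write_structure(e$structure, file.path(dir, idx$file[i]),
                    extra_atoms = e$ligand$atoms)
  }
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  if (!file.exists(idx_path)) stop("input path not found: ", idx_path)
  idx <- utils::read.table(idx_path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  entries <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    s <- read_structure(file.path(dir, idx$file[i]), format = "pdb",
                        struct_id = idx$source_id[i])
    lig_keys <- strsplit(idx$ligand_keys[i], ",", fixed = TRUE)[[1]]
    lig_atoms <- s$atoms[s$atoms$key %in% lig_keys, , drop = FALSE]
    lig <- new_ligand_instance(idx$ligand_id[i], idx$kind[i], lig_atoms,
                               lig_keys, source_id = idx$source_id[i])
    shell <- subset_structure(s, setdiff(residue_table(s)$key, lig_keys),
                              struct_id = idx$source_id[i])
    entries[[i]] <- structure(list(
      sphere_id = idx$sphere_id[i], structure = shell,
      interface_keys = strsplit(idx$interface_keys[i], ",", fixed = TRUE)[[1]],
      ligand = lig, ns = nrow(residue_table(shell)),
      source_sequence = idx$source_sequence[i],
      source_id = idx$source_id[i], kind = idx$kind[i]),
      class = "sphere_template")
  }
  new_sphere_library(entries)
}
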