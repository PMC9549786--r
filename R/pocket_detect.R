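#' Transplant a ligand by a rigid transform
#'
#' Maps every ligand atom by the alignment transform; the ligand's internal
#' conformation is untouched (no docking, minimisation or relaxation).
#'
#' @param t a `rigid_transform` (sphere onto query frame).
#' @param lig a `ligand_instance`.
#' @return the ligand atom data.frame with transformed coordinates.
#' @export
transplant_ligand <- function(t, lig) {
  at <- lig$atoms
  xyz <- apply_transform(t, as.matrix(at[, c("x", "y", "z")]))
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at
}

#' Contact and clash residues of a transplanted ligand
#'
#' A contact residue has at least one heavy atom within `contact_cutoff`
#' (inclusive) of any ligand heavy atom; a clash residue has a heavy atom
#' strictly closer than `clash_cutoff`.  Both are counted per residue, so
#' multiple clashing atoms within one residue count once.
#'
#' @param query a `ligsphere_structure`.
#' @param ligand_coords ligand atom data.frame (e.g. from
#'   [transplant_ligand()]) or an n x 3 heavy-atom matrix.
#' @param contact_cutoff contact distance in Angstrom (default 4.5).
#' @param clash_cutoff clash distance in Angstrom (default 1.0, exclusive).
#' @return list with `contact_keys`, `n4`, `clash_keys`, `cl`.
#' @export
contacts_and_clashes <- function(query, ligand_coords, contact_cutoff = 4.5,
                                 clash_cutoff = 1.0) {
  lxyz <- if (is.matrix(ligand_coords)) ligand_coords
          else as.matrix(ligand_coords[!(toupper(ligand_coords$element) %in% c("H", "D")),
                                       c("x", "y", "z"), drop = FALSE])
  if (nrow(lxyz) == 0) stop("invalid-ligand error: no ligand coordinates")
  prot <- heavy_atoms(query, polymer_keys(query))
  dmin <- min_dist_per_residue(prot, lxyz)
  contact_keys <- names(dmin)[dmin <= contact_cutoff]
  clash_keys <- names(dmin)[dmin < clash_cutoff]
  list(contact_keys = contact_keys, n4 = length(contact_keys),
       clash_keys = clash_keys, cl = length(clash_keys))
}

#' Evaluate an alignment into a pocket match
#'
#' Transplants the template ligand by the alignment transform, computes the
#' contact (N4) and clash (cl) statistics and the all/core ligand centroids,
#' and applies the acceptance and high-confidence filters.
#'
#' @param sphere a `sphere_template`.
#' @param query a `ligsphere_structure`.
#' @param alignment an `alignment_result` from [structural_align()].
#' @param config a [default_config()] list.
#' @return a `pocket_match`.
#' @export
evaluate_match <- function(sphere, query, alignment,
                           config = default_config()) {
  lig_atoms <- transplant_ligand(alignment$transform, sphere$ligand)
  cc <- contacts_and_clashes(query, lig_atoms, config$contact_cutoff,
                             config$clash_cutoff)
  lxyz <- as.matrix(lig_atoms[!lig_atoms$hyd, c("x", "y", "z"), drop = FALSE])
  centroid_all <- colMeans(lxyz)
  centroid_core <- tryCatch(
    ligand_centroid(lig_atoms, mode = "core", query = query,
                    min_neighbors = config$burial_min_neighbors,
                    radius = config$burial_radius),
    error = function(e) NULL)
  acc <- passes_filters(alignment$nc, alignment$gdc, cc$n4, cc$cl, config)
  hc <- high_confidence(alignment$nc, alignment$gdc, cc$n4, cc$cl, config)
  structure(list(
    sphere_id = sphere$sphere_id, ligand_id = sphere$ligand$ligand_id,
    alignment = alignment, ligand_coords = lig_atoms,
    contact_keys = cc$contact_keys, n4 = cc$n4,
    clash_keys = cc$clash_keys, cl = cc$cl,
    centroid_all = centroid_all, centroid_core = centroid_core,
    accepted = acc, high_confidence = hc), class = "pocket_match")
}

#' @export
print.pocket_match <- function(x, ...) {
  cat(sprintf("<pocket_match> %s: Nc=%d, GDC=%.1f, N4=%d, cl=%d -> %s%s\n",
              x$sphere_id, x$alignment$nc, x$alignment$gdc, x$n4, x$cl,
              if (x$accepted) "accepted" else "rejected",
              if (x$high_confidence) " (high confidence)" else ""))
  invisible(x)
}

#' Detect binding pockets in a query structure
#'
#' Aligns every library template onto the query, transplants its ligand and
#' applies the acceptance filters.  Accepted matches are returned sorted by
#' GDC (descending), then Nc (descending), then RMSD (ascending).
#'
#' @param query a `ligsphere_structure` (>= 10 residues).
#' @param lib a `sphere_library`.
#' @param config a [default_config()] list.
#' @param keep_rejected also return rejected matches (attribute `rejected`).
#' @param align_params overrides for the alignment search parameters.
#' @return list of accepted `pocket_match` objects; with
#'   `keep_rejected = TRUE` the rejected ones are attached as an attribute.
#' @export
detect_pockets <- function(query, lib, config = default_config(),
                           keep_rejected = FALSE, align_params = list()) {
  if (length(polymer_keys(query)) < 10)
    stop("query must have at least 10 polymer residues")
  if (length(lib$entries) == 0) {
    warning("empty sphere library; no pockets to detect")
    return(list())
  }
  ap <- utils::modifyList(list(conserved_cutoff = config$conserved_cutoff),
                          align_params)
  matches <- lapply(lib$entries, function(sp) {
    al <- tryCatch(structural_align(sp, query, unit = config$unit, params = ap),
                   error = function(e) empty_alignment(sp, config$unit))
    evaluate_match(sp, query, al, config)
  })
  acc <- vapply(matches, function(m) isTRUE(m$accepted), TRUE)
  sort_matches <- function(ms) {
    if (length(ms) == 0) return(ms)
    ord <- order(-vapply(ms, function(m) m$alignment$gdc, 0),
                 -vapply(ms, function(m) m$alignment$nc, 0L),
                 vapply(ms, function(m) {
                   r <- m$alignment$rmsd; if (is.na(r)) Inf else r
                 }, 0))
    ms[ord]
  }
  out <- sort_matches(matches[acc])
  if (keep_rejected) attr(out, "rejected") <- sort_matches(matches[!acc])
  out
}

#' Tabulate pocket matches
#'
#' One row per match with the reported statistics: sphere id, Ns, RMSD, Nc,
#' SeqID, LGA_S, GDC, N4, cl, accepted/high-confidence flags, the contact
#' residue list and the transplanted-ligand centroid.
#'
#' @param matches list of `pocket_match` objects.
#' @param cluster_summary optional output of [summarize_clusters()] merged in.
#' @return data.frame.
#' @export
match_table <- function(matches, cluster_summary = NULL) {
  if (length(matches) == 0)
    return(data.frame(sphere_id = character(0), ligand_id = character(0),
                      ns = integer(0), rmsd = numeric(0), nc = integer(0),
                      seq_id = numeric(0), lga_s = numeric(0), gdc = numeric(0),
                      n4 = integer(0), cl = integer(0), accepted = logical(0),
                      high_confidence = logical(0), contacts = character(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0)))
  tab <- do.call(rbind, lapply(matches, function(m) data.frame(
    sphere_id = m$sphere_id, ligand_id = m$ligand_id,
    ns = m$alignment$ns, rmsd = m$alignment$rmsd, nc = m$alignment$nc,
    seq_id = m$alignment$seq_id, lga_s = m$alignment$lga_s,
    gdc = m$alignment$gdc, n4 = m$n4, cl = m$cl,
    accepted = m$accepted, high_confidence = m$high_confidence,
    contacts = paste(m$contact_keys, collapse = ","),
    cx = m$centroid_all[1], cy = m$centroid_all[2], cz = m$centroid_all[3],
    stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  if (!is.null(cluster_summary))
    tab <- merge(tab, cluster_summary, by = "sphere_id", sort = FALSE)
  tab
}
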