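#' Ligand centroid (all-atom or buried core)
#'
#' `mode = "all"` is the unweighted mean of heavy-atom positions.
#' `mode = "core"` averages only buried atoms — those with at least
#' `min_neighbors` protein heavy atoms within `radius` — because exposed
#' parts of a ligand may adopt different orientations while the buried core
#' pose is conserved; when no atom qualifies the all-atom centroid is
#' returned with attribute `core_fallback = TRUE`.
#'
#' @param atoms ligand atom data.frame or n x 3 heavy-atom matrix.
#' @param mode `"all"` or `"core"`.
#' @param query the `ligsphere_structure` providing the protein context
#'   (required for `mode = "core"`).
#' @param min_neighbors,radius burial rule parameters.
#' @return length-3 centroid vector.
#' @export
ligand_centroid <- function(atoms, mode = c("all", "core"), query = NULL,
                            min_neighbors = 10, radius = 5.0) {
  mode <- match.arg(mode)
  xyz <- if (is.matrix(atoms)) atoms
         else as.matrix(atoms[!(toupper(atoms$element) %in% c("H", "D")),
                              c("x", "y", "z"), drop = FALSE])
  if (nrow(xyz) == 0) stop("invalid-ligand error: zero heavy atoms")
  if (mode == "all") return(colMeans(xyz))
  if (is.null(query)) stop("mode = 'core' requires the query structure")
  prot <- heavy_atoms(query, polymer_keys(query))
  if (nrow(prot) == 0) stop("mode = 'core' requires protein context")
  d <- cross_dist(xyz, as.matrix(prot[, c("x", "y", "z")]))
  buried <- rowSums(d <= radius) >= min_neighbors
  if (!any(buried)) {
    out <- colMeans(xyz)
    attr(out, "core_fallback") <- TRUE
    return(out)
  }
  colMeans(xyz[buried, , drop = FALSE])
}

#' Construct a minimal pocket match from tabulated statistics
#'
#' Builds a `pocket_match` carrying just the fields the clustering and
#' summary stages use; lets match tables written by `detect` be re-clustered
#' without the full alignment objects.
#'
#' @param sphere_id,ligand_id identifiers.
#' @param contact_keys character vector of contact residue keys.
#' @param centroid length-3 all-atom ligand centroid.
#' @param gdc,nc,rmsd,seq_id,lga_s,ns,n4,cl optional statistics.
#' @param accepted,high_confidence filter flags.
#' @return a `pocket_match`.
#' @export
match_stub <- function(sphere_id, ligand_id = sphere_id, contact_keys,
                       centroid, gdc = 0, nc = 0L, rmsd = NA_real_,
                       seq_id = 0, lga_s = 0, ns = 0L,
                       n4 = length(contact_keys), cl = 0L,
                       accepted = TRUE, high_confidence = FALSE) {
  structure(list(
    sphere_id = sphere_id, ligand_id = ligand_id,
    alignment = list(ns = ns, nc = nc, rmsd = rmsd, seq_id = seq_id,
                     lga_s = lga_s, gdc = gdc),
    ligand_coords = NULL, contact_keys = contact_keys, n4 = n4,
    clash_keys = character(0), cl = cl,
    centroid_all = as.numeric(centroid), centroid_core = NULL,
    accepted = accepted, high_confidence = high_confidence),
    class = "pocket_match")
}

# Overlap coefficient |A and B| / min(|A|, |B|); optionally Jaccard.
contact_overlap <- function(a, b, method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) return(0)
  inter <- length(intersect(a, b))
  if (method == "overlap") inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

#' Merge pocket matches into consensus clusters
#'
#' Two matches are linked when their predicted contact-residue sets overlap
#' by more than `overlap_frac` (overlap coefficient, intersection over the
#' smaller set) or their transplanted-ligand centroids lie within
#' `centroid_cutoff`; clusters are the connected components of this graph
#' (single-linkage transitive closure).  Cluster ids are assigned by
#' descending member count, ties broken by descending best GDC.
#'
#' @param matches list of `pocket_match` objects against one query.
#' @param overlap_frac contact-set overlap threshold (strict `>`).
#' @param centroid_cutoff centroid distance threshold in Angstrom
#'   (inclusive), on all-heavy-atom centroids.
#' @param overlap_method `"overlap"` (default) or `"jaccard"`.
#' @return list of `pocket_cluster` objects with `cluster_id`, `members`,
#'   `nm`, `nlig`, `nres`, `consensus_keys` and `representative`.
#' @export
cluster_matches <- function(matches, overlap_frac = 0.80,
                            centroid_cutoff = 2.0,
                            overlap_method = "overlap") {
  n <- length(matches)
  if (n == 0) return(list())
  cent <- do.call(rbind, lapply(matches, function(m) m$centroid_all))
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    cd <- cross_dist(cent, cent)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ov <- contact_overlap(matches[[i]]$contact_keys,
                              matches[[j]]$contact_keys, overlap_method)
        if (ov > overlap_frac || cd[i, j] <= centroid_cutoff)
          edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(seq_len(n), comp), function(ii) {
    mem <- matches[ii]
    gdcs <- vapply(mem, function(m) m$alignment$gdc, 0)
    keys <- unique(unlist(lapply(mem, function(m) m$contact_keys)))
    structure(list(
      cluster_id = NA_integer_, members = mem, nm = length(mem),
      nlig = length(unique(vapply(mem, function(m) m$ligand_id, ""))),
      nres = length(keys), consensus_keys = keys,
      representative = mem[[which.max(gdcs)]], max_gdc = max(gdcs)),
      class = "pocket_cluster")
  })
  ord <- order(-vapply(clusters, function(cl) cl$nm, 0L),
               -vapply(clusters, function(cl) cl$max_gdc, 0))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i
  clusters
}

#' @export
print.pocket_cluster <- function(x, ...) {
  cat(sprintf("<pocket_cluster> #%d: Nm=%d, Nlig=%d, Nres=%d (best GDC %.1f)\n",
              x$cluster_id, x$nm, x$nlig, x$nres, x$max_gdc))
  invisible(x)
}

#' Summary table of pocket clusters
#'
#' One row per member match, grouped by cluster, carrying the match
#' statistics plus the cluster summary (Nm members, Nlig distinct ligands,
#' Nres residues in the consensus contact union).
#'
#' @param clusters list of `pocket_cluster` objects.
#' @return data.frame.
#' @export
summarize_clusters <- function(clusters) {
  if (length(clusters) == 0)
    return(data.frame(cluster_id = integer(0), nm = integer(0),
                      nlig = integer(0), nres = integer(0),
                      consensus = character(0), sphere_id = character(0)))
  out <- do.call(rbind, lapply(clusters, function(cl) {
    mt <- match_table(cl$members)
    cbind(data.frame(cluster_id = cl$cluster_id, nm = cl$nm, nlig = cl$nlig,
                     nres = cl$nres,
                     consensus = paste(sort(cl$consensus_keys), collapse = ","),
                     stringsAsFactors = FALSE)[rep(1, nrow(mt)), , drop = FALSE],
          mt)
  }))
  rownames(out) <- NULL
  out
}
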