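#' Map residues between two family members by sequence alignment
#'
#' Global (Needleman-Wunsch) alignment of the observed-residue sequences;
#' returns the correspondence between residue keys so that contact sets from
#' different family members can be pooled in one reference frame.  Unaligned
#' positions are surfaced as NA rows, never silently dropped.
#'
#' @param s_from,s_to `ligsphere_structure` objects.
#' @return data.frame with columns `from_key`, `to_key` (NA where a residue
#'   has no counterpart).
#' @export
map_residues <- function(s_from, s_to) {
  keys_f <- polymer_keys(s_from); keys_t <- polymer_keys(s_to)
  seq_f <- chain_sequence(s_from); seq_t <- chain_sequence(s_to)
  pa <- Biostrings::pairwiseAlignment(
    seq_f, seq_t, type = "global", substitutionMatrix = get_blosum62(),
    gapOpening = 11, gapExtension = 1)
  pf <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  pt <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  i <- 0L; j <- 0L
  out <- data.frame(from_key = character(0), to_key = character(0))
  for (k in seq_along(pf)) {
    fi <- pf[k] != "-"; tj <- pt[k] != "-"
    if (fi) i <- i + 1L
    if (tj) j <- j + 1L
    out <- rbind(out, data.frame(
      from_key = if (fi) keys_f[i] else NA_character_,
      to_key = if (tj) keys_t[j] else NA_character_,
      stringsAsFactors = FALSE))
  }
  out
}

#' Build a unified binding site (UBS) reference
#'
#' The UBS of a protein family is the union of all residues contacted
#' (4.5 Angstrom, heavy atoms) by any bound ligand across the family
#' members, expressed in the residue frame of the first member.
#'
#' @param members list of lists, each with `structure` (holo
#'   `ligsphere_structure`) and optionally `ligands` (list of
#'   `ligand_instance`; defaults to all instances of the structure).
#' @param contact_cutoff contact distance (default 4.5).
#' @return a `ubs_reference` with `family_id`, `member_ids` and `ubs_keys`.
#' @param family_id label for the family.
#' @export
build_ubs <- function(members, family_id = "family", contact_cutoff = 4.5) {
  ref <- members[[1]]$structure
  all_keys <- character(0)
  any_lig <- FALSE
  for (m in members) {
    s <- m$structure
    ligs <- if (!is.null(m$ligands)) m$ligands else list_ligand_instances(s)
    if (length(ligs) == 0) next
    any_lig <- TRUE
    mapping <- if (identical(s$struct_id, ref$struct_id)) NULL
               else map_residues(s, ref)
    for (lig in ligs) {
      cc <- contacts_and_clashes(s, ligand_xyz(lig),
                                 contact_cutoff = contact_cutoff)
      keys <- cc$contact_keys
      if (!is.null(mapping)) {
        keys <- mapping$to_key[match(keys, mapping$from_key)]
        keys <- keys[!is.na(keys)]
      }
      all_keys <- union(all_keys, keys)
    }
  }
  if (!any_lig) stop("empty-reference error: no ligand in any family member")
  structure(list(family_id = family_id,
                 member_ids = vapply(members, function(m) m$structure$struct_id, ""),
                 ubs_keys = all_keys), class = "ubs_reference")
}

#' Confusion counts of a binding-residue prediction
#'
#' @param predicted character vector of predicted residue keys (subset of
#'   `universe`).
#' @param ubs a `ubs_reference` or character vector of reference keys.
#' @param universe all residue keys of the scored structure.
#' @return named list `tp`, `fp`, `tn`, `fn` (restricted to the universe).
#' @export
confusion_counts <- function(predicted, ubs, universe) {
  ref <- if (inherits(ubs, "ubs_reference")) ubs$ubs_keys else ubs
  predicted <- intersect(predicted, universe)
  ref <- intersect(ref, universe)
  tp <- length(intersect(predicted, ref))
  fp <- length(setdiff(predicted, ref))
  fn <- length(setdiff(ref, predicted))
  tn <- length(universe) - tp - fp - fn
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Matthews correlation coefficient and F score
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and
#' `F = 2*TP / (2*TP + FP + FN)`.  When a denominator factor is zero the
#' statistic is reported as 0 with attribute `undefined = TRUE`.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (from
#'   [confusion_counts()]).
#' @return list with `mcc` and `f`.
#' @export
mcc_f <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) {
    out <- 0; attr(out, "undefined") <- TRUE; out
  } else (tp * tn - fp * fn) / sqrt(den)
  fden <- 2 * tp + fp + fn
  f <- if (fden == 0) {
    out <- 0; attr(out, "undefined") <- TRUE; out
  } else 2 * tp / fden
  list(mcc = mcc, f = f)
}

#' Score a predicted residue set against a UBS reference
#'
#' @inheritParams confusion_counts
#' @return an `eval_scores` list: the confusion counts plus `mcc` and `f`.
#' @export
eval_scores <- function(predicted, ubs, universe) {
  counts <- confusion_counts(predicted, ubs, universe)
  structure(c(counts, mcc_f(counts)), class = "eval_scores")
}

#' Pairwise pocket similarity
#'
#' Aligns pocket `b`'s sphere template onto pocket `a`'s 16-Angstrom region
#' and reports the score bundle plus the distance between the transplanted
#' ligand centroid and `a`'s native ligand centroid.
#'
#' @param a,b lists with `region` (a `ligsphere_structure` from
#'   [extract_region()]) and `sphere` (a `sphere_template`).
#' @param unit representative point for the alignment.
#' @param align_params alignment parameter overrides.
#' @return list with `gdc`, `lga_s`, `nc`, `rmsd`, `centroid_distance` and
#'   `feasible` flag.
#' @export
pocket_similarity <- function(a, b, unit = "CA", align_params = list()) {
  al <- tryCatch(structural_align(b$sphere, a$region, unit = unit,
                                  params = align_params),
                 error = function(e) NULL)
  if (is.null(al) || al$nc == 0)
    return(list(gdc = 0, lga_s = 0, nc = 0L, rmsd = NA_real_,
                centroid_distance = NA_real_, feasible = FALSE))
  moved <- transplant_ligand(al$transform, b$sphere$ligand)
  cb <- ligand_centroid(moved, "all")
  ca <- ligand_centroid(a$sphere$ligand$atoms, "all")
  list(gdc = al$gdc, lga_s = al$lga_s, nc = al$nc, rmsd = al$rmsd,
       centroid_distance = sqrt(sum((cb - ca)^2)), feasible = TRUE)
}

#' Exclusive clustering of pockets from a similarity table
#'
#' Single-linkage connected components over pairs with similarity at or
#' above the threshold; the similarity relation is symmetrised by the
#' maximum of the two directions.  Clusters are ordered by size, then by
#' best internal similarity, so the partition is deterministic.
#'
#' @param sim data.frame with columns `a`, `b` (pocket ids) and `gdc`.
#' @param threshold minimum GDC linking two pockets (default 70).
#' @param ids optional full id set (singletons for ids absent from `sim`).
#' @return list of character vectors, one per cluster.
#' @export
exclusive_cluster <- function(sim, threshold = 70, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(sim$a, sim$b)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  agg <- tapply(sim$gdc, key(sim$a, sim$b), max)   # symmetrise by max
  pairs <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  link <- !is.na(agg) & agg >= threshold & pairs[, 1] != pairs[, 2]
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  if (any(link))
    g <- igraph::add_edges(g, t(matrix(match(pairs[link, ], ids), ncol = 2)))
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(ids, comp), sort)
  best <- vapply(clusters, function(cl) {
    if (length(cl) == 1) return(-Inf)
    inside <- pairs[, 1] %in% cl & pairs[, 2] %in% cl
    if (!any(inside)) -Inf else max(agg[inside], na.rm = TRUE)
  }, 0)
  unname(clusters[order(-lengths(clusters), -best,
                        vapply(clusters, `[`, "", 1))])
}

#' Affinity concordance across similar pocket pairs
#'
#' Filters pocket pairs by similarity constraints (default: GDC >= 95 and
#' ligand centroids within 0.5 Angstrom; the relaxed protocol uses GDC >= 90
#' and 1.0 Angstrom) and computes the coefficient of determination and the
#' Spearman rank correlation between the two affinity vectors.  Affinities
#' are expected on a log scale (e.g. -log10 molar Kd or Ki); Kd and Ki
#' populations should never be mixed in one call.
#'
#' @param pairs data.frame with columns `gdc`, `centroid_distance`,
#'   `affinity_a`, `affinity_b`; self-comparisons and symmetry duplicates
#'   must already be removed.
#' @param min_gdc,max_centroid the similarity constraints.
#' @return list with `r2`, `spearman`, `n_pairs` and `undefined` flag (TRUE
#'   when fewer than 3 pairs survive).
#' @export
affinity_concordance <- function(pairs, min_gdc = 95, max_centroid = 0.5) {
  keep <- pairs$gdc >= min_gdc & pairs$centroid_distance <= max_centroid
  kept <- pairs[keep & !is.na(keep), , drop = FALSE]
  if (nrow(kept) < 3)
    return(list(r2 = NA_real_, spearman = NA_real_, n_pairs = nrow(kept),
                undefined = TRUE))
  r <- stats::cor(kept$affinity_a, kept$affinity_b)
  list(r2 = r^2,
       spearman = stats::cor(kept$affinity_a, kept$affinity_b,
                             method = "spearman"),
       n_pairs = nrow(kept), undefined = FALSE)
}
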