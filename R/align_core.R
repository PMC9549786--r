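# Sequence-independent local structural alignment of a sphere template onto
# a query structure.  The search is seeded from gapless fragment
# superpositions and refined by alternating correspondence assignment
# (chain-consistent, order-monotone mutual nearest neighbours) with
# re-superposition, in the spirit of local-global alignment methods; the
# candidate with the highest combined GDT/LCS score wins.

align_defaults <- function() {
  list(conserved_cutoff = 4.0,   # rep-point distance defining a conserved pair
       nn_cutoff = 6.0,          # assignment radius during refinement
       frag_len = 7L,            # gapless seed fragment length
       query_stride = 2L,        # query fragment stride (bounds seed count)
       max_seeds = 48L,          # refined seeds, best fragment RMSD first
       max_iter = 20L,           # refinement rounds per seed
       full_score_top = 6L,      # candidates scored with the full LGA_S
       gdt_thresholds = c(1, 2, 4, 8),
       lcs_cutoffs = c(1, 2, 5),
       gdt_weight = 0.75)
}

# longest strictly-increasing subsequence (indices), O(n^2); n is small
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  out <- integer(len[i])
  k <- len[i]
  while (i > 0L) { out[k] <- i; k <- k - 1L; i <- prev[i] }
  out
}

# Chain-consistent, order-monotone mutual nearest-neighbour assignment.
# sx: transformed sphere rep points; returns matrix of (s_idx, q_idx) pairs.
assign_pairs <- function(sx, q_xyz, s_chain, q_chain, cutoff) {
  D <- cross_dist(sx, q_xyz)
  nn_q <- max.col(-D, ties.method = "first")          # best query per sphere
  nn_s <- max.col(-t(D), ties.method = "first")       # best sphere per query
  s_idx <- seq_len(nrow(sx))
  keep <- nn_s[nn_q] == s_idx & D[cbind(s_idx, nn_q)] <= cutoff
  if (!any(keep)) return(cbind(integer(0), integer(0)))
  p <- cbind(s = s_idx[keep], q = nn_q[keep])
  grp <- paste(s_chain[p[, 1]], q_chain[p[, 2]])
  out <- lapply(split(seq_len(nrow(p)), grp), function(ii) {
    pp <- p[ii, , drop = FALSE]
    pp <- pp[order(pp[, 1]), , drop = FALSE]
    pp[lis_indices(pp[, 2]), , drop = FALSE]
  })
  p <- do.call(rbind, out)
  p[order(p[, 1]), , drop = FALSE]
}

# contiguous single-chain fragment start positions
fragment_starts <- function(chain, len, stride = 1L) {
  n <- length(chain)
  if (n < len) return(integer(0))
  st <- seq.int(1L, n - len + 1L, by = stride)
  st[vapply(st, function(i) all(chain[i:(i + len - 1L)] == chain[i]), TRUE)]
}

#' Residue-level structure similarity score (GDT + LCS combination)
#'
#' Scores a set of aligned residue pairs: the GDT component is, for each
#' distance threshold, the maximal fraction of pairs superposable within the
#' threshold (iteratively refined superpositions), averaged over the
#' threshold set; the LCS component is the longest continuous aligned
#' segment fitting under each RMSD cutoff, as a fraction, averaged over the
#' cutoffs.  The combined score is `100 * (w * GDT + (1 - w) * LCS)`.
#'
#' @param ref,mov n x 3 matched coordinate matrices (reference and mobile).
#' @param transform optional `rigid_transform` giving the starting
#'   superposition of `mov` (identity when NULL).
#' @param gdt_thresholds,lcs_cutoffs distance (A) and RMSD (A) threshold sets.
#' @param weight weight of the GDT component.
#' @param n_ref denominator for all fractions (defaults to the pair count;
#'   alignment searches pass the maximal alignable length instead so that
#'   short spurious alignments cannot saturate the score).
#' @return list with `lga_s` (0-100), `gdt_fractions`, `lcs_score` and
#'   `empty` flag.
#' @export
score_lga_s <- function(ref, mov, transform = NULL,
                        gdt_thresholds = c(1, 2, 4, 8),
                        lcs_cutoffs = c(1, 2, 5),
                        weight = 0.75, n_ref = NULL) {
  ref <- matrix(as.numeric(ref), ncol = 3)
  mov <- matrix(as.numeric(mov), ncol = 3)
  n <- nrow(ref)
  if (n == 0)
    return(list(lga_s = 0, gdt_fractions = setNames(rep(0, length(gdt_thresholds)),
                                                    gdt_thresholds),
                lcs_score = 0, empty = TRUE))
  if (is.null(n_ref)) n_ref <- n
  if (is.null(transform)) transform <- new_rigid_transform()
  mt <- apply_transform(transform, mov)

  gdt_fr <- vapply(gdt_thresholds, function(d) {
    d0 <- sqrt(rowSums((mt - ref)^2))
    best <- sum(d0 <= d)               # verified inliers under the given transform
    # refine superpositions seeded from the current inliers and from all pairs;
    # only distance-verified inlier sets ever count towards the fraction
    for (sup in list(which(d0 <= d), seq_len(n))) {
      seen <- character(0)
      for (it in 1:6) {
        if (length(sup) < 3) break
        sig <- paste(sup, collapse = ",")
        if (sig %in% seen) break
        seen <- c(seen, sig)
        fit <- tryCatch(kabsch_superpose(ref[sup, , drop = FALSE],
                                         mov[sup, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(fit)) break
        dd <- sqrt(rowSums((apply_transform(fit$transform, mov) - ref)^2))
        inl <- which(dd <= d)
        best <- max(best, length(inl))
        sup <- inl
      }
    }
    best / n_ref
  }, 0)

  # longest continuous aligned segment superposable under the RMSD cutoff;
  # segments need >= 3 residues to count (shorter windows fit trivially)
  lcs_fr <- vapply(lcs_cutoffs, function(cc) {
    if (n < 3L) return(n / n_ref)
    feasible <- function(L) {
      for (i in seq_len(n - L + 1L)) {
        w <- i:(i + L - 1L)
        if (superpose_rmsd(ref[w, , drop = FALSE], mov[w, , drop = FALSE]) <= cc)
          return(TRUE)
      }
      FALSE
    }
    if (!feasible(3L)) return(0)
    lo <- 3L; hi <- n
    if (feasible(n)) lo <- n
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (feasible(mid)) lo <- mid else hi <- mid - 1L
    }
    lo / n_ref
  }, 0)

  gdt_fr <- pmin(gdt_fr, 1); lcs_fr <- pmin(lcs_fr, 1)
  list(lga_s = 100 * (weight * mean(gdt_fr) + (1 - weight) * mean(lcs_fr)),
       gdt_fractions = setNames(gdt_fr, gdt_thresholds),
       lcs_score = 100 * mean(lcs_fr), empty = FALSE)
}

#' All-atom similarity score (GDC)
#'
#' For each conserved residue pair, heavy atoms are matched by identical
#' atom name; `f_i` is the fraction of matched atoms within `d_i = 0.5 * i`
#' Angstrom (i = 1..10) under the alignment transform, with atoms present in
#' only one residue of a pair counting as never-within.  The score is
#' `100 * sum(w_i * f_i) / sum(w_i)` with linear weights `w_i = 11 - i`, so
#' side-chain placement agreement is credited.
#'
#' @param sphere a `sphere_template`.
#' @param query a `ligsphere_structure`.
#' @param pairs data.frame with columns `sphere_key`, `query_key`.
#' @param transform the alignment `rigid_transform` (sphere onto query).
#' @return GDC score in `[0, 100]`.
#' @export
score_gdc <- function(sphere, query, pairs, transform) {
  if (NROW(pairs) == 0) return(0)
  sa <- heavy_atoms(sphere$structure)
  qa <- heavy_atoms(query)
  sxyz <- apply_transform(transform, as.matrix(sa[, c("x", "y", "z")]))
  n_total <- 0L
  d_matched <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    s_at <- which(sa$key == pairs$sphere_key[i])
    q_at <- which(qa$key == pairs$query_key[i])
    s_names <- sa$atom[s_at]; q_names <- qa$atom[q_at]
    n_total <- n_total + length(union(s_names, q_names))
    common <- intersect(s_names, q_names)
    if (length(common) == 0) next
    si <- s_at[match(common, s_names)]
    qi <- q_at[match(common, q_names)]
    d_matched <- c(d_matched,
                   sqrt(rowSums((sxyz[si, , drop = FALSE] -
                                 as.matrix(qa[qi, c("x", "y", "z")]))^2)))
  }
  if (n_total == 0L || length(d_matched) == 0L) {
    warning("no atom-name overlap between aligned residues; GDC = 0")
    return(0)
  }
  i <- 1:10
  f <- vapply(0.5 * i, function(d) sum(d_matched <= d) / n_total, 0)
  w <- 11 - i
  100 * sum(w * f) / sum(w)
}

#' Align a sphere template onto a query structure
#'
#' Sequence-independent local alignment on residue representative points
#' (C-alpha, or C-beta with C-alpha fallback for glycine).  Superpositions
#' are seeded from all gapless fragment pairs (length `frag_len`, query
#' stride `query_stride`), refined by alternating mutual-nearest-neighbour
#' assignment and re-superposition, and the candidate with the highest
#' GDT/LCS combined score is kept (ties: larger Nc, then lower RMSD).
#' Conserved pairs are those within `conserved_cutoff` under the final
#' transform; Nc, RMSD and SeqID are computed over them and GDC over their
#' heavy atoms.
#'
#' @param sphere a `sphere_template`.
#' @param query a `ligsphere_structure` with >= 3 representative points.
#' @param unit `"CA"` or `"CB"` representative point.
#' @param params named list overriding the alignment defaults
#'   (see `ligsphere:::align_defaults()`).
#' @return an `alignment_result` with `pairs`, `transform`, `nc`, `rmsd`,
#'   `seq_id`, `lga_s`, `gdt_fractions`, `lcs_score` and `gdc`.
#' @export
structural_align <- function(sphere, query, unit = c("CA", "CB"),
                             params = list()) {
  unit <- match.arg(unit)
  p <- utils::modifyList(align_defaults(), params)
  S <- rep_points(sphere$structure, unit)
  Q <- rep_points(query, unit)
  nS <- length(S$keys); nQ <- length(Q$keys)
  if (nS < 3 || nQ < 3)
    stop("alignment-infeasible error: fewer than 3 representative points")
  n_ref <- min(nS, nQ)

  # --- seeds: gapless fragment superpositions ---
  L <- min(p$frag_len, nS, nQ)
  s_starts <- fragment_starts(S$chain, L, 1L)
  q_starts <- fragment_starts(Q$chain, L, p$query_stride)
  seeds <- list()
  if (length(s_starts) > 0 && length(q_starts) > 0) {
    grid <- expand.grid(i = s_starts, j = q_starts)
    rms <- vapply(seq_len(nrow(grid)), function(k) {
      i <- grid$i[k]; j <- grid$j[k]
      superpose_rmsd(Q$xyz[j:(j + L - 1L), , drop = FALSE],
                     S$xyz[i:(i + L - 1L), , drop = FALSE])
    }, 0)
    ord <- order(rms)[seq_len(min(p$max_seeds, nrow(grid)))]
    seeds <- lapply(ord, function(k) {
      i <- grid$i[k]; j <- grid$j[k]
      kabsch_superpose(Q$xyz[j:(j + L - 1L), , drop = FALSE],
                       S$xyz[i:(i + L - 1L), , drop = FALSE])$transform
    })
  }

  # --- refinement: alternate assignment / re-superposition ---
  cands <- list(); sigs <- character(0)
  for (tf in seeds) {
    pr <- NULL
    for (it in seq_len(p$max_iter)) {
      sx <- apply_transform(tf, S$xyz)
      pp <- assign_pairs(sx, Q$xyz, S$chain, Q$chain, p$nn_cutoff)
      if (nrow(pp) < 3) { pr <- NULL; break }
      if (!is.null(pr) && nrow(pp) == nrow(pr) && all(pp == pr)) break
      pr <- pp
      tf <- kabsch_superpose(Q$xyz[pp[, 2], , drop = FALSE],
                             S$xyz[pp[, 1], , drop = FALSE])$transform
    }
    if (is.null(pr)) next
    sig <- paste(pr[, 1], pr[, 2], sep = ">", collapse = ";")
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    cands[[length(cands) + 1L]] <- list(tf = tf, pairs = pr)
  }
  if (length(cands) == 0) return(empty_alignment(sphere, unit))

  # --- rank cheaply, then full GDT/LCS scoring of the best few ---
  cheap <- vapply(cands, function(cd) {
    d <- sqrt(rowSums((apply_transform(cd$tf, S$xyz[cd$pairs[, 1], , drop = FALSE]) -
                       Q$xyz[cd$pairs[, 2], , drop = FALSE])^2))
    mean(vapply(p$gdt_thresholds, function(th) sum(d <= th), 0)) / n_ref
  }, 0)
  top <- order(-cheap)[seq_len(min(p$full_score_top, length(cands)))]
  scored <- lapply(top, function(k) {
    cd <- cands[[k]]
    sc <- score_lga_s(Q$xyz[cd$pairs[, 2], , drop = FALSE],
                      S$xyz[cd$pairs[, 1], , drop = FALSE],
                      transform = cd$tf,
                      gdt_thresholds = p$gdt_thresholds,
                      lcs_cutoffs = p$lcs_cutoffs,
                      weight = p$gdt_weight, n_ref = n_ref)
    d <- sqrt(rowSums((apply_transform(cd$tf, S$xyz[cd$pairs[, 1], , drop = FALSE]) -
                       Q$xyz[cd$pairs[, 2], , drop = FALSE])^2))
    conserved <- d <= p$conserved_cutoff
    list(cand = cd, score = sc, nc = sum(conserved),
         rmsd = if (any(conserved)) sqrt(mean(d[conserved]^2)) else Inf)
  })
  ord <- order(-vapply(scored, function(x) x$score$lga_s, 0),
               -vapply(scored, function(x) x$nc, 0L),
               vapply(scored, function(x) x$rmsd, 0))
  best <- scored[[ord[1]]]

  # --- final statistics over conserved pairs ---
  pr <- best$cand$pairs
  tf <- best$cand$tf
  d <- sqrt(rowSums((apply_transform(tf, S$xyz[pr[, 1], , drop = FALSE]) -
                     Q$xyz[pr[, 2], , drop = FALSE])^2))
  cons <- which(d <= p$conserved_cutoff)
  if (length(cons) >= 3) {
    tf <- kabsch_superpose(Q$xyz[pr[cons, 2], , drop = FALSE],
                           S$xyz[pr[cons, 1], , drop = FALSE])$transform
    d <- sqrt(rowSums((apply_transform(tf, S$xyz[pr[, 1], , drop = FALSE]) -
                       Q$xyz[pr[, 2], , drop = FALSE])^2))
  }
  pairs_df <- data.frame(sphere_key = S$keys[pr[, 1]],
                         query_key = Q$keys[pr[, 2]],
                         dist = d, stringsAsFactors = FALSE)
  cons_df <- pairs_df[pairs_df$dist <= p$conserved_cutoff, , drop = FALSE]
  nc <- nrow(cons_df)
  rmsd <- if (nc > 0) sqrt(mean(cons_df$dist^2)) else NA_real_
  seq_id <- if (nc > 0)
    100 * mean(S$resname[pr[d <= p$conserved_cutoff, 1]] ==
               Q$resname[pr[d <= p$conserved_cutoff, 2]]) else 0
  gdc <- if (nc > 0) score_gdc(sphere, query, cons_df, tf) else 0
  structure(list(
    sphere_id = sphere$sphere_id, unit = unit, ns = sphere$ns,
    pairs = pairs_df, conserved = cons_df, transform = tf,
    nc = nc, rmsd = rmsd, seq_id = seq_id,
    lga_s = best$score$lga_s, gdt_fractions = best$score$gdt_fractions,
    lcs_score = best$score$lcs_score, gdc = gdc),
    class = "alignment_result")
}

empty_alignment <- function(sphere, unit) {
  structure(list(
    sphere_id = sphere$sphere_id, unit = unit, ns = sphere$ns,
    pairs = data.frame(sphere_key = character(0), query_key = character(0),
                       dist = numeric(0)),
    conserved = data.frame(sphere_key = character(0), query_key = character(0),
                           dist = numeric(0)),
    transform = new_rigid_transform(), nc = 0L, rmsd = NA_real_,
    seq_id = 0, lga_s = 0,
    gdt_fractions = setNames(rep(0, 4), c(1, 2, 4, 8)), lcs_score = 0,
    gdc = 0), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s (%s): Nc=%d/%d, RMSD=%.3f, SeqID=%.1f, LGA_S=%.1f, GDC=%.1f\n",
              x$sphere_id, x$unit, x$nc, x$ns,
              if (is.na(x$rmsd)) NA else x$rmsd, x$seq_id, x$lga_s, x$gdc))
  invisible(x)
}
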