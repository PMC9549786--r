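# Deterministic toy protein-ligand complexes, apo/homolog variants and decoy
# structures.  These stand in for experimentally solved complexes so that
# sphere construction, alignment, transplantation, filtering and evaluation
# are all testable offline.  Geometry is idealised: helical backbones carry
# N, CA, C, O and CB only (no full side chains), and the pseudo-ligand is a
# rigid cluster of carbon atoms planted in the bundle's central channel.

# amino-acid alphabet used by the generators; glycine excluded so every
# residue carries a CB side-chain representative
FIXTURE_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "HIS",
                "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
                "TRP", "TYR", "VAL")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic fixture
#'
#' @param n_res total residue count of the helix bundle (>= 30).
#' @param n_helices number of helices the residues are split across.
#' @param ligand_n_atoms heavy-atom count of the planted pseudo-ligand (>= 4).
#' @param noise_sigma per-atom Gaussian displacement (Angstrom) for variants.
#' @param mutate_frac fraction of residues whose type is substituted.
#' @param seed integer seed; identical specs give byte-identical output.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_res = 64L, n_helices = 4L, ligand_n_atoms = 12L,
                         noise_sigma = 0, mutate_frac = 0, seed = 1L) {
  stopifnot(n_res >= 30, ligand_n_atoms >= 4, noise_sigma >= 0,
            mutate_frac >= 0, mutate_frac <= 1)
  structure(list(n_res = as.integer(n_res), n_helices = as.integer(n_helices),
                 ligand_n_atoms = as.integer(ligand_n_atoms),
                 noise_sigma = noise_sigma, mutate_frac = mutate_frac,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A, 100 deg/residue,
# giving consecutive CA-CA distances of ~3.83 A.
helix_ca <- function(n, radius = 2.3, rise = 1.5, twist = 100 * pi / 180) {
  j <- seq_len(n) - 1
  cbind(radius * cos(j * twist), radius * sin(j * twist),
        rise * j - rise * (n - 1) / 2)
}

# Build backbone atoms around a CA trace.  `out_dir` gives the per-residue
# radial (side-chain) direction for CB placement.
backbone_atoms <- function(ca, out_dir, chain, resnames, start_resno = 1L) {
  n <- nrow(ca)
  t_prev <- rbind(ca[2, ] - ca[1, ], ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])
  t_next <- rbind(ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE], ca[n, ] - ca[n - 1, ])
  norm_rows <- function(m) m / sqrt(rowSums(m^2))
  t_prev <- norm_rows(t_prev); t_next <- norm_rows(t_next)
  out_dir <- norm_rows(out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nrm <- pracma_cross(t_next[i, ], out_dir[i, ])
    pos <- rbind(N  = ca[i, ] - 1.46 * t_prev[i, ],
                 CA = ca[i, ],
                 C  = ca[i, ] + 1.52 * t_next[i, ],
                 O  = ca[i, ] + 1.52 * t_next[i, ] + 1.23 * nrm,
                 CB = ca[i, ] + 1.53 * out_dir[i, ])
    rows[[i]] <- data.frame(
      chain = chain, resno = start_resno + i - 1L, icode = "",
      resname = resnames[i], atom = rownames(pos),
      element = c("N", "C", "C", "O", "C"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occ = 1, het = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rigid pseudo-ligand: seeded cluster of carbons within `radius` of the
# origin, pairwise spacing >= 1.2 A (rejection sampling).
ligand_cluster <- function(n_atoms, radius = 1.8, min_spacing = 1.2) {
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n_atoms) {
    p <- stats::runif(3, -radius, radius)
    if (sqrt(sum(p^2)) > radius) next
    if (nrow(pts) > 0 && min(cross_dist(matrix(p, 1), pts)) < min_spacing) next
    pts <- rbind(pts, p)
  }
  pts
}

#' Generate a toy holo complex with known ground truth
#'
#' Builds `n_helices` ideal alpha-helices arranged as a bundle around a
#' central channel (one continuous chain `A`, helix segments joined in
#' sequence), plants a rigid pseudo-ligand (component id `LIG`, chain `X`)
#' in the channel, and returns the exact 4.5-Angstrom contact residues as
#' ground truth.
#'
#' @param spec a [fixture_spec()].
#' @param bundle_radius distance of each helix axis from the channel axis.
#' @param ligand_radius radius of the ball the pseudo-ligand atoms fill.
#' @return list with `holo` (a `ligsphere_structure`), and `truth`: the
#'   planted `ligand_pose` (heavy-atom matrix), `contact_keys` (4.5 A) and
#'   the `ligand` instance.
#' @export
make_toy_complex <- function(spec = fixture_spec(), bundle_radius = 7.2,
                             ligand_radius = 2.4) {
  with_seed(spec$seed, {
    per <- floor(spec$n_res / spec$n_helices)
    counts <- rep(per, spec$n_helices)
    counts[spec$n_helices] <- spec$n_res - per * (spec$n_helices - 1)
    prot <- vector("list", spec$n_helices)
    start <- 1L
    for (h in seq_len(spec$n_helices)) {
      ca_local <- helix_ca(counts[h])
      phi <- 2 * pi * (h - 1) / spec$n_helices
      centre <- c(bundle_radius * cos(phi), bundle_radius * sin(phi), 0)
      ca <- sweep(ca_local, 2, centre, "+")
      out_dir <- cbind(ca_local[, 1], ca_local[, 2], 0)  # radially out of own axis
      resnames <- sample(FIXTURE_AA, counts[h], replace = TRUE)
      prot[[h]] <- backbone_atoms(ca, out_dir, "A", resnames,
                                  start_resno = start)
      start <- start + counts[h]
    }
    lig_xyz <- ligand_cluster(spec$ligand_n_atoms, radius = ligand_radius)
    lig <- data.frame(
      chain = "X", resno = 1L, icode = "", resname = "LIG",
      atom = sprintf("L%d", seq_len(spec$ligand_n_atoms)), element = "C",
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      occ = 1, het = TRUE, stringsAsFactors = FALSE)
    holo <- new_structure(rbind(do.call(rbind, prot), lig),
                          struct_id = sprintf("toy%d", spec$seed))
    ligs <- list_ligand_instances(holo)
    lig_inst <- ligs[[which(vapply(ligs, function(l) l$ligand_id, "") == "LIG")[1]]]
    # ground-truth 4.5 A contacts by direct distance scan
    prot_atoms <- heavy_atoms(holo, polymer_keys(holo))
    dmin <- min_dist_per_residue(prot_atoms, lig_xyz)
    truth_keys <- names(dmin)[dmin <= 4.5]
    list(holo = holo,
         truth = list(ligand_pose = lig_xyz, contact_keys = truth_keys,
                      ligand = lig_inst))
  })
}

#' Perturb a structure into an apo / homolog variant
#'
#' Adds i.i.d. Gaussian displacement to every atom, substitutes residue
#' types at a seeded random subset of polymer residues (the CB side-chain
#' representative is retained), and removes ligands to emulate an apo
#' conformation unless `retain_ligands` is set.
#'
#' @param s a `ligsphere_structure`.
#' @param noise_sigma displacement standard deviation per coordinate (A).
#' @param mutate_frac fraction of polymer residues substituted.
#' @param seed integer seed.
#' @param retain_ligands keep HETATM groups (default drops them).
#' @return a perturbed `ligsphere_structure`.
#' @export
perturb_structure <- function(s, noise_sigma = 0, mutate_frac = 0, seed = 1L,
                              retain_ligands = FALSE) {
  stopifnot(noise_sigma >= 0, mutate_frac >= 0, mutate_frac <= 1)
  with_seed(seed, {
    a <- s$atoms
    if (!retain_ligands) a <- a[!a$het, , drop = FALSE]
    if (noise_sigma > 0) {
      a$x <- a$x + stats::rnorm(nrow(a), 0, noise_sigma)
      a$y <- a$y + stats::rnorm(nrow(a), 0, noise_sigma)
      a$z <- a$z + stats::rnorm(nrow(a), 0, noise_sigma)
    }
    if (mutate_frac > 0) {
      keys <- unique(a$key[!a$het])
      n_mut <- round(mutate_frac * length(keys))
      if (n_mut > 0) {
        mut <- sample(keys, n_mut)
        for (k in mut) {
          cur <- a$resname[a$key == k][1]
          a$resname[a$key == k] <- sample(setdiff(FIXTURE_AA, cur), 1)
        }
      }
    }
    new_structure(a[, setdiff(names(a), c("hyd", "key"))],
                  struct_id = paste0(s$struct_id, "_v", seed),
                  source_format = s$source_format)
  })
}

#' Generate a decoy structure (negative control)
#'
#' Self-avoiding random-walk backbone with 3.8-Angstrom CA spacing and no
#' non-adjacent CA pair closer than 4.0 Angstrom; by construction it has no
#' concave binding channel.
#'
#' @param n_res residue count (>= 30).
#' @param seed integer seed.
#' @param max_turn maximum turn angle per step (radians).
#' @return a `ligsphere_structure` with chain `A`.
#' @export
make_decoy <- function(n_res = 60L, seed = 1L, max_turn = 1.2) {
  stopifnot(n_res >= 30)
  with_seed(seed, {
    step <- 3.8
    for (attempt in 1:200) {
      ca <- matrix(0, n_res, 3)
      dir <- rand_unit()
      ca[2, ] <- ca[1, ] + step * dir
      ok <- TRUE
      for (i in 3:n_res) {
        placed <- FALSE
        for (try in 1:60) {
          nd <- perturb_direction(dir, max_turn)
          cand <- ca[i - 1, ] + step * nd
          prev <- ca[seq_len(i - 2), , drop = FALSE]
          if (min(cross_dist(matrix(cand, 1), prev)) >= 4.0) {
            ca[i, ] <- cand; dir <- nd; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("generation error: self-avoiding walk failed")
    # outward direction: perpendicular component of a fixed random vector
    ref <- rand_unit()
    t_loc <- rbind(ca[2, ] - ca[1, ], ca[-1, , drop = FALSE] - ca[-n_res, , drop = FALSE])
    out_dir <- t(apply(t_loc, 1, function(tv) {
      v <- ref - sum(ref * tv) / sum(tv * tv) * tv
      if (sqrt(sum(v^2)) < 1e-8) v <- pracma_cross(tv, c(1, 0, 0))
      v
    }))
    resnames <- sample(FIXTURE_AA, n_res, replace = TRUE)
    new_structure(backbone_atoms(ca, out_dir, "A", resnames),
                  struct_id = sprintf("decoy%d", seed))
  })
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

perturb_direction <- function(dir, max_turn) {
  ang <- stats::runif(1, 0, max_turn)
  perp <- pracma_cross(dir, rand_unit())
  np <- sqrt(sum(perp^2))
  if (np < 1e-8) return(dir)
  perp <- perp / np
  nd <- cos(ang) * dir + sin(ang) * perp
  nd / sqrt(sum(nd^2))
}
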