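# Shared fixtures, cached per session so expensive alignments run once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy <- function(seed = 1L) {
  cached(paste0("toy", seed), make_toy_complex(fixture_spec(seed = seed)))
}

toy_sphere <- function(seed = 1L) {
  cached(paste0("sphere", seed), {
    tc <- toy(seed)
    build_sphere(tc$holo, tc$truth$ligand)
  })
}

toy_self_alignment <- function(seed = 1L) {
  cached(paste0("selfal", seed),
         structural_align(toy_sphere(seed), toy(seed)$holo))
}

# brute-force residue contact scan: all-pairs heavy-atom distances
brute_contacts <- function(s, lig_xyz, cutoff) {
  a <- s$atoms
  a <- a[!a$hyd & !a$het & !(a$resname %in% c("HOH", "WAT", "DOD")), ,
         drop = FALSE]
  keys <- unique(a$key)
  hit <- vapply(keys, function(k) {
    axyz <- as.matrix(a[a$key == k, c("x", "y", "z")])
    any(vapply(seq_len(nrow(axyz)), function(i)
      any(sqrt(colSums((t(lig_xyz) - axyz[i, ])^2)) <= cutoff), TRUE))
  }, TRUE)
  keys[hit]
}

# a tiny hand-built structure: residues at controlled distances from origin
point_structure <- function(dists, resname = "ALA", chain = "A") {
  rows <- lapply(seq_along(dists), function(i) data.frame(
    chain = chain, resno = i, icode = "", resname = resname,
    atom = "CA", element = "C", x = dists[i], y = 0.1 * i, z = 0,
    occ = 1, het = FALSE, stringsAsFactors = FALSE))
  new_structure(do.call(rbind, rows), struct_id = "points")
}

# minimal one-atom ligand instance at the origin
origin_ligand <- function() {
  at <- data.frame(chain = "X", resno = 1L, icode = "", resname = "LIG",
                   atom = "L1", element = "C", x = 0, y = 0, z = 0,
                   occ = 1, het = TRUE, stringsAsFactors = FALSE)
  at$hyd <- FALSE
  at$key <- residue_key(at$chain, at$resno, at$icode)
  ligsphere:::new_ligand_instance("LIG", "metal_or_ion", at, at$key[1])
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rigidly move every atom of a structure
transform_structure <- function(s, R, tvec) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + tvec[1]; a$y <- xyz[, 2] + tvec[2]; a$z <- xyz[, 3] + tvec[3]
  new_structure(a[, setdiff(names(a), c("hyd", "key"))], struct_id = s$struct_id,
                source_format = s$source_format)
}

minimal_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       2.000   2.500   0.800  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       3.200   3.300   1.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       4.400   2.600   1.700  1.00  0.00           C",
    "ATOM      7  N   SER A   3       5.500   3.300   2.000  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       6.700   2.700   2.600  1.00  0.00           C",
    "ATOM      9  C   SER A   3       7.900   3.600   2.900  1.00  0.00           C",
    "END", sep = "\n")
}
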