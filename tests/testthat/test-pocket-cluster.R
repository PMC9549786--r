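test_that("ligand_centroid computes all-atom and core means", {
  at <- data.frame(chain = "X", resno = 1L, icode = "", resname = "LIG",
                   atom = c("L1", "L2"), element = "C",
                   x = c(0, 2), y = 0, z = 0, occ = 1, het = TRUE,
                   stringsAsFactors = FALSE)
  expect_equal(unname(ligand_centroid(at, "all")), c(1, 0, 0))
  expect_error(ligand_centroid(at[0, ], "all"), "invalid-ligand")

  # fully buried ligand: core centroid equals the all-atom centroid.
  # Build a dense protein shell so every ligand atom has >= 10 heavy
  # protein atoms within 5 A.
  shell <- do.call(rbind, lapply(1:4, function(r) data.frame(
    chain = "A", resno = r, icode = "", resname = "ALA",
    atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = 3 * cos(r + 1:4), y = 3 * sin(r + 1:4), z = rep(c(-1, 1), 2),
    occ = 1, het = FALSE, stringsAsFactors = FALSE)))
  dense <- new_structure(shell, struct_id = "shell")
  c_all <- ligand_centroid(at, "all")
  c_core <- ligand_centroid(at, "core", query = dense)
  expect_equal(unname(c_core), unname(c_all), tolerance = 1e-9)
})

test_that("core centroid averages only buried atoms (burial oracle)", {
  tc <- toy(1)
  lig_at <- tc$truth$ligand$atoms
  # push half the atoms far outside the bundle so they lose protein neighbors
  out <- lig_at
  half <- seq_len(ceiling(nrow(out) / 2))
  out$x[half] <- out$x[half] + 60
  prot <- ligsphere:::heavy_atoms(tc$holo, ligsphere:::polymer_keys(tc$holo))
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  lxyz <- as.matrix(out[, c("x", "y", "z")])
  buried <- vapply(seq_len(nrow(lxyz)), function(i)
    sum(sqrt(colSums((t(pxyz) - lxyz[i, ])^2)) <= 5.0) >= 10, TRUE)
  expect_true(any(buried) && !all(buried))
  expect_equal(unname(ligand_centroid(out, "core", query = tc$holo)),
               unname(colMeans(lxyz[buried, , drop = FALSE])), tolerance = 1e-9)
})

test_that("exposed ligand falls back to the all-atom centroid with a flag", {
  at <- data.frame(chain = "X", resno = 1L, icode = "", resname = "LIG",
                   atom = c("L1", "L2"), element = "C",
                   x = c(500, 502), y = 0, z = 0, occ = 1, het = TRUE,
                   stringsAsFactors = FALSE)
  cc <- ligand_centroid(at, "core", query = toy(1)$holo)
  expect_true(isTRUE(attr(cc, "core_fallback")))
  expect_equal(unname(cc), c(501, 0, 0), ignore_attr = TRUE)
})

stub <- function(id, contacts, centroid, gdc = 80, lig = id) {
  match_stub(sphere_id = id, ligand_id = lig, contact_keys = contacts,
             centroid = centroid, gdc = gdc)
}

test_that("merge rules: contact overlap > 80% or centroids within 2.0 A", {
  keys <- residue_key("A", 1:10)
  # identical contact sets merge regardless of centroid distance
  cl <- cluster_matches(list(stub("a", keys[1:5], c(0, 0, 0)),
                             stub("b", keys[1:5], c(10, 0, 0))))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$nm, 2)
  # 50% overlap and 5 A apart: both criteria fail -> singletons
  cl2 <- cluster_matches(list(stub("a", keys[1:4], c(0, 0, 0)),
                              stub("b", keys[3:6], c(5, 0, 0))))
  expect_length(cl2, 2)
  # centroid rule alone merges at <= 2.0 A
  cl3 <- cluster_matches(list(stub("a", keys[1:4], c(0, 0, 0)),
                              stub("b", keys[6:9], c(2.0, 0, 0))))
  expect_length(cl3, 1)
})

test_that("merging is transitive across mixed criteria", {
  keys <- residue_key("A", 1:20)
  # A-B share >80% contacts; B-C centroids 1.5 A apart; A-C unrelated
  A <- stub("A", keys[1:10], c(0, 0, 0))
  B <- stub("B", keys[1:9], c(40, 0, 0))     # overlap 9/9 = 100% with A
  C <- stub("C", keys[15:20], c(41.5, 0, 0))
  cl <- cluster_matches(list(A, B, C))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$nm, 3)
})

test_that("clustering is a partition and idempotent", {
  set.seed(77)
  keys <- residue_key("A", 1:40)
  ms <- lapply(1:12, function(i)
    stub(paste0("m", i), sample(keys, 6), rnorm(3, sd = 6), gdc = 55 + i))
  cl <- cluster_matches(ms)
  ids <- unlist(lapply(cl, function(c) vapply(c$members, function(m) m$sphere_id, "")))
  expect_setequal(ids, paste0("m", 1:12))
  expect_equal(length(ids), 12)   # every match in exactly one cluster
  # idempotence: re-clustering cluster representatives of singletonized
  # clusters reproduces the same partition
  reps <- lapply(cl, function(c) c$representative)
  cl2 <- cluster_matches(reps)
  expect_length(cl2, length(cl))
})

test_that("tightening thresholds never decreases the cluster count", {
  set.seed(78)
  keys <- residue_key("A", 1:30)
  ms <- lapply(1:10, function(i)
    stub(paste0("m", i), sample(keys, 8), rnorm(3, sd = 3)))
  base <- length(cluster_matches(ms, overlap_frac = 0.80, centroid_cutoff = 2.0))
  expect_gte(length(cluster_matches(ms, overlap_frac = 0.95,
                                    centroid_cutoff = 2.0)), base)
  expect_gte(length(cluster_matches(ms, overlap_frac = 0.80,
                                    centroid_cutoff = 0.5)), base)
})

test_that("cluster summaries count members, ligands and residue unions", {
  keys <- residue_key("A", 1:12)
  one <- cluster_matches(list(stub("s1", keys[1:5], c(0, 0, 0), lig = "X")))
  tab1 <- summarize_clusters(one)
  expect_equal(tab1$nm, 1)
  expect_equal(tab1$nlig, 1)
  expect_equal(tab1$nres, 5)
  # two members sharing ligand id X with contact union of 7 residues
  two <- cluster_matches(list(stub("s1", keys[1:5], c(0, 0, 0), lig = "X"),
                              stub("s2", keys[3:7], c(0.5, 0, 0), lig = "X")))
  tab2 <- summarize_clusters(two)
  expect_equal(unique(tab2$nlig), 1)
  expect_equal(unique(tab2$nres), 7)
  expect_equal(unique(tab2$nm), 2)
  # cluster ids ordered by member count
  expect_equal(two[[1]]$cluster_id, 1)
})
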