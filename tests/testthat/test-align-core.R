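test_that("kabsch_superpose handles identity, translation and known rotation", {
  set.seed(11)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  fit <- kabsch_superpose(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-9)

  mov <- sweep(pts, 2, c(5, 0, 0), "+")
  fit <- kabsch_superpose(pts, mov)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(fit$transform, mov), pts, tolerance = 1e-9)

  # generator applies a known rotation; superposition must undo it exactly
  R <- random_rotation(3)
  mov <- pts %*% t(R)
  fit <- kabsch_superpose(pts, mov)
  expect_lte(fit$rmsd, 1e-9)
  expect_equal(fit$transform$rotation %*% R, diag(3), tolerance = 1e-6)
})

test_that("kabsch_superpose agrees with the bio3d least-squares fit", {
  set.seed(12)
  ref <- matrix(rnorm(36, sd = 4), 12, 3)
  mov <- ref %*% t(random_rotation(5)) + matrix(rnorm(36, sd = 0.5), 12, 3)
  fit <- kabsch_superpose(ref, mov)
  moved_b3d <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                              mobile = as.numeric(t(mov)),
                              fixed.inds = 1:36, mobile.inds = 1:36)
  rmsd_b3d <- sqrt(mean(rowSums((matrix(moved_b3d, ncol = 3, byrow = TRUE) -
                                 ref)^2)))
  expect_equal(fit$rmsd, rmsd_b3d, tolerance = 1e-6)
})

test_that("degenerate superposition inputs raise errors", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "degenerate-superposition")
})

test_that("rigid transforms invert and compose to identity", {
  tf <- new_rigid_transform(random_rotation(9), c(3, -2, 7))
  pts <- matrix(rnorm(15), 5, 3)
  back <- apply_transform(invert_transform(tf), apply_transform(tf, pts))
  expect_equal(back, pts, tolerance = 1e-9)
  expect_error(new_rigid_transform(diag(c(1, 1, -1))), "proper rotation")
})

test_that("score_lga_s saturates, zeroes and splits as constructed", {
  set.seed(21)
  ref <- matrix(rnorm(60, sd = 8), 20, 3)
  perfect <- score_lga_s(ref, ref)
  expect_equal(perfect$lga_s, 100)
  expect_equal(unname(perfect$gdt_fractions), rep(1, 4))

  # pairing broken by a seeded permutation over a widely spread point set:
  # no rigid motion brings any pair inside the largest threshold
  set.seed(22)
  spread <- matrix(rnorm(30, sd = 60), 10, 3)
  scrambled <- spread[c(6, 9, 2, 10, 4, 1, 8, 3, 5, 7), ]
  worst <- score_lga_s(spread, scrambled)
  expect_equal(worst$lga_s, 0)

  # contiguous half at distance 0, half displaced beyond all thresholds
  n <- 20
  ref2 <- helixish <- cbind(seq_len(n) * 3.8, sin(seq_len(n)), cos(seq_len(n)))
  mov2 <- ref2
  mov2[(n / 2 + 1):n, 3] <- mov2[(n / 2 + 1):n, 3] + 500
  half <- score_lga_s(ref2, mov2)
  expect_equal(unname(half$gdt_fractions), rep(0.5, 4))
  expect_equal(half$lcs_score, 50)
  expect_equal(half$lga_s, 100 * (0.75 * 0.5 + 0.25 * 0.5))
})

test_that("score_gdc saturates, zeroes and averages as the weighted formula", {
  tc <- toy(1)
  sp <- toy_sphere(1)
  al <- toy_self_alignment(1)
  expect_equal(score_gdc(sp, tc$holo, al$conserved, al$transform), 100,
               tolerance = 1e-6)

  # every atom displaced beyond 5 A
  shifted <- transform_structure(tc$holo, diag(3), c(500, 0, 0))
  expect_equal(score_gdc(sp, shifted, al$conserved, al$transform), 0)
})

test_that("score_gdc equals a brute-force threshold-weighted average", {
  # hand-built pair set: one residue perfectly placed, one displaced 1.2 A
  mk <- function(dx) {
    rows <- data.frame(
      chain = "A", resno = 1L, icode = "",
      resname = "ALA", atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(0, 1.5, 2.2, 3.1) + dx, y = 0, z = 0, occ = 1, het = FALSE,
      stringsAsFactors = FALSE)
    new_structure(rows, struct_id = paste0("r", dx))
  }
  s_query <- mk(0)
  sp_shell <- mk(1.2)
  sp <- structure(list(sphere_id = "T", structure = sp_shell,
                       interface_keys = character(0), ligand = origin_ligand(),
                       ns = 1L, source_sequence = "A", source_id = "r",
                       kind = "compound"), class = "sphere_template")
  pairs <- data.frame(sphere_key = residue_table(sp_shell)$key,
                      query_key = residue_table(s_query)$key)
  gdc <- score_gdc(sp, s_query, pairs, new_rigid_transform())
  # brute force: all 4 matched atoms at distance 1.2 -> within d_i for i >= 3
  f <- ifelse(0.5 * (1:10) >= 1.2, 1, 0)
  w <- 11 - (1:10)
  expect_equal(gdc, 100 * sum(w * f) / sum(w), tolerance = 1e-9)
})

test_that("self-alignment recovers the identity mapping exactly", {
  sp <- toy_sphere(1)
  al <- toy_self_alignment(1)
  expect_equal(al$nc, sp$ns)
  expect_lte(al$rmsd, 1e-6)
  expect_equal(al$seq_id, 100)
  expect_equal(al$lga_s, 100, tolerance = 1e-6)
  expect_true(all(al$conserved$sphere_key == al$conserved$query_key))
})

test_that("noisy self-alignment recovers most pairs at bounded RMSD", {
  tc <- toy(4)
  sp <- build_sphere(tc$holo, tc$truth$ligand)
  noisy <- perturb_structure(tc$holo, noise_sigma = 0.3, seed = 99,
                             retain_ligands = FALSE)
  al <- structural_align(sp, noisy)
  expect_gte(al$nc, ceiling(0.95 * sp$ns))
  expect_lte(al$rmsd, 0.6)
  # ground-truth correspondence: keys must map onto themselves
  expect_gte(mean(al$conserved$sphere_key == al$conserved$query_key), 0.95)
})

test_that("a random-walk decoy fails the conserved-pair filter", {
  sp <- toy_sphere(1)
  d <- make_decoy(60, seed = 101)
  al <- structural_align(sp, d)
  m <- evaluate_match(sp, d, al)
  expect_false(m$accepted)
})

test_that("alignment scores are invariant under rigid motion of the query", {
  sp <- toy_sphere(2)
  tc <- toy(2)
  al0 <- structural_align(sp, tc$holo)
  moved <- transform_structure(tc$holo, random_rotation(31), c(-20, 13, 8))
  al1 <- structural_align(sp, moved)
  expect_equal(al1$nc, al0$nc)
  expect_equal(al1$lga_s, al0$lga_s, tolerance = 1e-6)
  expect_equal(al1$gdc, al0$gdc, tolerance = 1e-6)
  expect_equal(al1$rmsd, al0$rmsd, tolerance = 1e-6)
})

test_that("scores degrade monotonically with coordinate noise", {
  tc <- toy(5)
  sp <- build_sphere(tc$holo, tc$truth$ligand)
  scores <- vapply(c(0, 0.3, 0.6, 1.0), function(sig) {
    q <- if (sig == 0) tc$holo
         else perturb_structure(tc$holo, noise_sigma = sig, seed = 7,
                                retain_ligands = TRUE)
    al <- structural_align(sp, q)
    c(al$lga_s, al$gdc)
  }, c(0, 0))
  expect_true(all(diff(scores[1, ]) <= 1e-6))
  expect_true(all(diff(scores[2, ]) <= 1e-6))
})

test_that("too few representative points is an alignment error", {
  sp <- toy_sphere(1)
  tiny <- point_structure(c(1, 2))
  expect_error(structural_align(sp, tiny), "alignment-infeasible")
})
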