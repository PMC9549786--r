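test_that("confusion_counts implements the TP/FP/TN/FN set arithmetic", {
  uni <- residue_key("A", 1:100)
  ubs <- uni[c(5, 7, 9)]
  expect_equal(confusion_counts(ubs, ubs, uni),
               list(tp = 3, fp = 0, tn = 97, fn = 0))
  disj <- confusion_counts(uni[1:4], ubs, uni)
  expect_equal(disj$tp, 0)
  expect_equal(disj$fp, 4)
  expect_equal(disj$fn, 3)
  # random subsets vs brute-force set arithmetic
  set.seed(41)
  for (i in 1:20) {
    pred <- sample(uni, 8); ref <- sample(uni, 10)
    cc <- confusion_counts(pred, ref, uni)
    expect_equal(cc$tp, length(intersect(pred, ref)))
    expect_equal(cc$fp, length(setdiff(pred, ref)))
    expect_equal(cc$fn, length(setdiff(ref, pred)))
    expect_equal(cc$tn, 100 - cc$tp - cc$fp - cc$fn)
  }
})

test_that("mcc_f evaluates the two formulas exactly", {
  perfect <- mcc_f(list(tp = 10, fp = 0, tn = 90, fn = 0))
  expect_equal(perfect$mcc, 1.0)
  expect_equal(perfect$f, 1.0)
  zero <- mcc_f(list(tp = 0, fp = 3, tn = 90, fn = 4))
  expect_equal(zero$f, 0)
  # hand-evaluated: (6*88 - 2*4)/sqrt(8*10*90*92) and 12/(12+2+4)
  hand <- mcc_f(list(tp = 6, fp = 2, tn = 88, fn = 4))
  expect_equal(hand$mcc, (6 * 88 - 2 * 4) / sqrt(8 * 10 * 90 * 92))
  expect_equal(hand$mcc, 0.639, tolerance = 1e-3)
  expect_equal(hand$f, 2 / 3, tolerance = 1e-9)
  # zero-denominator convention: 0 with undefined flag
  und <- mcc_f(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_equal(as.numeric(und$mcc), 0)
  expect_true(isTRUE(attr(und$mcc, "undefined")))
})

test_that("mcc_f agrees with direct formula over an exhaustive count sweep", {
  for (n in c(4, 8, 12)) {
    grid <- expand.grid(tp = 0:n, fp = 0:n, fn = 0:n)
    grid <- grid[rowSums(grid) <= n, ]
    grid$tn <- n - rowSums(grid)
    for (r in seq_len(nrow(grid))) {
      cc <- as.list(grid[r, ])
      out <- mcc_f(cc)
      den <- with(cc, (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      exp_mcc <- if (den == 0) 0 else
        with(cc, (tp * tn - fp * fn) / sqrt(den))
      exp_f <- if (2 * cc$tp + cc$fp + cc$fn == 0) 0 else
        2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
      expect_equal(as.numeric(out$mcc), exp_mcc)
      expect_equal(as.numeric(out$f), exp_f)
    }
  }
})

test_that("scores are permutation-invariant in residue labels", {
  uni <- residue_key("A", 1:30)
  set.seed(42)
  pred <- sample(uni, 7); ref <- sample(uni, 9)
  s1 <- eval_scores(pred, ref, uni)
  perm <- sample(uni)
  relab <- setNames(residue_key("B", 1:30), perm)
  s2 <- eval_scores(unname(relab[pred]), unname(relab[ref]), unname(relab[uni]))
  expect_equal(s2$mcc, s1$mcc)
  expect_equal(s2$f, s1$f)
})

test_that("build_ubs unions contacts across family members", {
  tc <- toy(1)
  # single member: UBS equals that member's own contact set
  ubs1 <- build_ubs(list(list(structure = tc$holo)), family_id = "toy")
  expect_setequal(ubs1$ubs_keys, tc$truth$contact_keys)
  # perturbed holo copies (ligand retained): UBS is the union of per-member scans
  members <- c(list(list(structure = tc$holo)),
               lapply(2:3, function(k) list(
                 structure = perturb_structure(tc$holo, noise_sigma = 0.4,
                                               seed = k, retain_ligands = TRUE))))
  ubs <- build_ubs(members, family_id = "toyfam")
  expected <- character(0)
  for (m in members) {
    s <- m$structure
    lig <- list_ligand_instances(s)[[1]]
    lx <- as.matrix(lig$atoms[, c("x", "y", "z")])
    mapped <- brute_contacts(s, lx, 4.5)
    expected <- union(expected, mapped)  # same numbering across members here
  }
  expect_setequal(ubs$ubs_keys, expected)
  # a family with no ligands is an error
  apo <- perturb_structure(tc$holo, seed = 1)
  expect_error(build_ubs(list(list(structure = apo, ligands = list()))),
               "empty-reference")
})

test_that("map_residues aligns identical sequences one-to-one", {
  tc <- toy(1)
  mp <- map_residues(tc$holo, tc$holo)
  expect_true(all(mp$from_key == mp$to_key))
  expect_equal(nrow(mp), length(ligsphere:::polymer_keys(tc$holo)))
})

test_that("pocket_similarity is reflexive and degrades with noise", {
  tc <- toy(1)
  lig <- tc$truth$ligand
  a <- list(region = extract_region(tc$holo, lig, 16.0),
            sphere = toy_sphere(1))
  self <- pocket_similarity(a, a)
  expect_gte(self$gdc, 99.9)
  expect_lte(self$centroid_distance, 1e-6)
  # noise-perturbed copy scores lower
  nz <- perturb_structure(tc$holo, noise_sigma = 0.5, seed = 3,
                          retain_ligands = TRUE)
  lig_n <- list_ligand_instances(nz)[[1]]
  b <- list(region = extract_region(nz, lig_n, 16.0),
            sphere = build_sphere(nz, lig_n))
  ab <- pocket_similarity(a, b)
  expect_lt(ab$gdc, self$gdc)
  ba <- pocket_similarity(b, a)
  expect_lte(abs(ab$lga_s - ba$lga_s), 1.0)
})

test_that("exclusive clustering follows the block structure of similarities", {
  ids <- sprintf("p%02d", 1:9)
  blocks <- list(ids[1:3], ids[4:6], ids[7:9])
  sim <- do.call(rbind, lapply(blocks, function(b) {
    g <- expand.grid(a = b, b = b, stringsAsFactors = FALSE)
    g$gdc <- 90
    g
  }))
  # complete all-against-all table: low background similarity between blocks
  bg <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  bg$gdc <- 10
  full <- rbind(sim, bg)
  part <- exclusive_cluster(full, threshold = 70)
  expect_length(part, 3)
  expect_setequal(part[[1]], blocks[[1]])
  # threshold 0: one cluster; threshold > 100: all singletons
  expect_length(exclusive_cluster(full, threshold = 0), 1)
  expect_length(exclusive_cluster(full, threshold = 101), 9)
})

test_that("affinity concordance filters pairs and computes r2/Spearman", {
  perfect <- data.frame(gdc = rep(97, 5), centroid_distance = 0.1,
                        affinity_a = 1:5, affinity_b = 1:5)
  out <- affinity_concordance(perfect)
  expect_equal(out$r2, 1)
  expect_equal(out$spearman, 1)
  # constraint set: gdc {96, 94} -> only the first pair survives a 95 cut
  mixed <- data.frame(gdc = c(96, 94), centroid_distance = 0.2,
                      affinity_a = c(1, 2), affinity_b = c(1, 2))
  kept <- affinity_concordance(mixed, min_gdc = 95, max_centroid = 0.5)
  expect_equal(kept$n_pairs, 1)
  expect_true(kept$undefined)
  # seeded noise: statistics equal textbook formulas computed directly
  set.seed(9)
  a <- rnorm(40, 6, 1.5); b <- a + rnorm(40, 0, 0.6)
  df <- data.frame(gdc = 99, centroid_distance = 0.1,
                   affinity_a = a, affinity_b = b)
  out2 <- affinity_concordance(df)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(out2$r2, r^2, tolerance = 1e-12)
  ra <- rank(a); rb <- rank(b)
  rs <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(out2$spearman, rs, tolerance = 1e-12)
})
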