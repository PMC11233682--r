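test_that("amplitude follows its definition and antisymmetry", {
  expect_equal(amplitude(2, 1), 1 / 1.5, tolerance = 1e-12)
  expect_equal(amplitude(3, 3), 0)
  set.seed(13)
  t <- runif(20, 0.1, 5); c <- runif(20, 0.1, 5)
  expect_equal(amplitude(t, c), -amplitude(c, t), tolerance = 1e-12)
  expect_warning(a <- amplitude(1, -1), "dropped")
  expect_true(is.na(a))
})

test_that("enrichment score reproduces the worked instance", {
  genes <- sprintf("G%02d", 1:10)
  ranking <- setNames(1:10, genes)
  up <- genes[1:2]      # ranks 1, 2
  dn <- genes[9:10]     # ranks 9, 10
  es <- enrichmentScore(ranking, up, dn)
  expect_equal(es$esUp, 0.8, tolerance = 1e-12)
  expect_equal(es$esDown, -0.9, tolerance = 1e-12)
  expect_equal(es$es, 1.7, tolerance = 1e-12)
  # both sets concentrated at the top -> same sign -> ES 0
  es0 <- enrichmentScore(ranking, genes[1:2], genes[3:4])
  expect_equal(es0$es, 0)
  expect_error(enrichmentScore(ranking, genes[1:2], genes[2:3]), "disjoint")
  # missing direction flagged as NA
  esNA <- enrichmentScore(ranking, c("ZZ1", "ZZ2"), dn)
  expect_true(is.na(esNA$es))
})

test_that("enrichment score matches a brute-force running-sum oracle", {
  set.seed(14)
  for (rep in 1:500) {
    r <- sample(20:120, 1)
    genes <- sprintf("G%03d", seq_len(r))
    ranking <- setNames(sample(r), genes)
    pick <- sample(genes, sample(4:16, 1))
    half <- length(pick) %/% 2
    up <- pick[seq_len(half)]; dn <- pick[(half + 1):length(pick)]
    expect_equal(enrichmentScore(ranking, up, dn)$es,
                 bruteEs(ranking, up, dn), tolerance = 1e-12)
  }
})

test_that("ES is rank-relabeling invariant and direction-consistent", {
  set.seed(15)
  r <- 60
  genes <- sprintf("G%03d", 1:r)
  ranking <- setNames(sample(r), genes)
  up <- sample(genes, 6); dn <- sample(setdiff(genes, up), 6)
  base <- enrichmentScore(ranking, up, dn)
  # renaming genes while preserving ranks and membership
  map <- setNames(sprintf("H%03d", 1:r), genes)
  rank2 <- setNames(unname(ranking), map[names(ranking)])
  same <- enrichmentScore(rank2, map[up], map[dn])
  expect_equal(same$es, base$es, tolerance = 1e-12)
  # reversing the ranking flips the directional scores consistently
  for (i in 1:20) {
    rk <- setNames(sample(r), genes)
    u <- sample(genes, 5); d <- sample(setdiff(genes, u), 5)
    fwd <- enrichmentScore(rk, u, d)
    rev <- enrichmentScore(setNames(r + 1 - rk, names(rk)), u, d)
    # a set concentrated at one end is concentrated at the other end
    # after reversal: the directional score cannot stay strongly
    # positive (or negative) on both orientations
    expect_lte(sign(fwd$esUp) * sign(rev$esUp) *
                 min(abs(fwd$esUp), abs(rev$esUp)), 0.35)
  }
})

test_that("permutation significance is calibrated, extreme for perfect reversers", {
  genes <- sprintf("G%03d", 1:100)
  # perfect reverser: up genes at the very bottom ranks, down at the top
  ranking <- setNames(sample(100), genes)
  up <- names(sort(ranking))[1:5]
  dn <- names(sort(ranking, decreasing = TRUE))[1:5]
  ps <- permutationSignificance(ranking, up, dn, nPerm = 100, seed = 3)
  expect_equal(ps$p, 1 / 101, tolerance = 1e-12)
  expect_identical(ps$p,
                   permutationSignificance(ranking, up, dn, 100, seed = 3)$p)
  # null drugs: p approximately uniform across 200 replicate drugs
  set.seed(16)
  pvals <- vapply(1:200, function(i) {
    rk <- setNames(sample(100), genes)
    u <- sample(genes, 5); d <- sample(setdiff(genes, u), 5)
    permutationSignificance(rk, u, d, nPerm = 50, seed = 100 + i)$p
  }, numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals < 0.1), 0.2)
})

test_that("drug prioritization selects planted reversers and is monotone", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(17)
  up <- sample(genes, 20); dn <- sample(setdiff(genes, up), 20)
  rev <- sprintf("drug%03d", 1:10)
  sig <- simulateDrugSignatures(genes, nDrugs = 80, reverserIds = rev,
                                diseaseUp = up, diseaseDown = dn,
                                strength = 2, seed = 18)
  res <- screenDrugs(sig, up, dn, nPerm = 200, seed = 19)
  pri <- prioritizeDrugs(res)
  sel <- pri$drug[pri$selected]
  expect_gte(mean(rev %in% sel), 0.9)
  # lowering the ES threshold never removes a selected drug
  pri2 <- prioritizeDrugs(res, esThreshold = 2)
  expect_true(all(sel %in% pri2$drug[pri2$selected]))
  # empty selection is a table, not an error
  none <- prioritizeDrugs(res, esThreshold = 1e6)
  expect_false(any(none$selected))
  # strength 0 -> reversers behave like nulls
  sig0 <- simulateDrugSignatures(genes, nDrugs = 40, reverserIds = rev[1:5],
                                 diseaseUp = up, diseaseDown = dn,
                                 strength = 0, seed = 20)
  res0 <- screenDrugs(sig0, up, dn, nPerm = 100, seed = 21)
  expect_gt(mean(res0$p[res0$drug %in% rev[1:5]]), 0.1)
})
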