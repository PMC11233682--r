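test_that("mixed-model rate is exact in the noiseless limit", {
  ids <- sprintf("P%02d", 1:12)
  tY <- 0:5
  d <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(participant = ids[i], time_years = tY,
               value = 1 + 0.25 * i + 2 * tY)))
  r <- suppressMessages(fitProgressionRate(d))
  expect_equal(r$beta, 2, tolerance = 1e-6)
  expect_true(r$ciLow <= r$beta && r$beta <= r$ciHigh)
})

test_that("mixed-model rate recovers planted slopes with honest coverage", {
  genLong <- function(slope, n = 60, seed) {
    set.seed(seed)
    u <- rnorm(n, 0, 1)
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(participant = sprintf("P%03d", i), time_years = 0:5,
                 value = 3 + u[i] + slope * (0:5) + rnorm(6, 0, 0.5))))
  }
  est <- cover0 <- numeric(40)
  for (r in 1:40) {
    f1 <- fitProgressionRate(genLong(1.5, seed = 1000 + r))
    est[r] <- f1$beta
    f0 <- fitProgressionRate(genLong(0, seed = 2000 + r))
    cover0[r] <- f0$ciLow <= 0 && 0 <= f0$ciHigh
  }
  expect_lt(abs(mean(est) - 1.5), 0.05)
  expect_gte(mean(cover0), 0.9)
})

test_that("baseline comparisons dispatch by type with correct nulls", {
  set.seed(6)
  # planted difference: group 3 shifted by 2 SD
  g <- factor(rep(1:3, each = 50))
  y <- rnorm(150) + 2 * (g == 3)
  res <- compareGroupsBaseline(y, g)
  expect_equal(res$type, "anova")
  expect_lt(res$p, 1e-6)
  flagged <- res$tukey$contrast[res$tukey$pAdj < 0.05]
  expect_true(all(grepl("3", flagged)))
  # chi-square on a perfectly balanced table: statistic 0, p 1
  vals <- rep(rep(c("x", "y"), each = 10), 3)
  grp <- rep(1:3, each = 20)
  r2 <- compareGroupsBaseline(vals, grp)
  expect_equal(r2$type, "chisq")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  expect_error(compareGroupsBaseline(y, rep(1, 150)), "2 groups")
})

test_that("ANOVA p-values are uniform under permuted labels", {
  set.seed(7)
  y <- rnorm(90)
  p <- replicate(200, compareGroupsBaseline(y, sample(rep(1:3, 30)))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches a hand-rolled step-up oracle", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustFdr(0.2), 0.2)
  expect_equal(adjustFdr(rep(1, 5)), rep(1, 5))
  bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(8)
  for (r in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjustFdr(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment equals brute-force enumeration", {
  expect_equal(snpEnrichment(10, 4, 5, 4), 6 / 252, tolerance = 1e-12)
  expect_equal(snpEnrichment(10, 4, 5, 0), 1)
  for (N in c(6, 9, 12)) for (K in seq(0, N, 3)) for (n in seq(1, N, 2))
    for (k in 0:min(K, n))
      expect_equal(snpEnrichment(N, K, n, k), bruteHyperTail(N, K, n, k),
                   tolerance = 1e-12)
  expect_error(snpEnrichment(10, 4, 5, 5), "impossible")
})

test_that("CSF comparisons compute ratios and detect planted shifts", {
  labels <- setNames(rep(1:2, each = 100), sprintf("S%04d", 1:200))
  hits <- replicate(30, {
    bm <- simulateBiomarkers(labels,
      effects = list(list(table = "csf", column = "ptau", subtype = 2,
                          shift = 1)),
      seed = sample.int(1e6, 1))
    res <- compareBiomarker(bm$csf, c(1, 2))
    res$p[res$biomarker == "ptau"] < 0.05
  })
  expect_gte(mean(hits), 0.95)
  # ratio arithmetic: ptau 20, alpha-syn 2000 -> 0.01
  bm <- simulateBiomarkers(labels, seed = 4)
  csf <- bm$csf[1:10, ]
  csf$ptau <- 20; csf$alpha_syn <- 2000
  csf$subtype <- rep(1:2, 5)
  d <- csf
  expect_equal(rep(0.01, 10), d$ptau / d$alpha_syn)
  # null calibration: ~5% false positives
  nullP <- unlist(replicate(25, {
    b <- simulateBiomarkers(labels, seed = sample.int(1e6, 1))
    compareBiomarker(b$csf, c(1, 2))$p
  }))
  expect_lt(mean(nullP < 0.05), 0.12)
})

test_that("ROI t-tests flag only the shifted region and match closed form", {
  labels <- setNames(rep(1:2, each = 120), sprintf("S%04d", 1:240))
  bm <- simulateBiomarkers(labels,
    effects = list(list(table = "roi", column = "insula", subtype = 2,
                        shift = 1.2)),
    seed = 10)
  res <- compareRoiAtrophy(bm$roi, c(1, 2))
  expect_true(res$significant[res$roi == "insula"])
  expect_lt(mean(res$significant[res$roi != "insula"]), 0.2)
  # Welch t on a 4-point example against direct arithmetic
  a <- c(1, 2); b <- c(4, 6)
  tm <- (mean(a) - mean(b)) / sqrt(var(a) / 2 + var(b) / 2)
  roi <- data.frame(subtype = c(1, 1, 2, 2), bankssts = c(a, b))
  r <- compareRoiAtrophy(roi, c(1, 2), roiColumns = "bankssts")
  expect_equal(r$t, tm, tolerance = 1e-12)
})
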