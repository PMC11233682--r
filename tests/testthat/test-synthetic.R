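test_that("noiseless cohort trajectories are exactly linear with the planted slope", {
  spec <- cohortSpec(nPerSubtype = c(5, 5), nVariables = 3, nVisits = 4,
                     randomInterceptSd = 0, noiseSd = 0,
                     missingRate = 0, dropoutHazard = 0, seed = 3)
  sim <- simulateCohort(spec)
  v <- panelValues(sim$panel)
  tY <- visitMonths(sim$panel) / 12
  for (i in c(1, 6)) {
    k <- sim$labels[[i]]
    for (j in 1:3) {
      expected <- spec$baselineMeans[k, j] + spec$subtypeSlopes[k, j] * tY
      expect_equal(unname(v[i, , j]), expected, tolerance = 1e-12)
    }
  }
})

test_that("cohort generation is bitwise reproducible under a fixed seed", {
  a <- simulateCohort(cohortSpec(seed = 7))
  b <- simulateCohort(cohortSpec(seed = 7))
  expect_identical(panelValues(a$panel), panelValues(b$panel))
  expect_identical(a$labels, b$labels)
})

test_that("per-subtype empirical OLS slopes recover the planted slopes", {
  spec <- cohortSpec(seed = 5)
  sim <- simulateCohort(spec)
  p <- sim$panel
  tY <- visitMonths(p) / 12
  for (k in 1:3) {
    ids <- which(sim$labels == k)
    for (v in c(1, 5)) {
      # pool all observed cells of the subtype for one variable
      ys <- c(); ts <- c()
      for (i in ids) {
        ok <- panelMask(p)[i, , v]
        ys <- c(ys, panelValues(p)[i, ok, v]); ts <- c(ts, tY[ok])
      }
      fit <- summary(lm(ys ~ ts))$coefficients
      expect_lt(abs(fit["ts", 1] - spec$subtypeSlopes[k, v]),
                3 * fit["ts", 2] + 1e-9)
    }
  }
})

test_that("planted network module is dense and the graph stays connected", {
  out <- simulatePpiNetwork(nGenes = 300, plantedSize = 20, seed = 2)
  net <- out$network
  expect_true(igraph::is_connected(net@graph))
  expect_gte(igraph::ecount(net@graph), 1 * (300 - 1) - 10) # PA lower bound
  sub <- igraph::induced_subgraph(net@graph, out$planted)
  dIn <- igraph::edge_density(sub)
  dAll <- igraph::edge_density(net@graph)
  expect_gt(dIn, 5 * dAll)
  # no planting
  plain <- simulatePpiNetwork(nGenes = 50, plantedSize = 0, seed = 2)
  expect_identical(plain$planted, character(0))
  expect_error(simulatePpiNetwork(nGenes = 5), "nGenes")
})

test_that("DEG table gates behave: planted rows pass, nulls and zero-effect fail", {
  net <- simulatePpiNetwork(nGenes = 100, plantedSize = 10, seed = 4)
  deg <- simulateDegTable(net$network, net$planted, effectLog2fc = 2,
                          nNull = 50, seed = 5)
  planted <- deg[deg$gene %in% net$planted, ]
  nulls <- deg[!deg$gene %in% net$planted, ]
  expect_true(all(planted$padj <= 0.05))
  expect_true(all(abs(abs(planted$log2fc) - 2) < 0.5))
  expect_true(all(nulls$padj > 0.05))
  z <- initGeneScores(net$network, deg)
  expect_equal(unname(z[planted$gene]), abs(planted$log2fc))
  expect_true(all(z[setdiff(names(z), planted$gene)] == 0))
  # zero effect: everything fails the gate
  deg0 <- simulateDegTable(net$network, net$planted, effectLog2fc = 0,
                           nNull = 50, seed = 5)
  expect_true(all(deg0$padj > 0.05))
})

test_that("genotype generator plants detectable subtype enrichment", {
  labels <- setNames(rep(1:2, each = 200), sprintf("S%04d", 1:400))
  hits <- replicate(50, {
    g <- simulateGenotypes(nSnps = 5, labels,
                           enrichedPairs = data.frame(snp = 1, subtype = 2),
                           odds = 8, seed = sample.int(1e6, 1))
    tab <- snpEnrichmentTable(g$genotypes, labels)
    tab$p[tab$snp == "rs0001" & tab$subtype == 2] < 0.05
  })
  expect_gte(mean(hits), 0.9)
  g <- simulateGenotypes(nSnps = 8, labels, seed = 3)
  expect_true(all(colSums(g$genotypes) <= 400))
  expect_true(all(table(g$snpGeneMap$snp) <= 3))
})

test_that("null genotypes give approximately uniform enrichment p-values", {
  labels <- setNames(rep(1:2, each = 150), sprintf("S%04d", 1:300))
  g <- simulateGenotypes(nSnps = 200, labels, enrichedPairs = NULL, seed = 9)
  tab <- snpEnrichmentTable(g$genotypes, labels)
  p <- tab$p[tab$subtype == 1]
  # discrete p-values are stochastically >= uniform under the null
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p < 0.05), 0.1)
})

test_that("biomarker generator emits 34 ROI columns and plants detectable shifts", {
  labels <- setNames(rep(1:2, each = 100), sprintf("S%04d", 1:200))
  bm <- simulateBiomarkers(labels, seed = 2)
  expect_length(intersect(pacenet:::dkRoiNames, names(bm$roi)), 34)
  hits <- replicate(30, {
    b <- simulateBiomarkers(labels,
      effects = list(list(table = "roi", column = "precuneus",
                          subtype = 2, shift = 1)),
      seed = sample.int(1e6, 1))
    res <- compareRoiAtrophy(b$roi, c(1, 2))
    res$p[res$roi == "precuneus"] < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("EHR generator respects date ordering and plants confounding", {
  ehr <- simulateEhrCohort(ehrSpec(nPatients = 3000, seed = 6))
  expect_setequal(names(ehr), c("patients", "diagnoses", "prescriptions",
                                "truth"))
  firstPd <- tapply(as.Date(ehr$diagnoses$date[ehr$diagnoses$code == "G20"]),
                    ehr$diagnoses$patient_id[ehr$diagnoses$code == "G20"], min)
  out <- ehr$diagnoses[ehr$diagnoses$code == "OUTCOME_DEM", ]
  expect_true(all(as.Date(out$date) >
                    as.Date(firstPd[out$patient_id],
                            origin = "1970-01-01") - 183))
  # treated patients have higher confounder scores on average
  z <- ehr$truth$confounder
  expect_gt(mean(z[ehr$truth$treated]),
            mean(z[setdiff(names(z), ehr$truth$treated)]) + 0.3)
  # reproducibility
  ehr2 <- simulateEhrCohort(ehrSpec(nPatients = 3000, seed = 6))
  expect_identical(ehr$diagnoses, ehr2$diagnoses)
})
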