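test_that("network building dedups, drops self-loops, keeps largest component", {
  el <- data.frame(from = c("a", "b", "a", "x", "y", "x"),
                   to = c("b", "a", "a", "y", "z", "z"))
  net <- buildNetwork(el)
  # components: {a,b} (1 edge) vs {x,y,z} (3 edges) -> keep the triangle
  expect_equal(net@N, 3L)
  expect_setequal(networkGenes(net), c("x", "y", "z"))
  expect_equal(sum(net@degree), 2L * igraph::ecount(net@graph))
  expect_error(buildNetwork(el[0, ]), "empty")
})

test_that("RWR smoothing matches the direct linear solve and conserves mass", {
  # two-node path, closed form
  el <- data.frame(from = "a", to = "b")
  net <- buildNetwork(el)
  p <- rwrSmooth(net, c(a = 1, b = 0), restartProb = 0.5, tol = 1e-14)
  W <- matrix(c(0, 1, 1, 0), 2)
  exact <- 0.5 * solve(diag(2) - 0.5 * W, c(1, 0))
  expect_equal(unname(p), exact, tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # random graphs up to 50 nodes vs dense solve
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    g <- igraph::sample_gnp(n, 0.15)
    if (!igraph::is_connected(g)) next
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    el2 <- igraph::as_edgelist(g)
    net2 <- buildNetwork(data.frame(from = el2[, 1], to = el2[, 2]))
    z0 <- setNames(runif(net2@N), networkGenes(net2))
    gamma <- runif(1, 0.2, 0.8)
    sm <- rwrSmooth(net2, z0, gamma, tol = 1e-14)
    A <- as.matrix(igraph::as_adjacency_matrix(net2@graph))
    Wc <- A %*% diag(1 / colSums(A))
    exact2 <- gamma * solve(diag(net2@N) - (1 - gamma) * Wc,
                            z0[networkGenes(net2)] / sum(z0))
    expect_equal(unname(sm), unname(as.vector(exact2)) * sum(z0),
                 tolerance = 1e-8)
    expect_equal(sum(sm), sum(z0), tolerance = 1e-9)
  }
  expect_error(rwrSmooth(net, c(a = 1, b = 0), restartProb = 0), "restartProb")
})

test_that("connectivity p-value equals brute-force term summation", {
  # worked instance: N=10, m=3, di=2, dn=1 -> 24/45
  expect_equal(connectivityPvalue(10, 3, 2, 1), 24 / 45, tolerance = 1e-12)
  expect_equal(connectivityPvalue(10, 3, 2, 0), 1)
  brute <- function(N, m, di, dn) {
    ds <- dn:di
    sum(vapply(ds, function(d)
      choose(m, d) * choose(N - m, di - d), numeric(1))) / choose(N, di)
  }
  set.seed(12)
  for (rep in 1:100) {
    N <- sample(5:25, 1)
    m <- sample(1:(N - 2), 1)
    di <- sample(1:(N - m), 1)
    dn <- sample(0:min(di, m), 1)
    expect_equal(connectivityPvalue(N, m, di, dn), brute(N, m, di, dn),
                 tolerance = 1e-12)
  }
  expect_error(connectivityPvalue(10, 3, 2, 3), "dn")
})

test_that("module score follows the mean-centred sqrt-size normalisation", {
  scores <- c(a = 1, b = 2, c = 0, d = 0)
  # omega supplied directly
  expect_equal(geneModuleScore(scores, c("a", "b"), omega = 0.5),
               (0.5 + 1.5) / sqrt(2), tolerance = 1e-12)
  expect_equal(geneModuleScore(c(x = 3, y = 3), c("x", "y"), omega = 3), 0)
  # doubling a module with the same score pattern multiplies S by sqrt(2)
  s1 <- geneModuleScore(c(a = 2, b = 1, c = 2, d = 1), c("a", "b"), omega = 0.3)
  s2 <- geneModuleScore(c(a = 2, b = 1, c = 2, d = 1),
                        c("a", "b", "c", "d"), omega = 0.3)
  expect_equal(s2, sqrt(2) * s1, tolerance = 1e-12)
  expect_error(geneModuleScore(scores, character(0)), "nonempty")
})

test_that("module growth obeys its gates and recovers a planted module", {
  out <- simulatePpiNetwork(nGenes = 500, plantedSize = 30, seed = 2)
  deg <- simulateDegTable(out$network, out$planted, 2, 200, seed = 3)
  z <- rwrSmooth(out$network, initGeneScores(out$network, deg), 0.5)
  # seed with an all-zero neighbourhood cannot grow
  z0 <- setNames(numeric(out$network@N), networkGenes(out$network))
  z0[["g0001"]] <- 1
  m0 <- growModule(out$network, z0, "g0001")
  expect_identical(moduleGenes(m0), "g0001")
  # growth trace strictly increases S(M)
  seedGene <- out$planted[which.max(z[out$planted])]
  m <- growModule(out$network, z, seedGene)
  expect_true(all(diff(m@trace$score) > 0))
  # recomputing S from the trace's final module matches
  expect_equal(m@score, geneModuleScore(z, moduleGenes(m)), tolerance = 1e-10)
  # every accepted candidate passed the connectivity gate
  expect_true(all(m@trace$p[-1] <= 0.01))
  # seeded inside the planted clique, growth recovers most of it
  expect_gte(mean(out$planted %in% moduleGenes(m)), 0.8)
})

test_that("module assembly is deterministic and respects nRestarts = 1", {
  out <- simulatePpiNetwork(nGenes = 200, plantedSize = 15, seed = 23)
  deg <- simulateDegTable(out$network, out$planted, 2, 80, seed = 24)
  z <- rwrSmooth(out$network, initGeneScores(out$network, deg), 0.5)
  a <- assembleModules(out$network, z, nRestarts = 50, seed = 7)
  b <- assembleModules(out$network, z, nRestarts = 50, seed = 7)
  expect_identical(moduleGenes(a), moduleGenes(b))
  one <- assembleModules(out$network, z, nRestarts = 1, seed = 8)
  set.seed(8)
  pool <- names(z)[z > 0]
  sg <- sample(pool, 1)
  expect_setequal(moduleGenes(one), moduleGenes(growModule(out$network, z, sg)))
  expect_error(assembleModules(out$network, z, nRestarts = 0), "nRestarts")
})

test_that("final module genes are enriched vs a degree-matched random null", {
  out <- simulatePpiNetwork(nGenes = 500, plantedSize = 30, seed = 25)
  deg <- simulateDegTable(out$network, out$planted, 2, 200, seed = 26)
  z <- rwrSmooth(out$network, initGeneScores(out$network, deg), 0.5)
  mod <- assembleModules(out$network, z, nRestarts = 200, seed = 9)
  hit <- sum(moduleGenes(mod) %in% out$planted)
  degs <- out$network@degree
  bins <- cut(degs, c(0, 1, 2, 3, 5, 10, Inf))
  modBins <- bins[match(moduleGenes(mod), networkGenes(out$network))]
  set.seed(10)
  nullHits <- replicate(500, {
    draw <- unlist(lapply(levels(bins), function(b) {
      need <- sum(modBins == b)
      if (need == 0) return(character(0))
      sample(networkGenes(out$network)[bins == b], need)
    }))
    sum(draw %in% out$planted)
  })
  pEmp <- (1 + sum(nullHits >= hit)) / 501
  expect_lt(pEmp, 0.01)
})

test_that("genetic module keeps only contextually linked genes", {
  el <- data.frame(
    from = c("gen1", "gen2", "ctx1", "ctx2", "oth1", "gen3"),
    to = c("ctx1", "oth1", "ctx2", "oth1", "gen3", "oth2"))
  net <- buildNetwork(el)
  mod <- buildGeneticModule(net, c("gen1", "gen2", "gen3"),
                            c("ctx1", "ctx2"))
  # gen1 links ctx1; gen2 and gen3 have no contextual neighbour
  expect_setequal(moduleGenes(mod), c("gen1", "ctx1"))
  expect_warning(buildGeneticModule(net, "gen2", "ctx2"), "empty")
})
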