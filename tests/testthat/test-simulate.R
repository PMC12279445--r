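smallCfg <- function(..., branchDivergence = c(5e-4, 5e-4), seed = 77) {
  simConfig(popNames = c("A", "B"), samplesPerPop = c(8, 8), nOutgroup = 0,
            branchDivergence = branchDivergence, driftF = c(0, 0),
            thetaShape = 0, migration = matrix(FALSE, 2, 2),
            expansionRate = c(0, 0), missingRate = 0,
            simulateDepth = FALSE, seed = seed, ...)
}

test_that("identical config and seed give identical outputs", {
  cfg <- simConfig(popNames = c("A", "B"), samplesPerPop = c(4, 4),
                   nOutgroup = 1, nRegions = 5, regionLengthBp = 200,
                   windowBp = 200, branchDivergence = c(1e-3, 1e-3),
                   migration = matrix(FALSE, 2, 2), driftF = c(0.02, 0.02),
                   expansionRate = c(0, 0), seed = 19)
  s1 <- simulateGenotypes(cfg)
  s2 <- simulateGenotypes(cfg)
  expect_identical(dosage(s1$genotypes), dosage(s2$genotypes))
  expect_identical(siteInfo(s1$genotypes), siteInfo(s2$genotypes))
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypeVcf(s1$genotypes, f1)
  writeGenotypeVcf(s2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(popNames = "A", samplesPerPop = 1L,
                         branchDivergence = 0, driftF = 0,
                         migration = matrix(FALSE, 1, 1),
                         expansionRate = 0),
               "at least 2 samples")
  expect_error(simConfig(popNames = c("A", "B"), samplesPerPop = c(4, 4),
                         branchDivergence = c(0, 0), driftF = c(0, 0),
                         migration = matrix(FALSE, 2, 2),
                         expansionRate = c(0, 0), missingRate = 1.5),
               "missingRate")
  expect_error(simConfig(popNames = c("A", "B"), samplesPerPop = c(4, 4),
                         branchDivergence = c(0, 0), driftF = c(0, 0),
                         migration = matrix(FALSE, 2, 2),
                         expansionRate = c(0, 0),
                         scenarioInjections = data.frame(
                           region = 1L, label = "bogus", popA = "A",
                           popB = "B", multiplier = 1)),
               "unknown scenario label")
})

test_that("mean window D_XY calibrates to theta plus added divergence", {
  cfg <- smallCfg(nRegions = 400L, regionLengthBp = 1000L, windowBp = 1000L)
  sim <- simulateGenotypes(cfg)
  win <- assignWindows(sim$genotypes, sim$regions, windowBp = 1000)
  st <- computeWindowStats(sim$genotypes, win)
  mDxy <- mean(st$value[st$stat == "dxy"], na.rm = TRUE)
  expect_equal(mDxy, 0.003 + 0.001, tolerance = 0.07)
  # Pi calibrates to theta when drift is off
  mPi <- mean(st$value[st$stat == "pi"], na.rm = TRUE)
  expect_equal(mPi, 0.003, tolerance = 0.07)
})

test_that("undiverged population pairs have near-zero mean F_ST", {
  cfg <- smallCfg(nRegions = 300L, regionLengthBp = 1000L, windowBp = 1000L,
                  branchDivergence = c(0, 0), seed = 79)
  sim <- simulateGenotypes(cfg)
  win <- assignWindows(sim$genotypes, sim$regions, windowBp = 1000)
  st <- computeWindowStats(sim$genotypes, win)
  mFst <- mean(st$value[st$stat == "fst"], na.rm = TRUE)
  expect_lt(abs(mFst), 0.02)
})

test_that("Tajima's D is near zero at equilibrium and negative under expansion", {
  eq <- simConfig(popNames = "P", samplesPerPop = 10L, nOutgroup = 0,
                  branchDivergence = 0, driftF = 0, thetaShape = 0,
                  migration = matrix(FALSE, 1, 1), expansionRate = 0,
                  missingRate = 0, simulateDepth = FALSE,
                  nRegions = 250L, regionLengthBp = 1000L, windowBp = 1000L,
                  seed = 83)
  simEq <- simulateGenotypes(eq)
  stEq <- computeWindowStats(simEq$genotypes,
                             assignWindows(simEq$genotypes, simEq$regions, 1000))
  dEq <- mean(stEq$value[stEq$stat == "tajima_d"], na.rm = TRUE)
  expect_gt(dEq, -0.3)
  expect_lt(dEq, 0.3)

  ex <- simConfig(popNames = "P", samplesPerPop = 10L, nOutgroup = 0,
                  branchDivergence = 0, driftF = 0, thetaShape = 0,
                  migration = matrix(FALSE, 1, 1), expansionRate = 0.02,
                  missingRate = 0, simulateDepth = FALSE,
                  nRegions = 250L, regionLengthBp = 1000L, windowBp = 1000L,
                  seed = 83)
  simEx <- simulateGenotypes(ex)
  stEx <- computeWindowStats(simEx$genotypes,
                             assignWindows(simEx$genotypes, simEx$regions, 1000))
  dEx <- mean(stEx$value[stEx$stat == "tajima_d"], na.rm = TRUE)
  expect_lt(dEx, 0)
  expect_lt(dEx, dEq)
})

test_that("scenario injections move expected frequencies as constructed", {
  set.seed(89)
  L <- 2000
  theta <- 0.003
  # neutral window frequencies for two populations
  p0 <- numeric(L)
  polymorphic <- runif(L) < 0.016
  p0[polymorphic] <- 0.005^(1 - runif(sum(polymorphic)))
  freq <- cbind(A = p0, B = p0)
  expPi <- function(f) mean(2 * f * (1 - f))
  expDxy <- function(f) mean(f[, 1] * (1 - f[, 2]) + f[, 2] * (1 - f[, 1]))

  bal <- injectScenario(freq, "balancing", theta = theta, dPair = 1e-3)
  expect_gt(expPi(bal[, "A", drop = FALSE]), expPi(freq[, "A", drop = FALSE]))
  expect_gt(expDxy(bal), expDxy(freq))

  al <- injectScenario(freq, "allopatric", theta = theta, dPair = 1e-3)
  expect_lt(expPi(al[, "A", drop = FALSE]), expPi(freq[, "A", drop = FALSE]))
  expect_gt(mean(abs(al[, 1] - al[, 2])), mean(abs(freq[, 1] - freq[, 2])))

  expect_error(injectScenario(freq, "nonsense"), "unknown scenario label")
})

test_that("injected windows are recovered by the classifier above chance", {
  nReg <- 240L
  inj <- data.frame(
    region = 1:16,
    label = rep(c("gene_flow", "allopatric", "recurrent", "balancing"), 4),
    popA = "A", popB = "B", multiplier = 1, stringsAsFactors = FALSE)
  cfg <- simConfig(popNames = c("A", "B"), samplesPerPop = c(10, 10),
                   nOutgroup = 0, branchDivergence = c(5e-4, 5e-4),
                   driftF = c(0, 0), thetaShape = 0,
                   migration = matrix(FALSE, 2, 2), expansionRate = c(0, 0),
                   missingRate = 0.02, simulateDepth = FALSE,
                   nRegions = nReg, regionLengthBp = 5000L, windowBp = 5000L,
                   seed = 97, scenarioInjections = inj)
  sim <- simulateGenotypes(cfg)
  win <- assignWindows(sim$genotypes, sim$regions, windowBp = 5000)
  st <- computeWindowStats(sim$genotypes, win)
  cl <- classifyWindows(st, "A", "B")
  truth <- sim$truth$windows
  called <- cl$scenario[match(truth$window_id, cl$window_id)]
  long <- c(gene_flow = "divergence_with_gene_flow",
            allopatric = "allopatric_selection",
            recurrent = "recurrent_selection",
            balancing = "balancing_selection")
  for (lab in names(long)) {
    injected <- truth$scenario == lab
    recall <- mean(called[injected] == long[[lab]])
    falseRate <- mean(called[truth$scenario == "neutral"] == long[[lab]])
    expect_gt(recall, 3 * max(falseRate, 1 / sum(truth$scenario == "neutral")))
  }
})

test_that("simulated truth tables are exhaustive and consistent", {
  cfg <- smallCfg(nRegions = 12L, regionLengthBp = 500L, windowBp = 200L)
  sim <- simulateGenotypes(cfg)
  truth <- sim$truth
  win <- tileWindows(sim$regions, windowBp = 200)
  expect_setequal(truth$windows$window_id, win$window_id)
  expect_true(all(truth$windows$scenario == "neutral"))
  expect_equal(truth$pairs$true_divergence, 1e-3)
  expect_true(all(truth$windows$chrom %in% sim$genotypes@chrom))
})
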