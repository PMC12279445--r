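test_that("per-site Pi, D_XY and Hudson F_ST match hand enumeration", {
  # alleles {0,0,0,1}: 3 differing pairs of 6
  sp <- sitePi(c0 = 3, c1 = 1)
  expect_equal(sp$diffs, 3)
  expect_equal(sp$comparisons, 6)
  # invariant site, n = 10 -> (0, 45); n = 1 excluded
  expect_equal(sitePi(10, 0), list(diffs = 0, comparisons = 45))
  expect_equal(sitePi(1, 0)$comparisons, 0)

  # A = {0,0}, B = {0,1}: 2 differing of 4 cross pairs
  sd <- siteDxy(2, 0, 1, 1)
  expect_equal(sd$diffs, 2)
  expect_equal(sd$comparisons, 4)
  # complete fixation
  expect_equal(siteDxy(4, 0, 0, 4), list(diffs = 16, comparisons = 16))
  # one side ungenotyped contributes nothing
  expect_equal(siteDxy(0, 0, 2, 2)$comparisons, 0)

  # Hudson per-site values
  h <- hudsonFstSite(1, 10, 0, 10)
  expect_equal(h$numerator, 1)
  expect_equal(h$denominator, 1)
  h <- hudsonFstSite(0.5, 10, 0.5, 10)
  expect_equal(h$numerator, -2 * 0.25 / 9, tolerance = 1e-12)
  expect_equal(h$denominator, 0.5)
  expect_equal(h$numerator / h$denominator, -1 / 9, tolerance = 1e-9)
  expect_equal(hudsonFstSite(0, 10, 0, 10),
               list(numerator = 0, denominator = 0))
  # insufficient sample size drops the site
  expect_equal(hudsonFstSite(0.5, 1, 0.5, 10)$denominator, 0)
})

test_that("window statistics are ratios of sums, not means of ratios", {
  # 10-site window: one site with one het of 5 diploids, 9 invariant
  dos <- matrix(0L, 10, 5)
  dos[1, 1] <- 1L
  gt <- makeGT(dos, rep("A", 5))
  win <- assignWindows(gt, oneRegion(10), windowBp = 10)
  st <- computeWindowStats(gt, win)
  pi <- st$value[st$stat == "pi"]
  # per site: 1*9/45 at site 1; summed: 9 / (10*45) = 0.02
  expect_equal(pi, 9 / 450)
  # mean of per-site ratios would be (9/45)/10 = 0.02 here too, so use an
  # uneven-missingness case where the two disagree
  dos2 <- matrix(0L, 2, 5)
  dos2[1, ] <- c(1L, 0L, 0L, 0L, 0L)
  dos2[2, ] <- c(1L, 0L, NA, NA, NA)
  gt2 <- makeGT(dos2, rep("A", 5))
  win2 <- assignWindows(gt2, oneRegion(2), windowBp = 2)
  st2 <- computeWindowStats(gt2, win2)
  # sums: diffs 9 + 3, comps 45 + 6 -> 12/51; mean of ratios = (0.2+0.5)/2
  expect_equal(st2$value[st2$stat == "pi"], 12 / 51)
  expect_false(isTRUE(all.equal(st2$value[st2$stat == "pi"], 0.35)))
})

test_that("all-invariant windows give Pi = 0 and no-data windows give NA", {
  dos <- matrix(0L, 5, 4)
  gt <- makeGT(dos, rep("A", 4))
  win <- assignWindows(gt, oneRegion(5), windowBp = 5)
  st <- computeWindowStats(gt, win)
  expect_equal(st$value[st$stat == "pi"], 0)
  # fully missing -> undefined, not zero
  dosNA <- matrix(NA_integer_, 5, 4)
  gtNA <- makeGT(dosNA, rep("A", 4))
  stNA <- computeWindowStats(gtNA, assignWindows(gtNA, oneRegion(5), 5))
  expect_true(is.na(stNA$value[stNA$stat == "pi"]))
  expect_equal(stNA$n_sites[stNA$stat == "pi"], 0L)
})

test_that("windowed Pi/D_XY/F_ST match exhaustive enumeration oracles", {
  set.seed(101)
  for (rep in 1:12) {
    gt <- randomFixture(nA = sample(2:5, 1), nB = sample(2:5, 1),
                        nSitesV = sample(5:20, 1), nSitesI = sample(0:10, 1))
    n <- nSites(gt)
    win <- assignWindows(gt, oneRegion(n), windowBp = n)
    st <- computeWindowStats(gt, win)
    dosA <- dosage(gt)[, populationOf(gt) == "A", drop = FALSE]
    dosB <- dosage(gt)[, populationOf(gt) == "B", drop = FALSE]
    expect_equal(st$value[st$stat == "pi" & st$group == "A"],
                 oraclePi(dosA), tolerance = 1e-12)
    expect_equal(st$value[st$stat == "pi" & st$group == "B"],
                 oraclePi(dosB), tolerance = 1e-12)
    expect_equal(st$value[st$stat == "dxy"], oracleDxy(dosA, dosB),
                 tolerance = 1e-12)
    expect_equal(st$value[st$stat == "fst"], oracleFst(dosA, dosB),
                 tolerance = 1e-12)
  }
})

test_that("D_XY and F_ST are symmetric in the pair order", {
  set.seed(7)
  gt <- randomFixture()
  n <- nSites(gt)
  win <- assignWindows(gt, oneRegion(n), windowBp = n)
  ab <- computeWindowStats(gt, win, pairs = data.frame(popA = "A", popB = "B"))
  ba <- computeWindowStats(gt, win, pairs = data.frame(popA = "B", popB = "A"))
  expect_equal(ab$value[ab$stat == "dxy"], ba$value[ba$stat == "dxy"])
  expect_equal(ab$value[ab$stat == "fst"], ba$value[ba$stat == "fst"])
})

test_that("adding fully-missing genotypes changes no statistic", {
  set.seed(13)
  gt <- randomFixture(nA = 3, nB = 3)
  n <- nSites(gt)
  dosPlus <- cbind(dosage(gt), xA = rep(NA_integer_, n),
                   xB = rep(NA_integer_, n))
  gtPlus <- makeGT(dosPlus, c(populationOf(gt), "A", "B"),
                   alt = gt@alt, pos = gt@pos)
  win <- assignWindows(gt, oneRegion(n), windowBp = n)
  winP <- assignWindows(gtPlus, oneRegion(n), windowBp = n)
  a <- computeWindowStats(gt, win)
  b <- computeWindowStats(gtPlus, winP)
  for (s in c("pi", "dxy", "fst"))
    expect_equal(a$value[a$stat == s], b$value[b$stat == s], tolerance = 1e-12)
})

test_that("Tajima's D reproduces SFS-oracle values on hand-built windows", {
  # n = 4 haplotypes (2 diploids); one singleton site among invariants
  dos <- matrix(0L, 10, 2)
  dos[4, 1] <- 1L
  gt <- makeGT(dos, rep("A", 2))
  st <- computeWindowStats(gt, assignWindows(gt, oneRegion(10), 10))
  d <- st$value[st$stat == "tajima_d"]
  expect_equal(d, -0.612, tolerance = 1e-3)
  expect_equal(d, oracleTajimaD(4, c(1)), tolerance = 1e-12)

  # one balanced 2/2 site
  dos2 <- matrix(0L, 10, 2)
  dos2[4, ] <- c(2L, 0L)
  gt2 <- makeGT(dos2, rep("A", 2))
  st2 <- computeWindowStats(gt2, assignWindows(gt2, oneRegion(10), 10))
  d2 <- st2$value[st2$stat == "tajima_d"]
  expect_equal(d2, 1.63, tolerance = 1e-2)
  expect_equal(d2, oracleTajimaD(4, c(2)), tolerance = 1e-12)

  # monomorphic window undefined
  gt3 <- makeGT(matrix(0L, 10, 2), rep("A", 2))
  st3 <- computeWindowStats(gt3, assignWindows(gt3, oneRegion(10), 10))
  expect_true(is.na(st3$value[st3$stat == "tajima_d"]))
})

test_that("Tajima's D excludes incomplete sites but keeps the full n", {
  # site 2 has a missing genotype: complete-case excludes it entirely
  dos <- matrix(0L, 6, 3)
  dos[1, 1] <- 1L
  dos[2, ] <- c(2L, NA, 0L)
  gt <- makeGT(dos, rep("A", 3))
  st <- computeWindowStats(gt, assignWindows(gt, oneRegion(6), 6))
  expect_equal(st$value[st$stat == "tajima_d"],
               oracleTajimaD(6, c(1)), tolerance = 1e-12)
  expect_equal(st$n_variant_sites[st$stat == "tajima_d"], 1L)
})

test_that("splitting one population in half makes D_XY track Pi", {
  set.seed(23)
  # same genotypes, two labelings: one population vs. two random halves
  dos <- matrix(0L, 400, 10)
  for (s in 1:400) {
    if (runif(1) < 0.2) dos[s, ] <- rbinom(10, 2, runif(1, 0.05, 0.95))
  }
  whole <- makeGT(dos, rep("A", 10))
  halves <- makeGT(dos, sample(rep(c("H1", "H2"), each = 5)))
  reg <- oneRegion(400)
  piW <- computeWindowStats(whole, assignWindows(whole, reg, 400))
  dxyH <- computeWindowStats(halves, assignWindows(halves, reg, 400))
  expect_equal(dxyH$value[dxyH$stat == "dxy"],
               piW$value[piW$stat == "pi"], tolerance = 0.05)
})
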