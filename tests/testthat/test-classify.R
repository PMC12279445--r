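test_that("z-standardization uses the population SD and flags constants", {
  z <- standardizeValues(c(1, 2, 3))
  expect_equal(z[3], 1.2247, tolerance = 1e-4)
  expect_equal(z[1], -1.2247, tolerance = 1e-4)
  expect_false(attr(z, "degenerate"))

  zc <- standardizeValues(rep(2, 5))
  expect_true(all(is.na(zc)))
  expect_true(attr(zc, "degenerate"))

  # undefined windows stay NA but do not poison the others
  zna <- standardizeValues(c(1, NA, 3))
  expect_true(is.na(zna[2]))
  expect_equal(zna[c(1, 3)], c(-1, 1))
})

test_that("the four scenario rules classify the textbook z-triples", {
  expect_equal(classifyScenario(2.5, 3.5, 0), "divergence_with_gene_flow")
  expect_equal(classifyScenario(2.5, 1.0, -1.5), "allopatric_selection")
  expect_equal(classifyScenario(1.2, -1.3, -1.2), "recurrent_selection")
  expect_equal(classifyScenario(-0.5, 3.2, 3.4), "balancing_selection")
  expect_equal(classifyScenario(0, 0, 0), "none")
  expect_equal(classifyScenario(NA, 3.5, 0), "none")
})

test_that("upper-boundary threshold semantics are available behind a flag", {
  # z_pi = -0.5: below +1 but not below -1
  expect_equal(classifyScenario(2.5, 1.0, -0.5, semantics = "upper"),
               "allopatric_selection")
  expect_equal(classifyScenario(2.5, 1.0, -0.5, semantics = "two-sided"),
               "none")
  expect_equal(classifyScenario(1.2, 0.5, 0.5, semantics = "upper"),
               "recurrent_selection")
})

test_that("categories are mutually exclusive and order-invariant", {
  set.seed(41)
  z <- matrix(rnorm(3000, sd = 2), ncol = 3)
  s <- classifyScenario(z[, 1], z[, 2], z[, 3])
  # exactly one label per window by construction; check against a literal
  # re-evaluation of each rule to confirm first-match-wins precedence
  gf <- z[, 1] > 2 & z[, 2] > 3 & z[, 3] < 3
  al <- z[, 1] > 2 & z[, 2] < 3 & z[, 3] < -1
  re <- z[, 1] > 1 & z[, 2] < -1 & z[, 3] < -1
  ba <- z[, 1] < 3 & z[, 2] > 3 & z[, 3] > 3
  expected <- rep("none", nrow(z))
  expected[ba] <- "balancing_selection"
  expected[re] <- "recurrent_selection"
  expected[al] <- "allopatric_selection"
  expected[gf] <- "divergence_with_gene_flow"
  expect_equal(s, expected)
  # permuting window order permutes calls identically
  p <- sample(nrow(z))
  expect_equal(classifyScenario(z[p, 1], z[p, 2], z[p, 3]), s[p])
})

test_that("classification is invariant to affine transforms of a statistic", {
  set.seed(43)
  n <- 60
  ids <- sprintf("w%02d", 1:n)
  fst <- rnorm(n, 0.2, 0.1)
  dxy <- rnorm(n, 0.004, 5e-4)
  piA <- rnorm(n, 0.003, 4e-4)
  piB <- rnorm(n, 0.003, 4e-4)
  mk <- function(f, d, pa, pb) rbind(
    statRows(ids, "A|B", "fst", f), statRows(ids, "A|B", "dxy", d),
    statRows(ids, "A", "pi", pa), statRows(ids, "B", "pi", pb))
  base <- classifyWindows(mk(fst, dxy, piA, piB), "A", "B")
  shifted <- classifyWindows(mk(10 + 3 * fst, dxy, piA, piB), "A", "B")
  expect_equal(shifted$scenario, base$scenario)
  expect_equal(shifted$z_fst, base$z_fst, tolerance = 1e-12)
})

test_that("Pi is averaged between the two populations before standardizing", {
  ids <- c("w1", "w2", "w3")
  stats <- rbind(
    statRows(ids, "A|B", "fst", c(0.1, 0.2, 0.3)),
    statRows(ids, "A|B", "dxy", c(0.003, 0.004, 0.005)),
    statRows(ids, "A", "pi", c(0.002, 0.002, 0.002)),
    statRows(ids, "B", "pi", c(0.004, 0.002, 0.002)))
  cl <- classifyWindows(stats, "A", "B")
  expect_equal(cl$pi, c(0.003, 0.002, 0.002))
})

test_that("windows with undefined statistics are never classified", {
  ids <- c("w1", "w2", "w3", "w4")
  stats <- rbind(
    statRows(ids, "A|B", "fst", c(0.1, NA, 0.3, 0.5)),
    statRows(ids, "A|B", "dxy", c(0.003, 0.004, 0.005, 0.004)),
    statRows(ids, "A", "pi", c(0.002, 0.003, 0.004, 0.003)),
    statRows(ids, "B", "pi", c(0.002, 0.003, 0.004, 0.003)))
  cl <- classifyWindows(stats, "A", "B")
  expect_true(is.na(cl$z_fst[2]))
  expect_equal(cl$scenario[2], "none")
  sm <- scenarioSummary(cl)
  expect_equal(sm$total_windows, 3L)
})

test_that("a degenerate comparison yields no classifications", {
  ids <- c("w1", "w2", "w3")
  stats <- rbind(
    statRows(ids, "A|B", "fst", rep(0.2, 3)),
    statRows(ids, "A|B", "dxy", c(0.003, 0.004, 0.005)),
    statRows(ids, "A", "pi", c(0.002, 0.003, 0.004)),
    statRows(ids, "B", "pi", c(0.002, 0.003, 0.004)))
  cl <- classifyWindows(stats, "A", "B")
  expect_true(attr(cl, "degenerate"))
  expect_true(all(cl$scenario == "none"))
})

test_that("D_XY ~ Pi relationship recovers identity and anti-ranking", {
  x <- c(0.001, 0.002, 0.003, 0.004)
  r <- dxyPiRelationship(dxy = x, pi = x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$rho, 1)
  r2 <- dxyPiRelationship(dxy = rev(x), pi = x)
  expect_equal(r2$rho, -1)
  # degenerate input flagged as NA
  r3 <- dxyPiRelationship(dxy = c(1, 1, 1), pi = x[1:3])
  expect_true(is.na(r3$slope))
  r4 <- dxyPiRelationship(dxy = c(1, 2), pi = c(1, 2))
  expect_true(is.na(r4$slope))
})

test_that("F_ST outliers use a strict +3 SD cut and map to genic regions", {
  n <- 200
  ids <- sprintf("w%03d", 1:n)
  calls <- data.frame(window_id = ids, chrom = "chr1",
                      window_start = seq(1, by = 100, length.out = n),
                      window_end = seq(100, by = 100, length.out = n),
                      z_fst = 0, stringsAsFactors = FALSE)
  calls$z_fst[1] <- 3.01
  calls$z_fst[2] <- 3.0
  calls$z_fst[3] <- 5
  regions <- data.frame(region_id = c("gene1", "geneNone"),
                        chrom = "chr1", start = c(0L, 150000L),
                        end = c(50L, 150100L), genic = 1L, frame = "0",
                        stringsAsFactors = FALSE)
  out <- fstOutlierWindows(calls, regions)
  expect_equal(out$window_id, c("w001", "w003"))
  expect_equal(out$genes, c("gene1", ""))
})

test_that("about 13.5 of 10,000 standard-normal windows exceed +3 SD", {
  set.seed(47)
  z <- standardizeValues(rnorm(10000))
  count <- sum(z > 3)
  expect_gt(count, 3)
  expect_lt(count, 28)
})
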