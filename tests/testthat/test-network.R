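test_that("Spearman matrix matches hand values and handles constants", {
  m <- cbind(a = 1:5, b = c(1, 3, 2, 5, 4), c = 5:1, flat = rep(2, 5))
  rownames(m) <- paste0("s", 1:5)
  cm <- spearmanMatrix(OtuTable(m))
  expect_equal(cm@r["a", "a"], 1)
  expect_equal(cm@r["a", "b"], 0.8)   # 1 - 6*4/(5*24)
  expect_equal(cm@r["a", "c"], -1)
  expect_equal(cm@p["a", "c"], 0)
  expect_equal(cm@r["a", "flat"], 0)
  expect_equal(cm@p["a", "flat"], 1)
  expect_identical(cm@flagged, "flat")
  expect_error(spearmanMatrix(rand_table(4, 3, seed = 1)), ">= 5 samples")
})

test_that("Spearman matrix equals the rank-then-Pearson oracle with ties", {
  for (s in 1:5) {
    x <- rand_table(15, 20, seed = 100 + s, lambda = 2)
    cm <- spearmanMatrix(x)
    ref <- brute_spearman(otuCounts(x))
    ref[is.na(ref)] <- 0
    diag(ref) <- 1
    expect_lt(max(abs(cm@r - ref)), 1e-10)
  }
})

test_that("network thresholding keeps only strong significant pairs", {
  x <- rand_table(20, 6, seed = 7, lambda = 10)
  cm <- spearmanMatrix(x)
  # random Poisson taxa: nothing reaches |r| > 0.8
  expect_equal(length(networkNodes(buildNetwork(cm))), 0L)
  # inject one strongly coupled pair
  m <- otuCounts(x)
  m[, 2] <- m[, 1] * 2 + rep(c(0, 1), 10)
  cm2 <- spearmanMatrix(OtuTable(m))
  net <- buildNetwork(cm2)
  expect_setequal(networkNodes(net), c("t01", "t02"))
  expect_equal(nrow(networkEdges(net)), 1L)
  # raising the threshold never adds edges; BH never adds nodes
  for (rt in c(0.5, 0.7, 0.9)) {
    e_lo <- nrow(networkEdges(buildNetwork(cm2, r_thresh = rt)))
    e_hi <- nrow(networkEdges(buildNetwork(cm2, r_thresh = rt + 0.05)))
    expect_lte(e_hi, e_lo)
    n_bh <- length(networkNodes(buildNetwork(cm2, r_thresh = rt,
                                             correction = "BH")))
    n_no <- length(networkNodes(buildNetwork(cm2, r_thresh = rt)))
    expect_lte(n_bh, n_no)
  }
})

test_that("network properties summarise topology", {
  empty <- buildNetwork(spearmanMatrix(rand_table(10, 4, seed = 3)))
  expect_equal(networkProperties(empty)$nodes, 0L)
  # hand-built triangle plus a disjoint edge
  tri <- new("CooccurrenceNetwork",
             edges = data.frame(taxon_a = c("a", "b", "c", "d"),
                                taxon_b = c("b", "c", "a", "e"),
                                r = c(0.9, 0.9, 0.9, 0.95),
                                p = rep(0, 4), sign = rep(1L, 4)),
             nodes = c("a", "b", "c", "d", "e"),
             r_thresh = 0.8, p_thresh = 0.05, correction = "none")
  props <- networkProperties(tri)
  expect_equal(props$nodes, 5L)
  expect_equal(props$edges, 4L)
  expect_equal(props$pos_fraction, 1)
  expect_equal(props$components, 2L)
})

test_that("node-area curves respect filters and sample thresholds", {
  p <- makeMetacommunity(150, 2, seed = 40)
  fr <- generateNestedDesign(5, 0.5, 2, samples_per_level = 4)  # 8 per level
  base <- simulateNeutral(p, fr, 2000, m = 0.3, seed = 41)
  expect_warning(nar <- buildNar(base, fr, min_samples = 16),
                 "skipped")
  expect_true(all(nar$nodes <= nar$n_taxa_filtered))
  expect_true(all(diff(nar$area) > 0))
  expect_error(suppressWarnings(buildNar(base, fr, min_samples = 1000)),
               "min_samples")
})

test_that("breakpoint fit classifies shapes and recovers exact apexes", {
  # strictly decreasing counts
  dec <- data.frame(level = 0:6, area = (0.5 * 2^(0:6))^2,
                    nodes = c(60, 50, 41, 30, 22, 10, 3))
  expect_equal(fitNarBreakpoint(dec)@shape, "monotonic-decreasing")
  # noiseless piecewise-linear counts with an apex at level 7 of 13
  lev <- 0:12
  xx <- log10((0.5 * 2^lev)^2)
  apex <- xx[8]
  nodes <- ifelse(lev <= 7, 10 + 20 * (xx - xx[1]), NA)
  nodes[lev > 7] <- nodes[8] - 15 * (xx[lev > 7] - apex)
  pw <- data.frame(level = lev, area = (0.5 * 2^lev)^2, nodes = nodes)
  bp <- fitNarBreakpoint(pw)
  expect_equal(bp@shape, "unimodal")
  expect_equal(bp@break_level, 7)
  expect_equal(bp@slope_before, 20, tolerance = 1e-8)
  expect_equal(bp@slope_after, -15, tolerance = 1e-8)
  expect_error(fitNarBreakpoint(dec[1:4, ]), ">= 5 points")
})
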