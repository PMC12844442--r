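test_that("alpha diversity matches closed forms", {
  expect_equal(alphaDiversity(10)[, -1],
               data.frame(richness = 1, shannon = 0, simpson = 0))
  a <- alphaDiversity(c(5, 5))
  expect_equal(a$shannon, log(2))
  expect_equal(a$simpson, 0.5)
  q <- (1:3) / 6
  expect_equal(alphaDiversity(c(1, 2, 3))$shannon, -sum(q * log(q)))
  expect_error(alphaDiversity(c(0, 0)), "all-zero")
  # Shannon is maximal at the uniform composition for fixed richness
  set.seed(1)
  for (i in 1:20) {
    v <- runif(6); v <- v / sum(v) * 60
    expect_lte(alphaDiversity(v)$shannon, log(6) + 1e-12)
  }
})

test_that("Bray-Curtis matches its closed form and a brute-force oracle", {
  x <- OtuTable(matrix(c(2, 0,
                         0, 2,
                         2, 0), 3, byrow = TRUE,
                       dimnames = list(c("a", "b", "c"), c("t1", "t2"))))
  d <- as.matrix(brayCurtis(x))
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 0)
  x2 <- OtuTable(matrix(c(1, 1,
                          1, 3), 2, byrow = TRUE,
                        dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_equal(as.numeric(brayCurtis(x2)), 1 / 3)
  y <- rand_table(10, 10, seed = 6, lambda = 5)
  expect_equal(unname(as.matrix(brayCurtis(y))),
               unname(brute_bray(otuCounts(y))), tolerance = 1e-12)
  bad <- OtuTable(matrix(c(1, 1, 0, 0), 2, byrow = TRUE,
                         dimnames = list(c("ok", "empty"), c("t1", "t2"))))
  expect_error(brayCurtis(bad), "empty")
})

test_that("environmental heterogeneity standardizes then measures distance", {
  fr <- data.frame(sample_id = c("a", "b"), group = "G", plot_id = "p1",
                   x = 0, y = 0, level = 0:1, area = c(1, 4))
  env <- data.frame(sample_id = c("a", "b"), v = c(0, 2))
  het <- envHeterogeneity(env, fr)
  expect_equal(unname(het$distances$G), sqrt(2))  # z-scores -/+ 1/sqrt(2)
  # identical samples are at distance zero; reordering variables is neutral
  env2 <- data.frame(sample_id = c("a", "b"), v1 = c(1, 1), v2 = c(3, 3))
  expect_warning(expect_error(envHeterogeneity(env2, fr), "no variable"))
  env3 <- data.frame(sample_id = c("a", "b"), v1 = c(1, 2), v2 = c(9, 4))
  h1 <- envHeterogeneity(env3, fr)
  h2 <- envHeterogeneity(env3[, c("sample_id", "v2", "v1")], fr)
  expect_equal(h1$means$mean_dist, h2$means$mean_dist)
  # Bray-Curtis variant stays within [0, 1]
  hb <- envHeterogeneity(env3, fr, metric = "braycurtis")
  expect_true(all(hb$distances$G >= 0 & hb$distances$G <= 1))
})

test_that("Mantel statistic and permutation p behave correctly", {
  y <- rand_table(12, 20, seed = 13, lambda = 8)
  d1 <- brayCurtis(y)
  expect_equal(mantelTest(d1, d1, seed = 1)@r, 1)
  # affine transforms leave Pearson r at 1
  d2 <- as.matrix(d1) * 3 + 0.2
  diag(d2) <- 0
  expect_equal(mantelTest(d1, d2, seed = 1)@r, 1)
  expect_error(mantelTest(d1, dist(matrix(rnorm(20), 5)), seed = 1),
               "differ in size")
  expect_error(mantelTest(d1, d1, n_perm = 50), "n_perm")
  # agreement with vegan on statistic and p-value
  env <- data.frame(sample_id = sampleIDs(y), v = rnorm(12))
  dv <- dist(env$v)
  attr(dv, "Labels") <- sampleIDs(y)
  mine <- mantelTest(d1, dv, n_perm = 999, seed = 4)
  ref <- vegan::mantel(d1, dv, permutations = 999)
  expect_equal(mine@r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine@p - ref$signif), 0.08)
  # p-value is stable under a joint relabeling of both matrices
  ord <- sample(12)
  m1 <- as.matrix(d1)[ord, ord]
  m2 <- as.matrix(dv)
  rownames(m2) <- colnames(m2) <- sampleIDs(y)
  m2 <- m2[ord, ord]
  rel <- mantelTest(m1, m2, n_perm = 999, seed = 4)
  expect_equal(rel@r, mine@r, tolerance = 1e-12)
  expect_lt(abs(rel@p - mine@p), 0.08)
})

test_that("Mantel permutation test is calibrated under independence", {
  # independent random matrices: rejection rate at alpha = 0.05 stays near
  # nominal (two-sided binomial band for 500 replicates)
  rej <- 0
  set.seed(99)
  for (i in 1:500) {
    d1 <- dist(matrix(rnorm(15 * 3), 15))
    d2 <- dist(matrix(rnorm(15 * 3), 15))
    p <- mantelTest(d1, d2, n_perm = 999, seed = i)@p
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / 500, 0.02)
  expect_lte(rej / 500, 0.08)
})
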