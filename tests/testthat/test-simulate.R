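test_that("metacommunity abundances are a normalized lognormal pool", {
  p <- makeMetacommunity(200, 2, seed = 3)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  # sigma -> 0 degenerates to the even pool
  p0 <- makeMetacommunity(50, 0, seed = 3)
  expect_equal(unname(p0), rep(1 / 50, 50))
  expect_true(all(diff(sort(p, decreasing = TRUE)) <= 0))
  expect_error(makeMetacommunity(1), "S must be")
})

test_that("nested design doubles quadrat side per level and nests plots", {
  fr <- generateNestedDesign(3, side0 = 0.5, n_plots = 2,
                             samples_per_level = 4)
  expect_equal(sort(unique(fr$area)), c(0.25, 1, 4))
  # every coordinate lies within the largest quadrat extent
  Lmax <- 0.5 * 2^2
  expect_true(all(fr$x <= Lmax & fr$y <= Lmax & fr$x >= 0 & fr$y >= 0))
  # 13 levels reproduce the 0.5 m .. 2048 m nested span
  fr13 <- generateNestedDesign(13, side0 = 0.5, n_plots = 1,
                               samples_per_level = 1)
  expect_equal(max(fr13$area), 2048^2)
  expect_equal(min(fr13$area), 0.25)
  # level-k samples lie inside the level-(k+1) quadrat of the same plot
  for (k in 0:1) {
    Lnext <- 0.5 * 2^(k + 1)
    sub <- fr[fr$level == k, ]
    expect_true(all(sub$x <= Lnext & sub$y <= Lnext))
  }
})

test_that("neutral simulation conserves depth and matches Sloan occupancy", {
  p <- makeMetacommunity(50, 1.5, seed = 7)
  x <- simulateNeutral(p, 100, N_reads = 1000, m = 0.2, seed = 8)
  expect_true(all(rowSums(otuCounts(x)) == 1000))
  expect_identical(otuCounts(simulateNeutral(p, 10, 500, 0.2, seed = 5)),
                   otuCounts(simulateNeutral(p, 10, 500, 0.2, seed = 5)))
  expect_error(simulateNeutral(p, 10, 500, m = 1e-5), "m must")

  # occupancy oracle: P(detected) = E_q[1 - (1 - q)^N] under the Beta law,
  # by numerical integration, checked within a 99% binomial band per taxon
  N <- 1000; m <- 0.2; Nm <- N * m
  occ_obs <- colMeans(otuCounts(x) > 0)
  idx <- order(p)[round(seq(1, 50, length.out = 8))]
  for (i in idx) {
    pred <- integrate(function(q)
      dbeta(q, Nm * p[i], Nm * (1 - p[i])) * (1 - (1 - q)^N),
      0, 1, rel.tol = 1e-9)$value
    band <- pred + c(-1, 1) * (2.58 * sqrt(pred * (1 - pred) / 100) + 0.02)
    expect_gte(occ_obs[i], band[1])
    expect_lte(occ_obs[i], band[2])
  }

  # taxa well above the detection limit approach occupancy 1 at large N m
  abundant <- p > 50 / 1000
  expect_true(all(colMeans(otuCounts(x) > 0)[abundant] > 0.99))
})

test_that("niche simulation induces an environmental distance decay", {
  p <- makeMetacommunity(150, 1.5, seed = 9)
  fr <- generateNestedDesign(4, 0.5, 2, samples_per_level = 4)
  sim <- simulateNiche(p, fr, N_reads = 3000, niche_strength = 10, seed = 10)
  expect_true(all(rowSums(otuCounts(sim$otu)) == 3000))
  expect_true(all(c("SWC", "pH", "SOC", "TN", "TP", "NH4", "NO3")
                  %in% names(sim$env)))
  # samples at identical coordinates see the identical field value
  same <- which(fr$x == 0 & fr$y == 0 & fr$plot_id == fr$plot_id[1])
  expect_equal(sim$env$E[same[1]], sim$env$E[same[2]])
  # composition diverges with environmental distance under strong filtering
  bc <- as.matrix(brayCurtis(sim$otu))
  dE <- as.matrix(dist(sim$env$E))
  lt <- lower.tri(bc)
  expect_gt(cor(dE[lt], bc[lt], method = "spearman"), 0.3)
  # niche_strength = 0 removes the environmental signal
  sim0 <- simulateNiche(p, fr, N_reads = 3000, niche_strength = 0, seed = 10)
  bc0 <- as.matrix(brayCurtis(sim0$otu))
  expect_lt(cor(dE[lt], bc0[lt], method = "spearman"), 0.3)
})

test_that("guild overlay creates, and collapse destroys, strong correlations", {
  p <- makeMetacommunity(100, 1.5, seed = 12)
  fr <- generateNestedDesign(5, 0.5, 2, samples_per_level = 4)  # 40 samples
  base <- simulateNeutral(p, fr, 4000, m = 0.5, seed = 3)
  # loading 0 is the identity
  g0 <- simulateGuilds(base, fr, list(list(size = 5, loading = 0,
                                           collapse_level = Inf)), seed = 3)
  expect_identical(otuCounts(g0$otu), otuCounts(base))
  # guild of 5 with loading 1.5: all 10 within-guild Spearman r exceed 0.8
  g1 <- simulateGuilds(base, fr, list(list(size = 5, loading = 1.5,
                                           collapse_level = Inf)), seed = 3)
  r <- cor(otuCounts(g1$otu)[, g1$members[[1]]], method = "spearman")
  expect_true(all(r[upper.tri(r)] > 0.8))
  # collapse at level 0: no within-guild edge survives thresholding
  g2 <- simulateGuilds(base, fr, list(list(size = 5, loading = 1.5,
                                           collapse_level = 0)), seed = 3)
  net <- buildNetwork(spearmanMatrix(g2$otu[, g2$members[[1]]]))
  expect_equal(nrow(networkEdges(net)), 0L)
  # depth conservation and determinism
  expect_equal(rowSums(otuCounts(g1$otu)), rowSums(otuCounts(base)))
  g1b <- simulateGuilds(base, fr, list(list(size = 5, loading = 1.5,
                                            collapse_level = Inf)), seed = 3)
  expect_identical(otuCounts(g1$otu), otuCounts(g1b$otu))
  expect_error(simulateGuilds(base, fr, list(list(size = 80, loading = 1,
                                                  collapse_level = Inf),
                                             list(size = 30, loading = 1,
                                                  collapse_level = Inf)),
                              seed = 1),
               "guild sizes")
})
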