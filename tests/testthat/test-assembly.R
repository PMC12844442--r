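test_that("neutral prediction equals the Beta integral and is monotone", {
  # oracle: numerical integration of the Beta density above the limit
  oracle <- integrate(function(q) dbeta(q, 1000 * 0.01, 1000 * 0.99),
                      5e-4, 1, rel.tol = 1e-10)$value
  expect_equal(ncmPredict(0.01, Nm = 1000, d = 5e-4), oracle,
               tolerance = 1e-8)
  # limits: concentration above/below the detection threshold
  expect_gt(ncmPredict(0.01, Nm = 1e7, d = 5e-4), 0.999)
  expect_lt(ncmPredict(1e-4, Nm = 1e7, d = 5e-4), 0.001)
  # monotone in p and in Nm (for p above d)
  ps <- seq(0.001, 0.2, length.out = 30)
  pred <- ncmPredict(ps, 500, 5e-4)
  expect_true(all(diff(pred) >= 0))
  expect_true(all(diff(pred[pred < 0.999]) > 0))
  nms <- 10^seq(0, 4, length.out = 25)
  f <- vapply(nms, function(nm) ncmPredict(0.01, nm, 5e-4), numeric(1))
  expect_true(all(diff(f) > -1e-12))
  expect_error(ncmPredict(0, 10, 0.01), "p must")
  expect_error(ncmPredict(0.1, -1, 0.01), "Nm")
})

test_that("NCM fitting recovers migration rates in order", {
  p <- makeMetacommunity(250, 2, seed = 50)
  fits <- lapply(c(0.05, 0.5), function(m) {
    x <- simulateNeutral(p, 60, N_reads = 1500, m = m, seed = 51)
    suppressWarnings(fitNcm(x))
  })
  expect_lt(fits[[1]]@m, fits[[2]]@m)
  expect_equal(fits[[1]]@m, 0.05, tolerance = 0.25)
  expect_gt(fits[[1]]@r2, 0.7)
  expect_equal(fits[[1]]@Nm, fits[[1]]@m * 1500)
  part <- fits[[1]]@taxa$partition
  expect_true(all(part %in% c("above", "within", "below")))
  # non-uniform depths are refused
  bad <- rand_table(25, 30, seed = 5, lambda = 10)
  expect_error(fitNcm(bad), "rarefy")
  # saturated tables push Nm to the bound with a warning
  sat <- OtuTable(matrix(50, 25, 4,
                         dimnames = list(paste0("s", 1:25), paste0("t", 1:4))))
  expect_warning(fitNcm(sat), "saturated")
})

test_that("NST is bounded and self-consistent under its own null", {
  fr <- generateNestedDesign(3, 0.5, 1, samples_per_level = 4)
  # random tables stay within [0, 1]
  for (s in 1:5) {
    x <- rand_table(12, 40, seed = 200 + s, lambda = 2)
    fr2 <- data.frame(sample_id = sampleIDs(x), group = "G", plot_id = "p",
                      x = 0, y = 0, level = 0, area = 1)
    fr2$level <- seq_len(12) %% 3
    fr2$area <- (0.5 * 2^fr2$level)^2
    nst <- computeNst(x, fr2, n_null = 50, seed = s)
    expect_gte(nst$nst, 0)
    expect_lte(nst$nst, 1)
  }
  # communities generated by the null model itself score as stochastic
  set.seed(77)
  reg_p <- as.numeric(makeMetacommunity(80, 1.5, seed = 78))
  occ <- pmin(0.2 + reg_p * 40, 1)
  m <- matrix(0, 16, 80, dimnames = list(paste0("s", 1:16),
                                         sprintf("t%03d", 1:80)))
  for (j in 1:16) {
    rich <- 30
    idx <- sample.int(80, rich, prob = occ)
    m[j, idx] <- as.numeric(rmultinom(1, 800, reg_p[idx] / sum(reg_p[idx])))
  }
  frn <- data.frame(sample_id = rownames(m), group = "G", plot_id = "p",
                    x = 0, y = 0, level = rep(0:3, 4),
                    area = (0.5 * 2^rep(0:3, 4))^2)
  nst_null <- computeNst(OtuTable(m), frn, n_null = 100, seed = 5)
  expect_gt(nst_null$nst, 0.5)
  # groups below 4 samples are skipped
  small <- frn[1:3, ]
  expect_warning(expect_error(
    computeNst(OtuTable(m[1:3, ]), small, n_null = 10, seed = 1),
    "no group"), "fewer than 4")
})

test_that("Levins niche breadth matches closed forms and the oracle", {
  m <- matrix(c(4, 4, 4, 4, 4,
                9, 0, 0, 0, 0,
                5, 5, 0, 0, 0), 5, 3,
              dimnames = list(paste0("s", 1:5), c("even", "one", "half")))
  nb <- nicheBreadth(OtuTable(m))
  B <- setNames(nb$taxa$B, nb$taxa$taxon_id)
  expect_equal(B[["even"]], 5)
  expect_equal(B[["one"]], 1)
  expect_equal(B[["half"]], 2)
  expect_equal(nb$Bcom, mean(c(5, 1, 2)))
  # brute-force 1/sum(P^2) oracle on random tables
  x <- rand_table(8, 15, seed = 9, lambda = 4)
  nb2 <- nicheBreadth(x)
  mm <- otuCounts(x)[, nb2$taxa$taxon_id, drop = FALSE]
  P <- sweep(mm, 2, colSums(mm), "/")
  expect_equal(nb2$taxa$B, unname(1 / colSums(P^2)), tolerance = 1e-12)
  # zero-total taxa are excluded
  mz <- cbind(m, none = 0)
  expect_false("none" %in% nicheBreadth(OtuTable(mz))$taxa$taxon_id)
  # abundance weighting shifts the community mean toward abundant taxa
  nbw <- nicheBreadth(OtuTable(m), weighted = TRUE)
  expect_equal(nbw$Bcom, sum(c(5, 1, 2) * c(20, 9, 10)) / 39)
})
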