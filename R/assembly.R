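#' Neutral-model predicted occurrence frequency
#'
#' Under the Sloan neutral community model, a taxon with source-pool relative
#' abundance p is detected (local frequency above the detection limit d) in a
#' fraction `1 - I_d(Nm p, Nm (1 - p))` of samples, where I is the
#' regularized incomplete beta function (the Beta CDF).
#'
#' @param p mean relative abundance in (0, 1) (vectorized).
#' @param Nm product of metacommunity size and migration rate (> 0).
#' @param d detection limit in (0, 1).
#' @return Predicted occurrence frequencies in [0, 1].
#' @examples
#' ncmPredict(0.01, Nm = 1000, d = 5e-4)
#' @export
ncmPredict <- function(p, Nm, d) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie in (0, 1)")
  if (Nm <= 0) stop("Nm must be > 0")
  if (d <= 0 || d >= 1) stop("d must lie in (0, 1)")
  1 - pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Fits Nm by least squares of observed occurrence frequencies on the
#' neutral prediction [ncmPredict()] evaluated at each taxon's mean relative
#' abundance. The default detection limit is `d = log(2)/N`: under
#' multinomial read sampling a taxon at relative frequency q is detected
#' with probability `1 - (1 - q)^N`, which crosses 1/2 exactly at
#' `q = log(2)/N`, so the hard-threshold approximation is unbiased where it
#' matters; the one-read convention `d = 1/N` remains available via `d`. The
#' optimizer is nonlinear least squares (Levenberg-Marquardt) initialized
#' from a log-spaced grid search. R^2 = 1 - SSres/SStot on the frequency
#' scale; the 95\% band around the fitted curve uses Wilson binomial
#' intervals at the number of samples, and each taxon is partitioned as
#' above / within / below that band.
#'
#' @param x an [OtuTable-class] with uniform per-sample depth (rarefy
#'   first; unequal depths raise an error).
#' @param d detection limit; default log(2)/N.
#' @param Nm_max upper bound of the Nm search (default 10 N).
#' @return An [NcmFit-class] (slot `taxa` holds the per-taxon table).
#' @export
fitNcm <- function(x, d = NULL, Nm_max = NULL) {
  stopifnot(is(x, "OtuTable"))
  m <- otuCounts(x)
  tot <- rowSums(m)
  if (diff(range(tot)) > 1e-8)
    stop("per-sample depths are not uniform; rarefy first (rarefyTable)")
  N <- unname(tot[1L])
  n <- nrow(m)
  if (n < 20L) warning("fewer than 20 samples; NCM fit will be unstable")
  if (is.null(d)) d <- log(2) / N
  if (is.null(Nm_max)) Nm_max <- 10 * N
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  p_mean <- colMeans(m / N)
  freq_obs <- colMeans(m > 0)
  # guard p strictly inside (0,1) for the Beta parameters
  p_fit <- pmin(pmax(p_mean, 1e-12), 1 - 1e-12)

  sse <- function(Nm) sum((freq_obs - ncmPredict(p_fit, Nm, d))^2)
  grid <- 10^seq(log10(0.1), log10(Nm_max), length.out = 80L)
  g_sse <- vapply(grid, sse, numeric(1))
  Nm0 <- grid[which.min(g_sse)]
  fit <- tryCatch(
    minpack.lm::nlsLM(freq_obs ~ 1 - pbeta(d, Nm * p_fit, Nm * (1 - p_fit)),
                      data = list(freq_obs = freq_obs, p_fit = p_fit, d = d),
                      start = list(Nm = Nm0),
                      lower = 1e-3, upper = Nm_max,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  Nm_hat <- if (is.null(fit)) {
    # fall back to refining the grid optimum
    optimize(sse, c(max(Nm0 / 10, 1e-3), min(Nm0 * 10, Nm_max)))$minimum
  } else coef(fit)[["Nm"]]
  if (all(freq_obs >= 1 - 1e-12))
    warning("occurrence frequencies are saturated (all taxa in all samples); ",
            "Nm is only weakly identified and tends to its upper bound")
  else if (Nm_hat >= Nm_max * 0.999)
    warning("Nm hit the search upper bound")

  freq_pred <- ncmPredict(p_fit, Nm_hat, d)
  sstot <- sum((freq_obs - mean(freq_obs))^2)
  r2 <- if (sstot > 0) 1 - sum((freq_obs - freq_pred)^2) / sstot
        else as.numeric(all(freq_obs == freq_pred))
  band <- wilson_band(freq_pred, n)
  partition <- ifelse(freq_obs > band[, "upper"], "above",
                      ifelse(freq_obs < band[, "lower"], "below", "within"))
  taxa <- data.frame(taxon_id = colnames(m), p = p_mean,
                     freq_obs = freq_obs, freq_pred = freq_pred,
                     lower = band[, "lower"], upper = band[, "upper"],
                     partition = partition,
                     row.names = NULL, stringsAsFactors = FALSE)
  new("NcmFit", Nm = Nm_hat, m = Nm_hat / N, N = as.numeric(N), d = d,
      r2 = r2, taxa = taxa)
}

# One draw of the NST null model: per-sample richness fixed, occupied taxa
# drawn (without replacement) proportional to regional occurrence frequency,
# abundances re-assigned multinomially proportional to regional relative
# abundances restricted to the occupied set.
nst_null_table <- function(m, rich, depth, occ_freq, reg_p) {
  S <- ncol(m)
  out <- matrix(0, nrow(m), S)
  for (j in seq_len(nrow(m))) {
    occ <- sample.int(S, rich[j], prob = occ_freq)
    w <- reg_p[occ]
    if (sum(w) == 0) w <- rep(1, length(occ))
    cnt <- rmultinom(1L, depth[j], w / sum(w))
    out[j, occ] <- cnt
  }
  out
}

#' Normalized stochasticity ratio per group
#'
#' For each group, observed pairwise dissimilarities D_ij are compared to
#' their expectation E_ij under a null model that preserves per-sample
#' richness and draws taxon occupancy proportional to regional occurrence
#' frequency, with abundances re-assigned proportional to regional relative
#' abundances. The per-pair selection strength is
#' `C_ij = (D_ij - E_ij) / (Dmax - E_ij)` when D_ij > E_ij and
#' `(E_ij - D_ij) / E_ij` otherwise (Dmax = 1); stochasticity is
#' `ST_ij = 1 - C_ij` and NST is the mean over pairs, clipped to [0, 1],
#' with a standard error over the pairwise values. NST > 0.5 is read as
#' stochastic assembly dominance, < 0.5 as deterministic dominance.
#'
#' @param x an [OtuTable-class].
#' @param frame sample frame supplying group labels.
#' @param metric `"braycurtis"` (abundance-based) or `"jaccard"`
#'   (presence/absence).
#' @param n_null number of null communities per group.
#' @param seed integer RNG seed.
#' @param groups groups to process (default: all with >= 4 samples; smaller
#'   groups are skipped with a warning).
#' @return data.frame with columns group, nst, se, n_pairs, n_excluded,
#'   n_null, metric; per-pair ST values are attached as
#'   `attr(, "pair_st")` (a named list).
#' @export
computeNst <- function(x, frame, metric = c("braycurtis", "jaccard"),
                       n_null = 1000L, seed = 1L, groups = NULL) {
  metric <- match.arg(metric)
  stopifnot(is(x, "OtuTable"))
  frame <- validateSampleFrame(frame)
  frame <- frame[frame$sample_id %in% sampleIDs(x), , drop = FALSE]
  if (is.null(groups)) groups <- unique(frame$group)
  vd <- function(mm) {
    if (metric == "braycurtis") vegan::vegdist(mm, method = "bray")
    else vegan::vegdist(mm > 0, method = "jaccard")
  }
  res <- list()
  pair_st <- list()
  for (g in groups) {
    ids <- frame$sample_id[frame$group == g]
    if (length(ids) < 4L) {
      warning("group ", g, " has fewer than 4 samples; skipped")
      next
    }
    m <- otuCounts(x)[ids, , drop = FALSE]
    m <- m[, colSums(m) > 0, drop = FALSE]
    rich <- rowSums(m > 0)
    depth <- rowSums(m)
    occ_freq <- colMeans(m > 0)
    reg_p <- colSums(m) / sum(m)
    D <- as.numeric(vd(m))
    E_acc <- numeric(length(D))
    with_seed(derive_seed(seed, paste0("nst_", g)), {
      for (b in seq_len(n_null)) {
        nulltab <- nst_null_table(m, rich, depth, occ_freq, reg_p)
        E_acc <- E_acc + as.numeric(vd(nulltab))
      }
    })
    E <- E_acc / n_null
    ok <- E > 0
    n_excl <- sum(!ok)
    Dk <- D[ok]; Ek <- E[ok]
    C <- ifelse(Dk > Ek, (Dk - Ek) / (1 - Ek), (Ek - Dk) / Ek)
    ST <- pmin(pmax(1 - C, 0), 1)
    res[[g]] <- data.frame(group = g, nst = mean(ST),
                           se = sd(ST) / sqrt(length(ST)),
                           n_pairs = length(ST), n_excluded = n_excl,
                           n_null = as.integer(n_null), metric = metric,
                           stringsAsFactors = FALSE)
    pair_st[[g]] <- ST
  }
  if (!length(res)) stop("no group with >= 4 samples")
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "pair_st") <- pair_st
  out
}

#' Levins niche breadth
#'
#' For taxon i with occurrence proportions P_ij = count_ij / total_i across
#' samples j, Levins' index is `B_i = 1 / sum_j P_ij^2` (inverse Simpson
#' concentration of the taxon across samples; 1 = found in a single sample,
#' n = spread evenly over all n samples). The community-level breadth is the
#' mean of B_i over taxa with nonzero totals, unweighted by default.
#'
#' @param x an [OtuTable-class] with >= 2 samples.
#' @param weighted if `TRUE`, weight the community mean by taxon total
#'   abundance.
#' @return `list(taxa = data.frame(taxon_id, B), Bcom = numeric)`.
#' @export
nicheBreadth <- function(x, weighted = FALSE) {
  stopifnot(is(x, "OtuTable"))
  m <- otuCounts(x)
  if (nrow(m) < 2L) stop("need >= 2 samples")
  tot <- colSums(m)
  keep <- tot > 0
  P <- sweep(m[, keep, drop = FALSE], 2L, tot[keep], "/")
  B <- 1 / colSums(P^2)
  Bcom <- if (weighted) sum(B * tot[keep]) / sum(tot[keep]) else mean(B)
  list(taxa = data.frame(taxon_id = colnames(m)[keep], B = unname(B),
                         row.names = NULL, stringsAsFactors = FALSE),
       Bcom = Bcom)
}
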