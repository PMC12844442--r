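#' Draw a metacommunity from a lognormal species-abundance distribution
#'
#' @param S number of taxa (>= 2).
#' @param lognormal_sigma log-scale standard deviation of the abundance
#'   distribution; 0 gives a perfectly even pool.
#' @param seed integer RNG seed.
#' @return Named numeric vector `p` of relative abundances summing to 1
#'   (the source-pool frequencies of the neutral model).
#' @examples
#' p <- makeMetacommunity(100, 2, seed = 1)
#' sum(p)
#' @export
makeMetacommunity <- function(S, lognormal_sigma = 2, seed = 1L) {
  if (!is.numeric(S) || length(S) != 1L || S < 2) stop("S must be >= 2")
  if (lognormal_sigma < 0) stop("lognormal_sigma must be >= 0")
  p <- with_seed(seed, rlnorm(S, meanlog = 0, sdlog = lognormal_sigma))
  p <- p / sum(p)
  names(p) <- sprintf("otu%04d", seq_len(S))
  p
}

#' Generate a nested quadrat sampling design
#'
#' Emulates a nested plot layout in which quadrats at level k have side
#' `side0 * 2^k` (so area `(side0 * 2^k)^2` m^2) and every smaller quadrat
#' lies inside the larger ones of the same plot. Samples sit at the corners
#' of each level's quadrat. With the defaults (`side0 = 0.5`), 13 levels span
#' 0.5 x 0.5 m^2 up to 2048 x 2048 m^2.
#'
#' @param levels number of nested scales (>= 3).
#' @param side0 base quadrat side in meters (> 0).
#' @param n_plots replicate plots per group.
#' @param groups character vector of group labels.
#' @param samples_per_level samples per plot and level (placed at quadrat
#'   corners, recycled if more than 4).
#' @return A sample frame data.frame with columns sample_id, group, plot_id,
#'   x, y, level, area.
#' @export
generateNestedDesign <- function(levels, side0 = 0.5, n_plots = 3L,
                                 groups = "G1", samples_per_level = 4L) {
  if (levels < 3) stop("levels must be >= 3")
  if (side0 <= 0) stop("side0 must be > 0")
  if (samples_per_level < 1) stop("samples_per_level must be >= 1")
  rows <- list()
  for (g in groups) {
    for (pl in seq_len(n_plots)) {
      for (k in seq_len(levels) - 1L) {
        L <- side0 * 2^k
        corners <- rbind(c(0, 0), c(L, 0), c(0, L), c(L, L))
        idx <- ((seq_len(samples_per_level) - 1L) %% 4L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_p%d_l%02d_s%d", g, pl, k,
                              seq_len(samples_per_level)),
          group = g, plot_id = sprintf("%s_p%d", g, pl),
          x = corners[idx, 1L], y = corners[idx, 2L],
          level = k, area = L^2, stringsAsFactors = FALSE)
      }
    }
  }
  validateSampleFrame(do.call(rbind, rows))
}

#' Simulate communities under the Sloan neutral model
#'
#' For each sample, the local relative abundance of taxon i is drawn from the
#' stationary Sloan distribution Beta(N m p_i, N m (1 - p_i)) — the
#' neutral balance between immigration from the source pool at rate m and
#' local drift at community size N — then renormalized across taxa, and read
#' counts are drawn multinomially at depth `N_reads`.
#'
#' @param p metacommunity relative abundances (see [makeMetacommunity()]).
#' @param n_samples number of samples, or a sample frame whose `sample_id`s
#'   name the rows.
#' @param N_reads reads per sample (also the local community size N).
#' @param m migration rate in (0, 1]; values below 1e-4 are rejected as
#'   numerically degenerate.
#' @param seed integer RNG seed.
#' @return An [OtuTable-class] whose rows all sum to `N_reads`.
#' @export
simulateNeutral <- function(p, n_samples, N_reads = 2000L, m = 0.1,
                            seed = 1L) {
  stopifnot(is.numeric(p), all(p >= 0), abs(sum(p) - 1) < 1e-8)
  if (m < 1e-4 || m > 1) stop("m must lie in [1e-4, 1]")
  if (N_reads < 1) stop("N_reads must be >= 1")
  ids <- if (is.data.frame(n_samples)) n_samples$sample_id
         else sprintf("s%04d", seq_len(n_samples))
  n <- length(ids)
  S <- length(p)
  Nm <- N_reads * m
  counts <- with_seed(seed, {
    a <- Nm * p
    b <- Nm * (1 - p)
    out <- matrix(0, n, S, dimnames = list(ids, names(p)))
    for (j in seq_len(n)) {
      freq <- rbeta(S, a, b)
      if (sum(freq) == 0) freq <- p
      out[j, ] <- rmultinom(1L, N_reads, freq / sum(freq))
    }
    out
  })
  OtuTable(counts)
}

# Smooth synthetic environmental field: linear gradient across the plot
# layout plus a low-frequency random cosine surface (deterministic in the
# coordinates for a fixed seed).
env_field <- function(gx, gy, env_range, seed, n_waves = 6L) {
  span <- max(max(gx) - min(gx), max(gy) - min(gy), 1)
  grad <- env_range * ((gx - min(gx)) + (gy - min(gy))) / (2 * span)
  waves <- with_seed(derive_seed(seed, "envwaves"), {
    k <- matrix(runif(2 * n_waves, 0.5, 3) / span * 2 * pi, ncol = 2)
    ph <- runif(n_waves, 0, 2 * pi)
    am <- rnorm(n_waves, 0, env_range / 4)
    rowSums(vapply(seq_len(n_waves), function(w)
      am[w] * cos(k[w, 1] * gx + k[w, 2] * gy + ph[w]),
      numeric(length(gx))))
  })
  grad + waves
}

#' Simulate niche-filtered communities along an environmental gradient
#'
#' A smooth environmental field E(x, y) (linear gradient plus smoothed
#' random surface, amplitude `env_range`) is evaluated at the sample
#' coordinates and standardized to unit variance. Each taxon receives an
#' environmental optimum; its expected share in a sample is its source-pool
#' frequency down-weighted by a Gaussian niche kernel
#' `exp(-niche_strength (E - E_i)^2)`, renormalized, and counts are drawn
#' multinomially. `niche_strength = 0` recovers neutral-like sampling of the
#' pool. The returned env table carries the latent field plus soil-style
#' variables (SWC, pH, SOC, TN, TP, NH4, NO3) that are noisy linear
#' transforms of it.
#'
#' @param p metacommunity relative abundances.
#' @param frame sample frame with coordinates (plots are offset on a spatial
#'   grid so the field varies across plots).
#' @param N_reads reads per sample.
#' @param niche_strength selection strength (>= 0) on the unit-variance field.
#' @param env_range gradient amplitude before standardization.
#' @param seed integer RNG seed.
#' @return `list(otu = OtuTable, env = data.frame)`.
#' @export
simulateNiche <- function(p, frame, N_reads = 2000L, niche_strength = 10,
                          env_range = 2, seed = 1L) {
  stopifnot(is.numeric(p), abs(sum(p) - 1) < 1e-8)
  if (niche_strength < 0) stop("niche_strength must be >= 0")
  frame <- validateSampleFrame(frame)
  n <- nrow(frame)
  S <- length(p)
  plots <- unique(frame$plot_id)
  span <- max(frame$x, frame$y) * 1.5 + 1
  off <- data.frame(plot_id = plots,
                    ox = (seq_along(plots) - 1L) %% 3L * span,
                    oy = (seq_along(plots) - 1L) %/% 3L * span)
  ii <- match(frame$plot_id, off$plot_id)
  gx <- frame$x + off$ox[ii]
  gy <- frame$y + off$oy[ii]
  E <- env_field(gx, gy, env_range, seed)
  E <- as.numeric(scale(E))

  opt <- with_seed(derive_seed(seed, "optima"), runif(S, min(E), max(E)))
  counts <- with_seed(derive_seed(seed, "nichecounts"), {
    out <- matrix(0, n, S, dimnames = list(frame$sample_id, names(p)))
    for (j in seq_len(n)) {
      w <- p * exp(-niche_strength * (E[j] - opt)^2)
      if (sum(w) == 0) w <- p
      out[j, ] <- rmultinom(1L, N_reads, w / sum(w))
    }
    out
  })

  env <- with_seed(derive_seed(seed, "envvars"), {
    mk <- function(a, b, noise_sd) a + b * E + rnorm(n, 0, noise_sd)
    data.frame(sample_id = frame$sample_id,
               SWC = mk(20, 5, 0.5), pH = mk(7, -0.4, 0.05),
               SOC = mk(30, 8, 1), TN = mk(2.5, 0.6, 0.1),
               TP = mk(0.6, 0.1, 0.02), NH4 = mk(5, 1.2, 0.2),
               NO3 = mk(8, -1.5, 0.3), E = E,
               stringsAsFactors = FALSE)
  })
  list(otu = OtuTable(counts), env = validateEnvTable(env))
}

#' Overlay correlated guilds on a simulated community
#'
#' Each guild is a set of taxa whose counts are jointly scaled, sample by
#' sample, by a shared log-normal latent factor (`exp(loading * z)` with
#' z ~ N(0,1)), inducing strong positive rank correlations among members.
#' For samples at nested levels at or above a guild's `collapse_level` the
#' factor is re-drawn independently per member taxon, destroying the
#' correlation at large spatial scales (a designed node-area tipping point).
#' `taxon_noise` adds independent per-taxon log-normal noise in *all*
#' samples, tempering the within-guild correlation; 0 keeps the coupling
#' essentially perfect.
#'
#' With `scale_ramp = TRUE` the factor's log-scale standard deviation grows
#' linearly with the sample's nested level (from `loading / n_levels` at the
#' smallest quadrat to `loading` at the largest). This emulates guilds driven
#' by environmental variation that only materializes across large distances:
#' within a small quadrat the driver barely varies, so member taxa appear
#' uncorrelated, and the correlation — hence the co-occurrence edge — only
#' emerges once the sampled extent is wide enough. Combined with a
#' `collapse_level` this yields a rise-then-fall node-area curve.
#'
#' Guild members are assigned from the most abundant unused taxa so they
#' survive abundance/prevalence filtering. After scaling, each affected
#' sample's counts are re-drawn multinomially at its original depth, so
#' per-sample totals are conserved. A guild with loading 0 (and
#' `taxon_noise = 0`) leaves the table untouched.
#'
#' @param base an [OtuTable-class] (e.g. from [simulateNeutral()]).
#' @param frame sample frame supplying each sample's nested `level`.
#' @param guilds list of guild specs, each `list(size =, loading =,
#'   collapse_level =)`; `collapse_level = Inf` never collapses, 0 collapses
#'   everywhere.
#' @param seed integer RNG seed.
#' @param taxon_noise sd of independent per-taxon log-scale noise (>= 0).
#' @param scale_ramp if `TRUE`, ramp the factor sd with nested level (see
#'   Details); default `FALSE` (constant sd `loading`).
#' @return `list(otu = OtuTable, members = list)` with the member taxon ids
#'   of each guild.
#' @export
simulateGuilds <- function(base, frame, guilds, seed = 1L, taxon_noise = 0,
                           scale_ramp = FALSE) {
  stopifnot(is(base, "OtuTable"))
  frame <- validateSampleFrame(frame)
  m <- otuCounts(base)
  stopifnot(all(rownames(m) %in% frame$sample_id))
  lev <- frame$level[match(rownames(m), frame$sample_id)]
  sizes <- vapply(guilds, function(g) as.integer(g$size), integer(1))
  if (sum(sizes) > ncol(m)) stop("guild sizes exceed taxon count")
  ord <- order(colSums(m), decreasing = TRUE)
  members <- list()
  used <- 0L
  for (i in seq_along(guilds)) {
    members[[i]] <- colnames(m)[ord[(used + 1L):(used + sizes[i])]]
    used <- used + sizes[i]
  }
  if (anyDuplicated(unlist(members))) stop("overlapping guilds")

  n <- nrow(m)
  n_levels <- max(frame$level) + 1
  sd_scale <- if (scale_ramp) (lev + 1) / n_levels else rep(1, n)
  factors <- matrix(1, n, ncol(m), dimnames = dimnames(m))
  with_seed(seed, {
    for (i in seq_along(guilds)) {
      g <- guilds[[i]]
      shared <- exp(g$loading * sd_scale * rnorm(n))
      for (tx in members[[i]]) {
        f <- shared
        collapsed <- lev >= g$collapse_level
        if (any(collapsed))
          f[collapsed] <- exp(g$loading * sd_scale[collapsed] *
                                rnorm(sum(collapsed)))
        if (taxon_noise > 0) f <- f * exp(taxon_noise * rnorm(n))
        factors[, tx] <- f
      }
    }
    out <- m
    touched <- which(apply(factors != 1, 1L, any))
    for (j in touched) {
      w <- m[j, ] * factors[j, ]
      tot <- sum(m[j, ])
      if (sum(w) > 0 && tot > 0)
        out[j, ] <- rmultinom(1L, tot, w / sum(w))
    }
    list(otu = OtuTable(out), members = members)
  })
}

#' Write a complete synthetic study to a fixture directory
#'
#' Generates a nested design, a metacommunity, per-group communities under
#' the requested regimes (optionally with guild structure), and writes
#' `otu.tsv`, `samples.tsv`, `env.tsv` and `truth.json` (the ground-truth
#' parameters) to `dir`.
#'
#' @param dir output directory (created if missing).
#' @param levels,side0,n_plots,samples_per_level design geometry
#'   (see [generateNestedDesign()]).
#' @param S,lognormal_sigma metacommunity size and evenness.
#' @param N_reads reads per sample.
#' @param groups named list of per-group regimes, each
#'   `list(regime = "neutral"|"niche", m =, niche_strength =, guilds =,
#'   taxon_noise =)`; missing fields fall back to defaults
#'   (`m = 0.1`, `niche_strength = 10`, no guilds).
#' @param seed master integer seed; every stage derives its own sub-seed.
#' @return Invisibly, `list(otu, frame, env, truth)`.
#' @export
simulateDataset <- function(dir, levels = 9L, side0 = 0.5, n_plots = 3L,
                            samples_per_level = 4L, S = 500L,
                            lognormal_sigma = 2, N_reads = 2000L,
                            groups = list(
                              TS = list(regime = "neutral", m = 0.1,
                                        guilds = list(list(size = 10,
                                                           loading = 3,
                                                           collapse_level = 0)),
                                        scale_ramp = TRUE),
                              AS = list(regime = "neutral", m = 0.3,
                                        guilds = list(list(size = 10,
                                                           loading = 3,
                                                           collapse_level = 7),
                                                      list(size = 10,
                                                           loading = 3,
                                                           collapse_level = 7),
                                                      list(size = 10,
                                                           loading = 3,
                                                           collapse_level = 7)),
                                        scale_ramp = TRUE),
                              AM = list(regime = "niche", niche_strength = 10)),
                            seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frame <- generateNestedDesign(levels, side0, n_plots,
                                groups = names(groups),
                                samples_per_level = samples_per_level)
  p <- makeMetacommunity(S, lognormal_sigma, seed = derive_seed(seed, "meta"))
  otus <- list()
  envs <- list()
  truth <- list(seed = as.integer(seed), levels = levels, side0 = side0,
                n_plots = n_plots, samples_per_level = samples_per_level,
                S = S, N_reads = N_reads, groups = list())
  for (g in names(groups)) {
    spec <- groups[[g]]
    gframe <- frame[frame$group == g, , drop = FALSE]
    gseed <- derive_seed(seed, paste0("group_", g))
    if (identical(spec$regime, "niche")) {
      ns <- if (is.null(spec$niche_strength)) 10 else spec$niche_strength
      sim <- simulateNiche(p, gframe, N_reads, niche_strength = ns,
                           seed = gseed)
      otu <- sim$otu
      envs[[g]] <- sim$env
      truth$groups[[g]] <- list(regime = "niche", niche_strength = ns)
    } else {
      mm <- if (is.null(spec$m)) 0.1 else spec$m
      otu <- simulateNeutral(p, gframe, N_reads, m = mm, seed = gseed)
      envs[[g]] <- data.frame(sample_id = gframe$sample_id,
                              SWC = 20, pH = 7, SOC = 30, TN = 2.5,
                              TP = 0.6, NH4 = 5, NO3 = 8, E = 0)
      truth$groups[[g]] <- list(regime = "neutral", m = mm)
    }
    if (!is.null(spec$guilds)) {
      tn <- if (is.null(spec$taxon_noise)) 0 else spec$taxon_noise
      ramp <- isTRUE(spec$scale_ramp)
      gs <- simulateGuilds(otu, gframe, spec$guilds,
                           seed = derive_seed(seed, paste0("guild_", g)),
                           taxon_noise = tn, scale_ramp = ramp)
      otu <- gs$otu
      truth$groups[[g]]$guilds <- lapply(seq_along(spec$guilds), function(i)
        c(spec$guilds[[i]], list(members = gs$members[[i]])))
      truth$groups[[g]]$taxon_noise <- tn
      truth$groups[[g]]$scale_ramp <- ramp
    }
    otus[[g]] <- otuCounts(otu)
  }
  all_counts <- do.call(rbind, otus)
  otu_all <- OtuTable(all_counts[frame$sample_id, , drop = FALSE])
  env_all <- do.call(rbind, envs)
  env_all <- env_all[match(frame$sample_id, env_all$sample_id), , drop = FALSE]
  rownames(env_all) <- NULL

  writeOtuTable(otu_all, file.path(dir, "otu.tsv"), seed = seed)
  write_tsv_commented(frame, file.path(dir, "samples.tsv"), "sample frame",
                      seed = seed)
  write_tsv_commented(env_all, file.path(dir, "env.tsv"), "env table",
                      seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(otu = otu_all, frame = frame, env = env_all, truth = truth))
}
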