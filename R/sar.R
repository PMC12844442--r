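#' Build taxa-area curves from a nested design
#'
#' For every plot and nested level k, all samples of the plot at levels
#' <= k (i.e. lying inside the level-k quadrat) are pooled and the richness
#' of the pooled counts is recorded against the level-k area. Plots observed
#' at a single level cannot support a fit and are excluded with a warning.
#'
#' @param x an [OtuTable-class].
#' @param frame sample frame with plot/level/area columns.
#' @return data.frame (class `"TarCurve"` prepended) with columns group,
#'   plot_id, level, area, richness.
#' @export
buildTar <- function(x, frame) {
  stopifnot(is(x, "OtuTable"))
  frame <- validateSampleFrame(frame)
  frame <- frame[frame$sample_id %in% sampleIDs(x), , drop = FALSE]
  if (!nrow(frame)) stop("no frame sample present in the OTU table")
  out <- list()
  for (pl in unique(frame$plot_id)) {
    pf <- frame[frame$plot_id == pl, , drop = FALSE]
    levs <- sort(unique(pf$level))
    if (length(levs) < 2L) {
      warning("plot ", pl, " has a single level; excluded")
      next
    }
    for (k in levs) {
      ids <- pf$sample_id[pf$level <= k]
      pooled <- poolSamples(x, ids)
      out[[length(out) + 1L]] <- data.frame(
        group = pf$group[1L], plot_id = pl, level = k,
        area = pf$area[pf$level == k][1L],
        richness = sum(pooled > 0), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no plot with at least two levels")
  res <- do.call(rbind, out)
  class(res) <- c("TarCurve", class(res))
  res
}

# Closed-form OLS slope/intercept of y on x.
ols_fit <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  z <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(intercept = ym - z * xm, slope = z)
}

#' Fit a taxa-area model
#'
#' Logarithm model `S = c + z log(A)` by ordinary least squares on
#' log-transformed area (closed form); power model `S = c A^z` by nonlinear
#' least squares on the original scale, initialized from the log-log OLS
#' solution. R^2 is computed on the original richness scale for both, making
#' the two models directly comparable. The slope z is the spatial turnover
#' rate; its scale under the logarithm model depends on `log_base`
#' (default 10), which is recorded in the fit.
#'
#' @param curve a data.frame with `area` and `richness` columns
#'   (e.g. from [buildTar()]), already subset to one group if desired.
#' @param model `"logarithm"` or `"power"`.
#' @param log_base base of the logarithm model.
#' @return A [SarFit-class].
#' @export
fitSar <- function(curve, model = c("logarithm", "power"), log_base = 10) {
  model <- match.arg(model)
  A <- curve$area
  S <- curve$richness
  if (length(unique(A)) < 3L) stop("need >= 3 distinct areas")
  sstot <- sum((S - mean(S))^2)
  if (model == "logarithm") {
    f <- ols_fit(log(A, base = log_base), S)
    pred <- f["intercept"] + f["slope"] * log(A, base = log_base)
    r2 <- if (sstot > 0) 1 - sum((S - pred)^2) / sstot
          else as.numeric(sum((S - pred)^2) == 0)
    return(new("SarFit", model = "logarithm",
               c = unname(f["intercept"]), z = unname(f["slope"]),
               r2 = r2, n_points = length(S), log_base = log_base))
  }
  # power model: log-log OLS start, then NLS on the original scale
  if (any(S <= 0)) stop("power model needs positive richness values")
  init <- ols_fit(log(A), log(S))
  fit <- NULL
  starts <- list(unname(c(exp(init["intercept"]), init["slope"])),
                 c(mean(S), 0.25), c(mean(S), 0.5))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(S ~ c0 * A^z0,
                        data = data.frame(A = A, S = S),
                        start = list(c0 = st[1], z0 = st[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("power-model fit failed to converge from ", length(starts),
         " starts (areas ", paste(signif(range(A), 3), collapse = ".."),
         ", richness ", paste(signif(range(S), 3), collapse = ".."), ")")
  cf <- coef(fit)
  pred <- cf["c0"] * A^cf["z0"]
  r2 <- if (sstot > 0) 1 - sum((S - pred)^2) / sstot
        else as.numeric(sum((S - pred)^2) == 0)
  new("SarFit", model = "power", c = unname(cf["c0"]), z = unname(cf["z0"]),
      r2 = r2, n_points = length(S), log_base = NA_real_)
}

#' Permutation test for a slope difference between two taxa-area curves
#'
#' The observed statistic is `delta = z_a - z_b`. Under the null, the pooled
#' (area, richness) points are randomly reassigned to the two groups
#' (preserving group sizes, or entire plots when `unit = "plot"`), the model
#' is refitted on each side, and
#' `p = (1 + #{|delta_perm| >= |delta_obs|}) / (n_perm + 1)`.
#'
#' @param a,b taxa-area curves (data.frames with `area`, `richness`, and
#'   `plot_id` when permuting plots).
#' @param model SAR model for the fits (the logarithm model uses a
#'   closed-form refit; the power model refits by NLS and is markedly
#'   slower).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @param unit permutation unit, `"point"` or `"plot"`.
#' @param log_base base for the logarithm model.
#' @return A [SlopeTest-class].
#' @export
compareSlopes <- function(a, b, model = c("logarithm", "power"),
                          n_perm = 999L, seed = 1L,
                          unit = c("point", "plot"), log_base = 10) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  if (n_perm < 99) stop("n_perm must be >= 99")
  fit_z <- if (model == "logarithm") {
    function(A, S) ols_fit(log(A, base = log_base), S)[["slope"]]
  } else {
    function(A, S) fitSar(data.frame(area = A, richness = S), "power")@z
  }
  z_a <- fit_z(a$area, a$richness)
  z_b <- fit_z(b$area, b$richness)
  delta <- z_a - z_b
  A <- c(a$area, b$area)
  S <- c(a$richness, b$richness)
  n_a <- nrow(a)
  n <- length(A)
  blocks <- n_blocks_a <- NULL
  if (unit == "plot") {
    if (is.null(a$plot_id) || is.null(b$plot_id))
      stop("plot-level permutation needs plot_id columns")
    blocks <- paste(rep(c("a", "b"), c(nrow(a), nrow(b))),
                    c(a$plot_id, b$plot_id))
    n_blocks_a <- length(unique(blocks[seq_len(n_a)]))
  }
  x_all <- if (model == "logarithm") log(A, base = log_base) else A
  perm_stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    in_a <- logical(n)
    if (is.null(blocks)) {
      in_a[sample.int(n, n_a)] <- TRUE
    } else {
      chosen <- sample(unique(blocks), n_blocks_a)
      in_a <- blocks %in% chosen
    }
    za <- if (model == "logarithm") ols_fit(x_all[in_a], S[in_a])[["slope"]]
          else fit_z(A[in_a], S[in_a])
    zb <- if (model == "logarithm") ols_fit(x_all[!in_a], S[!in_a])[["slope"]]
          else fit_z(A[!in_a], S[!in_a])
    abs(za - zb)
  }, numeric(1)))
  p <- (1 + sum(perm_stat >= abs(delta))) / (n_perm + 1)
  new("SlopeTest", z_a = z_a, z_b = z_b, delta = delta, p = p,
      n_perm = as.integer(n_perm), seed = as.integer(seed), model = model)
}
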