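#' Pairwise Spearman correlation matrix with p-values
#'
#' Spearman's rank correlation with average-rank tie handling between every
#' pair of taxa. Two-sided p-values use the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom; exact
#' `r = +/-1` gets p = 0. Taxa constant across samples have undefined
#' correlations; they are recorded as r = 0, p = 1 and flagged.
#'
#' @param x an [OtuTable-class] with at least 5 samples (below that the
#'   p-values are meaningless and an error is raised).
#' @return A [CorrelationMatrix-class].
#' @export
spearmanMatrix <- function(x) {
  stopifnot(is(x, "OtuTable"))
  m <- otuCounts(x)
  n <- nrow(m)
  if (n < 5L) stop("need >= 5 samples for correlation p-values")
  const <- apply(m, 2L, function(v) length(unique(v)) == 1L)
  r <- suppressWarnings(cor(m, method = "spearman"))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  p[const, ] <- 1
  p[, const] <- 1
  diag(p) <- 0
  new("CorrelationMatrix", r = r, p = p, n_samples = as.integer(n),
      flagged = colnames(m)[const])
}

#' Threshold a correlation matrix into a co-occurrence network
#'
#' Keeps edges with `|r| > r_thresh` (strictly) and `p < p_thresh`,
#' optionally after Benjamini-Hochberg correction of the off-diagonal
#' p-values. Taxa without a surviving edge are not nodes. The defaults
#' (|r| > 0.80, raw p < 0.05) are the conventional strong-correlation filter
#' for microbiome co-occurrence networks.
#'
#' @param cm a [CorrelationMatrix-class].
#' @param r_thresh correlation magnitude threshold.
#' @param p_thresh significance threshold.
#' @param correction `"none"` or `"BH"`.
#' @return A [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(cm, r_thresh = 0.80, p_thresh = 0.05,
                         correction = c("none", "BH")) {
  correction <- match.arg(correction)
  stopifnot(is(cm, "CorrelationMatrix"))
  r <- cm@r
  p <- cm@p
  ut <- upper.tri(r)
  pv <- p[ut]
  if (correction == "BH") pv <- p.adjust(pv, method = "BH")
  keep <- abs(r[ut]) > r_thresh & pv < p_thresh
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  edges <- data.frame(taxon_a = rownames(r)[idx[, 1L]],
                      taxon_b = colnames(r)[idx[, 2L]],
                      r = r[ut][keep], p = pv[keep],
                      sign = ifelse(r[ut][keep] > 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  new("CooccurrenceNetwork", edges = edges, nodes = nodes,
      r_thresh = r_thresh, p_thresh = p_thresh, correction = correction)
}

#' Topological summaries of a co-occurrence network
#'
#' @param net a [CooccurrenceNetwork-class] (may be empty).
#' @return data.frame with nodes, edges, pos_fraction, mean_degree, density
#'   and components (all zero for an empty network).
#' @export
networkProperties <- function(net) {
  stopifnot(is(net, "CooccurrenceNetwork"))
  e <- net@edges
  if (!nrow(e))
    return(data.frame(nodes = 0L, edges = 0L, pos_fraction = 0,
                      mean_degree = 0, density = 0, components = 0L))
  g <- igraph::graph_from_data_frame(e[, c("taxon_a", "taxon_b")],
                                     directed = FALSE)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  data.frame(nodes = nv, edges = ne,
             pos_fraction = mean(e$sign > 0),
             mean_degree = 2 * ne / nv,
             density = igraph::edge_density(g),
             components = igraph::components(g)$no)
}

#' Node-area relationship on a nested design
#'
#' For each group and nested level k, the samples at levels <= k (cumulative
#' nesting, the default) or exactly k (`mode = "per-level"`) are collected,
#' the abundance/prevalence filter is re-applied to that sample set, a
#' Spearman co-occurrence network is built under the given thresholds, and
#' node/edge counts are recorded against the level-k area. Levels whose
#' sample count falls below `min_samples` are skipped with a warning
#' (correlation estimates degenerate at very small n).
#'
#' @param x an [OtuTable-class].
#' @param frame sample frame.
#' @param groups groups to process (default: all in `frame`).
#' @param min_rel_abund,min_prevalence filter thresholds
#'   (see [filterTaxa()]).
#' @param r_thresh,p_thresh,correction network thresholds
#'   (see [buildNetwork()]).
#' @param min_samples minimum samples per usable level. The default of 16
#'   keeps the expected number of chance edges small: with roughly 10^4
#'   taxon pairs tested, sample sizes below ~16 admit dozens of spurious
#'   Spearman coefficients above 0.8.
#' @param mode `"cumulative"` or `"per-level"` sample inclusion.
#' @return data.frame (class `"NarCurve"` prepended) with columns group,
#'   level, area, n_samples, n_taxa_filtered, nodes, edges, pos_fraction.
#' @export
buildNar <- function(x, frame, groups = NULL,
                     min_rel_abund = 0.001, min_prevalence = 0.2,
                     r_thresh = 0.80, p_thresh = 0.05,
                     correction = c("none", "BH"), min_samples = 16L,
                     mode = c("cumulative", "per-level")) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  stopifnot(is(x, "OtuTable"))
  frame <- validateSampleFrame(frame)
  frame <- frame[frame$sample_id %in% sampleIDs(x), , drop = FALSE]
  if (is.null(groups)) groups <- unique(frame$group)
  out <- list()
  for (g in groups) {
    gf <- frame[frame$group == g, , drop = FALSE]
    levs <- sort(unique(gf$level))
    for (k in levs) {
      ids <- if (mode == "cumulative") gf$sample_id[gf$level <= k]
             else gf$sample_id[gf$level == k]
      if (length(ids) < min_samples) {
        warning(sprintf("group %s level %g: %d sample(s) < min_samples = %d; skipped",
                        g, k, length(ids), as.integer(min_samples)))
        next
      }
      sub <- suppressWarnings(
        filterTaxa(x[ids, ], min_rel_abund, min_prevalence))
      if (nTaxa(sub) < 2L) {
        props <- data.frame(nodes = 0L, edges = 0L, pos_fraction = 0,
                            mean_degree = 0, density = 0, components = 0L)
      } else {
        net <- buildNetwork(spearmanMatrix(sub), r_thresh, p_thresh,
                            correction)
        props <- networkProperties(net)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, level = k, area = gf$area[gf$level == k][1L],
        n_samples = length(ids), n_taxa_filtered = nTaxa(sub),
        nodes = props$nodes, edges = props$edges,
        pos_fraction = props$pos_fraction, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stop("no level reaches min_samples = ", as.integer(min_samples))
  res <- do.call(rbind, out)
  class(res) <- c("NarCurve", class(res))
  res
}

#' Breakpoint (tipping point) detection on a node-area curve
#'
#' Fits (a) a single line and (b) a continuous two-piece segmented
#' regression of node count on log10 area, searching the breakpoint over the
#' interior observed levels by residual sum of squares. The curve is
#' classified `unimodal` when the segmented model improves SSE by at least
#' `min_improvement` (relative) and the slope switches from positive to
#' negative at the break; otherwise it is monotonic with the single-line
#' slope's sign (flat curves count as monotonic-decreasing).
#'
#' @param curve data.frame with `level`, `area` and `nodes` columns for one
#'   group (>= 5 points).
#' @param min_improvement required relative SSE improvement of the segmented
#'   over the single-line model (default 10\%).
#' @return A [NarBreakpoint-class].
#' @export
fitNarBreakpoint <- function(curve, min_improvement = 0.10) {
  if (nrow(curve) < 5L) stop("need >= 5 points for breakpoint detection")
  curve <- curve[order(curve$level), , drop = FALSE]
  xx <- log10(curve$area)
  yy <- curve$nodes
  lf <- ols_fit(xx, yy)
  sse_line <- sum((yy - lf["intercept"] - lf["slope"] * xx)^2)

  n <- length(xx)
  cand <- 2:(n - 1L)   # interior breakpoints
  best <- NULL
  for (ci in cand) {
    b <- xx[ci]
    h <- pmax(xx - b, 0)
    fit <- lm(yy ~ xx + h)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(sse = sse, idx = ci, coefs = coef(fit))
  }
  s1 <- unname(best$coefs["xx"])
  s2 <- unname(best$coefs["xx"]) + unname(best$coefs["h"])
  improved <- best$sse <= (1 - min_improvement) * sse_line
  unimodal <- improved && s1 > 0 && s2 < 0
  if (unimodal) {
    new("NarBreakpoint", shape = "unimodal",
        break_level = curve$level[best$idx],
        break_area = curve$area[best$idx],
        slope_before = s1, slope_after = s2,
        sse_line = sse_line, sse_segmented = best$sse)
  } else {
    shape <- if (lf["slope"] > 0) "monotonic-increasing"
             else "monotonic-decreasing"
    new("NarBreakpoint", shape = shape,
        break_level = NA_real_, break_area = NA_real_,
        slope_before = unname(lf["slope"]), slope_after = unname(lf["slope"]),
        sse_line = sse_line, sse_segmented = best$sse)
  }
}
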