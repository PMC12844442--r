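#' @import methods
#' @importFrom stats cor dist optimize pbeta pt qnorm rbeta rlnorm rmultinom
#'   runif rnorm rpois sd setNames lm coef quantile p.adjust complete.cases
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' OtuTable: a samples x taxa community count matrix
#'
#' The central container of the package: a non-negative integer-valued matrix
#' with samples as rows and taxa (OTUs, 97\%-identity sequence clusters) as
#' columns. Row and column names are the unique sample and taxon identifiers.
#'
#' @slot counts numeric matrix, samples x taxa, non-negative, with unique
#'   dimnames.
#'
#' @seealso [readOtuTable()], [rarefyTable()], [filterTaxa()]
#' @export
setClass("OtuTable", representation(counts = "matrix"))

setValidity("OtuTable", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msg <- c(msg, "counts must have sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("duplicated sample id: %s",
                            rownames(m)[duplicated(rownames(m))][1L]))
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, sprintf("duplicated taxon id: %s",
                            colnames(m)[duplicated(colnames(m))][1L]))
  }
  if (is.numeric(m)) {
    if (anyNA(m)) msg <- c(msg, "counts contain NA")
    else if (length(m) && min(m) < 0) msg <- c(msg, "negative counts")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OtuTable from a matrix
#'
#' @param counts numeric samples x taxa matrix with dimnames.
#' @return An [OtuTable-class] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' OtuTable(m)
#' @export
OtuTable <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("OtuTable", counts = counts)
}

#' @describeIn OtuTable-class the underlying counts matrix (samples x taxa)
#' @param x,object an `OtuTable`
#' @export
otuCounts <- function(x) x@counts

#' @describeIn OtuTable-class sample identifiers (row names)
#' @export
sampleIDs <- function(x) rownames(x@counts)

#' @describeIn OtuTable-class taxon identifiers (column names)
#' @export
taxonIDs <- function(x) colnames(x@counts)

#' @describeIn OtuTable-class number of samples
#' @export
nSamples <- function(x) nrow(x@counts)

#' @describeIn OtuTable-class number of taxa
#' @export
nTaxa <- function(x) ncol(x@counts)

setMethod("show", "OtuTable", function(object) {
  m <- object@counts
  cat(sprintf("OtuTable: %d samples x %d taxa\n", nrow(m), ncol(m)))
  if (nrow(m) && ncol(m)) {
    tot <- rowSums(m)
    cat(sprintf("  per-sample totals: %s .. %s (median %s)\n",
                format(min(tot)), format(max(tot)), format(stats::median(tot))))
    cat(sprintf("  sparsity: %.1f%% zero cells\n", 100 * mean(m == 0)))
  }
})

#' Subset an OtuTable by sample and/or taxon ids or indices
#'
#' @param x an `OtuTable`; `i` selects samples, `j` taxa.
#' @param i,j,...,drop indices; `drop` is ignored (always `FALSE`).
#' @export
setMethod("[", "OtuTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@counts
  if (!missing(i)) {
    if (is.character(i) && !all(i %in% rownames(m)))
      stop("unknown sample id(s): ",
           paste(setdiff(i, rownames(m)), collapse = ", "))
    m <- m[i, , drop = FALSE]
  }
  if (!missing(j)) {
    if (is.character(j) && !all(j %in% colnames(m)))
      stop("unknown taxon id(s): ",
           paste(setdiff(j, colnames(m)), collapse = ", "))
    m <- m[, j, drop = FALSE]
  }
  OtuTable(m)
})

#' Pairwise Spearman correlations with significance
#'
#' @slot r symmetric matrix of Spearman coefficients (diagonal 1).
#' @slot p matrix of two-sided p-values from the t approximation.
#' @slot n_samples number of samples the correlations were computed on.
#' @slot flagged taxon ids whose counts were constant across samples (their
#'   correlations are recorded as r = 0, p = 1).
#' @seealso [spearmanMatrix()]
#' @export
setClass("CorrelationMatrix",
         representation(r = "matrix", p = "matrix", n_samples = "integer",
                        flagged = "character"))

setValidity("CorrelationMatrix", function(object) {
  if (!isTRUE(all.equal(dim(object@r), dim(object@p))))
    return("r and p must have identical dimensions")
  if (length(object@r) && max(abs(object@r), na.rm = TRUE) > 1 + 1e-12)
    return("|r| must not exceed 1")
  TRUE
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d taxa, n = %d samples (%d constant taxa flagged)\n",
              nrow(object@r), object@n_samples, length(object@flagged)))
})

#' Thresholded co-occurrence network
#'
#' Edges are taxon pairs with |r| above `r_thresh` and (optionally corrected)
#' p below `p_thresh`; taxa without any edge are not nodes.
#'
#' @slot edges data.frame with columns taxon_a, taxon_b, r, p, sign.
#' @slot nodes character vector of connected taxon ids.
#' @slot r_thresh,p_thresh numeric thresholds used.
#' @slot correction "none" or "BH".
#' @seealso [buildNetwork()], [networkProperties()]
#' @export
setClass("CooccurrenceNetwork",
         representation(edges = "data.frame", nodes = "character",
                        r_thresh = "numeric", p_thresh = "numeric",
                        correction = "character"))

setValidity("CooccurrenceNetwork", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$taxon_a == e$taxon_b)) return("self-edges are not allowed")
    if (any(abs(e$r) <= object@r_thresh)) return("edge below |r| threshold")
  }
  TRUE
})

#' @describeIn CooccurrenceNetwork-class edge table
#' @param x,object a `CooccurrenceNetwork`
#' @export
networkEdges <- function(x) x@edges

#' @describeIn CooccurrenceNetwork-class node (taxon) ids with at least one edge
#' @export
networkNodes <- function(x) x@nodes

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf("CooccurrenceNetwork: %d nodes, %d edges (|r| > %.2f, p < %g, correction = %s)\n",
              length(object@nodes), nrow(object@edges),
              object@r_thresh, object@p_thresh, object@correction))
  if (nrow(object@edges))
    cat(sprintf("  positive edges: %.1f%%\n",
                100 * mean(object@edges$sign > 0)))
})

#' Fitted taxa-area model
#'
#' Either the logarithm model S = c + z log(A) or the power model S = c A^z.
#' The slope z is the spatial turnover rate of the community.
#'
#' @slot model "logarithm" or "power".
#' @slot c,z fitted intercept/scale and slope.
#' @slot r2 coefficient of determination on the original richness scale.
#' @slot n_points number of (area, richness) points fitted.
#' @slot log_base logarithm base used by the logarithm model (NA for power).
#' @seealso [fitSar()]
#' @export
setClass("SarFit",
         representation(model = "character", c = "numeric", z = "numeric",
                        r2 = "numeric", n_points = "integer",
                        log_base = "numeric"))

setMethod("show", "SarFit", function(object) {
  form <- if (object@model == "logarithm")
    sprintf("S = %.4g + %.4g log%g(A)", object@c, object@z, object@log_base)
  else sprintf("S = %.4g * A^%.4g", object@c, object@z)
  cat(sprintf("SarFit (%s model): %s\n  z = %.4f, R^2 = %.4f, n = %d\n",
              object@model, form, object@z, object@r2, object@n_points))
})

#' Permutation test for a difference in taxa-area slopes
#'
#' @slot z_a,z_b fitted slopes of the two groups.
#' @slot delta observed z_a - z_b.
#' @slot p permutation p-value for |delta|.
#' @slot n_perm,seed permutation settings.
#' @slot model SAR model used for the refits.
#' @seealso [compareSlopes()]
#' @export
setClass("SlopeTest",
         representation(z_a = "numeric", z_b = "numeric", delta = "numeric",
                        p = "numeric", n_perm = "integer", seed = "integer",
                        model = "character"))

setMethod("show", "SlopeTest", function(object) {
  cat(sprintf("SlopeTest (%s model): z_a = %.4f, z_b = %.4f, delta = %.4f, p = %.4g (%d permutations)\n",
              object@model, object@z_a, object@z_b, object@delta,
              object@p, object@n_perm))
})

#' Breakpoint fit of a node-area relationship
#'
#' Compares a single line to a continuous two-piece (segmented) regression of
#' node count on log10 area. The curve is classified unimodal when the
#' segmented model clearly wins and the slope changes from positive to
#' negative at the breakpoint (the "tipping point" area).
#'
#' @slot shape "monotonic-increasing", "monotonic-decreasing" or "unimodal".
#' @slot break_level,break_area nested level and area (m^2) of the breakpoint
#'   (NA for monotonic shapes).
#' @slot slope_before,slope_after segment slopes (per log10 area unit).
#' @slot sse_line,sse_segmented residual sums of squares of both models.
#' @seealso [fitNarBreakpoint()]
#' @export
setClass("NarBreakpoint",
         representation(shape = "character", break_level = "numeric",
                        break_area = "numeric", slope_before = "numeric",
                        slope_after = "numeric", sse_line = "numeric",
                        sse_segmented = "numeric"))

setMethod("show", "NarBreakpoint", function(object) {
  cat(sprintf("NarBreakpoint: %s", object@shape))
  if (object@shape == "unimodal")
    cat(sprintf(" (tipping point at level %g, area %.4g m^2; slopes %.3g -> %.3g)",
                object@break_level, object@break_area,
                object@slope_before, object@slope_after))
  cat("\n")
})

#' Sloan neutral community model fit
#'
#' @slot Nm fitted product of metacommunity size and migration rate.
#' @slot m migration rate, Nm / N.
#' @slot N uniform per-sample read depth.
#' @slot d detection limit (relative abundance of one read by default).
#' @slot r2 goodness of fit on occurrence frequencies.
#' @slot taxa per-taxon data.frame: p (mean relative abundance), freq_obs,
#'   freq_pred, lower/upper 95\% band, partition (above/within/below).
#' @seealso [fitNcm()], [ncmPredict()]
#' @export
setClass("NcmFit",
         representation(Nm = "numeric", m = "numeric", N = "numeric",
                        d = "numeric", r2 = "numeric", taxa = "data.frame"))

setMethod("show", "NcmFit", function(object) {
  cat(sprintf("NcmFit: Nm = %.1f, m = %.4f (N = %g, d = %g), R^2 = %.3f, %d taxa\n",
              object@Nm, object@m, object@N, object@d, object@r2,
              nrow(object@taxa)))
  part <- table(factor(object@taxa$partition,
                       levels = c("above", "within", "below")))
  cat(sprintf("  partition: %d above / %d within / %d below the 95%% band\n",
              part[["above"]], part[["within"]], part[["below"]]))
})

#' Mantel test result
#'
#' @slot r matrix correlation of the lower triangles.
#' @slot p permutation p-value.
#' @slot n_perm,seed permutation settings.
#' @slot method "pearson" or "spearman".
#' @slot tail "greater" or "two.sided".
#' @seealso [mantelTest()]
#' @export
setClass("MantelResult",
         representation(r = "numeric", p = "numeric", n_perm = "integer",
                        seed = "integer", method = "character",
                        tail = "character"))

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("MantelResult: r = %.4f, p = %.4g (%s, %s, %d permutations)\n",
              object@r, object@p, object@method, object@tail, object@n_perm))
})
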