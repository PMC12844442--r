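#' Alpha diversity of one or more samples
#'
#' Richness (observed taxa), Shannon-Wiener index (natural log) and the
#' Gini-Simpson index `1 - sum(q^2)`.
#'
#' @param x an [OtuTable-class] or a single non-negative count vector.
#' @return data.frame with columns sample_id, richness, shannon, simpson.
#' @examples
#' alphaDiversity(c(5, 5))
#' @export
alphaDiversity <- function(x) {
  m <- if (is(x, "OtuTable")) otuCounts(x)
       else matrix(x, 1L, dimnames = list("sample", NULL))
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  q <- m / rowSums(m)
  shan <- -rowSums(ifelse(q > 0, q * log(q), 0))
  data.frame(sample_id = rownames(m),
             richness = rowSums(m > 0),
             shannon = shan,
             simpson = 1 - rowSums(q^2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` on the raw counts.
#'
#' @param x an [OtuTable-class] with at least two samples.
#' @return A `dist` object labelled with sample ids
#'   (`attr(, "metric") == "braycurtis"`).
#' @export
brayCurtis <- function(x) {
  stopifnot(is(x, "OtuTable"))
  m <- otuCounts(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("zero-total sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "braycurtis"
  d
}

#' Within-group environmental heterogeneity
#'
#' Variables are z-score standardized (sample sd, n - 1) over *all* samples;
#' pairwise distances are then computed within each group under the chosen
#' metric. Euclidean distance on z-scores is the default; the Bray-Curtis
#' option shifts each standardized variable to a minimum of zero first
#' (Bray-Curtis is undefined on negative values). Constant variables are
#' dropped with a warning.
#'
#' @param env environmental data.frame (see [readEnvTable()]).
#' @param frame sample frame supplying group labels.
#' @param metric `"euclidean"` or `"braycurtis"`.
#' @return `list(distances = named list of per-group distance vectors,
#'   means = data.frame(group, mean_dist, n_pairs))`.
#' @export
envHeterogeneity <- function(env, frame, metric = c("euclidean", "braycurtis")) {
  metric <- match.arg(metric)
  env <- validateEnvTable(env)
  frame <- validateSampleFrame(frame)
  miss <- setdiff(frame$sample_id, env$sample_id)
  if (length(miss))
    stop("samples missing from env table: ", paste(head(miss, 5), collapse = ", "))
  env <- env[match(frame$sample_id, env$sample_id), , drop = FALSE]
  vars <- setdiff(names(env), "sample_id")
  vm <- as.matrix(env[vars])
  sds <- apply(vm, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(vars[sds == 0], collapse = ", "))
    vm <- vm[, sds > 0, drop = FALSE]
    if (!ncol(vm)) stop("no variable left after dropping constants")
  }
  z <- scale(vm)
  if (metric == "braycurtis")
    z <- sweep(z, 2L, apply(z, 2L, min))
  rownames(z) <- frame$sample_id

  dists <- lapply(split(frame$sample_id, frame$group), function(ids) {
    if (length(ids) < 2L) return(numeric(0))
    sub <- z[ids, , drop = FALSE]
    d <- if (metric == "euclidean") dist(sub)
         else vegan::vegdist(sub, method = "bray")
    as.numeric(d)
  })
  means <- data.frame(group = names(dists),
                      mean_dist = vapply(dists, function(v)
                        if (length(v)) mean(v) else NA_real_, numeric(1)),
                      n_pairs = lengths(dists),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(distances = dists, means = means)
}

#' Mantel test between two distance matrices
#'
#' Correlates the lower triangles of two distance matrices and assesses
#' significance by jointly permuting the rows and columns of the second.
#' `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)` for the one-tailed test
#' (the conventional default), or the analogous two-sided count on |r|.
#'
#' @param d1,d2 `dist` objects or square symmetric matrices with matching
#'   ids (matching labels, if labelled).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @param tail `"greater"` or `"two.sided"`.
#' @return A [MantelResult-class].
#' @export
mantelTest <- function(d1, d2, method = c("pearson", "spearman"),
                       n_perm = 999L, seed = 1L,
                       tail = c("greater", "two.sided")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (n_perm < 99) stop("n_perm must be >= 99")
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2)))
      stop("distance matrix ids do not match")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- cor(v1, m2[lt], method = method)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(n)
    cor(v1, m2[ord, ord][lt], method = method)
  }, numeric(1)))
  p <- if (tail == "greater") (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
       else (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  new("MantelResult", r = r_obs, p = p, n_perm = as.integer(n_perm),
      seed = as.integer(seed), method = method, tail = tail)
}
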