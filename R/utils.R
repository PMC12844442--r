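# Internal helpers shared across modules.

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards so package functions never clobber the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stage label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(name, " must be a single finite number")
}

# Validate a sample frame (plot membership, nested geometry). Returns the
# frame with `level` and `area` coerced to numeric.
validateSampleFrame <- function(frame) {
  needed <- c("sample_id", "group", "plot_id", "x", "y", "level", "area")
  miss <- setdiff(needed, names(frame))
  if (length(miss))
    stop("sample frame lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(frame$sample_id))
    stop("duplicated sample_id in sample frame: ",
         frame$sample_id[duplicated(frame$sample_id)][1L])
  frame$level <- as.numeric(frame$level)
  frame$area <- as.numeric(frame$area)
  if (any(frame$area <= 0)) stop("areas must be positive")
  agg <- unique(frame[, c("level", "area")])
  agg <- agg[order(agg$level), ]
  if (is.unsorted(agg$area, strictly = TRUE) && nrow(agg) > 1 &&
      any(diff(tapply(agg$area, agg$level, min)) <= 0))
    stop("area must be strictly increasing in level")
  frame
}

validateEnvTable <- function(env) {
  if (!"sample_id" %in% names(env)) stop("env table lacks sample_id column")
  if (anyDuplicated(env$sample_id)) stop("duplicated sample_id in env table")
  vars <- setdiff(names(env), "sample_id")
  if (!length(vars)) stop("env table has no variables")
  num <- vapply(env[vars], is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric env variable(s): ", paste(vars[!num], collapse = ", "))
  if (any(!is.finite(as.matrix(env[vars]))))
    stop("non-finite values in env table")
  env
}

# Wilson 95% binomial interval for a proportion estimate at n trials.
wilson_band <- function(p_hat, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  ctr <- (p_hat + z^2 / (2 * n)) / den
  hw <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}
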