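#' Read an OTU count table from TSV
#'
#' The file is tab-separated with a header row; lines starting with `#` are
#' ignored. The first column holds ids. Orientation (whether rows are samples
#' or taxa) is auto-detected from the header id-column name
#' (`sample_id` vs `taxon_id`/`otu_id`) or, if a sample frame is supplied,
#' from id overlap; it can be forced with `orientation`. The returned table is
#' always samples x taxa.
#'
#' @param path TSV file path.
#' @param orientation `"auto"`, `"samples"` (rows are samples) or `"taxa"`
#'   (rows are taxa).
#' @param frame optional sample frame used to resolve orientation by id
#'   overlap.
#' @return An [OtuTable-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeOtuTable(OtuTable(matrix(1:4, 2,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2")))), tf)
#' readOtuTable(tf)
#' @export
readOtuTable <- function(path, orientation = c("auto", "samples", "taxa"),
                         frame = NULL) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("OTU table needs an id column plus counts")
  ids <- as.character(df[[1L]])
  id_name <- names(df)[1L]
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop(sprintf("non-numeric count at row %d, column '%s'",
                 cell, names(df)[bad + 1L]))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric count at row '%s', column '%s'",
                 ids[idx[1L]], colnames(m)[idx[2L]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 ids[idx[1L]], colnames(m)[idx[2L]]))
  }
  if (anyDuplicated(ids))
    stop("duplicated id in first column: ", ids[duplicated(ids)][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicated id in header: ",
         colnames(m)[duplicated(colnames(m))][1L])
  rownames(m) <- ids

  rows_are_samples <- switch(
    orientation,
    samples = TRUE,
    taxa = FALSE,
    auto = {
      if (grepl("sample", id_name, ignore.case = TRUE)) TRUE
      else if (grepl("taxon|otu", id_name, ignore.case = TRUE)) FALSE
      else if (!is.null(frame)) {
        ov_rows <- mean(ids %in% frame$sample_id)
        ov_cols <- mean(colnames(m) %in% frame$sample_id)
        ov_rows >= ov_cols
      } else {
        message("orientation ambiguous; assuming rows are taxa")
        FALSE
      }
    })
  if (!rows_are_samples) m <- t(m)
  OtuTable(m)
}

#' Write an OtuTable as TSV
#'
#' Samples x taxa, first column `sample_id`, preceded by a `#` header comment
#' recording the tool version and (optionally) the seed of the run that
#' produced it.
#'
#' @param x an [OtuTable-class].
#' @param path output file.
#' @param seed optional integer recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path, seed = NULL) {
  stopifnot(is(x, "OtuTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# microscale %s otu table%s",
                     as.character(packageVersion("microscale")),
                     if (is.null(seed)) "" else sprintf(" (seed %d)",
                                                        as.integer(seed))),
             con)
  df <- data.frame(sample_id = sampleIDs(x), otuCounts(x),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample frame (nested-design metadata) from TSV
#'
#' Requires columns `sample_id`, `group`, `plot_id`, `x`, `y`, `level`,
#' `area`; `#` comment lines are ignored.
#'
#' @param path TSV file path.
#' @return A validated data.frame.
#' @export
readSampleFrame <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  validateSampleFrame(df)
}

#' Read a soil environmental variable table from TSV
#'
#' One row per sample (`sample_id` column), numeric variables such as SWC,
#' pH, SOC, TN, TP, NH4, NO3.
#'
#' @param path TSV file path.
#' @return A validated data.frame.
#' @export
readEnvTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  validateEnvTable(df)
}

# Shared writer for metadata/env tables with a version header comment.
write_tsv_commented <- function(df, path, what, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# microscale %s %s%s",
                     as.character(packageVersion("microscale")), what,
                     if (is.null(seed)) "" else sprintf(" (seed %d)",
                                                        as.integer(seed))),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy every sample to a common read depth
#'
#' Samples whose total is below `depth` are dropped with a warning; each
#' surviving sample is subsampled without replacement so its counts sum to
#' exactly `depth`. Deterministic for a fixed seed.
#'
#' @param x an [OtuTable-class].
#' @param depth target reads per sample (>= 1).
#' @param seed integer RNG seed.
#' @return A rarefied [OtuTable-class].
#' @export
rarefyTable <- function(x, depth, seed = 1L) {
  stopifnot(is(x, "OtuTable"))
  stopifnot_scalar(depth, "depth")
  if (depth < 1) stop("depth must be >= 1")
  tot <- rowSums(otuCounts(x))
  drop <- tot < depth
  if (all(drop)) stop("all samples are below the rarefaction depth")
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), as.integer(depth),
                    paste(head(sampleIDs(x)[drop], 5L), collapse = ", ")))
  m <- otuCounts(x)[!drop, , drop = FALSE]
  # vegan warns whenever the smallest nonzero count exceeds 1, an
  # informational heuristic that is irrelevant for subsampling
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  OtuTable(out)
}

#' Filter taxa on overall relative abundance and prevalence
#'
#' Keeps taxa whose share of the grand total is at least `min_rel_abund` and
#' which occur (count > 0) in at least a fraction `min_prevalence` of the
#' samples in `x`. The default thresholds (0.1\% abundance, 20\% prevalence)
#' are the usual pre-filter for co-occurrence network construction.
#' Prevalence is computed over the samples handed in, so per-group filtering
#' is achieved by subsetting first.
#'
#' @param x an [OtuTable-class].
#' @param min_rel_abund minimum grand-total relative abundance in [0, 1].
#' @param min_prevalence minimum occurrence fraction in [0, 1].
#' @return The filtered [OtuTable-class] (samples unchanged).
#' @export
filterTaxa <- function(x, min_rel_abund = 0.001, min_prevalence = 0.2) {
  stopifnot(is(x, "OtuTable"))
  if (min_rel_abund < 0 || min_rel_abund > 1 ||
      min_prevalence < 0 || min_prevalence > 1)
    stop("thresholds must lie in [0, 1]")
  m <- otuCounts(x)
  grand <- sum(m)
  share <- if (grand > 0) colSums(m) / grand else rep(0, ncol(m))
  prev <- colMeans(m > 0)
  keep <- share >= min_rel_abund & prev >= min_prevalence
  if (!any(keep)) warning("no taxa pass the filter; returning an empty table")
  OtuTable(m[, keep, drop = FALSE])
}

#' Pool counts of a set of samples
#'
#' Element-wise sum over the selected rows, the aggregation underlying
#' taxa-area curves on a nested design.
#'
#' @param x an [OtuTable-class].
#' @param sample_ids character ids to pool (must all be present).
#' @return Named numeric vector of pooled counts per taxon.
#' @export
poolSamples <- function(x, sample_ids) {
  stopifnot(is(x, "OtuTable"))
  unknown <- setdiff(sample_ids, sampleIDs(x))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  colSums(otuCounts(x)[sample_ids, , drop = FALSE])
}
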