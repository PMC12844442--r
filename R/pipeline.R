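#' Default pipeline configuration
#'
#' Returns the full configuration list with the conventional defaults:
#' network filter |r| > 0.80 at p < 0.05, taxon pre-filter of 0.1\% relative
#' abundance and 20\% prevalence, logarithm+power TAR models in base 10 with
#' 999 permutations, NST with 1000 nulls on Bray-Curtis. Any subset of
#' fields can be overridden via `...` or a YAML file (see [runPipeline()]).
#'
#' @param ... named overrides of individual fields.
#' @return Named list of configuration values.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    rarefy_depth = NA,          # NA = skip rarefaction
    min_rel_abund = 0.001,
    min_prevalence = 0.2,
    r_thresh = 0.80,
    p_thresh = 0.05,
    correction = "none",
    min_samples = 16L,
    nar_mode = "cumulative",
    tar_models = c("logarithm", "power"),
    log_base = 10,
    n_perm = 999L,
    nst_metric = "braycurtis",
    n_null = 1000L,
    mantel_method = "pearson",
    mantel_tail = "greater",
    env_metric = "euclidean",
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full spatial-scaling analysis pipeline
#'
#' Executes, on an OTU table plus nested-design metadata (and optionally an
#' environmental table): rarefaction, taxon filtering, alpha/beta diversity
#' and environmental heterogeneity, taxa-area fits with permutation slope
#' tests between all group pairs, the node-area relationship with breakpoint
#' classification, the neutral community model, the normalized stochasticity
#' ratio, Levins niche breadth, and per-variable Mantel tests. All tabular
#' outputs are written as TSV into `out_dir` together with
#' `run_manifest.json` recording the configuration, derived stage seeds,
#' package version and accumulated warnings. Outputs are byte-identical
#' across runs with the same inputs and seed.
#'
#' @param otu an [OtuTable-class] or a path to an OTU TSV.
#' @param frame sample frame data.frame or TSV path.
#' @param env optional environmental table or TSV path (enables the
#'   heterogeneity and Mantel stages).
#' @param out_dir output directory (created if missing).
#' @param config configuration list from [defaultConfig()] or a YAML file
#'   path of overrides.
#' @param what stages to run, a subset of
#'   `c("diversity", "tar", "nar", "assembly", "mantel")`.
#' @return Invisibly, a named list of in-memory stage results.
#' @export
runPipeline <- function(otu, frame, env = NULL, out_dir,
                        config = defaultConfig(),
                        what = c("diversity", "tar", "nar", "assembly",
                                 "mantel")) {
  what <- match.arg(what, several.ok = TRUE)
  if (is.character(config) && length(config) == 1L)
    config <- do.call(defaultConfig, yaml::read_yaml(config))
  if (is.character(otu)) otu <- readOtuTable(otu, frame = if (is.character(frame)) NULL else frame)
  if (is.character(frame)) frame <- readSampleFrame(frame)
  frame <- validateSampleFrame(frame)
  if (is.character(env)) env <- readEnvTable(env)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  warns <- character()
  note <- function(w) warns[[length(warns) + 1L]] <<- conditionMessage(w)
  results <- list()
  emit <- function(df, name) {
    write_tsv_commented(df, file.path(out_dir, name), name, seed = seed)
  }

  withCallingHandlers({
    if (!is.na(config$rarefy_depth))
      otu <- rarefyTable(otu, config$rarefy_depth,
                         seed = derive_seed(seed, "rarefy"))
    frame <- frame[frame$sample_id %in% sampleIDs(otu), , drop = FALSE]

    if ("diversity" %in% what) {
      results$alpha <- alphaDiversity(otu)
      results$alpha$group <- frame$group[match(results$alpha$sample_id,
                                               frame$sample_id)]
      emit(results$alpha, "alpha_diversity.tsv")
      bc <- as.matrix(brayCurtis(otu))
      emit(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
           "beta_braycurtis.tsv")
      if (!is.null(env)) {
        het <- envHeterogeneity(env, frame, metric = config$env_metric)
        results$env_heterogeneity <- het$means
        emit(het$means, "env_heterogeneity.tsv")
      }
    }

    if ("tar" %in% what) {
      curve <- buildTar(otu, frame)
      emit(as.data.frame(curve), "tar_curve.tsv")
      fits <- list()
      for (g in unique(curve$group)) for (mod in config$tar_models) {
        f <- fitSar(curve[curve$group == g, ], mod,
                    log_base = config$log_base)
        fits[[length(fits) + 1L]] <- data.frame(
          group = g, model = mod, c = f@c, z = f@z, r2 = f@r2,
          n_points = f@n_points, log_base = f@log_base)
      }
      results$tar_fits <- do.call(rbind, fits)
      emit(results$tar_fits, "tar_fits.tsv")
      gs <- unique(curve$group)
      if (length(gs) > 1L) {
        st <- list()
        for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
          tst <- compareSlopes(curve[curve$group == gs[i], ],
                               curve[curve$group == gs[j], ],
                               model = "logarithm", n_perm = config$n_perm,
                               seed = derive_seed(seed,
                                                  paste0("slopes_", i, "_", j)),
                               log_base = config$log_base)
          st[[length(st) + 1L]] <- data.frame(
            group_a = gs[i], group_b = gs[j], z_a = tst@z_a, z_b = tst@z_b,
            delta = tst@delta, p = tst@p, n_perm = tst@n_perm)
        }
        results$slope_tests <- do.call(rbind, st)
        emit(results$slope_tests, "slope_tests.tsv")
      }
    }

    if ("nar" %in% what) {
      nar <- buildNar(otu, frame,
                      min_rel_abund = config$min_rel_abund,
                      min_prevalence = config$min_prevalence,
                      r_thresh = config$r_thresh, p_thresh = config$p_thresh,
                      correction = config$correction,
                      min_samples = config$min_samples,
                      mode = config$nar_mode)
      results$nar <- as.data.frame(nar)
      emit(results$nar, "nar_curve.tsv")
      bps <- list()
      for (g in unique(nar$group)) {
        sub <- nar[nar$group == g, ]
        if (nrow(sub) >= 5L) {
          bp <- fitNarBreakpoint(sub)
          bps[[length(bps) + 1L]] <- data.frame(
            group = g, shape = bp@shape, break_level = bp@break_level,
            break_area = bp@break_area, slope_before = bp@slope_before,
            slope_after = bp@slope_after)
        }
      }
      if (length(bps)) {
        results$breakpoints <- do.call(rbind, bps)
        emit(results$breakpoints, "nar_breakpoints.tsv")
      }
    }

    if ("assembly" %in% what) {
      ncms <- list()
      niches <- list()
      for (g in unique(frame$group)) {
        ids <- frame$sample_id[frame$group == g]
        sub <- otu[ids, ]
        fit <- fitNcm(sub)
        ncms[[length(ncms) + 1L]] <- data.frame(
          group = g, Nm = fit@Nm, m = fit@m, N = fit@N, d = fit@d,
          r2 = fit@r2, n_taxa = nrow(fit@taxa))
        nb <- nicheBreadth(sub)
        niches[[length(niches) + 1L]] <- data.frame(
          group = g, Bcom = nb$Bcom, n_taxa = nrow(nb$taxa))
      }
      results$ncm <- do.call(rbind, ncms)
      emit(results$ncm, "ncm_fit.tsv")
      results$niche <- do.call(rbind, niches)
      emit(results$niche, "niche_breadth.tsv")
      results$nst <- computeNst(otu, frame, metric = config$nst_metric,
                                n_null = config$n_null,
                                seed = derive_seed(seed, "nst"))
      emit(as.data.frame(results$nst), "nst.tsv")
    }

    if ("mantel" %in% what && !is.null(env)) {
      env <- validateEnvTable(env)
      rows <- list()
      for (g in unique(frame$group)) {
        ids <- frame$sample_id[frame$group == g]
        if (length(ids) < 4L) next
        sub <- otu[ids, ]
        dcom <- brayCurtis(sub)
        ge <- env[match(ids, env$sample_id), , drop = FALSE]
        for (v in setdiff(names(env), "sample_id")) {
          if (sd(ge[[v]]) == 0) next
          dv <- dist(ge[[v]])
          attr(dv, "Labels") <- ids
          mt <- mantelTest(dcom, dv, method = config$mantel_method,
                           n_perm = config$n_perm,
                           seed = derive_seed(seed, paste0("mantel_", g, v)),
                           tail = config$mantel_tail)
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, variable = v, r = mt@r, p = mt@p,
            method = mt@method, n_perm = mt@n_perm)
        }
      }
      if (length(rows)) {
        results$mantel <- do.call(rbind, rows)
        emit(results$mantel, "mantel.tsv")
      }
    }
  }, warning = function(w) { note(w); invokeRestart("muffleWarning") })

  manifest <- list(
    package = "microscale",
    version = as.character(packageVersion("microscale")),
    config = config,
    stages = what,
    seed = seed,
    stage_seeds = list(rarefy = derive_seed(seed, "rarefy"),
                       nst = derive_seed(seed, "nst")),
    n_samples = nSamples(otu), n_taxa = nTaxa(otu),
    warnings = warns)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
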