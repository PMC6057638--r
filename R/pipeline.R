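#' End-to-end pipeline on synthetic data
#'
#' Orchestrates the stages in dependency order (simulate, delimit, sdm,
#' krige, richness, gap, prioritize) from a single flat configuration.
#' Every tunable has a default matching the published workflow settings
#' (correlation ceiling 0.75, restricted-range cutoff 30%, kriging
#' threshold 0.5, 75th-percentile hotspots, boundary length penalty 0.4,
#' warp 1); unknown configuration keys are rejected so typos fail loudly.
#' All randomness derives from `seed`, and a rerun with an identical
#' configuration reproduces identical outputs.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @return named list of all configuration keys and their defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    nrows = 64L, ncols = 64L, n_vars = 6L, autocorr_range = 6,
    n_species = 5L, max_lineages = 3L, n_occ = 60L, n_genetic = 25L,
    tips_per_cluster = 6L, yule_rate = 1, coal_scale = 0.02,
    within_rate = 0.01, between_offset = 0.08, noise_sd = 0.002,
    category_fractions = c(0.3, 0.25, 0.4, 0.05),
    max_abs_corr = 0.75, select_k = 8L, thin_radius = 0,
    reg = 1, background_n = 10000L,
    breadth_cutoff = 0.30, krige_threshold = 0.5,
    variogram_family = "spherical",
    target_scale = "loglog", blp = 0.4, warp = 1L,
    outdir = NULL)
}

#' Run the pipeline
#'
#' @param config configuration list; missing keys take [default_config()]
#'   values, unknown keys are an error.
#' @return invisibly, a list with per-stage results and a `manifest`
#'   recording the full configuration, seeds and stage accounting.
#' @export
run_pipeline <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("run_pipeline: unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(stage = stage, sprintf(...))
  }

  ## ---- simulate ----------------------------------------------------------
  stack <- gen_landscape(cfg$seed, cfg$nrows, cfg$ncols, cfg$n_vars,
                         cfg$autocorr_range)
  zoning <- gen_zoning(stack, cfg$category_fractions, seed = cfg$seed)
  species <- vector("list", cfg$n_species)
  for (i in seq_len(cfg$n_species)) {
    sid <- sprintf("sp%02d", i)
    k_true <- ((i - 1L) %% cfg$max_lineages) + 1L
    lv <- ((i - 1L) %% cfg$n_vars) + 1L
    sgn <- if (i %% 2L) 1 else -1
    truth <- gen_virtual_species(
      stack, response = function(X) stats::plogis(2 * sgn * X[, lv]),
      n_lineages = k_true, seed = cfg$seed + 100L + i)
    occ <- sample_occurrences(truth, cfg$n_occ, seed = cfg$seed + 200L + i,
                              feature_id = sid)
    gen <- gen_tree(k_true, cfg$tips_per_cluster, cfg$yule_rate,
                    cfg$coal_scale, seed = cfg$seed + 300L + i)
    samples <- occ[seq_len(min(cfg$n_genetic, nrow(occ))), , drop = FALSE]
    gdm <- gen_genetic_distances(samples, cfg$within_rate,
                                 cfg$between_offset, cfg$noise_sd,
                                 seed = cfg$seed + 400L + i)
    species[[i]] <- list(id = sid, k_true = k_true, truth = truth, occ = occ,
                         tree = gen$tree, samples = samples, gdm = gdm)
    note("simulate", "%s: %d lineages, %d records, %d genetic samples",
         sid, k_true, nrow(occ), nrow(samples))
  }

  ## ---- delimit -----------------------------------------------------------
  for (i in seq_along(species)) {
    sp <- species[[i]]
    fit <- fit_gmyc(sp$tree)
    lrt <- lr_test(fit)
    species[[i]]$gmyc <- fit
    species[[i]]$k_hat <- if (lrt$p_value < 0.05) fit$k else 1L
    note("delimit", "%s: k_true %d, k_hat %d (LR %.2f, p %.3g)",
         sp$id, sp$k_true, species[[i]]$k_hat, lrt$LR, lrt$p_value)
  }

  ## ---- sdm ---------------------------------------------------------------
  vars <- select_variables(stack, cfg$max_abs_corr,
                           min(cfg$select_k, cfg$n_vars))
  features <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    occ <- if (cfg$thin_radius > 0)
      thin_occurrences_pca3(sp$occ, stack, cfg$thin_radius) else sp$occ
    if (nrow(occ) > 5L) {
      ev <- replicate_evaluate(occ, stack, vars, reg = cfg$reg,
                               background_n = cfg$background_n,
                               seed = cfg$seed + 500L + i)
      rng <- binarize_mtp(ev, occ, feature_id = sp$id, status = "LC")
      species[[i]]$evaluation <- ev
      species[[i]]$tss <- tss(rng, occ, seed = cfg$seed + 600L + i)
      note("sdm", "%s: %d reps, mean test AUC %.3f, range %d cells",
           sp$id, ev$n_rep, mean(ev$replicates$auc_test), rng$size)
    } else {
      rng <- records_to_range(occ, stack, feature_id = sp$id, status = "DD")
      note("sdm", "%s: %d records only, range = record cells", sp$id,
           nrow(occ))
    }
    species[[i]]$range <- rng
    features[[sp$id]] <- rng
  }

  ## ---- krige -------------------------------------------------------------
  for (i in seq_along(species)) {
    sp <- species[[i]]
    if (sp$k_true == 1L) {        # single-lineage bypass: range is the range
      lid <- paste0(sp$id, "_1")
      lr <- sp$range
      lr$feature_id <- lid; lr$kind <- "lineage"
      features[[lid]] <- lr
      next
    }
    emp <- empirical_variogram(sp$gdm)
    vgm <- fit_variogram(emp, family = cfg$variogram_family)
    probs <- krige_indicator(sp$samples, sp$samples$lineage, vgm,
                             stack$layers[[1L]])
    species[[i]]$variogram <- vgm
    for (L in names(probs)) {
      lid <- paste0(sp$id, "_", L)
      features[[lid]] <- lineage_binary(probs[[L]], sp$range, lid,
                                        cfg$krige_threshold)
      note("krige", "%s: %d cells", lid, features[[lid]]$size)
    }
  }

  ## ---- richness ----------------------------------------------------------
  n_island <- length(valid_cells(stack$layers[[1L]]))
  layers <- richness_layers(features, n_island, cfg$breadth_cutoff)
  diff_all <- difference_map(layers$species_all, layers$lineage_all)
  hotspots <- lapply(Filter(Negate(is.null), layers), top_quartile_binary)
  correlations <- lapply(Filter(Negate(is.null), layers), correlate_lv,
                         stack = stack)
  note("richness", "6-layer set built over %d features", length(features))

  ## ---- gap ---------------------------------------------------------------
  sizes <- vapply(features, `[[`, 0, "size")
  modelled <- sizes > 5
  A_min <- min(sizes[modelled]); A_max <- max(sizes[modelled])
  gap <- do.call(rbind, lapply(names(features), function(id) {
    f <- features[[id]]
    cc <- category_counts(f, zoning$zp)
    tau <- representation_target(f$size, A_min, A_max, f$status,
                                 cfg$target_scale)
    ach <- target_achievement(cc, tau)
    data.frame(feature = id, kind = f$kind, status = f$status,
               total = cc$total, range_pct = 100 * cc$total / n_island,
               target = tau,
               cells0 = cc$counts[["0"]], cells1 = cc$counts[["1"]],
               cells2 = cc$counts[["2"]], cells3 = cc$counts[["3"]],
               pa_pct = cc$pa_percent, achievement = ach$achievement,
               protected = ach$protected)
  }))
  ## hotspot representation (wide-range layers excluded)
  hot_gap <- lapply(hotspots[!grepl("wide", names(hotspots))],
                    richness_gap, zp = zoning$zp)
  in_out <- lapply(layers[c("species_all", "lineage_all")],
                   compare_in_out, zp = zoning$zp)
  note("gap", "targets interpolated on [%d, %d] cells", A_min, A_max)

  ## ---- prioritize --------------------------------------------------------
  prior <- list()
  for (kind in c("species", "lineage")) {
    fs <- Filter(function(f) f$kind == kind, features)
    ids <- vapply(fs, `[[`, "", "feature_id")
    tau <- gap$target[match(ids, gap$feature)]
    prob <- prioritization_problem(fs, tau, zoning$cost,
                                   blp = cfg$blp, warp = cfg$warp)
    res <- rank_cells(prob)
    prior[[kind]] <- list(result = res,
                          minimal = minimal_set(res, paste0(kind, "_minimal")))
    note("prioritize", "%s: minimal set %d cells", kind,
         prior[[kind]]$minimal$size)
  }
  comparison <- compare_solutions(prior$species$minimal,
                                  prior$lineage$minimal, zoning$zp)

  manifest <- list(package = "lineascape",
                   version = as.character(utils::packageVersion("lineascape")),
                   config = cfg[setdiff(names(cfg), "outdir")],
                   log = log)
  out <- list(stack = stack, zoning = zoning, species = species,
              features = features, richness = layers, difference = diff_all,
              hotspots = hotspots, correlations = correlations, gap = gap,
              hotspot_gap = hot_gap, in_out = in_out,
              prioritization = prior, comparison = comparison,
              manifest = manifest)
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg$outdir)
  invisible(out)
}

## Internal: serialize the main tabular and raster outputs.
write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$gap, file.path(outdir, "gap_analysis.csv"),
                   row.names = FALSE)
  for (nm in names(out$correlations))
    utils::write.csv(out$correlations[[nm]],
                     file.path(outdir, paste0("correlation_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(out$richness))
    if (!is.null(out$richness[[nm]]))
      write_asc(out$richness[[nm]]$count,
                file.path(outdir, paste0("richness_", nm, ".asc")))
  write_asc(out$zoning$zp, file.path(outdir, "zoning_plan.asc"))
  for (kind in names(out$prioritization)) {
    write_asc(out$prioritization[[kind]]$result$rank,
              file.path(outdir, paste0("rank_", kind, ".asc")))
    write_asc(out$prioritization[[kind]]$minimal$raster,
              file.path(outdir, paste0("minimal_", kind, ".asc")))
  }
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Published gap-analysis arithmetic fixture
#'
#' Returns the printed per-category cell counts, statuses, targets and
#' achievements of the 57 biodiversity features of the published
#' gap-analysis table, as packaged plain-text data.  The island total is
#' attached as the `island_cells` attribute (342865 cells).
#'
#' @return data frame with one row per biodiversity feature.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "gap_table_fixture.csv",
                      package = "lineascape")
  if (path == "")   # not installed: fall back to the source tree
    path <- file.path("inst", "extdata", "gap_table_fixture.csv")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(x, "island_cells") <- 342865L
  x
}
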