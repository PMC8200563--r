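#' Run configuration for the end-to-end analysis
#'
#' Exactly one input source must be given: a synthetic [cohort_spec()], or
#' an SWC directory with a `manifest.csv` (see [read_cohort()]).
#'
#' @param cohort a `cohort_spec` (synthetic input).
#' @param swc_dir directory of SWC files plus manifest (file input).
#' @param out_dir optional output directory; when given, all tables and
#'   the summary JSON are written there.
#' @param stability_pair the two age groups compared by the stability
#'   classifier (default the study convention: the two oldest groups).
#' @param n_bins,cutoff stability histogram bins and stable/varying
#'   cutoff.
#' @param iqr_multiplier outlier fence multiplier.
#' @param prune_threshold,prune_keep correlation-pruning controls.
#' @param variance_target cumulative-variance target (percent) for the
#'   clustering / PCA-based validation.
#' @param seed seed for the validation splits.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = NULL, swc_dir = NULL, out_dir = NULL,
                       stability_pair = NULL, n_bins = 20L, cutoff = 1,
                       iqr_multiplier = 3, prune_threshold = 0.8,
                       prune_keep = c("pathDistance", "n_bifs"),
                       variance_target = 95, seed = 1L) {
  if (is.null(cohort) == is.null(swc_dir)) {
    stop("exactly one input source (cohort or swc_dir) must be set")
  }
  structure(list(cohort = cohort, swc_dir = swc_dir, out_dir = out_dir,
                 stability_pair = stability_pair, n_bins = as.integer(n_bins),
                 cutoff = cutoff, iqr_multiplier = iqr_multiplier,
                 prune_threshold = prune_threshold, prune_keep = prune_keep,
                 variance_target = variance_target, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  stripped <- config[setdiff(names(config), "out_dir")]
  rlang::hash(stripped)
}

#' Run the full developmental-morphometry analysis
#'
#' Executes the whole pipeline: SWC input (or synthetic generation),
#' 15-feature morphometry, per-area outlier removal, z-scoring,
#' correlation pruning, stability classification of each feature between
#' the two oldest age groups, dual PCA (stable and varying subsets), Ward
#' clustering on the 95%-variance components, and SVM validation (70/30
#' hold-out and 10-fold CV, with and without PCA). Fully deterministic
#' given the seeds in the config.
#'
#' @param config a [run_config()].
#' @return a report bundle (list): `features` (raw feature matrix),
#'   `scaled`, `prune`, `outliers`, `stability`, `pca` (list with
#'   `stable` and `varying` `pca_result`s), `clusters` (same split),
#'   `validation` (list of `validation_report`s), `summary` (plain list,
#'   also written as JSON when `out_dir` is set).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (!is.null(config$cohort)) generate_cohort(config$cohort)
    else read_cohort(config$swc_dir)
  })
  fm <- stage("morphometry",
              suppressWarnings(build_feature_matrix(cohort$trees,
                                                    cohort$labels)))
  out <- stage("outliers", remove_outliers(fm, config$iqr_multiplier))
  pruned <- stage("prune", correlation_prune(out$matrix,
                                             config$prune_threshold,
                                             config$prune_keep))
  scaled <- stage("scale", scale_features(pruned$matrix))

  pair <- config$stability_pair
  if (is.null(pair)) {
    ages <- unique(scaled$age_group)
    pair <- utils::tail(ages, 2L)            # two oldest groups by order
  }
  stab <- stage("stability",
                classify_features(scaled, pair[1L], pair[2L],
                                  cutoff = config$cutoff,
                                  n_bins = config$n_bins))
  part <- stability_partition(stab)

  pca <- list(); clusters <- list(); polygons <- list()
  for (side in c("stable", "varying")) {
    subset <- part[[side]]
    if (length(subset) < 2L) next
    pca[[side]] <- stage(paste0("pca_", side), fit_pca(scaled, subset))
    polygons[[side]] <- stage(paste0("polygons_", side),
                              suppressWarnings(group_polygons(pca[[side]])))
    clusters[[side]] <- stage(paste0("cluster_", side),
                              ward_cluster(pca[[side]],
                                           variance_target =
                                             config$variance_target))
  }

  raw_pruned <- pruned$matrix
  validation <- stage("validation", list(
    holdout_raw = svm_holdout(raw_pruned, seed = config$seed),
    holdout_pca = svm_holdout(raw_pruned, with_pca = TRUE,
                              seed = config$seed),
    kfold_raw = kfold_cv(raw_pruned, k = 10L, seed = config$seed),
    kfold_pca = kfold_cv(raw_pruned, k = 10L, with_pca = TRUE,
                         seed = config$seed)))

  hull_medians <- stats::aggregate(
    fm$convex_hull, list(age_group = fm$age_group), stats::median)
  names(hull_medians)[2L] <- "median_convex_hull"

  summary <- list(
    config_hash = config_hash(config),
    n_neurons_input = nrow(fm),
    n_neurons_analyzed = nrow(scaled),
    outlier_fraction = out$report$fraction_removed,
    features_retained = feature_cols(scaled),
    n_features_retained = length(feature_cols(scaled)),
    stability_pair = pair,
    stable_features = part$stable,
    varying_features = part$varying,
    median_convex_hull_by_age = hull_medians,
    explained_variance_pct = lapply(pca, `[[`, "explained_variance_pct"),
    n_components_95 = lapply(pca, n_components_for_variance,
                             target_pct = config$variance_target),
    accuracy = lapply(validation, `[[`, "accuracy"))

  bundle <- list(features = fm, scaled = scaled, prune = pruned$report,
                 outliers = out$report, stability = stab, pca = pca,
                 polygons = polygons, clusters = clusters,
                 validation = validation, summary = summary)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# write the bundle's tables and summary JSON under out_dir
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$stability),
                   file.path(dir, "stability.csv"), row.names = FALSE)
  for (side in names(bundle$pca)) {
    p <- bundle$pca[[side]]
    utils::write.csv(as.data.frame(p$loadings),
                     file.path(dir, sprintf("loadings_%s.csv", side)))
    utils::write.csv(
      data.frame(component = seq_along(p$explained_variance_pct),
                 explained_pct = p$explained_variance_pct,
                 cumulative_pct = p$cumulative_pct),
      file.path(dir, sprintf("explained_variance_%s.csv", side)),
      row.names = FALSE)
    cluster_newick(bundle$clusters[[side]],
                   file.path(dir, sprintf("linkage_%s.nwk", side)))
  }
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Download reconstructions from the NeuroMorpho archive (optional)
#'
#' Queries the public NeuroMorpho.Org REST API for an archive and
#' downloads the standardized SWC files plus a manifest. Purely optional
#' convenience: it needs network access and is never used by the test
#' suite; all analyses run equally on [generate_cohort()] output or any
#' local SWC directory.
#'
#' @param archive NeuroMorpho archive name to query.
#' @param dir output directory.
#' @param max_neurons cap on the number of downloads.
#' @param retries HTTP retry count per request.
#' @return manifest data.frame (`filename`, `neuron_id`, `area`,
#'   `age_group`); rows whose age metadata cannot be parsed are flagged
#'   with `age_group = NA`, never guessed.
#' @export
fetch_neuromorpho <- function(archive, dir, max_neurons = Inf, retries = 3L) {
  base <- "https://neuromorpho.org/api/neuron/select"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  get_json <- function(url) {
    for (i in seq_len(retries)) {
      res <- tryCatch(jsonlite::fromJSON(url), error = function(e) NULL)
      if (!is.null(res)) return(res)
    }
    stop("request failed after ", retries, " retries: ", url)
  }
  rows <- list(); page <- 0L
  repeat {
    res <- get_json(sprintf("%s?q=archive:%s&page=%d", base, archive, page))
    neurons <- res$`_embedded`$neuronResources
    if (is.null(neurons) || nrow(neurons) == 0L) break
    for (i in seq_len(nrow(neurons))) {
      if (length(rows) >= max_neurons) break
      name <- neurons$neuron_name[i]
      url <- neurons$png_url[i]
      swc_url <- sub("images/imageFiles", "dableFiles", url)
      swc_url <- sub("\\.png$", ".CNG.swc", swc_url)
      dest <- file.path(dir, paste0(name, ".swc"))
      ok <- tryCatch({
        utils::download.file(swc_url, dest, quiet = TRUE); TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) next
      age <- suppressWarnings(as.numeric(neurons$min_age[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        filename = basename(dest), neuron_id = name,
        area = neurons$brain_region[i][[1]][1],
        age_group = if (is.na(age)) NA_character_ else as.character(age))
    }
    if (length(rows) >= max_neurons) break
    page <- page + 1L
    if (page >= res$page$totalPages) break
  }
  if (length(rows) == 0L) {
    warning("empty query result for archive '", archive, "'")
    manifest <- data.frame(filename = character(0), neuron_id = character(0),
                           area = character(0), age_group = character(0))
  } else {
    manifest <- do.call(rbind, rows)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
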