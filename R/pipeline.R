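#' Pipeline configuration
#'
#' Bundles every stage's tunables. Unknown arguments are rejected (the
#' formal argument list is the schema), and the object round-trips through
#' JSON via [write_config()] / [read_config()].
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param cv_iterations CV repetitions for both classification tasks.
#' @param outer_folds,inner_folds,cost_grid CV harness settings.
#' @param rank_iterations fold-split repetitions for feature ranking.
#' @param k_values feature counts for the accuracy-vs-k curve (`NULL`
#'   skips the curve).
#' @param n_pathways,n_enriched simulated pathway resource sizes.
#' @param n_permutations permutations for enrichment significance.
#' @param q_cutoff enrichment q-value cutoff used in the report.
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cv_iterations = 20,
                            outer_folds = 4, inner_folds = 3,
                            cost_grid = 1:10,
                            rank_iterations = 5,
                            k_values = NULL,
                            n_pathways = 60, n_enriched = 5,
                            n_permutations = 1000,
                            q_cutoff = 0.01,
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), cv_iterations >= 1,
            n_permutations >= 100, q_cutoff > 0, q_cutoff <= 1)
  structure(list(sim = sim, cv_iterations = cv_iterations,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 cost_grid = cost_grid, rank_iterations = rank_iterations,
                 k_values = k_values, n_pathways = n_pathways,
                 n_enriched = n_enriched, n_permutations = n_permutations,
                 q_cutoff = q_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$sim <- unclass(obj$sim)
  # named count vectors must become JSON objects, not nameless arrays
  obj$sim$n_samples_per_class <- lapply(obj$sim$n_samples_per_class, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- obj$sim
  sim_args$n_samples_per_class <- lapply(sim_args$n_samples_per_class, unlist)
  sim <- do.call(sim_config, sim_args)
  obj$sim <- NULL
  if (!is.null(obj$k_values)) obj$k_values <- as.numeric(obj$k_values)
  do.call(pipeline_config, c(list(sim = sim), obj))
}

#' Principal-component coordinates with a fixed sign convention
#'
#' PCA of the (already Z-scored) candidate-marker matrix, for
#' visualization. Each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x samples x features matrix.
#' @return list: `scores`, `rotation`, `var_explained` (fractions).
#' @export
pca_scores <- function(x) {
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  list(scores = pc$x, rotation = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

# Heatmap-ready sample ordering: Euclidean distance, average linkage.
hclust_order <- function(x) {
  hclust(dist(x), method = "average")$order
}

# Final screening + subtyping models for two-stage prediction.
.two_stage_fit <- function(features, inner_folds, cost_grid, seed) {
  x <- features$x
  y_bin <- factor(ifelse(features$class == "RL", "RL", "lymphoma"),
                  levels = c("RL", "lymphoma"))
  gamma <- 1 / (ncol(x) * var(as.vector(x)))
  set.seed(seed)
  cost_b <- .tune_cost(x, y_bin, "radial", cost_grid, inner_folds, gamma)
  screen <- e1071::svm(x, y_bin, kernel = "radial", cost = cost_b,
                       gamma = gamma, scale = FALSE)
  lym <- features$class != "RL"
  y_sub <- factor(features$class[lym], levels = LYMPHOMA_SUBTYPES)
  cost_m <- .tune_cost(x[lym, , drop = FALSE], y_sub, "radial", cost_grid,
                       inner_folds, gamma)
  subtype <- e1071::svm(x[lym, , drop = FALSE], y_sub, kernel = "radial",
                        cost = cost_m, gamma = gamma, scale = FALSE)
  list(screen = screen, subtype = subtype)
}

#' Two-stage diagnostic prediction
#'
#' Stage 1 screens reactive vs lymphoma; only samples predicted as
#' lymphoma proceed to stage 2 subtyping (samples called reactive get
#' `NA` subtype).
#'
#' @param models list with `screen` and `subtype` fitted models.
#' @param x feature matrix for the samples to classify.
#' @return data frame `sample_id, screen, subtype`.
#' @export
two_stage_predict <- function(models, x) {
  screen <- as.character(predict(models$screen, x))
  subtype <- rep(NA_character_, nrow(x))
  go <- screen == "lymphoma"
  if (any(go))
    subtype[go] <- as.character(predict(models$subtype, x[go, , drop = FALSE]))
  data.frame(sample_id = rownames(x), screen = screen, subtype = subtype,
             stringsAsFactors = FALSE)
}

# Quantify + normalize one cohort's plates up to the Z-scored matrix.
.prepare_cohort <- function(plates, sample_ids) {
  keep <- plates$well_role %in% c("standard", "ntc") |
    plates$sample_id %in% sample_ids
  quantify_plates(plates[keep, ])
}

#' Run the complete diagnostic workflow on a simulated study
#'
#' Executes simulate, quantify, normalize, panel construction, trend
#' validation, cohort merging, screening and subtyping cross-validation,
#' two-stage prediction, PCA/clustering reporting, and pathway enrichment,
#' all driven by one configuration and one master seed.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` bundle (see elements in the source).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage_seeds <- list(simulate = seed, pathways = seed + 11L,
                      screen = seed + 23L, subtype = seed + 37L,
                      ranking = seed + 53L, enrich = seed + 71L,
                      two_stage = seed + 89L)
  t0 <- Sys.time()
  stage <- function(nm) message(sprintf("[%s] %s", format(Sys.time() - t0), nm))

  stage("simulate: generating cohorts")
  config$sim$seed <- stage_seeds$simulate
  sim <- simulate_cohort(config$sim)
  ann <- sim$annotation

  stage("quantify: Ct -> log2 copies")
  disc_ids <- ann$sample_id[ann$cohort == "discovery"]
  q_disc <- .prepare_cohort(sim$plates, disc_ids)
  has_validation <- "validation" %in% ann$cohort

  stage("normalize: detection filter + global mean + Z-score (discovery)")
  em_disc <- filter_detection(q_disc$matrix)
  norm_disc <- zscore_standardize(global_mean_normalize(em_disc))

  stage("panel: differential testing + tiered marker selection")
  disc_labels <- ann$class[match(rownames(norm_disc$values), ann$sample_id)]
  pb <- build_marker_panel(norm_disc, disc_labels)
  panel <- pb$panel

  trends <- cv_screen <- cv_subtype <- features <- two_stage <- NULL
  curve_screen <- NULL
  if (has_validation) {
    stage("quantify/normalize: validation cohort on the panel")
    val_ids <- ann$sample_id[ann$cohort == "validation"]
    q_val <- .prepare_cohort(sim$plates, val_ids)
    em_val <- q_val$matrix
    keep <- intersect(colnames(em_val$values), panel$entries$mirna_id)
    em_val$values <- em_val$values[, keep, drop = FALSE]
    em_val$mask <- em_val$mask[, keep, drop = FALSE]

    stage("panel: cross-cohort trend validation")
    vann <- ann[match(rownames(em_val$values), ann$sample_id), ]
    vnorm <- housekeeping_normalize(em_val, panel_tier(panel, "housekeeping"))
    vnorm <- combat_correct(vnorm, vann$collection_site,
                            vann[, c("class", "tissue_site")])$matrix
    classes <- sort(unique(vann$class))
    vstats <- rbind(
      do.call(rbind, lapply(classes, function(cl)
        ttest_contrast(vnorm, vann$class, cl))),
      do.call(rbind, lapply(combn(classes, 2, simplify = FALSE), function(pr)
        ttest_contrast(vnorm, vann$class, pr)))
    )
    trends <- validate_trends(pb$stats, vstats, panel)

    stage("normalize: merging cohorts (housekeeping + ComBat)")
    features <- merge_cohorts(em_disc, q_val$matrix, ann, panel)

    stage("classify: reactive-vs-lymphoma screening CV")
    y_bin <- factor(ifelse(features$class == "RL", "RL", "lymphoma"),
                    levels = c("RL", "lymphoma"))
    cv_screen <- run_cv(features$x, y_bin, "binary",
                        n_iterations = config$cv_iterations,
                        outer_folds = config$outer_folds,
                        inner_folds = config$inner_folds,
                        cost_grid = config$cost_grid,
                        seed = stage_seeds$screen)

    stage("classify: 4-way subtype CV")
    lym <- features$class != "RL"
    cv_subtype <- run_cv(features$x[lym, , drop = FALSE],
                         factor(features$class[lym], levels = LYMPHOMA_SUBTYPES),
                         "multiclass",
                         n_iterations = config$cv_iterations,
                         outer_folds = config$outer_folds,
                         inner_folds = config$inner_folds,
                         cost_grid = config$cost_grid,
                         seed = stage_seeds$subtype)

    if (!is.null(config$k_values)) {
      stage("classify: accuracy-vs-feature-count curve (screening)")
      rk <- rank_features(features$x, y_bin, "binary",
                          n_iterations = config$rank_iterations,
                          seed = stage_seeds$ranking)
      curve_screen <- accuracy_vs_k(features$x, y_bin, "binary", rk,
                                    config$k_values,
                                    n_iterations = config$cv_iterations,
                                    outer_folds = config$outer_folds,
                                    inner_folds = config$inner_folds,
                                    cost_grid = config$cost_grid,
                                    seed = stage_seeds$screen)
    }

    stage("classify: two-stage screen-then-subtype prediction")
    models <- .two_stage_fit(features, config$inner_folds, config$cost_grid,
                             stage_seeds$two_stage)
    two_stage <- two_stage_predict(models, features$x)
  }

  stage("enrich: miRSEA on lymphoma-vs-reactive fold changes")
  resources <- simulate_pathway_resources(
    sim$truth, n_pathways = config$n_pathways, n_enriched = config$n_enriched,
    seed = stage_seeds$pathways)
  lab_bin <- ifelse(disc_labels == "RL", "RL", "LYM")
  dstats <- ttest_contrast(norm_disc, lab_bin, c("LYM", "RL"))
  enrichment <- run_mirsea(dstats, resources$target_map, resources$pathways,
                           n_permutations = config$n_permutations,
                           seed = stage_seeds$enrich)

  stage("report: PCA + clustering")
  cand <- intersect(colnames(norm_disc$values),
                    panel$entries$mirna_id[panel$entries$tier != "housekeeping"])
  pca <- pca_scores(norm_disc$values[, cand, drop = FALSE])
  cluster_order <- hclust_order(norm_disc$values[, cand, drop = FALSE])

  manifest <- list(
    package = "lymphomiR",
    version = as.character(utils::packageVersion("lymphomiR")),
    seed = seed, stage_seeds = stage_seeds,
    parameters = list(cv_iterations = config$cv_iterations,
                      n_permutations = config$n_permutations,
                      q_cutoff = config$q_cutoff,
                      n_mirnas = config$sim$n_mirnas)
  )
  structure(list(
    config = config, manifest = manifest,
    simulation = sim, curves_qc = q_disc$curves,
    expression_discovery = em_disc, normalized_discovery = norm_disc,
    panel = panel, panel_stats = pb$stats, trends = trends,
    features = features, cv_screen = cv_screen, cv_subtype = cv_subtype,
    feature_curve = curve_screen, two_stage = two_stage,
    enrichment = enrichment,
    enriched_at_cutoff = enrichment$pathway[enrichment$q_value < config$q_cutoff &
                                              enrichment$score > 0],
    pca = pca, cluster_order = cluster_order
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("lymphomiR pipeline result\n")
  cat(" miRNAs detected:", ncol(x$expression_discovery$values), "\n")
  print(x$panel)
  if (!is.null(x$trends))
    cat(sprintf(" Trend concordance: %d/%d candidate markers\n",
                x$trends$n_concordant, x$trends$n_markers))
  if (!is.null(x$cv_screen))
    cat(sprintf(" Screening: accuracy %.1f%%, mean AUC %.3f\n",
                100 * x$cv_screen$accuracy, x$cv_screen$auc$mean))
  if (!is.null(x$cv_subtype))
    cat(sprintf(" Subtyping: accuracy %.1f%%\n", 100 * x$cv_subtype$accuracy))
  cat(sprintf(" Enriched pathways at q<%g: %d\n", x$config$q_cutoff,
              length(x$enriched_at_cutoff)))
  invisible(x)
}
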