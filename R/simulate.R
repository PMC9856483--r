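#' Configuration for the synthetic qPCR cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults mirror
#' the study design the workflow targets: a discovery cohort of 100 FFPE
#' samples (SLL 23, FL 21, MCL 20, MZL 19, RL 17) profiled at a single site
#' and a validation cohort of 282 samples (SLL 20, FL 74, MCL 22, MZL 74,
#' RL 92) collected at three sites, with ~360 assayed miRNAs of which a
#' configurable fraction is engineered to fail the detection filter.
#'
#' @param n_mirnas number of assayed miRNAs.
#' @param n_samples_per_class named list (per cohort) of named integer
#'   vectors giving samples per diagnostic class; class names must come from
#'   `SLL, FL, MCL, MZL, RL`. `NULL` uses the default cohort sizes above.
#' @param cohorts which cohorts to emit (`"discovery"`, `"validation"`).
#' @param n_markers_per_class number of truly differential miRNAs planted
#'   per one-vs-rest contrast (half up-, half down-regulated).
#' @param effect_size log2-copy shift applied to planted markers.
#' @param batch_shift_sd sd of per-site, per-miRNA additive log2 shifts.
#' @param batch_scale_sd sd (log scale) of per-site multiplicative noise
#'   distortions.
#' @param cohort_shift_sd sd of the per-miRNA additive log2 shift separating
#'   the validation cohort from discovery (platform/chemistry drift).
#' @param spike_in_sd per-sample workflow-variation sd, in Ct units
#'   (recovered by spike-in correction).
#' @param replicate_sd technical duplicate sd in Ct units.
#' @param dropout_fraction fraction of miRNAs expressed below the detection
#'   floor, engineered to fail the `>10%` undetected filter.
#' @param well_dropout_rate per-well probability of sporadic amplification
#'   failure (emitted as Ct above the NTC level).
#' @param baseline_mean,baseline_sd mean/sd of per-miRNA baseline log2 copy
#'   numbers for detectable miRNAs.
#' @param biological_sd range (min, max) of per-miRNA biological sd in log2
#'   copies.
#' @param ntc_ct no-template-control Ct level (the detection floor).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mirnas = 360,
                       n_samples_per_class = NULL,
                       cohorts = c("discovery", "validation"),
                       n_markers_per_class = 12,
                       effect_size = 1.5,
                       batch_shift_sd = 0.4,
                       batch_scale_sd = 0.1,
                       cohort_shift_sd = 0.3,
                       spike_in_sd = 0.3,
                       replicate_sd = 0.15,
                       dropout_fraction = 0.13,
                       well_dropout_rate = 0.02,
                       baseline_mean = 10,
                       baseline_sd = 1.5,
                       biological_sd = c(0.3, 0.8),
                       ntc_ct = 38,
                       seed = 1L) {
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  if (is.null(n_samples_per_class)) {
    n_samples_per_class <- list(
      discovery  = c(SLL = 23, FL = 21, MCL = 20, MZL = 19, RL = 17),
      validation = c(SLL = 20, FL = 74, MCL = 22, MZL = 74, RL = 92)
    )[cohorts]
  }
  if (!is.list(n_samples_per_class)) {
    if (length(cohorts) != 1L)
      stop("`n_samples_per_class` must be a per-cohort list when >1 cohort requested")
    n_samples_per_class <- setNames(list(n_samples_per_class), cohorts)
  }
  if (!setequal(names(n_samples_per_class), cohorts))
    stop("`n_samples_per_class` names must match `cohorts`")
  for (co in names(n_samples_per_class)) {
    cnt <- n_samples_per_class[[co]]
    bad <- setdiff(names(cnt), ALL_CLASSES)
    if (length(bad))
      stop("unknown diagnostic class(es) in `n_samples_per_class`: ",
           paste(bad, collapse = ", "))
    if (any(cnt < 1)) stop("all class counts must be >= 1")
  }
  stopifnot(
    n_mirnas >= 1, n_markers_per_class >= 1,
    batch_shift_sd >= 0, batch_scale_sd >= 0, cohort_shift_sd >= 0,
    spike_in_sd >= 0, replicate_sd >= 0,
    dropout_fraction >= 0, dropout_fraction < 1,
    well_dropout_rate >= 0, well_dropout_rate < 1,
    length(biological_sd) == 2, all(biological_sd >= 0)
  )
  structure(list(
    n_mirnas = as.integer(n_mirnas),
    n_samples_per_class = n_samples_per_class,
    cohorts = cohorts,
    n_markers_per_class = as.integer(n_markers_per_class),
    effect_size = effect_size,
    batch_shift_sd = batch_shift_sd,
    batch_scale_sd = batch_scale_sd,
    cohort_shift_sd = cohort_shift_sd,
    spike_in_sd = spike_in_sd,
    replicate_sd = replicate_sd,
    dropout_fraction = dropout_fraction,
    well_dropout_rate = well_dropout_rate,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    biological_sd = biological_sd,
    ntc_ct = ntc_ct,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Nodal counts / totals per class, used to assign tissue sites with the
# observed nodal:extranodal balance (MZL predominantly extranodal, SLL
# predominantly nodal, etc.).
.nodal_fraction <- function(cohort, cls) {
  tab <- list(
    discovery  = c(SLL = 20 / 23, FL = 5 / 21, MCL = 12 / 20, MZL = 0 / 19, RL = 15 / 17),
    validation = c(SLL = 14 / 20, FL = 53 / 74, MCL = 13 / 22, MZL = 5 / 74, RL = 54 / 92)
  )
  tab[[cohort]][cls]
}

#' Simulate a multi-site qPCR cohort with known ground truth
#'
#' Generates plate-level Ct observations (sample duplicates, six-point
#' 10-fold standard-dilution series per miRNA per plate, two no-template
#' controls per plate, three spike-in wells per sample), a sample annotation
#' table, and the latent ground truth. Latent log2 copy numbers are
#' baseline + class effect (planted markers) + cohort shift + per-site batch
#' effect + biological noise; Ct values follow the perfect-efficiency curve
#' `Ct = intercept - log2(copies)` with per-miRNA intercept jitter, plus a
#' per-sample workflow offset (shared with the spike-ins) and technical
#' replicate noise.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_cohort` with elements `plates` (a
#'   `plate_set` data frame), `annotation` (sample annotation data frame)
#'   and `truth` (a `ground_truth` list).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- config$n_mirnas
  mirnas <- sprintf("miR-%04d", seq_len(M))

  intercept <- rnorm(M, 40, 0.5)
  bio_sd <- runif(M, config$biological_sd[1], config$biological_sd[2])
  baseline <- rnorm(M, config$baseline_mean, config$baseline_sd)
  n_drop <- round(config$dropout_fraction * M)
  dropout_idx <- if (n_drop > 0) sort(sample.int(M, n_drop)) else integer(0)
  # dropout miRNAs sit ~3+ cycles beyond the NTC floor
  baseline[dropout_idx] <- rnorm(n_drop, -1.5, 0.5)

  # planted differential markers: disjoint sets per one-vs-rest contrast
  avail <- setdiff(seq_len(M), dropout_idx)
  k <- config$n_markers_per_class
  if (length(avail) < k * length(ALL_CLASSES))
    stop("not enough detectable miRNAs to plant markers for all classes")
  marker_idx <- sample(avail, k * length(ALL_CLASSES))
  true_markers <- data.frame(
    contrast = rep(ALL_CLASSES, each = k),
    mirna_id = mirnas[marker_idx],
    direction = rep(rep(c("up", "down"), c(ceiling(k / 2), floor(k / 2))),
                    times = length(ALL_CLASSES)),
    stringsAsFactors = FALSE
  )

  # sample annotation
  ann <- do.call(rbind, lapply(config$cohorts, function(co) {
    cnt <- config$n_samples_per_class[[co]]
    do.call(rbind, lapply(names(cnt), function(cls) {
      n <- cnt[[cls]]
      sites <- if (co == "discovery") rep("NUH", n)
               else c("NUH", "TTSH", "UMMC")[(seq_len(n) - 1L) %% 3L + 1L]
      n_nodal <- round(.nodal_fraction(co, cls) * n)
      tissue <- sample(rep(c("nodal", "extranodal"), c(n_nodal, n - n_nodal)))
      data.frame(
        sample_id = sprintf("%s_%s_%03d", toupper(substr(co, 1, 1)), cls, seq_len(n)),
        class = cls, tissue_site = tissue, collection_site = sites,
        cohort = co, plate_id = paste(co, sites, sep = "_"),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(ann) <- NULL
  N <- nrow(ann)
  plates <- sort(unique(ann$plate_id))

  # per-plate (RT batch) additive and multiplicative effects per miRNA
  gamma <- matrix(rnorm(length(plates) * M, 0, config$batch_shift_sd),
                  nrow = length(plates), dimnames = list(plates, mirnas))
  delta <- matrix(exp(rnorm(length(plates) * M, 0, config$batch_scale_sd)),
                  nrow = length(plates), dimnames = list(plates, mirnas))
  cohort_shift <- setNames(rnorm(M, 0, config$cohort_shift_sd), mirnas)

  # latent log2 copies: samples x miRNAs
  pl <- match(ann$plate_id, plates)
  eps <- matrix(rnorm(N * M), N, M) * matrix(bio_sd, N, M, byrow = TRUE)
  L <- matrix(baseline, N, M, byrow = TRUE) +
    gamma[pl, , drop = FALSE] +
    delta[pl, , drop = FALSE] * eps
  L <- L + outer(ann$cohort == "validation", cohort_shift)
  for (cls in ALL_CLASSES) {
    rows <- which(ann$class == cls)
    if (!length(rows)) next
    mk <- true_markers[true_markers$contrast == cls, ]
    j <- match(mk$mirna_id, mirnas)
    shift <- ifelse(mk$direction == "up", 1, -1) * config$effect_size
    L[rows, j] <- L[rows, j] + rep(shift, each = length(rows))
  }
  dimnames(L) <- list(ann$sample_id, mirnas)

  offsets <- setNames(rnorm(N, 0, config$spike_in_sd), ann$sample_id)

  # sample wells: technical duplicates
  i <- rep(seq_len(N), times = M * 2L)
  j <- rep(rep(seq_len(M), each = N), times = 2L)
  rep_idx <- rep(1:2, each = N * M)
  ct <- intercept[j] - L[cbind(i, j)] + offsets[i] +
    rnorm(length(i), 0, config$replicate_sd)
  dropped <- runif(length(i)) < config$well_dropout_rate
  ct[dropped] <- config$ntc_ct + runif(sum(dropped), 0.5, 3)
  ct <- pmin(ct, 45)
  sample_wells <- data.frame(
    plate_id = ann$plate_id[i], well_role = "sample",
    sample_id = ann$sample_id[i], mirna_id = mirnas[j],
    replicate = rep_idx, ct = ct, known_copies = NA_real_,
    stringsAsFactors = FALSE
  )

  # standard-dilution series: 6 ten-fold points per miRNA per plate
  sg <- expand.grid(dil = 1:6, mirna = seq_len(M), plate = seq_along(plates))
  std_wells <- data.frame(
    plate_id = plates[sg$plate], well_role = "standard",
    sample_id = NA_character_, mirna_id = mirnas[sg$mirna],
    replicate = 1L,
    ct = intercept[sg$mirna] - log2(10^sg$dil) +
      rnorm(nrow(sg), 0, config$replicate_sd),
    known_copies = 10^sg$dil, stringsAsFactors = FALSE
  )

  ntc_wells <- data.frame(
    plate_id = rep(plates, each = 2L), well_role = "ntc",
    sample_id = NA_character_, mirna_id = NA_character_,
    replicate = rep(1:2, times = length(plates)),
    ct = rep(config$ntc_ct + c(0, 0.3), times = length(plates)),
    known_copies = NA_real_, stringsAsFactors = FALSE
  )

  spike_levels <- c(`spike-1` = 21, `spike-2` = 23, `spike-3` = 25)
  si <- rep(seq_len(N), each = 3L)
  spike_wells <- data.frame(
    plate_id = ann$plate_id[si], well_role = "spike",
    sample_id = ann$sample_id[si],
    mirna_id = rep(names(spike_levels), times = N),
    replicate = 1L,
    ct = rep(unname(spike_levels), times = N) + offsets[si] +
      rnorm(length(si), 0, config$replicate_sd),
    known_copies = NA_real_, stringsAsFactors = FALSE
  )

  plate_df <- rbind(sample_wells, std_wells, ntc_wells, spike_wells)
  rownames(plate_df) <- NULL
  class(plate_df) <- c("plate_set", "data.frame")

  truth <- structure(list(
    true_markers = true_markers,
    batch = list(gamma = gamma, delta = delta),
    cohort_shift = cohort_shift,
    latent_log2 = L,
    intercepts = setNames(intercept, mirnas),
    sample_offsets = offsets,
    dropout_ids = mirnas[dropout_idx],
    config = config
  ), class = "ground_truth")

  structure(list(plates = plate_df, annotation = ann, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated qPCR cohort:",
      nrow(x$annotation), "samples,",
      x$truth$config$n_mirnas, "miRNAs,",
      length(unique(x$plates$plate_id)), "plate(s)\n")
  print(table(x$annotation$class, x$annotation$cohort))
  invisible(x)
}

#' Simulate miRNA target and pathway resources with planted enrichment
#'
#' Emits a strong-evidence style miRNA-to-gene target table and a GMT-like
#' pathway collection in which a configurable number of pathways is enriched
#' for targets of the planted lymphoma-up miRNAs (markers of the RL
#' one-vs-rest contrast with direction "down", i.e. higher in lymphoma than
#' in reactive tissue), so the planted pathways are coherently up-regulated
#' in lymphoma. Optionally adds size-extreme pathways (targeted by fewer
#' than 10 or, when enough miRNAs exist, more than 500 miRNAs) to exercise
#' the size filter.
#'
#' @param truth a `ground_truth` object from [simulate_cohort()].
#' @param n_pathways number of ordinary pathways to emit.
#' @param n_genes size of the gene universe.
#' @param targets_per_mirna validated targets sampled per miRNA.
#' @param n_enriched number of planted enriched pathways (first pathways).
#' @param enriched_overlap fraction of each planted pathway's genes drawn
#'   from the marker-target pool.
#' @param pathway_size_range gene-count range for ordinary pathways.
#' @param include_extremes add the size-filter edge-case pathways.
#' @param seed integer seed.
#' @return list with `target_map` (data frame `mirna_id, gene_id, evidence`)
#'   and `pathways` (named list of gene-id vectors; names carry a
#'   KEGG/REACTOME/PID/BIOCARTA-style source prefix).
#' @export
simulate_pathway_resources <- function(truth, n_pathways = 50, n_genes = 3000,
                                       targets_per_mirna = 15,
                                       n_enriched = 5, enriched_overlap = 0.8,
                                       pathway_size_range = c(20, 60),
                                       include_extremes = TRUE, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_pathways >= 1, n_genes >= 10,
            n_enriched <= n_pathways, enriched_overlap >= 0, enriched_overlap <= 1)
  set.seed(as.integer(seed))
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  mirnas <- names(truth$intercepts)
  target_map <- data.frame(
    mirna_id = rep(mirnas, each = targets_per_mirna),
    gene_id = as.vector(vapply(mirnas, function(m)
      sample(genes, targets_per_mirna), character(targets_per_mirna))),
    evidence = "strong", stringsAsFactors = FALSE
  )
  target_map <- unique(target_map)

  tm <- truth$true_markers
  lymphoma_up <- tm$mirna_id[tm$contrast == "RL" & tm$direction == "down"]
  pool <- unique(target_map$gene_id[target_map$mirna_id %in% lymphoma_up])
  sources <- c("KEGG", "REACTOME", "PID", "BIOCARTA")
  pathways <- list()
  for (p in seq_len(n_pathways)) {
    size <- sample(pathway_size_range[1]:pathway_size_range[2], 1)
    if (p <= n_enriched && length(pool)) {
      n_pool <- min(round(enriched_overlap * size), length(pool))
      gs <- c(sample(pool, n_pool), sample(setdiff(genes, pool), size - n_pool))
      nm <- sprintf("KEGG_PLANTED_PW_%03d", p)
    } else {
      gs <- sample(genes, size)
      nm <- sprintf("%s_NULL_PW_%03d", sources[(p - 1L) %% 4L + 1L], p)
    }
    pathways[[nm]] <- sort(unique(gs))
  }
  if (include_extremes) {
    pathways[["KEGG_TINY_PW"]] <- sample(genes, 1)
    if (length(mirnas) >= 501) {
      # enough genes that essentially every miRNA has a target inside
      pathways[["REACTOME_HUGE_PW"]] <- sort(sample(genes, min(n_genes, 1500)))
    }
  }
  list(target_map = target_map, pathways = pathways)
}
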