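# Accept either an expr_matrix or a bare samples-x-miRNAs matrix.
.values <- function(x) if (inherits(x, "expr_matrix")) x$values else x

.rewrap <- function(x, values) {
  if (inherits(x, "expr_matrix")) {
    x$values <- values
    x
  } else values
}

#' Detection filter
#'
#' Removes miRNAs undetected in more than `max_undetected_fraction` of
#' samples (the default keeps a miRNA undetected in exactly 10% of
#' samples, since only ">10%" is filtered). Column order is preserved.
#'
#' @param x an `expr_matrix` (the detectability mask is required).
#' @param max_undetected_fraction retention threshold.
#' @return the filtered `expr_matrix`.
#' @export
filter_detection <- function(x, max_undetected_fraction = 0.10) {
  stopifnot(inherits(x, "expr_matrix"))
  undet <- colMeans(!x$mask)
  keep <- undet <= max_undetected_fraction
  if (!any(keep))
    stop("no miRNA passes the detection filter; consider relaxing ",
         "`max_undetected_fraction`")
  x$values <- x$values[, keep, drop = FALSE]
  x$mask <- x$mask[, keep, drop = FALSE]
  x
}

#' Global-mean normalization
#'
#' Subtracts each sample's mean log2 expression (over all retained miRNAs)
#' from that sample's values, the global normalization strategy for
#' genome-scale miRNA qPCR panels.
#'
#' @param x `expr_matrix` or samples-x-miRNAs matrix.
#' @return same type as input, with per-sample mean 0.
#' @export
global_mean_normalize <- function(x) {
  v <- .values(x)
  if (ncol(v) < 2) stop("global-mean normalization needs >= 2 miRNAs")
  .rewrap(x, v - rowMeans(v))
}

#' Z-score standardization per miRNA
#'
#' Centers and scales each miRNA to mean 0, sample sd 1 (n - 1 denominator).
#'
#' @param x `expr_matrix` or matrix.
#' @return same type as input.
#' @export
zscore_standardize <- function(x) {
  v <- .values(x)
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop("zero-variance miRNA(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  .rewrap(x, scale(v, center = TRUE, scale = sds))
}

#' Housekeeping normalization
#'
#' Subtracts, per sample, the mean log2 expression of the housekeeping
#' miRNA set from every value, making cohorts profiled on different panels
#' comparable.
#'
#' @param x `expr_matrix` or matrix.
#' @param housekeeping_ids miRNA ids; all must be present.
#' @return same type as input.
#' @export
housekeeping_normalize <- function(x, housekeeping_ids) {
  v <- .values(x)
  missing <- setdiff(housekeeping_ids, colnames(v))
  if (length(missing))
    stop("housekeeping miRNA(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  .rewrap(x, v - rowMeans(v[, housekeeping_ids, drop = FALSE]))
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Parametric empirical-Bayes location/scale batch adjustment with the
#' collection site as batch and diagnostic class + tissue site protected as
#' covariates. A single batch is returned unchanged (identity transform).
#' The adjustment itself is delegated to `sva::ComBat`; the report carries
#' naive (unshrunk) per-batch location/scale estimates computed from the
#' covariate-model residuals for audit.
#'
#' @param x `expr_matrix` or samples-x-miRNAs matrix.
#' @param batch factor/character of batch labels (one per sample).
#' @param covariates data frame of covariates to protect (e.g. class,
#'   tissue site); may be `NULL`.
#' @return list with `matrix` (corrected, same type as input) and `report`
#'   (a `normalization_report`).
#' @export
combat_correct <- function(x, batch, covariates = NULL) {
  v <- .values(x)
  batch <- factor(batch)
  if (length(batch) != nrow(v)) stop("one batch label per sample required")
  report <- list(n_mirnas_in = ncol(v), n_mirnas_retained = ncol(v),
                 batches = levels(batch), gamma_hat = NULL, delta2_hat = NULL)
  class(report) <- "normalization_report"
  if (nlevels(batch) < 2) {
    return(list(matrix = x, report = report))
  }
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mod <- model.matrix(~ ., data = covariates)
    full <- cbind(mod, model.matrix(~ batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full))
      stop("covariate design is rank-deficient given the batch variable")
  }
  corrected <- t(suppressMessages(
    sva::ComBat(dat = t(v), batch = batch, mod = mod, par.prior = TRUE)
  ))
  dimnames(corrected) <- dimnames(v)

  # naive per-batch estimates for the report (pre-shrinkage scale)
  design <- if (is.null(mod)) matrix(1, nrow(v), 1) else mod
  resid <- v - design %*% qr.coef(qr(design), v)
  report$gamma_hat <- t(vapply(levels(batch), function(b)
    colMeans(resid[batch == b, , drop = FALSE]), numeric(ncol(v))))
  report$delta2_hat <- t(vapply(levels(batch), function(b)
    apply(resid[batch == b, , drop = FALSE], 2, var), numeric(ncol(v))))
  list(matrix = .rewrap(x, corrected), report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("Normalization report:", x$n_mirnas_retained, "of", x$n_mirnas_in,
      "miRNAs retained;", length(x$batches), "batch(es)\n")
  invisible(x)
}

#' Merge discovery and validation cohorts on the shared marker panel
#'
#' Restricts both cohorts to the panel's miRNAs (matched by id, not
#' position), housekeeping-normalizes each cohort with the panel's
#' housekeeping tier, batch-corrects the validation cohort across its
#' collection sites, then batch-corrects across the cohort pair, protecting
#' diagnostic class and tissue site throughout. The tissue-site indicator
#' (nodal = 0, extranodal = 1) is appended as a numeric feature.
#'
#' @param discovery,validation `expr_matrix` or matrix for each cohort.
#' @param annotation sample annotation covering all samples of both
#'   cohorts (columns `sample_id, class, tissue_site, collection_site,
#'   cohort`).
#' @param panel a `marker_panel` from [assemble_panel()].
#' @param zscore re-standardize each candidate miRNA across the merged
#'   cohort before classification (off by default; the housekeeping +
#'   batch-corrected scale is used as-is).
#' @return list of class `feature_table`: `x` (samples x (candidates +
#'   tissue_site)), `class` (5-level labels), `annotation`.
#' @export
merge_cohorts <- function(discovery, validation, annotation, panel,
                          zscore = FALSE) {
  dv <- .values(discovery); vv <- .values(validation)
  shared <- intersect(panel$entries$mirna_id,
                      intersect(colnames(dv), colnames(vv)))
  if (!length(shared)) stop("no shared panel miRNAs between cohorts")
  hk <- intersect(panel_tier(panel, "housekeeping"), shared)
  if (!length(hk)) stop("no housekeeping miRNAs shared between cohorts")
  dv <- housekeeping_normalize(dv[, shared, drop = FALSE], hk)
  vv <- housekeeping_normalize(vv[, shared, drop = FALSE], hk)

  ann <- annotation[match(c(rownames(dv), rownames(vv)), annotation$sample_id), ]
  if (anyNA(ann$sample_id)) stop("annotation is missing some samples")
  vann <- ann[ann$cohort == "validation", ]
  if (length(unique(vann$collection_site)) > 1) {
    vv <- combat_correct(vv, vann$collection_site,
                         vann[, c("class", "tissue_site")])$matrix
  }
  merged <- rbind(dv, vv)
  merged <- combat_correct(merged, ann$cohort,
                           ann[, c("class", "tissue_site")])$matrix

  candidates <- intersect(
    panel$entries$mirna_id[panel$entries$tier != "housekeeping"], shared)
  if (zscore) merged <- zscore_standardize(merged)
  x <- cbind(merged[, candidates, drop = FALSE],
             tissue_site = as.numeric(ann$tissue_site == "extranodal"))
  structure(list(x = x, class = ann$class, annotation = ann),
            class = "feature_table")
}
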