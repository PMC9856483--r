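#' Spike-in correction of sample Ct values
#'
#' Uses the synthetic spike-in wells to correct per-sample workflow
#' variation (RNA isolation and RT-qPCR efficiency): every sample well's Ct
#' is shifted by minus (that sample's mean spike-in Ct minus the cohort
#' median of per-sample mean spike-in Cts). Spike-in wells themselves are
#' retained unchanged for audit, and the applied offsets are recorded so
#' that reapplying the correction is a no-op.
#'
#' @param plates a `plate_set` data frame.
#' @return the corrected `plate_set`, with per-sample offsets in
#'   `attr(, "spike_offsets")`.
#' @export
correct_spike_ins <- function(plates) {
  stopifnot(inherits(plates, "data.frame"))
  spike <- plates[plates$well_role == "spike", ]
  samp <- plates$well_role == "sample"
  sample_ids <- unique(plates$sample_id[samp])
  missing <- setdiff(sample_ids, unique(spike$sample_id))
  if (length(missing))
    stop("sample(s) without spike-in wells: ", paste(missing, collapse = ", "))
  mean_spike <- tapply(spike$ct, spike$sample_id, mean, na.rm = TRUE)
  target <- mean_spike - median(mean_spike)
  applied <- attr(plates, "spike_offsets")
  if (is.null(applied)) applied <- setNames(numeric(length(target)), names(target))
  delta <- target - applied[names(target)]
  idx <- which(samp)
  plates$ct[idx] <- plates$ct[idx] - delta[plates$sample_id[idx]]
  attr(plates, "spike_offsets") <- target
  plates
}

#' Fit a standard curve from a serial-dilution series
#'
#' Least-squares regression of Ct on log10(known copies) for one miRNA's
#' synthetic-standard dilution wells. Amplification efficiency is
#' `10^(-1/slope) - 1` (1.0 at perfect doubling, slope -3.321928).
#'
#' @param series data frame with columns `ct` and `known_copies` (one
#'   miRNA's standard wells), or a `plate_set` subset.
#' @param mirna_id optional id recorded on the curve.
#' @return a `standard_curve` list: `slope` (cycles per log10 copies),
#'   `intercept` (Ct at 1 copy), `r_squared`, `efficiency`, `n_points`,
#'   `flagged` (TRUE when `r_squared < 0.95`).
#' @export
fit_standard_curve <- function(series, mirna_id = NA_character_) {
  ok <- is.finite(series$ct) & is.finite(series$known_copies) &
    series$known_copies > 0
  series <- series[ok, ]
  if (length(unique(series$known_copies)) < 2)
    stop("standard curve needs >= 2 distinct dilution points with finite Ct")
  fit <- lm(ct ~ log10(known_copies), data = series)
  slope <- unname(coef(fit)[2])
  sst <- sum((series$ct - mean(series$ct))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(list(
    mirna_id = mirna_id,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    n_points = nrow(series),
    flagged = r2 < 0.95
  ), class = "standard_curve")
}

#' Fit standard curves for every (plate, miRNA) dilution series
#'
#' @param plates a `plate_set`.
#' @return data frame of class `standard_curves` with one row per
#'   (plate, miRNA): slope, intercept, r_squared, efficiency, flagged.
#' @export
fit_standard_curves <- function(plates) {
  std <- plates[plates$well_role == "standard", ]
  if (!nrow(std)) stop("plate set contains no standard wells")
  key <- paste(std$plate_id, std$mirna_id, sep = "\r")
  rows <- lapply(split(std, key), function(s) {
    cv <- fit_standard_curve(s, mirna_id = s$mirna_id[1])
    data.frame(plate_id = s$plate_id[1], mirna_id = s$mirna_id[1],
               slope = cv$slope, intercept = cv$intercept,
               r_squared = cv$r_squared, efficiency = cv$efficiency,
               n_points = cv$n_points, flagged = cv$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("standard_curves", "data.frame")
  out
}

#' Detectability call against no-template controls
#'
#' A well is detectable iff its Ct lies strictly below the lowest NTC Ct on
#' the plate (the strictest reading of "higher than NTCs is undetectable");
#' a missing Ct is undetectable, and an NTC that never amplified counts as
#' Ct 40.
#'
#' @param ct numeric vector of Ct values (NA = no amplification).
#' @param ntc_cts NTC Ct values from the same plate.
#' @return logical vector.
#' @export
call_detectable <- function(ct, ntc_cts) {
  if (!length(ntc_cts)) stop("at least one NTC well is required")
  ntc_cts[is.na(ntc_cts)] <- 40
  !is.na(ct) & ct < min(ntc_cts)
}

#' Interpolate absolute copy number from a standard curve
#'
#' @param ct Ct value(s).
#' @param curve a `standard_curve` (or anything with `slope` and
#'   `intercept`); `slope` must be negative.
#' @return copies per reaction, `10^((ct - intercept)/slope)`.
#' @export
interpolate_copies <- function(ct, curve) {
  if (!is.finite(curve$slope) || curve$slope >= 0)
    stop("standard-curve slope must be negative")
  10^((ct - curve$intercept) / curve$slope)
}

#' Build the sample-by-miRNA expression matrix of log2 copy numbers
#'
#' Technical duplicates are averaged on the Ct scale after per-well
#' detectability calls: a pair with one detectable member uses that value; a
#' pair with none is undetected and imputed at the plate's detection limit
#' (the copies corresponding to the lowest NTC Ct, through the miRNA's
#' curve). Averaged Ct is interpolated to copies and stored as log2 copies.
#' Duplicate pairs with both members detectable and |dCt| > 1 are flagged in
#' the QC table.
#'
#' @param plates a `plate_set` (ideally spike-in corrected).
#' @param curves a `standard_curves` table covering every (plate, miRNA)
#'   with sample wells.
#' @return an `expr_matrix`: list with `values` (samples x miRNAs log2
#'   copies), `mask` (logical detectability), `qc` (flagged duplicate
#'   pairs).
#' @export
build_expression_matrix <- function(plates, curves) {
  sw <- plates[plates$well_role == "sample", ]
  ntc <- plates[plates$well_role == "ntc", ]
  ntc$ct[is.na(ntc$ct)] <- 40
  ntc_min <- tapply(ntc$ct, ntc$plate_id, min)

  samples <- unique(sw$sample_id)
  mirnas <- unique(sw$mirna_id)
  ckey <- paste(curves$plate_id, curves$mirna_id, sep = "\r")
  wkey <- paste(sw$plate_id, sw$mirna_id, sep = "\r")
  cm <- match(wkey, ckey)
  if (anyNA(cm)) {
    miss <- unique(sw$mirna_id[is.na(cm)])
    stop("no standard curve for miRNA(s): ", paste(head(miss, 5), collapse = ", "))
  }
  if (any(curves$slope[cm] >= 0)) stop("non-negative standard-curve slope")

  i <- match(sw$sample_id, samples)
  j <- match(sw$mirna_id, mirnas)
  det <- call_detectable(sw$ct, 40) & sw$ct < ntc_min[sw$plate_id]
  g <- (j - 1L) * length(samples) + i
  sum_ct <- rowsum(ifelse(det, sw$ct, 0), g)
  n_det <- rowsum(as.integer(det), g)
  gi <- as.integer(rownames(sum_ct))

  ns <- length(samples)
  mean_ct <- matrix(NA_real_, ns, length(mirnas),
                    dimnames = list(samples, mirnas))
  mask <- matrix(FALSE, ns, length(mirnas), dimnames = dimnames(mean_ct))
  mask[gi] <- n_det[, 1] > 0
  mean_ct[gi] <- ifelse(n_det[, 1] > 0, sum_ct[, 1] / n_det[, 1], NA_real_)

  # per-(sample, miRNA) curve parameters via the sample's plate
  sample_plate <- sw$plate_id[match(samples, sw$sample_id)]
  slope <- intercept <- matrix(NA_real_, ns, length(mirnas),
                               dimnames = dimnames(mean_ct))
  slope[cbind(i, j)] <- curves$slope[cm]
  intercept[cbind(i, j)] <- curves$intercept[cm]

  # undetected entries: impute at the detection limit Ct = min NTC of plate
  limit_ct <- matrix(ntc_min[sample_plate], ns, length(mirnas))
  ct_final <- ifelse(mask, mean_ct, limit_ct)
  values <- log2(10^((ct_final - intercept) / slope))

  # QC: discordant duplicate pairs (both detectable, |dCt| > 1)
  qc <- data.frame(sample_id = character(0), mirna_id = character(0),
                   delta_ct = numeric(0), stringsAsFactors = FALSE)
  r1 <- sw[sw$replicate == 1L, ]
  r2 <- sw[sw$replicate == 2L, ]
  if (nrow(r1) && nrow(r2)) {
    m <- match(paste(r1$sample_id, r1$mirna_id),
               paste(r2$sample_id, r2$mirna_id))
    ok <- !is.na(m)
    d1 <- call_detectable(r1$ct, 40) & r1$ct < ntc_min[r1$plate_id]
    d2 <- call_detectable(r2$ct, 40) & r2$ct < ntc_min[r2$plate_id]
    dd <- ok & d1 & d2[m]
    delta <- abs(r1$ct - r2$ct[m])
    flag <- which(dd & delta > 1.0)
    if (length(flag))
      qc <- data.frame(sample_id = r1$sample_id[flag],
                       mirna_id = r1$mirna_id[flag],
                       delta_ct = delta[flag], stringsAsFactors = FALSE)
  }

  structure(list(values = values, mask = mask, qc = qc),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "samples x", ncol(x$values),
      "miRNAs (log2 copies);",
      sprintf("%.1f%% detected", 100 * mean(x$mask)), "\n")
  invisible(x)
}

#' Run the full quantification stage
#'
#' Spike-in correction, per-(plate, miRNA) standard curves, detectability
#' calls and duplicate averaging in one call.
#'
#' @param plates a `plate_set`.
#' @return list with `matrix` (an `expr_matrix`) and `curves`
#'   (a `standard_curves` QC table).
#' @export
quantify_plates <- function(plates) {
  plates <- correct_spike_ins(plates)
  curves <- fit_standard_curves(plates)
  list(matrix = build_expression_matrix(plates, curves), curves = curves)
}
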