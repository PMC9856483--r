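#' Per-miRNA Student's t-test for a one-vs-rest or one-vs-one contrast
#'
#' Equal-variance two-sample t-test per miRNA (the classical Student form;
#' Welch available via `var_equal = FALSE`). The mean difference is reported
#' as group-of-interest minus rest/other, so `direction == "up"` means
#' higher in the group of interest.
#'
#' @param x `expr_matrix` or samples-x-miRNAs matrix.
#' @param labels class label per sample.
#' @param contrast either a single class (one-vs-rest) or a length-2 vector
#'   `c(class_of_interest, other_class)` (one-vs-one).
#' @param var_equal use the pooled-variance Student form (default).
#' @return a `diff_stats` data frame: `mirna_id, contrast, mean_diff, t,
#'   p_value, direction`.
#' @export
ttest_contrast <- function(x, labels, contrast, var_equal = TRUE) {
  v <- .values(x)
  stopifnot(length(labels) == nrow(v))
  if (length(contrast) == 1) {
    g1 <- labels == contrast
    g2 <- !g1
    cname <- paste0(contrast, "_vs_rest")
  } else if (length(contrast) == 2) {
    g1 <- labels == contrast[1]
    g2 <- labels == contrast[2]
    cname <- paste0(contrast[1], "_vs_", contrast[2])
  } else stop("`contrast` must have length 1 or 2")
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2)
    stop("both contrast groups need >= 2 samples (got ", n1, " and ", n2, ")")
  st <- col_ttests(v[g1, , drop = FALSE], v[g2, , drop = FALSE],
                   var_equal = var_equal)
  out <- data.frame(
    mirna_id = colnames(v), contrast = cname,
    mean_diff = st$mean_diff, t = st$t, p_value = st$p,
    direction = ifelse(st$mean_diff > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("diff_stats", "data.frame")
  out
}

# Vectorized column-wise two-sample t statistics.
col_ttests <- function(a, b, var_equal = TRUE) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- ifelse(se > 0, d / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(t), df), 1)
  list(mean_diff = d, t = t, p = p, df = df)
}

#' Select top up- and down-regulated markers per contrast
#'
#' Per contrast, takes the `k_up` most significant upregulated and `k_down`
#' most significant downregulated miRNAs. A candidate already selected (for
#' another contrast, or in `exclude`) is skipped and the next-best by
#' p-value is taken, so tier counts are exact and the panel stays a set.
#' Ties are broken by larger |t|, then lexicographic miRNA id.
#'
#' @param stats one or more row-bound `diff_stats` tables (may cover several
#'   contrasts).
#' @param k_up,k_down markers per direction per contrast.
#' @param exclude miRNA ids never to select.
#' @return data frame `mirna_id, source_contrast, direction`.
#' @export
select_subtype_markers <- function(stats, k_up = 3, k_down = 3,
                                   exclude = character(0)) {
  taken <- exclude
  out <- list()
  for (cn in unique(stats$contrast)) {
    sub <- stats[stats$contrast == cn, ]
    for (dir in c("up", "down")) {
      k <- if (dir == "up") k_up else k_down
      cand <- sub[sub$direction == dir & !(sub$mirna_id %in% taken), ]
      cand <- cand[order(cand$p_value, -abs(cand$t), cand$mirna_id), ]
      if (nrow(cand) < k)
        stop("contrast ", cn, ": only ", nrow(cand), " ", dir,
             "-regulated candidates available, need ", k)
      pick <- cand[seq_len(k), ]
      taken <- c(taken, pick$mirna_id)
      out[[paste(cn, dir)]] <- data.frame(
        mirna_id = pick$mirna_id, source_contrast = cn, direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select housekeeping miRNAs by lowest variance
#'
#' @param x `expr_matrix` or matrix.
#' @param n number of housekeeping miRNAs.
#' @param exclude miRNA ids (e.g. already-selected markers) to skip.
#' @return character vector of `n` miRNA ids (ties broken by id).
#' @export
select_housekeeping <- function(x, n = 10, exclude = character(0)) {
  v <- .values(x)
  cand <- setdiff(colnames(v), exclude)
  if (length(cand) < n)
    stop("only ", length(cand), " non-excluded miRNAs available, need ", n)
  vars <- apply(v[, cand, drop = FALSE], 2, var)
  cand[order(vars, cand)][seq_len(n)]
}

#' Assemble the tiered marker panel
#'
#' Combines one-vs-rest markers, one-vs-one markers and housekeeping
#' miRNAs into a single panel; tiers must be disjoint (the panel is a set).
#' With the default workflow this yields 30 + 60 + 10 = 100 entries, of
#' which the 90 non-housekeeping entries are the candidate markers.
#'
#' @param ovr,ovo data frames from [select_subtype_markers()].
#' @param housekeeping character vector of housekeeping ids.
#' @return a `marker_panel`: `entries` data frame (`mirna_id, tier,
#'   source_contrast, direction`) plus tier counts.
#' @export
assemble_panel <- function(ovr, ovo, housekeeping) {
  entries <- rbind(
    data.frame(mirna_id = ovr$mirna_id, tier = "ovr",
               source_contrast = ovr$source_contrast,
               direction = ovr$direction, stringsAsFactors = FALSE),
    data.frame(mirna_id = ovo$mirna_id, tier = "ovo",
               source_contrast = ovo$source_contrast,
               direction = ovo$direction, stringsAsFactors = FALSE),
    data.frame(mirna_id = housekeeping, tier = "housekeeping",
               source_contrast = NA_character_, direction = NA_character_,
               stringsAsFactors = FALSE)
  )
  if (anyDuplicated(entries$mirna_id))
    stop("panel tiers overlap: ",
         paste(unique(entries$mirna_id[duplicated(entries$mirna_id)]),
               collapse = ", "))
  structure(list(
    entries = entries,
    counts = c(ovr = nrow(ovr), ovo = nrow(ovo),
               housekeeping = length(housekeeping), total = nrow(entries))
  ), class = "marker_panel")
}

#' Extract the ids of one panel tier
#' @param panel a `marker_panel`.
#' @param tier `"ovr"`, `"ovo"` or `"housekeeping"`.
#' @export
panel_tier <- function(panel, tier) {
  panel$entries$mirna_id[panel$entries$tier == tier]
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", x$counts["total"], "miRNAs (",
      x$counts["ovr"], "one-vs-rest,", x$counts["ovo"], "one-vs-one,",
      x$counts["housekeeping"], "housekeeping )\n")
  invisible(x)
}

#' Build the full marker panel from a normalized discovery matrix
#'
#' Runs the five one-vs-rest contrasts, the ten one-vs-one contrasts
#' (unordered pairs in alphabetical order, "up" meaning higher in the
#' first class), selects 3 up + 3 down markers per contrast with
#' next-best substitution for collisions, and adds the `n_housekeeping`
#' lowest-variance non-marker miRNAs.
#'
#' @param x normalized discovery `expr_matrix` or matrix.
#' @param labels diagnostic class per sample.
#' @param k_up,k_down markers per direction per contrast.
#' @param n_housekeeping housekeeping tier size.
#' @return list with `panel` (a `marker_panel`) and `stats` (the combined
#'   `diff_stats` of all contrasts).
#' @export
build_marker_panel <- function(x, labels, k_up = 3, k_down = 3,
                               n_housekeeping = 10) {
  classes <- sort(intersect(ALL_CLASSES, unique(labels)))
  ovr_stats <- do.call(rbind, lapply(classes, function(cl)
    ttest_contrast(x, labels, cl)))
  pairs <- combn(classes, 2, simplify = FALSE)
  ovo_stats <- do.call(rbind, lapply(pairs, function(pr)
    ttest_contrast(x, labels, pr)))
  ovr <- select_subtype_markers(ovr_stats, k_up, k_down)
  ovo <- select_subtype_markers(ovo_stats, k_up, k_down,
                                exclude = ovr$mirna_id)
  hk <- select_housekeeping(x, n_housekeeping,
                            exclude = c(ovr$mirna_id, ovo$mirna_id))
  stats <- rbind(ovr_stats, ovo_stats)
  class(stats) <- c("diff_stats", "data.frame")
  list(panel = assemble_panel(ovr, ovo, hk), stats = stats)
}

#' Cross-cohort trend validation of candidate markers
#'
#' A candidate marker is concordant iff the sign of its mean difference for
#' its source contrast matches between the discovery and validation
#' statistics (a zero difference in either cohort is non-concordant: strict
#' sign match).
#'
#' @param discovery_stats,validation_stats `diff_stats` tables covering all
#'   candidate markers' source contrasts.
#' @param panel a `marker_panel`.
#' @return list with `table` (per-marker flags) and `n_concordant`.
#' @export
validate_trends <- function(discovery_stats, validation_stats, panel) {
  cand <- panel$entries[panel$entries$tier != "housekeeping", ]
  key <- function(s) paste(s$mirna_id, s$contrast)
  dk <- key(discovery_stats); vk <- key(validation_stats)
  want <- paste(cand$mirna_id, cand$source_contrast)
  di <- match(want, dk); vi <- match(want, vk)
  if (anyNA(vi) || anyNA(di)) {
    miss <- cand$source_contrast[is.na(vi) | is.na(di)]
    stop("contrast(s) missing from stats for marker validation: ",
         paste(unique(miss), collapse = ", "))
  }
  dd <- discovery_stats$mean_diff[di]
  vd <- validation_stats$mean_diff[vi]
  conc <- sign(dd) != 0 & sign(dd) == sign(vd)
  tab <- data.frame(
    mirna_id = cand$mirna_id, source_contrast = cand$source_contrast,
    discovery_diff = dd, validation_diff = vd, concordant = conc,
    stringsAsFactors = FALSE
  )
  list(table = tab, n_concordant = sum(conc), n_markers = nrow(tab))
}
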