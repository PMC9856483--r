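#' Hypergeometric targeting p-value of a miRNA for a pathway
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' `k = |targets ∩ pathway|` pathway genes when drawing `|targets|` genes
#' from the target universe containing `|pathway|` successes. Quantifies how
#' specifically a miRNA's validated targets concentrate in the pathway.
#'
#' @param mirna_targets gene ids targeted by the miRNA.
#' @param pathway gene ids of the pathway (intersected with the universe).
#' @param universe all genes in the target map.
#' @return p-value in (0, 1].
#' @export
targeting_pvalue <- function(mirna_targets, pathway, universe) {
  if (!length(universe)) stop("empty gene universe")
  universe <- unique(universe)
  pathway <- intersect(unique(pathway), universe)
  mirna_targets <- intersect(unique(mirna_targets), universe)
  k <- length(intersect(mirna_targets, pathway))
  phyper(k - 1, length(pathway), length(universe) - length(pathway),
         length(mirna_targets), lower.tail = FALSE)
}

# Weighted KS running sum on vectors already in ranked (descending fold
# change) order. `weights` are the raw member weights; non-members step
# down by 1/(N - M). Returns the signed maximum deviation.
.ks_score <- function(weights, member) {
  n <- length(member)
  m <- sum(member)
  if (m == 0L || m == n) return(0)
  w <- weights
  tot <- sum(w[member])
  if (!is.finite(tot) || tot <= 0) { # degenerate all-zero weights: fall back to unit
    w[] <- 1
    tot <- m
  }
  step <- ifelse(member, w / tot, -1 / (n - m))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Weighted Kolmogorov-Smirnov-like pathway regulation score
#'
#' GSEA-style running sum over the miRNA list ranked by descending log2
#' fold change: each pathway-member miRNA (one with at least one validated
#' target in the pathway) increments the sum by its weight
#' `(|log2FC| * (-log10 targeting-p))^weight_exponent` normalized to the
#' member total; each non-member decrements by `1/(N - N_members)`. The
#' score is the signed maximum deviation, bounded in [-1, 1]. With
#' `weight_exponent = 0` this reduces to the classical unweighted statistic.
#'
#' @param log2fc per-miRNA log2 fold change (ranking metric).
#' @param member logical, pathway membership per miRNA.
#' @param targeting_p per-miRNA targeting p-value for this pathway (only
#'   member entries are used; default 0.1 gives unit -log10 weight).
#' @param weight_exponent exponent on the combined weight.
#' @return scalar enrichment score.
#' @export
pathway_score <- function(log2fc, member, targeting_p = NULL,
                          weight_exponent = 1) {
  stopifnot(length(member) == length(log2fc))
  if (is.null(targeting_p)) targeting_p <- rep(0.1, length(log2fc))
  o <- order(log2fc, decreasing = TRUE)
  w <- if (weight_exponent == 0) rep(1, length(log2fc))
       else (abs(log2fc[o]) * (-log10(targeting_p[o])))^weight_exponent
  .ks_score(w, member[o])
}

#' Permutation significance of pathway scores
#'
#' Permutes miRNA identities over the ranked list (severing the link
#' between fold-change rank and pathway membership/targeting strength),
#' recomputes every pathway's score per permutation, and reports
#' sign-matched permutation p-values `(1 + #{null beats observed}) /
#' (1 + #{null of matching sign})` together with the pooled null used for
#' FDR control.
#'
#' @param observed named vector of observed pathway scores.
#' @param log2fc per-miRNA log2 fold change (any order; ranked internally).
#' @param member miRNAs x pathways logical membership matrix.
#' @param targeting_p miRNAs x pathways targeting p-value matrix.
#' @param n_permutations number of permutations (>= 100).
#' @param weight_exponent exponent passed to the score.
#' @param seed integer seed.
#' @return list: `p_values` (named), `null` (n_permutations x pathways
#'   matrix).
#' @export
permutation_test <- function(observed, log2fc, member, targeting_p,
                             n_permutations = 10000, weight_exponent = 1,
                             seed = 1) {
  if (n_permutations < 100) stop("use at least 100 permutations")
  stopifnot(nrow(member) == length(log2fc),
            ncol(member) == length(observed))
  set.seed(as.integer(seed))
  o <- order(log2fc, decreasing = TRUE)
  fc_ranked <- log2fc[o]
  absfc <- abs(fc_ranked)
  member <- member[o, , drop = FALSE]
  targeting_p <- targeting_p[o, , drop = FALSE]
  n <- length(fc_ranked); P <- ncol(member)
  null <- matrix(NA_real_, n_permutations, P,
                 dimnames = list(NULL, colnames(member)))
  for (b in seq_len(n_permutations)) {
    pi <- sample.int(n)
    for (p in seq_len(P)) {
      w <- if (weight_exponent == 0) rep(1, n)
           else (absfc * (-log10(targeting_p[pi, p])))^weight_exponent
      null[b, p] <- .ks_score(w, member[pi, p])
    }
  }
  pv <- vapply(seq_len(P), function(p) {
    s <- observed[p]
    nl <- null[, p]
    if (s >= 0) (1 + sum(nl >= s & nl >= 0)) / (1 + sum(nl >= 0))
    else (1 + sum(nl <= s & nl < 0)) / (1 + sum(nl < 0))
  }, numeric(1))
  list(p_values = setNames(pv, names(observed)), null = null)
}

#' Pooled-null FDR q-values for enrichment scores
#'
#' GSEA-style false-discovery control: for an observed score `s`, q is the
#' fraction of the pooled (all-pathway) null at least as extreme as `s`
#' divided by the fraction of observed scores at least as extreme, computed
#' separately per sign, clipped to [0, 1] and made monotone (a stronger
#' score never has a larger q).
#'
#' @param observed named vector of observed scores.
#' @param null pooled null scores (vector or matrix).
#' @return named numeric q-values.
#' @export
fdr_correct <- function(observed, null) {
  if (!length(null)) stop("pooled null distribution is empty")
  null <- as.vector(null)
  q <- rep(NA_real_, length(observed))
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(observed >= 0) else which(observed < 0)
    if (!length(idx)) next
    obs <- observed[idx]
    nl <- if (sgn > 0) null[null >= 0] else null[null < 0]
    raw <- vapply(obs, function(s) {
      fn <- if (length(nl)) {
        if (sgn > 0) mean(nl >= s) else mean(nl <= s)
      } else 0
      fo <- if (sgn > 0) mean(obs >= s) else mean(obs <= s)
      min(1, fn / fo)
    }, numeric(1))
    # monotone: a stronger score takes the running minimum of raw q over
    # weaker-or-equal scores (BH-style enforcement)
    ord <- order(sgn * obs) # weakest first
    raw[ord] <- cummin(raw[ord])
    q[idx] <- raw
  }
  setNames(q, names(observed))
}

#' miRNA set enrichment analysis (miRSEA)
#'
#' Links differential miRNA expression to pathway regulation: pathways
#' targeted by fewer than `size_filter[1]` or more than `size_filter[2]`
#' miRNAs are ignored; each retained pathway gets a hypergeometric
#' targeting p-value per member miRNA, a weighted KS-like score over the
#' fold-change-ranked miRNA list, a sign-matched permutation p-value, and a
#' pooled-null FDR q-value; results are tagged by pathway source
#' (KEGG/REACTOME/PID/BIOCARTA prefix).
#'
#' @param diff_stats a `diff_stats` table for a single contrast (typically
#'   lymphoma vs reactive); `mean_diff` is the ranking log2 fold change.
#' @param target_map data frame `mirna_id, gene_id` of strong-evidence
#'   interactions.
#' @param pathways named list of gene-id vectors.
#' @param size_filter inclusive (min, max) number of targeting miRNAs.
#' @param n_permutations permutations for significance.
#' @param weight_exponent exponent on the member weight.
#' @param seed integer seed.
#' @return an `enrichment_result` data frame: `pathway, source, n_mirnas,
#'   score, p_value, q_value`, sorted by q then p.
#' @export
run_mirsea <- function(diff_stats, target_map, pathways,
                       size_filter = c(10, 500), n_permutations = 10000,
                       weight_exponent = 1, seed = 1) {
  if (length(unique(diff_stats$contrast)) > 1)
    stop("`diff_stats` must cover a single contrast")
  if (anyDuplicated(diff_stats$mirna_id)) stop("duplicate miRNA ids")
  fc <- setNames(diff_stats$mean_diff, diff_stats$mirna_id)
  universe <- unique(target_map$gene_id)
  targets <- split(target_map$gene_id, target_map$mirna_id)
  targets <- lapply(targets[intersect(names(fc), names(targets))], unique)

  mirnas <- names(fc)
  n_targets <- setNames(integer(length(mirnas)), mirnas)
  n_targets[names(targets)] <- lengths(targets)
  psets <- lapply(pathways, function(g) intersect(unique(g), universe))
  overlap <- vapply(psets, function(ps)
    vapply(mirnas, function(m) {
      tg <- targets[[m]]
      if (is.null(tg)) 0L else length(intersect(tg, ps))
    }, integer(1)), integer(length(mirnas)))
  member <- overlap >= 1L
  n_targeting <- colSums(member)
  keep <- n_targeting >= size_filter[1] & n_targeting <= size_filter[2]
  if (!any(keep)) {
    warning("no pathway passes the size filter")
    return(structure(data.frame(pathway = character(0), source = character(0),
                                n_mirnas = integer(0), score = numeric(0),
                                p_value = numeric(0), q_value = numeric(0)),
                     class = c("enrichment_result", "data.frame")))
  }
  member <- member[, keep, drop = FALSE]
  overlap <- overlap[, keep, drop = FALSE]
  psets <- psets[keep]

  U <- length(universe)
  tp <- vapply(seq_along(psets), function(p) {
    K <- length(psets[[p]])
    phyper(overlap[, p] - 1, K, U - K, n_targets, lower.tail = FALSE)
  }, numeric(length(mirnas)))
  dimnames(tp) <- dimnames(member)

  observed <- vapply(seq_along(psets), function(p)
    pathway_score(fc, member[, p], tp[, p], weight_exponent), numeric(1))
  names(observed) <- names(psets)

  perm <- permutation_test(observed, fc, member, tp,
                           n_permutations = n_permutations,
                           weight_exponent = weight_exponent, seed = seed)
  qv <- fdr_correct(observed, perm$null)

  out <- data.frame(
    pathway = names(psets),
    source = sub("_.*$", "", names(psets)),
    n_mirnas = unname(colSums(member)),
    score = unname(observed),
    p_value = unname(perm$p_values),
    q_value = unname(qv),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q_value, out$p_value, -abs(out$score)), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
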