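# Exhaustive-draw oracle for the upper-tail hypergeometric probability.
enum_hyper <- function(universe, pathway, n_draw, k_min) {
  draws <- combn(universe, n_draw, simplify = FALSE)
  mean(vapply(draws, function(d) sum(d %in% pathway) >= k_min, logical(1)))
}

# Step-by-step unweighted running-sum oracle (classical KS/GSEA statistic).
enum_unweighted_es <- function(member) {
  n <- length(member); m <- sum(member)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (member[i]) 1 / m else -1 / (n - m)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

test_that("hypergeometric targeting p matches exhaustive enumeration", {
  u <- paste0("g", 1:10)
  expect_equal(targeting_pvalue(u[1:3], u[1:5], u), 10 / 120, tolerance = 1e-12)
  expect_equal(targeting_pvalue(u[1:3], u[1:5], u),
               enum_hyper(u, u[1:5], 3, 3), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:8) {
    U <- sample(6:12, 1)
    u <- paste0("g", seq_len(U))
    pw <- sample(u, sample(2:(U - 1), 1))
    tg <- sample(u, sample(2:(U - 1), 1))
    k <- length(intersect(tg, pw))
    expect_equal(targeting_pvalue(tg, pw, u),
                 enum_hyper(u, pw, length(tg), k), tolerance = 1e-12)
  }

  expect_equal(targeting_pvalue(character(0), u[1:5], u), 1)
  expect_equal(targeting_pvalue(u, u[1:5], u), 1)
  expect_error(targeting_pvalue(u[1:2], u[1:3], character(0)), "empty")
})

test_that("running-sum score: extremes and reduction to the classical statistic", {
  fc <- c(5, 4, 3, 2, 1)
  member <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(pathway_score(fc, member), 1.0)

  set.seed(4)
  for (i in 1:5) {
    fc <- rnorm(10)
    member <- runif(10) < 0.4
    if (!any(member) || all(member)) next
    o <- order(fc, decreasing = TRUE)
    expect_equal(pathway_score(fc, member, weight_exponent = 0),
                 enum_unweighted_es(member[o]), tolerance = 1e-12)
  }
  # |score| bounded by 1
  set.seed(5)
  for (i in 1:10) {
    fc <- rnorm(30); member <- runif(30) < 0.3
    tp <- 10^-runif(30, 0, 3)
    expect_lte(abs(pathway_score(fc, member, tp)), 1)
  }
})

test_that("uniformly interleaved members score within their permutation null", {
  fc <- seq(100, 1, by = -1)
  member <- rep(c(TRUE, FALSE, FALSE, FALSE), 25)
  obs <- pathway_score(fc, member)
  pt <- permutation_test(setNames(obs, "pw"), fc,
                         matrix(member, ncol = 1, dimnames = list(NULL, "pw")),
                         matrix(0.1, 100, 1, dimnames = list(NULL, "pw")),
                         n_permutations = 400, seed = 8)
  expect_lt(abs(obs), quantile(abs(pt$null[, 1]), 0.95))
})

test_that("permutation p-values follow the sign-matched counting formula", {
  set.seed(10)
  fc <- rnorm(40); names(fc) <- paste0("m", 1:40)
  member <- matrix(runif(80) < 0.3, 40, 2,
                   dimnames = list(names(fc), c("a", "b")))
  tp <- matrix(0.05, 40, 2, dimnames = dimnames(member))
  obs <- c(a = pathway_score(fc, member[, 1], tp[, 1]),
           b = pathway_score(fc, member[, 2], tp[, 2]))
  pt <- permutation_test(obs, fc, member, tp, n_permutations = 200, seed = 3)
  for (j in 1:2) {
    s <- obs[j]; nl <- pt$null[, j]
    expected <- if (s >= 0) (1 + sum(nl >= s & nl >= 0)) / (1 + sum(nl >= 0))
                else (1 + sum(nl <= s & nl < 0)) / (1 + sum(nl < 0))
    expect_equal(unname(pt$p_values[j]), expected)
  }
  # determinism
  pt2 <- permutation_test(obs, fc, member, tp, n_permutations = 200, seed = 3)
  expect_identical(pt$null, pt2$null)
  expect_error(permutation_test(obs, fc, member, tp, n_permutations = 50),
               "at least 100")
})

test_that("null fixture yields uniform permutation p-values", {
  set.seed(11)
  N <- 120; P <- 200
  fc <- rnorm(N); names(fc) <- sprintf("m%03d", seq_len(N))
  member <- matrix(runif(N * P) < 0.15, N, P,
                   dimnames = list(names(fc), sprintf("pw%03d", seq_len(P))))
  tp <- matrix(10^-runif(N * P, 0.1, 2), N, P, dimnames = dimnames(member))
  obs <- vapply(seq_len(P), function(p)
    pathway_score(fc, member[, p], tp[, p]), numeric(1))
  names(obs) <- colnames(member)
  pt <- permutation_test(obs, fc, member, tp, n_permutations = 400, seed = 3)
  ks <- suppressWarnings(stats::ks.test(pt$p_values, "punif"))
  expect_gt(ks$p.value, 0.01)
  # empirical type-I error at the nominal 5% level
  expect_lt(abs(mean(pt$p_values < 0.05) - 0.05), 0.04)
})

test_that("pooled-null FDR: null scores get q near 1, planted signal q < 0.01", {
  set.seed(12)
  null_scores <- rnorm(2000, 0, 0.3)
  obs <- setNames(sample(null_scores, 40), paste0("pw", 1:40))
  q <- fdr_correct(obs, null_scores)
  expect_true(all(q >= 0 & q <= 1))
  expect_gt(median(q), 0.5)

  obs2 <- c(obs, planted = 3.5)
  q2 <- fdr_correct(obs2, null_scores)
  expect_lt(q2["planted"], 0.01)
  # monotone: stronger positive score never has larger q
  pos <- sort(obs2[obs2 >= 0], decreasing = TRUE)
  expect_true(all(diff(q2[names(pos)]) >= -1e-12))
})

test_that("miRSEA applies the 10-500 targeting-miRNA size filter", {
  set.seed(13)
  n_mir <- 620
  mirnas <- sprintf("m%03d", seq_len(n_mir))
  genes <- sprintf("g%03d", seq_len(650))
  # miRNA i targets gene i (plus shared filler so the universe is common)
  target_map <- data.frame(mirna_id = mirnas,
                           gene_id = genes[seq_len(n_mir)],
                           stringsAsFactors = FALSE)
  pathways <- list(
    KEGG_SMALL = genes[1:5],      # 5 targeting miRNAs: removed
    KEGG_MID = genes[10:59],      # 50 targeting miRNAs: retained
    KEGG_BIG = genes[1:620]       # 620 targeting miRNAs: removed
  )
  ds <- data.frame(mirna_id = mirnas, contrast = "LYM_vs_RL",
                   mean_diff = rnorm(n_mir), t = 0, p_value = 0.5,
                   direction = "up", stringsAsFactors = FALSE)
  res <- run_mirsea(ds, target_map, pathways, n_permutations = 100, seed = 1)
  expect_identical(res$pathway, "KEGG_MID")
  expect_equal(res$n_mirnas, 50)
  expect_identical(res$source, "KEGG")

  res2 <- run_mirsea(ds, target_map, pathways, n_permutations = 100, seed = 1)
  expect_identical(res, res2)

  expect_warning(
    empty <- run_mirsea(ds, target_map, pathways["KEGG_SMALL"],
                        n_permutations = 100, seed = 1),
    "size filter")
  expect_equal(nrow(empty), 0)
})

test_that("planted enrichment in simulated resources is recovered at q < 0.01", {
  d <- default_discovery()
  res <- simulate_pathway_resources(d$sim$truth, n_pathways = 40, seed = 21)
  lab <- ifelse(d$labels == "RL", "RL", "LYM")
  ds <- ttest_contrast(d$norm, lab, c("LYM", "RL"))
  enr <- run_mirsea(ds, res$target_map, res$pathways,
                    n_permutations = 500, seed = 2)
  planted <- grep("PLANTED", enr$pathway, value = TRUE)
  expect_length(planted, 5)
  called <- enr$pathway[enr$q_value < 0.01 & enr$score > 0]
  expect_setequal(called, planted)
})
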