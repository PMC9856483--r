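test_that("detection filter keeps the >10% boundary and matches a recount", {
  vals <- matrix(rnorm(10 * 3), 10, 3,
                 dimnames = list(paste0("s", 1:10), paste0("m", 1:3)))
  mask <- matrix(TRUE, 10, 3, dimnames = dimnames(vals))
  mask[1, 2] <- FALSE            # 1/10 undetected: retained (not >10%)
  mask[1:2, 3] <- FALSE          # 2/10 undetected: removed
  em <- mk_em(vals, mask)
  out <- filter_detection(em)
  expect_identical(colnames(out$values), c("m1", "m2"))

  q <- small_quantified()
  f <- filter_detection(q$matrix)
  expect_equal(ncol(f$values), sum(colMeans(!q$matrix$mask) <= 0.10))
  mask[] <- FALSE
  expect_error(filter_detection(mk_em(vals, mask)), "detection filter")
})

test_that("global-mean normalization removes per-sample means and is idempotent", {
  m <- matrix(c(4, 6, 1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  out <- global_mean_normalize(m)
  expect_equal(unname(out["a", ]), c(-1, 1))
  expect_lt(max(abs(rowMeans(out))), 1e-9)
  expect_equal(global_mean_normalize(out), out, tolerance = 1e-12)

  set.seed(8)
  r <- matrix(rnorm(20 * 50), 20, 50)
  colnames(r) <- paste0("m", 1:50); rownames(r) <- paste0("s", 1:20)
  expect_equal(global_mean_normalize(r), r - rowMeans(r) %o% rep(1, 50),
               ignore_attr = TRUE)
  expect_error(global_mean_normalize(r[, 1, drop = FALSE]), ">= 2")
})

test_that("Z-score standardization gives mean 0, sd 1 per miRNA (n-1 form)", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "m1"))
  out <- zscore_standardize(m)
  expect_equal(unname(out[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(9)
  r <- matrix(rnorm(30 * 40, sd = 3), 30, 40)
  dimnames(r) <- list(paste0("s", 1:30), paste0("m", 1:40))
  z <- zscore_standardize(r)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # two-pass oracle and idempotence
  oracle <- apply(r, 2, function(v) (v - mean(v)) / sd(v))
  expect_equal(unclass(z), oracle, ignore_attr = TRUE)
  expect_equal(unclass(zscore_standardize(z)), unclass(z), tolerance = 1e-9,
               ignore_attr = TRUE)

  r[, 5] <- 2
  expect_error(zscore_standardize(r), "m5")
})

test_that("housekeeping normalization subtracts the housekeeping mean", {
  set.seed(10)
  m <- matrix(rnorm(6 * 5), 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("m", 1:5)))
  out <- housekeeping_normalize(m, c("m2", "m4"))
  expect_equal(out, m - rowMeans(m[, c("m2", "m4")]) %o% rep(1, 5),
               ignore_attr = TRUE)
  # housekeeping set = all miRNAs coincides with global-mean normalization
  expect_equal(housekeeping_normalize(m, colnames(m)),
               global_mean_normalize(m))
  expect_error(housekeeping_normalize(m, "m9"), "m9")
})

test_that("ComBat with a single batch is the identity transform", {
  set.seed(11)
  m <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("m", 1:8)))
  out <- combat_correct(m, rep("A", 12))
  expect_identical(out$matrix, m)
})

test_that("ComBat is near-identity when batches share a distribution", {
  s <- simulate_cohort(sim_config(
    cohorts = "validation",
    n_samples_per_class = list(
      validation = c(SLL = 30, FL = 50, MCL = 30, MZL = 50, RL = 40)),
    batch_shift_sd = 0, batch_scale_sd = 0, seed = 17))
  q <- quantify_plates(s$plates)
  v <- global_mean_normalize(filter_detection(q$matrix))$values
  ann <- s$annotation[match(rownames(v), s$annotation$sample_id), ]
  out <- combat_correct(v, ann$collection_site,
                        ann[, c("class", "tissue_site")])$matrix
  # the empirical-Bayes scale adjustment has a sampling-noise floor of
  # about sd * sqrt(2 / n_batch), so the typical (median) change is
  # bounded rather than every single value
  d <- abs(out - v)
  expect_lt(median(d), 0.05)
  expect_lt(quantile(d, 0.95), 0.15)
})

test_that("ComBat recovers planted site shifts and protects class effects", {
  s <- simulate_cohort(sim_config(
    cohorts = "validation",
    n_samples_per_class = list(
      validation = c(SLL = 30, FL = 50, MCL = 30, MZL = 50, RL = 40)),
    seed = 9))
  q <- quantify_plates(s$plates)
  v <- global_mean_normalize(filter_detection(q$matrix))$values
  ann <- s$annotation[match(rownames(v), s$annotation$sample_id), ]
  out <- combat_correct(v, ann$collection_site,
                        ann[, c("class", "tissue_site")])$matrix

  null_mir <- setdiff(colnames(out), s$truth$true_markers$mirna_id)
  mod <- model.matrix(~ class + tissue_site, ann)
  resid_of <- function(m) m - mod %*% qr.coef(qr(mod), m)
  r_pre <- resid_of(v[, null_mir]); r_post <- resid_of(out[, null_mir])
  sds <- apply(r_post, 2, sd)
  site_dev <- function(r) vapply(unique(ann$collection_site), function(st)
    mean(abs(colMeans(r[ann$collection_site == st, ]) / sds)), numeric(1))
  expect_gt(mean(site_dev(r_pre)), 0.2)   # planted shifts are visible before
  expect_lt(mean(site_dev(r_post)), 0.05) # and removed after

  tm <- s$truth$true_markers
  tm <- tm[tm$mirna_id %in% colnames(out), ]
  eff <- function(m) mapply(function(mir, cl)
    mean(m[ann$class == cl, mir]) - mean(m[ann$class != cl, mir]),
    tm$mirna_id, tm$contrast)
  rel <- abs(eff(out) - eff(v)) / abs(eff(v))
  expect_lt(mean(rel), 0.10)
})

test_that("ComBat rejects degenerate batch/covariate designs", {
  set.seed(12)
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:6)))
  expect_error(combat_correct(m, c(rep("A", 9), "B")), ">= 2 samples")
  confounded <- data.frame(grp = rep(c("x", "y"), each = 5))
  expect_error(combat_correct(m, rep(c("A", "B"), each = 5), confounded),
               "rank-deficient")
})

test_that("batch F-tests on corrected null miRNAs reject at or below nominal rate", {
  set.seed(30)
  n <- 90
  batch <- rep(c("A", "B", "C"), each = 30)
  cls <- rep(rep(c("RL", "FL", "MCL"), times = 10), 3)
  shift <- c(A = -0.8, B = 0, C = 0.8)
  m <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:100)))
  m <- m + shift[batch]
  out <- combat_correct(m, batch, data.frame(class = cls))$matrix
  pvals <- apply(out, 2, function(v)
    anova(lm(v ~ cls + batch))["batch", "Pr(>F)"])
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("cohort merging aligns by id, removes cohort shift, keeps tissue feature", {
  s <- small_sim()
  ann <- s$annotation
  q_all <- quantify_plates(s$plates)
  disc <- rownames(q_all$matrix$values) %in%
    ann$sample_id[ann$cohort == "discovery"]
  em_d <- q_all$matrix; em_v <- q_all$matrix
  em_d$values <- em_d$values[disc, ]; em_d$mask <- em_d$mask[disc, ]
  em_v$values <- em_v$values[!disc, ]; em_v$mask <- em_v$mask[!disc, ]
  em_d <- filter_detection(em_d)

  norm <- zscore_standardize(global_mean_normalize(em_d))
  labels <- ann$class[match(rownames(norm$values), ann$sample_id)]
  pb <- build_marker_panel(norm, labels, k_up = 2, k_down = 2,
                           n_housekeeping = 5)

  # scramble validation column order: merging must align by miRNA id
  em_v_scr <- em_v
  set.seed(77)
  perm <- sample(ncol(em_v$values))
  em_v_scr$values <- em_v_scr$values[, perm]; em_v_scr$mask <- em_v_scr$mask[, perm]
  ft1 <- merge_cohorts(em_d, em_v, ann, pb$panel)
  ft2 <- merge_cohorts(em_d, em_v_scr, ann, pb$panel)
  expect_equal(ft1$x, ft2$x[, colnames(ft1$x)])
  expect_true(all(ft1$x[, "tissue_site"] %in% c(0, 1)))

  # the simulated per-miRNA cohort shift is corrected in the merged matrix
  coh <- ft1$annotation$cohort
  cand <- setdiff(colnames(ft1$x), "tissue_site")
  null_cand <- setdiff(cand, s$truth$true_markers$mirna_id)
  gap <- colMeans(ft1$x[coh == "discovery", null_cand]) -
    colMeans(ft1$x[coh == "validation", null_cand])
  sds <- apply(ft1$x[, null_cand], 2, sd)
  expect_lt(mean(abs(gap / sds)), 0.10)
})
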