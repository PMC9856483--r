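# Memoised fixtures: simulations are deterministic, so each is built once
# per test run and shared across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small two-cohort simulation for module-level tests.
small_sim <- function() fixture("small_sim", simulate_cohort(sim_config(
  n_mirnas = 90,
  n_samples_per_class = list(
    discovery  = c(SLL = 8, FL = 8, MCL = 8, MZL = 8, RL = 8),
    validation = c(SLL = 8, FL = 10, MCL = 8, MZL = 10, RL = 10)),
  n_markers_per_class = 4, dropout_fraction = 0.1, seed = 101
)))

small_quantified <- function() fixture("small_quantified", {
  s <- small_sim()
  ids <- s$annotation$sample_id[s$annotation$cohort == "discovery"]
  keep <- s$plates$well_role %in% c("standard", "ntc") |
    s$plates$sample_id %in% ids
  quantify_plates(s$plates[keep, ])
})

# Default-scale discovery cohort (the study conditions): 100 samples,
# 360 miRNAs, used by the panel worked-example checks.
default_discovery <- function() fixture("default_discovery", {
  s <- simulate_cohort(sim_config(cohorts = "discovery", seed = 1))
  q <- quantify_plates(s$plates)
  em <- filter_detection(q$matrix)
  norm <- zscore_standardize(global_mean_normalize(em))
  labels <- s$annotation$class[match(rownames(norm$values),
                                     s$annotation$sample_id)]
  list(sim = s, quant = q, em = em, norm = norm, labels = labels)
})

default_panel <- function() fixture("default_panel", {
  d <- default_discovery()
  build_marker_panel(d$norm, d$labels)
})

# Hand-built plate set: standards on a perfect-efficiency curve
# (intercept 40), two NTCs at 38/39, three samples with spike-ins.
hand_plates <- function(sample_cts = list(A = c(30, 30), B = c(31, 31),
                                          C = c(29, 29)),
                        spike_shift = c(A = 0, B = 0.5, C = -0.2)) {
  std <- data.frame(
    plate_id = "P1", well_role = "standard", sample_id = NA_character_,
    mirna_id = "miR-X", replicate = 1L,
    ct = 40 - log2(10) * (1:6), known_copies = 10^(1:6),
    stringsAsFactors = FALSE)
  ntc <- data.frame(
    plate_id = "P1", well_role = "ntc", sample_id = NA_character_,
    mirna_id = NA_character_, replicate = 1:2, ct = c(38, 39),
    known_copies = NA_real_, stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(names(sample_cts), function(s) data.frame(
    plate_id = "P1", well_role = "sample", sample_id = s,
    mirna_id = "miR-X", replicate = seq_along(sample_cts[[s]]),
    ct = sample_cts[[s]], known_copies = NA_real_,
    stringsAsFactors = FALSE)))
  sp <- do.call(rbind, lapply(names(spike_shift), function(s) data.frame(
    plate_id = "P1", well_role = "spike", sample_id = s,
    mirna_id = paste0("spike-", 1:3), replicate = 1L,
    ct = c(21, 23, 25) + spike_shift[[s]], known_copies = NA_real_,
    stringsAsFactors = FALSE)))
  out <- rbind(std, ntc, sm, sp)
  class(out) <- c("plate_set", "data.frame")
  out
}

# Bare expression matrix container for normalization fixtures.
mk_em <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values),
                                    dimnames = dimnames(values))
  structure(list(values = values, mask = mask,
                 qc = data.frame()), class = "expr_matrix")
}
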