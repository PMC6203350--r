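test_that("generation is bit-reproducible from the seed", {
  cfg <- sim_config(seed = 17)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$metabolites$values, b$metabolites$values)
  expect_identical(a$transcripts$values, b$transcripts$values)
  expect_identical(a$design, b$design)
  expect_identical(a$truth, b$truth)
  c2 <- generate_synthetic(sim_config(seed = 18))
  expect_false(identical(a$metabolites$values, c2$metabolites$values))
})

test_that("the emitted design matches the targeted sampling structure", {
  d <- generate_synthetic(sim_config(seed = 2))
  counts <- table(d$design$condition)
  expect_equal(unname(counts[["control"]]), 12)
  expect_equal(unname(counts[["treatment"]]), 11)
  # transcriptome samples are a nested 8 + 8 subset of the metabolome set
  expect_equal(ncol(d$transcripts$values), 16L)
  expect_true(all(d$transcripts$sample_ids %in% d$metabolites$sample_ids))
  tr_cond <- d$design$condition[match(d$transcripts$sample_ids,
                                      d$design$sample_id)]
  expect_equal(as.vector(table(tr_cond)), c(8L, 8L))
  # planted members exist in the metabolite matrix, nulls are null
  expect_true(all(unlist(d$truth$planted[, c("A", "B", "C")]) %in%
                    d$metabolites$feature_id))
  expect_true(all(d$truth$null_features %in% d$metabolites$feature_id))
})

test_that("transcripts are FPKM-like: non-negative with measured zeros", {
  d <- generate_synthetic(sim_config(seed = 5))
  expect_true(all(d$transcripts$values >= 0))
  expect_gt(sum(d$transcripts$values == 0), 0)
  expect_false(anyNA(d$transcripts$values))
})

test_that("masking never removes every observation of a feature", {
  d <- generate_synthetic(sim_config(missing_rate = 0.9, seed = 9))
  expect_true(all(rowSums(!is.na(d$metabolites$values)) >= 1))
  clean <- generate_synthetic(sim_config(missing_rate = 0, seed = 9))
  expect_false(anyNA(clean$metabolites$values))
})

test_that("planted slopes are recoverable by per-condition regression", {
  # essentially noiseless: estimates equal configured slopes
  cfg <- sim_config(planted_forks = data.frame(slope_control = 1.5,
                                               slope_treatment = -0.5,
                                               noise_sd = 1e-9),
                    missing_rate = 0, seed = 23)
  d <- generate_synthetic(cfg)
  met <- log_transform(impute_min(d$metabolites))
  tp <- d$truth$planted
  cond <- d$design$condition[match(met$sample_ids, d$design$sample_id)]
  ratio <- met$values[tp$B, ] - met$values[tp$C, ]
  a <- met$values[tp$A, ]
  for (lev in c("control", "treatment")) {
    sl <- coef(lm(a[cond == lev] ~ ratio[cond == lev]))[2]
    want <- if (lev == "control") 1.5 else -0.5
    expect_equal(unname(sl), want, tolerance = 1e-6)
  }

  # with noise: estimate within 3 standard errors in nearly all runs
  hits <- 0L
  for (seed in 1:60) {
    cfgn <- sim_config(missing_rate = 0, seed = 1000 + seed)
    dn <- generate_synthetic(cfgn)
    mn <- log_transform(impute_min(dn$metabolites))
    tp <- dn$truth$planted
    cond <- dn$design$condition[match(mn$sample_ids, dn$design$sample_id)]
    r <- mn$values[tp$B, ] - mn$values[tp$C, ]
    av <- mn$values[tp$A, ]
    ok <- TRUE
    for (lev in c("control", "treatment")) {
      f <- summary(lm(av[cond == lev] ~ r[cond == lev]))$coefficients
      want <- if (lev == "control") tp$slope_control else tp$slope_treatment
      ok <- ok && abs(f[2, 1] - want) <= 3 * f[2, 2]
    }
    hits <- hits + ok
  }
  expect_gte(hits / 60, 0.9)
})

test_that("an equal-slope (null) fork shows a near-zero screening delta", {
  deltas <- vapply(generate_null_battery(sim_config(n_null_features = 0,
                                                    missing_rate = 0,
                                                    seed = 300), 30),
                   function(d) {
                     met <- log_transform(impute_min(d$metabolites))
                     tp <- d$truth$planted
                     screen_triplet(tp$A, tp$B, tp$C, met, d$design)$delta
                   }, numeric(1))
  expect_lt(stats::median(deltas), 0.2)
  expect_false(any(deltas >= 1.2))
})

test_that("null batteries derive distinct seeds and validate inputs", {
  batt <- generate_null_battery(sim_config(n_null_features = 2, seed = 40), 3)
  expect_length(batt, 3)
  sigs <- vapply(batt, function(d) d$metabolites$values[1, 1], numeric(1))
  expect_equal(length(unique(sigs)), 3L)
  # nullify replaces the treatment slope with the control slope
  expect_true(all(vapply(batt, function(d)
    d$truth$planted$slope_treatment == d$truth$planted$slope_control,
    logical(1))))
  expect_error(generate_null_battery(sim_config(), 0), "replicates")
})

test_that("null feature log-values look Gaussian", {
  d <- generate_synthetic(sim_config(n_null_features = 30, missing_rate = 0,
                                     seed = 77))
  lv <- log(d$metabolites$values[d$truth$null_features, ])
  p <- stats::shapiro.test(as.vector(lv)[1:500])$p.value
  expect_gt(p, 0.001)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(n_control = 2), "at least 3")
  expect_error(sim_config(n_transcriptome_per_group = 20), "subset")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(planted_forks = data.frame(slope_control = 1,
                                                     slope_treatment = 0,
                                                     noise_sd = 0)),
               "noise_sd")
})
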