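test_that("pearson_cor matches exact cases and the summation oracle", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_true(is.na(pearson_cor(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_cor(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("triplet enumeration yields m(m-1)(m-2)/2 ordered candidates", {
  t3 <- enumerate_triplets(c("b", "a", "c"))
  expect_equal(nrow(t3), 3L)
  expect_true(all(t3$B < t3$C))
  t4 <- enumerate_triplets(sprintf("f%d", 1:4))
  expect_equal(nrow(t4), 12L)
  t60 <- enumerate_triplets(sprintf("f%02d", 1:60))
  expect_equal(nrow(t60), 60 * choose(59, 2))   # 102,660
  expect_equal(nrow(t60), 102660L)
  # deterministic lexicographic order
  expect_identical(t60, t60[order(t60$A, t60$B, t60$C, method = "radix"), ],
                   ignore_attr = TRUE)
  expect_error(enumerate_triplets(c("a", "b")), "at least 3")
})

test_that("cross-omic triplets can be excluded from enumeration", {
  feats <- c("m1", "m2", "m3", "g1")
  types <- c("metabolite", "metabolite", "metabolite", "transcript")
  all_t <- enumerate_triplets(feats, types, allow_cross_omic = TRUE)
  same_t <- enumerate_triplets(feats, types, allow_cross_omic = FALSE)
  expect_equal(nrow(all_t), 12L)
  expect_equal(nrow(same_t), 3L)
  expect_true(all(unlist(same_t) %in% c("m1", "m2", "m3")))
})

test_that("the screen passes at 'threshold or greater' and records n", {
  set.seed(42)
  ds <- random_log_dataset(4, seed = 42)
  out <- screen_triplets(ds$m, ds$design)
  expect_equal(nrow(out), 12L)
  expect_true(all(out$delta >= 0 & out$delta <= 2))
  expect_true(all(out$n_control == 12L & out$n_treatment == 11L))
  expect_equal(out$delta, abs(out$cor_treatment - out$cor_control))

  # boundary semantics: a threshold equal to the observed delta passes,
  # anything above it does not
  one <- out[5, ]
  at <- screen_triplet(one$A, one$B, one$C, ds$m, ds$design,
                       screen_config(delta_threshold = one$delta))
  expect_true(at$passed)
  above <- screen_triplet(one$A, one$B, one$C, ds$m, ds$design,
                          screen_config(delta_threshold =
                                          min(2, one$delta + 1e-9)))
  expect_false(above$passed)
})

test_that("identical data in both conditions gives delta 0", {
  set.seed(9)
  half <- matrix(rnorm(36), nrow = 3)
  vals <- cbind(half, half)
  dimnames(vals) <- list(c("a", "b", "c"), sprintf("s%02d", 1:24))
  m <- log_matrix(vals)
  d <- design_for_matrix(vals, 12)
  out <- screen_triplets(m, d)
  expect_true(all(out$delta < 1e-12))
  expect_false(any(out$passed))
})

test_that("a planted fork with opposite slopes passes the 1.2 screen", {
  d <- generate_synthetic(sim_config(seed = 101))
  met <- log_transform(impute_min(d$metabolites))
  tp <- d$truth$planted
  out <- screen_triplet(tp$A, tp$B, tp$C, met, d$design)
  expect_true(out$passed)
  expect_gt(out$delta, 1.2)
  expect_gt(out$cor_control, 0)   # slope +1 under control
  expect_lt(out$cor_treatment, 0) # slope -1 under treatment
})

test_that("swapping B and C negates correlations but preserves the decision", {
  ds <- random_log_dataset(10, seed = 7)
  cand <- enumerate_triplets(ds$m$feature_id)
  set.seed(8)
  cand <- cand[sample(nrow(cand), 50), ]
  fwd <- screen_triplets(ds$m, ds$design, screen_config(delta_threshold = 0.3),
                         triplets = cand)
  swapped <- data.frame(A = cand$A, B = cand$C, C = cand$B)
  rev <- screen_triplets(ds$m, ds$design, screen_config(delta_threshold = 0.3),
                         triplets = swapped)
  expect_equal(rev$cor_control, -fwd$cor_control)
  expect_equal(rev$cor_treatment, -fwd$cor_treatment)
  expect_identical(rev$delta, fwd$delta)
  expect_identical(rev$passed, fwd$passed)
})

test_that("the screen is invariant to global rescaling and per-feature shifts", {
  ds <- random_log_dataset(6, seed = 13)
  cfg <- screen_config(delta_threshold = 0.5)
  base <- screen_triplets(ds$m, ds$design, cfg)
  # a shared scale factor (e.g. a change of log base, including sign
  # flips) and arbitrary per-feature offsets both cancel in every
  # within-condition correlation
  set.seed(14)
  for (a in c(1 / log(2), -0.7, 3.2)) {
    shifted <- ds$m
    shifted$values <- a * shifted$values + rnorm(6, 0, 5)
    out <- screen_triplets(shifted, ds$design, cfg)
    expect_equal(out$delta, base$delta, tolerance = 1e-10)
    expect_identical(out$passed, base$passed)
  }
  # rescaling the focal feature alone flips/scales nothing but the sign
  ax <- ds$m
  ax$values["f01", ] <- -2.5 * ax$values["f01", ] + 1
  out <- screen_triplets(ax, ds$design, cfg)
  focal <- out$A == "f01"
  expect_equal(out$delta[focal], base$delta[focal], tolerance = 1e-10)
  expect_equal(out$cor_control[focal], -base$cor_control[focal],
               tolerance = 1e-10)
})

test_that("covariance fast path agrees with the direct per-triplet path", {
  # force the slow path by adding NA columns via a transcript matrix
  d <- generate_synthetic(sim_config(n_null_features = 6,
                                     n_transcript_features = 3,
                                     missing_rate = 0, seed = 21))
  met <- log_transform(impute_min(d$metabolites))
  tr <- log_transform(d$transcripts)
  comb <- combine_omics(met, tr)
  out <- suppressMessages(screen_triplets(comb, d$design))
  # direct recomputation with plain cor() for a sample of rows
  set.seed(22)
  cond <- d$design$condition[match(comb$sample_ids, d$design$sample_id)]
  for (i in sample(nrow(out), 40)) {
    xa <- comb$values[out$A[i], ]; xb <- comb$values[out$B[i], ]
    xc <- comb$values[out$C[i], ]
    ok <- !is.na(xa) & !is.na(xb) & !is.na(xc)
    r_ctl <- cor(xa[ok & cond == "control"],
                 (xb - xc)[ok & cond == "control"])
    r_trt <- cor(xa[ok & cond == "treatment"],
                 (xb - xc)[ok & cond == "treatment"])
    expect_equal(out$cor_control[i], r_ctl, tolerance = 1e-12)
    expect_equal(out$cor_treatment[i], r_trt, tolerance = 1e-12)
    expect_equal(out$n_control[i] + out$n_treatment[i], sum(ok))
  }
  # cross-omic triplets use the 8+8 shared samples
  cross <- out$B %in% tr$feature_id | out$C %in% tr$feature_id |
    out$A %in% tr$feature_id
  expect_true(all(out$n_control[cross] == 8 & out$n_treatment[cross] == 8))
})

test_that("zero-variance members are skipped with a logged reason", {
  vals <- rbind(flat = rep(1, 23),
                x = rnorm(23), y = rnorm(23), z = rnorm(23))
  colnames(vals) <- sprintf("s%02d", 1:23)
  m <- log_matrix(vals)
  d <- design_for_matrix(vals, 12)
  out <- suppressMessages(screen_triplets(m, d))
  flat_rows <- out$A == "flat" | out$B == "flat" | out$C == "flat"
  expect_true(all(out$note[flat_rows & out$A == "flat"] == "zero_variance"))
  expect_false(any(out$passed[out$A == "flat"]))
  clean <- out[!flat_rows, ]
  expect_true(all(clean$note == ""))
})
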