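fork_df <- function(triplets) {
  do.call(rbind, lapply(triplets, function(tr)
    data.frame(A = tr[1], B = tr[2], C = tr[3],
               p_forward = 0.01, p_reverse = 0.02,
               stringsAsFactors = FALSE)))
}

test_that("disjoint and overlapping forks merge as expected", {
  two <- merge_forks(fork_df(list(c("A", "B", "C"), c("D", "E", "F"))))
  expect_equal(nrow(two$nodes), 6L)
  expect_equal(nrow(two$edges), 6L)
  expect_equal(length(unique(two$nodes$component)), 2L)

  shared <- merge_forks(fork_df(list(c("A", "B", "C"), c("C", "D", "E"))))
  expect_equal(nrow(shared$nodes), 5L)
  expect_equal(nrow(shared$edges), 6L)
  expect_equal(length(unique(shared$nodes$component)), 1L)
  # the shared member's edges carry both owning forks where applicable
  expect_true(all(c("fork_001", "fork_002") %in%
                    unlist(strsplit(shared$edges$fork_ids, ";"))))
})

test_that("components match a brute-force union-find oracle", {
  feats <- sprintf("n%02d", 1:20)
  for (seed in 1:50) {
    set.seed(seed)
    k <- sample(1:12, 1)
    triplets <- lapply(seq_len(k), function(i) sample(feats, 3))
    circ <- suppressWarnings(merge_forks(fork_df(triplets)))
    oracle <- unionfind_components(triplets)
    got <- split(circ$nodes$feature_id, circ$nodes$component)
    canon <- function(p) unname(lapply(p, sort))[order(vapply(p, min, ""))]
    expect_equal(canon(got), canon(oracle))
    # forks sharing a member always co-locate
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j && length(intersect(triplets[[i]], triplets[[j]])) > 0) {
        ci <- circ$nodes$component[match(triplets[[i]][1],
                                         circ$nodes$feature_id)]
        cj <- circ$nodes$component[match(triplets[[j]][1],
                                         circ$nodes$feature_id)]
        expect_equal(ci, cj)
      }
    }
  }
})

test_that("merging is order-invariant and deduplicates repeats", {
  triplets <- list(c("A", "B", "C"), c("C", "D", "E"), c("F", "G", "H"))
  a <- merge_forks(fork_df(triplets))
  b <- merge_forks(fork_df(rev(triplets)))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$forks, b$forks)

  expect_warning(dup <- merge_forks(fork_df(list(c("A", "B", "C"),
                                                 c("A", "B", "C")))),
                 "duplicate")
  expect_equal(nrow(dup$forks), 1L)
  expect_error(merge_forks(data.frame(A = "x", B = "y", C = "z",
                                      is_fork = FALSE)), "validated")
})

test_that("component count is monotone non-increasing as forks accrue", {
  set.seed(99)
  feats <- sprintf("n%02d", 1:15)
  triplets <- lapply(1:10, function(i) sample(feats, 3))
  prev <- Inf
  seen_nodes <- character(0)
  for (k in 1:10) {
    circ <- suppressWarnings(merge_forks(fork_df(triplets[1:k])))
    n_comp <- length(unique(circ$nodes$component))
    new_nodes <- setdiff(unlist(triplets[1:k]), seen_nodes)
    # adding a fork can add at most one new component
    expect_lte(n_comp, prev + 1)
    prev <- n_comp
    seen_nodes <- union(seen_nodes, new_nodes)
  }
})

test_that("pairwise annotation reproduces per-condition correlations", {
  d <- generate_synthetic(sim_config(n_null_features = 5, missing_rate = 0,
                                     seed = 55))
  met <- log_transform(impute_min(d$metabolites))
  tp <- d$truth$planted
  circ <- merge_forks(data.frame(A = tp$A, B = tp$B, C = tp$C,
                                 p_forward = 0.001, p_reverse = 0.002))
  circ <- annotate_pairwise(circ, met, d$design)
  eAB <- which((circ$edges$source == tp$A & circ$edges$target == tp$B) |
                 (circ$edges$source == tp$B & circ$edges$target == tp$A))
  # logA tracks +R under control and -R under treatment; logB carries +R
  expect_gt(circ$edges$cor_control[eAB], 0)
  expect_lt(circ$edges$cor_treatment[eAB], 0)
  cond <- d$design$condition[match(met$sample_ids, d$design$sample_id)]
  direct <- cor(met$values[tp$A, cond == "control"],
                met$values[tp$B, cond == "control"])
  expect_equal(circ$edges$cor_control[eAB], direct, tolerance = 1e-12)
})

test_that("duplicated feature rows correlate at 1 in both conditions", {
  set.seed(60)
  base <- rnorm(23)
  vals <- rbind(a = base, b = base, c = rnorm(23))
  colnames(vals) <- sprintf("s%02d", 1:23)
  m <- log_matrix(vals)
  d <- design_for_matrix(vals, 12)
  circ <- merge_forks(data.frame(A = "a", B = "b", C = "c",
                                 p_forward = 0.01, p_reverse = 0.01))
  circ <- annotate_pairwise(circ, m, d)
  eAB <- which(circ$edges$source == "a" & circ$edges$target == "b")
  expect_equal(circ$edges$cor_control[eAB], 1, tolerance = 1e-12)
  expect_equal(circ$edges$cor_treatment[eAB], 1, tolerance = 1e-12)
})

test_that("zero-variance endpoints export as explicit nulls", {
  vals <- rbind(a = rep(1, 23), b = rnorm(23), c = rnorm(23))
  colnames(vals) <- sprintf("s%02d", 1:23)
  m <- log_matrix(vals)
  d <- design_for_matrix(vals, 12)
  circ <- merge_forks(data.frame(A = "a", B = "b", C = "c",
                                 p_forward = 0.01, p_reverse = 0.01))
  circ <- annotate_pairwise(circ, m, d)
  eAB <- which(circ$edges$source == "a" & circ$edges$target == "b")
  expect_true(is.na(circ$edges$cor_control[eAB]))
  f <- tempfile(fileext = ".json")
  write_circuit(circ, f, "json")
  expect_match(paste(readLines(f), collapse = ""), "null")
  back <- read_circuit(f, "json")
  expect_true(is.na(back$edges$cor_control[eAB]))
})

test_that("regulator genes attach with their DE annotation", {
  circ <- merge_forks(fork_df(list(c("A", "B", "C"))))
  de <- data.frame(feature_id = c("geneX", "geneY"),
                   direction = c("down", "up"),
                   p_value = c(0.01, 0.2), stringsAsFactors = FALSE)
  reg <- data.frame(gene_id = "geneX", target = "A--B",
                    relation = "catalyzes", stringsAsFactors = FALSE)
  out <- attach_regulators(circ, reg, de)
  gx <- out$nodes[out$nodes$feature_id == "geneX", ]
  expect_identical(gx$node_role, "regulator")
  expect_identical(gx$de_direction, "down")
  reg_edges <- out$edges[out$edges$edge_type == "regulator", ]
  expect_setequal(reg_edges$target, c("A", "B"))
  # regulator joins the component of its target
  expect_equal(out$nodes$component[out$nodes$feature_id == "geneX"],
               out$nodes$component[out$nodes$feature_id == "A"])

  expect_identical(attach_regulators(circ, reg[0, ], de), circ)
  bad <- data.frame(gene_id = "geneX", target = "Z", relation = "r")
  expect_error(attach_regulators(circ, bad, de), "Z")
  absent <- data.frame(gene_id = "geneQ", target = "A", relation = "r")
  expect_error(attach_regulators(circ, absent, de), "geneQ")
})

test_that("component summary counts nodes and forks per component", {
  circ <- merge_forks(fork_df(list(c("A", "B", "C"), c("C", "D", "E"),
                                   c("X", "Y", "Z"))))
  s <- circuit_components(circ)
  expect_equal(nrow(s), 2L)
  expect_equal(sort(s$n_nodes), c(3L, 5L))
  expect_equal(sort(s$n_forks), c(1L, 2L))
})
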