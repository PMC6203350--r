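# Independent oracles used to cross-check the implementation. These are
# deliberately written from the defining formulas (explicit normal
# equations, summation identities, hand-rolled disjoint sets) and share
# no code with the package paths they verify.

# Pearson correlation from the raw summation formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# OLS interaction fit via explicit normal equations + Student-t CDF
ols_interaction_oracle <- function(y, x, g) {
  X <- cbind(1, x, g, x * g)
  n <- length(y)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- n - 4
  sigma2 <- sum(resid^2) / df
  covb <- sigma2 * solve(XtX)
  se <- sqrt(covb[4, 4])
  tval <- beta[4] / se
  list(coef = beta[4], se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df))
}

# Welch statistic and Welch-Satterthwaite df from the defining formulas
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  sx2 <- vx / nx; sy2 <- vy / ny
  tval <- (mean(y) - mean(x)) / sqrt(sx2 + sy2)
  df <- (sx2 + sy2)^2 / (sx2^2 / (nx - 1) + sy2^2 / (ny - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

# connected components of fork member sets by brute-force union-find
unionfind_components <- function(fork_members) {
  nodes <- sort(unique(unlist(fork_members)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  for (mem in fork_members) {
    r <- find(mem[1])
    for (b in mem[-1]) {
      rb <- find(b)
      if (rb != r) parent[[rb]] <- r
    }
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# small helper: log-scale matrix straight from a numeric matrix
log_matrix <- function(vals, omic_type = "metabolite", base = exp(1)) {
  omics_matrix(vals, omic_type = omic_type, log_scale = TRUE,
               log_base = base)
}

# two-condition design over the columns of a matrix: first n_ctl
# columns control, rest treatment
design_for_matrix <- function(vals, n_ctl) {
  n <- ncol(vals)
  sample_design(colnames(vals),
                c(rep("control", n_ctl), rep("treatment", n - n_ctl)))
}

# random log-scale dataset: nf features, 12 control + 11 treatment
random_log_dataset <- function(nf, seed, n_ctl = 12, n_trt = 11) {
  set.seed(seed)
  n <- n_ctl + n_trt
  vals <- matrix(rnorm(nf * n), nrow = nf,
                 dimnames = list(sprintf("f%02d", seq_len(nf)),
                                 sprintf("s%02d", seq_len(n))))
  list(m = log_matrix(vals), design = design_for_matrix(vals, n_ctl))
}
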