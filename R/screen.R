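#' Pearson product-moment correlation
#'
#' The screening primitive. Thin wrapper around [stats::cor()] that
#' enforces the preconditions the screen relies on (paired values,
#' enough points, non-degenerate variance) and signals degeneracy as
#' `NA` rather than an error so that callers can skip and log.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` if either input has zero
#'   variance.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed here")
  r <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(r)) return(NA_real_)
  r
}

#' Screening configuration
#'
#' @param delta_threshold minimum absolute between-condition difference
#'   in cor(A, log-ratio) for a triplet to pass (default 1.2; the
#'   admissible range is `[0, 2]` since each correlation lies in
#'   `[-1, 1]`). The rule is "threshold or greater" (`>=`).
#' @param min_samples_per_condition smallest per-condition n on which
#'   a correlation is computed (default 3).
#' @param allow_cross_omic whether triplets mixing metabolites and
#'   transcripts are enumerated (default `TRUE`); cross-omic triplets
#'   use the samples measured in both omics.
#' @return A `screen_config` list.
#' @export
screen_config <- function(delta_threshold = 1.2,
                          min_samples_per_condition = 3,
                          allow_cross_omic = TRUE) {
  if (!is.numeric(delta_threshold) || delta_threshold < 0 ||
      delta_threshold > 2)
    stop("'delta_threshold' must lie in [0, 2]")
  if (min_samples_per_condition < 3)
    stop("'min_samples_per_condition' must be >= 3")
  structure(list(delta_threshold = delta_threshold,
                 min_samples_per_condition = as.integer(min_samples_per_condition),
                 allow_cross_omic = isTRUE(allow_cross_omic)),
            class = "screen_config")
}

#' Enumerate candidate triplets
#'
#' Every triplet (A, {B, C}) of pairwise-distinct features, with the
#' ratio pair unordered: only the orientation with B < C
#' (lexicographically, C collation) is emitted, since swapping B and C
#' merely flips the sign of the log-ratio and leaves the screen's
#' delta unchanged. For m features this yields m(m-1)(m-2)/2 triplets,
#' in deterministic lexicographic (A, B, C) order.
#'
#' @param features character vector of feature ids (>= 3), or an
#'   [omics_matrix()].
#' @param omic_type optional character vector parallel to `features`,
#'   used to drop cross-omic triplets when `allow_cross_omic` is off.
#' @param allow_cross_omic see [screen_config()].
#' @return Data frame with columns `A`, `B`, `C`.
#' @export
enumerate_triplets <- function(features, omic_type = NULL,
                               allow_cross_omic = TRUE) {
  if (inherits(features, "omics_matrix")) {
    omic_type <- features$omic_type
    features <- features$feature_id
  }
  features <- as.character(features)
  if (anyDuplicated(features)) stop("feature ids must be unique")
  m <- length(features)
  if (m < 3) stop("need at least 3 features to form a triplet")
  ord <- order(features, method = "radix")
  features <- features[ord]
  if (!is.null(omic_type)) omic_type <- omic_type[ord]
  pairs <- utils::combn(m, 2)              # columns (b, c) with b < c
  k <- ncol(pairs)
  a <- rep(seq_len(m), each = k)
  b <- rep(pairs[1, ], times = m)
  cc <- rep(pairs[2, ], times = m)
  keep <- a != b & a != cc
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]
  if (!allow_cross_omic && !is.null(omic_type)) {
    same <- omic_type[a] == omic_type[b] & omic_type[a] == omic_type[cc]
    a <- a[same]; b <- b[same]; cc <- cc[same]
  }
  out <- data.frame(A = features[a], B = features[b], C = features[cc],
                    stringsAsFactors = FALSE)
  out[order(out$A, out$B, out$C, method = "radix"), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

# per-condition correlation of A with the log-ratio B - C on one
# complete sample block; returns c(cor, n) with NA cor on zero variance
.cor_block <- function(xa, xb, xc) {
  ratio <- xb - xc
  n <- length(xa)
  if (stats::sd(xa) == 0 || stats::sd(ratio) == 0)
    return(c(NA_real_, n))
  c(stats::cor(xa, ratio), n)
}

#' Screen a single triplet
#'
#' Computes the per-condition Pearson correlations of A's log values
#' with the log-ratio of B over C (log B - log C), their absolute
#' difference (the screening delta), and the pass flag at the
#' configured threshold. Samples with a missing value in any of the
#' three features (cross-omic triplets outside the shared sample set)
#' are dropped before splitting by condition.
#'
#' @param A,B,C feature ids forming the triplet.
#' @param m a log-scale [omics_matrix()].
#' @param design a [sample_design()] covering `m`'s samples.
#' @param config a [screen_config()].
#' @return One-row data frame: `A, B, C, cor_control, cor_treatment,
#'   delta, n_control, n_treatment, passed, note` (`note` records the
#'   skip reason when the triplet could not be evaluated).
#' @export
screen_triplet <- function(A, B, C, m, design, config = screen_config()) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!m$log_scale) stop("screening requires a log-transformed matrix")
  if (length(unique(c(A, B, C))) != 3)
    stop("triplet members must be pairwise distinct")
  screen_triplets(m, design, config,
                  triplets = data.frame(A = A, B = B, C = C,
                                        stringsAsFactors = FALSE))
}

#' Screen candidate triplets for condition-dependent coupling
#'
#' The differential-correlation screen: a triplet passes when
#' `|cor_treatment - cor_control| >= delta_threshold`, with each
#' correlation taken between feature A and the log-ratio B/C (computed
#' as log B - log C) within one condition. Triplets whose A or ratio
#' series is constant within a condition, or with too few usable
#' samples, are skipped with a reason in `note`.
#'
#' For fully observed features the correlations are evaluated through
#' the per-condition feature covariance matrix
#' (`cov(A, B - C) = cov(A,B) - cov(A,C)` etc.), which makes exhaustive
#' screens over tens of thousands of triplets cheap; triplets touching
#' incompletely observed features fall back to a direct per-triplet
#' computation on complete samples.
#'
#' @param m a log-scale [omics_matrix()].
#' @param design a [sample_design()].
#' @param config a [screen_config()].
#' @param triplets optional data frame (`A`, `B`, `C`) of candidates;
#'   by default all triplets from [enumerate_triplets()].
#' @return Data frame of screened triplets (see [screen_triplet()]),
#'   one row per candidate, in the input candidate order.
#' @export
screen_triplets <- function(m, design, config = screen_config(),
                            triplets = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!m$log_scale) stop("screening requires a log-transformed matrix")
  cond <- design_for(m, design)
  if (is.null(triplets))
    triplets <- enumerate_triplets(m$feature_id, m$omic_type,
                                   allow_cross_omic = config$allow_cross_omic)
  unknown <- setdiff(unique(c(triplets$A, triplets$B, triplets$C)),
                     m$feature_id)
  if (length(unknown) > 0)
    stop("triplet members absent from matrix: ",
         paste(unknown, collapse = ", "))
  nt <- nrow(triplets)
  ia <- match(triplets$A, m$feature_id)
  ib <- match(triplets$B, m$feature_id)
  ic <- match(triplets$C, m$feature_id)

  cor_ctl <- cor_trt <- rep(NA_real_, nt)
  n_ctl <- n_trt <- integer(nt)
  note <- character(nt)

  complete_feat <- rowSums(is.na(m$values)) == 0
  fast <- complete_feat[ia] & complete_feat[ib] & complete_feat[ic]

  for (lev in c("control", "treatment")) {
    sel <- cond == lev
    n_lev <- sum(sel)
    if (lev == "control") n_ctl[fast] <- n_lev else n_trt[fast] <- n_lev
    if (!any(fast)) next
    X <- m$values[, sel, drop = FALSE]
    Xc <- X[complete_feat, , drop = FALSE]
    S <- stats::cov(t(Xc))
    v <- diag(S)
    map <- match(seq_along(m$feature_id), which(complete_feat))
    fa <- map[ia]; fb <- map[ib]; fc <- map[ic]
    num <- S[cbind(fa[fast], fb[fast])] - S[cbind(fa[fast], fc[fast])]
    var_sum <- v[fb[fast]] + v[fc[fast]]
    var_ratio <- var_sum - 2 * S[cbind(fb[fast], fc[fast])]
    var_a <- v[fa[fast]]
    # relative guard: the identity can leave O(eps) residue when B - C
    # is constant, which would otherwise masquerade as correlation +-1
    bad <- var_a <= 0 | var_ratio <= 1e-12 * var_sum
    r <- ifelse(bad, NA_real_, num / sqrt(pmax(var_a * var_ratio, 0)))
    r[!is.na(r)] <- pmin(1, pmax(-1, r[!is.na(r)]))
    if (lev == "control") cor_ctl[fast] <- r else cor_trt[fast] <- r
  }

  slow <- which(!fast)
  for (i in slow) {
    xa <- m$values[ia[i], ]; xb <- m$values[ib[i], ]; xc <- m$values[ic[i], ]
    ok <- !is.na(xa) & !is.na(xb) & !is.na(xc)
    for (lev in c("control", "treatment")) {
      sel <- ok & cond == lev
      n <- sum(sel)
      if (lev == "control") n_ctl[i] <- n else n_trt[i] <- n
      if (n >= config$min_samples_per_condition) {
        blk <- .cor_block(xa[sel], xb[sel], xc[sel])
        if (lev == "control") cor_ctl[i] <- blk[1] else cor_trt[i] <- blk[1]
      }
    }
  }

  too_few <- n_ctl < config$min_samples_per_condition |
    n_trt < config$min_samples_per_condition
  degenerate <- !too_few & (is.na(cor_ctl) | is.na(cor_trt))
  note[too_few] <- "insufficient_samples"
  note[degenerate] <- "zero_variance"
  delta <- abs(cor_trt - cor_ctl)
  delta[too_few] <- NA_real_
  passed <- !is.na(delta) & delta >= config$delta_threshold
  n_skip <- sum(too_few | degenerate)
  if (n_skip > 0)
    message(sprintf("screen: skipped %d of %d triplets (%s)", n_skip, nt,
                    paste(unique(note[note != ""]), collapse = ", ")))
  data.frame(A = triplets$A, B = triplets$B, C = triplets$C,
             cor_control = cor_ctl, cor_treatment = cor_trt,
             delta = delta, n_control = n_ctl, n_treatment = n_trt,
             passed = passed, note = note, stringsAsFactors = FALSE)
}
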