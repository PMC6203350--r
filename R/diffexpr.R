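#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, the standard per-feature test for log-scale abundance and
#' FPKM data (and R's `t.test()` default). Degenerate inputs are
#' resolved by convention rather than error: two constant groups with
#' equal means carry no evidence (`t = 0, p = 1`); constant groups
#' with unequal means are flagged degenerate (`p = 0`).
#'
#' @param x,y numeric vectors (>= 2 each), the two groups.
#' @return List: `t_stat`, `df`, `p_value`, `degenerate` (logical).
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t_stat = 0, df = NA_real_, p_value = 1, degenerate = FALSE))
    return(list(t_stat = sign(mean(y) - mean(x)) * Inf, df = NA_real_,
                p_value = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(y, x, var.equal = FALSE)   # t > 0 <=> group y higher
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE)
}

#' Per-feature differential abundance / expression table
#'
#' Welch's t-test for every feature of a log-scale matrix, comparing
#' treatment against control; `direction` is `up`/`down` by the sign
#' of the treatment-minus-control mean difference when `p < alpha`,
#' otherwise `unchanged`.
#'
#' @param m log-scale [omics_matrix()].
#' @param design a [sample_design()].
#' @param alpha significance level for the direction call (default
#'   0.05).
#' @return Data frame: `feature_id`, `omic_type`, `mean_control`,
#'   `mean_treatment`, `t_stat`, `df`, `p_value`, `direction`, in the
#'   matrix's feature order.
#' @export
de_table <- function(m, design, alpha = 0.05) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!m$log_scale) stop("differential testing expects log-scale values")
  cond <- design_for(m, design)
  nf <- length(m$feature_id)
  out <- data.frame(feature_id = m$feature_id, omic_type = m$omic_type,
                    mean_control = rep(NA_real_, nf),
                    mean_treatment = rep(NA_real_, nf),
                    t_stat = rep(NA_real_, nf), df = rep(NA_real_, nf),
                    p_value = rep(NA_real_, nf),
                    direction = rep("unchanged", nf),
                    stringsAsFactors = FALSE)
  if (nf == 0) return(out)
  for (i in seq_len(nf)) {
    v <- m$values[i, ]
    xc <- v[cond == "control"]; xt <- v[cond == "treatment"]
    out$mean_control[i] <- mean(xc, na.rm = TRUE)
    out$mean_treatment[i] <- mean(xt, na.rm = TRUE)
    w <- welch_test(xc, xt)
    out$t_stat[i] <- w$t_stat
    out$df[i] <- w$df
    out$p_value[i] <- w$p_value
    if (!is.na(w$p_value) && w$p_value < alpha) {
      d <- out$mean_treatment[i] - out$mean_control[i]
      out$direction[i] <- if (d > 0) "up" else if (d < 0) "down" else "unchanged"
    }
  }
  out
}
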