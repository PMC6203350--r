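#' Model-validation configuration
#'
#' @param alpha significance level for the interaction term, strictly
#'   between 0 and 1 (default 0.05). The dual rule uses a strict `<`.
#' @param fdr_adjust if `TRUE`, [batch_evaluate()] appends
#'   Benjamini-Hochberg adjusted columns per direction (reporting
#'   only; the fork decision always uses the raw p-values).
#' @param allow_zero_residual whether a noiseless (zero-residual) fit,
#'   reported with p = 0, may count towards the dual rule. Off by
#'   default: measured data never produces one, so in practice it
#'   flags a synthetic degeneracy rather than evidence.
#' @return A `model_config` list.
#' @export
model_config <- function(alpha = 0.05, fdr_adjust = FALSE,
                         allow_zero_residual = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  structure(list(alpha = alpha, fdr_adjust = isTRUE(fdr_adjust),
                 allow_zero_residual = isTRUE(allow_zero_residual)),
            class = "model_config")
}

# normalize a condition vector to the 0/1 treatment indicator
.condition_indicator <- function(condition) {
  if (is.factor(condition)) condition <- as.character(condition)
  if (is.character(condition)) {
    bad <- setdiff(unique(condition), c("control", "treatment"))
    if (length(bad) > 0)
      stop("unknown condition labels: ", paste(bad, collapse = ", "))
    return(as.integer(condition == "treatment"))
  }
  if (!all(condition %in% c(0, 1)))
    stop("numeric condition must be 0 (control) / 1 (treatment)")
  as.integer(condition)
}

#' Fit a two-group linear model with a condition interaction
#'
#' Ordinary least squares on the design `[1, x, g, x*g]` with `g = 0`
#' for control and `g = 1` for treatment — the standard
#' different-slopes model `lm(y ~ x * g)`. The interaction coefficient
#' is the treatment-minus-control slope difference; its two-sided
#' t-test on `n - 4` residual degrees of freedom is the quantity the
#' fork validation thresholds.
#'
#' Degenerate cases are signalled, not errored mid-pipeline: a
#' rank-deficient design (e.g. x constant within a group) yields
#' `degenerate = "rank_deficient"` with `NA` statistics; an exact fit
#' (zero residual variance) yields `degenerate = "zero_residual"` with
#' p = 0.
#'
#' @param y,x numeric response and predictor (equal length).
#' @param condition condition labels (`control`/`treatment`, a factor,
#'   or a 0/1 indicator), same length; each group needs >= 3 points
#'   and `n - 4 > 0` overall.
#' @param direction label stored with the fit (`"A_on_ratio"` or
#'   `"ratio_on_A"` in pipeline use).
#' @return An `interaction_fit` list: `direction`, `intercept`,
#'   `slope_control`, `condition_offset`, `interaction_coefficient`,
#'   `interaction_se`, `interaction_t`, `interaction_p`,
#'   `df_residual`, `n_used`, `degenerate` (`"none"`,
#'   `"rank_deficient"` or `"zero_residual"`).
#' @export
fit_interaction <- function(y, x, condition, direction = "A_on_ratio") {
  g <- .condition_indicator(condition)
  n <- length(y)
  if (length(x) != n || length(g) != n)
    stop("'y', 'x' and 'condition' lengths differ")
  if (anyNA(y) || anyNA(x)) stop("missing values not allowed in the fit")
  if (min(table(factor(g, levels = 0:1))) < 3)
    stop("each condition group needs at least 3 observations")
  if (n - 4 <= 0) stop("no residual degrees of freedom (n - 4 <= 0)")

  out <- list(direction = direction, intercept = NA_real_,
              slope_control = NA_real_, condition_offset = NA_real_,
              interaction_coefficient = NA_real_,
              interaction_se = NA_real_, interaction_t = NA_real_,
              interaction_p = NA_real_, df_residual = n - 4L,
              n_used = n, degenerate = "none")
  class(out) <- "interaction_fit"

  fit <- stats::lm(y ~ x * g)
  if (fit$rank < 4L) {
    out$degenerate <- "rank_deficient"
    return(out)
  }
  beta <- stats::coef(fit)
  out$intercept <- unname(beta[["(Intercept)"]])
  out$slope_control <- unname(beta[["x"]])
  out$condition_offset <- unname(beta[["g"]])
  out$interaction_coefficient <- unname(beta[["x:g"]])

  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (rss <= 1e-12 * max(tss, .Machine$double.xmin)) {
    out$degenerate <- "zero_residual"
    out$interaction_se <- 0
    out$interaction_t <- sign(out$interaction_coefficient) * Inf
    out$interaction_p <- 0
    return(out)
  }
  cf <- stats::summary.lm(fit)$coefficients
  out$interaction_se <- cf["x:g", "Std. Error"]
  out$interaction_t <- cf["x:g", "t value"]
  out$interaction_p <- cf["x:g", "Pr(>|t|)"]
  out
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("interaction_fit [%s]: slope diff = %.4g (se %.4g), t = %.3f, p = %.4g, df = %d%s\n",
              x$direction, x$interaction_coefficient, x$interaction_se,
              x$interaction_t, x$interaction_p, x$df_residual,
              if (x$degenerate != "none") paste0(" [", x$degenerate, "]") else ""))
  invisible(x)
}

# pull the three aligned series (A, log-ratio, condition) for a triplet,
# restricted to samples observed in all three features
.triplet_series <- function(A, B, C, m, design) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!m$log_scale) stop("fork models require a log-transformed matrix")
  idx <- match(c(A, B, C), m$feature_id)
  if (anyNA(idx))
    stop("triplet members absent from matrix: ",
         paste(c(A, B, C)[is.na(idx)], collapse = ", "))
  xa <- m$values[idx[1], ]; xb <- m$values[idx[2], ]; xc <- m$values[idx[3], ]
  ok <- !is.na(xa) & !is.na(xb) & !is.na(xc)
  cond <- design_for(m, design)
  list(a = xa[ok], ratio = (xb - xc)[ok], condition = cond[ok])
}

#' Validate one screened triplet with bidirectional interaction models
#'
#' Fits both directions — A as a function of the log-ratio
#' (`A_on_ratio`) and the log-ratio as a function of A
#' (`ratio_on_A`) — on identical samples. A triplet is a validated
#' metabolic fork only when the interaction term is significant in
#' *both* models (strict `p < alpha`), the dual-significance rule that
#' hedges the unknown direction of causality between the focal
#' compound and the branch ratio.
#'
#' @param A,B,C feature ids of the triplet.
#' @param m log-scale [omics_matrix()].
#' @param design a [sample_design()].
#' @param config a [model_config()].
#' @return A `fork_model_result` list: `A`, `B`, `C`, `fit_forward`,
#'   `fit_reverse`, `alpha`, `is_fork`.
#' @export
evaluate_fork <- function(A, B, C, m, design, config = model_config()) {
  s <- .triplet_series(A, B, C, m, design)
  fwd <- fit_interaction(s$a, s$ratio, s$condition, direction = "A_on_ratio")
  rev <- fit_interaction(s$ratio, s$a, s$condition, direction = "ratio_on_A")
  ok_fit <- function(f)
    f$degenerate == "none" ||
      (f$degenerate == "zero_residual" && config$allow_zero_residual)
  is_fork <- ok_fit(fwd) && ok_fit(rev) &&
    !is.na(fwd$interaction_p) && !is.na(rev$interaction_p) &&
    fwd$interaction_p < config$alpha && rev$interaction_p < config$alpha
  structure(list(A = A, B = B, C = C, fit_forward = fwd, fit_reverse = rev,
                 alpha = config$alpha, is_fork = is_fork),
            class = "fork_model_result")
}

#' Evaluate all screened candidates
#'
#' Runs [evaluate_fork()] over every triplet that passed the screen,
#' in the candidates' (deterministic) order, and assembles the flat
#' results table.
#'
#' @param screened data frame from [screen_triplets()]; only rows with
#'   `passed == TRUE` are evaluated (others are ignored with a
#'   message).
#' @param m log-scale [omics_matrix()].
#' @param design a [sample_design()].
#' @param config a [model_config()].
#' @return Data frame with one row per evaluated candidate: triplet
#'   ids, both directions' coefficient/SE/t/p, degeneracy flags,
#'   `n_used`, `is_fork`, and BH-adjusted columns (`q_forward`,
#'   `q_reverse`) when `config$fdr_adjust`.
#' @export
batch_evaluate <- function(screened, m, design, config = model_config()) {
  cand <- screened[screened$passed %in% TRUE, , drop = FALSE]
  if (nrow(cand) < nrow(screened))
    message(sprintf("models: evaluating %d screened candidates (of %d rows)",
                    nrow(cand), nrow(screened)))
  cols <- list(
    A = character(0), B = character(0), C = character(0),
    n_used = integer(0),
    coef_forward = numeric(0), se_forward = numeric(0),
    t_forward = numeric(0), p_forward = numeric(0),
    degenerate_forward = character(0),
    coef_reverse = numeric(0), se_reverse = numeric(0),
    t_reverse = numeric(0), p_reverse = numeric(0),
    degenerate_reverse = character(0),
    is_fork = logical(0))
  if (nrow(cand) == 0) {
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
    if (config$fdr_adjust) { out$q_forward <- numeric(0); out$q_reverse <- numeric(0) }
    return(out)
  }
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    r <- evaluate_fork(cand$A[i], cand$B[i], cand$C[i], m, design, config)
    data.frame(A = r$A, B = r$B, C = r$C,
               n_used = r$fit_forward$n_used,
               coef_forward = r$fit_forward$interaction_coefficient,
               se_forward = r$fit_forward$interaction_se,
               t_forward = r$fit_forward$interaction_t,
               p_forward = r$fit_forward$interaction_p,
               degenerate_forward = r$fit_forward$degenerate,
               coef_reverse = r$fit_reverse$interaction_coefficient,
               se_reverse = r$fit_reverse$interaction_se,
               t_reverse = r$fit_reverse$interaction_t,
               p_reverse = r$fit_reverse$interaction_p,
               degenerate_reverse = r$fit_reverse$degenerate,
               is_fork = r$is_fork, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (config$fdr_adjust) {
    out$q_forward <- stats::p.adjust(out$p_forward, method = "BH")
    out$q_reverse <- stats::p.adjust(out$p_reverse, method = "BH")
  }
  message(sprintf("models: %d of %d candidates validated as forks",
                  sum(out$is_fork), nrow(out)))
  rownames(out) <- NULL
  out
}
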