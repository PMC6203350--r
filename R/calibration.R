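#' Screen and validate the planted triplet across simulated replicates
#'
#' The workhorse of the package's calibration and power studies: for
#' each replicate a fresh dataset is generated (seed `config$seed + r`),
#' preprocessed with the standard chain (minimum-value imputation, log
#' transform), and the *planted* triplet is pushed through the
#' differential-correlation screen and the bidirectional interaction
#' models. With equal planted slopes this measures type-I behaviour;
#' with differing slopes, power and recovery.
#'
#' @param replicates number of simulated datasets.
#' @param config a [sim_config()] with exactly one planted fork.
#' @param delta_threshold screening threshold (default 1.2).
#' @param alpha interaction significance level (default 0.05).
#' @return Data frame, one row per replicate: `seed`, `delta`,
#'   `screen_passed`, `p_forward`, `p_reverse`, `is_fork` (dual rule on
#'   the model p-values alone), and `recovered`
#'   (`screen_passed & is_fork`, the full-pipeline event).
#' @export
simulate_fork_replicates <- function(replicates, config = sim_config(),
                                     delta_threshold = 1.2, alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$planted_forks) != 1)
    stop("calibration runs expect exactly one planted fork")
  if (!is.numeric(replicates) || replicates < 1)
    stop("'replicates' must be >= 1")
  scfg <- screen_config(delta_threshold = delta_threshold)
  mcfg <- model_config(alpha = alpha)
  rows <- lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    d <- generate_synthetic(cfg)
    met <- log_transform(impute_min(d$metabolites))
    tp <- d$truth$planted
    sc <- screen_triplet(tp$A, tp$B, tp$C, met, d$design, scfg)
    ev <- evaluate_fork(tp$A, tp$B, tp$C, met, d$design, mcfg)
    data.frame(seed = cfg$seed, delta = sc$delta,
               screen_passed = isTRUE(sc$passed),
               p_forward = ev$fit_forward$interaction_p,
               p_reverse = ev$fit_reverse$interaction_p,
               is_fork = ev$is_fork,
               recovered = isTRUE(sc$passed) && ev$is_fork)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type-I calibration of the fork test under the null
#'
#' Simulates equal-slope (null) triplets and reports the rejection
#' rate of each directional interaction test at `alpha`, the rate of
#' the dual rule, and the screening pass rate at the given threshold.
#' Under the generator's Gaussian log-linear null the single-direction
#' rates should sit at the nominal level; the dual rule, being an
#' intersection, can only be more conservative.
#'
#' @param replicates number of null datasets.
#' @param config base [sim_config()]; its planted fork is forced to
#'   equal slopes (`slope_treatment <- slope_control`).
#' @param delta_threshold,alpha screen threshold and test level.
#' @return List: `rates` (named vector: `reject_forward`,
#'   `reject_reverse`, `reject_dual`, `screen_pass`), `replicates`,
#'   and the per-replicate `detail` table.
#' @export
null_calibration <- function(replicates = 2000, config = sim_config(),
                             delta_threshold = 1.2, alpha = 0.05) {
  cfg <- config
  cfg$planted_forks$slope_treatment <- cfg$planted_forks$slope_control
  detail <- simulate_fork_replicates(replicates, cfg,
                                     delta_threshold = delta_threshold,
                                     alpha = alpha)
  rates <- c(reject_forward = mean(detail$p_forward < alpha),
             reject_reverse = mean(detail$p_reverse < alpha),
             reject_dual = mean(detail$p_forward < alpha &
                                  detail$p_reverse < alpha),
             screen_pass = mean(detail$screen_passed))
  list(rates = rates, replicates = replicates, detail = detail)
}

#' Power of fork recovery across slope differences
#'
#' Fixes the control slope at `+d/2` and the treatment slope at
#' `-d/2` for each slope difference `d` in the grid, so the
#' interaction coefficient is exactly `-d`, and measures how often the
#' planted triplet is screened *and* validated.
#'
#' @param slope_diffs numeric grid of |slope_treatment -
#'   slope_control| values.
#' @param replicates replicates per grid point.
#' @param noise_sd residual noise of the planted focal feature.
#' @param config base [sim_config()] (its planted fork is replaced).
#' @param delta_threshold,alpha screen threshold and test level.
#' @return Data frame: `slope_diff`, `power_screen`, `power_model`,
#'   `power_recovered`.
#' @export
power_grid <- function(slope_diffs = c(0.5, 1, 2), replicates = 300,
                       noise_sd = 1.5, config = sim_config(),
                       delta_threshold = 1.2, alpha = 0.05) {
  rows <- lapply(seq_along(slope_diffs), function(i) {
    d <- slope_diffs[i]
    cfg <- config
    cfg$planted_forks <- data.frame(slope_control = d / 2,
                                    slope_treatment = -d / 2,
                                    noise_sd = noise_sd)
    cfg$seed <- config$seed + (i - 1) * replicates
    det <- simulate_fork_replicates(replicates, cfg,
                                    delta_threshold = delta_threshold,
                                    alpha = alpha)
    data.frame(slope_diff = d,
               power_screen = mean(det$screen_passed),
               power_model = mean(det$is_fork),
               power_recovered = mean(det$recovered))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
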