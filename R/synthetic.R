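#' Synthetic two-condition multi-omics generator configuration
#'
#' Emulates the design this pipeline targets: 12 control and 11
#' treatment metabolome samples with an 8 + 8 transcriptome subset
#' nested inside them, log-normal abundances, and "planted" fork
#' triplets in which the slope between a focal compound A and a
#' log-ratio B/C differs between conditions — exactly the signal the
#' screen and the interaction models target.
#'
#' @param n_control,n_treatment metabolome samples per condition
#'   (defaults 12 / 11).
#' @param n_transcriptome_per_group transcriptome samples per
#'   condition, taken as the first samples of each group (nested
#'   subset; default 8).
#' @param n_null_features number of null metabolite features, drawn
#'   i.i.d. log-normal with no planted structure (default 40).
#' @param n_transcript_features number of null transcript features,
#'   emitted as FPKM-like values on the transcriptome samples only
#'   (default 20).
#' @param planted_forks data frame with one row per planted fork:
#'   `slope_control`, `slope_treatment`, `noise_sd` (default one fork
#'   with slopes +1 / -1 and noise sd 0.1).
#' @param base_abundance_log_mean,log_sd location and spread of
#'   feature log-abundances (defaults 2 and 1).
#' @param ratio_log_mean,ratio_log_sd distribution of each planted
#'   fork's log-ratio driver (defaults 0 and 1).
#' @param missing_rate Bernoulli masking rate for metabolite cells
#'   (non-detects; default 0.02). Masking never removes all values of
#'   a feature.
#' @param transcript_zero_rate probability that a transcript cell is a
#'   measured zero FPKM (default 0.1), exercising the pseudocount
#'   path.
#' @param seed RNG seed; every generated dataset is fully reproducible
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_control = 12, n_treatment = 11,
                       n_transcriptome_per_group = 8,
                       n_null_features = 40, n_transcript_features = 20,
                       planted_forks = data.frame(slope_control = 1,
                                                  slope_treatment = -1,
                                                  noise_sd = 0.1),
                       base_abundance_log_mean = 2, log_sd = 1,
                       ratio_log_mean = 0, ratio_log_sd = 1,
                       missing_rate = 0.02, transcript_zero_rate = 0.1,
                       seed = 1) {
  planted_forks <- as.data.frame(planted_forks)
  if (nrow(planted_forks) > 0) {
    need <- c("slope_control", "slope_treatment", "noise_sd")
    if (!all(need %in% names(planted_forks)))
      stop("'planted_forks' needs columns: ", paste(need, collapse = ", "))
    if (any(planted_forks$noise_sd <= 0)) stop("'noise_sd' must be > 0")
  }
  if (n_control < 3 || n_treatment < 3)
    stop("need at least 3 samples per condition")
  if (n_transcriptome_per_group > min(n_control, n_treatment))
    stop("transcriptome samples must be a subset of each condition's samples")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (log_sd <= 0 || ratio_log_sd <= 0) stop("spreads must be positive")
  structure(list(n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment),
                 n_transcriptome_per_group = as.integer(n_transcriptome_per_group),
                 n_null_features = as.integer(n_null_features),
                 n_transcript_features = as.integer(n_transcript_features),
                 planted_forks = planted_forks,
                 base_abundance_log_mean = base_abundance_log_mean,
                 log_sd = log_sd, ratio_log_mean = ratio_log_mean,
                 ratio_log_sd = ratio_log_sd,
                 missing_rate = missing_rate,
                 transcript_zero_rate = transcript_zero_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic two-condition multi-omics dataset
#'
#' For each planted fork a per-sample log-ratio driver
#' `R ~ N(ratio_log_mean, ratio_log_sd)` is drawn; the focal feature
#' is `log A = mu + slope(condition) * R + N(0, noise_sd)`, and R is
#' decomposed into the pair by drawing `log C` and setting
#' `log B = R + log C`. All log-values are exponentiated to raw
#' abundances, so the planted linear structure lives exactly on the
#' scale the pipeline models after its log transform. Null metabolite
#' and transcript features are i.i.d. log-normal; metabolite cells are
#' masked at `missing_rate`; transcript cells are zeroed at
#' `transcript_zero_rate` (measured zeros, handled by the
#' pseudocount).
#'
#' @param config a [sim_config()].
#' @return List: `metabolites` and `transcripts` (raw-scale
#'   [omics_matrix()]), `design` ([sample_design()]), and `truth`
#'   (list with the `planted` fork table and `null_features` ids).
#' @export
generate_synthetic <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_control; nt <- config$n_treatment
  n <- nc + nt
  samples <- c(sprintf("ctl_%02d", seq_len(nc)),
               sprintf("trt_%02d", seq_len(nt)))
  cond <- c(rep("control", nc), rep("treatment", nt))
  design <- sample_design(samples, cond)
  mu <- config$base_abundance_log_mean

  nf <- nrow(config$planted_forks)
  fork_rows <- list()
  classes <- c("sulfur", "lipid", "sugar")
  truth_planted <- data.frame(fork = character(0), A = character(0),
                              B = character(0), C = character(0),
                              slope_control = numeric(0),
                              slope_treatment = numeric(0),
                              noise_sd = numeric(0), stringsAsFactors = FALSE)
  if (nf == 0 && config$n_null_features == 0)
    stop("config generates no metabolite features")
  if (nf > 0) {
    truth_planted <- cbind(
      data.frame(fork = sprintf("fork%02d", seq_len(nf)),
                 A = sprintf("fork%02d_A", seq_len(nf)),
                 B = sprintf("fork%02d_B", seq_len(nf)),
                 C = sprintf("fork%02d_C", seq_len(nf)),
                 stringsAsFactors = FALSE),
      config$planted_forks)
    for (k in seq_len(nf)) {
      slopes <- ifelse(cond == "control",
                       config$planted_forks$slope_control[k],
                       config$planted_forks$slope_treatment[k])
      R <- stats::rnorm(n, config$ratio_log_mean, config$ratio_log_sd)
      logC <- stats::rnorm(n, mu, config$log_sd)
      logB <- R + logC
      logA <- mu + slopes * R +
        stats::rnorm(n, 0, config$planted_forks$noise_sd[k])
      block <- rbind(logA, logB, logC)
      rownames(block) <- c(truth_planted$A[k], truth_planted$B[k],
                           truth_planted$C[k])
      fork_rows[[k]] <- block
    }
  }
  null_ids <- character(0)
  null_block <- NULL
  if (config$n_null_features > 0) {
    null_ids <- sprintf("null_%03d", seq_len(config$n_null_features))
    null_block <- matrix(stats::rnorm(config$n_null_features * n, mu,
                                      config$log_sd),
                         nrow = config$n_null_features,
                         dimnames = list(null_ids, samples))
  }
  log_met <- do.call(rbind, c(fork_rows, list(null_block)))
  colnames(log_met) <- samples
  met_vals <- exp(log_met)
  # planted fork members inherit the fork's pathway class (cycled);
  # nulls cycle through in-scope classes plus unannotated features so
  # the subsetting funnel has something to drop
  fork_class <- rep(classes, length.out = nf)
  pc <- c(rep(fork_class, each = 3),
          rep(c(classes, ""), length.out = length(null_ids)))
  if (config$missing_rate > 0) {
    # left-censoring at a global detection limit: the lowest cells of
    # the matrix go missing, matching the non-detect semantics that
    # minimum-value imputation presumes
    lod <- stats::quantile(met_vals, probs = config$missing_rate,
                           names = FALSE)
    mask <- met_vals < lod
    keep_one <- rowSums(!mask) == 0
    mask[keep_one, 1] <- FALSE
    met_vals[mask] <- NA_real_
  }
  metabolites <- omics_matrix(met_vals, omic_type = "metabolite",
                              pathway_class = pc)

  tr_samples <- c(samples[seq_len(config$n_transcriptome_per_group)],
                  samples[nc + seq_len(config$n_transcriptome_per_group)])
  ntr <- config$n_transcript_features
  tr_ids <- if (ntr > 0) sprintf("tr_null_%03d", seq_len(ntr)) else character(0)
  tr_vals <- matrix(exp(stats::rnorm(ntr * length(tr_samples), mu,
                                     config$log_sd)),
                    nrow = ntr, ncol = length(tr_samples),
                    dimnames = list(tr_ids, tr_samples))
  if (ntr > 0 && config$transcript_zero_rate > 0) {
    zero <- matrix(stats::runif(length(tr_vals)) <
                     config$transcript_zero_rate, nrow = ntr)
    tr_vals[zero] <- 0
  }
  transcripts <- omics_matrix(tr_vals, omic_type = "transcript")

  list(metabolites = metabolites, transcripts = transcripts,
       design = design,
       truth = list(planted = truth_planted, null_features = null_ids))
}

#' Generate independent null datasets for calibration studies
#'
#' Re-runs [generate_synthetic()] with seeds derived from the base
#' seed (`seed + replicate index`), by default replacing any planted
#' forks with their equal-slope null version so that every dataset
#' satisfies the no-interaction null hypothesis.
#'
#' @param config a [sim_config()].
#' @param replicates number of datasets (>= 1).
#' @param nullify if `TRUE` (default), planted forks keep their
#'   control slope in both conditions.
#' @return List of `replicates` datasets as from
#'   [generate_synthetic()].
#' @export
generate_null_battery <- function(config = sim_config(), replicates,
                                  nullify = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(replicates) || replicates < 1)
    stop("'replicates' must be >= 1")
  pf <- config$planted_forks
  if (nullify && nrow(pf) > 0) pf$slope_treatment <- pf$slope_control
  lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg$planted_forks <- pf
    cfg$seed <- config$seed + r
    generate_synthetic(cfg)
  })
}
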