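#' Subset features by pathway class
#'
#' Feature selection funnel: retain only features whose pathway class
#' matches one of the requested tags (case-insensitive exact tag
#' match). This mirrors the usual reduction of a full metabolomics
#' panel (hundreds of compounds) to the few dozen representing the
#' pathways under study before triplet enumeration.
#'
#' @param m an [omics_matrix()] with pathway-class annotations.
#' @param classes character vector of tags to retain (e.g.
#'   `c("sulfur", "lipid", "sugar")`).
#' @param keep_all if `TRUE`, skip filtering entirely (identity).
#' @param min_features smallest admissible result; below this no
#'   triplet can be formed, so it is an error. Default 3.
#' @return The filtered `omics_matrix`. The before/after funnel counts
#'   are attached as attribute `"funnel"` and reported via `message()`.
#' @export
subset_features <- function(m, classes, keep_all = FALSE, min_features = 3) {
  stopifnot(inherits(m, "omics_matrix"))
  n_before <- length(m$feature_id)
  if (keep_all) {
    message(sprintf("feature subset: kept all %d features", n_before))
    attr(m, "funnel") <- c(before = n_before, after = n_before)
    return(m)
  }
  keep <- tolower(trimws(m$pathway_class)) %in% tolower(trimws(classes))
  if (sum(keep) < min_features)
    stop("pathway-class subset retains ", sum(keep),
         " feature(s); need at least ", min_features, " to form triplets")
  out <- subset_omics(m, features = m$feature_id[keep])
  message(sprintf("feature subset: %d -> %d features (classes: %s)",
                  n_before, sum(keep), paste(classes, collapse = ", ")))
  attr(out, "funnel") <- c(before = n_before, after = sum(keep))
  out
}

#' Impute missing values with the per-feature minimum
#'
#' Each missing cell is replaced by the minimum observed value of that
#' feature across all samples, both conditions pooled — the standard
#' treatment of non-detects in platform metabolomics exports, where a
#' missing compound is assumed to sit at or below the detection floor.
#' Observed cells are unchanged; the operation is idempotent.
#'
#' @param m a raw-scale [omics_matrix()].
#' @return An `omics_matrix` with no missing values.
#' @export
impute_min <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$log_scale) stop("impute_min() operates on the raw scale")
  vals <- m$values
  all_missing <- rowSums(!is.na(vals)) == 0
  if (any(all_missing))
    stop("feature(s) with no observed values: ",
         paste(m$feature_id[all_missing], collapse = ", "))
  has_na <- which(rowSums(is.na(vals)) > 0)
  for (i in has_na) {
    row <- vals[i, ]
    row[is.na(row)] <- min(row, na.rm = TRUE)
    vals[i, ] <- row
  }
  out <- m
  out$values <- vals
  out
}

#' Log-transform abundances
#'
#' Metabolites must be strictly positive (run [impute_min()] first;
#' measured zeros are not transformable). Transcript FPKM values may
#' legitimately be zero, so a pseudocount is added before the log.
#' Downstream correlations and interaction p-values are invariant to
#' the base (the transform differs by a positive scalar factor).
#'
#' @param m a raw-scale [omics_matrix()] without missing values.
#' @param log_base base of the logarithm (default `exp(1)`).
#' @param pseudocount value added to transcript abundances before the
#'   log (default 1); not applied to metabolites.
#' @return The log-scale `omics_matrix`.
#' @export
log_transform <- function(m, log_base = exp(1), pseudocount = 1) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$log_scale) stop("matrix is already log-transformed")
  if (!is.numeric(log_base) || log_base <= 0 || log_base == 1)
    stop("'log_base' must be positive and != 1")
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  vals <- m$values
  is_met <- m$omic_type == "metabolite"
  met_vals <- vals[is_met, , drop = FALSE]
  if (any(is.na(met_vals)))
    stop("metabolite matrix has missing values; run impute_min() first")
  if (any(met_vals <= 0)) {
    bad <- m$feature_id[is_met][which(rowSums(met_vals <= 0) > 0)]
    stop("non-positive metabolite value(s); log undefined for: ",
         paste(bad, collapse = ", "))
  }
  vals[is_met, ] <- log(met_vals, base = log_base)
  if (any(!is_met)) {
    tr <- vals[!is_met, , drop = FALSE]
    ok <- is.na(tr) | tr + pseudocount > 0
    if (!all(ok)) stop("transcript value + pseudocount must be positive")
    vals[!is_met, ] <- log(tr + pseudocount, base = log_base)
  }
  out <- m
  out$values <- vals
  out$log_scale <- TRUE
  out$log_base <- log_base
  out
}

#' Standard preprocessing chain for a metabolite matrix
#'
#' Convenience wrapper: pathway-class subset (optional), minimum-value
#' imputation, log transform.
#'
#' @inheritParams subset_features
#' @inheritParams log_transform
#' @return A log-scale `omics_matrix`.
#' @export
preprocess_metabolites <- function(m, classes = NULL, keep_all = is.null(classes),
                                   log_base = exp(1)) {
  if (!keep_all || !is.null(classes))
    m <- subset_features(m, classes, keep_all = keep_all)
  log_transform(impute_min(m), log_base = log_base)
}

#' Standard preprocessing chain for a transcript matrix
#'
#' @inheritParams log_transform
#' @param m a raw FPKM [omics_matrix()].
#' @return A log-scale `omics_matrix`.
#' @export
preprocess_transcripts <- function(m, log_base = exp(1), pseudocount = 1) {
  log_transform(m, log_base = log_base, pseudocount = pseudocount)
}
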