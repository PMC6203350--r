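#' Construct an omics abundance matrix
#'
#' The central data container of the package: a features-by-samples
#' abundance matrix carrying per-feature metadata (omic type, pathway
#' class) and a log-scale flag. Metabolite abundances are arbitrary
#' (platform) units; transcript abundances are FPKM. Missing metabolite
#' measurements are stored as `NA` — a zero is a measured zero, not a
#' non-detect.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names (or `feature_id`) identify features; column names (or
#'   `sample_ids`) identify samples.
#' @param omic_type character scalar or vector: `"metabolite"` or
#'   `"transcript"` per feature.
#' @param pathway_class character vector of pathway tags, one per
#'   feature; `""` for unannotated features.
#' @param feature_id,sample_ids optional explicit identifiers,
#'   defaulting to the dimnames of `values`.
#' @param log_scale logical; `TRUE` once [log_transform()] has been
#'   applied.
#' @param log_base base of the logarithm used, when `log_scale`.
#'
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omic_type = "metabolite",
                         pathway_class = NULL,
                         feature_id = rownames(values),
                         sample_ids = colnames(values),
                         log_scale = FALSE, log_base = NA_real_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(feature_id)) {
    if (nrow(values) > 0)
      stop("feature ids are required (rownames or 'feature_id')")
    feature_id <- character(0)
  }
  if (is.null(sample_ids)) {
    if (ncol(values) > 0)
      stop("sample ids are required (colnames or 'sample_ids')")
    sample_ids <- character(0)
  }
  feature_id <- as.character(feature_id)
  sample_ids <- as.character(sample_ids)
  if (length(feature_id) != nrow(values))
    stop("length of 'feature_id' does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' does not match number of columns")
  dup <- unique(feature_id[duplicated(feature_id)])
  if (length(dup) > 0)
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  omic_type <- rep_len(as.character(omic_type), nrow(values))
  bad <- setdiff(unique(omic_type), c("metabolite", "transcript"))
  if (length(bad) > 0)
    stop("unknown omic_type: ", paste(bad, collapse = ", "))
  if (is.null(pathway_class)) pathway_class <- rep("", nrow(values))
  pathway_class <- rep_len(as.character(pathway_class), nrow(values))
  if (!log_scale && any(values < 0, na.rm = TRUE))
    stop("raw abundances must be non-negative")
  dimnames(values) <- list(feature_id, sample_ids)
  structure(
    list(values = values,
         feature_id = feature_id,
         sample_ids = sample_ids,
         omic_type = omic_type,
         pathway_class = pathway_class,
         log_scale = isTRUE(log_scale),
         log_base = log_base),
    class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$omic_type)
  cat("  omic types:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  cat(sprintf("  scale: %s%s; missing cells: %d\n",
              if (x$log_scale) "log" else "raw",
              if (x$log_scale) sprintf(" (base %.4g)", x$log_base) else "",
              n_na))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by feature and/or sample
#'
#' @param m an [omics_matrix()].
#' @param features character vector of feature ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return An `omics_matrix` restricted to the requested rows/columns,
#'   preserving the input order of the selectors.
#' @export
subset_omics <- function(m, features = m$feature_id, samples = m$sample_ids) {
  stopifnot(inherits(m, "omics_matrix"))
  missing_f <- setdiff(features, m$feature_id)
  if (length(missing_f) > 0)
    stop("unknown features: ", paste(missing_f, collapse = ", "))
  missing_s <- setdiff(samples, m$sample_ids)
  if (length(missing_s) > 0)
    stop("unknown samples: ", paste(missing_s, collapse = ", "))
  fi <- match(features, m$feature_id)
  si <- match(samples, m$sample_ids)
  omics_matrix(m$values[fi, si, drop = FALSE],
               omic_type = m$omic_type[fi],
               pathway_class = m$pathway_class[fi],
               feature_id = features, sample_ids = samples,
               log_scale = m$log_scale, log_base = m$log_base)
}

#' Combine metabolite and transcript matrices on the sample union
#'
#' Stacks two omics matrices feature-wise. Samples present in only one
#' matrix get `NA` in the other's rows, so downstream per-triplet
#' computations naturally restrict cross-omic triplets to the sample
#' intersection (typically the transcriptome samples are a nested
#' subset of the metabolome samples).
#'
#' Both matrices must be on the same scale (both raw or both log with
#' the same base).
#'
#' @param a,b two [omics_matrix()] objects with disjoint feature ids.
#' @return A combined `omics_matrix`.
#' @export
combine_omics <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  if (a$log_scale != b$log_scale)
    stop("cannot combine matrices on different scales (raw vs log)")
  if (a$log_scale && !isTRUE(all.equal(a$log_base, b$log_base)))
    stop("cannot combine log matrices with different bases")
  overlap <- intersect(a$feature_id, b$feature_id)
  if (length(overlap) > 0)
    stop("feature ids present in both matrices: ",
         paste(overlap, collapse = ", "))
  samples <- union(a$sample_ids, b$sample_ids)
  expand <- function(m) {
    out <- matrix(NA_real_, nrow(m$values), length(samples),
                  dimnames = list(m$feature_id, samples))
    out[, m$sample_ids] <- m$values
    out
  }
  omics_matrix(rbind(expand(a), expand(b)),
               omic_type = c(a$omic_type, b$omic_type),
               pathway_class = c(a$pathway_class, b$pathway_class),
               log_scale = a$log_scale, log_base = a$log_base)
}

#' Construct a two-condition sample design
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param condition character/factor vector with exactly the two levels
#'   `"control"` and `"treatment"`.
#' @param min_per_condition minimum samples required in each condition
#'   (default 3, the smallest n for which a correlation has any
#'   residual degrees of freedom).
#' @return A `sample_design` data frame with columns `sample_id`,
#'   `condition`.
#' @export
sample_design <- function(sample_id, condition, min_per_condition = 3) {
  sample_id <- as.character(sample_id)
  condition <- as.character(condition)
  if (length(sample_id) != length(condition))
    stop("'sample_id' and 'condition' lengths differ")
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(unique(condition), c("control", "treatment"))
  if (length(bad) > 0)
    stop("condition labels must be 'control'/'treatment'; got: ",
         paste(bad, collapse = ", "),
         " (use a condition_map in read_design() to translate study labels)")
  counts <- table(factor(condition, levels = c("control", "treatment")))
  if (any(counts == 0))
    stop("both condition levels must be present; counts: control=",
         counts[["control"]], ", treatment=", counts[["treatment"]])
  if (any(counts < min_per_condition))
    stop("need at least ", min_per_condition, " samples per condition; ",
         "counts: control=", counts[["control"]],
         ", treatment=", counts[["treatment"]])
  out <- data.frame(sample_id = sample_id,
                    condition = factor(condition,
                                       levels = c("control", "treatment")),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

# samples of `m` (in column order) annotated with condition; errors if any
# matrix sample is absent from the design
design_for <- function(m, design) {
  stopifnot(inherits(m, "omics_matrix"), inherits(design, "sample_design"))
  missing_s <- setdiff(m$sample_ids, design$sample_id)
  if (length(missing_s) > 0)
    stop("samples absent from design: ", paste(missing_s, collapse = ", "))
  design$condition[match(m$sample_ids, design$sample_id)]
}
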