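#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. Paths may be
#' replaced by in-memory objects ([omics_matrix()], [sample_design()],
#' data frames), which is how the analysis scripts and tests drive the
#' pipeline.
#'
#' @param metabolites metabolite table: path (wide CSV) or
#'   [omics_matrix()].
#' @param design sample design: path (TSV) or [sample_design()].
#' @param expression optional transcript FPKM table: path (TSV) or
#'   [omics_matrix()].
#' @param regulators optional curated regulator map: path (TSV with
#'   columns gene_id, target, relation) or data frame.
#' @param out_dir output directory for artifacts (`NULL` = in-memory
#'   only).
#' @param pathway_classes classes retained by the feature-selection
#'   funnel (`NULL` = keep all features).
#' @param delta_threshold screening threshold on
#'   |cor_treatment - cor_control| (default 1.2).
#' @param alpha interaction-term significance level (default 0.05,
#'   strict `<`).
#' @param de_alpha significance level for differential-abundance
#'   direction calls (default 0.05).
#' @param log_base logarithm base for the transform (default `exp(1)`;
#'   results downstream of the screen are invariant to it).
#' @param pseudocount transcript pseudocount before log (default 1).
#' @param allow_cross_omic enumerate triplets mixing omics (default
#'   `TRUE`).
#' @param fdr_adjust append BH-adjusted reporting columns (default
#'   `FALSE`).
#' @param condition_map named vector translating study condition
#'   labels (see [read_design()]).
#' @param pathway_class_col name of the pathway-class column in the
#'   metabolite file (default `"pathway_class"`; `NULL` if absent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(metabolites, design, expression = NULL,
                            regulators = NULL, out_dir = NULL,
                            pathway_classes = NULL, delta_threshold = 1.2,
                            alpha = 0.05, de_alpha = 0.05,
                            log_base = exp(1), pseudocount = 1,
                            allow_cross_omic = TRUE, fdr_adjust = FALSE,
                            condition_map = NULL,
                            pathway_class_col = "pathway_class") {
  structure(list(metabolites = metabolites, design = design,
                 expression = expression, regulators = regulators,
                 out_dir = out_dir, pathway_classes = pathway_classes,
                 delta_threshold = delta_threshold, alpha = alpha,
                 de_alpha = de_alpha, log_base = log_base,
                 pseudocount = pseudocount,
                 allow_cross_omic = isTRUE(allow_cross_omic),
                 fdr_adjust = isTRUE(fdr_adjust),
                 condition_map = condition_map,
                 pathway_class_col = pathway_class_col),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `condition_map`
#' may be a YAML mapping.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$condition_map)) raw$condition_map <- unlist(raw$condition_map)
  do.call(pipeline_config, raw)
}

.load_stage <- function(config) {
  met <- config$metabolites
  if (is.character(met))
    met <- read_omics_table(met, "metabolite",
                            pathway_class_col = config$pathway_class_col)
  des <- config$design
  if (is.character(des))
    des <- read_design(des, condition_map = config$condition_map)
  expr <- config$expression
  if (is.character(expr)) expr <- read_omics_table(expr, "transcript")
  reg <- config$regulators
  if (is.character(reg))
    reg <- utils::read.table(reg, header = TRUE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  list(metabolites = met, design = des, expression = expr, regulators = reg)
}

#' Run the full fork-discovery workflow
#'
#' Stages, in order: preprocess (pathway subset, minimum-value
#' imputation, log transform) -> differential-correlation screen ->
#' bidirectional interaction models -> per-feature differential
#' abundance/expression -> circuit assembly and annotation. With
#' `out_dir` set, writes `screened.tsv`, `forks.tsv`, `de.tsv`,
#' `circuit.graphml`, `circuit.json` and `funnel.log`; identical
#' inputs and configuration produce identical files. Any stage error
#' aborts the run, prefixed with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) a list with the log-scale matrices, `screened`,
#'   `forks`, `de`, `circuit`, and the `funnel` count vector.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- stage("load", .load_stage(config))

  met_log <- stage("preprocess", {
    m <- inputs$metabolites
    if (!is.null(config$pathway_classes))
      m <- subset_features(m, config$pathway_classes)
    log_transform(impute_min(m), log_base = config$log_base)
  })
  tr_log <- NULL
  if (!is.null(inputs$expression))
    tr_log <- stage("preprocess",
                    log_transform(inputs$expression,
                                  log_base = config$log_base,
                                  pseudocount = config$pseudocount))
  combined <- if (is.null(tr_log)) met_log else
    stage("preprocess", combine_omics(met_log, tr_log))

  scfg <- screen_config(delta_threshold = config$delta_threshold,
                        allow_cross_omic = config$allow_cross_omic)
  screened <- stage("screen",
                    screen_triplets(combined, inputs$design, scfg))

  mcfg <- model_config(alpha = config$alpha,
                       fdr_adjust = config$fdr_adjust)
  forks <- stage("model",
                 batch_evaluate(screened, combined, inputs$design, mcfg))

  de <- stage("de", {
    tabs <- list(de_table(met_log, inputs$design, alpha = config$de_alpha))
    if (!is.null(tr_log))
      tabs <- c(tabs, list(de_table(tr_log, inputs$design,
                                    alpha = config$de_alpha)))
    do.call(rbind, tabs)
  })

  circuit <- stage("circuit", {
    validated <- forks[forks$is_fork, , drop = FALSE]
    si <- match(paste(validated$A, validated$B, validated$C),
                paste(screened$A, screened$B, screened$C))
    validated$cor_control <- screened$cor_control[si]
    validated$cor_treatment <- screened$cor_treatment[si]
    validated$delta <- screened$delta[si]
    ot <- stats::setNames(combined$omic_type, combined$feature_id)
    circ <- merge_forks(validated, omic_type = ot)
    circ <- annotate_pairwise(circ, combined, inputs$design)
    circ <- annotate_de(circ, de)
    if (!is.null(inputs$regulators) && nrow(inputs$regulators) > 0)
      circ <- attach_regulators(circ, inputs$regulators, de)
    circ
  })

  funnel <- c(features_input = length(inputs$metabolites$feature_id) +
                (if (is.null(inputs$expression)) 0L
                 else length(inputs$expression$feature_id)),
              features_selected = length(combined$feature_id),
              triplets_enumerated = nrow(screened),
              candidates_passed = sum(screened$passed, na.rm = TRUE),
              forks_validated = sum(forks$is_fork),
              components = length(unique(circuit$nodes$component)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_result_tsv(screened, p("screened.tsv"))
    write_result_tsv(forks, p("forks.tsv"))
    write_result_tsv(de, p("de.tsv"))
    write_circuit(circuit, p("circuit.json"), "json")
    write_circuit(circuit, p("circuit.graphml"), "graphml")
    writeLines(sprintf("%s\t%d", names(funnel), funnel), p("funnel.log"))
  }
  message(paste(sprintf("%s=%d", names(funnel), funnel), collapse = " "))
  invisible(list(metabolites_log = met_log, transcripts_log = tr_log,
                 combined = combined, screened = screened, forks = forks,
                 de = de, circuit = circuit, funnel = funnel))
}
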