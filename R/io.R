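#' Read a wide features-by-samples abundance table
#'
#' Reads a metabolite (CSV) or transcript FPKM (TSV) table in the wide
#' layout: first column feature ids, remaining columns one per sample,
#' optionally one column of pathway-class tags. Empty cells and the
#' string `NA` are recorded as missing; zeros are measured zeros. The
#' input column (sample) order is preserved.
#'
#' Numbers are parsed with a decimal point regardless of locale.
#'
#' @param path path to a delimited text file.
#' @param omic_type `"metabolite"` or `"transcript"`.
#' @param sep field separator; by default `","` for `.csv` files and
#'   tab otherwise.
#' @param pathway_class_col name of the pathway-class column, or `NULL`
#'   if the table has none.
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, omic_type = c("metabolite", "transcript"),
                             sep = NULL, pathway_class_col = NULL) {
  omic_type <- match.arg(omic_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("table must have a feature-id column and at least one sample column: ",
         path)
  feature_id <- trimws(raw[[1]])
  dup <- unique(feature_id[duplicated(feature_id)])
  if (length(dup) > 0)
    stop("duplicate feature ids in ", path, ": ", paste(dup, collapse = ", "))
  pathway_class <- NULL
  value_cols <- names(raw)[-1]
  if (!is.null(pathway_class_col)) {
    if (!pathway_class_col %in% names(raw))
      stop("pathway class column '", pathway_class_col, "' not found in ", path)
    pathway_class <- trimws(raw[[pathway_class_col]])
    value_cols <- setdiff(value_cols, pathway_class_col)
  }
  if (length(value_cols) == 0) stop("no sample columns in ", path)
  vals <- matrix(NA_real_, nrow(raw), length(value_cols),
                 dimnames = list(feature_id, value_cols))
  for (j in seq_along(value_cols)) {
    cell <- trimws(raw[[value_cols[j]]])
    empty <- cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad) > 0)
      stop("non-numeric value '", cell[bad[1]], "' at row '",
           feature_id[bad[1]], "', column '", value_cols[j], "' in ", path)
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  omics_matrix(vals, omic_type = omic_type, pathway_class = pathway_class)
}

#' Read a sample design table
#'
#' Two columns (with header): `sample_id` and `condition`. Study-specific
#' condition labels (e.g. thermoneutral/heat-stress house codes) are
#' translated to the canonical `control`/`treatment` levels through
#' `condition_map`.
#'
#' @param path path to a TSV/CSV design table.
#' @param condition_map named character vector mapping study labels to
#'   `"control"`/`"treatment"`, e.g. `c(TN = "control", HS = "treatment")`.
#'   `NULL` if the file already uses the canonical labels.
#' @param sep field separator (default as in [read_omics_table()]).
#' @return A [sample_design()]; per-condition counts are reported via
#'   `message()`.
#' @export
read_design <- function(path, condition_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("cannot read design table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(raw) == 0) stop("design table is empty: ", path)
  if (ncol(raw) < 2)
    stop("design table needs columns (sample_id, condition): ", path)
  sid <- trimws(raw[[1]])
  cond <- trimws(raw[[2]])
  if (!is.null(condition_map)) {
    unknown <- setdiff(unique(cond), names(condition_map))
    if (length(unknown) > 0)
      stop("condition labels not in condition_map: ",
           paste(unknown, collapse = ", "))
    cond <- unname(condition_map[cond])
  }
  lev <- unique(cond)
  if (length(lev) != 2)
    stop("design must have exactly two condition levels, found ",
         length(lev), ": ", paste(lev, collapse = ", "))
  d <- sample_design(sid, cond)
  counts <- table(d$condition)
  message(sprintf("design: %d samples (%d control, %d treatment)",
                  nrow(d), counts[["control"]], counts[["treatment"]]))
  d
}

# ---- circuit export -------------------------------------------------------

# shared column layout of the three circuit tables
.circuit_node_cols <- c("feature_id", "omic_type", "node_role",
                        "de_direction", "de_p")
.circuit_edge_cols <- c("source", "target", "edge_type", "fork_ids",
                        "cor_control", "cor_treatment", "relation")
.circuit_fork_cols <- c("fork_id", "A", "B", "C",
                        "cor_control", "cor_treatment", "delta",
                        "p_forward", "p_reverse")

validate_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_graph"))
  nodes <- circuit$nodes; edges <- circuit$edges; forks <- circuit$forks
  bad_nodes <- setdiff(c(edges$source, edges$target), nodes$feature_id)
  if (length(bad_nodes) > 0)
    stop("edge endpoints missing from node table: ",
         paste(unique(bad_nodes), collapse = ", "))
  ref <- unlist(strsplit(edges$fork_ids[edges$fork_ids != ""], ";"),
                use.names = FALSE)
  bad_forks <- setdiff(unique(ref), forks$fork_id)
  if (length(bad_forks) > 0)
    stop("edges reference unknown fork ids: ",
         paste(bad_forks, collapse = ", "))
  invisible(circuit)
}

#' Write a circuit graph to disk
#'
#' Supported formats:
#' \describe{
#'   \item{`json`}{single file, full numeric precision; the exact
#'     round-trip format.}
#'   \item{`graphml`}{via igraph; node/edge annotations become GraphML
#'     attributes and the fork table is carried as a JSON-encoded graph
#'     attribute so that [read_circuit()] can reconstruct the object.}
#'   \item{`tsv`}{three files `<stem>_nodes.tsv`, `<stem>_edges.tsv`,
#'     `<stem>_forks.tsv`; numbers at 6 significant digits.}
#' }
#'
#' @param circuit a `circuit_graph` (see [merge_forks()]).
#' @param path output path; for `tsv` the stem from which the three
#'   file names are derived.
#' @param format one of `"json"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path, format = c("json", "graphml", "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported circuit format: '",
                                              format[1], "'"))
  validate_circuit(circuit)
  nodes <- circuit$nodes[, .circuit_node_cols]
  edges <- circuit$edges[, .circuit_edge_cols]
  forks <- circuit$forks[, .circuit_fork_cols]
  if (format == "json") {
    jsonlite::write_json(
      list(nodes = nodes, edges = edges, forks = forks),
      path, dataframe = "columns", digits = NA, auto_unbox = TRUE,
      na = "null")
  } else if (format == "graphml") {
    g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
    for (col in names(nodes))
      g <- igraph::set_vertex_attr(g, if (col == "feature_id") "name" else col,
                                   value = nodes[[col]])
    if (nrow(edges) > 0) {
      idx <- rbind(match(edges$source, nodes$feature_id),
                   match(edges$target, nodes$feature_id))
      g <- igraph::add_edges(g, as.vector(idx))
      for (col in setdiff(names(edges), c("source", "target")))
        g <- igraph::set_edge_attr(g, col, value = edges[[col]])
    }
    g <- igraph::set_graph_attr(
      g, "forks",
      as.character(jsonlite::toJSON(forks, dataframe = "columns",
                                    digits = NA, na = "null")))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    fmt6 <- function(df) {
      df[] <- lapply(df, function(x)
        if (is.numeric(x)) ifelse(is.na(x), NA, signif(x, 6)) else x)
      df
    }
    stem <- sub("\\.tsv$", "", path)
    for (part in c("nodes", "edges", "forks")) {
      df <- fmt6(get(part))
      utils::write.table(df, paste0(stem, "_", part, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "")
    }
  }
  invisible(path)
}

#' Read a circuit graph written by [write_circuit()]
#'
#' @param path path (or TSV stem) given to [write_circuit()].
#' @param format one of `"json"`, `"graphml"`, `"tsv"`.
#' @return A `circuit_graph`.
#' @export
read_circuit <- function(path, format = c("json", "graphml", "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported circuit format: '",
                                              format[1], "'"))
  as_chr <- function(x) if (is.null(x)) character(0) else as.character(x)
  as_num <- function(x) {
    if (is.null(x)) return(numeric(0))
    x[vapply(x, is.null, logical(1))] <- NA
    as.numeric(unlist(x))
  }
  rebuild <- function(lst, cols, num_cols) {
    out <- lapply(cols, function(col)
      if (col %in% num_cols) as_num(lst[[col]]) else as_chr(lst[[col]]))
    names(out) <- cols
    n <- max(c(0L, lengths(out)))
    out <- lapply(out, function(x) { length(x) <- n; x })
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  num_node <- "de_p"
  num_edge <- c("cor_control", "cor_treatment")
  num_fork <- c("cor_control", "cor_treatment", "delta",
                "p_forward", "p_reverse")
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    nodes <- rebuild(obj$nodes, .circuit_node_cols, num_node)
    edges <- rebuild(obj$edges, .circuit_edge_cols, num_edge)
    forks <- rebuild(obj$forks, .circuit_fork_cols, num_fork)
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- rebuild(c(list(feature_id = va$name), va),
                     .circuit_node_cols, num_node)
    ea <- igraph::edge_attr(g)
    ends <- igraph::as_edgelist(g, names = TRUE)
    edges <- rebuild(c(list(source = ends[, 1], target = ends[, 2]), ea),
                     .circuit_edge_cols, num_edge)
    forks <- jsonlite::fromJSON(igraph::graph_attr(g, "forks"),
                                simplifyDataFrame = FALSE)
    forks <- rebuild(forks, .circuit_fork_cols, num_fork)
  } else {
    stem <- sub("\\.tsv$", "", path)
    read_part <- function(part, cols, num_cols) {
      df <- utils::read.table(paste0(stem, "_", part, ".tsv"), header = TRUE,
                              sep = "\t", colClasses = "character",
                              na.strings = character(0),
                              stringsAsFactors = FALSE)
      lst <- as.list(df)
      lst <- lapply(lst, function(x) { x[x == ""] <- NA; x })
      for (col in intersect(num_cols, names(lst)))
        lst[[col]] <- as.numeric(lst[[col]])
      for (col in setdiff(names(lst), num_cols))
        lst[[col]][is.na(lst[[col]])] <- ""
      rebuild(lst, cols, num_cols)
    }
    nodes <- read_part("nodes", .circuit_node_cols, num_node)
    edges <- read_part("edges", .circuit_edge_cols, num_edge)
    forks <- read_part("forks", .circuit_fork_cols, num_fork)
  }
  new_circuit(nodes, edges, forks)
}

#' Write an omics matrix as a wide delimited table
#'
#' Inverse of [read_omics_table()]: first column feature ids, one
#' column per sample, optional pathway-class column. Missing cells are
#' written empty; numbers are written with enough digits ("%.17g") to
#' round-trip the doubles exactly.
#'
#' @param m a raw-scale [omics_matrix()].
#' @param path output path; `.csv` selects comma separation, anything
#'   else tab (unless `sep` is given).
#' @param sep field separator override.
#' @param pathway_class_col name for the pathway-class column, or
#'   `NULL` to omit it.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(m, path, sep = NULL,
                              pathway_class_col = "pathway_class") {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cells <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values),
                  ncol = ncol(m$values))
  cells[is.na(m$values)] <- ""
  df <- data.frame(feature_id = m$feature_id, stringsAsFactors = FALSE)
  if (!is.null(pathway_class_col)) df[[pathway_class_col]] <- m$pathway_class
  colnames(cells) <- m$sample_ids
  df <- cbind(df, as.data.frame(cells, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample design table
#'
#' @param design a [sample_design()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  out <- data.frame(sample_id = design$sample_id,
                    condition = as.character(design$condition))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the three input tables the pipeline consumes —
#' `metabolites.csv`, `expression.tsv`, `design.tsv` — plus the
#' ground-truth record `truth.json`.
#'
#' @param dataset a dataset from [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_table(dataset$metabolites, file.path(dir, "metabolites.csv"))
  write_omics_table(dataset$transcripts, file.path(dir, "expression.tsv"),
                    pathway_class_col = NULL)
  write_design(dataset$design, file.path(dir, "design.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write a result table as TSV
#'
#' Fixed documented column order (the input's), tab-separated, floats
#' at 6 significant digits, `NA` written as empty cells.
#'
#' @param df a data frame (screened triplets, fork models, DE results...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path) {
  out <- as.data.frame(df)
  out[] <- lapply(out, function(x)
    if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
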