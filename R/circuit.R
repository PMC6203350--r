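# internal constructor; normalizes column types and computes components
new_circuit <- function(nodes, edges, forks) {
  chr <- function(x) { x <- as.character(x); x[is.na(x)] <- ""; x }
  for (col in setdiff(.circuit_node_cols, "de_p"))
    nodes[[col]] <- chr(nodes[[col]])
  for (col in c("source", "target", "edge_type", "fork_ids", "relation"))
    edges[[col]] <- chr(edges[[col]])
  for (col in c("fork_id", "A", "B", "C"))
    forks[[col]] <- chr(forks[[col]])
  circuit <- structure(list(nodes = nodes, edges = edges, forks = forks),
                       class = "circuit_graph")
  validate_circuit(circuit)
  circuit$nodes$component <- .circuit_components(circuit)
  circuit
}

# component label per node, deterministic: components are numbered by
# their lexicographically smallest member
.circuit_components <- function(circuit) {
  nodes <- circuit$nodes$feature_id
  if (length(nodes) == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(
    circuit$edges[, c("source", "target"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  memb <- igraph::components(g)$membership[nodes]
  smallest <- vapply(split(nodes, memb), min, character(1))
  ord_ids <- names(smallest)[order(smallest, method = "radix")]
  as.integer(match(as.character(memb), ord_ids))
}

#' Merge validated forks into a circuit graph
#'
#' Each validated fork contributes a 3-clique over its members (A, B,
#' C); forks sharing at least one member end up in the same connected
#' component, which is how isolated branch points join into candidate
#' pathway circuits. Edges record the fork(s) that own them; the fork
#' table keeps each triplet's screening correlations and both
#' interaction p-values.
#'
#' @param forks data frame of validated forks: columns `A`, `B`, `C`,
#'   `p_forward`, `p_reverse` (from [batch_evaluate()], rows with
#'   `is_fork == TRUE`), optionally `cor_control`, `cor_treatment`,
#'   `delta` from the screen.
#' @param omic_type named character vector mapping feature id to
#'   `"metabolite"`/`"transcript"` (optional; unknown types left "").
#' @return A `circuit_graph`: list of `nodes` (with a `component`
#'   label), `edges`, `forks` data frames.
#' @export
merge_forks <- function(forks, omic_type = NULL) {
  forks <- as.data.frame(forks)
  if (nrow(forks) > 0 && !all(c("A", "B", "C") %in% names(forks)))
    stop("'forks' needs columns A, B, C")
  if ("is_fork" %in% names(forks) && any(!forks$is_fork))
    stop("all forks passed to merge_forks() must be validated (is_fork)")
  if (nrow(forks) > 0) {
    key <- paste(forks$A, forks$B, forks$C, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate triplets dropped: ",
              paste(gsub("\r", "/", unique(key[duplicated(key)])),
                    collapse = "; "))
      forks <- forks[!duplicated(key), , drop = FALSE]
    }
    forks <- forks[order(forks$A, forks$B, forks$C, method = "radix"), ,
                   drop = FALSE]
  }
  n_forks <- nrow(forks)
  getcol <- function(col) if (col %in% names(forks)) forks[[col]] else
    rep(NA_real_, n_forks)
  fork_tab <- data.frame(
    fork_id = if (n_forks > 0) sprintf("fork_%03d", seq_len(n_forks)) else character(0),
    A = forks$A %||% character(0), B = forks$B %||% character(0),
    C = forks$C %||% character(0),
    cor_control = getcol("cor_control"),
    cor_treatment = getcol("cor_treatment"),
    delta = getcol("delta"),
    p_forward = getcol("p_forward"), p_reverse = getcol("p_reverse"),
    stringsAsFactors = FALSE)

  members <- sort(unique(c(fork_tab$A, fork_tab$B, fork_tab$C)),
                  method = "radix")
  ot <- rep("", length(members))
  if (!is.null(omic_type))
    ot <- ifelse(members %in% names(omic_type),
                 unname(omic_type[members]), "")
  nodes <- data.frame(feature_id = members, omic_type = ot,
                      node_role = rep("feature", length(members)),
                      de_direction = rep("", length(members)),
                      de_p = rep(NA_real_, length(members)),
                      stringsAsFactors = FALSE)

  edge_map <- list()
  for (i in seq_len(n_forks)) {
    trio <- c(fork_tab$A[i], fork_tab$B[i], fork_tab$C[i])
    prs <- utils::combn(sort(trio, method = "radix"), 2)
    for (j in seq_len(ncol(prs))) {
      k <- paste(prs[1, j], prs[2, j], sep = "\r")
      edge_map[[k]] <- c(edge_map[[k]], fork_tab$fork_id[i])
    }
  }
  keys <- sort(names(edge_map) %||% character(0), method = "radix")
  ends <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- data.frame(
    source = if (length(keys)) ends[, 1] else character(0),
    target = if (length(keys)) ends[, 2] else character(0),
    edge_type = rep("fork", length(keys)),
    fork_ids = vapply(keys, function(k)
      paste(edge_map[[k]], collapse = ";"), character(1), USE.NAMES = FALSE),
    cor_control = rep(NA_real_, length(keys)),
    cor_treatment = rep(NA_real_, length(keys)),
    relation = rep("", length(keys)),
    stringsAsFactors = FALSE)
  new_circuit(nodes, edges, fork_tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.circuit_graph <- function(x, ...) {
  cat(sprintf("circuit_graph: %d nodes, %d edges, %d forks, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$forks),
              length(unique(x$nodes$component))))
  invisible(x)
}

#' Annotate circuit edges with per-condition pairwise correlations
#'
#' Every feature-feature edge receives the Pearson correlation of its
#' endpoints' log values within each condition, the per-triplet-member
#' correlation display that accompanies fork circuits. Cross-omic
#' edges use the shared samples; a zero-variance endpoint leaves the
#' annotation `NA` (exported as null).
#'
#' @param circuit a `circuit_graph`.
#' @param m log-scale [omics_matrix()] containing every feature node.
#' @param design a [sample_design()].
#' @return The annotated `circuit_graph`.
#' @export
annotate_pairwise <- function(circuit, m, design) {
  stopifnot(inherits(circuit, "circuit_graph"), inherits(m, "omics_matrix"))
  if (!m$log_scale) stop("annotation requires a log-transformed matrix")
  feat_nodes <- circuit$nodes$feature_id[circuit$nodes$node_role == "feature"]
  missing_f <- setdiff(feat_nodes, m$feature_id)
  if (length(missing_f) > 0)
    stop("circuit features absent from matrix: ",
         paste(missing_f, collapse = ", "))
  cond <- design_for(m, design)
  for (i in seq_len(nrow(circuit$edges))) {
    if (circuit$edges$edge_type[i] != "fork") next
    xi <- m$values[match(circuit$edges$source[i], m$feature_id), ]
    yi <- m$values[match(circuit$edges$target[i], m$feature_id), ]
    ok <- !is.na(xi) & !is.na(yi)
    for (lev in c("control", "treatment")) {
      sel <- ok & cond == lev
      r <- if (sum(sel) >= 3 && stats::sd(xi[sel]) > 0 &&
               stats::sd(yi[sel]) > 0)
        stats::cor(xi[sel], yi[sel]) else NA_real_
      col <- if (lev == "control") "cor_control" else "cor_treatment"
      circuit$edges[[col]][i] <- r
    }
  }
  circuit
}

#' Attach differential-abundance annotations to circuit nodes
#'
#' @param circuit a `circuit_graph`.
#' @param de a DE table from [de_table()].
#' @return The `circuit_graph` with `de_direction`/`de_p` filled for
#'   nodes present in the DE table.
#' @export
annotate_de <- function(circuit, de) {
  idx <- match(circuit$nodes$feature_id, de$feature_id)
  hit <- !is.na(idx)
  circuit$nodes$de_direction[hit] <- de$direction[idx[hit]]
  circuit$nodes$de_p[hit] <- de$p_value[idx[hit]]
  circuit
}

#' Attach curated regulator genes to a circuit
#'
#' Regulator placement (which enzyme gene acts on which compound or
#' conversion) comes from curated biochemistry, so it is supplied as
#' an explicit map, not inferred. Each regulator becomes a node
#' annotated with its differential-expression call and is linked to
#' its target: a feature node, or both endpoints of an edge written
#' `"X--Y"`.
#'
#' @param circuit a `circuit_graph`.
#' @param regulators data frame with columns `gene_id`, `target`
#'   (feature id or `"X--Y"` edge spec), `relation` (free-text label,
#'   e.g. `"catalyzes"`, `"inhibits"`).
#' @param de DE table from [de_table()] covering every `gene_id`.
#' @return The extended `circuit_graph`.
#' @export
attach_regulators <- function(circuit, regulators, de) {
  regulators <- as.data.frame(regulators)
  if (nrow(regulators) == 0) return(circuit)
  need <- c("gene_id", "target", "relation")
  if (!all(need %in% names(regulators)))
    stop("'regulators' needs columns: ", paste(need, collapse = ", "))
  missing_g <- setdiff(regulators$gene_id, de$feature_id)
  if (length(missing_g) > 0)
    stop("regulator genes absent from DE table: ",
         paste(missing_g, collapse = ", "))
  node_ids <- circuit$nodes$feature_id
  edge_keys <- paste(circuit$edges$source, circuit$edges$target, sep = "--")
  edge_keys_rev <- paste(circuit$edges$target, circuit$edges$source, sep = "--")
  target_nodes <- function(tgt) {
    if (tgt %in% node_ids) return(tgt)
    hit <- which(edge_keys == tgt | edge_keys_rev == tgt)
    if (length(hit) == 1)
      return(c(circuit$edges$source[hit], circuit$edges$target[hit]))
    NULL
  }
  resolved <- lapply(regulators$target, target_nodes)
  bad <- which(vapply(resolved, is.null, logical(1)))
  if (length(bad) > 0)
    stop("regulator targets not found in circuit: ",
         paste(sprintf("%s -> %s", regulators$gene_id[bad],
                       regulators$target[bad]), collapse = "; "))
  di <- match(regulators$gene_id, de$feature_id)
  new_nodes <- data.frame(feature_id = regulators$gene_id,
                          omic_type = "transcript",
                          node_role = "regulator",
                          de_direction = de$direction[di],
                          de_p = de$p_value[di],
                          stringsAsFactors = FALSE)
  new_nodes <- new_nodes[!duplicated(new_nodes$feature_id) &
                           !(new_nodes$feature_id %in% node_ids), ,
                         drop = FALSE]
  nodes <- rbind(circuit$nodes[, .circuit_node_cols], new_nodes)
  new_edges <- do.call(rbind, lapply(seq_len(nrow(regulators)), function(i) {
    data.frame(source = regulators$gene_id[i], target = resolved[[i]],
               edge_type = "regulator", fork_ids = "",
               cor_control = NA_real_, cor_treatment = NA_real_,
               relation = regulators$relation[i], stringsAsFactors = FALSE)
  }))
  edges <- rbind(circuit$edges[, .circuit_edge_cols], new_edges)
  edges <- edges[!duplicated(edges[, c("source", "target", "relation")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new_circuit(nodes, edges, circuit$forks)
}

#' Per-component summary of a circuit
#'
#' @param circuit a `circuit_graph`.
#' @return Data frame: one row per connected component with node/fork
#'   counts and the member list.
#' @export
circuit_components <- function(circuit) {
  comp <- circuit$nodes$component
  if (length(comp) == 0)
    return(data.frame(component = integer(0), n_nodes = integer(0),
                      n_forks = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  by_comp <- split(circuit$nodes$feature_id,
                   factor(comp, levels = sort(unique(comp))))
  fork_comp <- comp[match(circuit$forks$A, circuit$nodes$feature_id)]
  data.frame(
    component = as.integer(names(by_comp)),
    n_nodes = lengths(by_comp),
    n_forks = as.integer(table(factor(fork_comp,
                                      levels = names(by_comp)))),
    members = vapply(by_comp, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)
}
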