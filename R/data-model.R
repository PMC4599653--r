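#' Construct an expression dataset for one disease
#'
#' Bundles a genes-by-samples matrix of normalized intensities with
#' per-sample condition labels. Values are assumed already normalized
#' (e.g. MAS5); the package never renormalizes.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). Entries must be
#'   non-negative and finite.
#' @param condition Character vector of per-sample labels, either named by
#'   sample id or in column order; every entry must be `"disease"` or
#'   `"normal"`.
#' @param disease_id,tissue Identifiers for the disease and the assayed
#'   tissue.
#' @param min_samples_per_condition Minimum number of samples required in
#'   each condition (default 6, i.e. more than five).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, condition, disease_id, tissue = "unknown",
                               min_samples_per_condition = 6L) {
  stopifnot(is.matrix(values), is.numeric(values))
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix must carry gene rownames and sample colnames")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (!is.null(names(condition))) {
    missing <- setdiff(sample_ids, names(condition))
    if (length(missing))
      stop("sample(s) without a condition label: ", paste(missing, collapse = ", "))
    condition <- condition[sample_ids]
  } else if (length(condition) != ncol(values)) {
    stop("condition must be named by sample id or have one entry per sample")
  }
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), c("disease", "normal"))
  if (length(bad))
    stop("condition labels must be 'disease' or 'normal', got: ",
         paste(bad, collapse = ", "))
  names(condition) <- sample_ids
  for (cond in c("disease", "normal")) {
    n <- sum(condition == cond)
    if (n < min_samples_per_condition)
      stop(sprintf("condition '%s' has %d samples; at least %d required",
                   cond, n, min_samples_per_condition))
  }
  structure(
    list(disease_id = as.character(disease_id), tissue = as.character(tissue),
         values = values, condition = condition),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("<ExpressionDataset> %s [%s]: %d genes x %d samples (%d disease / %d normal)\n",
              x$disease_id, x$tissue, nrow(x$values), ncol(x$values),
              sum(x$condition == "disease"), sum(x$condition == "normal")))
  invisible(x)
}

#' Construct a pathway collection
#'
#' A named list of gene sets together with the bipartite gene-to-pathway
#' membership structure implied by them.
#'
#' @param sets Named list of character vectors (pathway id -> member genes).
#'   Genes are deduplicated within each set.
#' @param provenance Free-text origin of the collection.
#' @return An object of class `PathwayCollection`.
#' @export
pathway_collection <- function(sets, provenance = "unspecified") {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every pathway needs a non-empty id")
    if (anyDuplicated(names(sets)))
      stop("duplicate pathway id(s): ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) < 1L))
    stop("pathway sizes must be >= 1")
  structure(list(sets = sets, provenance = provenance),
            class = "PathwayCollection")
}

#' Number of pathways each gene belongs to
#'
#' @param pathways A `PathwayCollection`.
#' @return Named integer vector over the collection's gene universe.
#' @export
membership_degree <- function(pathways) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  tab <- table(unlist(pathways$sets, use.names = FALSE))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Gene universe of a pathway collection
#' @param pathways A `PathwayCollection`.
#' @return Character vector of all genes appearing in any set.
#' @export
pathway_universe <- function(pathways) {
  sort(unique(unlist(pathways$sets, use.names = FALSE)))
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("<PathwayCollection> %d pathways over %d genes (%s)\n",
              length(x$sets), length(pathway_universe(x)), x$provenance))
  invisible(x)
}

#' Construct a disease-to-item association table
#'
#' Maps diseases to sets of associated items (known disease genes or
#' approved drugs); the universe is the union of items across diseases
#' unless given explicitly.
#'
#' @param sets Named list of character vectors (disease id -> items).
#' @param kind `"gene"` or `"drug"`.
#' @param universe Optional superset of all items; defaults to the union.
#' @return An object of class `AssociationTable`.
#' @export
association_table <- function(sets, kind = c("gene", "drug"), universe = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(sets))
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("disease ids must be non-empty strings")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  all_items <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(all_items)
  } else {
    universe <- sort(unique(as.character(universe)))
    stray <- setdiff(all_items, universe)
    if (length(stray))
      stop("item(s) outside the declared universe: ",
           paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(kind = kind, sets = sets, universe = universe),
            class = "AssociationTable")
}

#' Construct a disease category annotation
#'
#' @param sets Named list of character vectors (disease id -> category
#'   labels under one taxonomy). Multi-membership is allowed; a disease may
#'   carry zero labels.
#' @param taxonomy Taxonomy name (e.g. "MeSH", "ICD-10", "DO").
#' @return An object of class `CategoryAnnotation`.
#' @export
category_annotation <- function(sets, taxonomy = "unspecified") {
  stopifnot(is.list(sets))
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("disease ids must be non-empty strings")
  sets <- lapply(sets, function(x) {
    x <- unique(as.character(x))
    if (any(!nzchar(x))) stop("category labels must be non-empty")
    x
  })
  structure(list(taxonomy = taxonomy, sets = sets),
            class = "CategoryAnnotation")
}

#' Construct a disease-disease similarity network
#'
#' Signed, weighted, undirected graph over diseases: each edge carries the
#' partial Spearman coefficient, its permutation p-value, the BH q-value,
#' and the edge sign.
#'
#' @param nodes Character vector of disease ids (includes isolated nodes).
#' @param edges Data frame with columns `disease_a`, `disease_b`, `rho`,
#'   `p`, `q`. Pairs are stored lexicographically ordered.
#' @param p_threshold The construction threshold every edge satisfies.
#' @return An object of class `DiseaseNetwork`.
#' @export
disease_network <- function(nodes, edges, p_threshold = 0.05) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node id(s)")
  need <- c("disease_a", "disease_b", "rho", "p", "q")
  if (!all(need %in% names(edges)))
    stop("edges must have columns: ", paste(need, collapse = ", "))
  edges <- as.data.frame(edges)[, need, drop = FALSE]
  if (nrow(edges)) {
    if (any(edges$disease_a == edges$disease_b)) stop("self-loops are not allowed")
    stray <- setdiff(c(edges$disease_a, edges$disease_b), nodes)
    if (length(stray)) stop("edge endpoint(s) not in nodes: ",
                            paste(stray, collapse = ", "))
    if (any(abs(edges$rho) > 1)) stop("|rho| must be <= 1")
    if (any(edges$p <= 0 | edges$p > 1)) stop("edge p-values must lie in (0, 1]")
    if (any(edges$p > p_threshold))
      stop("every edge must satisfy the construction threshold")
    # canonical lexicographic pair order, then sort rows
    flip <- edges$disease_a > edges$disease_b
    tmp <- edges$disease_a[flip]
    edges$disease_a[flip] <- edges$disease_b[flip]
    edges$disease_b[flip] <- tmp
    if (anyDuplicated(edges[, c("disease_a", "disease_b")]))
      stop("duplicate edge(s)")
    edges <- edges[order(edges$disease_a, edges$disease_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  structure(list(nodes = nodes, edges = edges, p_threshold = p_threshold),
            class = "DiseaseNetwork")
}

#' @export
print.DiseaseNetwork <- function(x, ...) {
  cat(sprintf("<DiseaseNetwork> %d diseases, %d links (p < %g; %d negative)\n",
              length(x$nodes), nrow(x$edges), x$p_threshold,
              sum(x$edges$sign == "negative")))
  invisible(x)
}

# igraph view of a DiseaseNetwork (all nodes kept, incl. isolated ones)
as_igraph <- function(network) {
  stopifnot(inherits(network, "DiseaseNetwork"))
  igraph::graph_from_data_frame(
    network$edges[, c("disease_a", "disease_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes))
}
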