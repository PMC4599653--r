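#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' the body must be numeric.
#'
#' @param path TSV file path.
#' @param disease_id,tissue Dataset identifiers.
#' @param labels Named character vector mapping every sample id to
#'   `"disease"` or `"normal"`.
#' @param min_samples_per_condition Passed to [expression_dataset()].
#' @return An `ExpressionDataset`.
#' @export
read_expression_tsv <- function(path, disease_id, tissue = "unknown", labels,
                                min_samples_per_condition = 6L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus sample columns")
  gene_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- gene_ids[apply(is.na(num) & !is.na(as.matrix(body)), 1, any) |
                    apply(is.na(as.matrix(body)), 1, any)]
  if (length(bad))
    stop("non-numeric entries in row(s): ", paste(unique(bad), collapse = ", "))
  rownames(num) <- gene_ids
  expression_dataset(num, labels, disease_id = disease_id, tissue = tissue,
                     min_samples_per_condition = min_samples_per_condition)
}

#' Write an expression dataset to TSV
#'
#' Inverse of [read_expression_tsv()]; condition labels are not stored in
#' the matrix file and must be carried separately.
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Output file path.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(gene = rownames(dataset$values), dataset$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard dialect: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Genes listed twice within one pathway are counted once.
#'
#' @param path GMT file path.
#' @param provenance Recorded origin string (defaults to the file path).
#' @return A `PathwayCollection`.
#' @export
read_gmt <- function(path, provenance = path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(pathway_collection(list(), provenance = provenance))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  pathway_collection(sets, provenance = provenance)
}

#' Write a pathway collection in GMT format
#' @param pathways A `PathwayCollection`.
#' @param path Output file path.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "PathwayCollection"))
  lines <- vapply(names(pathways$sets), function(id) {
    paste(c(id, "na", pathways$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column disease-to-item TSV
#'
#' One row per (disease, item) pair; a header row `disease_id<TAB>item` is
#' accepted and skipped.
#'
#' @param path TSV file path.
#' @param kind `"gene"` or `"drug"`.
#' @return An `AssociationTable`.
#' @export
read_association_tsv <- function(path, kind = c("gene", "drug")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("association TSV needs two columns")
  if (nrow(df) && identical(tolower(df[1, 1]), "disease_id")) df <- df[-1, , drop = FALSE]
  association_table(split(df[[2]], df[[1]]), kind = kind)
}

#' Read a two-column disease-to-category TSV
#' @param path TSV file path.
#' @param taxonomy Taxonomy name recorded on the annotation.
#' @return A `CategoryAnnotation`.
#' @export
read_category_tsv <- function(path, taxonomy = "unspecified") {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("category TSV needs two columns")
  if (nrow(df) && identical(tolower(df[1, 1]), "disease_id")) df <- df[-1, , drop = FALSE]
  category_annotation(split(df[[2]], df[[1]]), taxonomy = taxonomy)
}

#' Write a disease network as an edge-list TSV
#'
#' Columns `disease_a, disease_b, rho, p, q, sign`; one row per edge with
#' lexicographically ordered pairs for deterministic diffs.
#'
#' @param network A `DiseaseNetwork`.
#' @param path Output file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "DiseaseNetwork"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV written by [write_edge_list()]
#'
#' @param path TSV file path.
#' @param nodes Optional full node set (to retain isolated diseases);
#'   defaults to the union of edge endpoints.
#' @param p_threshold Construction threshold of the stored network.
#' @return A `DiseaseNetwork`.
#' @export
read_edge_list <- function(path, nodes = NULL, p_threshold = 0.05) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$disease_a, df$disease_b)))
  disease_network(nodes, df[, c("disease_a", "disease_b", "rho", "p", "q")],
                  p_threshold = p_threshold)
}

#' Merge expression datasets that study the same disease in the same tissue
#'
#' Datasets sharing a (disease, tissue) key are concatenated sample-wise on
#' the intersection of their gene vocabularies; sample ids are
#' disambiguated with a source prefix. Diseases assayed in more than one
#' tissue are renamed `"disease - tissue"` so each tissue context becomes
#' its own node downstream. No batch correction is applied (a warning
#' notes multi-source merges).
#'
#' @param datasets List of `ExpressionDataset` objects.
#' @param min_samples_per_condition Required per-condition depth of every
#'   merged dataset.
#' @return List of merged `ExpressionDataset` objects, one per
#'   (disease, tissue) key, ordered by key.
#' @export
merge_by_disease_tissue <- function(datasets, min_samples_per_condition = 6L) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "ExpressionDataset")))
  keys <- vapply(datasets, function(d) paste(d$disease_id, d$tissue, sep = "\r"),
                 character(1))
  diseases <- vapply(datasets, `[[`, character(1), "disease_id")
  multi_tissue <- names(which(vapply(
    split(vapply(datasets, `[[`, character(1), "tissue"), diseases),
    function(t) length(unique(t)) > 1L, logical(1))))
  groups <- split(seq_along(datasets), keys)
  out <- lapply(groups[order(names(groups))], function(idx) {
    ds <- datasets[idx]
    first <- ds[[1]]
    genes <- Reduce(intersect, lapply(ds, function(d) rownames(d$values)))
    if (!length(genes))
      stop(sprintf("merge for '%s' [%s]: empty gene intersection",
                   first$disease_id, first$tissue))
    if (length(ds) > 1L) {
      warning(sprintf("merging %d sources for '%s' [%s] without batch correction",
                      length(ds), first$disease_id, first$tissue))
      mats <- lapply(seq_along(ds), function(i) {
        m <- ds[[i]]$values[genes, , drop = FALSE]
        colnames(m) <- paste0("src", i, ".", colnames(m))
        m
      })
      values <- do.call(cbind, mats)
      condition <- unlist(lapply(seq_along(ds), function(i) {
        cc <- ds[[i]]$condition
        names(cc) <- paste0("src", i, ".", names(cc))
        cc
      }))
    } else {
      values <- first$values[genes, , drop = FALSE]
      condition <- first$condition
    }
    disease_id <- if (first$disease_id %in% multi_tissue)
      paste(first$disease_id, first$tissue, sep = " - ") else first$disease_id
    expression_dataset(values, condition, disease_id = disease_id,
                       tissue = first$tissue,
                       min_samples_per_condition = min_samples_per_condition)
  })
  names(out) <- vapply(out, `[[`, character(1), "disease_id")
  out
}
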