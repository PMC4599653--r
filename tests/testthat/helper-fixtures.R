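# Shared fixtures: small deterministic objects built in code.

# tiny labelled expression dataset: `genes` x (2 * samples_per_condition)
make_toy_dataset <- function(n_genes = 10, spc = 6, seed = 1,
                             disease_id = "toy", tissue = "tissue") {
  set.seed(seed)
  values <- matrix(stats::runif(n_genes * 2 * spc, 10, 100), nrow = n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(2 * spc))))
  condition <- stats::setNames(rep(c("disease", "normal"), each = spc),
                               colnames(values))
  expression_dataset(values, condition, disease_id = disease_id,
                     tissue = tissue, min_samples_per_condition = min(6, spc))
}

# CoexpressionPair built directly from two symmetric matrices
make_coex_pair <- function(R_disease, R_normal) {
  genes <- rownames(R_disease)
  structure(list(gene_ids = genes, R_disease = R_disease,
                 R_normal = R_normal, flagged = character(0)),
            class = "CoexpressionPair")
}

sym_matrix <- function(genes, fill = 0) {
  m <- matrix(fill, length(genes), length(genes),
              dimnames = list(genes, genes))
  diag(m) <- 1
  m
}

# the synthetic study conditions used by the end-to-end checks: two groups
# of four diseases with strong, group-aligned pathway decoupling
study_config <- function(seed, decoupling = 1.0) {
  cohort_config(n_diseases = 8, n_groups = 2, n_genes = 400, n_pathways = 40,
                pathway_size_range = c(8, 15), samples_per_condition = 50,
                dysregulated_pathways_per_disease = 16,
                within_group_overlap = 0.8,
                decoupling_strength = decoupling,
                base_correlation = 0.7, loading_jitter_sd = 0.4, seed = seed)
}

# neighbor percentile used with the 400-gene study cohorts (the top-25%
# default is tuned to genome-scale universes; see the methods vignette)
STUDY_Q <- 0.95
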