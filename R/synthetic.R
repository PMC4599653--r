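#' Configuration for a synthetic multi-disease cohort
#'
#' Defines the study conditions a simulated cohort emulates: several
#' diseases organised into groups, pathway-structured coexpression in the
#' normal condition, and planted decoupling of that coexpression in each
#' disease's dysregulated pathways, with per-gene means unchanged between
#' conditions (differential coexpression without differential expression).
#'
#' @param n_diseases Number of diseases in the cohort.
#' @param n_groups Number of disease groups (must not exceed `n_diseases`).
#' @param n_genes Size of the gene universe.
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Integer pair `(min, max)` of pathway sizes
#'   (each >= 2).
#' @param samples_per_condition Samples per condition per disease.
#' @param dysregulated_pathways_per_disease Number of pathways decoupled in
#'   each disease.
#' @param within_group_overlap Fraction in `[0, 1]` of a disease's
#'   dysregulated pathways drawn from its group's shared core.
#' @param decoupling_strength Fraction in `[0, 1]` scaling how much of a
#'   dysregulated pathway's shared factor signal is removed in the disease
#'   condition (0 = no signal planted anywhere, 1 = pathway-specific
#'   depths up to full decorrelation).
#' @param base_correlation Target pairwise Pearson correlation, in (0, 1),
#'   among co-pathway genes in the normal condition.
#' @param noise_sd Standard deviation of each gene's independent noise, in
#'   intensity units.
#' @param loading_jitter_sd Standard deviation of the per-gene,
#'   per-condition multiplicative jitter on factor loadings (gene-level
#'   idiosyncrasy in how strongly a gene couples to its block).
#' @param items_per_disease Number of associated genes/drugs per disease in
#'   the planted association tables.
#' @param seed Master seed; all randomness flows from it through
#'   per-disease substreams.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_diseases = 8L, n_groups = 2L, n_genes = 200L,
                          n_pathways = 30L, pathway_size_range = c(8L, 15L),
                          samples_per_condition = 30L,
                          dysregulated_pathways_per_disease = 5L,
                          within_group_overlap = 0.8,
                          decoupling_strength = 1.0,
                          base_correlation = 0.7, noise_sd = 1.0,
                          loading_jitter_sd = 0.2,
                          items_per_disease = 10L, seed = 1L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_groups = as.integer(n_groups),
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              samples_per_condition = as.integer(samples_per_condition),
              dysregulated_pathways_per_disease =
                as.integer(dysregulated_pathways_per_disease),
              within_group_overlap = within_group_overlap,
              decoupling_strength = decoupling_strength,
              base_correlation = base_correlation,
              noise_sd = noise_sd,
              loading_jitter_sd = loading_jitter_sd,
              items_per_disease = as.integer(items_per_disease),
              seed = as.integer(seed))
  if (cfg$n_groups > cfg$n_diseases) stop("n_groups must not exceed n_diseases")
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2])
    stop("pathway_size_range must be an ordered pair")
  if (cfg$pathway_size_range[1] < 2L) stop("pathway sizes must be >= 2")
  if (cfg$within_group_overlap < 0 || cfg$within_group_overlap > 1)
    stop("within_group_overlap must lie in [0, 1]")
  if (cfg$decoupling_strength < 0 || cfg$decoupling_strength > 1)
    stop("decoupling_strength must lie in [0, 1]")
  if (cfg$base_correlation <= 0 || cfg$base_correlation >= 1)
    stop("base_correlation must lie in (0, 1)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$loading_jitter_sd < 0) stop("loading_jitter_sd must be non-negative")
  if (cfg$dysregulated_pathways_per_disease > cfg$n_pathways)
    stop("dysregulated_pathways_per_disease must not exceed n_pathways")
  if (cfg$samples_per_condition < 3L) stop("samples_per_condition must be >= 3")
  class(cfg) <- "CohortConfig"
  cfg
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive named 32-bit substream seeds from a master seed
substream_seeds <- function(seed, n, tag) {
  with_seed(seed + 0L, {
    # burn a tag-specific offset so different stages decouple
    offset <- sum(utf8ToInt(tag)) %% 1000L
    s <- sample.int(.Machine$integer.max - 1000L, n + offset)
    s[(offset + 1L):(offset + n)]
  })
}

#' Generate a random pathway collection covering the gene universe
#'
#' Built in two layers. First a balanced "home" partition assigns every
#' gene to exactly one pathway, so the collection covers the universe
#' (each pathway's home members are the coexpression block that decouples
#' when the pathway is dysregulated). Then each pathway is topped up with
#' "guest" genes drawn from the rest of the universe until it reaches a
#' size sampled from `pathway_size_range`, which puts a tunable fraction
#' of genes into two or more pathways and keeps the membership
#' permutation null non-trivial.
#'
#' @param config A `CohortConfig`.
#' @return A `PathwayCollection` over genes `g0001, g0002, ...`; the home
#'   assignment is attached as attribute `home` (named character vector
#'   gene -> pathway id).
#' @export
generate_pathways <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  if (config$n_genes < config$pathway_size_range[2])
    stop("pathway size range infeasible: max size exceeds n_genes")
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  np <- config$n_pathways
  pw_ids <- sprintf("pw%03d", seq_len(np))
  with_seed(substream_seeds(config$seed, 1L, "pathways"), {
    homes <- split(sample(genes),
                   factor(rep_len(seq_len(np), length(genes)),
                          levels = seq_len(np)))
    names(homes) <- pw_ids
    if (max(lengths(homes)) > config$pathway_size_range[2])
      stop("pathway size range infeasible: n_pathways * max size cannot cover n_genes")
    size_range <- seq(config$pathway_size_range[1],
                      config$pathway_size_range[2])
    sizes <- pmax(size_range[sample.int(length(size_range), np,
                                        replace = TRUE)],
                  lengths(homes))
    sets <- lapply(seq_len(np), function(i) {
      guests <- sample(setdiff(genes, homes[[i]]), sizes[i] - length(homes[[i]]))
      c(homes[[i]], guests)
    })
    names(sets) <- pw_ids
    out <- pathway_collection(sets, provenance = "synthetic")
    attr(out, "home") <- stats::setNames(
      rep(pw_ids, lengths(homes)), unlist(homes, use.names = FALSE))[genes]
    out
  })
}

# sample one disease's two-condition expression matrix under the
# single-factor-per-pathway model; `depth` maps each dysregulated pathway
# to its decoupling depth in [0, 1]
simulate_disease_expression <- function(genes, factor_of_gene, depth,
                                        config, seed, disease_id, tissue) {
  r <- config$base_correlation
  s <- config$noise_sd
  a <- s * sqrt(r / (1 - r))            # loading giving corr a^2/(a^2+s^2) = r
  n <- config$samples_per_condition
  with_seed(seed, {
    mu <- stats::runif(length(genes), 50, 500)
    names(mu) <- genes
    pws <- unique(stats::na.omit(factor_of_gene))
    make_cond <- function(decouple) {
      fac <- matrix(stats::rnorm(length(pws) * n), length(pws), n,
                    dimnames = list(pws, NULL))
      eps <- matrix(stats::rnorm(length(genes) * n, sd = s), length(genes), n)
      # per-gene, per-condition loading heterogeneity: individual genes
      # couple to their block with varying strength in each condition, the
      # gene-level idiosyncrasy real cohorts show
      lam <- pmax(0.2, 1 + stats::rnorm(length(genes), sd = config$loading_jitter_sd))
      x <- mu + eps
      for (g in seq_along(genes)) {
        p <- factor_of_gene[[g]]
        if (is.na(p)) next
        ds <- if (decouple && !is.na(depth[p])) depth[[p]] else 0
        if (ds > 0) {
          # per-gene response depth within a perturbed pathway; attenuate the
          # shared signal and replace it with private noise so the marginal
          # variance (and mean) is unchanged
          ds <- ds * stats::runif(1, 0.5, 1)
          x[g, ] <- x[g, ] + a * lam[g] * (sqrt(1 - ds) * fac[p, ] +
            sqrt(ds) * stats::rnorm(n))
        } else {
          x[g, ] <- x[g, ] + a * lam[g] * fac[p, ]
        }
      }
      x
    }
    normal <- make_cond(decouple = FALSE)
    disease <- make_cond(decouple = TRUE)
    values <- cbind(disease, normal)
    values[values < 0.01] <- 0.01
    rownames(values) <- genes
    colnames(values) <- c(sprintf("%s.d%02d", disease_id, seq_len(n)),
                          sprintf("%s.n%02d", disease_id, seq_len(n)))
    condition <- setNames(rep(c("disease", "normal"), each = n),
                          colnames(values))
    expression_dataset(values, condition, disease_id = disease_id,
                       tissue = tissue,
                       min_samples_per_condition = min(6L, n))
  })
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' For each disease, normal-condition samples follow a latent-factor model
#' in which each pathway's members load on one shared factor (pairwise
#' correlation about `base_correlation`); disease-condition samples are
#' identical in marginal distribution except that in the disease's
#' dysregulated pathways part of the shared signal is replaced by private
#' noise, so member correlations drop toward zero while per-gene means are
#' untouched. Each dysregulated pathway carries its own perturbation
#' depth, drawn uniformly in `[0.3, 1]` and scaled by
#' `decoupling_strength`; core pathways share both identity and depth
#' within a disease group (per `within_group_overlap`), so pathway-level
#' differential coexpression spreads over a continuous, group-aligned
#' range rather than being all-or-nothing. Genes belonging to several pathways take the
#' factor of their home pathway (the covering partition of
#' [generate_pathways()]), so each pathway's decoupling acts on its home
#' members while guest members keep their own block's coexpression.
#'
#' @param config A `CohortConfig`.
#' @return A list with elements `datasets` (list of `ExpressionDataset`),
#'   `pathways` (`PathwayCollection`), and `truth` (list with
#'   `group_of_disease`, `dysregulated`, `depths` (per-disease pathway
#'   perturbation depths), `factor_of_gene`, and planted association
#'   tables `gene_assoc`, `drug_assoc`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  pathways <- generate_pathways(config)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  factor_of_gene <- attr(pathways, "home")
  disease_ids <- sprintf("disease%02d", seq_len(config$n_diseases))
  groups <- setNames(rep(seq_len(config$n_groups),
                         length.out = config$n_diseases), disease_ids)
  n_dys <- config$dysregulated_pathways_per_disease
  n_core <- round(config$within_group_overlap * n_dys)
  pw_ids <- names(pathways$sets)
  core_seed <- substream_seeds(config$seed, 1L, "cores")
  # each group's core pathways carry group-shared perturbation depths, so
  # same-group diseases decouple the same pathways to similar degrees
  cores <- with_seed(core_seed, {
    lapply(seq_len(config$n_groups), function(g) {
      ids <- sample(pw_ids, n_core)
      stats::setNames(stats::runif(n_core, 0.3, 1), ids)
    })
  })
  dys_seeds <- substream_seeds(config$seed, config$n_diseases, "dysregulation")
  depths <- lapply(seq_len(config$n_diseases), function(i) {
    with_seed(dys_seeds[i], {
      core <- cores[[groups[i]]]
      extra_ids <- sample(setdiff(pw_ids, names(core)), n_dys - length(core))
      d <- c(core, stats::setNames(stats::runif(length(extra_ids), 0.3, 1),
                                   extra_ids))
      d[sort(names(d))] * config$decoupling_strength
    })
  })
  names(depths) <- disease_ids
  dysregulated <- lapply(depths, function(d) names(d)[d > 0])
  expr_seeds <- substream_seeds(config$seed, config$n_diseases, "expression")
  datasets <- lapply(seq_len(config$n_diseases), function(i) {
    depth_map <- stats::setNames(rep(NA_real_, length(pw_ids)), pw_ids)
    depth_map[names(depths[[i]])] <- depths[[i]]
    simulate_disease_expression(genes, factor_of_gene, depth_map,
                                config, expr_seeds[i], disease_ids[i],
                                tissue = sprintf("tissue%02d", groups[i]))
  })
  names(datasets) <- disease_ids
  truth <- list(group_of_disease = groups, dysregulated = dysregulated,
                depths = depths, factor_of_gene = factor_of_gene)
  assoc <- generate_associations(truth, config)
  truth$gene_assoc <- assoc$gene
  truth$drug_assoc <- assoc$drug
  list(datasets = datasets, pathways = pathways, truth = truth)
}

#' Generate planted disease-gene and disease-drug association tables
#'
#' Each group holds a core item set of size
#' `round(within_group_overlap * items_per_disease)`; every disease takes
#' its group's core plus disease-specific items sampled from the rest of
#' the universe, so within-group pairs share more items than between-group
#' pairs in expectation (and exactly the random baseline at overlap 0).
#'
#' @param truth Ground-truth list with `group_of_disease` (as produced by
#'   [generate_cohort()]).
#' @param config A `CohortConfig`.
#' @return List with `gene` and `drug` `AssociationTable`s.
#' @export
generate_associations <- function(truth, config) {
  stopifnot(inherits(config, "CohortConfig"))
  groups <- truth$group_of_disease
  make_table <- function(universe, kind, tag) {
    n_core <- round(config$within_group_overlap * config$items_per_disease)
    core_seed <- substream_seeds(config$seed, 1L, paste0(tag, "-cores"))
    cores <- with_seed(core_seed, {
      lapply(seq_len(config$n_groups), function(g) sample(universe, n_core))
    })
    seeds <- substream_seeds(config$seed, length(groups), tag)
    sets <- lapply(seq_along(groups), function(i) {
      with_seed(seeds[i], {
        core <- cores[[groups[i]]]
        extra <- sample(setdiff(universe, core),
                        config$items_per_disease - length(core))
        sort(c(core, extra))
      })
    })
    names(sets) <- names(groups)
    association_table(sets, kind = kind, universe = universe)
  }
  gene_universe <- sprintf("g%04d", seq_len(config$n_genes))
  drug_universe <- sprintf("drug%03d", seq_len(max(50L, 5L * config$items_per_disease)))
  list(gene = make_table(gene_universe, "gene", "assoc-genes"),
       drug = make_table(drug_universe, "drug", "assoc-drugs"))
}

#' Write a synthetic cohort as a fixture directory
#'
#' Emits the same formats the readers consume: one expression TSV and one
#' label TSV per disease, a GMT file, association TSVs, and a ground-truth
#' JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in cohort$datasets) {
    write_expression_tsv(d, file.path(dir, paste0(d$disease_id, ".expr.tsv")))
    utils::write.table(
      data.frame(sample_id = names(d$condition), condition = d$condition),
      file.path(dir, paste0(d$disease_id, ".labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(cohort$pathways, file.path(dir, "pathways.gmt"))
  assoc_df <- function(tab) data.frame(
    disease_id = rep(names(tab$sets), lengths(tab$sets)),
    item = unlist(tab$sets, use.names = FALSE))
  utils::write.table(assoc_df(cohort$truth$gene_assoc),
                     file.path(dir, "disease_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(assoc_df(cohort$truth$drug_assoc),
                     file.path(dir, "disease_drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(group_of_disease = as.list(cohort$truth$group_of_disease),
         dysregulated = cohort$truth$dysregulated),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
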