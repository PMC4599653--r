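test_that("condition-wise Pearson correlation handles exact and degenerate cases", {
  spc <- 5
  values <- matrix(0, 3, 2 * spc,
                   dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:10)))
  set.seed(1)
  values["A", ] <- runif(10, 1, 5)
  values["B", ] <- 2 * values["A", ]
  values["C", ] <- 10 - values["A", ]
  cond <- stats::setNames(rep(c("disease", "normal"), each = spc),
                          colnames(values))
  ds <- expression_dataset(values, cond, "toy", min_samples_per_condition = 5)
  r <- pairwise_correlation(ds, "disease")
  expect_equal(r["A", "B"], 1)
  expect_equal(r["A", "C"], -1)
  expect_equal(diag(r), c(A = 1, B = 1, C = 1))

  # constant gene: zeroed row/column plus a warning
  values["C", ] <- 7
  ds2 <- expression_dataset(values, cond, "toy", min_samples_per_condition = 5)
  expect_warning(r2 <- pairwise_correlation(ds2, "disease"), "zero-variance")
  expect_true(all(r2["C", c("A", "B")] == 0))
  expect_identical(attr(r2, "flagged"), "C")

  # fewer than 3 samples in a condition is an error
  cond3 <- stats::setNames(rep(c("disease", "normal"), c(2, 8)),
                           colnames(values))
  ds3 <- expression_dataset(values, cond3, "toy",
                            min_samples_per_condition = 2)
  expect_error(pairwise_correlation(ds3, "disease"), "2 samples")
})

test_that("neighbor sets follow the per-condition percentile rule", {
  genes <- c("A", "B", "C", "D")
  rd <- sym_matrix(genes)
  rd["A", "B"] <- rd["B", "A"] <- 0.95
  rd["C", "D"] <- rd["D", "C"] <- 0.30
  rd["A", "C"] <- rd["C", "A"] <- 0.10
  rn <- rd
  coex <- make_coex_pair(rd, rn)
  expect_error(neighbor_sets(coex, q = 0), "q must")
  expect_error(neighbor_sets(coex, q = 1.2), "q must")

  # a threshold below every |r| makes everyone everyone's neighbor
  nb <- neighbor_sets(coex, q = 1e-6)
  expect_true(all(lengths(nb) == 3))

  # a high percentile keeps only the dominant pair mutually neighbored
  nb99 <- neighbor_sets(coex, q = 0.99)
  expect_identical(nb99$A, "B")
  expect_identical(nb99$B, "A")
  expect_length(nb99$C, 0)

  # a gene with an empty neighbor set is excluded with a warning
  expect_warning(prof <- compute_dC(coex, nb99), "empty neighbor")
  expect_setequal(prof$gene, c("A", "B"))
})

test_that("dC equals the root-mean-square profile change", {
  genes <- c("A", "B", "C", "D")
  rd <- sym_matrix(genes); rn <- sym_matrix(genes)
  rd["A", c("B", "C", "D")] <- rd[c("B", "C", "D"), "A"] <- c(1, 0, -1)
  rn["A", c("B", "C", "D")] <- rn[c("B", "C", "D"), "A"] <- c(-1, 0, 1)
  coex <- make_coex_pair(rd, rn)
  nb <- list(A = c("B", "C", "D"))
  prof <- compute_dC(coex, nb)
  expect_equal(prof$dC, sqrt(8 / 3), tolerance = 1e-12)

  # identical profiles give exactly zero
  prof0 <- compute_dC(make_coex_pair(rd, rd), nb)
  expect_identical(prof0$dC, 0)

  # the upper bound 2 is attained at full sign reversal
  rd2 <- sym_matrix(c("A", "B", "C"))
  rn2 <- sym_matrix(c("A", "B", "C"))
  rd2["A", c("B", "C")] <- rd2[c("B", "C"), "A"] <- 1
  rn2["A", c("B", "C")] <- rn2[c("B", "C"), "A"] <- -1
  prof2 <- compute_dC(make_coex_pair(rd2, rn2), list(A = c("B", "C")))
  expect_equal(prof2$dC, 2)
})

test_that("dC is invariant to neighbor order and condition relabeling", {
  set.seed(42)
  genes <- sprintf("g%02d", 1:8)
  for (rep in 1:20) {
    rd <- sym_matrix(genes); rn <- sym_matrix(genes)
    rd[upper.tri(rd)] <- runif(sum(upper.tri(rd)), -1, 1)
    rn[upper.tri(rn)] <- runif(sum(upper.tri(rn)), -1, 1)
    rd[lower.tri(rd)] <- t(rd)[lower.tri(rd)]
    rn[lower.tri(rn)] <- t(rn)[lower.tri(rn)]
    nbg <- sample(genes[-1], 5)
    prof <- compute_dC(make_coex_pair(rd, rn), list(g01 = nbg))
    prof_perm <- compute_dC(make_coex_pair(rd, rn), list(g01 = sample(nbg)))
    prof_swap <- compute_dC(make_coex_pair(rn, rd), list(g01 = nbg))
    # brute-force Euclidean distance oracle
    d <- sqrt(sum((rd["g01", nbg] - rn["g01", nbg])^2))
    expect_equal(prof$dC, d / sqrt(5), tolerance = 1e-12)
    expect_equal(prof_perm$dC, prof$dC, tolerance = 1e-12)
    expect_equal(prof_swap$dC, prof$dC, tolerance = 1e-12)
  }
})

test_that("dC permutation significance recovers planted genes and is smoothed", {
  expect_error(dcg_significance(make_toy_dataset(), reps = 50), ">= 100")
  recovered <- c(); background <- c()
  for (seed in c(5, 7)) {
    cfg <- cohort_config(n_diseases = 2, n_groups = 1, n_genes = 60,
                         n_pathways = 6, pathway_size_range = c(10, 12),
                         samples_per_condition = 40,
                         dysregulated_pathways_per_disease = 2,
                         within_group_overlap = 1, decoupling_strength = 1,
                         seed = seed)
    coh <- generate_cohort(cfg)
    planted <- names(coh$truth$factor_of_gene)[
      coh$truth$factor_of_gene %in% coh$truth$dysregulated[[1]]]
    res <- suppressWarnings(
      dcg_significance(coh$datasets[[1]], q = 0.9, reps = 200, seed = seed))
    expect_true(all(res$p >= 1 / 201) && all(res$p <= 1))
    recovered <- c(recovered, mean(res$p[res$gene %in% planted] < 0.05))
    background <- c(background, mean(res$p[!res$gene %in% planted] < 0.05))
    # genes whose observed dC beats every permutation get the smoothed minimum
    if (any(res$p == 1 / 201)) expect_true(min(res$p) == 1 / 201)
  }
  expect_true(all(recovered > 0.5))
  expect_lt(mean(background), 0.25)
})

test_that("DCL classification matches the worked correlation changes", {
  genes <- c("TGFBI", "FZD8", "GHR")
  rd <- sym_matrix(genes); rn <- sym_matrix(genes)
  # positive correlation in normal reversed to negative in disease
  rn["TGFBI", "FZD8"] <- rn["FZD8", "TGFBI"] <- 0.63
  rd["TGFBI", "FZD8"] <- rd["FZD8", "TGFBI"] <- -0.86
  # negative correlation in normal disappearing in disease
  rn["GHR", "FZD8"] <- rn["FZD8", "GHR"] <- -0.69
  rd["GHR", "FZD8"] <- rd["FZD8", "GHR"] <- 0.05
  coex <- make_coex_pair(rd, rn)

  dcls <- identify_dcls(coex, rc = 0.6, dr = 0.8)
  rev_row <- dcls[dcls$gene_a == "FZD8" & dcls$gene_b == "TGFBI", ]
  expect_identical(rev_row$class, "reversal")

  dcls2 <- identify_dcls(coex, rc = 0.6, dr = 0.5)
  loss_row <- dcls2[dcls2$gene_a == "FZD8" & dcls2$gene_b == "GHR", ]
  expect_identical(loss_row$class, "loss")

  # below both thresholds: not a DCL
  rn["TGFBI", "GHR"] <- rn["GHR", "TGFBI"] <- 0.10
  rd["TGFBI", "GHR"] <- rd["GHR", "TGFBI"] <- 0.15
  dcls3 <- identify_dcls(make_coex_pair(rd, rn), rc = 0.6, dr = 0.5)
  expect_false(any(dcls3$gene_a == "GHR" & dcls3$gene_b == "TGFBI"))
  # gain: qualified only in disease
  rn["TGFBI", "GHR"] <- rn["GHR", "TGFBI"] <- 0.05
  rd["TGFBI", "GHR"] <- rd["GHR", "TGFBI"] <- 0.9
  dcls4 <- identify_dcls(make_coex_pair(rd, rn), rc = 0.6, dr = 0.5)
  gain_row <- dcls4[dcls4$gene_a == "GHR" & dcls4$gene_b == "TGFBI", ]
  expect_identical(gain_row$class, "gain")
})

test_that("log fold change is log2 of the condition-mean ratio", {
  spc <- 6
  values <- matrix(rep(c(8, 5, 3), each = 2 * spc), nrow = 3, byrow = TRUE,
                   dimnames = list(c("up", "flat", "zero"),
                                   sprintf("s%d", 1:12)))
  values["up", 7:12] <- 2       # normal mean 2, disease mean 8
  values["zero", 7:12] <- 0
  cond <- stats::setNames(rep(c("disease", "normal"), each = spc),
                          colnames(values))
  ds <- expression_dataset(values, cond, "toy")
  expect_error(log_fold_change(ds), "zero")
  values2 <- values[c("up", "flat"), ]
  ds2 <- expression_dataset(values2, cond, "toy")
  lfc <- log_fold_change(ds2)
  expect_equal(lfc[["up"]], 2)
  expect_equal(lfc[["flat"]], 0)
})
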