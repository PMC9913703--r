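test_that("cell-line simulation is deterministic and truth-consistent", {
  cfg <- cell_line_sim_config(n_genes = 300, n_line_specific = 10, seed = 7)
  a <- simulate_cell_lines(cfg)
  b <- simulate_cell_lines(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)

  expect_length(a$truth$up, cfg$n_core_up)
  expect_length(a$truth$down, cfg$n_core_down)
  expect_true(all(c(a$truth$up, a$truth$down,
                    unlist(a$truth$line_specific)) %in% rownames(a$matrix)))
  expect_length(intersect(c(a$truth$up, a$truth$down),
                          unlist(a$truth$line_specific)), 0)
  expect_identical(nrow(a$anno), ncol(a$matrix))
  expect_equal(sum(a$anno$group == "parental"), cfg$n_replicates)
  expect_length(unique(a$anno$group), cfg$n_conditions + 1L)
})

test_that("noiseless cell-line simulation is recovered exactly", {
  cfg <- cell_line_sim_config(n_genes = 300, n_line_specific = 10,
                              core_effect = 1.0, line_effect = 2.0,
                              noise_sd = 0, seed = 3)
  sim <- simulate_cell_lines(cfg)
  parental <- sim$anno$sample_id[sim$anno$group == "parental"]
  specs <- lapply(sim$truth$conditions, function(cn)
    comparison_spec(cn, sim$anno$sample_id[sim$anno$group == cn], parental))
  fc <- compute_fold_changes(sim$matrix, specs)
  sig <- derive_core_signature(fc, cutoff = 2.0)   # log2(2) = core_effect
  expect_setequal(sig$up, sim$truth$up)
  expect_setequal(sig$down, sim$truth$down)
})

test_that("cell-line config rejects overlapping planted sets", {
  expect_error(cell_line_sim_config(n_genes = 100, n_line_specific = 50),
               "overlap|below n_genes")
})

test_that("cohort simulation plants dilution, confounder, and stemness", {
  cfg <- cohort_sim_config(n_genes = 400, seed = 11)
  sim <- simulate_cohort(cfg)
  expect_identical(simulate_cohort(cfg)$matrix, sim$matrix)

  expect_true(all(sim$truth$f >= 0 & sim$truth$f <= 1))
  expect_true(all(sim$truth$inflammation_genes %in% sim$truth$down))
  expect_length(sim$truth$inflammation_genes,
                floor(cfg$inflammation_fraction * cfg$n_core_down))
  expect_identical(names(sim$truth$f), sim$anno$sample_id)
  expect_true("stemness" %in% colnames(sim$anno))

  # stemness couples to f (sanity, generous bound at coupling 0.8)
  expect_gt(cor(sim$truth$f, sim$anno$stemness), 0.4)

  # confounder direction: module genes rise in diseased samples
  diseased <- sim$anno$sample_id[sim$anno$group != "healthy"]
  healthy <- sim$anno$sample_id[sim$anno$group == "healthy"]
  mod_delta <- rowMeans(sim$matrix[sim$truth$inflammation_genes, diseased]) -
    rowMeans(sim$matrix[sim$truth$inflammation_genes, healthy])
  expect_gt(mean(mod_delta), 0.5)

  # non-module down genes fall in diseased samples
  rest <- setdiff(sim$truth$down, sim$truth$inflammation_genes)
  rest_delta <- rowMeans(sim$matrix[rest, diseased]) -
    rowMeans(sim$matrix[rest, healthy])
  expect_lt(mean(rest_delta), 0)
})

test_that("two cohorts with equal counts share their planted core", {
  a <- simulate_cohort(cohort_sim_config(n_genes = 400, seed = 1,
                                         cohort_id = "A"))
  b <- simulate_cohort(cohort_sim_config(n_genes = 400, seed = 2,
                                         cohort_id = "B"))
  expect_identical(a$truth$up, b$truth$up)
  expect_identical(a$truth$inflammation_genes, b$truth$inflammation_genes)
  expect_false(identical(a$matrix[1, 1], b$matrix[1, 1]))
})

test_that("cohort config validates fractions, sizes, and coupling", {
  expect_error(cohort_sim_config(inflammation_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_sim_config(group_sizes = c(healthy = 2, disease = 5,
                                                 disease_neoplasia = 5)),
               ">= 3")
  expect_error(cohort_sim_config(f_means = c(0, 0.5)), "align")
  expect_error(cohort_sim_config(stem_coupling = 1.5), "stem_coupling")
})

test_that("sorted-population simulation carries undiluted signal and drivers", {
  cfg <- sorted_sim_config(n_genes = 400, seed = 19)
  sim <- simulate_sorted_populations(cfg)
  expect_identical(simulate_sorted_populations(cfg)$matrix, sim$matrix)
  expect_true(all(sim$truth$drivers %in% rownames(sim$matrix)))
  expect_length(intersect(sim$truth$drivers,
                          c(sim$truth$up, sim$truth$down)), 0)

  # adenoma groups (higher f) score above normal groups on the up genes
  scores <- score_samples(sim$matrix, gene_signature("core", sim$truth$up),
                          ssgsea_params(normalize = FALSE))["core", ]
  adenoma <- grepl("^adenoma", sim$anno$group)
  expect_lt(mann_whitney(scores[!adenoma], scores[adenoma])$p_value, 0.01)
  expect_gt(mean(scores[adenoma]), mean(scores[!adenoma]))

  # drivers track f
  expect_gt(spearman_cor(sim$matrix["driver_1", ], scores)$rho, 0.5)
})

test_that("flat sorted design yields a near-zero driver-score correlation", {
  # scaled down to 10 seeds (full null run lives in the acceptance suite's
  # calibration check); bound widened accordingly
  rhos <- vapply(1:10, function(seed) {
    cfg <- sorted_sim_config(n_genes = 200, f_levels = rep(0.3, 4),
                             seed = seed)
    sim <- simulate_sorted_populations(cfg)
    scores <- score_samples(sim$matrix,
                            gene_signature("core", sim$truth$up),
                            ssgsea_params(normalize = FALSE))["core", ]
    spearman_cor(sim$matrix["driver_1", ], scores)$rho
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.25)
})

test_that("truth serializes to JSON", {
  sim <- simulate_cohort(cohort_sim_config(n_genes = 50, n_core_up = 5,
                                           n_core_down = 6, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$up, sim$truth$up)
  expect_identical(back$inflammation_genes, sim$truth$inflammation_genes)
})
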