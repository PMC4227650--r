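test_that("compendium generation is deterministic and noiseless values equal archetype means", {
  a <- generate_compendium(default_archetypes(), noise_sd_log = 0.1, seed = 9)
  b <- generate_compendium(default_archetypes(), noise_sd_log = 0.1, seed = 9)
  expect_identical(a$compendium$values, b$compendium$values)
  expect_identical(a$truth, b$truth)
  c2 <- generate_compendium(default_archetypes(), noise_sd_log = 0.1, seed = 10)
  expect_false(identical(a$compendium$values, c2$compendium$values))

  nl <- generate_compendium(anchor_archetypes(), noise_sd_log = 0, seed = 1)
  cc <- nl$compendium
  ann <- cc$annotations
  panel_ids <- ann$sample_id[ann$tissue != "seedling"]
  expect_true(all(cc$values["Os.hsp82", panel_ids] == 0.033))
  heat_ids <- ann$sample_id[ann$condition == "heat"]
  expect_true(all(cc$values["Os.hsp18", heat_ids] == 1.190))
  # every generated gene has exactly one truth entry
  expect_setequal(rownames(cc$values), nl$truth$gene_id)
})

test_that("generator rejects invalid specifications", {
  expect_error(generate_compendium(list(), seed = 1),
               class = "promscreen_usage_error")
  expect_error(generate_compendium(archetype("SILENT", 1, 1, 1, count = 0L),
                                   seed = 1),
               class = "promscreen_usage_error")
  expect_error(archetype("NOT_A_TYPE", 1, 1, 1),
               class = "promscreen_usage_error")
  expect_error(generate_compendium(default_archetypes(), replicates = 0L),
               class = "promscreen_usage_error")
})

test_that("time-course starts at fold 1, peaks as configured and decays monotonically", {
  tc <- generate_timecourse(peak_fold = 516, peak_time_h = 4)
  expect_equal(tc$fold[tc$timepoint_h == 0], 1)
  expect_equal(max(tc$fold), 516)
  expect_equal(tc$timepoint_h[which.max(tc$fold)], 4)
  f8 <- tc$fold[tc$timepoint_h == 8]; f16 <- tc$fold[tc$timepoint_h == 16]
  expect_lt(f16, f8)
  expect_lt(f8, 516)
  for (dr in c(0.05, 0.5, 2)) {
    tc2 <- generate_timecourse(decay_rate = dr)
    expect_lt(tc2$fold[tc2$timepoint_h == 16], tc2$fold[tc2$timepoint_h == 8])
  }
  # reproducible under noise
  n1 <- generate_timecourse(noise_sd_log = 0.05, seed = 4)
  n2 <- generate_timecourse(noise_sd_log = 0.05, seed = 4)
  expect_identical(n1, n2)
})

test_that("Ct generation inverts relative expression exactly when noiseless", {
  folds <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                          target_id = c("gA", "gB", "gA"),
                          fold = c(1024, 2, 0.5))
  ct <- generate_ct_table(folds, reference_gene = "ef1a", ct_ref = 20)
  a1 <- ct$ct[ct$sample_id == "s1" & ct$target_id == "gA"]
  r1 <- ct$ct[ct$sample_id == "s1" & ct$target_id == "ef1a"]
  expect_equal(r1 - a1, 10)  # log2(1024)

  back <- relative_expression_table(ct, "ef1a")
  key <- paste(back$sample_id, back$target_id)
  expect_equal(back$fold[match(paste(folds$sample_id, folds$target_id), key)],
               folds$fold, tolerance = 1e-12)
  expect_error(
    generate_ct_table(dplyr::mutate(folds, target_id = "ef1a"), "ef1a"),
    class = "promscreen_usage_error")
})

test_that("a generated stable reference ranks lowest-M against noisy targets in >= 95% of seeds", {
  # Targets behave like differently regulated genes (each strongly induced
  # in a different half of the samples, with biological scatter), so they
  # vary against the reference and against each other; the reference
  # gene's abundance is flat up to Ct noise.
  hits <- 0L
  for (s in 1:50) {
    folds <- withr::with_seed(s, {
      tidyr::expand_grid(sample_id = sprintf("s%d", 1:8),
                         target_id = c("noisyA", "noisyB")) |>
        dplyr::mutate(
          half = rep(rep(c(1L, 2L), each = 2), 4),
          induced = (.data$target_id == "noisyA") == (.data$half == 2L),
          fold = 2^rnorm(dplyr::n(), ifelse(.data$induced, 8, 0), 0.5)
        ) |>
        dplyr::select(-"half", -"induced")
    })
    ct <- generate_ct_table(folds, reference_gene = "stable_ref",
                            ct_ref = 20, noise_sd = 0.1, seed = s + 1000L)
    q <- ct_to_quantity(ct)
    m <- genorm_m(q)
    if (m$gene_id[which.min(m$M)] == "stable_ref") hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})

test_that("the planted suitable set is recovered exactly across seeds (pipeline round trip)", {
  anc <- default_synth_anchors()
  for (s in 1:20) {
    sim <- generate_compendium(default_archetypes(), noise_sd_log = 0.1,
                               seed = s)
    ranked <- prospective_screen(sim$compendium, anc)
    planted <- sim$truth$gene_id[sim$truth$archetype == "IDEAL_INDUCIBLE"]
    suitable <- ranked$gene_id[ranked$class == "SUITABLE"]
    expect_setequal(suitable, planted)
    expect_true(all(ranked$rank[ranked$gene_id %in% planted] <=
                      length(planted)),
                label = sprintf("seed %d: planted genes ranked first", s))
  }
})
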