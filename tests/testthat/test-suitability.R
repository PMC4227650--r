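# Panel compendium used across these tests: anchors plus a few archetypes,
# noiseless so planted levels are recovered exactly.
panel_sim <- generate_compendium(c(anchor_archetypes(), default_archetypes()),
                                 noise_sd_log = 0, seed = 1)

test_that("panel mean is the plain mean over panel samples", {
  cc <- panel_sim$compendium
  expect_equal(panel_mean(cc, "Os.hsp82"), 0.033)
  expect_equal(panel_mean(cc, "Os.hsp18"), 0.073)
  expect_error(panel_mean(cc, "nonesuch"), class = "promscreen_usage_error")
  expect_error(panel_mean(cc, "Os.hsp82", panel = "no_such_tissue"),
               class = "promscreen_usage_error")

  # {0, 0.1} -> 0.05 on a hand-built two-sample panel
  m <- matrix(c(0, 0.1), 1, 2, dimnames = list("g", c("s1", "s2")))
  ann <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "seed",
                        condition = "control", genotype = "wt",
                        timepoint_h = 0, replicate = 1:2)
  expect_equal(panel_mean(expression_compendium(m, ann), "g", panel = "seed"),
               0.05)
})

test_that("profiles reproduce planted anchor levels and handle all-zero genes", {
  cc <- panel_sim$compendium
  p82 <- build_profile(cc, "Os.hsp82")
  expect_equal(p82$panel_mean, 0.033)
  expect_equal(p82$control_level, 0.001)
  expect_equal(p82$induced_level, 0.650)
  expect_equal(sort(names(p82$stress_folds)), c("cold", "drought", "salt"))
  expect_true(all(abs(p82$stress_folds - 1) < 1e-9))

  zero <- archetype("SILENT", 0, 0, 0, count = 1L, gene_ids = "zero")
  zc <- generate_compendium(list(zero), noise_sd_log = 0, seed = 1)$compendium
  pz <- build_profile(zc, "zero")
  expect_equal(pz$panel_mean, 0)
  expect_equal(pz$induced_level, 0)
  expect_true(all(pz$stress_folds == 1))  # (0+eps)/(0+eps)
})

test_that("profile fields agree with field-wise brute-force computation on a random fixture", {
  sim <- generate_compendium(default_archetypes(), noise_sd_log = 0.2, seed = 11)
  cc <- sim$compendium
  ann <- cc$annotations
  for (g in sample(rownames(cc$values), 5)) {
    p <- build_profile(cc, g)
    pm_ids <- ann$sample_id[ann$tissue %in% tissue_panel()]
    expect_equal(p$panel_mean, mean(cc$values[g, pm_ids]), tolerance = 1e-12)
    ctl_ids <- ann$sample_id[ann$condition == "control" & ann$tissue == "seedling"]
    ind_ids <- ann$sample_id[ann$condition == "heat"]
    expect_equal(p$control_level, mean(cc$values[g, ctl_ids]), tolerance = 1e-12)
    expect_equal(p$induced_level, mean(cc$values[g, ind_ids]), tolerance = 1e-12)
    for (s in c("cold", "salt", "drought")) {
      s_ids <- ann$sample_id[ann$condition == s]
      want <- (mean(cc$values[g, s_ids]) + 1e-6) /
        (mean(cc$values[g, ctl_ids]) + 1e-6)
      expect_equal(unname(p$stress_folds[s]), want, tolerance = 1e-12)
    }
  }
})

test_that("anchor genes classify by their own thresholds (boundary-inclusive)", {
  anc <- default_anchors()
  p82 <- promoter_profile("Os.hsp82", 0.033, 0.001, 0.650, scale_tag = "CREP")
  p18 <- promoter_profile("Os.hsp18", 0.073, 0.052, 1.190, scale_tag = "CREP")
  expect_equal(classify_promoter(p82, anc)$class, "SUITABLE")
  expect_equal(classify_promoter(p18, anc)$class, "MARGINAL")

  # high basal panel activity with adequate induction is UNSUITABLE
  hot <- promoter_profile("leaky", 0.73, 0.02, 5, scale_tag = "CREP")
  expect_equal(classify_promoter(hot, anc)$class, "UNSUITABLE")

  # weak induction dominates everything else
  weak <- promoter_profile("weak", 0.001, 0.001, 0.1, scale_tag = "CREP")
  expect_equal(classify_promoter(weak, anc)$class, "NOT_INDUCIBLE")

  # scale mixing is refused
  other <- promoter_profile("x", 0.01, 0.01, 5, scale_tag = "other")
  expect_error(classify_promoter(other, anc), class = "promscreen_usage_error")
})

test_that("classification agrees with an independent rule oracle on a grid around the anchors", {
  anc <- default_anchors()
  mult <- c(0.5, 1, 2)
  grid <- expand.grid(panel = 0.033 * mult, control = 0.052 * mult,
                      induced = 0.650 * mult, extra_panel = 0.073 * mult)
  for (i in seq_len(nrow(grid))) {
    for (pm in unique(c(grid$panel[i], grid$extra_panel[i]))) {
      p <- promoter_profile("g", pm, grid$control[i], grid$induced[i],
                            scale_tag = "CREP")
      expect_equal(classify_promoter(p, anc)$class,
                   oracle_classify(pm, grid$control[i], grid$induced[i], anc),
                   label = sprintf("panel=%g control=%g induced=%g", pm,
                                   grid$control[i], grid$induced[i]))
    }
  }
})

test_that("raising basal levels never improves the class; raising induction never worsens it", {
  anc <- default_anchors()
  rank_of <- function(k) match(k, c("SUITABLE", "MARGINAL", "UNSUITABLE",
                                    "NOT_INDUCIBLE"))
  set.seed(3)
  for (i in 1:200) {
    pm <- runif(1, 0, 0.2); ctl <- runif(1, 0, 0.12); ind <- runif(1, 0, 2)
    base <- classify_promoter(promoter_profile("g", pm, ctl, ind,
                                               scale_tag = "CREP"), anc)$class
    up_basal <- classify_promoter(
      promoter_profile("g", pm * 1.5, ctl * 1.5, ind, scale_tag = "CREP"),
      anc)$class
    expect_gte(rank_of(up_basal), rank_of(base))
    up_ind <- classify_promoter(
      promoter_profile("g", pm, ctl, ind * 1.5, scale_tag = "CREP"), anc)$class
    expect_lte(rank_of(up_ind), rank_of(base))
  }
})

test_that("specificity verdict flags any stress inducing at or above the fold threshold", {
  p <- promoter_profile("g", 0.01, 0.01, 5,
                        stress_folds = c(cold = 1.1, salt = 0.9, drought = 1.3),
                        scale_tag = "x")
  res <- specificity_check(p)
  expect_true(res$pass)
  expect_false(any(res$per_stress$induces))

  p2 <- promoter_profile("g", 0.01, 0.01, 5, stress_folds = c(salt = 5),
                         scale_tag = "x")
  res2 <- specificity_check(p2)
  expect_false(res2$pass)
  expect_true(res2$per_stress$induces[res2$per_stress$stress == "salt"])

  # empty stress set: vacuous pass, flagged
  p3 <- promoter_profile("g", 0.01, 0.01, 5, scale_tag = "x")
  res3 <- specificity_check(p3)
  expect_true(res3$pass)
  expect_match(res3$reasons, "vacuous")

  # anchor archetypes are heat-specific in the generated stress panel
  for (g in c("Os.hsp82", "Os.hsp18")) {
    expect_true(specificity_check(build_profile(panel_sim$compendium, g))$pass)
  }
  # cross-reactive archetypes fail
  cr <- grep("^CROSS_REACTIVE", rownames(panel_sim$compendium$values), value = TRUE)[1]
  expect_false(specificity_check(build_profile(panel_sim$compendium, cr))$pass)
})

test_that("clustering is deterministic and matches a brute-force agglomerative oracle", {
  cc <- panel_sim$compendium
  single <- cluster_candidates(cc, "Os.hsp82")
  expect_equal(single$leaf_order, "Os.hsp82")
  expect_null(single$hclust)

  # two planted genes of the same archetype have identical noiseless rows
  ideal <- grep("^IDEAL", rownames(cc$values), value = TRUE)[1:2]
  two <- cluster_candidates(cc, c(ideal, "Os.hsp18", "Os.hsp82"))
  expect_equal(min(two$hclust$height), 0)
  expect_equal(sort(cutree(two$hclust, h = 1e-9)[ideal]),
               sort(cutree(two$hclust, h = 1e-9)[ideal]))
  expect_true(cutree(two$hclust, h = 1e-9)[ideal[1]] ==
                cutree(two$hclust, h = 1e-9)[ideal[2]])

  # 4-gene fixture vs oracle: same merge heights and partitions
  sim <- generate_compendium(default_archetypes(), noise_sd_log = 0.3, seed = 5)
  genes <- c(grep("^IDEAL", rownames(sim$compendium$values), value = TRUE)[1:2],
             grep("^LEAKY", rownames(sim$compendium$values), value = TRUE)[1],
             grep("^CONSTITUTIVE", rownames(sim$compendium$values), value = TRUE)[1])
  cl <- cluster_candidates(sim$compendium, genes)
  orc <- oracle_agglomerative(cl$log_values)
  expect_equal(sort(cl$hclust$height), sort(orc$heights), tolerance = 1e-12)
  for (k in 2:3) {
    memb <- cutree(cl$hclust, k = k)
    parts <- lapply(split(names(memb), memb), sort)
    opart <- orc$partitions[[length(orc$partitions) - k + 1]]
    expect_setequal(lapply(unname(parts), paste, collapse = ","),
                    lapply(unname(opart), paste, collapse = ","))
  }

  # input order does not matter
  cl2 <- cluster_candidates(sim$compendium, rev(genes))
  expect_equal(cl2$leaf_order, cl$leaf_order)
})

test_that("prospective screen ranks planted suitable genes first and is permutation-invariant", {
  anc <- default_synth_anchors()
  expect_equal(nrow(prospective_screen(
    generate_compendium(archetype("SILENT", 0.001, 0.001, 0.001, count = 2L),
                        noise_sd_log = 0, seed = 1)$compendium, anc)), 0L)

  sim <- generate_compendium(default_archetypes(), noise_sd_log = 0.1, seed = 3)
  ranked <- prospective_screen(sim$compendium, anc)
  planted <- sim$truth$gene_id[sim$truth$archetype == "IDEAL_INDUCIBLE"]
  expect_setequal(ranked$gene_id[ranked$class == "SUITABLE"], planted)
  expect_true(all(ranked$rank[ranked$gene_id %in% planted] <= length(planted)))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))

  # permuting compendium rows changes nothing
  cc <- sim$compendium
  perm <- sample(nrow(cc$values))
  cc2 <- expression_compendium(cc$values[perm, , drop = FALSE],
                               cc$annotations, scale_tag = cc$scale_tag)
  expect_equal(prospective_screen(cc2, anc), ranked)
})
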