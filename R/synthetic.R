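# Synthetic expression compendia, stress panels, induction time-courses and
# Ct tables with planted ground truth. All generation is reproducible from
# an explicit seed (Mersenne-Twister via withr; no global RNG state leaks).

#' Archetype specification for synthetic genes
#'
#' Each synthetic gene belongs to one behavioural archetype defined by its
#' mean basal level across the transformation panel, its level in
#' uninduced seedlings, its level under the inducing condition, and
#' per-stress induction folds for non-target stresses.
#'
#' Archetypes: `IDEAL_INDUCIBLE` (basal activity safely below the
#' suitability anchor, strong specific induction), `MARGINAL_INDUCIBLE`
#' (hsp18-like: tolerable for reporters, too leaky for phytotoxic cargo),
#' `LEAKY_INDUCIBLE` (inducible but basally active), `CONSTITUTIVE`
#' (ef1a-like, flat and high), `CROSS_REACTIVE` (responds to several
#' stresses) and `SILENT` (near-zero everywhere).
#'
#' @param name Archetype name (one of the six above).
#' @param basal_panel_level Mean level in transformation-panel tissues.
#' @param control_level Level in uninduced seedlings.
#' @param induced_level Level under the inducing condition.
#' @param stress_fold_map Named list/vector of fold inductions for
#'   non-target stress conditions (unlisted stresses default to fold 1).
#' @param count Number of genes to plant.
#' @param gene_ids Optional explicit gene identifiers (length `count`).
#' @return A list of class `archetype_spec`.
#' @export
archetype <- function(name, basal_panel_level, control_level, induced_level,
                      stress_fold_map = list(), count = 1L, gene_ids = NULL) {
  valid <- c("IDEAL_INDUCIBLE", "MARGINAL_INDUCIBLE", "LEAKY_INDUCIBLE",
             "CONSTITUTIVE", "CROSS_REACTIVE", "SILENT")
  if (!name %in% valid) {
    abort(paste0("unknown archetype: ", name), class = "promscreen_usage_error")
  }
  stopifnot(count >= 0, basal_panel_level >= 0, control_level >= 0,
            induced_level >= 0)
  if (!is.null(gene_ids) && length(gene_ids) != count) {
    abort("gene_ids length must equal count", class = "promscreen_usage_error")
  }
  structure(list(name = name, basal_panel_level = basal_panel_level,
                 control_level = control_level, induced_level = induced_level,
                 stress_fold_map = as.list(stress_fold_map), count = as.integer(count),
                 gene_ids = gene_ids),
            class = "archetype_spec")
}

#' Default archetype mixture (100 genes)
#'
#' Five ideal inducible genes hidden among 95 others: 10 hsp18-like
#' marginals, 10 leaky inducibles, 10 constitutives, 10 cross-reactive
#' stress responders and 55 silent genes. Levels are on the multi-tissue
#' compendium scale; the marginal archetype carries the published
#' hsp18-anchor levels, and the ideal archetype sits well below the hsp82
#' anchor so that planted suitable genes are separated from the decision
#' boundary by several noise standard deviations.
#'
#' @return List of [archetype()] specs.
#' @export
default_archetypes <- function() {
  list(
    archetype("IDEAL_INDUCIBLE", 0.010, 0.001, 2.0, count = 5L),
    archetype("MARGINAL_INDUCIBLE", 0.073, 0.052, 1.190, count = 10L),
    archetype("LEAKY_INDUCIBLE", 0.5, 0.3, 5.0, count = 10L),
    archetype("CONSTITUTIVE", 5, 5, 5, count = 10L),
    archetype("CROSS_REACTIVE", 0.15, 0.08, 2.0,
              stress_fold_map = list(cold = 10, salt = 10, drought = 10),
              count = 10L),
    archetype("SILENT", 0.002, 0.002, 0.002, count = 55L)
  )
}

#' Anchor-gene archetypes with the published expression levels
#'
#' Plants the two anchor genes with their printed levels: Os.hsp82
#' (panel 0.033, control 0.001, induced 0.650) and Os.hsp18 (0.073,
#' 0.052, 1.190). Generated noiselessly and classified against
#' [default_anchors()] on the same scale, they reproduce the experimental
#' outcome: the hsp82-like gene classifies SUITABLE, the hsp18-like gene
#' MARGINAL.
#'
#' @return List of two [archetype()] specs.
#' @export
anchor_archetypes <- function() {
  list(
    archetype("IDEAL_INDUCIBLE", 0.033, 0.001, 0.650, count = 1L,
              gene_ids = "Os.hsp82"),
    archetype("MARGINAL_INDUCIBLE", 0.073, 0.052, 1.190, count = 1L,
              gene_ids = "Os.hsp18")
  )
}

archetype_mean <- function(spec, tissue, condition, induced_condition) {
  if (tissue != "seedling") return(spec$basal_panel_level)
  if (condition == induced_condition) return(spec$induced_level)
  if (condition == "control") return(spec$control_level)
  f <- spec$stress_fold_map[[condition]]
  spec$control_level * (if (is.null(f)) 1 else f)
}

#' Generate a synthetic expression compendium with planted ground truth
#'
#' Builds a compendium emulating the designs the screening pipeline
#' consumes: every transformation-panel tissue sampled under control
#' conditions, plus whole seedlings under control, the inducing condition
#' and any additional stresses, all with replication. Each gene's value in
#' each sample is its archetype mean for that (tissue, condition) times a
#' log-normal multiplicative noise term with log10 standard deviation
#' `noise_sd_log`; with `noise_sd_log = 0` values equal the archetype
#' means exactly. Fully reproducible from `seed`.
#'
#' @param archetypes List of [archetype()] specs (total count >= 1).
#' @param panel Tissue labels sampled under control conditions.
#' @param conditions Condition labels for the seedling samples; must
#'   include `"control"` and the inducing condition.
#' @param induced_condition Label of the inducing condition.
#' @param replicates Replicates per (tissue, condition) cell (>= 1).
#' @param noise_sd_log Log10 SD of the multiplicative noise (default 0.1).
#' @param seed Integer seed; all randomness derives from it.
#' @param scale_tag Scale recorded on the compendium (anchors used against
#'   it must carry the same tag).
#' @return A list with `compendium` (an [expression_compendium()]) and
#'   `truth` (tibble: `gene_id`, `archetype`, planted levels; attributes
#'   `seed` and `noise_sd_log`).
#' @examples
#' sim <- generate_compendium(anchor_archetypes(), noise_sd_log = 0, seed = 1)
#' build_profile(sim$compendium, "Os.hsp82")
#' @export
generate_compendium <- function(archetypes,
                                panel = tissue_panel(),
                                conditions = c("control", "heat", "cold",
                                               "salt", "drought"),
                                induced_condition = "heat",
                                replicates = 3L,
                                noise_sd_log = 0.1,
                                seed = 1L,
                                scale_tag = "synthetic") {
  if (inherits(archetypes, "archetype_spec")) archetypes <- list(archetypes)
  total <- sum(vapply(archetypes, function(a) a$count, integer(1)))
  if (total < 1L) abort("no genes to generate", class = "promscreen_usage_error")
  if (replicates < 1L) abort("replicates must be >= 1", class = "promscreen_usage_error")
  if (!"control" %in% conditions) {
    abort("conditions must include 'control'", class = "promscreen_usage_error")
  }

  truth <- bind_rows(imap(archetypes, function(a, i) {
    if (a$count == 0L) return(NULL)
    ids <- a$gene_ids %||% sprintf("%s_%03d_%02d", a$name, seq_len(a$count), i)
    tibble(gene_id = ids, archetype = a$name,
           basal_panel_level = a$basal_panel_level,
           control_level = a$control_level,
           induced_level = a$induced_level,
           spec_index = i)
  }))
  if (anyDuplicated(truth$gene_id)) {
    abort("duplicate gene_ids across archetype specs",
          class = "promscreen_usage_error")
  }

  ann <- bind_rows(
    tidyr::expand_grid(tissue = panel, condition = "control",
                       replicate = seq_len(replicates)),
    tidyr::expand_grid(tissue = "seedling", condition = conditions,
                       replicate = seq_len(replicates))
  ) |>
    mutate(
      sample_id = sprintf("%s.%s.r%d", .data$tissue, .data$condition,
                          .data$replicate),
      genotype = "wt",
      timepoint_h = dplyr::case_when(
        .data$condition == induced_condition ~ 2,
        .data$condition %in% c("cold", "salt", "drought") ~ 3,
        TRUE ~ 0
      )
    ) |>
    select("sample_id", "tissue", "condition", "genotype", "timepoint_h",
           "replicate")

  means <- matrix(0, nrow(truth), nrow(ann),
                  dimnames = list(truth$gene_id, ann$sample_id))
  for (g in seq_len(nrow(truth))) {
    spec <- archetypes[[truth$spec_index[g]]]
    means[g, ] <- vapply(seq_len(nrow(ann)), function(s) {
      archetype_mean(spec, ann$tissue[s], ann$condition[s], induced_condition)
    }, numeric(1))
  }
  values <- withr::with_seed(seed, {
    if (noise_sd_log > 0) {
      means * 10^matrix(rnorm(length(means), 0, noise_sd_log),
                        nrow(means), ncol(means))
    } else {
      means
    }
  })
  truth <- select(truth, -"spec_index")
  attr(truth, "seed") <- seed
  attr(truth, "noise_sd_log") <- noise_sd_log
  list(
    compendium = expression_compendium(values, ann, scale_tag = scale_tag),
    truth = truth
  )
}

#' Deterministic induction time-course
#'
#' Rise-then-decay fold-expression curve modelling the transcriptional
#' response to a sustained heat treatment: the log fold rises linearly
#' from 0 (fold 1) at time 0 to `log(peak_fold)` at `peak_time_h`, then
#' decays exponentially at `decay_rate` per hour. Defaults reproduce the
#' strongest observed leaf response (peak 516-fold versus the reference
#' gene, peak at 4 h within the observed 2-4 h window); peak folds of
#' 294, 326 or 796 reproduce the other organ/gene combinations.
#'
#' @param peak_fold Maximum fold versus the reference gene (>= 1).
#' @param peak_time_h Time of the maximum, hours (2-4 h is realistic).
#' @param decay_rate Exponential decay rate after the peak (per hour, > 0).
#' @param timepoints Hours at which to evaluate (>= 0).
#' @param noise_sd_log Optional log10 SD of multiplicative noise.
#' @param seed Seed used when `noise_sd_log > 0`.
#' @return Tibble with `timepoint_h` and `fold`.
#' @examples
#' generate_timecourse()  # noiseless 516-fold peak at 4 h
#' @export
generate_timecourse <- function(peak_fold = 516, peak_time_h = 4,
                                decay_rate = 0.35,
                                timepoints = c(0, 1, 2, 4, 8, 16),
                                noise_sd_log = 0, seed = 1L) {
  stopifnot(peak_fold >= 1, peak_time_h > 0, decay_rate > 0,
            all(timepoints >= 0))
  fold <- ifelse(
    timepoints <= peak_time_h,
    exp(log(peak_fold) * timepoints / peak_time_h),
    peak_fold * exp(-decay_rate * (timepoints - peak_time_h))
  )
  if (noise_sd_log > 0) {
    fold <- withr::with_seed(seed,
      fold * 10^rnorm(length(fold), 0, noise_sd_log))
  }
  tibble(timepoint_h = timepoints, fold = fold)
}

#' Generate a synthetic qPCR Ct table from true folds
#'
#' Inverse of [relative_expression()] at efficiency 2: for each
#' (sample, target) true fold versus the reference gene, the target Ct is
#' `ct_ref - log2(fold)` plus Gaussian noise; the reference gene's Ct is
#' stable at `ct_ref` up to the same noise. Applying
#' [relative_expression_table()] to noiseless output recovers the true
#' folds exactly.
#'
#' @param folds Data frame with columns `sample_id`, `target_id`, `fold`
#'   (true fold versus the reference, > 0).
#' @param reference_gene Identifier used for the reference rows.
#' @param ct_ref Baseline reference Ct (cycles).
#' @param efficiency Amplification factor written to the table.
#' @param noise_sd Gaussian SD added to every Ct (cycles).
#' @param seed Seed for the noise.
#' @return Tibble with `sample_id`, `target_id`, `ct`, `efficiency`.
#' @export
generate_ct_table <- function(folds, reference_gene = "ef1a", ct_ref = 20,
                              efficiency = 2, noise_sd = 0, seed = 1L) {
  folds <- as_tibble(folds)
  stopifnot(all(c("sample_id", "target_id", "fold") %in% names(folds)),
            all(folds$fold > 0))
  if (reference_gene %in% folds$target_id) {
    abort("reference gene must not appear among the targets",
          class = "promscreen_usage_error")
  }
  targets <- mutate(folds, ct = ct_ref - log2(.data$fold))
  refs <- tibble(sample_id = unique(folds$sample_id),
                 target_id = reference_gene, ct = ct_ref)
  out <- bind_rows(select(targets, "sample_id", "target_id", "ct"), refs)
  if (noise_sd > 0) {
    out$ct <- withr::with_seed(seed, out$ct + rnorm(nrow(out), 0, noise_sd))
  }
  mutate(out, efficiency = efficiency)
}

# ---------------------------------------------------------------------------
# Heat-shock screen emulation (synthetic stand-in for a published
# two-condition seedling experiment; all values are synthetic plants).

#' Synthetic heat-shock screen table (planted truth)
#'
#' A synthetic stand-in for a summarized two-condition (control vs 42 C
#' heat shock) seedling microarray screen table: 19 probes over 16 genes,
#' all with induced-minus-control differences above 5500 normalized
#' fluorescence units. The structure plants the screen's published
#' landmarks: the top fold change is 615 (probe AK063751.1, the Hsp82
#' anchor gene); the Hsp18 anchor probe AK071240.1 is among the
#' highest-expressing induced probes; and exactly five further genes
#' (AB110191.1, AU165294, AK069860.1, X60820.1, AB098712.1) pass the
#' prospective pre-screen cutoffs taken from the two anchor rows (induced
#' mean at or above the hsp82 row, control mean at or below the hsp18
#' row). All values are synthetic constructions, not measured data.
#'
#' @return Tibble with `probe_id`, `gene_id`, `mean_control`, `mean_heat`.
#' @export
hs_screen_truth <- function() {
  tibble::tribble(
    ~probe_id,    ~gene_id,     ~mean_control, ~mean_heat,
    "AK063751.1", "Os.hsp82",      10,  6150,
    "AK063751.2", "Os.hsp82",      15,  5600,
    "AK071240.1", "Os.hsp18",     450, 12000,
    "AK071613.1", "AK071613",    6200, 16300,
    "AK071613.2", "AK071613",    3500,  9500,
    "CB621753",   "CB621753.g",  4800, 11000,
    "CB621753.2", "CB621753.g",  3900,  9450,
    "AB110191.1", "AB110191",     300,  7500,
    "AU165294",   "AU165294.g",   400,  9800,
    "AK069860.1", "AK069860",     250,  6600,
    "X60820.1",   "X60820",       120,  6400,
    "AB098712.1", "AB098712",     440,  8200,
    "SYN001_at",  "SYNG10",       900,  6900,
    "SYN002_at",  "SYNG11",      1500,  7600,
    "SYN003_at",  "SYNG12",      2000,  8100,
    "SYN004_at",  "SYNG13",       600,  6700,
    "SYN005_at",  "SYNG14",      3000,  9200,
    "SYN006_at",  "SYNG15",      1100,  7000,
    "SYN007_at",  "SYNG16",       500,  6100
  )
}

#' Generate a synthetic two-condition heat-shock compendium
#'
#' Embeds the [hs_screen_truth()] probes in a larger compendium of
#' replicate control and heat-shocked seedling profiles, emulating a
#' summarized 3 + 3 array design. Besides the 19 inducible probes it
#' plants 14 constitutively high-expressed probes (above 10,000 units in
#' both conditions), one probe high in control arrays only (13,800 units,
#' the compendium's control maximum; heat maximum 16,300), and
#' `n_background` unresponsive low-level probes, so the absolute-level
#' counts of very high expressors are 17 (heat) and 15 (control) by
#' construction. Because the fixture emulates one fixed summarized
#' dataset, replicate values default to the per-condition means exactly
#' (`noise_sd_log = 0`); noise and the seed only matter when robustness to
#' replicate scatter is being exercised.
#'
#' @param n_background Number of unresponsive background probes.
#' @param replicates Replicates per condition.
#' @param noise_sd_log Log10 SD of multiplicative replicate noise.
#' @param seed Seed for background levels and noise.
#' @return List with `compendium`, `truth` (full probe table with a
#'   `planted` flag) and `gene_map` (tibble `probe_id`, `gene_id`).
#' @export
generate_hs_compendium <- function(n_background = 150L, replicates = 3L,
                                   noise_sd_log = 0, seed = 1L) {
  planted <- hs_screen_truth()
  const_high <- tibble(
    probe_id = sprintf("CONSTHI%02d_at", seq_len(14)),
    gene_id = sprintf("CONSTHI%02d", seq_len(14)),
    mean_control = 10400 + 200 * seq_len(14),
    mean_heat = 10400 + 200 * seq_len(14)
  )
  ctrl_high <- tibble(probe_id = "CTRLHI01_at", gene_id = "CTRLHI01",
                      mean_control = 13800, mean_heat = 9000)
  background <- withr::with_seed(seed, {
    base <- stats::runif(n_background, 20, 2000)
    tibble(
      probe_id = sprintf("BG%04d_at", seq_len(n_background)),
      gene_id = sprintf("BG%04d", seq_len(n_background)),
      mean_control = base,
      mean_heat = base * stats::runif(n_background, 0.7, 1.4)
    )
  })
  truth <- bind_rows(planted, const_high, ctrl_high, background) |>
    mutate(planted = .data$probe_id %in% planted$probe_id)

  ann <- tibble(
    sample_id = c(sprintf("C%d", seq_len(replicates)),
                  sprintf("H%d", seq_len(replicates))),
    tissue = "seedling",
    condition = rep(c("control", "heat"), each = replicates),
    genotype = "wt",
    timepoint_h = rep(c(0, 2), each = replicates),
    replicate = rep(seq_len(replicates), 2L)
  )
  means <- cbind(
    matrix(rep(truth$mean_control, replicates), nrow(truth), replicates),
    matrix(rep(truth$mean_heat, replicates), nrow(truth), replicates)
  )
  dimnames(means) <- list(truth$probe_id, ann$sample_id)
  values <- if (noise_sd_log > 0) {
    withr::with_seed(seed + 1L,
      means * 10^matrix(rnorm(length(means), 0, noise_sd_log),
                        nrow(means), ncol(means)))
  } else {
    means
  }
  list(
    compendium = expression_compendium(values, ann, scale_tag = "hs-synthetic"),
    truth = truth,
    gene_map = select(truth, "probe_id", "gene_id")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
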