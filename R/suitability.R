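# Basal-activity profiling over the transformation tissue panel, anchor-based
# suitability classification, cross-stress specificity and clustering.

#' Default transformation-relevant tissue panel
#'
#' The tissues and developmental stages traversed while producing a
#' transgenic plant by Agrobacterium-mediated transformation and
#' hygromycin selection: embryogenic callus through infection,
#' co-cultivation, selection and regeneration, plus embryos, seed,
#' imbibition stages and early seedlings. A phytotoxic transgene must stay
#' silent in all of them. Fourteen labels by default; user-configurable.
#'
#' @return Character vector of tissue labels.
#' @export
tissue_panel <- function() {
  c("callus_induction", "callus_infection", "callus_cocultivation",
    "callus_selection_r2s", "callus_selection_nbs", "callus_selection_prag",
    "callus_regeneration", "plantlet", "mature_embryo",
    "imbibed_embryo_2h", "imbibed_embryo_5h", "seed",
    "seedling_leaf", "seedling_root")
}

#' Construct a promoter expression profile
#'
#' @param gene_id Gene identifier.
#' @param panel_mean Mean expression over all transformation-panel samples.
#' @param control_level Mean expression in uninduced seedlings.
#' @param induced_level Mean expression under the inducing condition.
#' @param stress_folds Named numeric vector of induced-over-control folds
#'   for non-target stresses (may be empty).
#' @param scale_tag Scale identifier; must match the anchor set at
#'   classification time.
#' @return An object of class `promoter_profile`.
#' @export
promoter_profile <- function(gene_id, panel_mean, control_level, induced_level,
                             stress_folds = numeric(0),
                             scale_tag = "unspecified") {
  stopifnot(panel_mean >= 0, control_level >= 0, induced_level >= 0,
            all(stress_folds > 0))
  structure(list(gene_id = gene_id, panel_mean = panel_mean,
                 control_level = control_level, induced_level = induced_level,
                 stress_folds = stress_folds, scale_tag = scale_tag),
            class = "promoter_profile")
}

#' @export
print.promoter_profile <- function(x, ...) {
  cat(sprintf("<promoter_profile> %s (scale: %s)\n", x$gene_id, x$scale_tag))
  cat(sprintf("  panel mean %.4g | control %.4g | induced %.4g\n",
              x$panel_mean, x$control_level, x$induced_level))
  if (length(x$stress_folds)) {
    cat("  stress folds:",
        paste(sprintf("%s=%.3g", names(x$stress_folds), x$stress_folds),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Anchor thresholds for suitability classification
#'
#' Classification is anchored to two empirically characterized heat-shock
#' genes. The *suitability anchor* (an Hsp82-like gene) marks the basal
#' level at which phytotoxic transgene expression was experimentally shown
#' to be tolerated during transformation, and its induced level is the
#' minimum useful induction. The *upper basal anchor* (an Hsp18-like small
#' HSP) marks a basal level that still permits reporter expression but is
#' already incompatible with phytotoxic cargo. Both anchors must have been
#' measured on the same scale (`scale_tag`), and a compendium screened
#' against them must share it.
#'
#' @param upper_basal [promoter_profile()] of the hsp18-like anchor.
#' @param suitability [promoter_profile()] of the hsp82-like anchor.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(upper_basal, suitability) {
  stopifnot(inherits(upper_basal, "promoter_profile"),
            inherits(suitability, "promoter_profile"))
  if (!identical(upper_basal$scale_tag, suitability$scale_tag)) {
    abort("anchors measured on different scales", class = "promscreen_usage_error")
  }
  if (suitability$panel_mean > upper_basal$panel_mean) {
    abort("suitability anchor must have panel_mean <= upper basal anchor",
          class = "promscreen_usage_error")
  }
  structure(list(upper_basal = upper_basal, suitability = suitability,
                 scale_tag = upper_basal$scale_tag),
            class = "anchor_set")
}

#' Default anchor set (multi-tissue compendium scale)
#'
#' The published panel/control/induced expression levels of the two anchor
#' genes in the multi-tissue rice expression compendium used for
#' basal-activity profiling: 0.073 / 0.052 / 1.190 normalized fluorescence
#' units for the Os.hsp18 anchor and 0.033 / 0.001 / 0.650 for the
#' Os.hsp82 anchor. These constants are only valid on that compendium's
#' scale; override them (and the `scale_tag`) when screening any other
#' compendium.
#'
#' @param scale_tag Scale the anchors are declared on.
#' @return An [anchor_set()].
#' @export
default_anchors <- function(scale_tag = "CREP") {
  anchor_set(
    upper_basal = promoter_profile("Os.hsp18", 0.073, 0.052, 1.190,
                                   scale_tag = scale_tag),
    suitability = promoter_profile("Os.hsp82", 0.033, 0.001, 0.650,
                                   scale_tag = scale_tag)
  )
}

#' Mean basal expression over a tissue panel
#'
#' Arithmetic mean of the gene's expression across all samples whose tissue
#' belongs to the panel, pooled over genotypes and replicates.
#'
#' @param compendium An [expression_compendium()].
#' @param gene_id Gene present in the compendium.
#' @param panel Character vector of tissue labels ([tissue_panel()] by
#'   default).
#' @return Nonnegative scalar.
#' @export
panel_mean <- function(compendium, gene_id, panel = tissue_panel()) {
  if (!gene_id %in% rownames(compendium$values)) {
    abort(paste0("gene not in compendium: ", gene_id),
          class = "promscreen_usage_error")
  }
  ids <- compendium$annotations$sample_id[compendium$annotations$tissue %in% panel]
  if (!length(ids)) {
    abort("no samples match the tissue panel", class = "promscreen_usage_error")
  }
  mean(compendium$values[gene_id, ids])
}

#' Assemble a promoter profile from a compendium
#'
#' Computes the panel mean, the control level (mean over uninduced samples
#' of the same tissue(s) as the inducing treatment), the induced level, and
#' one induced-over-control fold per additional stress condition
#' (pseudocount `eps` in the denominator, as in the induction screen).
#'
#' @inheritParams panel_mean
#' @param control,induced Condition labels. Control and stress levels are
#'   measured in the same tissue(s) in which the inducing condition was
#'   applied, so basal tissue activity does not leak into stress folds.
#' @param stresses Character vector of non-target stress condition labels;
#'   conditions absent from the compendium are skipped.
#' @param eps Pseudocount for fold denominators.
#' @return A [promoter_profile()] carrying the compendium's `scale_tag`.
#' @export
build_profile <- function(compendium, gene_id, panel = tissue_panel(),
                          control = "control", induced = "heat",
                          stresses = c("cold", "salt", "drought"),
                          eps = 1e-6) {
  ann <- compendium$annotations
  v <- compendium$values
  if (!gene_id %in% rownames(v)) {
    abort(paste0("gene not in compendium: ", gene_id),
          class = "promscreen_usage_error")
  }
  ind_ids <- select_samples(compendium, induced)
  ind_tissues <- unique(ann$tissue[ann$sample_id %in% ind_ids])
  ctl_ids <- ann$sample_id[ann$condition == control & ann$tissue %in% ind_tissues]
  if (!length(ctl_ids)) ctl_ids <- select_samples(compendium, control)
  pm <- panel_mean(compendium, gene_id, panel)
  ctl <- mean(v[gene_id, ctl_ids])
  ind <- mean(v[gene_id, ind_ids])
  stresses <- intersect(stresses, unique(ann$condition))
  folds <- vapply(stresses, function(s) {
    s_ids <- ann$sample_id[ann$condition == s]
    s_tissues <- unique(ann$tissue[ann$sample_id %in% s_ids])
    c_ids <- ann$sample_id[ann$condition == control & ann$tissue %in% s_tissues]
    if (!length(c_ids)) c_ids <- ctl_ids
    (mean(v[gene_id, s_ids]) + eps) / (mean(v[gene_id, c_ids]) + eps)
  }, numeric(1))
  promoter_profile(gene_id, pm, ctl, ind, stress_folds = folds,
                   scale_tag = compendium$scale_tag)
}

#' Classify a candidate promoter against the anchor thresholds
#'
#' Rules, applied in order (all anchor comparisons inclusive, so an anchor
#' gene classifies by its own thresholds):
#' 1. `NOT_INDUCIBLE` — induced level below the suitability anchor's
#'    induced level, or control level above the upper basal anchor's
#'    control level (the pre-screen conditions fail);
#' 2. `SUITABLE` — panel mean at or below the suitability anchor's panel
#'    mean (basal activity low enough for phytotoxic cargo);
#' 3. `MARGINAL` — panel mean at or below the upper basal anchor's panel
#'    mean (reporter-compatible, phytotoxic-incompatible);
#' 4. `UNSUITABLE` — otherwise.
#'
#' `NOT_INDUCIBLE` takes precedence so constitutive low-expression genes
#' are never reported as suitable. The call is a pure function of the
#' profile and the anchors.
#'
#' @param profile A [promoter_profile()].
#' @param anchors An [anchor_set()] on the same scale as the profile.
#' @return A one-row tibble of class `suitability_call` with columns
#'   `gene_id`, `class`, `panel_mean`, `control_level`, `induced_level` and
#'   a `reasons` list-column recording every comparison made.
#' @examples
#' p <- promoter_profile("Os.hsp82", 0.033, 0.001, 0.650, scale_tag = "CREP")
#' classify_promoter(p, default_anchors())
#' @export
classify_promoter <- function(profile, anchors) {
  stopifnot(inherits(profile, "promoter_profile"), inherits(anchors, "anchor_set"))
  if (!identical(profile$scale_tag, anchors$scale_tag)) {
    abort(sprintf("profile scale '%s' does not match anchor scale '%s'",
                  profile$scale_tag, anchors$scale_tag),
          class = "promscreen_usage_error")
  }
  up <- anchors$upper_basal
  su <- anchors$suitability
  reasons <- character(0)
  note <- function(txt) reasons <<- c(reasons, txt)

  induc_ok <- profile$induced_level >= su$induced_level
  note(sprintf("induced %.4g %s suitability-anchor induced %.4g",
               profile$induced_level, if (induc_ok) ">=" else "<",
               su$induced_level))
  basal_ok <- profile$control_level <= up$control_level
  note(sprintf("control %.4g %s upper-anchor control %.4g",
               profile$control_level, if (basal_ok) "<=" else ">",
               up$control_level))
  if (!induc_ok || !basal_ok) {
    klass <- "NOT_INDUCIBLE"
  } else if (profile$panel_mean <= su$panel_mean) {
    note(sprintf("panel mean %.4g <= suitability-anchor panel %.4g",
                 profile$panel_mean, su$panel_mean))
    klass <- "SUITABLE"
  } else if (profile$panel_mean <= up$panel_mean) {
    note(sprintf("panel mean %.4g in (suitability %.4g, upper %.4g]",
                 profile$panel_mean, su$panel_mean, up$panel_mean))
    klass <- "MARGINAL"
  } else {
    note(sprintf("panel mean %.4g > upper-anchor panel %.4g",
                 profile$panel_mean, up$panel_mean))
    klass <- "UNSUITABLE"
  }
  out <- tibble(
    gene_id = profile$gene_id,
    class = klass,
    panel_mean = profile$panel_mean,
    control_level = profile$control_level,
    induced_level = profile$induced_level,
    reasons = list(reasons)
  )
  class(out) <- c("suitability_call", class(out))
  out
}

#' Cross-stress specificity check
#'
#' A candidate inducible promoter must respond to its target stimulus only.
#' Each non-target stress counts as inducing when its fold is at least
#' `induction_fold_min` (default 2, operationalizing "no induction" as
#' fold below 2); the overall verdict passes when no stress induces. An
#' empty stress set passes vacuously and is flagged.
#'
#' @param profile A [promoter_profile()] with `stress_folds`.
#' @param induction_fold_min Fold at or above which a stress counts as
#'   inducing.
#' @return A list with `per_stress` (tibble: stress, fold, induces),
#'   `pass` (logical) and `reasons`.
#' @export
specificity_check <- function(profile, induction_fold_min = 2) {
  folds <- profile$stress_folds
  if (!length(folds)) {
    return(list(per_stress = tibble(stress = character(0), fold = numeric(0),
                                    induces = logical(0)),
                pass = TRUE,
                reasons = "no non-target stresses measured: vacuous pass"))
  }
  per <- tibble(stress = names(folds), fold = unname(folds),
                induces = unname(folds) >= induction_fold_min)
  list(per_stress = per,
       pass = !any(per$induces),
       reasons = sprintf("%s fold %.3g %s threshold %.3g", per$stress, per$fold,
                         ifelse(per$induces, ">=", "<"), induction_fold_min))
}

#' Hierarchically cluster candidate genes over the tissue panel
#'
#' Agglomerative clustering of genes by their expression across all panel
#' samples, using Euclidean distance on `log10(x + eps)` with average
#' linkage by default (basal expression spans orders of magnitude, so the
#' log scale keeps high expressors from dominating). Genes are ordered by
#' `gene_id` before clustering so the result is deterministic and
#' independent of input order.
#'
#' @inheritParams panel_mean
#' @param gene_ids Genes to cluster (at least one).
#' @param eps Offset before the log transform.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list with `leaf_order` (gene ids in dendrogram order),
#'   `hclust` (the merge tree, `NULL` for a single gene) and `log_values`
#'   (the transformed gene x panel-sample matrix).
#' @export
cluster_candidates <- function(compendium, gene_ids, panel = tissue_panel(),
                               eps = 1e-6, linkage = "average") {
  stopifnot(length(gene_ids) >= 1)
  missing <- setdiff(gene_ids, rownames(compendium$values))
  if (length(missing)) {
    abort(paste0("gene(s) not in compendium: ", paste(missing, collapse = ", ")),
          class = "promscreen_usage_error")
  }
  ids <- compendium$annotations$sample_id[compendium$annotations$tissue %in% panel]
  if (!length(ids)) {
    abort("no samples match the tissue panel", class = "promscreen_usage_error")
  }
  gene_ids <- sort(unique(gene_ids))
  lv <- log10(compendium$values[gene_ids, ids, drop = FALSE] + eps)
  if (length(gene_ids) == 1L) {
    return(list(leaf_order = gene_ids, hclust = NULL, log_values = lv))
  }
  hc <- hclust(dist(lv, method = "euclidean"), method = linkage)
  list(leaf_order = gene_ids[hc$order], hclust = hc, log_values = lv)
}

klass_levels <- c("SUITABLE", "MARGINAL", "UNSUITABLE", "NOT_INDUCIBLE")

#' Prospective genome-wide screen for suitable inducible promoters
#'
#' Profiles every gene of the compendium, applies the pre-screen (induced
#' level at or above the suitability anchor's induced level AND control
#' level at or below the upper basal anchor's control level), classifies
#' the survivors against the anchors and ranks them: class
#' (SUITABLE < MARGINAL < UNSUITABLE), then induced level descending, then
#' panel mean ascending, then `gene_id`. The ranking is invariant under
#' permutation of the compendium's gene rows.
#'
#' @inheritParams build_profile
#' @param anchors An [anchor_set()] on the compendium's scale.
#' @return A tibble of ranked suitability calls (pre-screen survivors
#'   only), with columns `rank`, `gene_id`, `class`, `panel_mean`,
#'   `control_level`, `induced_level` and `reasons`.
#' @export
prospective_screen <- function(compendium, anchors, panel = tissue_panel(),
                               control = "control", induced = "heat",
                               stresses = c("cold", "salt", "drought"),
                               eps = 1e-6) {
  genes <- rownames(compendium$values)
  if (!length(genes)) {
    return(tibble(rank = integer(0), gene_id = character(0), class = character(0),
                  panel_mean = numeric(0), control_level = numeric(0),
                  induced_level = numeric(0), reasons = list()))
  }
  profs <- map(genes, build_profile, compendium = compendium, panel = panel,
               control = control, induced = induced, stresses = stresses,
               eps = eps)
  keep <- map_dbl(profs, "induced_level") >= anchors$suitability$induced_level &
    map_dbl(profs, "control_level") <= anchors$upper_basal$control_level
  profs <- profs[keep]
  if (!length(profs)) {
    return(tibble(rank = integer(0), gene_id = character(0), class = character(0),
                  panel_mean = numeric(0), control_level = numeric(0),
                  induced_level = numeric(0), reasons = list()))
  }
  calls <- bind_rows(map(profs, classify_promoter, anchors = anchors))
  calls <- calls |>
    mutate(class = factor(.data$class, levels = klass_levels)) |>
    arrange(.data$class, desc(.data$induced_level), .data$panel_mean,
            .data$gene_id) |>
    mutate(class = as.character(.data$class), rank = dplyr::row_number()) |>
    select("rank", dplyr::everything())
  calls
}
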