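# Induction screen: per-probe control/induced means, fold and difference,
# plus the threshold filters used to shortlist heat-shock-inducible genes.

#' Screening criteria for inducible candidates
#'
#' The primary filter is the induced-minus-control difference on the
#' normalized linear scale (default 5500 units, applied strictly: a
#' candidate must be *more than* `difference_min` units higher under
#' induction). Two optional absolute bounds reproduce secondary
#' observations: `induced_min` (e.g. 10000 units flags the very-high
#' expressors) and `control_max`.
#'
#' @param difference_min Minimum induced-minus-control difference
#'   (exclusive). Must be `>= 0`.
#' @param induced_min Optional inclusive lower bound on the induced mean.
#' @param control_max Optional inclusive upper bound on the control mean.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(difference_min = 5500, induced_min = NULL,
                            control_max = NULL) {
  if (!is.null(difference_min) && difference_min < 0) {
    abort("difference_min must be >= 0", class = "promscreen_usage_error")
  }
  structure(list(difference_min = difference_min, induced_min = induced_min,
                 control_max = control_max),
            class = "screen_criteria")
}

select_samples <- function(compendium, condition) {
  ids <- compendium$annotations$sample_id[compendium$annotations$condition == condition]
  if (!length(ids)) {
    abort(paste0("condition selector matches no samples: '", condition, "'"),
          class = "promscreen_usage_error")
  }
  ids
}

#' Per-probe induction statistics
#'
#' For every gene (probe) row of the compendium, computes the arithmetic
#' mean over control replicates and over induced replicates on the linear
#' scale, their difference (induced minus control) and the fold change
#' `mean_induced / max(mean_control, eps)`. The pseudocount `eps` only
#' matters for probes whose control mean is exactly zero, which real
#' normalized arrays do not produce but synthetic data may.
#'
#' @param compendium An [expression_compendium()].
#' @param control,induced Condition labels selecting the control and
#'   induced replicate samples; each must match at least one sample.
#' @param gene_map Optional two-column data frame (`probe_id`, `gene_id`)
#'   mapping each probe to its gene (many probes to one gene). When absent,
#'   `gene_id` equals `probe_id`.
#' @param eps Pseudocount guarding the fold denominator.
#' @return A tibble with columns `probe_id`, `gene_id`, `mean_control`,
#'   `mean_induced`, `fold`, `difference`, one row per compendium row.
#' @examples
#' cc <- generate_hs_compendium()$compendium
#' stats <- compute_induction_stats(cc, control = "control", induced = "heat")
#' stats[which.max(stats$fold), ]
#' @export
compute_induction_stats <- function(compendium, control = "control",
                                    induced = "heat", gene_map = NULL,
                                    eps = 1e-6) {
  ctl <- select_samples(compendium, control)
  ind <- select_samples(compendium, induced)
  v <- compendium$values
  mean_control <- rowMeans(v[, ctl, drop = FALSE])
  mean_induced <- rowMeans(v[, ind, drop = FALSE])
  probe_id <- rownames(v)
  if (is.null(gene_map)) {
    gene_id <- probe_id
  } else {
    if (anyDuplicated(gene_map$probe_id)) {
      abort("gene_map maps some probe to more than one gene",
            class = "promscreen_usage_error")
    }
    gene_id <- gene_map$gene_id[match(probe_id, gene_map$probe_id)]
    gene_id[is.na(gene_id)] <- probe_id[is.na(gene_id)]
  }
  tibble(
    probe_id = probe_id,
    gene_id = gene_id,
    mean_control = unname(mean_control),
    mean_induced = unname(mean_induced),
    fold = unname(mean_induced / pmax(mean_control, eps)),
    difference = unname(mean_induced - mean_control)
  )
}

#' Filter induction records against screening criteria
#'
#' Keeps records whose difference strictly exceeds `difference_min`, whose
#' induced mean is at least `induced_min` (when set) and whose control mean
#' is at most `control_max` (when set). Output is sorted by difference
#' descending with ties broken by `probe_id` lexicographically, so the
#' result is deterministic regardless of input order.
#'
#' @param records Tibble of induction records from
#'   [compute_induction_stats()].
#' @param criteria A [screen_criteria()] object.
#' @return The surviving subset of `records`, re-sorted.
#' @export
screen_candidates <- function(records, criteria = screen_criteria()) {
  stopifnot(inherits(criteria, "screen_criteria"))
  out <- records
  if (!is.null(criteria$difference_min)) {
    out <- filter(out, .data$difference > .env$criteria$difference_min)
  }
  if (!is.null(criteria$induced_min)) {
    out <- filter(out, .data$mean_induced >= .env$criteria$induced_min)
  }
  if (!is.null(criteria$control_max)) {
    out <- filter(out, .data$mean_control <= .env$criteria$control_max)
  }
  arrange(out, desc(.data$difference), .data$probe_id)
}

#' Collapse probe-level records to one record per gene
#'
#' Several array probes can interrogate the same gene. For each distinct
#' `gene_id` the probe with the highest induced mean is kept as the
#' representative (ties broken by `probe_id` lexicographic order), so the
#' operation is idempotent and invariant under input permutation.
#'
#' @param records Tibble of induction records carrying `gene_id`.
#' @return One record per distinct gene, sorted by difference descending
#'   then `probe_id`.
#' @export
collapse_to_genes <- function(records) {
  if (!nrow(records)) return(records)
  out <- records |>
    arrange(desc(.data$mean_induced), .data$probe_id) |>
    group_by(.data$gene_id) |>
    dplyr::slice(1L) |>
    ungroup()
  arrange(out, desc(.data$difference), .data$probe_id)
}
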