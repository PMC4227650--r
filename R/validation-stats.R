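# Quantitative validation statistics: efficiency-corrected qPCR relative
# expression, geNORM reference-gene stability, transgene copy-number calls
# and normalized transformation efficiency.

check_efficiency <- function(e, what = "efficiency") {
  if (any(e <= 1 | e > 2)) {
    abort(paste0(what, " must be an amplification factor in (1, 2]"),
          class = "promscreen_usage_error")
  }
  invisible(e)
}

#' Efficiency-corrected relative expression from Ct values
#'
#' Expression of a target relative to a reference gene from quantification
#' cycles: `eff_ref^ct_ref / eff_target^ct_target`, which reduces to the
#' familiar `2^(ct_ref - ct_target)` when both assays amplify perfectly
#' (factor 2 per cycle). Vectors of replicate Ct values are averaged
#' *before* exponentiation. Efficiencies are amplification factors in
#' (1, 2]; a 0-1 efficiency `e` from a standard curve corresponds to
#' `1 + e`.
#'
#' @param ct_target,ct_ref Ct values (replicates allowed; averaged).
#' @param eff_target,eff_ref Amplification factors in (1, 2].
#' @return Fold expression of the target relative to the reference.
#' @examples
#' relative_expression(20, 30)            # 2^10 = 1024
#' relative_expression(20, 22, 1.9, 2.0)  # efficiency-corrected
#' @export
relative_expression <- function(ct_target, ct_ref, eff_target = 2, eff_ref = 2) {
  check_efficiency(eff_target, "eff_target")
  check_efficiency(eff_ref, "eff_ref")
  if (any(c(ct_target, ct_ref) <= 0)) {
    abort("Ct values must be positive", class = "promscreen_usage_error")
  }
  eff_ref^mean(ct_ref) / eff_target^mean(ct_target)
}

#' Summarise a Ct table into fold expression versus a reference gene
#'
#' Convenience wrapper over [relative_expression()]: for every
#' (sample, target) pair in a long Ct table, averages replicate Ct values
#' and reports the efficiency-corrected fold versus the reference gene
#' measured in the same sample.
#'
#' @param ct_table Data frame with columns `sample_id`, `target_id`, `ct`
#'   and `efficiency` (amplification factor per cycle in (1, 2]).
#' @param reference Identifier of the reference gene in `target_id`.
#' @return Tibble with `sample_id`, `target_id`, `fold`.
#' @export
relative_expression_table <- function(ct_table, reference) {
  ct_table <- as_tibble(ct_table)
  stopifnot(all(c("sample_id", "target_id", "ct", "efficiency") %in% names(ct_table)))
  check_efficiency(ct_table$efficiency)
  if (!reference %in% ct_table$target_id) {
    abort(paste0("reference gene absent from Ct table: ", reference),
          class = "promscreen_usage_error")
  }
  means <- ct_table |>
    group_by(.data$sample_id, .data$target_id) |>
    summarise(ct = mean(.data$ct), efficiency = mean(.data$efficiency),
              .groups = "drop")
  ref <- means |>
    filter(.data$target_id == reference) |>
    select("sample_id", ct_ref = "ct", eff_ref = "efficiency")
  means |>
    filter(.data$target_id != reference) |>
    dplyr::inner_join(ref, by = "sample_id") |>
    mutate(fold = .data$eff_ref^.data$ct_ref / .data$efficiency^.data$ct) |>
    select("sample_id", "target_id", "fold")
}

#' geNORM expression-stability measure M
#'
#' For candidate reference genes measured as relative quantities across a
#' common sample set, the stability of gene *j* is the average, over every
#' other candidate *k*, of the standard deviation (n-1 denominator) across
#' samples of `log2(q_j / q_k)`. A perfectly stable pair has constant
#' ratio, hence SD 0; `M = 0` exactly when the gene is proportional to
#' every other candidate. Lower M means more stable; M below 0.5 is the
#' conventional bar for a usable reference gene. M is invariant to
#' per-sample global scaling and to gene order.
#'
#' @param quantities Numeric matrix (genes x samples, rownames required) or
#'   wide data frame with first column `gene_id`, of strictly positive
#'   relative quantities. At least 2 genes and 2 samples.
#' @return Tibble of class `genorm_result` with columns `gene_id` and `M`,
#'   in input gene order.
#' @examples
#' q <- rbind(A = c(1, 2, 4, 8), B = c(2, 4, 8, 16), C = c(1, 1, 1, 1))
#' genorm_m(q)
#' @export
genorm_m <- function(quantities) {
  if (is.data.frame(quantities)) {
    m <- as.matrix(quantities[-1])
    rownames(m) <- as.character(quantities[[1]])
    quantities <- m
  }
  if (!is.matrix(quantities) || nrow(quantities) < 2L || ncol(quantities) < 2L) {
    abort("need a matrix of at least 2 genes x 2 samples",
          class = "promscreen_usage_error")
  }
  if (any(!is.finite(quantities) | quantities <= 0)) {
    abort("all quantities must be finite and > 0",
          class = "promscreen_usage_error")
  }
  lg <- log2(quantities)
  g <- nrow(lg)
  M <- vapply(seq_len(g), function(j) {
    sds <- vapply(setdiff(seq_len(g), j),
                  function(k) sd(lg[j, ] - lg[k, ]), numeric(1))
    mean(sds)
  }, numeric(1))
  out <- tibble(gene_id = rownames(lg), M = M)
  class(out) <- c("genorm_result", class(out))
  out
}

#' Iterative geNORM ranking by stepwise exclusion
#'
#' Optional mode: repeatedly drops the least stable gene (highest M,
#' ties broken by `gene_id`) and recomputes M among the remainder, until
#' two genes are left. The exclusion order ranks candidates from least to
#' most stable.
#'
#' @inheritParams genorm_m
#' @return Tibble with `gene_id`, `M_at_exclusion` and `order_excluded`
#'   (`NA` for the final, most stable pair).
#' @export
genorm_rank <- function(quantities) {
  if (is.data.frame(quantities)) {
    m <- as.matrix(quantities[-1]); rownames(m) <- as.character(quantities[[1]])
    quantities <- m
  }
  excluded <- character(0); m_at <- numeric(0)
  current <- quantities
  while (nrow(current) > 2L) {
    res <- genorm_m(current)
    worst <- res$gene_id[order(-res$M, res$gene_id)][1]
    excluded <- c(excluded, worst)
    m_at <- c(m_at, res$M[res$gene_id == worst])
    current <- current[setdiff(rownames(current), worst), , drop = FALSE]
  }
  final <- genorm_m(current)
  tibble(
    gene_id = c(excluded, final$gene_id),
    M_at_exclusion = c(m_at, final$M),
    order_excluded = c(seq_along(excluded), NA_integer_, NA_integer_)
  )
}

#' Convert a Ct table to relative quantities for stability analysis
#'
#' The classic transformation: per gene, quantity `E^(Ct_min - Ct)` so the
#' best-expressed sample has quantity 1. Replicate Ct rows are averaged
#' per (sample, gene) first.
#'
#' @inheritParams relative_expression_table
#' @return Wide matrix of relative quantities (genes x samples).
#' @export
ct_to_quantity <- function(ct_table) {
  ct_table <- as_tibble(ct_table)
  check_efficiency(ct_table$efficiency)
  means <- ct_table |>
    group_by(.data$sample_id, .data$target_id) |>
    summarise(ct = mean(.data$ct), efficiency = mean(.data$efficiency),
              .groups = "drop")
  wide <- means |>
    group_by(.data$target_id) |>
    mutate(q = .data$efficiency^(min(.data$ct) - .data$ct)) |>
    ungroup() |>
    select("target_id", "sample_id", "q") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "q")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$target_id
  m
}

#' Call transgene copy number from a qPCR ratio
#'
#' The ratio of transgene to a diploid endogenous reference sequence is
#' about 0.5 for a hemizygous single-copy insertion (one transgene allele
#' versus two endogene alleles). Default windows: below 0.1 `absent`;
#' 0.25 to 1.0 `single`; above 1.0 `multi`; ratios in [0.1, 0.25) are
#' called `single` but flagged indeterminate with a warning. Windows are
#' configurable.
#'
#' @param ratio Nonnegative numeric vector of transgene/endogene relative
#'   quantities.
#' @param absent_below,single_min,single_max Window bounds.
#' @return Tibble with `ratio`, `call` (absent | single | multi) and
#'   `indeterminate`.
#' @examples
#' copy_number_call(c(0.63, 0.0, 2.1))
#' @export
copy_number_call <- function(ratio, absent_below = 0.1, single_min = 0.25,
                             single_max = 1.0) {
  if (any(ratio < 0)) {
    abort("ratio must be >= 0", class = "promscreen_usage_error")
  }
  call <- dplyr::case_when(
    ratio < absent_below ~ "absent",
    ratio > single_max ~ "multi",
    TRUE ~ "single"
  )
  indet <- ratio >= absent_below & ratio < single_min
  if (any(indet)) {
    warn(sprintf("%d ratio(s) in [%.3g, %.3g): indeterminate single-copy call",
                 sum(indet), absent_below, single_min))
  }
  tibble(ratio = ratio, call = call, indeterminate = indet)
}

#' Normalized transformation efficiency and workability
#'
#' Raw efficiency is fertile transgenic plants per initial callus;
#' normalized efficiency expresses it as a percentage of the control
#' (empty-vector) construct. A construct whose efficiency falls 30-fold or
#' more below the control (normalized efficiency under 100/30 ~ 3.33%) is
#' classed not workable.
#'
#' @param records Data frame with columns `construct_id`, `n_fertile`,
#'   `n_calli` (nonnegative counts).
#' @param control_id `construct_id` of the control construct; must be
#'   present with positive counts.
#' @param workable_min Normalized-efficiency workability bound (percent).
#' @return Tibble with `construct_id`, `n_fertile`, `n_calli`,
#'   `raw_efficiency`, `normalized_efficiency` (percent of control) and
#'   `workable`.
#' @examples
#' rec <- tibble::tibble(construct_id = c("ctrl", "hsp82", "hsp18"),
#'                       n_fertile = c(10, 5, 0), n_calli = c(100, 50, 120))
#' transformation_efficiency(rec, "ctrl")
#' @export
transformation_efficiency <- function(records, control_id,
                                      workable_min = 100 / 30) {
  records <- as_tibble(records)
  stopifnot(all(c("construct_id", "n_fertile", "n_calli") %in% names(records)))
  if (any(records$n_fertile < 0) || any(records$n_calli < 0)) {
    abort("counts must be >= 0", class = "promscreen_usage_error")
  }
  if (any(records$n_calli == 0)) {
    abort("zero initial calli for some construct", class = "promscreen_usage_error")
  }
  if (!control_id %in% records$construct_id) {
    abort(paste0("control construct absent: ", control_id),
          class = "promscreen_usage_error")
  }
  raw_control <- with(records[records$construct_id == control_id, ],
                      n_fertile / n_calli)[1]
  if (raw_control <= 0) {
    abort("control construct produced no fertile plants; cannot normalize",
          class = "promscreen_usage_error")
  }
  records |>
    mutate(raw_efficiency = .data$n_fertile / .data$n_calli,
           normalized_efficiency = 100 * .data$raw_efficiency / raw_control,
           workable = .data$normalized_efficiency >= workable_min)
}
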