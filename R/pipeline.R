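# End-to-end orchestration: screen -> collapse -> profile -> specificity ->
# classify -> rank, with config handling and report/log emission.

#' Assemble a pipeline configuration
#'
#' All thresholds and anchors flow through the configuration; nothing is
#' hard-coded in the pipeline body. Either an in-memory compendium or a
#' pair of matrix/annotation paths must be supplied.
#'
#' @param compendium An [expression_compendium()], or `NULL` to read from
#'   `matrix_path`/`annotation_path`.
#' @param matrix_path,annotation_path TSV paths (used when `compendium` is
#'   `NULL`).
#' @param geo_style Tolerant matrix parsing (skip `!` lines).
#' @param scale_tag Scale tag for a compendium read from disk.
#' @param control,induced,stresses Condition labels.
#' @param panel Tissue panel for basal profiling.
#' @param criteria A [screen_criteria()] object.
#' @param anchors An [anchor_set()], or a path to a JSON/YAML anchor file
#'   (see [read_anchors()]).
#' @param gene_map Optional probe-to-gene map (tibble or TSV path with
#'   columns `probe_id`, `gene_id`).
#' @param specificity_fold_min Fold at or above which a non-target stress
#'   counts as inducing.
#' @param eps Pseudocount shared by fold computations.
#' @param out_dir Optional directory for `report.tsv`, `report.json` and
#'   `run_log.txt`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(compendium = NULL, matrix_path = NULL,
                            annotation_path = NULL, geo_style = FALSE,
                            scale_tag = "unspecified",
                            control = "control", induced = "heat",
                            stresses = c("cold", "salt", "drought"),
                            panel = tissue_panel(),
                            criteria = screen_criteria(),
                            anchors = NULL, gene_map = NULL,
                            specificity_fold_min = 2, eps = 1e-6,
                            out_dir = NULL) {
  if (is.null(compendium) &&
      (is.null(matrix_path) || is.null(annotation_path))) {
    abort("supply a compendium or both matrix_path and annotation_path",
          class = "promscreen_usage_error")
  }
  if (is.null(anchors)) {
    abort("an anchor set (object or file path) is required",
          class = "promscreen_usage_error")
  }
  structure(list(compendium = compendium, matrix_path = matrix_path,
                 annotation_path = annotation_path, geo_style = geo_style,
                 scale_tag = scale_tag, control = control, induced = induced,
                 stresses = stresses, panel = panel, criteria = criteria,
                 anchors = anchors, gene_map = gene_map,
                 specificity_fold_min = specificity_fold_min, eps = eps,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read an anchor set from a JSON or YAML file
#'
#' The file holds `scale_tag` plus `upper_basal` and `suitability` entries,
#' each with `gene_id`, `panel_mean`, `control_level`, `induced_level`.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return An [anchor_set()].
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such anchor file: ", path), class = "promscreen_io_error")
  }
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  mk <- function(p) promoter_profile(p$gene_id, p$panel_mean, p$control_level,
                                     p$induced_level,
                                     scale_tag = spec$scale_tag)
  anchor_set(upper_basal = mk(spec$upper_basal),
             suitability = mk(spec$suitability))
}

#' Write an anchor set to JSON
#'
#' @param anchors An [anchor_set()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  as_list <- function(p) list(gene_id = p$gene_id, panel_mean = p$panel_mean,
                              control_level = p$control_level,
                              induced_level = p$induced_level)
  jsonlite::write_json(
    list(scale_tag = anchors$scale_tag,
         upper_basal = as_list(anchors$upper_basal),
         suitability = as_list(anchors$suitability)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "promscreen_pipeline_error", parent = e)
  })
}

empty_report <- function() {
  out <- tibble(rank = integer(0), gene_id = character(0),
                probe_id = character(0), mean_control = numeric(0),
                mean_induced = numeric(0), fold = numeric(0),
                difference = numeric(0), panel_mean = numeric(0),
                control_level = numeric(0), induced_level = numeric(0),
                class = character(0), specific = logical(0),
                reasons = character(0))
  class(out) <- c("candidate_report", class(out))
  out
}

#' Run the full promoter-selection pipeline
#'
#' Deterministic chain: per-probe induction statistics, threshold screen,
#' probe-to-gene collapse, basal profiling over the tissue panel,
#' cross-stress specificity, anchor classification and ranking. When
#' `out_dir` is set, writes `report.tsv`, `report.json` (including full
#' rule firings) and `run_log.txt` recording every resolved threshold, so
#' a run is auditable and byte-identically repeatable.
#'
#' @param config A [pipeline_config()].
#' @return A `candidate_report` tibble: one ranked row per candidate gene
#'   with induction statistics, profile levels, class, specificity verdict
#'   and reasons.
#' @examples
#' sim <- generate_compendium(c(anchor_archetypes(), default_archetypes()),
#'                            noise_sd_log = 0, seed = 7)
#' cfg <- pipeline_config(compendium = sim$compendium,
#'                        criteria = screen_criteria(difference_min = 0.5),
#'                        anchors = default_anchors(scale_tag = "synthetic"))
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  compendium <- stage("read", {
    if (is.null(config$compendium)) {
      read_compendium(config$matrix_path, config$annotation_path,
                      geo_style = config$geo_style,
                      scale_tag = config$scale_tag)
    } else {
      validate_compendium(config$compendium)
    }
  })
  anchors <- stage("anchors", {
    if (inherits(config$anchors, "anchor_set")) config$anchors
    else read_anchors(config$anchors)
  })
  gene_map <- stage("gene_map", {
    gm <- config$gene_map
    if (is.character(gm)) {
      gm <- readr::read_tsv(gm, show_col_types = FALSE, progress = FALSE)
    }
    gm
  })

  records <- stage("induction", {
    compute_induction_stats(compendium, control = config$control,
                            induced = config$induced, gene_map = gene_map,
                            eps = config$eps)
  })
  survivors <- stage("screen", screen_candidates(records, config$criteria))
  collapsed <- stage("collapse", collapse_to_genes(survivors))

  if (!nrow(collapsed)) {
    report <- empty_report()
  } else {
    rows <- stage("profile+classify", {
      map(seq_len(nrow(collapsed)), function(i) {
        rec <- collapsed[i, ]
        prof <- build_profile(compendium, rec$probe_id, panel = config$panel,
                              control = config$control, induced = config$induced,
                              stresses = config$stresses, eps = config$eps)
        prof$gene_id <- rec$gene_id
        call <- classify_promoter(prof, anchors)
        spec_res <- specificity_check(prof, config$specificity_fold_min)
        tibble(
          gene_id = rec$gene_id, probe_id = rec$probe_id,
          mean_control = rec$mean_control, mean_induced = rec$mean_induced,
          fold = rec$fold, difference = rec$difference,
          panel_mean = call$panel_mean, control_level = call$control_level,
          induced_level = call$induced_level, class = call$class,
          specific = spec_res$pass,
          reasons = paste(c(call$reasons[[1]], spec_res$reasons), collapse = "; ")
        )
      })
    })
    report <- bind_rows(rows) |>
      mutate(class = factor(.data$class, levels = klass_levels)) |>
      arrange(.data$class, desc(.data$induced_level), .data$panel_mean,
              .data$gene_id) |>
      mutate(class = as.character(.data$class), rank = dplyr::row_number()) |>
      select("rank", dplyr::everything())
    class(report) <- c("candidate_report", class(report))
  }
  attr(report, "config") <- resolved_config(config, compendium, anchors)
  if (!is.null(config$out_dir)) {
    stage("write", write_candidate_report(report, config$out_dir))
  }
  report
}

resolved_config <- function(config, compendium, anchors) {
  list(
    n_genes = nrow(compendium$values),
    n_samples = ncol(compendium$values),
    scale_tag = compendium$scale_tag,
    control = config$control, induced = config$induced,
    stresses = config$stresses, panel = config$panel,
    difference_min = config$criteria$difference_min,
    induced_min = config$criteria$induced_min,
    control_max = config$criteria$control_max,
    specificity_fold_min = config$specificity_fold_min,
    eps = config$eps,
    anchors = list(
      scale_tag = anchors$scale_tag,
      upper_basal = anchors$upper_basal[c("gene_id", "panel_mean",
                                          "control_level", "induced_level")],
      suitability = anchors$suitability[c("gene_id", "panel_mean",
                                          "control_level", "induced_level")]
    ),
    package_version = as.character(utils::packageVersion("promscreen"))
  )
}

write_candidate_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(report, file.path(out_dir, "report.tsv"))
  jsonlite::write_json(
    list(config = attr(report, "config"),
         candidates = as.data.frame(report)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- attr(report, "config")
  log_lines <- c(
    "promscreen run log",
    paste0("package_version\t", cfg$package_version),
    paste0("n_genes\t", cfg$n_genes),
    paste0("n_samples\t", cfg$n_samples),
    paste0("scale_tag\t", cfg$scale_tag),
    paste0("control\t", cfg$control),
    paste0("induced\t", cfg$induced),
    paste0("stresses\t", paste(cfg$stresses, collapse = ",")),
    paste0("panel\t", paste(cfg$panel, collapse = ",")),
    paste0("difference_min\t", format(cfg$difference_min)),
    paste0("induced_min\t", format(cfg$induced_min %||% NA)),
    paste0("control_max\t", format(cfg$control_max %||% NA)),
    paste0("specificity_fold_min\t", format(cfg$specificity_fold_min)),
    paste0("eps\t", format(cfg$eps)),
    paste0("anchor_scale\t", cfg$anchors$scale_tag),
    paste0("anchor_upper\t", paste(unlist(cfg$anchors$upper_basal), collapse = "\t")),
    paste0("anchor_suitability\t", paste(unlist(cfg$anchors$suitability), collapse = "\t")),
    paste0("n_candidates\t", nrow(report))
  )
  con <- file(file.path(out_dir, "run_log.txt"), open = "wb")
  on.exit(close(con))
  writeLines(log_lines, con, sep = "\n", useBytes = TRUE)
  invisible(out_dir)
}

#' Export a clustered matrix for heatmap plotting
#'
#' Orders the report's genes by the [cluster_candidates()] dendrogram leaf
#' order and exports their panel expression on the log10 scale, ready for
#' tile plotting or external tools. The export is a plain gene x sample
#' table (first column `gene_id`) readable by [read_matrix_tsv()].
#'
#' @param report A `candidate_report` (or any data frame with `gene_id`).
#' @param compendium The compendium the report was computed from. Genes are
#'   looked up by the report's `probe_id` when present (compendia are
#'   probe-indexed), else by `gene_id`.
#' @param panel Tissue panel defining the exported columns.
#' @param eps Offset before the log transform.
#' @return Tibble: `gene_id` plus one column per panel sample, log10 scale,
#'   rows in dendrogram leaf order.
#' @export
render_heatmap_table <- function(report, compendium, panel = tissue_panel(),
                                 eps = 1e-6) {
  key <- if ("probe_id" %in% names(report)) report$probe_id else report$gene_id
  if (!length(key)) {
    abort("report contains no genes", class = "promscreen_usage_error")
  }
  cl <- cluster_candidates(compendium, key, panel = panel, eps = eps)
  lv <- cl$log_values[cl$leaf_order, , drop = FALSE]
  out <- tibble(gene_id = rownames(lv))
  bind_cols(out, as_tibble(as.data.frame(lv, check.names = FALSE)))
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> %d candidate gene(s)\n", nrow(x)))
  if (nrow(x)) {
    counts <- table(factor(x$class, levels = klass_levels))
    cat("  ", paste(sprintf("%s: %d", names(counts), counts), collapse = " | "), "\n")
  }
  NextMethod()
}

#' Tidy a candidate report
#'
#' @param x A `candidate_report`.
#' @param ... Unused.
#' @return A plain tibble of per-gene rows (reasons dropped).
#' @export
tidy.candidate_report <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  select(out, -dplyr::any_of("reasons"))
}

#' One-row summary of a candidate report
#'
#' @param x A `candidate_report`.
#' @param ... Unused.
#' @return Tibble with candidate counts per class, the number of
#'   stress-specific candidates and the screening threshold used.
#' @export
glance.candidate_report <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_candidates = nrow(x),
    n_suitable = sum(x$class == "SUITABLE"),
    n_marginal = sum(x$class == "MARGINAL"),
    n_unsuitable = sum(x$class == "UNSUITABLE"),
    n_not_inducible = sum(x$class == "NOT_INDUCIBLE"),
    n_specific = sum(x$specific),
    difference_min = cfg$difference_min %||% NA_real_
  )
}
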