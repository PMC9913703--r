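#' Validate a pipeline configuration
#'
#' Checks, without running anything, that every stage's preconditions are
#' satisfiable from the configuration alone. Problems are returned, not
#' raised.
#'
#' @param config A named list; see [run_pipeline()] for the recognized keys.
#' @return Character vector of problems (empty when the config is valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need_file <- function(key) {
    if (is.null(config[[key]])) {
      problems <<- c(problems, paste0("missing required input path: ", key))
    } else if (!file.exists(config[[key]])) {
      problems <<- c(problems,
                     paste0(key, ": file not found: ", config[[key]]))
    }
  }
  for (key in c("expr", "contrasts", "cohort_a_expr", "cohort_a_anno",
                "cohort_b_expr", "cohort_b_anno")) need_file(key)
  cutoff <- config$cutoff %||% 1.5
  if (!is.numeric(cutoff) || cutoff <= 1)
    problems <- c(problems, "cutoff must exceed 1")
  alpha <- config$alpha %||% 0.25
  if (!is.numeric(alpha) || alpha < 0)
    problems <- c(problems, "alpha must be >= 0")
  p_threshold <- config$p_threshold %||% 0.05
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    problems <- c(problems, "p_threshold must be in (0, 1]")
  for (key in c("case_group", "control_group")) {
    if (is.null(config[[key]]))
      problems <- c(problems, paste0("missing required key: ", key))
  }
  if (is.null(config$out_dir))
    problems <- c(problems, "missing required key: out_dir")
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end signature pipeline
#'
#' Executes the four stages in order -- derive (fold-change intersection on
#' the cell-line matrix), refine (directional rank tests in two cohorts),
#' score (ssGSEA of the refined signature in both cohorts), associate
#' (group rank tests and stemness correlations on the scores) -- and writes
#' per-stage plain-text artifacts plus a machine-readable manifest
#' (parameters, input checksums, package version) and a log into `out_dir`.
#' Re-running on identical inputs reproduces identical outputs. A stage
#' failure halts the run, names the stage, and leaves partial outputs behind
#' alongside a `FAILED` marker file.
#'
#' Config keys: `expr`, `contrasts` (cell-line stage inputs); `cohort_a_expr`,
#' `cohort_a_anno`, `cohort_b_expr`, `cohort_b_anno` (cohort inputs);
#' `case_group`, `control_group`; optional `cutoff` (1.5), `alpha` (0.25),
#' `normalize` (TRUE), `p_threshold` (0.05), `signature_name` ("OSAP");
#' `out_dir`.
#'
#' @param config Named list, validated by [validate_config()] first.
#' @return Path of the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = log_path,
                                append = TRUE)
  completed <- character(0)
  run_stage <- function(stage, fun) {
    log_line("stage ", stage, ": start")
    res <- tryCatch(fun(), error = function(e) {
      log_line("stage ", stage, ": FAILED: ", conditionMessage(e))
      writeLines(paste0("failed at stage: ", stage), failed_marker)
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    log_line("stage ", stage, ": done")
    completed <<- c(completed, stage)
    res
  }

  cutoff <- config$cutoff %||% 1.5
  alpha <- config$alpha %||% 0.25
  normalize <- config$normalize %||% TRUE
  p_threshold <- config$p_threshold %||% 0.05
  sig_name <- config$signature_name %||% "OSAP"

  sig <- run_stage("derive", function() {
    expr <- read_expression(config$expr)
    specs <- read_contrasts(config$contrasts)
    fc <- compute_fold_changes(expr, specs)
    sig <- derive_core_signature(fc, cutoff = cutoff, name = sig_name)
    write_gmt(sig, file.path(out_dir, "signature.gmt"))
    utils::write.table(
      data.frame(gene_id = rownames(fc), fc, check.names = FALSE),
      file.path(out_dir, "fold_changes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sig
  })

  cohorts <- run_stage("refine", function() {
    load_cohort <- function(expr_key, anno_key, id) {
      expr <- read_expression(config[[expr_key]])
      anno <- read_sample_table(config[[anno_key]])
      for (grp in c(config$case_group, config$control_group)) {
        if (!grp %in% anno$group)
          stop("group '", grp, "' absent from ", anno_key)
      }
      list(expr = expr, anno = anno, id = id)
    }
    a <- load_cohort("cohort_a_expr", "cohort_a_anno", "A")
    b <- load_cohort("cohort_b_expr", "cohort_b_anno", "B")
    genes <- c(sig$up, sig$down)
    stats_of <- function(co) per_gene_rank_test(
      co$expr,
      case_ids = co$anno$sample_id[co$anno$group == config$case_group],
      control_ids = co$anno$sample_id[co$anno$group == config$control_group],
      genes = genes, cohort_id = co$id)
    stats_a <- stats_of(a)
    stats_b <- stats_of(b)
    refined <- refine_signature(sig, stats_a, stats_b,
                                p_threshold = p_threshold)
    write_gmt(refined, file.path(out_dir, "signature_refined.gmt"))
    utils::write.table(rbind(stats_a, stats_b),
                       file.path(out_dir, "gene_cohort_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(a = a, b = b, refined = refined)
  })

  scores <- run_stage("score", function() {
    params <- ssgsea_params(alpha = alpha, normalize = normalize)
    lapply(list(cohorts$a, cohorts$b), function(co) {
      sm <- suppressWarnings(
        score_samples(co$expr, list(sig, cohorts$refined), params))
      write_scores(sm, file.path(out_dir,
                                 paste0("scores_cohort_", co$id, ".tsv")))
      sm
    })
  })

  run_stage("associate", function() {
    rows <- do.call(rbind, lapply(seq_along(scores), function(i) {
      co <- list(cohorts$a, cohorts$b)[[i]]
      sm <- scores[[i]]
      do.call(rbind, lapply(rownames(sm), function(sig_nm) {
        v <- sm[sig_nm, co$anno$sample_id]
        cmp <- compare_groups(v, co$anno$group)
        out <- data.frame(cohort = co$id, signature = sig_nm,
                          test = cmp$test, statistic = cmp$statistic,
                          p_value = cmp$p_value, stringsAsFactors = FALSE)
        if ("stemness" %in% colnames(co$anno)) {
          sp <- spearman_cor(v, co$anno$stemness)
          out$stemness_rho <- sp$rho
          out$stemness_p <- sp$p_value
        }
        out
      }))
    }))
    utils::write.table(rows, file.path(out_dir, "association_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rows
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("osap")),
    parameters = list(cutoff = cutoff, alpha = alpha, normalize = normalize,
                      p_threshold = p_threshold,
                      case_group = config$case_group,
                      control_group = config$control_group,
                      signature_name = sig_name),
    inputs = as.list(tools::md5sum(unlist(config[c(
      "expr", "contrasts", "cohort_a_expr", "cohort_a_anno",
      "cohort_b_expr", "cohort_b_anno")]))),
    outputs = as.list(tools::md5sum(file.path(out_dir, c(
      "signature.gmt", "fold_changes.tsv", "signature_refined.gmt",
      "gene_cohort_stats.tsv", "scores_cohort_A.tsv", "scores_cohort_B.tsv",
      "association_stats.tsv")))),
    completed_stages = completed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("pipeline complete: ", length(completed), " stages")
  invisible(out_dir)
}
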