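#' Per-gene Wilcoxon rank-sum tests with Hodges-Lehmann shift estimates
#'
#' For each gene, compares case versus control samples of one cohort. The
#' location-shift estimate is the Hodges-Lehmann estimator: the median of all
#' pairwise differences (case value - control value), in log2 expression
#' units. The p-value is the two-sided Wilcoxon/Mann-Whitney rank-sum p,
#' computed by exact enumeration when the pooled size is at most
#' `exact_cutoff` and there are no ties, otherwise by the normal approximation
#' with tie and continuity corrections.
#'
#' @param matrix Expression matrix.
#' @param case_ids,control_ids Sample IDs of the two groups (>= 2 each).
#' @param genes Genes to test; genes absent from the matrix are skipped with
#'   a warning. Default: all genes.
#' @param cohort_id Label recorded in the output.
#' @param exact_cutoff Pooled-size threshold for the exact test. Default 20.
#' @return A data.frame: `gene_id`, `cohort_id`, `estimate`, `p_value`,
#'   `method`.
#' @export
per_gene_rank_test <- function(matrix, case_ids, control_ids,
                               genes = rownames(matrix),
                               cohort_id = "cohort", exact_cutoff = 20) {
  validate_expression_matrix(matrix)
  if (length(case_ids) < 2 || length(control_ids) < 2)
    stop("each group needs >= 2 samples")
  unknown <- setdiff(c(case_ids, control_ids), colnames(matrix))
  if (length(unknown))
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(genes, rownames(matrix))
  if (length(absent))
    warning("skipping gene(s) absent from cohort '", cohort_id, "': ",
            paste(absent, collapse = ", "), call. = FALSE)
  genes <- intersect(genes, rownames(matrix))
  if (!length(genes)) stop("no requested gene present in the matrix")
  res <- lapply(genes, function(g) {
    x <- matrix[g, case_ids]
    y <- matrix[g, control_ids]
    mw <- mann_whitney(x, y, exact_cutoff = exact_cutoff)
    data.frame(gene_id = g, cohort_id = cohort_id,
               estimate = stats::median(outer(x, y, "-")),
               p_value = mw$p_value, method = mw$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Refine a signature against two independent cohorts
#'
#' A gene of the input signature is retained when its case-versus-control
#' shift estimate has the same non-zero sign in both cohorts and its
#' rank-test p-value is below `p_threshold` in both (set
#' `p_threshold = NULL`, or 1, to require sign agreement only). Retained
#' genes are relabeled from the patient data: shared positive sign puts a
#' gene in the refined up set even if it was down in vitro -- this is how
#' inflammation-driven genes that fall in vitro but rise in diseased mucosa
#' are excluded from the refined down set.
#'
#' @param sig Input [gene_signature()].
#' @param stats_a,stats_b Per-cohort data.frames from [per_gene_rank_test()],
#'   covering the signature genes (genes missing from either cohort are
#'   dropped with a warning).
#' @param p_threshold Per-cohort two-sided p-value threshold (default 0.05).
#' @param adjust Optional multiple-testing adjustment applied per cohort
#'   before thresholding: `"none"` (default, per-gene screening use) or
#'   `"BH"` (Benjamini-Hochberg).
#' @return A [gene_signature()] named `"<name>_refined"`; genes within each
#'   side ordered by the mean absolute estimate, descending.
#' @export
refine_signature <- function(sig, stats_a, stats_b, p_threshold = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(p_threshold)) p_threshold <- 1
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]")
  universe <- c(sig$up, sig$down)
  a <- stats_a[match(universe, stats_a$gene_id), ]
  b <- stats_b[match(universe, stats_b$gene_id), ]
  covered <- !is.na(a$gene_id) & !is.na(b$gene_id)
  if (any(!covered))
    warning("gene(s) missing from a cohort, dropped: ",
            paste(universe[!covered], collapse = ", "), call. = FALSE)
  a <- a[covered, ]
  b <- b[covered, ]
  if (!nrow(a))
    stop("no signature gene is covered by both cohorts")
  pa <- if (adjust == "BH") stats::p.adjust(a$p_value, "BH") else a$p_value
  pb <- if (adjust == "BH") stats::p.adjust(b$p_value, "BH") else b$p_value
  keep <- sign(a$estimate) == sign(b$estimate) & sign(a$estimate) != 0 &
    pa < p_threshold & pb < p_threshold
  if (!any(keep))
    stop("refined signature is empty; consider relaxing p_threshold")
  strength <- (abs(a$estimate) + abs(b$estimate)) / 2
  up <- a$gene_id[keep & a$estimate > 0]
  down <- a$gene_id[keep & a$estimate < 0]
  up <- up[order(-strength[match(up, a$gene_id)], up, method = "radix")]
  down <- down[order(-strength[match(down, a$gene_id)], down,
                     method = "radix")]
  gene_signature(paste0(sig$name, "_refined"), up = up, down = down)
}
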