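#' Define a case-versus-reference comparison
#'
#' @param name Comparison name (e.g. `"esc_inf_A"`).
#' @param case_sample_ids,reference_sample_ids Disjoint, non-empty sample-ID
#'   vectors.
#' @return An object of class `ComparisonSpec`.
#' @export
comparison_spec <- function(name, case_sample_ids, reference_sample_ids) {
  case_sample_ids <- as.character(case_sample_ids)
  reference_sample_ids <- as.character(reference_sample_ids)
  if (!length(case_sample_ids) || !length(reference_sample_ids))
    stop("comparison '", name, "': case and reference must be non-empty")
  if (length(intersect(case_sample_ids, reference_sample_ids)))
    stop("comparison '", name, "': case and reference overlap")
  structure(list(name = name, case = case_sample_ids,
                 reference = reference_sample_ids),
            class = "ComparisonSpec")
}

#' Per-gene log2 fold changes for a set of comparisons
#'
#' Fold change is the difference of group means on the log2 scale:
#' `lfc[g, c] = mean(case) - mean(reference)` for gene `g` in comparison `c`.
#' (This differs from the log2 of the ratio of linear-scale means when groups
#' are replicated; the log-scale difference is used throughout.)
#'
#' @param matrix Log2-scale expression matrix with unique gene IDs.
#' @param specs List of [comparison_spec()] objects.
#' @return A genes x comparisons numeric matrix of log2 fold changes.
#' @export
compute_fold_changes <- function(matrix, specs) {
  validate_expression_matrix(matrix)
  if (inherits(specs, "ComparisonSpec")) specs <- list(specs)
  if (!length(specs)) stop("no comparisons given")
  lfc <- vapply(specs, function(sp) {
    unknown <- setdiff(c(sp$case, sp$reference), colnames(matrix))
    if (length(unknown))
      stop("comparison '", sp$name, "' references unknown sample ID(s): ",
           paste(unknown, collapse = ", "))
    rowMeans(matrix[, sp$case, drop = FALSE]) -
      rowMeans(matrix[, sp$reference, drop = FALSE])
  }, numeric(nrow(matrix)))
  lfc <- matrix(lfc, nrow = nrow(matrix),
                dimnames = list(rownames(matrix),
                                vapply(specs, `[[`, character(1), "name")))
  if (anyDuplicated(colnames(lfc))) stop("duplicate comparison names")
  lfc
}

#' Derive a core signature by fold-change intersection across comparisons
#'
#' A gene enters the up set when its log2 fold change meets the cutoff in
#' *every* comparison, and the down set when it falls below the negated cutoff
#' in every comparison. The cutoff is given as a linear ratio (e.g. 1.5) and
#' applied on the log2 scale as `|lfc| >= log2(cutoff)` (inclusive by default;
#' set `inclusive = FALSE` for a strict inequality). Both sets are ordered by
#' descending mean absolute log2 fold change, so the head of the up list holds
#' the most strongly induced genes.
#'
#' @param fc Genes x comparisons log2 fold-change matrix from
#'   [compute_fold_changes()].
#' @param cutoff Linear fold-change cutoff, must exceed 1. Default 1.5.
#' @param name Name for the resulting signature.
#' @param inclusive Use `>=` (default) rather than `>` at the threshold.
#' @return A [gene_signature()] with `up` and `down` ordered by effect size.
#' @export
derive_core_signature <- function(fc, cutoff = 1.5, name = "core",
                                  inclusive = TRUE) {
  if (!is.matrix(fc) || !is.numeric(fc) || is.null(rownames(fc)))
    stop("fc must be a numeric matrix with gene rownames")
  if (any(!is.finite(fc))) stop("fold-change table contains non-finite values")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 1)
    stop("cutoff must be a single number > 1 (linear fold-change ratio)")
  thr <- log2(cutoff)
  hit_up <- if (inclusive) fc >= thr else fc > thr
  hit_dn <- if (inclusive) fc <= -thr else fc < -thr
  up <- rownames(fc)[rowSums(hit_up) == ncol(fc)]
  down <- rownames(fc)[rowSums(hit_dn) == ncol(fc)]
  strength <- rowMeans(abs(fc))
  up <- up[order(-strength[up], up, method = "radix")]
  down <- down[order(-strength[down], down, method = "radix")]
  if (length(up) + length(down) == 0)
    stop("no gene passes cutoff ", cutoff, " in all ", ncol(fc),
         " comparisons")
  gene_signature(name, up = up, down = down)
}

#' Read comparison specs from a contrasts TSV
#'
#' Columns: `name`, `case_ids`, `ref_ids`; the ID columns are comma-joined
#' sample-ID lists.
#'
#' @param path Path to the contrasts file.
#' @return List of [comparison_spec()] objects.
#' @export
read_contrasts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "case_ids", "ref_ids")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("contrasts file missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    comparison_spec(tab$name[i],
                    strsplit(tab$case_ids[i], ",", fixed = TRUE)[[1]],
                    strsplit(tab$ref_ids[i], ",", fixed = TRUE)[[1]])
  })
}
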