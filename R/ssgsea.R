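#' ssGSEA scoring parameters
#'
#' @param alpha Rank-weight exponent applied to integer ranks (>= 0,
#'   default 0.25, the standard ssGSEA weighting).
#' @param normalize Range-normalize the score matrix across the whole
#'   analysis (divide by global max - min). Default `TRUE`.
#' @param min_overlap Minimum number of signature genes that must be present
#'   in the matrix (counting up and down together). Default 3.
#' @param stat `"sum"` (ssGSEA convention: sum of running differences,
#'   default) or `"max"` (GSEA convention: maximum deviation).
#' @return A list of class `SsgseaParams`.
#' @export
ssgsea_params <- function(alpha = 0.25, normalize = TRUE, min_overlap = 3,
                          stat = c("sum", "max")) {
  stat <- match.arg(stat)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    stop("alpha must be a single number >= 0")
  if (!is.numeric(min_overlap) || min_overlap < 1)
    stop("min_overlap must be >= 1")
  structure(list(alpha = alpha, normalize = isTRUE(normalize),
                 min_overlap = as.integer(min_overlap), stat = stat),
            class = "SsgseaParams")
}

#' Rank profile of one sample
#'
#' Genes sorted by expression, descending; exact ties are ordered by gene ID
#' ascending (C-locale radix order), making every downstream score
#' bit-reproducible. The gene with the highest expression receives rank `N`,
#' the lowest rank 1.
#'
#' @param matrix Expression matrix with unique gene IDs.
#' @param sample_id Column to profile.
#' @return A list of class `RankProfile` with `gene_order` (descending) and
#'   `ranks` (`N` down to 1, aligned with `gene_order`).
#' @export
rank_profile <- function(matrix, sample_id) {
  validate_expression_matrix(matrix)
  if (!sample_id %in% colnames(matrix))
    stop("unknown sample: ", sample_id)
  if (nrow(matrix) < 2) stop("rank profile needs >= 2 genes")
  v <- matrix[, sample_id]
  ord <- order(-v, rownames(matrix), method = "radix")
  structure(list(gene_order = rownames(matrix)[ord],
                 ranks = seq.int(nrow(matrix), 1L),
                 sample_id = sample_id,
                 tie_policy = "gene-id-ascending"),
            class = "RankProfile")
}

#' Single-sample enrichment score (rank-weighted running sum)
#'
#' With genes ordered by descending expression and integer ranks
#' `r in {N, ..., 1}`, the enrichment score is the sum over all positions `i`
#' of the difference between the weighted in-set ECDF and the out-of-set ECDF:
#' `ES = sum_i [ P_in(i) - P_out(i) ]`, where
#' `P_in(i) = sum(r_g^alpha : g in set, pos(g) <= i) / sum(r_g^alpha : g in set)`
#' and `P_out(i) = #(g not in set, pos(g) <= i) / (N - |set|)`.
#' Positive scores mean the set concentrates at the top of the profile.
#'
#' @param profile A [rank_profile()].
#' @param gene_set Character vector of gene IDs; genes absent from the profile
#'   are ignored by the caller ([score_samples()] warns about them).
#' @param alpha Rank-weight exponent (>= 0).
#' @param stat `"sum"` (default) or `"max"` (maximum deviation).
#' @return A single finite numeric score.
#' @export
enrichment_score <- function(profile, gene_set, alpha = 0.25,
                             stat = c("sum", "max")) {
  stat <- match.arg(stat)
  if (!inherits(profile, "RankProfile")) stop("profile must be a RankProfile")
  inset <- profile$gene_order %in% gene_set
  n_in <- sum(inset)
  N <- length(inset)
  if (n_in == 0) stop("signature gene overlap below min_overlap: ",
                      "no gene of the set is in the profile")
  if (n_in == N) stop("gene set covers every profiled gene: P_out undefined")
  w <- numeric(N)
  w[inset] <- profile$ranks[inset]^alpha
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (N - n_in)
  d <- p_in - p_out
  if (stat == "sum") sum(d) else d[which.max(abs(d))]
}

#' Score samples against gene signatures (ssGSEA)
#'
#' Per signature and sample, the raw score is `ES(up) - ES(down)` for
#' two-sided signatures and `ES(up)` when the down set is empty or entirely
#' absent from the matrix. Signature genes missing from the matrix are dropped
#' with a warning that lists them. With `params$normalize`, every raw score is
#' divided by the range (max - min) of the whole raw score matrix, the usual
#' within-analysis normalization (scores are only comparable between samples
#' of the same analysis).
#'
#' @param matrix Expression matrix (unique gene IDs).
#' @param signatures A `GeneSignature` or list of them.
#' @param params [ssgsea_params()].
#' @return A signatures x samples numeric matrix of class `ScoreMatrix`, with
#'   attribute `raw` holding the unnormalized scores when normalization is on.
#' @export
score_samples <- function(matrix, signatures, params = ssgsea_params()) {
  validate_expression_matrix(matrix)
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)
  if (!length(signatures)) stop("no signatures given")
  profs <- lapply(colnames(matrix), function(s) rank_profile(matrix, s))
  names(profs) <- colnames(matrix)
  score_one <- function(sig) {
    up <- intersect(sig$up, rownames(matrix))
    down <- intersect(sig$down, rownames(matrix))
    missing <- setdiff(c(sig$up, sig$down), rownames(matrix))
    if (length(missing))
      warning("signature '", sig$name, "': dropping gene(s) absent from the ",
              "matrix: ", paste(missing, collapse = ", "), call. = FALSE)
    if (length(up) + length(down) < params$min_overlap)
      stop("signature '", sig$name, "': gene overlap ",
           length(up) + length(down), " below min_overlap ",
           params$min_overlap)
    if (!length(up))
      stop("signature '", sig$name, "': no up-regulated gene in the matrix")
    vapply(profs, function(pr) {
      es <- enrichment_score(pr, up, params$alpha, params$stat)
      if (length(down))
        es <- es - enrichment_score(pr, down, params$alpha, params$stat)
      es
    }, numeric(1))
  }
  scores <- do.call(rbind, lapply(signatures, score_one))
  dimnames(scores) <- list(vapply(signatures, `[[`, character(1), "name"),
                           colnames(matrix))
  if (params$normalize) {
    raw <- scores
    scores <- normalize_scores(scores)
    attr(scores, "raw") <- raw
  }
  class(scores) <- c("ScoreMatrix", class(scores))
  scores
}

#' Range-normalize a score matrix
#'
#' Divides every raw score by the global range (max - min) of the matrix.
#' A monotone map: sample orderings per signature are unchanged.
#'
#' @param scores Numeric signatures x samples matrix.
#' @return Matrix of the same shape.
#' @export
normalize_scores <- function(scores) {
  if (!is.numeric(scores)) stop("scores must be numeric")
  rng <- max(scores) - min(scores)
  if (rng == 0) stop("constant score matrix: range normalization undefined")
  scores / rng
}

#' Write a score matrix as TSV (signatures in rows, samples in columns)
#' @param scores Score matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  tab <- cbind(signature = rownames(scores),
               as.data.frame(formatC(unclass(scores), digits = 17,
                                     format = "g")))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
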