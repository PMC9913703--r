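#' Read an expression matrix from GCT 1.2 or plain TSV
#'
#' GCT 1.2 files carry a `#1.2` version line, a dimensions line
#' (`n_genes<TAB>n_samples`) and a header row starting `Name<TAB>Description`.
#' Plain TSV files have one header row of sample IDs and gene/probe IDs in the
#' first column. Values are taken as-is (log2 intensity units are assumed
#' throughout the package); use `log2_transform = TRUE` for linear-intensity
#' inputs, which applies `log2(x + 1)` explicitly -- never silently.
#'
#' Duplicate gene IDs are allowed at this stage (probe-level data); collapse
#' them with [collapse_probes()].
#'
#' @param path Path to the file.
#' @param format `"gct"` or `"tsv"`. Default guesses from the file extension.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the parsed values.
#' @return A numeric matrix, genes in rows (rownames = gene/probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv"),
                            log2_transform = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
      stop("parse error at line 1: GCT files must start with '#1.2'")
    dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
    nd <- suppressWarnings(as.integer(dims))
    if (length(nd) < 2 || anyNA(nd[1:2]))
      stop("parse error at line 2: expected '<n_genes>\\t<n_samples>'")
    header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
    if (length(header) < 3 || header[1] != "Name")
      stop("parse error at line 3: expected 'Name\\tDescription\\t<samples...>'")
    sample_ids <- header[-(1:2)]
    if (length(sample_ids) != nd[2])
      stop("parse error at line 3: header declares ", length(sample_ids),
           " samples but dimensions line declares ", nd[2])
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != nd[1])
      stop("parse error at line 2: GCT declares ", nd[1],
           " rows but file contains ", length(body))
    parsed <- .parse_matrix_rows(body, n_meta = 2L,
                                 n_values = length(sample_ids),
                                 line_offset = 3L)
    vals <- parsed$values
    rownames(vals) <- parsed$ids
    colnames(vals) <- sample_ids
  } else {
    if (length(lines) < 2) stop("parse error: TSV needs a header and >=1 row")
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    sample_ids <- header[-1]
    if (length(sample_ids) < 1)
      stop("parse error at line 1: no sample IDs in header")
    body <- lines[-1]
    body <- body[nzchar(body)]
    parsed <- .parse_matrix_rows(body, n_meta = 1L,
                                 n_values = length(sample_ids),
                                 line_offset = 1L)
    vals <- parsed$values
    rownames(vals) <- parsed$ids
    colnames(vals) <- sample_ids
  }
  if (log2_transform) {
    if (any(vals < 0)) stop("negative values: cannot log2(x + 1)-transform")
    vals <- log2(vals + 1)
  }
  validate_expression_matrix(vals, allow_duplicates = TRUE)
  vals
}

# Parse tab-separated body rows into ids + numeric matrix, reporting the
# 1-based file line of the first malformed row.
.parse_matrix_rows <- function(body, n_meta, n_values, line_offset) {
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_expected <- n_meta + n_values
  lens <- lengths(fields)
  if (any(lens != n_expected)) {
    bad <- which(lens != n_expected)[1]
    stop("parse error at line ", bad + line_offset, ": expected ",
         n_expected, " fields, found ", lens[bad])
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  raw <- vapply(fields, function(f) f[(n_meta + 1):n_expected],
                character(n_values))
  raw <- matrix(raw, nrow = n_values)         # columns = rows of the file
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    bad <- which(is.na(matrix(num, nrow = n_values)), arr.ind = TRUE)[1, 2]
    stop("parse error at line ", bad + line_offset, ": non-numeric cell")
  }
  list(ids = ids, values = t(matrix(num, nrow = n_values)))
}

#' Write an expression matrix to GCT 1.2 or TSV
#'
#' Full precision (17 significant digits) so that write/read round-trips are
#' lossless to below 1e-12.
#'
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param format `"gct"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  if (!is.matrix(matrix)) stop("expression matrix must be a numeric matrix")
  if (ncol(matrix) < 1) stop("cannot write a matrix with no samples")
  if (nrow(matrix) < 1) stop("cannot write a matrix with no genes")
  validate_expression_matrix(matrix, allow_duplicates = TRUE)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  rows <- apply(matrix, 1, function(r) paste(fmt(r), collapse = "\t"))
  if (format == "gct") {
    lines <- c("#1.2",
               paste(nrow(matrix), ncol(matrix), sep = "\t"),
               paste(c("Name", "Description", colnames(matrix)),
                     collapse = "\t"),
               paste(rownames(matrix), "na", rows, sep = "\t"))
  } else {
    lines <- c(paste(c("gene_id", colnames(matrix)), collapse = "\t"),
               paste(rownames(matrix), rows, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' @param x Candidate matrix.
#' @param allow_duplicates Allow duplicate gene IDs (probe-level data).
#' @return `x`, invisibly.
#' @export
validate_expression_matrix <- function(x, allow_duplicates = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(x))) stop("duplicate sample IDs")
  if (!allow_duplicates && anyDuplicated(rownames(x)))
    stop("duplicate gene IDs (collapse probes first)")
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read a sample annotation table
#'
#' Tab-delimited with mandatory columns `sample_id`, `group`, `cohort`;
#' any further numeric columns are kept as covariates.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group", "cohort")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("annotation table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in annotation")
  tab
}

#' Write a sample annotation table
#' @param anno Data frame with `sample_id`, `group`, `cohort` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(anno, path) {
  utils::write.table(anno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's value distribution onto the common reference
#' distribution (the across-sample mean of sorted value vectors). Within-sample
#' rank order is preserved; tied input values receive the mean of their tied
#' target quantiles, so the result is deterministic and independent of input
#' order.
#'
#' @param matrix Numeric genes x samples matrix, no missing values.
#' @return Matrix of the same shape, quantile-normalized.
#' @export
quantile_normalize <- function(matrix) {
  validate_expression_matrix(matrix, allow_duplicates = TRUE)
  if (ncol(matrix) < 2)
    stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(matrix, 2, sort))
  out <- apply(matrix, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # tied values -> mean of their target quantiles
    stats::ave(res, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Collapse probe-level rows to unique gene symbols
#'
#' For genes measured by several probes, the probe with the highest mean
#' expression across samples is kept (max-mean policy); exact ties keep the
#' probe whose ID sorts first lexicographically. Probes absent from the map
#' are dropped.
#'
#' @param matrix Probe-level matrix (probe IDs as rownames).
#' @param probe_to_gene Named character vector: `names()` are probe IDs,
#'   values are gene symbols.
#' @return Gene-level matrix with unique gene rownames.
#' @export
collapse_probes <- function(matrix, probe_to_gene) {
  validate_expression_matrix(matrix, allow_duplicates = TRUE)
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping")
  if (is.null(names(probe_to_gene)))
    stop("probe_to_gene must be a named character vector (names = probe IDs)")
  keep <- rownames(matrix) %in% names(probe_to_gene)
  if (!any(keep)) stop("no probe in the matrix is covered by the mapping")
  m <- matrix[keep, , drop = FALSE]
  genes <- unname(probe_to_gene[rownames(m)])
  means <- rowMeans(m)
  # order: gene, then mean desc, then probe ID asc -> first row per gene wins
  ord <- order(genes, -means, rownames(m), method = "radix")
  m <- m[ord, , drop = FALSE]
  genes <- genes[ord]
  sel <- !duplicated(genes)
  out <- m[sel, , drop = FALSE]
  rownames(out) <- genes[sel]
  out
}
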