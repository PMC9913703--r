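#' Construct a two-sided gene signature
#'
#' A signature is a named, ordered pair of gene-ID sets: genes up-regulated
#' and genes down-regulated in the condition of interest. The down set may be
#' empty (one-sided signatures, e.g. scoring on up-regulated genes only).
#'
#' @param name Signature name.
#' @param up Character vector of up-regulated gene IDs (ordered).
#' @param down Character vector of down-regulated gene IDs (ordered, may be
#'   empty).
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(name, up, down = character(0)) {
  up <- as.character(up)
  down <- as.character(down)
  if (!nzchar(name)) stop("signature needs a non-empty name")
  if (anyDuplicated(up) || anyDuplicated(down))
    stop("duplicate gene IDs within a signature side")
  if (length(intersect(up, down)))
    stop("up and down sets must be disjoint in signature '", name, "': ",
         paste(intersect(up, down), collapse = ", "))
  if (length(up) + length(down) == 0)
    stop("signature '", name, "' is empty")
  structure(list(name = name, up = up, down = down),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat("GeneSignature '", x$name, "': ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  if (length(x$up)) cat("  up:   ", paste(utils::head(x$up, 8),
                                          collapse = ", "),
                        if (length(x$up) > 8) ", ..." else "", "\n", sep = "")
  if (length(x$down)) cat("  down: ", paste(utils::head(x$down, 8),
                                            collapse = ", "),
                          if (length(x$down) > 8) ", ..." else "", "\n",
                          sep = "")
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Pairs of sets named `<stem>_UP` and `<stem>_DN` are merged into a single
#' two-sided signature named `<stem>` (case-sensitive on the stem); all other
#' sets become one-sided signatures (up only).
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(fields)
  if (any(lens < 3)) {
    bad <- which(lens < 3)[1]
    stop("parse error at line ", bad, ": GMT lines need >= 3 tab-separated ",
         "fields, found ", lens[bad])
  }
  set_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_names))
    stop("duplicate gene-set name(s): ",
         paste(unique(set_names[duplicated(set_names)]), collapse = ", "))
  genes <- lapply(fields, function(f) f[-(1:2)])
  names(genes) <- set_names

  is_up <- grepl("_UP$", set_names)
  is_dn <- grepl("_DN$", set_names)
  stems_up <- sub("_UP$", "", set_names[is_up])
  stems_dn <- sub("_DN$", "", set_names[is_dn])
  merged_stems <- intersect(stems_up, stems_dn)

  out <- list()
  for (stem in merged_stems) {
    out[[stem]] <- gene_signature(stem,
                                  up = genes[[paste0(stem, "_UP")]],
                                  down = genes[[paste0(stem, "_DN")]])
  }
  rest <- set_names[!(set_names %in%
                        c(paste0(merged_stems, "_UP"),
                          paste0(merged_stems, "_DN")))]
  for (nm in rest) out[[nm]] <- gene_signature(nm, up = genes[[nm]])
  out[order(match(names(out), sub("_UP$|_DN$", "", set_names)))]
}

#' Write gene signatures to a GMT file
#'
#' Two-sided signatures are written as `<name>_UP` / `<name>_DN` line pairs so
#' they survive the single-set GMT format and round-trip through [read_gmt()].
#'
#' @param signatures A `GeneSignature` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(sig) {
    if (length(sig$down)) {
      c(paste(c(paste0(sig$name, "_UP"), "up-regulated", sig$up),
              collapse = "\t"),
        paste(c(paste0(sig$name, "_DN"), "down-regulated", sig$down),
              collapse = "\t"))
    } else {
      paste(c(sig$name, "up-regulated", sig$up), collapse = "\t")
    }
  }))
  writeLines(lines, path)
  invisible(path)
}
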