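test_that("TSV and GCT round-trips are lossless", {
  m <- toy_matrix(c(1.25, 2.5, 3.125, 4.0625), c("g1", "g2"), c("s1", "s2"))
  for (fmt in c("tsv", "gct")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_expression(m, path, fmt)
    back <- read_expression(path, fmt)
    expect_identical(dimnames(back), dimnames(m))
    expect_equal(back, m, tolerance = 1e-12)
  }
  # full-precision round trip on irrational-ish values
  m2 <- rmat(20, 4, seed = 7)
  path <- withr::local_tempfile(fileext = ".gct")
  write_expression(m2, path, "gct")
  expect_lt(max(abs(read_expression(path) - m2)), 1e-12)
})

test_that("GCT format contract is enforced", {
  path <- withr::local_tempfile(fileext = ".gct")
  m <- toy_matrix(1:4 + 0.5, c("g1", "g2"), c("s1", "s2"))
  write_expression(m, path, "gct")
  expect_identical(readLines(path)[1], "#1.2")

  # declared 3 rows, contains 2
  writeLines(c("#1.2", "3\t2", "Name\tDescription\ts1\ts2",
               "g1\tna\t1\t2", "g2\tna\t3\t4"), path)
  expect_error(read_expression(path, "gct"), "line 2.*declares 3")

  # non-numeric cell names a line
  writeLines(c("#1.2", "2\t2", "Name\tDescription\ts1\ts2",
               "g1\tna\t1\t2", "g2\tna\tNaNo\t4"), path)
  expect_error(read_expression(path, "gct"), "line 5.*non-numeric")

  # missing version line
  writeLines(c("2\t2", "Name\tDescription\ts1\ts2"), path)
  expect_error(read_expression(path, "gct"), "#1.2")
})

test_that("degenerate matrices are rejected on write", {
  m <- toy_matrix(1:4 + 0.5, c("g1", "g2"), c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".gct")
  expect_error(write_expression(m[, 0, drop = FALSE], path), "no samples")
  expect_error(write_expression(m[0, , drop = FALSE], path), "no genes")
})

test_that("GMT reading merges _UP/_DN stems and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("OSAP_UP\tdesc\tQPRT\tAPOE",
               "OSAP_DN\tdesc\tCCL20\tCXCL1\tCXCL2",
               "S\td\tg1"), path)
  sigs <- read_gmt(path)
  expect_named(sigs, c("OSAP", "S"))
  expect_identical(sigs$OSAP$up, c("QPRT", "APOE"))
  expect_identical(sigs$OSAP$down, c("CCL20", "CXCL1", "CXCL2"))
  expect_identical(sigs$S$up, "g1")
  expect_length(sigs$S$down, 0)

  writeLines(c("X_UP\td\tg1\tg2", "X_DN\td\tg2"), path)
  expect_error(read_gmt(path), "disjoint")

  writeLines(c("A\td\tg1", "A\td\tg2"), path)
  expect_error(read_gmt(path), "duplicate")

  writeLines(c("A\td\tg1", "B\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("GMT write/read round-trips two-sided signatures", {
  sig <- gene_signature("SIG", up = c("u1", "u2"), down = c("d1", "d2", "d3"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sig, path)
  back <- read_gmt(path)[["SIG"]]
  expect_identical(back$up, sig$up)
  expect_identical(back$down, sig$down)
})

test_that("quantile normalization forces the common reference distribution", {
  m <- toy_matrix(c(1, 4, 2, 5, 3, 6), c("g1", "g2", "g3"), c("s1", "s2"))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "s2"]), c(2.5, 3.5, 4.5))

  # identical samples are a fixed point
  ident <- toy_matrix(rep(c(5, 1, 3), 2), c("g1", "g2", "g3"),
                      c("s1", "s2"))
  ident[, 2] <- ident[, 1]
  expect_equal(quantile_normalize(ident), ident)

  # property: all column-sorted vectors identical afterwards
  r <- rmat(50, 5, seed = 3)
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)

  # idempotence and rank preservation (tie-free input)
  expect_lt(max(abs(quantile_normalize(qn) - qn)), 1e-12)
  for (j in seq_len(ncol(r)))
    expect_identical(rank(qn[, j]), rank(r[, j]))

  expect_error(quantile_normalize(r[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("quantile normalization matches the limma reference on tie-free data", {
  skip_if_not_installed("limma")
  r <- rmat(40, 6, seed = 11)
  expect_equal(unclass(quantile_normalize(r)),
               unclass(limma::normalizeQuantiles(r)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("tied values receive the mean of their target quantiles", {
  m <- toy_matrix(c(1, 3, 1, 4, 2, 5), c("g1", "g2", "g3"),
                  c("s1", "s2"))   # s1 = (1, 1, 2) carries the tie
  qn <- quantile_normalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(unname(qn[c("g1", "g2"), "s1"]),
               rep(mean(ref[1:2]), 2))
})

test_that("probe collapsing keeps the max-mean probe per gene", {
  m <- toy_matrix(c(5, 5, 7, 7, 1, 2), c("p1", "p2", "p3"),
                  c("s1", "s2"))
  map <- c(p1 = "G", p2 = "G", p3 = "H")
  out <- collapse_probes(m, map)
  expect_identical(sort(rownames(out)), c("G", "H"))
  expect_equal(unname(out["G", ]), c(7, 7))   # mean-7 probe beats mean-5

  # one-to-one mapping: values unchanged, IDs renamed
  out2 <- collapse_probes(m, c(p1 = "A", p2 = "B", p3 = "C"))
  expect_equal(unname(out2[c("A", "B", "C"), ]), unname(m))

  # exact tie in means -> lexicographically first probe ID wins
  tie <- toy_matrix(c(3, 5, 5, 3), c("pB", "pA"), c("s1", "s2"))
  out3 <- collapse_probes(tie, c(pA = "G", pB = "G"))
  expect_equal(unname(out3["G", ]), c(5, 3))  # pA's row

  # unmapped probes dropped; row count == distinct mapped genes
  out4 <- collapse_probes(m, c(p1 = "G", p2 = "G"))
  expect_identical(rownames(out4), "G")

  expect_error(collapse_probes(m, character(0)), "empty")
})

test_that("sample tables require mandatory columns and unique IDs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  anno <- data.frame(sample_id = c("a", "b"), group = c("x", "y"),
                     cohort = "c1")
  write_sample_table(anno, path)
  expect_identical(read_sample_table(path)$sample_id, c("a", "b"))

  writeLines("sample_id\tgroup\na\tx", path)
  expect_error(read_sample_table(path), "cohort")

  writeLines("sample_id\tgroup\tcohort\na\tx\tc\na\ty\tc", path)
  expect_error(read_sample_table(path), "duplicate")
})

test_that("linear-scale input is only transformed via the explicit flag", {
  m <- toy_matrix(c(0, 1, 3, 7), c("g1", "g2"), c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path, "tsv")
  expect_equal(read_expression(path, "tsv"), m)
  expect_equal(unname(read_expression(path, "tsv", log2_transform = TRUE)),
               unname(log2(m + 1)))
})
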