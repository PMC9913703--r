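# Writes a complete set of pipeline input files (simulated cell lines plus
# two patient cohorts sharing the planted core) into `dir` and returns a
# ready-to-run pipeline config.
make_pipeline_inputs <- function(dir, seed = 1, n_genes = 400) {
  cl <- simulate_cell_lines(cell_line_sim_config(n_genes = n_genes,
                                                 n_line_specific = 10,
                                                 seed = seed))
  write_expression(cl$matrix, file.path(dir, "cell_lines.gct"), "gct")
  parental <- cl$anno$sample_id[cl$anno$group == "parental"]
  contrasts <- data.frame(
    name = cl$truth$conditions,
    case_ids = vapply(cl$truth$conditions, function(cn)
      paste(cl$anno$sample_id[cl$anno$group == cn], collapse = ","),
      character(1)),
    ref_ids = paste(parental, collapse = ","))
  utils::write.table(contrasts, file.path(dir, "contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  for (co in c("A", "B")) {
    sim <- simulate_cohort(cohort_sim_config(
      n_genes = n_genes, cohort_id = co,
      seed = seed + ifelse(co == "A", 100, 200)))
    write_expression(sim$matrix,
                     file.path(dir, sprintf("cohort_%s.gct", co)), "gct")
    write_sample_table(sim$anno,
                       file.path(dir, sprintf("cohort_%s_anno.tsv", co)))
  }

  list(expr = file.path(dir, "cell_lines.gct"),
       contrasts = file.path(dir, "contrasts.tsv"),
       cohort_a_expr = file.path(dir, "cohort_A.gct"),
       cohort_a_anno = file.path(dir, "cohort_A_anno.tsv"),
       cohort_b_expr = file.path(dir, "cohort_B.gct"),
       cohort_b_anno = file.path(dir, "cohort_B_anno.tsv"),
       case_group = "disease_neoplasia", control_group = "healthy",
       out_dir = file.path(dir, "run"))
}
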