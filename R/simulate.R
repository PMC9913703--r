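# Planted-signal expression simulators.
#
# All generators emit log2-scale, microarray-like Gaussian intensities:
# per-gene baseline drawn uniformly in [6, 12] log2 units, plus planted
# shifts, plus Normal(0, noise_sd) replicate noise. Planted gene positions
# are deterministic functions of the counts (the first genes of the
# universe), so two cohorts simulated with the same counts but different
# seeds share their planted core -- as two patient series profiling the same
# biology would.

.gene_ids <- function(n) sprintf("g%05d", seq_len(n))

.planted_sets <- function(n_genes, n_core_up, n_core_down) {
  ids <- .gene_ids(n_genes)
  list(up = ids[seq_len(n_core_up)],
       down = ids[n_core_up + seq_len(n_core_down)])
}

#' Configuration for the cell-line simulator
#'
#' Defaults emulate the design the signature is derived from: a parental
#' line plus six derived conditions (two escape lines per stress for two
#' stresses, plus two ectopic-expression lines), a shared planted core of
#' 27 up- and 32 down-regulated genes at 1.5 log2 units, and 50 private
#' noise-DE genes per condition.
#'
#' @param n_genes Universe size (default 2000).
#' @param n_core_up,n_core_down Planted core sizes (defaults 27, 32).
#' @param n_line_specific Private DE genes per condition (default 50).
#' @param core_effect,line_effect Planted log2 shifts (defaults 1.5).
#' @param noise_sd Replicate noise, log2 units (default 0.15).
#' @param n_replicates Samples per condition (default 3).
#' @param n_conditions Derived conditions (default 6).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return List of class `CellLineSimConfig`.
#' @export
cell_line_sim_config <- function(n_genes = 2000, n_core_up = 27,
                                 n_core_down = 32, n_line_specific = 50,
                                 core_effect = 1.5, line_effect = 1.5,
                                 noise_sd = 0.15, n_replicates = 3,
                                 n_conditions = 6, seed = 1) {
  cfg <- list(n_genes = n_genes, n_core_up = n_core_up,
              n_core_down = n_core_down, n_line_specific = n_line_specific,
              core_effect = core_effect, line_effect = line_effect,
              noise_sd = noise_sd, n_replicates = n_replicates,
              n_conditions = n_conditions, seed = seed)
  n_planted <- n_core_up + n_core_down + n_conditions * n_line_specific
  if (n_planted >= n_genes)
    stop("planted gene counts (", n_planted, ") must stay below n_genes (",
         n_genes, "): sets would overlap")
  if (noise_sd < 0 || n_replicates < 1 || n_conditions < 1)
    stop("invalid cell-line simulation config")
  structure(cfg, class = "CellLineSimConfig")
}

#' Simulate the multi-condition cell-line design
#'
#' A parental condition plus `n_conditions` derived conditions sharing a
#' planted up/down core; each derived condition additionally shifts its own
#' private gene block by `+/- line_effect` (alternating signs). Deterministic
#' given the config seed.
#'
#' @param config A [cell_line_sim_config()].
#' @return List with `matrix` (genes x samples), `anno` (sample table), and
#'   `truth` (planted `up`/`down` IDs and per-condition private genes).
#' @export
simulate_cell_lines <- function(config = cell_line_sim_config()) {
  stopifnot(inherits(config, "CellLineSimConfig"))
  set.seed(config$seed)
  ids <- .gene_ids(config$n_genes)
  core <- .planted_sets(config$n_genes, config$n_core_up, config$n_core_down)
  cond_names <- if (config$n_conditions == 6) {
    c("esc_inf_A", "esc_inf_B", "esc_tbhp_A", "esc_tbhp_B", "zeb1", "zeb2")
  } else {
    sprintf("cond_%02d", seq_len(config$n_conditions))
  }
  offset <- config$n_core_up + config$n_core_down
  line_specific <- lapply(seq_len(config$n_conditions), function(i) {
    ids[offset + (i - 1) * config$n_line_specific +
          seq_len(config$n_line_specific)]
  })
  names(line_specific) <- cond_names
  if (length(intersect(unlist(line_specific), unlist(core))))
    stop("planted core and line-specific sets overlap")

  conditions <- c("parental", cond_names)
  sample_ids <- unlist(lapply(conditions, function(cn)
    paste(cn, seq_len(config$n_replicates), sep = "_")))
  group <- rep(conditions, each = config$n_replicates)

  mu <- stats::runif(config$n_genes, 6, 12)
  shift <- matrix(0, config$n_genes, length(sample_ids),
                  dimnames = list(ids, sample_ids))
  for (i in seq_len(config$n_conditions)) {
    cols <- group == cond_names[i]
    shift[core$up, cols] <- config$core_effect
    shift[core$down, cols] <- -config$core_effect
    sgn <- rep_len(c(1, -1), config$n_line_specific)
    shift[line_specific[[i]], cols] <- sgn * config$line_effect
  }
  noise <- matrix(stats::rnorm(length(shift), sd = config$noise_sd),
                  nrow = config$n_genes)
  mat <- mu + shift + noise
  dimnames(mat) <- list(ids, sample_ids)

  anno <- data.frame(sample_id = sample_ids, group = group,
                     cohort = "cell_lines", stringsAsFactors = FALSE)
  truth <- list(up = core$up, down = core$down,
                line_specific = line_specific, conditions = cond_names)
  list(matrix = mat, anno = anno, truth = truth)
}

#' Configuration for the patient-cohort simulator
#'
#' Emulates a bulk-tissue cohort of healthy, diseased, and
#' disease-with-neoplasia mucosa. The planted epithelial reprogramming
#' signal is attenuated per sample by a reprogrammed-cell fraction `f`
#' (group mean plus jitter, clamped to `[0, 1]`): core-up genes shift by
#' `+f * core_effect`, core-down by `-f * core_effect`. An inflammation
#' module -- a fixed subset of the core-down genes -- instead shifts *up* by
#' `inflammation_shift` in every diseased sample, overriding dilution: the
#' confounder that motivates cohort refinement. A per-sample stemness
#' covariate is coupled to `f` at correlation `stem_coupling`.
#'
#' @param n_genes,n_core_up,n_core_down Universe and planted-core sizes
#'   (defaults 2000, 27, 32; positions are shared across cohorts simulated
#'   with the same counts).
#' @param group_sizes Named integer vector; the FIRST group is the control.
#'   Default `c(healthy = 15, disease = 15, disease_neoplasia = 15)`.
#' @param f_means Per-group mean reprogrammed-cell fraction, aligned with
#'   `group_sizes`. Default `c(0, 0.2, 0.4)`.
#' @param f_jitter_sd Per-sample jitter on `f` (default 0.05).
#' @param core_effect Full-strength planted shift, log2 units (default 1.5).
#' @param inflammation_fraction Fraction of core-down genes in the
#'   inflammation module (default 0.6; must be in `[0, 1]`).
#' @param inflammation_shift Log2 shift of module genes in diseased samples
#'   (default +1.0).
#' @param stem_coupling Target correlation between the stemness covariate
#'   and `f` (default 0.8).
#' @param noise_sd Log2 noise (default 0.3; bulk patient tissue is noisier
#'   than cell lines).
#' @param cohort_id Cohort label written into the sample table.
#' @param seed RNG seed.
#' @return List of class `CohortSimConfig`.
#' @export
cohort_sim_config <- function(n_genes = 2000, n_core_up = 27,
                              n_core_down = 32,
                              group_sizes = c(healthy = 15, disease = 15,
                                              disease_neoplasia = 15),
                              f_means = c(0, 0.2, 0.4),
                              f_jitter_sd = 0.05, core_effect = 1.5,
                              inflammation_fraction = 0.6,
                              inflammation_shift = 1.0,
                              stem_coupling = 0.8, noise_sd = 0.3,
                              cohort_id = "cohort", seed = 1) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be named")
  if (any(group_sizes < 3)) stop("every group needs >= 3 samples")
  if (length(f_means) != length(group_sizes))
    stop("f_means must align with group_sizes")
  if (any(f_means < 0 | f_means > 1)) stop("f must lie in [0, 1]")
  if (inflammation_fraction < 0 || inflammation_fraction > 1)
    stop("inflammation_fraction must lie in [0, 1]")
  if (abs(stem_coupling) > 1) stop("stem_coupling must lie in [-1, 1]")
  if (n_core_up + n_core_down >= n_genes)
    stop("planted core must stay below n_genes")
  structure(list(n_genes = n_genes, n_core_up = n_core_up,
                 n_core_down = n_core_down, group_sizes = group_sizes,
                 f_means = f_means, f_jitter_sd = f_jitter_sd,
                 core_effect = core_effect,
                 inflammation_fraction = inflammation_fraction,
                 inflammation_shift = inflammation_shift,
                 stem_coupling = stem_coupling, noise_sd = noise_sd,
                 cohort_id = cohort_id, seed = seed),
            class = "CohortSimConfig")
}

#' Simulate a heterogeneous patient cohort
#'
#' @param config A [cohort_sim_config()].
#' @return List with `matrix`, `anno` (including the `stemness` covariate),
#'   and `truth` (planted sets, per-sample `f`, inflammation-module IDs,
#'   stemness values).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "CohortSimConfig"))
  set.seed(config$seed)
  ids <- .gene_ids(config$n_genes)
  core <- .planted_sets(config$n_genes, config$n_core_up, config$n_core_down)
  n_module <- floor(config$inflammation_fraction * config$n_core_down)
  module <- core$down[seq_len(n_module)]

  groups <- names(config$group_sizes)
  group <- rep(groups, times = config$group_sizes)
  sample_ids <- unlist(lapply(seq_along(groups), function(i)
    sprintf("%s_%s_%02d", config$cohort_id, groups[i],
            seq_len(config$group_sizes[i]))))
  n <- length(sample_ids)
  f <- stats::rnorm(n, mean = rep(config$f_means,
                                  times = config$group_sizes),
                    sd = config$f_jitter_sd)
  f <- pmin(pmax(f, 0), 1)
  names(f) <- sample_ids
  diseased <- group != groups[1]

  mu <- stats::runif(config$n_genes, 6, 12)
  shift <- matrix(0, config$n_genes, n, dimnames = list(ids, sample_ids))
  shift[core$up, ] <- rep(f * config$core_effect, each = config$n_core_up)
  shift[core$down, ] <- rep(-f * config$core_effect,
                            each = config$n_core_down)
  if (n_module > 0 && any(diseased))
    shift[module, diseased] <- config$inflammation_shift
  mat <- mu + shift +
    matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
           nrow = config$n_genes)
  dimnames(mat) <- list(ids, sample_ids)

  z <- if (stats::sd(f) > 0) (f - mean(f)) / stats::sd(f) else rep(0, n)
  stemness <- config$stem_coupling * z +
    sqrt(1 - config$stem_coupling^2) * stats::rnorm(n)

  anno <- data.frame(sample_id = sample_ids, group = group,
                     cohort = config$cohort_id, stemness = stemness,
                     stringsAsFactors = FALSE)
  truth <- list(up = core$up, down = core$down, f = f,
                inflammation_genes = module, stemness = stemness)
  list(matrix = mat, anno = anno, truth = truth)
}

#' Configuration for the flow-sorted population simulator
#'
#' Emulates sorted stem (`high`) and precursor (`low`) epithelial fractions
#' from normal and adenoma tissue: four groups with group-specific program
#' activation `f` and *undiluted* (pure-population) signal, plus a small
#' number of driver genes whose expression tracks `f` linearly (stand-ins
#' for the transcription factors orchestrating the program), excluded from
#' the signature itself.
#'
#' @param n_genes,n_core_up,n_core_down As in [cohort_sim_config()].
#' @param group_sizes Named vector, default 12 per group for
#'   `normal_high, normal_low, adenoma_high, adenoma_low`.
#' @param f_levels Group activation levels, default `c(0, 0.1, 0.5, 0.7)`.
#' @param f_jitter_sd Per-sample jitter on `f` (default 0.05).
#' @param core_effect Planted shift at `f = 1` (default 1.5).
#' @param driver_coupling Slope `a` of driver expression on `f` (default 1).
#' @param n_drivers Number of driver genes (default 2).
#' @param noise_sd Log2 noise (default 0.3).
#' @param seed RNG seed.
#' @return List of class `SortedSimConfig`.
#' @export
sorted_sim_config <- function(n_genes = 2000, n_core_up = 27,
                              n_core_down = 32,
                              group_sizes = c(normal_high = 12,
                                              normal_low = 12,
                                              adenoma_high = 12,
                                              adenoma_low = 12),
                              f_levels = c(0, 0.1, 0.5, 0.7),
                              f_jitter_sd = 0.05, core_effect = 1.5,
                              driver_coupling = 1, n_drivers = 2,
                              noise_sd = 0.3, seed = 1) {
  if (is.null(names(group_sizes))) stop("group_sizes must be named")
  if (any(group_sizes < 3)) stop("every group needs >= 3 samples")
  if (length(f_levels) != length(group_sizes))
    stop("f_levels must align with group_sizes")
  if (any(f_levels < 0 | f_levels > 1)) stop("f must lie in [0, 1]")
  if (n_core_up + n_core_down >= n_genes)
    stop("planted core must stay below n_genes")
  structure(list(n_genes = n_genes, n_core_up = n_core_up,
                 n_core_down = n_core_down, group_sizes = group_sizes,
                 f_levels = f_levels, f_jitter_sd = f_jitter_sd,
                 core_effect = core_effect,
                 driver_coupling = driver_coupling,
                 n_drivers = n_drivers, noise_sd = noise_sd, seed = seed),
            class = "SortedSimConfig")
}

#' Simulate flow-sorted cell populations
#'
#' @param config A [sorted_sim_config()].
#' @return List with `matrix` (planted genes plus `driver_*` rows), `anno`,
#'   and `truth` (planted sets, per-sample `f`, driver gene IDs).
#' @export
simulate_sorted_populations <- function(config = sorted_sim_config()) {
  stopifnot(inherits(config, "SortedSimConfig"))
  set.seed(config$seed)
  ids <- .gene_ids(config$n_genes)
  core <- .planted_sets(config$n_genes, config$n_core_up, config$n_core_down)
  drivers <- sprintf("driver_%d", seq_len(config$n_drivers))

  groups <- names(config$group_sizes)
  group <- rep(groups, times = config$group_sizes)
  sample_ids <- unlist(lapply(seq_along(groups), function(i)
    sprintf("%s_%02d", groups[i], seq_len(config$group_sizes[i]))))
  n <- length(sample_ids)
  f <- stats::rnorm(n, mean = rep(config$f_levels,
                                  times = config$group_sizes),
                    sd = config$f_jitter_sd)
  f <- pmin(pmax(f, 0), 1)
  names(f) <- sample_ids

  mu <- stats::runif(config$n_genes, 6, 12)
  shift <- matrix(0, config$n_genes, n, dimnames = list(ids, sample_ids))
  shift[core$up, ] <- rep(f * config$core_effect, each = config$n_core_up)
  shift[core$down, ] <- rep(-f * config$core_effect,
                            each = config$n_core_down)
  mat <- mu + shift +
    matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
           nrow = config$n_genes)
  driver_mu <- stats::runif(config$n_drivers, 6, 12)
  driver_rows <- driver_mu + config$driver_coupling * rep(f,
                                                          each = config$n_drivers) +
    stats::rnorm(config$n_drivers * n, sd = config$noise_sd)
  driver_rows <- matrix(driver_rows, nrow = config$n_drivers,
                        dimnames = list(drivers, sample_ids))
  mat <- rbind(mat, driver_rows)
  rownames(mat) <- c(ids, drivers)
  colnames(mat) <- sample_ids

  anno <- data.frame(sample_id = sample_ids, group = group,
                     cohort = "sorted_populations", stringsAsFactors = FALSE)
  truth <- list(up = core$up, down = core$down, f = f, drivers = drivers)
  list(matrix = mat, anno = anno, truth = truth)
}

#' Write simulation truth as JSON
#' @param truth Truth list from a simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
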