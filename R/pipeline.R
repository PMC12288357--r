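# End-to-end orchestration: simulate -> SEM scan -> associations ->
# grouping/classification -> report, each stage writing TSV outputs plus a
# YAML manifest (seed, config hash, row counts, package version; no
# timestamps, so reruns with the same seed produce identical manifests).

#' Demo run configuration
#'
#' 200 CpGs (50 per scenario template), 378 MZ + 159 DZ pairs, BMI, plus a
#' small SNP layer with two shared-effect SNPs feeding the G4 rule.
#'
#' @param n_cpgs Total CpGs (split equally over the four scenarios).
#' @param n_mz_pairs,n_dz_pairs Pair counts.
#' @param seed Root seed.
#' @return A `run_config` list.
#' @export
demo_config <- function(n_cpgs = 200L, n_mz_pairs = 378L, n_dz_pairs = 159L,
                        seed = 1L) {
  per <- ceiling(n_cpgs / 4)
  run_config(
    simulation = simulation_config(
      n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs, n_cpgs = n_cpgs,
      scenarios = rep(scenario_levels(), each = per)[seq_len(n_cpgs)],
      trait_name = "bmi", seed = seed),
    snp_layer = list(n_snps = 59L,
                     meqtl_effects = data.frame(
                       cpg = sprintf("cg%08d", c(per + 1L, per + 2L)),
                       beta_cpg = c(0.02, 0.02),
                       beta_trait = c(0.8, 0.8))),
    seed = seed)
}

#' Assemble a pipeline run configuration
#'
#' @param simulation A [simulation_config()] (or `NULL` when reading a cohort
#'   from `input_dir`).
#' @param input_dir Directory of cohort text files (used when `simulation`
#'   is `NULL`).
#' @param snp_layer Optional list of [simulate_snp_layer()] arguments.
#' @param thresholds A [group_thresholds()] list.
#' @param alpha Significance level for outcome classification.
#' @param n_starts,workers Passed to [twinsem_scan()].
#' @param seed Root seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, input_dir = NULL, snp_layer = NULL,
                       thresholds = group_thresholds(), alpha = 0.05,
                       n_starts = 5L, workers = 1L, seed = 1L) {
  if (is.null(simulation) && is.null(input_dir))
    stop("either a simulation block or an input_dir is required")
  structure(list(simulation = simulation, input_dir = input_dir,
                 snp_layer = snp_layer, thresholds = thresholds,
                 alpha = alpha, n_starts = n_starts, workers = workers,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: a `simulation` block ([simulation_config()] arguments),
#' `input_dir`, a `thresholds` block, `alpha`, `n_starts`, `workers`, `seed`.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
  th <- if (!is.null(y$thresholds)) do.call(group_thresholds, y$thresholds)
  else group_thresholds()
  run_config(simulation = sim, input_dir = y$input_dir,
             thresholds = th,
             alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
             n_starts = if (is.null(y$n_starts)) 5L else y$n_starts,
             workers = if (is.null(y$workers)) 1L else y$workers,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  dump <- rapply(unclass(config), function(x) {
    if (inherits(x, "path_coefficients")) unlist(unclass(x)) else x
  }, how = "replace")
  yaml::write_yaml(dump, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, stage, config, seed, counts) {
  yaml::write_yaml(list(stage = stage, seed = seed,
                        config_hash = config_hash(config),
                        package_version = as.character(
                          utils::packageVersion("twinmeth")),
                        rows = counts),
                   file.path(dir, "manifest.yaml"))
}

stage_log <- function(quiet, ...) if (!quiet) message("[twinmeth] ", ...)

#' Run the full analysis pipeline
#'
#' Stages: `simulate` (or load a cohort from `input_dir`), `sem_scan`,
#' `associate` (full-population and MZ-paired), `classify` (group assignment
#' and outcome labels) and `report`. Each stage writes its tables and a
#' manifest under its own subdirectory of `out_dir`. The whole run is a pure
#' function of the configuration and seed.
#'
#' @param config A `run_config` (see [run_config()], [demo_config()],
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param through Last stage to execute: `"simulate"`, `"sem_scan"`,
#'   `"associate"`, `"classify"` or `"report"` (default: the whole run).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `sem`, `assoc_full`, `assoc_mz`, `groups`, `outcomes`, `report`),
#'   filled up to the requested stage.
#' @export
run_pipeline <- function(config, out_dir,
                         through = c("report", "classify", "associate",
                                     "sem_scan", "simulate"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  through <- match.arg(through)
  stages <- c("simulate", "sem_scan", "associate", "classify", "report")
  last <- match(through, stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # -- simulate / load ------------------------------------------------------
  sim_dir <- file.path(out_dir, "simulate")
  dir.create(sim_dir, showWarnings = FALSE)
  if (!is.null(config$simulation)) {
    stage_log(quiet, "simulate: ", config$simulation$n_cpgs, " CpGs, ",
              config$simulation$n_mz_pairs, "/",
              config$simulation$n_dz_pairs, " pairs")
    cohort <- simulate_cohort(config$simulation)
    if (!is.null(config$snp_layer))
      cohort <- do.call(simulate_snp_layer,
                        c(list(cohort = cohort), config$snp_layer,
                          list(seed = child_seed(seed, 777L))))
    write_cohort(cohort, sim_dir)
  } else {
    stage_log(quiet, "loading cohort from ", config$input_dir)
    cohort <- read_cohort(config$input_dir)
  }
  trait <- if (!is.null(config$simulation)) config$simulation$trait_name
  else "bmi"
  write_manifest(sim_dir, "simulate", config, seed,
                 list(cpgs = nrow(cohort$beta), samples = ncol(cohort$beta)))
  if (last < 2L) return(invisible(list(cohort = cohort)))

  # -- SEM scan -------------------------------------------------------------
  sem_dir <- file.path(out_dir, "sem")
  dir.create(sem_dir, showWarnings = FALSE)
  stage_log(quiet, "sem-scan: ", nrow(cohort$beta), " CpGs (trait ", trait, ")")
  sem <- twinsem_scan(cohort, trait, n_starts = config$n_starts,
                      workers = config$workers, seed = seed)
  write_table_with_header(sem, file.path(sem_dir, "sem_scan.tsv"),
                          "sem_scan", "\t")
  write_table_with_header(attr(sem, "failures"),
                          file.path(sem_dir, "failures.tsv"),
                          "sem_failures", "\t")
  write_manifest(sem_dir, "sem_scan", config, seed,
                 list(fitted = nrow(sem),
                      failed = nrow(attr(sem, "failures"))))
  if (last < 3L) return(invisible(list(cohort = cohort, sem = sem)))

  # -- associations ---------------------------------------------------------
  assoc_dir <- file.path(out_dir, "assoc")
  dir.create(assoc_dir, showWarnings = FALSE)
  stage_log(quiet, "associate: full population")
  af <- assoc_scan(cohort, trait, "full")
  stage_log(quiet, "associate: MZ within-pair")
  am <- assoc_scan(cohort, trait, "mz_paired")
  write_table_with_header(rbind(af, am),
                          file.path(assoc_dir, "associations.tsv"),
                          "associations", "\t")
  write_manifest(assoc_dir, "associate", config, seed,
                 list(full = nrow(af), mz_paired = nrow(am)))
  if (last < 4L) return(invisible(list(cohort = cohort, sem = sem,
                                       assoc_full = af, assoc_mz = am)))

  # -- grouping & classification -------------------------------------------
  cls_dir <- file.path(out_dir, "classify")
  dir.create(cls_dir, showWarnings = FALSE)
  shared <- if (!is.null(cohort$meqtl) && !is.null(cohort$gwas))
    shared_snps(cohort$meqtl, cohort$gwas)
  groups <- assign_groups(sem, shared, config$thresholds)
  outcomes <- classify_outcome(af, am, config$alpha)
  write_table_with_header(groups, file.path(cls_dir, "groups.tsv"),
                          "groups", "\t")
  write_table_with_header(outcomes, file.path(cls_dir, "outcomes.tsv"),
                          "outcomes", "\t")
  for (g in c("g1", "g2", "g3", "g4"))
    writeLines(groups$cpg[groups[[g]]],
               file.path(cls_dir, paste0(g, "_cpgs.txt")))
  write_manifest(cls_dir, "classify", config, seed,
                 list(g1 = sum(groups$g1), g2 = sum(groups$g2),
                      g3 = sum(groups$g3), g4 = sum(groups$g4)))
  if (last < 5L) return(invisible(list(cohort = cohort, sem = sem,
                                       assoc_full = af, assoc_mz = am,
                                       groups = groups,
                                       outcomes = outcomes)))

  # -- report ---------------------------------------------------------------
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  summ <- summarize_groups(groups, outcomes)
  report <- data.frame(trait = trait,
                       n_cpgs = nrow(sem),
                       n_sig_full = sum(af$fdr_p < config$alpha),
                       n_sig_mz = sum(am$fdr_p < config$alpha),
                       n_g1 = sum(groups$g1), n_g2 = sum(groups$g2),
                       n_g3 = sum(groups$g3), n_g4 = sum(groups$g4))
  write_table_with_header(report, file.path(rep_dir, "report.tsv"),
                          "report", "\t")
  write_table_with_header(summ$counts, file.path(rep_dir, "group_outcomes.tsv"),
                          "group_outcomes", "\t")
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    m <- match(outcomes$cpg, tr$cpg_id)
    recovery <- table(truth = tr$scenario[m], labelled = outcomes$outcome)
    utils::write.table(as.data.frame(recovery),
                       file.path(rep_dir, "scenario_recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(rep_dir, "report", config, seed,
                 list(n_sig_full = report$n_sig_full,
                      n_sig_mz = report$n_sig_mz))
  stage_log(quiet, "done: ", report$n_sig_full, " full-population and ",
            report$n_sig_mz, " MZ-paired significant associations")
  invisible(list(cohort = cohort, sem = sem, assoc_full = af, assoc_mz = am,
                 groups = groups, outcomes = outcomes, report = report,
                 group_outcomes = summ))
}
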