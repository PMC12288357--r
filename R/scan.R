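# Per-CpG genome scan: residualize on age/sex, assemble complete-case twin
# quadruples, fit ACE and ADE, select by AIC, and test the cross paths.

# pair bookkeeping shared by the SEM scan and the association models
pair_index <- function(pheno) {
  idx <- split(seq_len(nrow(pheno)), pheno$pair_id)
  keep <- lengths(idx) == 2L
  if (!all(keep)) idx <- idx[keep]
  # preserve cohort order
  idx[order(vapply(idx, `[`, 0L, 1L))]
}

# complete-case quadruples for one CpG: returns list(mz, dz) on the
# age/sex-adjusted scale, or NULL when too few pairs remain
cpg_quadruples <- function(x, tv, pheno, pidx) {
  ok <- is.finite(x) & is.finite(tv) & is.finite(pheno$age) &
    !is.na(pheno$sex)
  keep_pair <- vapply(pidx, function(ii) all(ok[ii]), TRUE)
  pidx <- pidx[keep_pair]
  if (length(pidx) == 0L) return(NULL)
  samp <- unlist(pidx, use.names = FALSE)
  xr <- adjust_covariates(x[samp], pheno$age[samp], pheno$sex[samp])
  yr <- adjust_covariates(tv[samp], pheno$age[samp], pheno$sex[samp])
  pos <- matrix(seq_along(samp), ncol = 2L, byrow = TRUE) # row per pair
  zyg <- pheno$zygosity[vapply(pidx, `[`, 0L, 1L)]
  quad <- cbind(x1 = xr[pos[, 1]], y1 = yr[pos[, 1]],
                x2 = xr[pos[, 2]], y2 = yr[pos[, 2]])
  list(mz = quad[zyg == "MZ", , drop = FALSE],
       dz = quad[zyg == "DZ", , drop = FALSE])
}

scan_columns <- function() {
  c("cpg", "trait", "model", "loglik", "aic", "rph", "ra", "re", "rcd",
    "p_rph", "p_ra", "p_re", "n_mz", "n_dz", "converged")
}

#' Genome scan of bivariate twin models across CpGs
#'
#' For each CpG: residualizes methylation and the trait on age and sex
#' (complete cases per CpG), fits the bivariate ACE and ADE models, selects
#' by AIC, derives Rph/Ra/Re, and computes one-sided constraint tests: the
#' genetic cross path (`p_ra`), the unique-environment cross path (`p_re`),
#' and all cross paths jointly (`p_rph`, df = 3). `p_ra`/`p_re` use the
#' directional one-sided convention by default (see [constraint_test()]);
#' `p_rph` always uses the halved chi-square. Per-CpG failures are collected
#' in the `"failures"` attribute; the scan never aborts.
#'
#' Determinism: restart perturbations use per-CpG child seeds derived from
#' `seed` by counter, so results are identical for any `workers` count and
#' independent of CpG order.
#'
#' @param cohort A `twin_cohort` (or any list with `beta` and `pheno`).
#' @param trait Phenotype column: `"bmi"`, `"wc"` or `"whr"`.
#' @param cpgs CpG ids to scan (default: all rows of `beta`).
#' @param n_starts Optimizer starts per model fit.
#' @param p_method `"directional"` (default) or `"mixture"` for `p_ra`/`p_re`.
#' @param min_pairs Pair-count floors passed to [twinsem()].
#' @param workers Parallel workers (forked via `parallel::mclapply`).
#' @param seed Integer root seed for restart perturbations.
#' @return data.frame with one row per CpG (columns `cpg, trait, model,
#'   loglik, aic, rph, ra, re, rcd, p_rph, p_ra, p_re, n_mz, n_dz,
#'   converged`) and attribute `"failures"` (data.frame `cpg`, `message`).
#' @export
twinsem_scan <- function(cohort, trait = c("bmi", "wc", "whr"), cpgs = NULL,
                         n_starts = 5L, p_method = c("directional", "mixture"),
                         min_pairs = c(mz = 30L, dz = 10L), workers = 1L,
                         seed = 1L) {
  trait <- match.arg(trait)
  p_method <- match.arg(p_method)
  beta <- cohort$beta; pheno <- cohort$pheno
  if (is.null(cpgs)) cpgs <- rownames(beta)
  missing_cpg <- setdiff(cpgs, rownames(beta))
  if (length(missing_cpg)) stop("unknown CpG id(s): ",
                                paste(utils::head(missing_cpg, 5), collapse = ", "))
  tv <- pheno[[trait]]
  if (is.null(tv)) stop("trait column '", trait, "' not found in phenotypes")
  pidx <- pair_index(pheno)

  one <- function(k) {
    cpg <- cpgs[k]
    cs <- child_seed(seed, k)
    tryCatch({
      q <- cpg_quadruples(beta[cpg, ], tv, pheno, pidx)
      if (is.null(q)) stop("no complete twin pairs")
      if (stats::var(c(q$mz[, c(1, 3)], q$dz[, c(1, 3)])) < 1e-12)
        stop("zero methylation variance")
      fit_ace <- twinsem(q$mz, q$dz, "ACE", n_starts = n_starts, seed = cs,
                         min_pairs = min_pairs)
      fit_ade <- twinsem(q$mz, q$dz, "ADE", n_starts = n_starts,
                         seed = cs + 1L, min_pairs = min_pairs)
      fit <- select_model(fit_ace, fit_ade)
      cross <- path_names(fit$model)[c(2, 5, 8)]
      sub_a <- fit_constrained(fit, cross[1], seed = cs + 2L)
      sub_e <- fit_constrained(fit, cross[3], seed = cs + 3L)
      sub_all <- fit_constrained(fit, cross, seed = cs + 4L)
      dir <- sign(fit$correlations$rph)
      p_ra <- constraint_test(fit, sub_a, method = p_method, direction = dir)
      p_re <- constraint_test(fit, sub_e, method = p_method, direction = dir)
      p_rph <- constraint_test(fit, sub_all, df = 3L, method = "mixture")
      r <- fit$correlations
      data.frame(cpg = cpg, trait = trait, model = fit$model,
                 loglik = fit$loglik, aic = fit$aic,
                 rph = r$rph, ra = r$ra, re = r$re, rcd = r$rcd,
                 p_rph = p_rph, p_ra = p_ra, p_re = p_re,
                 n_mz = fit$n_mz, n_dz = fit$n_dz,
                 converged = fit$converged &&
                   is.null(attr(fit, "selection_warning")),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      structure(list(cpg = cpg, message = conditionMessage(e)),
                class = "scan_failure")
    })
  }

  rows <- if (workers > 1L)
    parallel::mclapply(seq_along(cpgs), one, mc.cores = workers)
  else lapply(seq_along(cpgs), one)

  failed <- vapply(rows, inherits, TRUE, "scan_failure")
  failures <- if (any(failed))
    data.frame(cpg = vapply(rows[failed], `[[`, "", "cpg"),
               message = vapply(rows[failed], `[[`, "", "message"),
               stringsAsFactors = FALSE)
  else data.frame(cpg = character(0), message = character(0))
  res <- if (all(failed)) {
    empty <- data.frame(cpg = character(0), trait = character(0),
                        model = character(0), loglik = numeric(0),
                        aic = numeric(0), rph = numeric(0), ra = numeric(0),
                        re = numeric(0), rcd = numeric(0), p_rph = numeric(0),
                        p_ra = numeric(0), p_re = numeric(0),
                        n_mz = integer(0), n_dz = integer(0),
                        converged = logical(0))
    empty
  } else do.call(rbind, rows[!failed])
  rownames(res) <- NULL
  attr(res, "failures") <- failures
  res
}
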