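# CpG-trait association models: full-population linear mixed model and the
# MZ within-pair difference design, both through lme4, with a
# cluster-robust ordinary-regression fallback for singular fits. Wald
# p-values use the large-sample normal approximation (documented choice for
# per-CpG speed at genome scale).

wald_row <- function(est, se, n_used, method) {
  data.frame(beta = est, se = se, p = 2 * stats::pnorm(-abs(est / se)),
             n_used = n_used, direction = ifelse(est >= 0, "+", "-"),
             method = method, stringsAsFactors = FALSE)
}

lmer_quiet <- function(formula, data) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  suppressWarnings(suppressMessages(lme4::lmer(formula, data = data,
                                               REML = TRUE, control = ctrl)))
}

cat_factor <- function(x, what) {
  lev <- c("current", "former", "never")
  bad <- setdiff(unique(as.character(x)), c(lev, NA))
  if (length(bad)) stop(what, " has unknown level(s): ",
                        paste(bad, collapse = ", "))
  droplevels(factor(x, levels = lev))
}

#' Full-population CpG-trait association (linear mixed model)
#'
#' Regresses methylation on the trait with age, sex, smoking, drinking and
#' zygosity as fixed effects and a random intercept per twin pair. Zygosity
#' enters as a fixed covariate: a random intercept over a 2-level factor is
#' degenerate (its variance is unidentifiable); a nested random intercept
#' (pair within zygosity) is available as a sensitivity option. A singular or
#' failed mixed fit falls back to ordinary regression with pair-cluster
#' robust standard errors, flagged in `method`.
#'
#' @param y Methylation beta values, one per sample (aligned with `pheno`).
#' @param pheno Phenotype data.frame with `pair_id`, `zygosity`, `age`,
#'   `sex`, `smoking`, `drinking` and the trait column.
#' @param trait Trait column name.
#' @param zygosity_as `"fixed"` (default) or `"nested_random"`.
#' @param min_pairs Minimum number of complete pairs (default 20).
#' @return One-row data.frame: `beta`, `se`, `p`, `n_used`, `direction`,
#'   `method` (trait-coefficient Wald test, normal approximation).
#' @export
fit_full_population <- function(y, pheno, trait,
                                zygosity_as = c("fixed", "nested_random"),
                                min_pairs = 20L) {
  zygosity_as <- match.arg(zygosity_as)
  tv <- pheno[[trait]]
  if (is.null(tv)) stop("trait column '", trait, "' not found")
  d <- data.frame(y = y, trait_v = tv, age = pheno$age,
                  sex = factor(pheno$sex), pair_id = pheno$pair_id,
                  zyg = factor(pheno$zygosity),
                  smoking = cat_factor(pheno$smoking, "smoking"),
                  drinking = cat_factor(pheno$drinking, "drinking"))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$pair_id)) < min_pairs)
    stop("fewer than ", min_pairs, " pairs with complete data")
  if (stats::var(d$trait_v) < 1e-12) stop("trait is constant")
  fixed <- y ~ trait_v + age + sex + smoking + drinking
  if (zygosity_as == "fixed" && nlevels(droplevels(d$zyg)) > 1L)
    fixed <- stats::update(fixed, . ~ . + zyg)
  form <- if (zygosity_as == "nested_random")
    stats::update(fixed, . ~ . + (1 | zyg / pair_id))
  else stats::update(fixed, . ~ . + (1 | pair_id))
  fit <- tryCatch(lmer_quiet(form, d), error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))["trait_v"]
    return(wald_row(unname(cf["trait_v"]), unname(se), nrow(d), "lmm"))
  }
  # pair-cluster robust ordinary regression fallback
  lmfit <- stats::lm(fixed, data = d)
  vc <- sandwich::vcovCL(lmfit, cluster = d$pair_id)
  wald_row(unname(stats::coef(lmfit)["trait_v"]),
           sqrt(vc["trait_v", "trait_v"]), nrow(d), "lm_cluster")
}

#' Build the MZ within-pair difference design
#'
#' For every complete MZ pair, emits two rows (one per twin) with
#' `x_diff` = own trait minus co-twin trait (exactly antisymmetric within
#' pair), `x_mean` = pair mean (shared), and the twin's own smoking/drinking.
#' DZ pairs are excluded; MZ pairs missing a twin's trait are dropped and
#' counted in the `"n_dropped"` attribute. Which twin is "first" is
#' irrelevant: both orientations are included as rows.
#'
#' @param cohort A `twin_cohort` (or list with a `pheno` data.frame).
#' @param trait Trait column name.
#' @return data.frame `sample_id`, `pair_id`, `x_diff`, `x_mean`, `smoking`,
#'   `drinking` with attribute `"n_dropped"`.
#' @export
make_within_pair_design <- function(cohort, trait = c("bmi", "wc", "whr")) {
  trait <- match.arg(trait)
  pheno <- cohort$pheno
  mz <- pheno[pheno$zygosity == "MZ", , drop = FALSE]
  pidx <- pair_index(mz)
  tv <- mz[[trait]]
  complete <- vapply(pidx, function(ii) all(is.finite(tv[ii])), TRUE)
  n_dropped <- sum(!complete)
  pidx <- pidx[complete]
  rows <- lapply(pidx, function(ii) {
    t1 <- tv[ii[1]]; t2 <- tv[ii[2]]
    data.frame(sample_id = mz$sample_id[ii], pair_id = mz$pair_id[ii],
               x_diff = c(t1 - t2, t2 - t1),
               x_mean = rep((t1 + t2) / 2, 2),
               smoking = mz$smoking[ii], drinking = mz$drinking[ii],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sample_id = character(0), pair_id = character(0),
                  x_diff = numeric(0), x_mean = numeric(0),
                  smoking = character(0), drinking = character(0))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' MZ within-pair CpG-trait association
#'
#' Fits `y ~ x_diff + x_mean + smoking + drinking + (1 | pair_id)` on the MZ
#' within-pair design and reports the `x_diff` coefficient — the association
#' free of shared genetic and familial confounding. Falls back to
#' pair-cluster robust ordinary regression when the mixed fit is singular.
#'
#' @param y Methylation values aligned with `design$sample_id`.
#' @param design Output of [make_within_pair_design()].
#' @param min_pairs Minimum complete pairs (default 20).
#' @return One-row data.frame as in [fit_full_population()].
#' @export
fit_mz_within_pair <- function(y, design, min_pairs = 20L) {
  d <- data.frame(y = y, x_diff = design$x_diff, x_mean = design$x_mean,
                  pair_id = design$pair_id,
                  smoking = cat_factor(design$smoking, "smoking"),
                  drinking = cat_factor(design$drinking, "drinking"))
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  keep <- names(which(table(d$pair_id) == 2L))
  d <- d[d$pair_id %in% keep, , drop = FALSE]
  if (length(keep) < min_pairs)
    stop("fewer than ", min_pairs, " complete MZ pairs")
  if (stats::var(d$x_diff) < 1e-12)
    stop("within-pair trait differences have zero variance")
  form <- y ~ x_diff + x_mean + smoking + drinking + (1 | pair_id)
  fit <- tryCatch(lmer_quiet(form, d), error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))["x_diff"]
    return(wald_row(unname(cf["x_diff"]), unname(se), nrow(d), "lmm"))
  }
  lmfit <- stats::lm(y ~ x_diff + x_mean + smoking + drinking, data = d)
  vc <- sandwich::vcovCL(lmfit, cluster = d$pair_id)
  wald_row(unname(stats::coef(lmfit)["x_diff"]),
           sqrt(vc["x_diff", "x_diff"]), nrow(d), "lm_cluster")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; each adjusted
#' value is attached to its original index, so the result is stable under
#' input reordering. Input p-values must lie in (0, 1].
#'
#' @param pvals Numeric vector of p-values.
#' @return Numeric vector of FDR-adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Association scan over CpGs in one design
#'
#' Runs [fit_full_population()] or [fit_mz_within_pair()] per CpG and
#' BH-adjusts the p-values within the scan (one FDR family per
#' trait-by-design analysis; pass pre-selected `cpgs` to reproduce
#' per-group families).
#'
#' @param cohort A `twin_cohort`.
#' @param trait Trait column name.
#' @param design `"full"` or `"mz_paired"`.
#' @param cpgs CpG ids (default: all).
#' @param ... Passed to the per-CpG fitting function.
#' @return data.frame `cpg, trait, design, beta, se, p, fdr_p, n_used,
#'   direction, method`, with failures in the `"failures"` attribute.
#' @export
assoc_scan <- function(cohort, trait = c("bmi", "wc", "whr"),
                       design = c("full", "mz_paired"), cpgs = NULL, ...) {
  trait <- match.arg(trait)
  design <- match.arg(design)
  if (is.null(cpgs)) cpgs <- rownames(cohort$beta)
  wpd <- if (design == "mz_paired") make_within_pair_design(cohort, trait)
  rows <- lapply(cpgs, function(cpg) {
    tryCatch({
      r <- if (design == "full")
        fit_full_population(cohort$beta[cpg, ], cohort$pheno, trait, ...)
      else
        fit_mz_within_pair(cohort$beta[cpg, wpd$sample_id], wpd, ...)
      cbind(data.frame(cpg = cpg, trait = trait, design = design,
                       stringsAsFactors = FALSE), r)
    }, error = function(e)
      structure(list(cpg = cpg, message = conditionMessage(e)),
                class = "scan_failure"))
  })
  failed <- vapply(rows, inherits, TRUE, "scan_failure")
  failures <- if (any(failed))
    data.frame(cpg = vapply(rows[failed], `[[`, "", "cpg"),
               message = vapply(rows[failed], `[[`, "", "message"),
               stringsAsFactors = FALSE)
  else data.frame(cpg = character(0), message = character(0))
  if (all(failed)) {
    res <- data.frame(cpg = character(0), trait = character(0),
                      design = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), fdr_p = numeric(0),
                      n_used = integer(0), direction = character(0),
                      method = character(0))
    attr(res, "failures") <- failures
    return(res)
  }
  res <- do.call(rbind, rows[!failed])
  res$fdr_p <- bh_adjust(res$p)
  res <- res[, c("cpg", "trait", "design", "beta", "se", "p", "fdr_p",
                 "n_used", "direction", "method")]
  rownames(res) <- NULL
  attr(res, "failures") <- failures
  res
}
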