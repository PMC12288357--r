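# Synthetic twin-cohort generator. Latent variables are simulated per
# component (A shared at 1/0.5 across MZ/DZ co-twins, C at 1, D at 1/0.25, E
# independent) so that the realized covariance is an independent route to the
# model-implied matrix assembled by expected_twin_covariance().

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic, order-independent child seed per unit of work
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(i)) %% 2147483587) + 1L
}

# n x 2 matrix of a latent factor with cross-twin correlation r
draw_factor <- function(n, r) {
  zs <- rnorm(n)
  sr <- sqrt(r); si <- sqrt(1 - r)
  cbind(sr * zs + si * rnorm(n), sr * zs + si * rnorm(n))
}

#' Simulate twin-pair quadruples from a bivariate twin model
#'
#' Draws `(X_twin1, Y_twin1, X_twin2, Y_twin2)` for MZ and DZ pairs by
#' simulating the latent A, C (or D) and E factors with their defining
#' cross-twin correlations (A: 1 / 0.5; C: 1; D: 1 / 0.25; E: 0) and
#' combining them through the Cholesky loadings, rather than by factoring
#' the implied 4x4 covariance — so the sample covariance of the output is an
#' independent check on [expected_twin_covariance()].
#'
#' @param paths A [path_coefficients()] object.
#' @param n_mz,n_dz Number of MZ and DZ pairs (>= 0).
#' @param seed Optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return List with matrices `mz` (`n_mz` x 4) and `dz` (`n_dz` x 4), columns
#'   `x1, y1, x2, y2`.
#' @export
simulate_twin_pairs <- function(paths, n_mz, n_dz, seed = NULL) {
  stopifnot(inherits(paths, "path_coefficients"), n_mz >= 0, n_dz >= 0)
  sim_zyg <- function(n, zyg) {
    out <- matrix(numeric(0), 0L, 4L,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
    if (n == 0) return(out)
    w <- cross_twin_weights(paths$model, zyg)
    FA1 <- draw_factor(n, w["A"]); FA2 <- draw_factor(n, w["A"])
    FS1 <- draw_factor(n, w["CD"]); FS2 <- draw_factor(n, w["CD"])
    FE1 <- draw_factor(n, 0); FE2 <- draw_factor(n, 0)
    a <- paths$a; s <- paths$cd; e <- paths$e
    x <- a[1] * FA1 + s[1] * FS1 + e[1] * FE1
    y <- a[2] * FA1 + a[3] * FA2 + s[2] * FS1 + s[3] * FS2 +
      e[2] * FE1 + e[3] * FE2
    cbind(x1 = x[, 1], y1 = y[, 1], x2 = x[, 2], y2 = y[, 2])
  }
  with_seed(seed, list(mz = sim_zyg(n_mz, "MZ"), dz = sim_zyg(n_dz, "DZ")))
}

trait_moments <- function(trait) {
  switch(trait,
         bmi = c(mean = 24.8, sd = 3.9),
         wc = c(mean = 86.9, sd = 10.8),
         whr = c(mean = 0.9, sd = 0.1),
         stop("unknown trait '", trait, "'"))
}

#' Configuration for a simulated twin cohort
#'
#' Defaults mirror a registry-style adult twin cohort: 378 MZ and 159 DZ
#' pairs, mean age 49.9 (SD 12.2) shared within pair, 31.8% female (MZ
#' co-twins share sex, DZ co-twins drawn independently), smoking prevalences
#' 32.9/13.0/54.1% and drinking 42.5/6.8/50.7% (current/former/never, no true
#' effect on either variable so association nulls stay clean).
#'
#' @param n_mz_pairs,n_dz_pairs Pair counts (>= 1).
#' @param n_cpgs Number of CpG sites.
#' @param scenarios Scenario labels per CpG (recycled), or `NULL` for an
#'   equal mix of the four [scenario_paths()] templates.
#' @param paths_per_cpg Optional list of [path_coefficients()] overriding
#'   `scenarios` (recycled to `n_cpgs`). All sets must share the variable-1
#'   (trait) triplet, since one phenotype column serves every CpG.
#' @param trait_name `"bmi"`, `"wc"` or `"whr"`; sets the phenotype mean/SD.
#' @param age_effect Slope on each variable per year of age, in SD units
#'   (trait) and latent-SD units (methylation). Default 0.01.
#' @param sex_effect Additive male-minus-female shift in SD units. Default 0.2.
#' @param beta_link `"identity-clip"` (latent scale mapped linearly and
#'   clipped to \[0.001, 0.999\]; keeps the simulated truth linear so recovery
#'   is exact in expectation) or `"inverse-logit"`.
#' @param baseline_beta Methylation level at the latent mean, in (0, 1).
#' @param beta_scale Methylation SD per latent SD. Default 0.08.
#' @param seed Integer root seed; per-CpG child seeds are derived by counter
#'   so per-CpG re-simulation is order-independent.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_mz_pairs = 378L, n_dz_pairs = 159L,
                              n_cpgs = 100L, scenarios = NULL,
                              paths_per_cpg = NULL,
                              trait_name = c("bmi", "wc", "whr"),
                              age_effect = 0.01, sex_effect = 0.2,
                              beta_link = c("identity-clip", "inverse-logit"),
                              baseline_beta = 0.5, beta_scale = 0.08,
                              seed = 1L) {
  trait_name <- match.arg(trait_name)
  beta_link <- match.arg(beta_link)
  stopifnot(n_mz_pairs >= 1, n_dz_pairs >= 1, n_cpgs >= 1,
            baseline_beta > 0, baseline_beta < 1, beta_scale > 0,
            is.finite(age_effect), is.finite(sex_effect))
  seed <- as.integer(seed)
  if (is.null(paths_per_cpg)) {
    if (is.null(scenarios))
      scenarios <- rep_len(scenario_levels(), n_cpgs)
    else {
      bad <- setdiff(unique(scenarios), scenario_levels())
      if (length(bad)) stop("unknown scenario label(s): ",
                            paste(bad, collapse = ", "))
      scenarios <- rep_len(scenarios, n_cpgs)
    }
    paths_per_cpg <- lapply(scenarios, scenario_paths)
  } else {
    paths_per_cpg <- rep_len(paths_per_cpg, n_cpgs)
    if (is.null(scenarios)) scenarios <- rep_len("custom", n_cpgs)
    else scenarios <- rep_len(scenarios, n_cpgs)
  }
  v1 <- vapply(paths_per_cpg,
               function(p) c(p$a[1], p$cd[1], p$e[1]), numeric(3))
  if (max(apply(v1, 1, function(r) diff(range(r)))) > 1e-12)
    stop("all CpG path sets must share the same variable-1 (trait) triplet")
  if (any(v1[2, ] != 0) &&
      length(unique(vapply(paths_per_cpg, `[[`, "", "model"))) > 1L)
    stop("mixed ACE/ADE path sets require a zero trait C/D path")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_cpgs = as.integer(n_cpgs),
                 scenarios = scenarios, paths_per_cpg = paths_per_cpg,
                 trait_name = trait_name, age_effect = age_effect,
                 sex_effect = sex_effect, beta_link = beta_link,
                 baseline_beta = baseline_beta, beta_scale = beta_scale,
                 smoking_prev = c(current = 0.329, former = 0.130,
                                  never = 0.541),
                 drinking_prev = c(current = 0.425, former = 0.068,
                                   never = 0.507),
                 female_prop = 0.318, age_mean = 49.9, age_sd = 12.2,
                 seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Twin-cohort simulation config:", x$n_mz_pairs, "MZ +", x$n_dz_pairs,
      "DZ pairs,", x$n_cpgs, "CpGs, trait", x$trait_name,
      "\n  scenarios:", paste(sprintf("%s=%d", names(table(x$scenarios)),
                                      table(x$scenarios)), collapse = " "),
      "\n  beta link:", x$beta_link, " seed:", x$seed, "\n")
  invisible(x)
}

link_beta <- function(lin, config) {
  if (config$beta_link == "identity-clip") {
    pmin(pmax(config$baseline_beta + config$beta_scale * lin, 0.001), 0.999)
  } else {
    b0 <- config$baseline_beta
    # logit-scale slope chosen so the derivative at baseline matches
    # beta_scale on the beta scale
    stats::plogis(stats::qlogis(b0) + config$beta_scale / (b0 * (1 - b0)) * lin)
  }
}

#' Simulate a twin cohort with known per-CpG path coefficients
#'
#' Generates a complete cohort: a CpG-by-sample methylation beta matrix, a
#' phenotype table (trait, age, sex, smoking, drinking, pair id, zygosity,
#' consistent anthropometrics), and a truth table recording each CpG's
#' scenario, paths and implied Rph/Ra/Re for recovery tests. The trait is
#' Cholesky variable 1 so that its latent factors are shared by every CpG;
#' correlations are invariant to this orientation.
#'
#' @param config A [simulation_config()].
#' @return An object of class `twin_cohort`: list with `beta` (matrix CpGs x
#'   samples), `pheno` (data.frame), `truth` (data.frame), `config`, and
#'   optional `genotypes`, `meqtl`, `gwas` slots (see [simulate_snp_layer()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n_mz <- config$n_mz_pairs; n_dz <- config$n_dz_pairs
    n_p <- n_mz + n_dz
    n <- 2L * n_p
    zyg_pair <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
    pair_id <- sprintf("P%04d", seq_len(n_p))
    i1 <- 2L * seq_len(n_p) - 1L; i2 <- i1 + 1L

    pheno <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                        pair_id = rep(pair_id, each = 2L),
                        zygosity = rep(zyg_pair, each = 2L),
                        stringsAsFactors = FALSE)
    age_p <- pmin(pmax(rnorm(n_p, config$age_mean, config$age_sd), 18), 90)
    pheno$age <- rep(round(age_p, 1), each = 2L)
    sex1 <- ifelse(runif(n_p) < config$female_prop, "F", "M")
    sex2 <- ifelse(zyg_pair == "MZ", sex1,
                   ifelse(runif(n_p) < config$female_prop, "F", "M"))
    sx <- character(n); sx[i1] <- sex1; sx[i2] <- sex2
    pheno$sex <- sx
    pheno$smoking <- sample(names(config$smoking_prev), n, TRUE,
                            prob = config$smoking_prev)
    pheno$drinking <- sample(names(config$drinking_prev), n, TRUE,
                             prob = config$drinking_prev)

    # shared trait factors (variable 1 of every CpG's Cholesky)
    mz_idx <- which(zyg_pair == "MZ"); dz_idx <- which(zyg_pair == "DZ")
    model1 <- config$paths_per_cpg[[1L]]$model
    draw_shared <- function(kind) {
      f <- matrix(0, n_p, 2L)
      for (z in c("MZ", "DZ")) {
        idx <- if (z == "MZ") mz_idx else dz_idx
        r <- switch(kind, A = if (z == "MZ") 1 else 0.5,
                    CD = cross_twin_weights(model1, z)["CD"], E = 0)
        f[idx, ] <- draw_factor(length(idx), r)
      }
      f
    }
    FA1 <- draw_shared("A"); FS1 <- draw_shared("CD"); FE1 <- draw_shared("E")
    p1 <- config$paths_per_cpg[[1L]]
    trait_lat <- p1$a[1] * FA1 + p1$cd[1] * FS1 + p1$e[1] * FE1 # n_p x 2
    v1_sd <- sqrt(p1$a[1]^2 + p1$cd[1]^2 + p1$e[1]^2)

    male <- as.numeric(pheno$sex == "M")
    age_c <- pheno$age - 50
    lat_ind <- numeric(n); lat_ind[i1] <- trait_lat[, 1]; lat_ind[i2] <- trait_lat[, 2]
    tm <- trait_moments(config$trait_name)
    trait_val <- tm["mean"] + tm["sd"] *
      (lat_ind / max(v1_sd, 1e-12) + config$age_effect * age_c +
         config$sex_effect * male)

    # remaining anthropometrics, familially clustered but independent of CpGs
    aux_latent <- function() {
      f <- matrix(0, n_p, 2L)
      f[mz_idx, ] <- sqrt(0.6) * draw_factor(length(mz_idx), 1) +
        sqrt(0.4) * draw_factor(length(mz_idx), 0)
      f[dz_idx, ] <- sqrt(0.6) * draw_factor(length(dz_idx), 0.5) +
        sqrt(0.4) * draw_factor(length(dz_idx), 0)
      v <- numeric(n); v[i1] <- f[, 1]; v[i2] <- f[, 2]
      v
    }
    aux <- function(trait) {
      m <- trait_moments(trait)
      m["mean"] + m["sd"] * (aux_latent() + config$age_effect * age_c +
                               config$sex_effect * male)
    }
    pheno$bmi <- if (config$trait_name == "bmi") trait_val else aux("bmi")
    pheno$wc <- if (config$trait_name == "wc") trait_val else aux("wc")
    pheno$whr <- if (config$trait_name == "whr") trait_val else aux("whr")
    pheno$whr <- pmax(pheno$whr, 0.55)
    pheno$height <- round(rnorm(n, 1.64, 0.08), 3)
    pheno$weight <- round(pheno$bmi * pheno$height^2, 2)
    pheno$hc <- round(pheno$wc / pheno$whr, 1)
    pheno$wc <- round(pheno$wc, 1)
    pheno$bmi <- round(pheno$bmi, 2)
    pheno$whr <- round(pheno$whr, 4)
    pheno <- pheno[, c("sample_id", "pair_id", "zygosity", "age", "sex",
                       "weight", "height", "wc", "hc", "bmi", "whr",
                       "smoking", "drinking")]

    cpg_ids <- sprintf("cg%08d", seq_len(config$n_cpgs))
    beta <- matrix(NA_real_, config$n_cpgs, n,
                   dimnames = list(cpg_ids, pheno$sample_id))
    truth <- vector("list", config$n_cpgs)
    for (k in seq_len(config$n_cpgs)) {
      p <- config$paths_per_cpg[[k]]
      beta[k, ] <- with_seed(child_seed(config$seed, k), {
        w2 <- function(kind) {
          f <- matrix(0, n_p, 2L)
          for (z in c("MZ", "DZ")) {
            idx <- if (z == "MZ") mz_idx else dz_idx
            r <- switch(kind, A = if (z == "MZ") 1 else 0.5,
                        CD = cross_twin_weights(p$model, z)["CD"], E = 0)
            f[idx, ] <- draw_factor(length(idx), r)
          }
          f
        }
        FA2 <- w2("A"); FS2 <- w2("CD"); FE2 <- w2("E")
        m_lat <- p$a[2] * FA1 + p$a[3] * FA2 + p$cd[2] * FS1 +
          p$cd[3] * FS2 + p$e[2] * FE1 + p$e[3] * FE2
        mv <- numeric(n); mv[i1] <- m_lat[, 1]; mv[i2] <- m_lat[, 2]
        link_beta(mv + config$age_effect * age_c + config$sex_effect * male,
                  config)
      })
      rr <- derive_correlations(p)
      truth[[k]] <- data.frame(cpg_id = cpg_ids[k],
                               scenario = config$scenarios[k],
                               model = p$model,
                               a11 = p$a[1], a21 = p$a[2], a22 = p$a[3],
                               cd11 = p$cd[1], cd21 = p$cd[2], cd22 = p$cd[3],
                               e11 = p$e[1], e21 = p$e[2], e22 = p$e[3],
                               rph = rr$rph, ra = rr$ra, re = rr$re,
                               rcd = rr$rcd, stringsAsFactors = FALSE)
    }
    structure(list(beta = beta, pheno = pheno,
                   truth = do.call(rbind, truth), config = config,
                   genotypes = NULL, meqtl = NULL, gwas = NULL),
              class = "twin_cohort")
  })
}

#' @export
print.twin_cohort <- function(x, ...) {
  nmz <- sum(x$pheno$zygosity == "MZ") / 2
  ndz <- sum(x$pheno$zygosity == "DZ") / 2
  cat("Twin cohort:", nrow(x$beta), "CpGs x", ncol(x$beta), "samples (",
      nmz, "MZ +", ndz, "DZ pairs )\n")
  if (!is.null(x$truth))
    cat("  truth table present (",
        paste(sprintf("%s=%d", names(table(x$truth$scenario)),
                      table(x$truth$scenario)), collapse = " "), ")\n")
  if (!is.null(x$genotypes))
    cat("  SNP layer:", nrow(x$genotypes), "SNPs,",
        nrow(x$meqtl), "meQTL pairs,", length(x$gwas), "GWAS SNPs\n")
  invisible(x)
}

#' Add a SNP layer to a simulated cohort
#'
#' Simulates biallelic genotypes in Hardy-Weinberg equilibrium at each SNP's
#' minor-allele frequency: MZ co-twins are genotype-identical; DZ co-twins
#' each inherit one random allele per parent from simulated parental
#' genotypes. Optionally injects SNPs with linear effects on both one CpG and
#' the trait (the "shared genetic basis" group structure), builds a SNP-CpG
#' meQTL map and a trait-associated GWAS SNP list.
#'
#' @param cohort A `twin_cohort` from [simulate_cohort()].
#' @param n_snps Number of SNPs (default 59, a zygosity-panel-sized set).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param meqtl_effects Optional data.frame with columns `cpg` (CpG id),
#'   `beta_cpg` (beta-units per allele) and `beta_trait` (trait units per
#'   allele); one effect SNP is created per row, mapped to that CpG in the
#'   meQTL table and listed as a GWAS SNP.
#' @param n_meqtl Number of additional no-effect SNP-CpG meQTL rows.
#' @param n_gwas_decoy Number of GWAS-listed SNPs without any simulated effect.
#' @param seed Optional integer seed.
#' @return The cohort with `genotypes` (SNPs x samples matrix of 0/1/2),
#'   `meqtl` (data.frame `snp`, `cpg`) and `gwas` (character vector) filled,
#'   and with the effect SNPs' contributions added to `beta` and the trait.
#' @export
simulate_snp_layer <- function(cohort, n_snps = 59L, maf_range = c(0.05, 0.5),
                               meqtl_effects = NULL, n_meqtl = 20L,
                               n_gwas_decoy = 5L, seed = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  n_eff <- if (is.null(meqtl_effects)) 0L else nrow(meqtl_effects)
  n_snps <- max(n_snps, n_eff + n_gwas_decoy)
  with_seed(seed, {
    pheno <- cohort$pheno
    pairs <- unique(pheno$pair_id)
    n_p <- length(pairs)
    zyg <- pheno$zygosity[match(pairs, pheno$pair_id)]
    snp_ids <- sprintf("rs%06d", seq_len(n_snps))
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    G <- matrix(0L, n_snps, nrow(pheno),
                dimnames = list(snp_ids, pheno$sample_id))
    i1 <- 2L * seq_len(n_p) - 1L; i2 <- i1 + 1L
    for (s in seq_len(n_snps)) {
      # parental allele pairs per twin pair
      mo <- matrix(rbinom(2L * n_p, 1L, maf[s]), n_p)
      fa <- matrix(rbinom(2L * n_p, 1L, maf[s]), n_p)
      pick <- function() cbind(seq_len(n_p), sample(2L, n_p, TRUE))
      g1 <- mo[pick()] + fa[pick()]
      g2 <- ifelse(zyg == "MZ", g1, mo[pick()] + fa[pick()])
      G[s, i1] <- g1; G[s, i2] <- g2
    }
    cpg_ids <- rownames(cohort$beta)
    meqtl <- data.frame(snp = character(0), cpg = character(0))
    gwas <- character(0)
    if (n_eff > 0) {
      eff_snps <- snp_ids[seq_len(n_eff)]
      tv <- cohort$pheno[[cohort$config$trait_name]]
      for (j in seq_len(n_eff)) {
        g <- G[eff_snps[j], ] - 2 * maf[j]
        cpg <- meqtl_effects$cpg[j]
        if (!cpg %in% cpg_ids) stop("meqtl_effects references unknown CpG ", cpg)
        cohort$beta[cpg, ] <- pmin(pmax(
          cohort$beta[cpg, ] + meqtl_effects$beta_cpg[j] * g, 0.001), 0.999)
        tv <- tv + meqtl_effects$beta_trait[j] * g
      }
      cohort$pheno[[cohort$config$trait_name]] <- tv
      meqtl <- data.frame(snp = eff_snps, cpg = meqtl_effects$cpg,
                          stringsAsFactors = FALSE)
      gwas <- eff_snps[meqtl_effects$beta_trait != 0]
    }
    free_snps <- setdiff(snp_ids, meqtl$snp)
    if (n_meqtl > 0 && length(free_snps) > 0) {
      extra <- data.frame(snp = sample(free_snps, n_meqtl, replace = TRUE),
                          cpg = sample(cpg_ids, n_meqtl, replace = TRUE),
                          stringsAsFactors = FALSE)
      meqtl <- unique(rbind(meqtl, extra))
    }
    if (n_gwas_decoy > 0)
      gwas <- unique(c(gwas, sample(setdiff(snp_ids, gwas),
                                    min(n_gwas_decoy, n_snps - length(gwas)))))
    cohort$genotypes <- G
    cohort$meqtl <- meqtl
    cohort$gwas <- gwas
    cohort$maf <- stats::setNames(maf, snp_ids)
    cohort
  })
}
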