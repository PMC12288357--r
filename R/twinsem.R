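# Maximum-likelihood fitting of the bivariate ACE/ADE Cholesky twin model.
#
# The likelihood of n pairs with centred quadruples X (n x 4) and implied
# covariance Sigma is computed from the scatter matrix S = t(X) X:
#   ll = -0.5 * ( n*4*log(2*pi) + n*log|Sigma| + tr(Sigma^-1 S) )
# so each likelihood evaluation is O(1) in the number of pairs. The analytic
# gradient with respect to each lower-triangular loading matrix L_K is
# (sum_z G_Kz) %*% L_K, where G_Kz combines the 2x2 blocks of
# n_z*Sigma_z^-1 - Sigma_z^-1 S_z Sigma_z^-1 with that component's cross-twin
# weight.

PATH_LOWER <- c(0, -Inf, 0, 0, -Inf, 0, 1e-6, -Inf, 1e-6)

resolve_constraints <- function(constraints, model) {
  if (length(constraints) == 0L) return(integer(0))
  nm <- path_names(model)
  # accept the other model's letter for the middle triplet for convenience
  alt <- chartr("cd", "dc", constraints)
  idx <- match(constraints, nm)
  idx[is.na(idx)] <- match(alt[is.na(idx)], nm)
  if (anyNA(idx)) stop("unknown path name(s) in constraints: ",
                       paste(constraints[is.na(idx)], collapse = ", "))
  sort(unique(idx))
}

# scatter-matrix objective with analytic gradient and a last-point cache
make_objective <- function(S_mz, n_mz, S_dz, n_dz, model) {
  wA <- c(MZ = 1, DZ = 0.5)
  wS <- if (model == "ACE") c(MZ = 1, DZ = 1) else c(MZ = 1, DZ = 0.25)
  cache_th <- NULL; cache_val <- NULL
  eval_point <- function(th) {
    La <- lower2(th[1:3]); Ls <- lower2(th[4:6]); Le <- lower2(th[7:9])
    A <- tcrossprod(La); Scd <- tcrossprod(Ls); E <- tcrossprod(Le)
    V <- A + Scd + E
    nll <- 0
    GA <- matrix(0, 2, 2); GS <- matrix(0, 2, 2); GE <- matrix(0, 2, 2)
    for (z in c("MZ", "DZ")) {
      n <- if (z == "MZ") n_mz else n_dz
      if (n == 0) next
      S <- if (z == "MZ") S_mz else S_dz
      R <- wA[[z]] * A + wS[[z]] * Scd
      Sig <- rbind(cbind(V, R), cbind(R, V))
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch) || any(diag(ch) < 1e-10))
        return(list(nll = 1e10 + sum(th^2), grad = 2 * th))
      logdet <- 2 * sum(log(diag(ch)))
      P <- chol2inv(ch)
      nll <- nll + 0.5 * (n * 4 * log(2 * pi) + n * logdet + sum(P * S))
      M <- n * P - P %*% S %*% P
      Gbase <- M[1:2, 1:2] + M[3:4, 3:4]
      Gcross <- M[1:2, 3:4] + M[3:4, 1:2]
      GA <- GA + Gbase + wA[[z]] * Gcross
      GS <- GS + Gbase + wS[[z]] * Gcross
      GE <- GE + Gbase
    }
    gA <- GA %*% La; gS <- GS %*% Ls; gE <- GE %*% Le
    list(nll = nll,
         grad = c(gA[1, 1], gA[2, 1], gA[2, 2],
                  gS[1, 1], gS[2, 1], gS[2, 2],
                  gE[1, 1], gE[2, 1], gE[2, 2]))
  }
  get <- function(th) {
    if (!identical(th, cache_th)) {
      cache_val <<- eval_point(th); cache_th <<- th
    }
    cache_val
  }
  list(nll = function(th) get(th)$nll, grad = function(th) get(th)$grad)
}

# sum of squared cross-products by zygosity after centring/scaling
pair_scatter <- function(X) if (nrow(X)) crossprod(X) else matrix(0, 4, 4)

# project a symmetric 2x2 component estimate to PSD and take its Cholesky
safe_chol_paths <- function(M, floor = 1e-4) {
  M <- (M + t(M)) / 2
  ei <- eigen(M, symmetric = TRUE)
  ei$values <- pmax(ei$values, floor)
  M2 <- ei$vectors %*% diag(ei$values) %*% t(ei$vectors)
  L <- t(chol(M2))
  c(L[1, 1], L[2, 1], L[2, 2])
}

moment_start <- function(S_mz, n_mz, S_dz, n_dz, model) {
  V <- (S_mz[1:2, 1:2] + S_mz[3:4, 3:4] + S_dz[1:2, 1:2] + S_dz[3:4, 3:4]) /
    (2 * (n_mz + n_dz))
  half <- function(S, n) (S[1:2, 3:4] + t(S[3:4, 1:2])) / (2 * max(n, 1))
  Rmz <- half(S_mz, n_mz); Rdz <- half(S_dz, n_dz)
  Rmz <- (Rmz + t(Rmz)) / 2; Rdz <- (Rdz + t(Rdz)) / 2
  if (model == "ACE") {
    A <- 2 * (Rmz - Rdz); S2 <- 2 * Rdz - Rmz
  } else {
    A <- 4 * Rdz - Rmz; S2 <- 2 * Rmz - 4 * Rdz
  }
  E <- V - Rmz
  c(safe_chol_paths(A), safe_chol_paths(S2), safe_chol_paths(E, 1e-3))
}

#' Log-likelihood of twin-pair data under given path coefficients
#'
#' Zero-mean multivariate-normal log-density of the quadruples
#' `(x1, y1, x2, y2)`, summed over pairs, with the zygosity-appropriate
#' model-implied covariance. The data are used as supplied (no centring);
#' residualize and centre beforehand for a covariance-only fit.
#'
#' @param paths A [path_coefficients()] object.
#' @param mz,dz Matrices with 4 columns (`x1, y1, x2, y2`); either may have
#'   zero rows.
#' @return Log-likelihood in nats (`-Inf` with a warning if an implied
#'   covariance is numerically singular).
#' @export
twin_loglik <- function(paths, mz, dz = NULL) {
  stopifnot(inherits(paths, "path_coefficients"))
  mz <- as_quad(mz); dz <- as_quad(dz)
  obj <- make_objective(pair_scatter(mz), nrow(mz),
                        pair_scatter(dz), nrow(dz), paths$model)
  v <- obj$nll(c(paths$a, paths$cd, paths$e))
  if (v >= 1e10) {
    warning("implied covariance singular; returning -Inf")
    return(-Inf)
  }
  -v
}

as_quad <- function(m) {
  if (is.null(m)) return(matrix(numeric(0), 0, 4))
  m <- as.matrix(m)
  if (ncol(m) != 4L) stop("twin-pair data must have 4 columns (x1,y1,x2,y2)")
  storage.mode(m) <- "double"
  m
}

#' Fit a bivariate ACE or ADE twin model by maximum likelihood
#'
#' Estimates the nine Cholesky paths from MZ and DZ twin-pair quadruples by
#' L-BFGS-B with analytic gradients, diagonal loadings bounded at zero, and
#' multi-start (a moment-based start from the empirical within- and
#' cross-twin covariance blocks, plus `n_starts - 1` perturbed restarts).
#' Variables are centred and (by default) scaled to unit variance pooling
#' both twins and zygosity groups; the derived correlations are
#' scale-invariant and paths are also reported on the original scale.
#'
#' @param mz,dz Matrices with columns `x1, y1, x2, y2` (one row per pair).
#' @param model `"ACE"` or `"ADE"`.
#' @param constraints Character vector of paths fixed to zero (e.g.
#'   `c("a21")` or `c("a21", "c21", "e21")`).
#' @param scale Scale variables to unit variance before fitting (default).
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Optional seed controlling the perturbed restarts.
#' @param min_pairs Named lower bounds on pair counts; the bivariate model is
#'   not identifiable from a single zygosity group.
#' @param start Optional full-length-9 start vector overriding the moment
#'   start (standardized scale).
#' @return Object of class `twinsem` with elements `paths` (standardized
#'   scale), `paths_raw` (data scale), `loglik`, `aic`, `np`, `correlations`
#'   (from [derive_correlations()]), `converged`, `n_mz`, `n_dz`,
#'   `constraints`, and internal scatter matrices enabling fast nested
#'   refits.
#' @seealso [constraint_test()], [select_model()], [twinsem_scan()]
#' @export
twinsem <- function(mz, dz, model = c("ACE", "ADE"), constraints = character(),
                    scale = TRUE, n_starts = 5L, seed = NULL,
                    min_pairs = c(mz = 30L, dz = 10L), start = NULL) {
  model <- match.arg(model)
  mz <- as_quad(mz); dz <- as_quad(dz)
  if (nrow(mz) == 0L || nrow(dz) == 0L)
    stop("both zygosity groups are required: the bivariate twin model is ",
         "not identifiable from one zygosity alone")
  if (nrow(mz) < min_pairs[["mz"]] || nrow(dz) < min_pairs[["dz"]])
    stop("too few pairs (", nrow(mz), " MZ / ", nrow(dz), " DZ); floors are ",
         min_pairs[["mz"]], "/", min_pairs[["dz"]])
  if (anyNA(mz) || anyNA(dz)) stop("twin-pair quadruples must be complete")

  ctr <- c(x = mean(c(mz[, c(1, 3)], dz[, c(1, 3)])),
           y = mean(c(mz[, c(2, 4)], dz[, c(2, 4)])))
  sds <- if (scale)
    c(x = stats::sd(c(mz[, c(1, 3)], dz[, c(1, 3)])),
      y = stats::sd(c(mz[, c(2, 4)], dz[, c(2, 4)])))
  else c(x = 1, y = 1)
  if (any(sds < 1e-12) || anyNA(sds))
    stop("a variable has (near-)zero variance; model is degenerate")
  std <- function(m) sweep(sweep(m, 2, ctr[c(1, 2, 1, 2)]), 2,
                           sds[c(1, 2, 1, 2)], "/")
  mzs <- std(mz); dzs <- std(dz)

  S_mz <- pair_scatter(mzs); S_dz <- pair_scatter(dzs)
  fit <- twinsem_refit(S_mz, nrow(mz), S_dz, nrow(dz), model, constraints,
                       n_starts = n_starts, seed = seed, start = start)
  th <- fit$th
  paths <- path_coefficients(model, a = th[1:3],
                             c = if (model == "ACE") th[4:6] else NULL,
                             d = if (model == "ADE") th[4:6] else NULL,
                             e = pmax(th[7:9], c(1e-12, -Inf, 1e-12)))
  raw <- function(t) t * c(sds["x"], sds["y"], sds["y"])
  paths_raw <- path_coefficients(model, a = raw(paths$a),
                                 c = if (model == "ACE") raw(paths$cd),
                                 d = if (model == "ADE") raw(paths$cd),
                                 e = raw(paths$e))
  n_tot <- nrow(mz) + nrow(dz)
  ll <- -fit$nll
  structure(list(model = model, paths = paths, paths_raw = paths_raw,
                 loglik = ll,
                 loglik_raw = ll - 2 * n_tot * (log(sds["x"]) + log(sds["y"])),
                 np = fit$np, aic = -2 * ll + 2 * fit$np,
                 correlations = derive_correlations(paths),
                 converged = fit$converged, constraints = fit$constraints,
                 n_mz = nrow(mz), n_dz = nrow(dz),
                 center = ctr, scale_sd = sds,
                 scatter = list(S_mz = S_mz, S_dz = S_dz),
                 optim = fit$optim),
            class = "twinsem")
}

# core optimizer over scatter matrices; reused for nested submodel refits
twinsem_refit <- function(S_mz, n_mz, S_dz, n_dz, model, constraints,
                          n_starts = 5L, seed = NULL, start = NULL) {
  fixed <- resolve_constraints(constraints, model)
  free <- setdiff(1:9, fixed)
  obj <- make_objective(S_mz, n_mz, S_dz, n_dz, model)
  th0 <- moment_start(S_mz, n_mz, S_dz, n_dz, model)
  th0[fixed] <- 0
  starts <- list(th0)
  if (!is.null(start)) {
    s <- start; s[fixed] <- 0
    starts <- c(list(s), starts)
  }
  n_extra <- max(0L, n_starts - length(starts))
  if (n_extra > 0) {
    pert <- with_seed(seed, lapply(seq_len(n_extra), function(i) {
      s <- th0 * runif(9, 0.7, 1.3) + rnorm(9, 0, 0.05)
      s[fixed] <- 0
      s <- pmax(s, PATH_LOWER + (PATH_LOWER == 0) * 1e-3)
      s
    }))
    starts <- c(starts, pert)
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s[free],
                   fn = function(p) { th <- s; th[free] <- p; obj$nll(th) },
                   gr = function(p) { th <- s; th[free] <- p; obj$grad(th)[free] },
                   method = "L-BFGS-B", lower = PATH_LOWER[free],
                   control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-10 ||
        (o$value < best$value + 1e-10 && o$convergence == 0 &&
           best$convergence != 0))
      best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- numeric(9); th[free] <- best$par
  list(th = th, nll = best$value, np = length(free),
       converged = best$convergence == 0 && is.finite(best$value) &&
         best$value < 1e9,
       constraints = path_names(model)[fixed],
       optim = list(convergence = best$convergence,
                    counts = best$counts, message = best$message))
}

#' Refit a nested submodel with additional paths constrained to zero
#'
#' Re-optimizes a fitted [twinsem()] model with extra paths fixed at zero,
#' warm-started from the full fit's solution (plus a moment-based restart).
#' The result is nested in `fit` and suitable for [constraint_test()].
#'
#' @param fit A `twinsem` fit.
#' @param constraints Additional path names to fix at zero.
#' @param n_starts Optimizer starts.
#' @param seed Optional seed for restart perturbations.
#' @return A `twinsem` object (without raw-scale paths).
#' @export
fit_constrained <- function(fit, constraints, n_starts = 3L, seed = NULL) {
  stopifnot(inherits(fit, "twinsem"))
  all_con <- union(fit$constraints, constraints)
  sub <- twinsem_refit(fit$scatter$S_mz, fit$n_mz, fit$scatter$S_dz, fit$n_dz,
                       fit$model, all_con, n_starts = n_starts, seed = seed,
                       start = c(fit$paths$a, fit$paths$cd, fit$paths$e))
  out <- fit
  th <- sub$th
  out$paths <- path_coefficients(fit$model, a = th[1:3],
                                 c = if (fit$model == "ACE") th[4:6],
                                 d = if (fit$model == "ADE") th[4:6],
                                 e = pmax(th[7:9], c(1e-12, -Inf, 1e-12)))
  out$loglik <- -sub$nll
  out$np <- sub$np
  out$aic <- -2 * out$loglik + 2 * sub$np
  out$correlations <- derive_correlations(out$paths)
  out$converged <- sub$converged
  out$constraints <- sub$constraints
  out$optim <- sub$optim
  out$paths_raw <- NULL
  out
}

#' One-sided likelihood-ratio test of nested path constraints
#'
#' Computes the LRT statistic `2 * (loglik_full - loglik_constrained)`
#' (clipped at zero) and a one-sided p-value. Two conventions are offered:
#' \describe{
#'   \item{mixture}{`p = 0.5 * P(chisq_df >= LRT)` — the 50:50 point-mass /
#'     chi-square boundary mixture used throughout twin modelling when a
#'     variance-type parameter is dropped. For a sign-free cross path this is
#'     anticonservative at nominal levels (empirical size about `2 * alpha`).}
#'   \item{directional}{a genuinely one-sided test of the freed path in a
#'     reference direction: `p = P(Z >= s_ref * s_obs * sqrt(LRT))` where
#'     `s_obs` is the sign of the freed path in the full fit and `s_ref` the
#'     hypothesized direction (by default the sign of the full fit's
#'     phenotypic correlation). Has exact asymptotic size and equals the
#'     mixture p when the estimate lies in the hypothesized direction.}
#' }
#' The genome scan uses the directional form; see the package vignette.
#'
#' @param full,constrained `twinsem` fits; `constrained` must be nested in
#'   `full` (its constraint set a superset).
#' @param df Degrees of freedom; defaults to the number of extra constraints.
#' @param method `"mixture"` or `"directional"`.
#' @param direction Reference sign for the directional test (+1/-1); default
#'   `sign(full$correlations$rph)`.
#' @return One-sided p-value in (0, 1].
#' @examples
#' # LRT = 2.706 with df = 1 gives p = 0.05 under either convention
#' @export
constraint_test <- function(full, constrained, df = NULL,
                            method = c("mixture", "directional"),
                            direction = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(full, "twinsem"), inherits(constrained, "twinsem"))
  extra <- setdiff(constrained$constraints, full$constraints)
  if (!all(full$constraints %in% constrained$constraints))
    stop("'constrained' is not nested in 'full'")
  if (is.null(df)) df <- max(length(extra), 1L)
  lam <- 2 * (full$loglik - constrained$loglik)
  if (lam < -1e-4) {
    # full fit under-optimized: re-optimize it from the constrained solution
    rescue <- tryCatch(
      twinsem_refit(full$scatter$S_mz, full$n_mz, full$scatter$S_dz,
                    full$n_dz, full$model, full$constraints, n_starts = 1L,
                    start = c(constrained$paths$a, constrained$paths$cd,
                              constrained$paths$e)),
      error = function(e) NULL)
    if (!is.null(rescue) && -rescue$nll > full$loglik) {
      full$loglik <- -rescue$nll
      th <- rescue$th
      full$paths <- path_coefficients(
        full$model, a = th[1:3],
        c = if (full$model == "ACE") th[4:6],
        d = if (full$model == "ADE") th[4:6],
        e = pmax(th[7:9], c(1e-12, -Inf, 1e-12)))
      lam <- 2 * (full$loglik - constrained$loglik)
    }
    if (lam < -1e-4)
      warning("negative LRT statistic (", signif(lam, 3),
              "): optimizer failure in the full fit; statistic clipped at 0")
  }
  lam <- max(lam, 0)
  if (method == "mixture")
    return(0.5 * stats::pchisq(lam, df, lower.tail = FALSE))
  if (df != 1L)
    stop("directional test is defined for a single freed path (df = 1)")
  if (length(extra) == 0L) return(0.5) # identical constraint sets
  if (is.null(direction)) direction <- sign(full$correlations$rph)
  if (direction == 0) direction <- 1
  est <- path_estimate(full, extra[1L])
  s_obs <- sign(est)
  if (s_obs == 0) return(0.5)
  stats::pnorm(direction * s_obs * sqrt(lam), lower.tail = FALSE)
}

path_estimate <- function(fit, name) {
  idx <- resolve_constraints(name, fit$model)
  c(fit$paths$a, fit$paths$cd, fit$paths$e)[idx]
}

#' Choose between ACE and ADE fits by AIC
#'
#' Returns the fit with the lower AIC. If only one converged, that fit is
#' returned with a warning flag; exact ties (|dAIC| < 1e-9) go to ACE.
#'
#' @param fit_ace,fit_ade `twinsem` objects fitted to the same data.
#' @return The selected `twinsem` fit, with attribute `"selection_warning"`
#'   set when the choice was forced by non-convergence.
#' @export
select_model <- function(fit_ace, fit_ade) {
  stopifnot(inherits(fit_ace, "twinsem"), inherits(fit_ade, "twinsem"))
  if (!fit_ace$converged && !fit_ade$converged)
    stop("neither the ACE nor the ADE fit converged")
  if (!fit_ade$converged) {
    attr(fit_ace, "selection_warning") <- "ADE fit did not converge"
    return(fit_ace)
  }
  if (!fit_ace$converged) {
    attr(fit_ade, "selection_warning") <- "ACE fit did not converge"
    return(fit_ade)
  }
  if (abs(fit_ace$aic - fit_ade$aic) < 1e-9) return(fit_ace)
  if (fit_ace$aic < fit_ade$aic) fit_ace else fit_ade
}

#' Residualize a variable on age and sex
#'
#' Ordinary least-squares residuals of `values` on an intercept, age, and a
#' sex indicator; original units are preserved (residuals are not rescaled).
#'
#' @param values Numeric response vector.
#' @param age Numeric vector (at least 3 distinct values).
#' @param sex Character/factor vector with two levels, or 0/1 numeric.
#' @return Numeric vector of residuals.
#' @export
adjust_covariates <- function(values, age, sex) {
  n <- length(values)
  if (length(age) != n || length(sex) != n)
    stop("values, age and sex must have equal length")
  if (length(unique(age)) < 3L) stop("need at least 3 distinct ages")
  sexn <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  X <- cbind(1, age, sexn)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  stats::lm.fit(X, values)$residuals
}

#' @export
print.twinsem <- function(x, ...) {
  cat("Bivariate", x$model, "twin model (", x$n_mz, "MZ /", x$n_dz,
      "DZ pairs )\n")
  if (length(x$constraints))
    cat("  constrained to 0:", paste(x$constraints, collapse = ", "), "\n")
  cat(sprintf("  logLik %.3f  AIC %.3f  (np = %d, converged: %s)\n",
              x$loglik, x$aic, x$np, x$converged))
  r <- x$correlations
  cat(sprintf("  Rph %+.3f  Ra %+.3f  Re %+.3f  R%s %+.3f\n",
              r$rph, r$ra, r$re, if (x$model == "ACE") "c" else "d", r$rcd))
  invisible(x)
}

#' @export
summary.twinsem <- function(object, ...) {
  structure(list(fit = object), class = "summary.twinsem")
}

#' @export
print.summary.twinsem <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nStandardized paths:\n")
  print(f$paths)
  comp <- component_matrices(f$paths)
  vx <- vapply(comp, function(m) m[1, 1], 0)
  vy <- vapply(comp, function(m) m[2, 2], 0)
  tab <- rbind(`var1 share` = vx / sum(vx), `var2 share` = vy / sum(vy))
  colnames(tab) <- c("A", if (f$model == "ACE") "C" else "D", "E")
  cat("\nVariance shares:\n")
  print(round(tab, 3))
  invisible(x)
}

#' @export
coef.twinsem <- function(object, standardized = TRUE, ...) {
  p <- if (standardized || is.null(object$paths_raw)) object$paths
  else object$paths_raw
  stats::setNames(c(p$a, p$cd, p$e), path_names(object$model))
}

#' @export
logLik.twinsem <- function(object, ...) {
  structure(object$loglik, df = object$np,
            nobs = object$n_mz + object$n_dz, class = "logLik")
}

#' @export
simulate.twinsem <- function(object, nsim = 1, seed = NULL,
                             n_mz = object$n_mz, n_dz = object$n_dz, ...) {
  paths <- if (is.null(object$paths_raw)) object$paths else object$paths_raw
  sims <- with_seed(seed, lapply(seq_len(nsim), function(i) {
    s <- simulate_twin_pairs(paths, n_mz, n_dz)
    add <- object$center[c(1, 2, 1, 2)]
    s$mz <- sweep(s$mz, 2, add, "+")
    s$dz <- sweep(s$dz, 2, add, "+")
    s
  }))
  if (nsim == 1) sims[[1L]] else sims
}

#' @export
plot.twinsem <- function(x, ...) {
  comp <- component_matrices(x$paths)
  vx <- vapply(comp, function(m) m[1, 1], 0)
  vy <- vapply(comp, function(m) m[2, 2], 0)
  m <- cbind(`variable 1` = vx / sum(vx), `variable 2` = vy / sum(vy))
  rownames(m) <- c("A", if (x$model == "ACE") "C" else "D", "E")
  graphics::barplot(m, beside = FALSE, legend.text = rownames(m),
                    ylab = "variance share",
                    main = paste("Bivariate", x$model, "decomposition"), ...)
  invisible(x)
}
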