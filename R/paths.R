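# Cholesky path algebra for bivariate twin models.
#
# A bivariate ACE or ADE decomposition writes the covariance of two traits
# (per twin) as A + C + E or A + D + E, each component the outer product of a
# 2x2 lower-triangular loading matrix. Cross-twin sharing: A is weighted 1
# (MZ) or 0.5 (DZ); C is shared fully; D is weighted 1 (MZ) or 0.25 (DZ); E
# is never shared.

lower2 <- function(t) matrix(c(t[1L], t[2L], 0, t[3L]), 2L, 2L)

#' Names of the nine Cholesky paths of a bivariate twin model
#'
#' @param model `"ACE"` or `"ADE"`.
#' @return Character vector of nine path names (`a11`, `a21`, `a22`, then the
#'   `c` or `d` triplet, then `e11`, `e21`, `e22`).
#' @export
path_names <- function(model = c("ACE", "ADE")) {
  model <- match.arg(model)
  s <- if (model == "ACE") "c" else "d"
  c("a11", "a21", "a22", paste0(s, c("11", "21", "22")), "e11", "e21", "e22")
}

#' Construct Cholesky path coefficients for a bivariate twin model
#'
#' Bundles the nine free loadings of a bivariate ACE or ADE Cholesky
#' decomposition. Each triplet `(l11, l21, l22)` fills a lower-triangular 2x2
#' matrix `L`; the implied component covariance is `L %*% t(L)`, so `l11^2`
#' is the component variance of variable 1, `l21^2 + l22^2` that of variable
#' 2, and `l11 * l21` their component covariance. Diagonal loadings are
#' constrained non-negative for identifiability; the unique-environment
#' diagonals must be strictly positive (measurement noise never vanishes).
#'
#' @param model `"ACE"` (additive genetic, common environment, unique
#'   environment) or `"ADE"` (dominance instead of common environment).
#' @param a Numeric length-3: `(a11, a21, a22)` additive-genetic paths.
#' @param c Numeric length-3 common-environment paths (ACE only).
#' @param d Numeric length-3 dominance paths (ADE only).
#' @param e Numeric length-3 unique-environment paths.
#' @return An object of class `path_coefficients`: a list with elements
#'   `model`, `a`, `cd` (the C or D triplet) and `e`.
#' @examples
#' p <- path_coefficients("ACE", a = c(0.8, 0.3, 0.4), e = c(0.6, 0, 0.5))
#' expected_twin_covariance(p, "MZ")
#' @export
path_coefficients <- function(model = c("ACE", "ADE"), a = c(1, 0, 1),
                              c = NULL, d = NULL, e = c(1, 0, 1)) {
  model <- match.arg(model)
  if (model == "ACE") {
    if (!is.null(d)) stop("an ACE model takes 'c' paths, not 'd'")
    cd <- if (is.null(c)) c(0, 0, 0) else c
  } else {
    if (!is.null(c)) stop("an ADE model takes 'd' paths, not 'c'")
    cd <- if (is.null(d)) c(0, 0, 0) else d
  }
  trip <- list(a = a, cd = cd, e = e)
  for (nm in names(trip)) {
    v <- trip[[nm]]
    if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)))
      stop("path triplet '", nm, "' must be three finite numbers")
  }
  if (a[1L] < 0 || a[3L] < 0 || cd[1L] < 0 || cd[3L] < 0)
    stop("diagonal paths must be non-negative (identifiability constraint)")
  if (e[1L] <= 0 || e[3L] <= 0)
    stop("unique-environment diagonals e11 and e22 must be strictly positive")
  structure(list(model = model, a = as.numeric(a), cd = as.numeric(cd),
                 e = as.numeric(e)),
            class = "path_coefficients")
}

#' @export
print.path_coefficients <- function(x, ...) {
  cat("Bivariate", x$model, "Cholesky paths\n")
  lab <- if (x$model == "ACE") "c" else "d"
  m <- rbind(a = x$a, x$cd, e = x$e)
  rownames(m)[2L] <- lab
  colnames(m) <- c("l11", "l21", "l22")
  print(round(m, 4))
  invisible(x)
}

component_matrices <- function(paths) {
  list(A = tcrossprod(lower2(paths$a)),
       CD = tcrossprod(lower2(paths$cd)),
       E = tcrossprod(lower2(paths$e)))
}

cross_twin_weights <- function(model, zygosity) {
  wA <- if (zygosity == "MZ") 1 else 0.5
  wCD <- if (model == "ACE") 1 else if (zygosity == "MZ") 1 else 0.25
  c(A = wA, CD = wCD)
}

#' Model-implied 4x4 twin-pair covariance
#'
#' Assembles the expected covariance of the quadruple
#' `(X_twin1, Y_twin1, X_twin2, Y_twin2)` under a bivariate twin model. The
#' within-twin block is `A + C + E` (or `A + D + E`); the cross-twin block
#' weights A by 1 (MZ) or 0.5 (DZ) and C by 1, or D by 1 (MZ) / 0.25 (DZ).
#' E never crosses twins.
#'
#' @param paths A [path_coefficients()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric 4x4 matrix with dimnames `x1, y1, x2, y2`.
#' @export
expected_twin_covariance <- function(paths, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  stopifnot(inherits(paths, "path_coefficients"))
  comp <- component_matrices(paths)
  w <- cross_twin_weights(paths$model, zygosity)
  V <- comp$A + comp$CD + comp$E
  R <- w["A"] * comp$A + w["CD"] * comp$CD
  sig <- rbind(cbind(V, R), cbind(R, V))
  dimnames(sig) <- list(c("x1", "y1", "x2", "y2"), c("x1", "y1", "x2", "y2"))
  sig
}

#' Phenotypic, genetic and environmental correlations implied by paths
#'
#' For each component K in \{A, C-or-D, E\}, the component covariance between
#' the two variables is `k11 * k21`, the component variances are `k11^2` and
#' `k21^2 + k22^2`, and the component correlation is their ratio (defined as
#' 0 when either component variance is below `tol`). The phenotypic
#' correlation Rph is the total cross-covariance over the product of total
#' standard deviations. All correlations are returned signed.
#'
#' @param paths A [path_coefficients()] object.
#' @param tol Variance floor below which a component correlation is set to 0.
#' @return A list with elements `rph`, `ra`, `re`, `rcd` (the C or D
#'   correlation) and `model`.
#' @examples
#' p <- path_coefficients("ACE", a = c(0.8, 0.3, 0.4), e = c(0.6, 0, 0.5))
#' derive_correlations(p)$ra # 0.24 / (0.8 * 0.5) = 0.6
#' @export
derive_correlations <- function(paths, tol = 1e-10) {
  stopifnot(inherits(paths, "path_coefficients"))
  one <- function(t) {
    vx <- t[1L]^2
    vy <- t[2L]^2 + t[3L]^2
    r <- if (vx < tol || vy < tol) 0 else (t[1L] * t[2L]) / sqrt(vx * vy)
    c(cov = t[1L] * t[2L], vx = vx, vy = vy, r = r)
  }
  ka <- one(paths$a); kcd <- one(paths$cd); ke <- one(paths$e)
  tot_vx <- ka["vx"] + kcd["vx"] + ke["vx"]
  tot_vy <- ka["vy"] + kcd["vy"] + ke["vy"]
  rph <- (ka["cov"] + kcd["cov"] + ke["cov"]) / sqrt(tot_vx * tot_vy)
  list(rph = unname(rph), ra = unname(ka["r"]), re = unname(ke["r"]),
       rcd = unname(kcd["r"]), model = paths$model)
}

#' Scenario path templates for the four association outcomes
#'
#' Returns the documented path template for one of the four canonical
#' CpG-trait scenarios. Variable 1 is the obesity trait (heritability 0.6, no
#' shared environment), variable 2 the CpG (total variance 1, heritability
#' 0.5 where applicable):
#' \describe{
#'   \item{independent}{only the unique-environment cross path is nonzero
#'     (Re = 0.4, Ra = 0): the association survives genetic control.}
#'   \item{genetically_driven}{only the genetic cross path is nonzero
#'     (Ra = 0.6, Re = 0): the association vanishes within MZ pairs.}
#'   \item{confounded}{genetic and unique-environment cross paths of opposite
#'     sign, balanced so that the full-population mixed model's estimand
#'     vanishes (the pair random intercept weights the within-pair channel
#'     more heavily than the between-family channel, so the balance point is
#'     not the marginal zero; the marginal Rph is ~0.04, Ra ~ 0.49,
#'     Re ~ -0.29): the association test finds nothing in the full
#'     population while the within-pair design exposes it.}
#'   \item{null}{all cross paths zero.}
#' }
#'
#' @param label One of `"independent"`, `"genetically_driven"`,
#'   `"confounded"`, `"null"`.
#' @return A [path_coefficients()] object (ACE, with zero C paths).
#' @export
scenario_paths <- function(label = c("null", "independent",
                                     "genetically_driven", "confounded")) {
  label <- match.arg(label)
  a11 <- sqrt(0.6); e11 <- sqrt(0.4) # trait: h^2 = 0.6
  switch(label,
    null = path_coefficients("ACE",
      a = c(a11, 0, sqrt(0.5)), e = c(e11, 0, sqrt(0.5))),
    independent = {
      e21 <- 0.4 * sqrt(0.5) # Re = 0.4 with E-variance 0.5 for the CpG
      path_coefficients("ACE",
        a = c(a11, 0, sqrt(0.5)),
        e = c(e11, e21, sqrt(0.5 - e21^2)))
    },
    genetically_driven = {
      a21 <- 0.6 * sqrt(0.5) # Ra = 0.6 with CpG heritability 0.5
      path_coefficients("ACE",
        a = c(a11, a21, sqrt(0.5 - a21^2)),
        e = c(e11, 0, sqrt(0.5)))
    },
    confounded = {
      e21 <- -0.25
      # genetic cross path at 1.25x the marginal-cancellation value: the
      # point (calibrated at large n) where the pair-random-intercept
      # mixed model's trait coefficient vanishes
      a21 <- -1.25 * (e11 * e21) / a11
      a22 <- 0.45
      e22 <- sqrt(1 - a21^2 - a22^2 - e21^2)
      path_coefficients("ACE", a = c(a11, a21, a22), e = c(e11, e21, e22))
    })
}

scenario_levels <- function() {
  c("independent", "genetically_driven", "confounded", "null")
}
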