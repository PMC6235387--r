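## Bivariate polygenic model for two traits (TSH, fT4).  Stacking the two
## trait values of each individual (individual-major, trait-minor), the
## per-block covariance is 2 Phi (x) G + I (x) E with 2x2 genetic and
## environmental (co)variance matrices
##   G = [[s2_g1, rho_g s_g1 s_g2], [., s2_g2]],   E analogous with rho_e.
## A nonzero genetic correlation rho_g indicates pleiotropy: a shared set
## of genes influencing both traits.

## theta = (s2_g1, s2_g2, c_g, s2_e1, s2_e2, c_e)
biv_structures <- function(kin2_b) {
  n <- nrow(kin2_b)
  E11 <- matrix(c(1, 0, 0, 0), 2, 2)
  E22 <- matrix(c(0, 0, 0, 1), 2, 2)
  E12 <- matrix(c(0, 1, 1, 0), 2, 2)
  I <- diag(n)
  list(kin2_b %x% E11, kin2_b %x% E22, kin2_b %x% E12,
       I %x% E11, I %x% E22, I %x% E12)
}

#' Bivariate polygenic log-likelihood
#'
#' Exact block-diagonal Gaussian log-density of two traits under the
#' bivariate polygenic model (see Details in [fit_bivariate()]).
#'
#' @param params list with `sigma_g` (length-2 genetic SDs), `sigma_e`
#'   (length-2 environmental SDs), `rho_g`, `rho_e`, and optionally
#'   `beta` (2-column matrix of fixed effects per trait; `NULL` profiles
#'   them out).
#' @param traits 2-column matrix of trait values, rows grouped by block.
#' @param X per-individual design matrix (or `NULL` for zero mean).
#' @param kinship list of per-block kinship matrices \eqn{\Phi_b}.
#' @return log-likelihood; `-Inf` when the implied covariance is not
#'   positive definite.
#' @export
bivariate_loglik <- function(params, traits, X = NULL, kinship) {
  sizes <- vapply(kinship, nrow, integer(1))
  stopifnot(nrow(traits) == sum(sizes), ncol(traits) == 2)
  y <- as.numeric(t(traits))  # individual-major, trait-minor
  if (is.null(X)) X <- matrix(0, nrow(traits), 0)
  Xb <- X %x% diag(2)
  Vlist <- lapply(kinship, function(phi) biv_structures(2 * phi))
  frame <- lincov_frame(y, Xb, Vlist)
  th <- c(params$sigma_g[1]^2, params$sigma_g[2]^2,
          params$rho_g * params$sigma_g[1] * params$sigma_g[2],
          params$sigma_e[1]^2, params$sigma_e[2]^2,
          params$rho_e * params$sigma_e[1] * params$sigma_e[2])
  beta <- if (is.null(params$beta)) NULL else as.numeric(t(params$beta))
  r <- lincov_loglik(frame, th, beta = beta)
  if (!r$ok) return(-Inf)
  r$loglik
}

#' Phenotypic correlation implied by the bivariate polygenic model
#'
#' \deqn{\rho_p = \rho_g \sqrt{h^2_1 h^2_2} +
#'   \rho_e \sqrt{(1 - h^2_1)(1 - h^2_2)}}
#'
#' @param rho_g,rho_e genetic and environmental correlations in \[-1, 1\].
#' @param h2_1,h2_2 heritabilities of the two traits in \[0, 1\].
#' @return the phenotypic correlation (always in \[-1, 1\]).
#' @examples phenotypic_correlation(-0.150, -0.056, 0.54, 0.56)
#' @export
phenotypic_correlation <- function(rho_g, rho_e, h2_1, h2_2) {
  if (any(c(h2_1, h2_2) < 0 | c(h2_1, h2_2) > 1)) {
    stop("heritabilities must lie in [0, 1]")
  }
  if (any(abs(c(rho_g, rho_e)) > 1)) {
    stop("correlations must lie in [-1, 1]")
  }
  rho_g * sqrt(h2_1 * h2_2) + rho_e * sqrt((1 - h2_1) * (1 - h2_2))
}

#' Fit the bivariate polygenic model
#'
#' Maximum-likelihood fit for two traits over pedigree family blocks,
#' estimating per-trait genetic/environmental variances, the genetic
#' correlation `rho_g`, and the environmental correlation `rho_e`
#' (complete-case rows on both traits and all covariates). Correlations
#' are optimized through the atanh transform, variances on the log scale.
#'
#' The `rho_p_zero` constraint forces the model-implied phenotypic
#' correlation (see [phenotypic_correlation()]) to zero by eliminating
#' `rho_e` through the formula, with a smooth penalty when the implied
#' value leaves \[-1, 1\].
#'
#' @param ped pedigree object.
#' @param tab phenotype data frame.
#' @param traits two trait column names.
#' @param covariates covariate names (applied to both traits, with
#'   separate coefficients per trait).
#' @param subset optional logical vector over `tab` rows (e.g. one sex).
#' @param constraint `"none"`, `"rho_g_zero"`, `"rho_e_zero"`, or
#'   `"rho_p_zero"`.
#' @param n_starts deterministic multi-starts (1-3).
#' @return object of class `bivariate_fit`: `params` (sigma_g, sigma_e,
#'   rho_g, rho_e, beta), `h2_1`, `h2_2`, `rho_p`, `loglik`,
#'   `constraint`, `converged`, `n_used`.
#' @export
fit_bivariate <- function(ped, tab, traits = c("tsh", "ft4"),
                          covariates = character(0), subset = NULL,
                          constraint = c("none", "rho_g_zero",
                                         "rho_e_zero", "rho_p_zero"),
                          n_starts = 3) {
  constraint <- match.arg(constraint)
  dat <- prepare_vc_data(ped, tab, traits, covariates, subset = subset)
  y <- as.numeric(t(dat$y))
  Xb <- dat$X %x% diag(2)
  colnames(Xb) <- paste(rep(colnames(dat$X), each = 2),
                        rep(traits, ncol(dat$X)), sep = ":")
  Vlist <- lapply(dat$kin2, biv_structures)
  frame <- lincov_frame(y, Xb, Vlist)

  theta_of <- function(s2g1, s2g2, rg, s2e1, s2e2, re) {
    c(s2g1, s2g2, rg * sqrt(s2g1 * s2g2), s2e1, s2e2, re * sqrt(s2e1 * s2e2))
  }
  pen <- 0
  par2theta <- switch(constraint,
    none = function(p)
      theta_of(exp(p[1]), exp(p[2]), tanh(p[3]), exp(p[4]), exp(p[5]),
               tanh(p[6])),
    rho_g_zero = function(p)
      theta_of(exp(p[1]), exp(p[2]), 0, exp(p[3]), exp(p[4]), tanh(p[5])),
    rho_e_zero = function(p)
      theta_of(exp(p[1]), exp(p[2]), tanh(p[3]), exp(p[4]), exp(p[5]), 0),
    rho_p_zero = function(p) {
      s2g1 <- exp(p[1]); s2g2 <- exp(p[2]); rg <- tanh(p[3])
      s2e1 <- exp(p[4]); s2e2 <- exp(p[5])
      h1 <- s2g1 / (s2g1 + s2e1); h2 <- s2g2 / (s2g2 + s2e2)
      denom <- sqrt((1 - h1) * (1 - h2))
      re_imp <- if (denom > 1e-12) -rg * sqrt(h1 * h2) / denom else 0
      re <- max(-0.999, min(0.999, re_imp))
      pen <<- 1e4 * max(0, abs(re_imp) - 0.999)^2
      theta_of(s2g1, s2g2, rg, s2e1, s2e2, re)
    })
  penalty <- if (constraint == "rho_p_zero") {
    function(p) { par2theta(p); pen }
  } else {
    function(p) 0
  }

  s2 <- apply(dat$y, 2, function(col) {
    max(var(lm.fit(dat$X, col)$residuals), 1e-8)
  })
  mk_start <- function(h2, r) {
    lg <- log(s2 * h2); le <- log(s2 * (1 - h2)); tr <- atanh(r)
    switch(constraint,
      none = c(lg[1], lg[2], tr, le[1], le[2], tr),
      rho_g_zero = c(lg[1], lg[2], le[1], le[2], tr),
      rho_e_zero = c(lg[1], lg[2], tr, le[1], le[2]),
      rho_p_zero = c(lg[1], lg[2], tr, le[1], le[2]))
  }
  starts <- list(mk_start(0.5, 0), mk_start(0.3, -0.3), mk_start(0.7, 0.3))
  starts <- starts[seq_len(min(3, max(1, n_starts)))]

  fit <- fit_lincov(frame, par2theta, starts, penalty = penalty)
  th <- fit$theta
  rho_g <- if (th[1] > 0 && th[2] > 0) th[3] / sqrt(th[1] * th[2]) else 0
  rho_e <- th[6] / sqrt(th[4] * th[5])
  h2_1 <- th[1] / (th[1] + th[4])
  h2_2 <- th[2] / (th[2] + th[5])
  beta <- matrix(as.numeric(fit$beta), ncol = 2, byrow = TRUE,
                 dimnames = list(colnames(dat$X), traits))
  structure(list(
    params = list(sigma_g = sqrt(th[1:2]), sigma_e = sqrt(th[4:5]),
                  rho_g = rho_g, rho_e = rho_e, beta = beta),
    h2_1 = h2_1, h2_2 = h2_2,
    rho_p = phenotypic_correlation(rho_g, rho_e, h2_1, h2_2),
    loglik = fit$loglik, constraint = constraint,
    converged = fit$converged, n_used = dat$n_used, traits = traits),
    class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf(
    "bivariate polygenic fit (%s ~ %s, constraint: %s): n = %d, logL = %.3f\n",
    x$traits[1], x$traits[2], x$constraint, x$n_used, x$loglik))
  cat(sprintf("  h2 = (%.3f, %.3f), rho_g = %.3f, rho_e = %.3f, rho_p = %.3f\n",
              x$h2_1, x$h2_2, x$params$rho_g, x$params$rho_e, x$rho_p))
  invisible(x)
}

#' Zero-constraint test of a bivariate correlation
#'
#' Fits the full bivariate model and the model with the requested
#' correlation (`rho_g`, `rho_e`, or the implied phenotypic correlation
#' `rho_p`) constrained to zero, and compares them by a plain
#' chi-square(1) LRT (an interior null).
#'
#' @inheritParams fit_bivariate
#' @param which which correlation to test.
#' @param full optional pre-computed unconstrained `bivariate_fit` (to
#'   avoid refitting when several correlations are tested on one sample).
#' @return list with `estimate` (the full-model value of the tested
#'   correlation), `lrt` ([lrt_result()]), `full` and `nested` fits.
#' @export
test_correlation <- function(ped, tab, traits = c("tsh", "ft4"),
                             covariates = character(0), subset = NULL,
                             which = c("rho_g", "rho_e", "rho_p"),
                             full = NULL) {
  which <- match.arg(which)
  if (is.null(full)) {
    full <- fit_bivariate(ped, tab, traits, covariates, subset, "none")
  }
  nested <- fit_bivariate(ped, tab, traits, covariates, subset,
                          constraint = paste0(which, "_zero"))
  if (!nested$converged) warning("constrained fit did not converge")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  est <- switch(which, rho_g = full$params$rho_g,
                rho_e = full$params$rho_e, rho_p = full$rho_p)
  list(estimate = est, lrt = lrt_result(stat, "chi2_1", df = 1),
       full = full, nested = nested)
}
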