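## Sex-limitation (genotype-by-sex) model.  The genetic variance is split
## into sex-specific variances; cross-sex relative pairs share a genetic
## correlation rho_gMF whose upper limit 1 corresponds to the same genes
## acting in both sexes.  Covariances between relatives:
##   cov(M1, M2) = 2 phi sigma2_gM          (male pair)
##   cov(F1, F2) = 2 phi sigma2_gF          (female pair)
##   cov(M, F)   = 2 phi sigma_gM sigma_gF rho_gMF
## with the unique-environment variance (sex-specific) on the diagonal only.

#' Sex-limitation model covariance entry
#'
#' @param sex_i,sex_j `"male"`/`"female"` for the pair.
#' @param phi kinship coefficient of the pair (use \eqn{\phi_{ii}} with
#'   `same_individual = TRUE` for a diagonal entry).
#' @param same_individual logical; diagonal entry?
#' @param params list with `sigma_gM`, `sigma_gF`, `sigma_eM`,
#'   `sigma_eF` (standard deviations) and `rho_gMF`.
#' @return the covariance entry implied by the model.
#' @export
gxs_covariance <- function(sex_i, sex_j, phi, same_individual = FALSE,
                           params) {
  sg <- c(male = params$sigma_gM, female = params$sigma_gF)
  se <- c(male = params$sigma_eM, female = params$sigma_eF)
  g <- if (sex_i == sex_j) {
    2 * phi * sg[[sex_i]]^2
  } else {
    2 * phi * sg[[sex_i]] * sg[[sex_j]] * params$rho_gMF
  }
  g + if (same_individual) se[[sex_i]]^2 else 0
}

## per-block structure matrices; theta = (s2_gM, s2_gF, c_g, s2_eM, s2_eF)
## with c_g = sigma_gM sigma_gF rho_gMF
gxs_structures <- function(kin2_b, sex_b) {
  m <- as.numeric(sex_b == "male")
  f <- 1 - m
  list(kin2_b * tcrossprod(m),
       kin2_b * tcrossprod(f),
       kin2_b * (tcrossprod(m, f) + tcrossprod(f, m)),
       diag(m, nrow = length(m)),
       diag(f, nrow = length(f)))
}

#' Fit the sex-limitation (genotype-by-sex) model
#'
#' Maximum-likelihood fit of the model with sex-specific genetic and
#' unique-environmental standard deviations and a cross-sex genetic
#' correlation, optionally under one of the two nested constraints the
#' sex-limitation workflow tests: `rho_eq_1` (same genes in both sexes)
#' or `sigma_g_equal` (equal genetic magnitude).
#'
#' @param ped pedigree object.
#' @param tab phenotype data frame.
#' @param trait trait column name.
#' @param covariates covariate names (sex is typically included so
#'   sex-specific means are absorbed by the fixed effects).
#' @param constraint `"none"`, `"rho_eq_1"`, or `"sigma_g_equal"`.
#' @param rho_bounds `c(0, 1)` (default; 1 is the tested upper limit) or
#'   `c(-1, 1)`.
#' @param n_starts deterministic multi-starts (1-3).
#' @return object of class `gxs_fit` with `params` (sigma_gM, sigma_gF,
#'   sigma_eM, sigma_eF, rho_gMF, beta), per-sex heritabilities `h2_M`,
#'   `h2_F`, `loglik`, `constraint`, `converged`, `n_used`.
#' @export
fit_gxs <- function(ped, tab, trait, covariates = c("age", "age2", "sex"),
                    constraint = c("none", "rho_eq_1", "sigma_g_equal"),
                    rho_bounds = c(0, 1), n_starts = 3) {
  constraint <- match.arg(constraint)
  dat <- prepare_vc_data(ped, tab, trait, covariates)
  sexes <- unlist(dat$sexes)
  if (length(unique(sexes)) < 2) {
    warning("sample contains a single sex; sex-limitation parameters are ",
            "not identifiable")
  }
  has_cross <- any(vapply(seq_along(dat$kin2), function(b) {
    k <- dat$kin2[[b]]; s <- dat$sexes[[b]]
    any(k[s == "male", s == "female", drop = FALSE] > 0)
  }, logical(1)))
  if (!has_cross && constraint == "none") {
    warning("no opposite-sex relative pair: rho_gMF is unidentified")
  }
  y <- dat$y[, 1]
  Vlist <- lapply(seq_along(dat$kin2), function(b)
    gxs_structures(dat$kin2[[b]], dat$sexes[[b]]))
  frame <- lincov_frame(y, dat$X, Vlist)

  rho_map <- if (isTRUE(all.equal(rho_bounds, c(0, 1)))) {
    function(t) 1 / (1 + exp(-t))
  } else {
    tanh
  }
  rho_unmap <- if (isTRUE(all.equal(rho_bounds, c(0, 1)))) {
    function(r) log(r / (1 - r))
  } else {
    atanh
  }

  par2theta <- switch(constraint,
    none = function(p) {
      s2gM <- exp(p[1]); s2gF <- exp(p[2]); rho <- rho_map(p[3])
      c(s2gM, s2gF, sqrt(s2gM * s2gF) * rho, exp(p[4]), exp(p[5]))
    },
    rho_eq_1 = function(p) {
      s2gM <- exp(p[1]); s2gF <- exp(p[2])
      c(s2gM, s2gF, sqrt(s2gM * s2gF), exp(p[3]), exp(p[4]))
    },
    sigma_g_equal = function(p) {
      s2g <- exp(p[1]); rho <- rho_map(p[2])
      c(s2g, s2g, s2g * rho, exp(p[3]), exp(p[4]))
    })

  s2 <- max(var(lm.fit(dat$X, y)$residuals), 1e-8)
  mk_start <- function(h2, rho) {
    lg <- log(s2 * h2); le <- log(s2 * (1 - h2))
    tr <- rho_unmap(min(rho, 0.95))
    switch(constraint,
      none = c(lg, lg, tr, le, le),
      rho_eq_1 = c(lg, lg, le, le),
      sigma_g_equal = c(lg, tr, le, le))
  }
  starts <- list(mk_start(0.5, 0.9), mk_start(0.2, 0.9), mk_start(0.8, 0.5))
  starts <- starts[seq_len(min(3, max(1, n_starts)))]

  fit <- fit_lincov(frame, par2theta, starts)
  th <- fit$theta
  params <- list(sigma_gM = sqrt(th[1]), sigma_gF = sqrt(th[2]),
                 sigma_eM = sqrt(th[4]), sigma_eF = sqrt(th[5]),
                 rho_gMF = if (th[1] > 0 && th[2] > 0)
                   th[3] / sqrt(th[1] * th[2]) else NA_real_,
                 beta = setNames(as.numeric(fit$beta), colnames(dat$X)))
  structure(list(params = params,
                 h2_M = th[1] / (th[1] + th[4]),
                 h2_F = th[2] / (th[2] + th[5]),
                 loglik = fit$loglik, constraint = constraint,
                 converged = fit$converged, n_used = dat$n_used,
                 trait = trait),
            class = "gxs_fit")
}

#' @export
print.gxs_fit <- function(x, ...) {
  cat(sprintf(
    "sex-limitation fit (constraint: %s), trait %s: n = %d, logL = %.3f\n",
    x$constraint, x$trait, x$n_used, x$loglik))
  cat(sprintf(
    "  sigma_gM = %.3f, sigma_gF = %.3f, sigma_eM = %.3f, sigma_eF = %.3f, rho_gMF = %.3f\n",
    x$params$sigma_gM, x$params$sigma_gF, x$params$sigma_eM,
    x$params$sigma_eF, x$params$rho_gMF))
  cat(sprintf("  h2 male = %.3f, h2 female = %.3f\n", x$h2_M, x$h2_F))
  invisible(x)
}

#' Likelihood-ratio test of a sex-limitation constraint
#'
#' `rho_eq_1` tests the cross-sex genetic correlation against its upper
#' limit 1, so the statistic follows a 50:50 mixture of a point mass at
#' zero and chi-square(1) (a zero statistic gives p = 0.5);
#' `sigma_g_equal` is an interior constraint tested against plain
#' chi-square(1). The statistic is clamped at zero when the constrained
#' optimum marginally exceeds the full one within numerical tolerance.
#'
#' @param full `gxs_fit` with `constraint = "none"`.
#' @param nested `gxs_fit` with one of the two constraints.
#' @return [lrt_result()] object.
#' @export
test_gxs <- function(full, nested) {
  if (full$constraint != "none" || nested$constraint == "none") {
    stop("`full` must be unconstrained and `nested` constrained")
  }
  if (full$n_used != nested$n_used) stop("fits use different rows")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  kind <- if (nested$constraint == "rho_eq_1") "mixture_50_50" else "chi2_1"
  lrt_result(stat, kind, df = 1)
}
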