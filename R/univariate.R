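## Univariate polygenic variance decomposition.  Within each family
## block the trait is multivariate normal with mean X beta and covariance
##   Sigma = 2 Phi sigma2_g + H sigma2_c + I sigma2_e,
## where Phi holds kinship coefficients and H indicates shared household
## (by default: same family block).  The total log-likelihood is the sum
## over blocks; ML is full maximum likelihood (not REML) so that nested
## models with identical fixed effects are comparable by LRT.

uv_structures <- function(kin2_b, components, household = TRUE) {
  n <- nrow(kin2_b)
  out <- list()
  if ("A" %in% components) out <- c(out, list(kin2_b))
  if ("C" %in% components) {
    out <- c(out, list(if (household) matrix(1, n, n) else diag(n)))
  }
  c(out, list(diag(n)))  # E always present
}

#' Univariate polygenic log-likelihood
#'
#' Exact block-diagonal Gaussian log-density of a trait under the
#' variance-components model \eqn{\Sigma_b = 2\Phi_b \sigma^2_g +
#' H_b \sigma^2_c + I \sigma^2_e} with mean \eqn{X\beta}.
#'
#' @param sigma2_g,sigma2_c,sigma2_e variance components (>= 0; `sigma2_e`
#'   > 0 for a positive-definite covariance).
#' @param beta fixed-effect vector (length `ncol(X)`), or `NULL` to
#'   profile the ML fixed effects out.
#' @param y trait vector, rows grouped by block in the order of `kinship`.
#' @param X design matrix (include an intercept column if wanted); `NULL`
#'   for a zero mean.
#' @param kinship list of per-block kinship matrices \eqn{\Phi_b}
#'   (coefficients, not relationships: the model uses `2 *` them).
#' @param household optional list of per-block household indicator
#'   matrices \eqn{H_b}; default: all members of a block share one
#'   household.
#' @return `-Inf` (with a warning suppressed into the return value) when
#'   the covariance is not positive definite for the given parameters;
#'   otherwise the log-likelihood.
#' @export
vc_loglik <- function(sigma2_g, sigma2_c, sigma2_e, beta = NULL, y,
                      X = NULL, kinship, household = NULL) {
  sizes <- vapply(kinship, nrow, integer(1))
  stopifnot(sum(sizes) == length(y))
  if (is.null(X)) X <- matrix(0, length(y), 0)
  Vlist <- lapply(seq_along(kinship), function(b) {
    n <- sizes[b]
    H <- if (is.null(household)) matrix(1, n, n) else household[[b]]
    list(2 * kinship[[b]], H, diag(n))
  })
  frame <- lincov_frame(y, X, Vlist)
  r <- lincov_loglik(frame, c(sigma2_g, sigma2_c, sigma2_e), beta = beta)
  if (!r$ok) return(-Inf)
  r$loglik
}

#' Fit a univariate variance-components (ACE family) model
#'
#' Maximum-likelihood fit of an `A`(dditive genetic) / `C`(ommon
#' household environment) / `E`(unique environment) decomposition of a
#' trait over pedigree family blocks. Variances are optimized on the log
#' scale from three deterministic starts (E-heavy, A-heavy, balanced
#' splits of the residual variance); a component whose estimate collapses
#' toward zero is refit pinned to the boundary and reported as 0.
#'
#' @param ped pedigree object.
#' @param tab phenotype data frame with `fid`, `id`, `sex` and the trait.
#' @param trait trait column name.
#' @param components subset of `c("A","C","E")`; `E` is always included.
#' @param covariates covariate names for [build_covariates()] (an
#'   intercept is always added).
#' @param subset optional logical vector over `tab` rows (e.g. one sex).
#' @param household `"family"` (default: C shared by all members of a
#'   family block) or `"none"`.
#' @param n_starts 1-3 deterministic starting points.
#' @param se compute the delta-method standard error of h2 from the
#'   numerically differentiated observed information (default TRUE).
#' @return object of class `vc_fit`: variance components `sigma2`
#'   (named `g`, `c`, `e`), `beta`, `loglik`, `h2`, `h2_se`, `converged`,
#'   `n_used`, plus bookkeeping fields.
#' @export
fit_vc <- function(ped, tab, trait, components = c("A", "C", "E"),
                   covariates = character(0), subset = NULL,
                   household = c("family", "none"), n_starts = 3,
                   se = TRUE) {
  household <- match.arg(household)
  components <- unique(c(intersect(components, c("A", "C")), "E"))
  dat <- prepare_vc_data(ped, tab, trait, covariates, subset = subset)
  if (dat$n_used == 0) stop("no analyzable rows")
  if (!any(lengths(dat$blocks) >= 2) && "A" %in% components) {
    warning("no family block with >= 2 members: sigma2_g is unidentifiable")
  }
  y <- dat$y[, 1]
  Vlist <- lapply(dat$kin2, uv_structures, components = components,
                  household = household == "family")
  frame <- lincov_frame(y, dat$X, Vlist)

  s2 <- max(var(lm.fit(dat$X, y)$residuals), 1e-8)
  K <- length(Vlist[[1]])
  splits <- if (K == 1) {
    list(balanced = numeric(0))
  } else {
    list(balanced = rep(1 / K, K - 1),
         a_heavy = c(0.8, rep(0.1, K - 2)),
         e_heavy = rep(0.1, K - 1))
  }
  splits <- lapply(splits, function(f) c(f, 1 - sum(f)))  # last = E share
  starts <- lapply(splits[seq_len(min(length(splits), max(1, n_starts)))],
                   function(f) log(s2 * f))

  fit <- fit_lincov(frame, par2theta = exp, starts = starts)

  ## boundary handling: pin collapsed components to exactly zero
  comp_names <- c(intersect(c("A", "C"), components), "E")
  theta <- fit$theta
  tiny <- theta < 1e-6 * sum(theta) & comp_names != "E"
  pinned <- character(0)
  if (any(tiny)) {
    keep <- !tiny
    Vlist2 <- lapply(Vlist, function(v) v[keep])
    frame2 <- lincov_frame(y, dat$X, Vlist2)
    starts2 <- lapply(starts, function(s) s[keep])
    fit2 <- fit_lincov(frame2, par2theta = exp, starts = starts2)
    if (fit2$loglik >= fit$loglik - 1e-6) {
      theta <- numeric(length(comp_names))
      theta[keep] <- fit2$theta
      fit <- fit2
      pinned <- comp_names[tiny]
    }
  }

  sigma2 <- c(g = 0, c = 0, e = 0)
  sigma2[c(A = "g", C = "c", E = "e")[comp_names]] <- theta
  total <- sum(sigma2)
  h2 <- unname(sigma2["g"] / total)

  h2_se <- NA_real_
  if (se && "A" %in% components && !("A" %in% pinned)) {
    free <- which(theta > 0)
    Vfree <- lapply(Vlist, function(v) v[free])
    frame_f <- lincov_frame(y, dat$X, Vfree)
    llfun <- function(th) {
      if (any(th <= 0)) return(-1e10)
      r <- lincov_loglik(frame_f, th)
      if (!r$ok) return(-1e10) else r$loglik
    }
    info <- numeric_obs_info(llfun, theta[free])
    V <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(V)) {
      ## delta method for h2 = theta_g / sum(theta)
      g_idx <- 1  # A is first among free components when present
      grad <- rep(-theta[free][g_idx] / sum(theta[free])^2, length(free))
      grad[g_idx] <- grad[g_idx] + 1 / sum(theta[free])
      v <- drop(t(grad) %*% V %*% grad)
      if (is.finite(v) && v >= 0) h2_se <- sqrt(v)
    }
  }

  beta <- setNames(as.numeric(fit$beta), colnames(dat$X))
  structure(list(sigma2 = sigma2, beta = beta, loglik = fit$loglik,
                 h2 = h2, h2_se = h2_se, converged = fit$converged,
                 n_used = dat$n_used, components = comp_names,
                 pinned = pinned, trait = trait, covariates = covariates),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf(
    "polygenic fit (%s), trait %s: n = %d, logL = %.3f\n",
    paste(x$components, collapse = ""), x$trait, x$n_used, x$loglik))
  cat(sprintf("  sigma2_g = %.4f, sigma2_c = %.4f, sigma2_e = %.4f\n",
              x$sigma2["g"], x$sigma2["c"], x$sigma2["e"]))
  cat(sprintf("  h2 = %.3f (SE %.3f)\n", x$h2, x$h2_se))
  invisible(x)
}

#' Likelihood-ratio comparison of nested variance-components models
#'
#' Removing a variance component (A or C) pins it to the boundary of its
#' space, so by default the null distribution is the 50:50 mixture of a
#' point mass at zero and chi-square(1); other constraints use a plain
#' chi-square with `df` equal to the number of removed components.
#'
#' @param full,nested `vc_fit` objects on the same data (checked via
#'   `n_used`), nested's components a subset of full's.
#' @param null `"auto"` (mixture for a single boundary constraint, plain
#'   chi-square otherwise), `"mixture"`, or `"chi2"`.
#' @return [lrt_result()] object.
#' @export
compare_models <- function(full, nested, null = c("auto", "mixture", "chi2")) {
  null <- match.arg(null)
  if (full$n_used != nested$n_used) {
    stop("fits use different numbers of rows (", full$n_used, " vs ",
         nested$n_used, ")")
  }
  if (!all(nested$components %in% full$components)) {
    stop("`nested` is not nested in `full`")
  }
  df <- length(setdiff(full$components, nested$components))
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  kind <- switch(null,
    mixture = "mixture_50_50",
    chi2 = if (df == 1) "chi2_1" else "chi2_df",
    auto = if (df == 1) "mixture_50_50" else "chi2_df")
  lrt_result(stat, kind, df = df)
}
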