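## Shared machinery for block-diagonal Gaussian models whose per-block
## covariance is a linear combination of fixed structure matrices,
## Sigma_b = sum_k theta_k V_{b,k}.  Fixed effects enter the mean linearly
## and are profiled out by GLS inside the likelihood, so the ML search
## runs only over the variance parameters.

## Build a likelihood frame from per-block structure matrices.
## y: response (rows in block order); X: fixed-effect design; Vlist:
## list over blocks, each a list of K matrices.
lincov_frame <- function(y, X, Vlist) {
  sizes <- vapply(Vlist, function(v) nrow(v[[1]]), integer(1))
  stopifnot(sum(sizes) == length(y), nrow(X) == length(y))
  K <- length(Vlist[[1]])
  vflat <- unlist(lapply(Vlist, function(v) {
    stopifnot(length(v) == K)
    unlist(v, use.names = FALSE)
  }), use.names = FALSE)
  list(y = as.numeric(y), X = X, block_sizes = as.integer(sizes),
       vflat = as.numeric(vflat), K = K, N = length(y))
}

## Profiled (beta = NULL) or fixed-beta log-likelihood of a frame.
lincov_loglik <- function(frame, theta, beta = NULL) {
  .lincov_loglik_cpp(frame$y, frame$X, frame$block_sizes, frame$vflat,
                     as.numeric(theta),
                     if (is.null(beta)) numeric(0) else as.numeric(beta))
}

## Deterministic multi-start quasi-Newton ML over an unconstrained
## parameterization.  par2theta maps the unconstrained parameter vector
## to the K covariance coefficients; penalty() may add a smooth penalty
## (default none).  Returns the best converged fit.
fit_lincov <- function(frame, par2theta, starts,
                       penalty = function(par) 0,
                       reltol = 1e-10, maxit = 1000) {
  negll <- function(par) {
    th <- par2theta(par)
    # overflowed / degenerate coefficients: failure before the algebra
    if (any(!is.finite(th)) || max(abs(th)) > 1e12) return(1e10)
    r <- lincov_loglik(frame, th)
    if (!r$ok || !is.finite(r$loglik)) return(1e10)
    -r$loglik + penalty(par)
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, negll, method = "BFGS",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(opt)) next
    ## Nelder-Mead polish guards against BFGS stalls near boundaries
    if (length(s) > 1) {
      opt2 <- tryCatch(
        optim(opt$par, negll, method = "Nelder-Mead",
              control = list(reltol = reltol, maxit = maxit)),
        error = function(e) opt)
      if (!is.null(opt2) && opt2$value < opt$value) opt <- opt2
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(list(par = starts[[1]], theta = par2theta(starts[[1]]),
                loglik = -Inf, beta = NULL, converged = FALSE))
  }
  th <- unname(par2theta(best$par))
  r <- lincov_loglik(frame, th)
  list(par = best$par, theta = th, loglik = r$loglik, beta = r$beta,
       converged = is.finite(r$loglik) && best$convergence %in% c(0L, 1L))
}

## ---- analysis dataset preparation ----------------------------------------

## Assemble the complete-case analysis dataset for one trait (or two):
## rows grouped into likelihood blocks by family id (households, so the
## shared-environment component stays block-diagonal), per-block additive
## relationship matrices 2*Phi subset to analyzed individuals, and the
## fixed-effect design (intercept + covariates).
prepare_vc_data <- function(ped, tab, traits, covariates = character(0),
                            subset = NULL) {
  stopifnot(all(traits %in% names(tab)))
  if (!all(tab$id %in% ped$id)) {
    stop("phenotype rows with ids absent from the pedigree")
  }
  Xc <- build_covariates(tab, covariates)
  Y <- as.matrix(tab[, traits, drop = FALSE])
  ok <- complete.cases(Y) & (if (ncol(Xc)) complete.cases(Xc) else TRUE)
  if (!is.null(subset)) ok <- ok & subset
  tab <- tab[ok, , drop = FALSE]
  Xc <- Xc[ok, , drop = FALSE]
  Y <- Y[ok, , drop = FALSE]

  ## order rows by family id so blocks are contiguous
  ord <- order(match(tab$fid, unique(tab$fid)))
  tab <- tab[ord, , drop = FALSE]
  Xc <- Xc[ord, , drop = FALSE]
  Y <- Y[ord, , drop = FALSE]

  blocks <- split(seq_len(nrow(tab)), match(tab$fid, unique(tab$fid)))
  kin2 <- vector("list", length(blocks))
  sexes <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    fid <- tab$fid[rows[1]]
    fam_ped <- ped[ped$fid == fid, , drop = FALSE]
    class(fam_ped) <- c("pedigree", "data.frame")
    kin2[[b]] <- 2 * kinship_matrix(fam_ped, ids = tab$id[rows])
    sexes[[b]] <- tab$sex[rows]
  }
  ## drop covariates that are constant on the analyzed rows (e.g. sex
  ## within a single-sex subset) so the GLS cross-product stays full rank
  if (ncol(Xc)) {
    keep <- apply(Xc, 2, function(cl) length(unique(cl)) > 1)
    Xc <- Xc[, keep, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, Xc)
  list(y = Y, X = X, tab = tab, blocks = blocks, kin2 = kin2,
       sexes = sexes, n_used = nrow(tab))
}

## numeric observed information (negative Hessian of loglik) by central
## differences on the natural (variance) scale, with beta profiled
numeric_obs_info <- function(fn, theta, rel_h = 1e-4) {
  p <- length(theta)
  h <- pmax(abs(theta), 1e-3) * rel_h
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ti <- theta; tj <- theta
      if (i == j) {
        tp <- theta; tm <- theta
        tp[i] <- theta[i] + h[i]; tm[i] <- theta[i] - h[i]
        H[i, i] <- (fn(tp) - 2 * f0 + fn(tm)) / h[i]^2
      } else {
        tpp <- theta; tpm <- theta; tmp <- theta; tmm <- theta
        tpp[c(i, j)] <- theta[c(i, j)] + h[c(i, j)]
        tmm[c(i, j)] <- theta[c(i, j)] - h[c(i, j)]
        tpm[i] <- theta[i] + h[i]; tpm[j] <- theta[j] - h[j]
        tmp[i] <- theta[i] - h[i]; tmp[j] <- theta[j] + h[j]
        H[i, j] <- H[j, i] <-
          (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[i] * h[j])
      }
    }
  }
  -H
}
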