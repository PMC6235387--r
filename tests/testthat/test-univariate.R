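sib_pair_ped <- function() {
  as_pedigree(data.frame(
    fid = "S", id = c("f", "m", "s1", "s2"),
    father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m"),
    sex = c("M", "F", "M", "F"),
    observed = c(FALSE, FALSE, TRUE, TRUE)))
}

test_that("polygenic log-likelihood matches closed forms and is additive", {
  # single individual, pure environmental unit variance: standard normal
  ll1 <- vc_loglik(0, 0, 1, beta = numeric(0), y = 0,
                   X = matrix(0, 1, 0), kinship = list(matrix(0.5, 1, 1)))
  expect_equal(ll1, -0.5 * log(2 * pi))

  # sib pair under A = 0.6, E = 0.4: bivariate normal, covariance 0.3
  phi <- kinship_matrix(sib_pair_ped(), ids = c("s1", "s2"))
  y <- c(0.7, -0.2)
  ll2 <- vc_loglik(0.6, 0, 0.4, beta = numeric(0), y = y,
                   X = matrix(0, 2, 0), kinship = list(phi))
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(ll2, dmvn_log(y, c(0, 0), S))

  # two independent blocks: log-likelihoods add
  ll_both <- vc_loglik(0.6, 0, 0.4, beta = numeric(0), y = c(y, 0.1),
                       X = matrix(0, 3, 0),
                       kinship = list(phi, matrix(0.5, 1, 1)))
  ll_single <- vc_loglik(0.6, 0, 0.4, beta = numeric(0), y = 0.1,
                         X = matrix(0, 1, 0),
                         kinship = list(matrix(0.5, 1, 1)))
  expect_equal(ll_both, ll2 + ll_single)

  # non-positive-definite covariance: defined failure, not a crash
  expect_identical(vc_loglik(0, 0, 0, beta = numeric(0), y = 0,
                             X = matrix(0, 1, 0),
                             kinship = list(matrix(0.5, 1, 1))), -Inf)
})

test_that("univariate likelihood equals the dense MVN oracle on random pedigrees", {
  set.seed(41)
  for (rep in 1:10) {
    ped <- random_pedigree(sample(3:8, 1))
    n <- nrow(ped)
    phi <- kinship_matrix(ped)
    s2 <- c(g = 0.7, c = 0.2, e = 0.5)
    y <- rnorm(n)
    X <- cbind(1, rnorm(n))
    beta <- c(0.3, -0.1)
    ll <- vc_loglik(s2["g"], s2["c"], s2["e"], beta = beta, y = y, X = X,
                    kinship = list(phi))
    S <- 2 * phi * s2["g"] + matrix(s2["c"], n, n) + diag(n) * s2["e"]
    expect_equal(ll, dmvn_log(y, X %*% beta, S), tolerance = 1e-8)
  }
})

test_that("E-only model recovers the closed-form ML residual variance", {
  set.seed(42)
  sc <- latent_scenario("knhanes_total", n_families = 80)
  d <- simulate_dataset(sc, 8)
  tab <- d$phenotypes
  fit <- fit_vc(d$pedigree, tab, "tsh", components = "E",
                covariates = c("age", "sex"), se = FALSE)
  X <- cbind(1, build_covariates(tab, c("age", "sex")))
  r <- lm.fit(X, tab$tsh)$residuals
  expect_equal(unname(fit$sigma2["e"]), sum(r^2) / length(r),
               tolerance = 1e-6)
  expect_equal(fit$h2, 0)
})

test_that("fit is invariant to block order and equivariant under rescaling", {
  sc <- latent_scenario("knhanes_total", n_families = 120)
  d <- simulate_dataset(sc, 9)
  tab <- d$phenotypes
  f1 <- fit_vc(d$pedigree, tab, "tsh", c("A", "E"), se = FALSE)

  # shuffle family order (blocks are rebuilt internally)
  set.seed(10)
  tab_shuf <- tab[order(sample(unique(tab$fid))[match(tab$fid, unique(tab$fid))]), ]
  f2 <- fit_vc(d$pedigree, tab_shuf, "tsh", c("A", "E"), se = FALSE)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-4)

  # affine rescaling: h2 invariant, variances scale quadratically
  tab$tsh_resc <- 3 * tab$tsh + 10
  f3 <- fit_vc(d$pedigree, tab, "tsh_resc", c("A", "E"), se = FALSE)
  expect_equal(f3$h2, f1$h2, tolerance = 1e-3)
  expect_equal(unname(f3$sigma2["g"]), unname(9 * f1$sigma2["g"]),
               tolerance = 1e-2)
})

test_that("a zero-heritability trait is fit at or near the boundary", {
  sc <- latent_scenario("knhanes_total", n_families = 150)
  sc$params$sigma2_g <- c(1e-9, 1e-9)  # all variance environmental
  sc$params$sigma2_e <- c(1, 1)
  set.seed(55)
  h2s <- vapply(1:20, function(i) {
    d <- simulate_dataset(sc, 1000 + i)
    fit_vc(d$pedigree, d$phenotypes, "tsh", c("A", "E"), se = FALSE)$h2
  }, numeric(1))
  expect_lt(median(h2s), 0.05)
})

test_that("model comparison uses the right null distributions", {
  sc <- latent_scenario("knhanes_total", n_families = 100)
  d <- simulate_dataset(sc, 77)
  ace <- fit_vc(d$pedigree, d$phenotypes, "tsh", c("A", "C", "E"), se = FALSE)
  ae <- fit_vc(d$pedigree, d$phenotypes, "tsh", c("A", "E"), se = FALSE)
  e <- fit_vc(d$pedigree, d$phenotypes, "tsh", "E", se = FALSE)

  cmp <- compare_models(ace, ae)             # C removal: boundary mixture
  expect_equal(cmp$null_kind, "mixture_50_50")
  expect_gte(cmp$statistic, 0)
  expect_equal(cmp$p_value,
               0.5 * pchisq(cmp$statistic, 1, lower.tail = FALSE))

  cmp2 <- compare_models(ace, e, null = "chi2")  # 2 components removed
  expect_equal(cmp2$df, 2)

  # identical fits: statistic 0 -> mixture p 0.5, plain chi-square p 1
  expect_equal(compare_models(ae, ae, null = "mixture")$p_value, 0.5)
  expect_equal(compare_models(ae, ae, null = "chi2")$p_value, 1.0)

  # chi-square(1) tail value at the textbook 10% point
  expect_equal(lrt_pvalue(2.706, "chi2_1"), 0.0999, tolerance = 1e-3)

  expect_error(compare_models(ae, fit_vc(d$pedigree,
    d$phenotypes[1:50, ], "tsh", "E", se = FALSE)), "different numbers")
})

test_that("heritability is recovered within uncertainty at survey scale", {
  d <- simulate_dataset(scenario_presets("knhanes_total"), 4242)
  tab <- d$phenotypes
  tab$tsh_int <- inverse_normal_transform(tab$tsh)
  fit <- fit_vc(d$pedigree, tab, "tsh_int", c("A", "E"),
                covariates = c("age", "age2", "sex"))
  expect_true(fit$converged)
  expect_lt(abs(fit$h2 - 0.54), 3 * fit$h2_se)
  expect_true(fit$h2_se > 0.02 && fit$h2_se < 0.15)
})
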