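gxs_pars <- function(sgM = 1, sgF = 1, seM = 1, seF = 1, rho = 1) {
  list(sigma_gM = sgM, sigma_gF = sgF, sigma_eM = seM, sigma_eF = seF,
       rho_gMF = rho)
}

test_that("sex-limitation covariance entries follow the model formulas", {
  # male sib pair, phi = 0.25: 2 phi sigma2_gM
  expect_equal(gxs_covariance("male", "male", 0.25, FALSE,
                              gxs_pars(sgM = 1)), 0.5)
  # brother-sister pair with rho = 1 and equal SDs: same as same-sex
  expect_equal(gxs_covariance("male", "female", 0.25, FALSE, gxs_pars()), 0.5)
  # rho = 0 kills the cross-sex genetic covariance
  expect_equal(gxs_covariance("male", "female", 0.25, FALSE,
                              gxs_pars(rho = 0)), 0)
  # diagonal: genetic plus unique environmental variance
  expect_equal(gxs_covariance("female", "female", 0.5, TRUE,
                              gxs_pars(sgF = 2, seF = 3)), 4 + 9)
})

test_that("G x S likelihood matches the dense MVN oracle on random pedigrees", {
  set.seed(61)
  pars <- gxs_pars(sgM = 0.8, sgF = 1.1, seM = 0.9, seF = 0.7, rho = 0.6)
  theta <- c(pars$sigma_gM^2, pars$sigma_gF^2,
             pars$sigma_gM * pars$sigma_gF * pars$rho_gMF,
             pars$sigma_eM^2, pars$sigma_eF^2)
  for (rep in 1:10) {
    ped <- random_pedigree(sample(3:8, 1))
    n <- nrow(ped)
    phi <- kinship_matrix(ped)
    y <- rnorm(n)
    # oracle covariance assembled entry by entry from the pair formulas
    S <- matrix(NA_real_, n, n)
    for (i in 1:n) for (j in 1:n) {
      S[i, j] <- gxs_covariance(ped$sex[i], ped$sex[j], phi[i, j],
                                same_individual = (i == j), pars)
    }
    oracle <- dmvn_log(y, rep(0, n), S)
    Vb <- thyrovc:::gxs_structures(2 * phi, ped$sex)
    fr <- thyrovc:::lincov_frame(y, matrix(0, n, 0), list(Vb))
    expect_equal(thyrovc:::lincov_loglik(fr, theta, beta = numeric(0))$loglik,
                 oracle, tolerance = 1e-8)
  }
})

test_that("with equal SDs and rho = 1 the model collapses to univariate AE", {
  set.seed(62)
  ped <- random_pedigree(6)
  y <- rnorm(6)
  phi <- kinship_matrix(ped)
  Vb <- thyrovc:::gxs_structures(2 * phi, ped$sex)
  fr <- thyrovc:::lincov_frame(y, matrix(0, 6, 0), list(Vb))
  ll_gxs <- thyrovc:::lincov_loglik(fr, c(0.6, 0.6, 0.6, 0.4, 0.4),
                                    beta = numeric(0))$loglik
  ll_ae <- vc_loglik(0.6, 0, 0.4, beta = numeric(0), y = y,
                     X = matrix(0, 6, 0), kinship = list(phi))
  expect_equal(ll_gxs, ll_ae, tolerance = 1e-8)
})

test_that("constraint fits are ordered and the LRT nulls are as declared", {
  d <- simulate_dataset(latent_scenario("null_gxs", n_families = 250), 63)
  tab <- d$phenotypes
  cv <- c("age", "sex")
  full <- fit_gxs(d$pedigree, tab, "tsh", cv)
  rho1 <- fit_gxs(d$pedigree, tab, "tsh", cv, constraint = "rho_eq_1")
  sgeq <- fit_gxs(d$pedigree, tab, "tsh", cv, constraint = "sigma_g_equal")
  expect_lte(rho1$loglik, full$loglik + 1e-6)
  expect_lte(sgeq$loglik, full$loglik + 1e-6)
  # symmetric truth: constrained fit nearly as good as the full one
  expect_lt(2 * (full$loglik - sgeq$loglik), qchisq(0.999, 1))

  t_rho <- test_gxs(full, rho1)
  expect_equal(t_rho$null_kind, "mixture_50_50")
  expect_equal(t_rho$p_value,
               0.5 * pchisq(t_rho$statistic, 1, lower.tail = FALSE))
  t_sg <- test_gxs(full, sgeq)
  expect_equal(t_sg$null_kind, "chi2_1")
  expect_gte(t_sg$statistic, 0)  # clamped, never negative

  expect_error(test_gxs(rho1, full), "unconstrained")
})

test_that("a true sex difference in genetic variance is detected", {
  # truth: female genetic variance ratio 0.75 vs male 0.41
  rej <- 0; dh2 <- numeric(8)
  for (i in 1:8) {
    d <- simulate_dataset(scenario_presets("knhanes_gxs"), 8800 + i)
    tab <- d$phenotypes
    tab$tsh_int <- inverse_normal_transform(tab$tsh)
    full <- fit_gxs(d$pedigree, tab, "tsh_int", c("age", "age2", "sex"))
    sgeq <- fit_gxs(d$pedigree, tab, "tsh_int", c("age", "age2", "sex"),
                    constraint = "sigma_g_equal")
    rej <- rej + (test_gxs(full, sgeq)$p_value < 0.05)
    dh2[i] <- full$h2_F - full$h2_M
  }
  expect_gte(rej, 1)              # power well above the 5% level
  expect_gt(mean(dh2), 0.15)      # recovered difference near truth 0.34
})

test_that("single-sex or no-cross-pair samples raise identifiability warnings", {
  d <- simulate_dataset(latent_scenario("knhanes_bivariate_female",
                                        n_families = 30), 64)
  w <- capture_warnings(
    fit_gxs(d$pedigree, d$phenotypes, "tsh", c("age"), n_starts = 1))
  expect_match(w, "single sex", all = FALSE)
  expect_match(w, "opposite-sex", all = FALSE)
})
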