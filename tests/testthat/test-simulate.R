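test_that("identical scenario and seed reproduce the dataset exactly", {
  sc <- scenario_presets("knhanes_total", n_families = 80)
  d1 <- simulate_dataset(sc, 31)
  d2 <- simulate_dataset(sc, 31)
  expect_identical(as.data.frame(d1$pedigree), as.data.frame(d2$pedigree))
  expect_identical(d1$phenotypes, d2$phenotypes)
  d3 <- simulate_dataset(sc, 32)
  expect_false(identical(d1$phenotypes$tsh, d3$phenotypes$tsh))
  # the generator leaves the global RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_dataset(sc, 33)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("survey-scale preset yields the expected cohort size", {
  sizes <- vapply(1:12, function(s) {
    ped <- simulate_pedigrees(scenario_presets("knhanes_total"), 300 + s)
    sum(ped$observed)
  }, numeric(1))
  expect_gt(mean(sizes), 2100)
  expect_lt(mean(sizes), 2400)
  # sex ratio near the emulated cohort's 53.4% male
  ped <- simulate_pedigrees(scenario_presets("knhanes_total"), 99)
  expect_lt(abs(mean(ped$sex[ped$observed] == "male") - 0.534), 0.05)
})

test_that("sibship composition gives observed sib pairs with hidden founders", {
  sc <- scenario_presets("knhanes_total", n_families = 40)
  sc$composition <- "sibpair"; sc$size_probs <- c(`2` = 1)
  ped <- simulate_pedigrees(sc, 41)
  obs_per_fam <- tapply(ped$observed, ped$fid, sum)
  expect_true(all(obs_per_fam == 2))
  expect_true(all(tapply(!ped$observed, ped$fid, sum) == 2))
  # observed sibs are related through the carried founders
  fam1 <- ped[ped$fid == ped$fid[1], ]
  class(fam1) <- c("pedigree", "data.frame")
  k <- kinship_matrix(fam1, ids = fam1$id[fam1$observed])
  expect_equal(unname(k[1, 2]), 0.25)
})

test_that("a zero-heritability scenario produces uncorrelated sibs", {
  sc <- latent_scenario("knhanes_total", n_families = 2000)
  sc$composition <- "sibpair"; sc$size_probs <- c(`2` = 1)
  sc$params$sigma2_g <- c(0, 0); sc$params$sigma2_e <- c(1, 1)
  tab <- simulate_dataset(sc, 43)$phenotypes
  s1 <- tab[!duplicated(tab$fid), ]; s2 <- tab[duplicated(tab$fid), ]
  expect_lt(abs(cor(s1$tsh, s2$tsh)), 0.05)
})

test_that("without G x S, same- and opposite-sex sib correlations agree", {
  sc <- latent_scenario("null_gxs", n_families = 1500)
  sc$composition <- "sibpair"; sc$size_probs <- c(`2` = 1)
  tab <- simulate_dataset(sc, 44)$phenotypes
  s1 <- tab[!duplicated(tab$fid), ]; s2 <- tab[duplicated(tab$fid), ]
  same <- s1$sex == s2$sex
  r_same <- cor(s1$tsh[same], s2$tsh[same])
  r_opp <- cor(s1$tsh[!same], s2$tsh[!same])
  z <- abs(atanh(r_same) - atanh(r_opp)) /
    sqrt(1 / (sum(same) - 3) + 1 / (sum(!same) - 3))
  expect_lt(z, 3)
})

test_that("empirical sib covariance matches the analytic model covariance", {
  sc <- latent_scenario("knhanes_total", n_families = 3000)
  sc$composition <- "sibpair"; sc$size_probs <- c(`2` = 1)
  tab <- simulate_dataset(sc, 45)$phenotypes
  s1 <- tab[!duplicated(tab$fid), ]; s2 <- tab[duplicated(tab$fid), ]
  n <- nrow(s1)
  # analytic: var = s2g + s2e = 1; cov(sib) = 0.5 * s2g = 0.27;
  # cross-trait within person = rho_g sg1 sg2 + rho_e se1 se2
  checks <- rbind(
    c(var(tab$tsh), 1), c(var(tab$ft4), 1),
    c(cov(s1$tsh, s2$tsh), 0.5 * 0.54),
    c(cov(s1$ft4, s2$ft4), 0.5 * 0.56),
    c(cov(tab$tsh, tab$ft4),
      -0.150 * sqrt(0.54 * 0.56) - 0.056 * sqrt(0.46 * 0.44)),
    c(cov(s1$tsh, s2$ft4), 0.5 * -0.150 * sqrt(0.54 * 0.56)))
  # 3 Monte-Carlo SEs (~1/sqrt(n) scale for covariances of unit traits)
  expect_true(all(abs(checks[, 1] - checks[, 2]) < 3 * 1.1 / sqrt(n)))
})

test_that("presets carry the study parameter values and nulls", {
  tot <- scenario_presets("knhanes_total")
  expect_equal(tot$params$sigma2_g, c(0.54, 0.56))
  expect_equal(tot$n_families, 1115)
  gxs <- scenario_presets("knhanes_gxs")
  expect_equal(gxs$params$sigma2_gF, 0.75)
  expect_equal(gxs$params$sigma2_gM, 0.41)
  null <- scenario_presets("null_gxs")
  expect_equal(null$params$sigma2_gM, null$params$sigma2_gF)
  expect_equal(null$params$rho_gMF, 1)
  expect_equal(scenario_presets("null_pleiotropy")$params$rho_g, 0)
  expect_error(scenario_presets("nope"))
})

test_that("datasets round-trip through the delimited-text formats", {
  d <- simulate_dataset(scenario_presets("knhanes_total", n_families = 25), 46)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  ped2 <- read_pedigree(file.path(dir, "pedigree.tsv"))
  tab2 <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(ped2$id, d$pedigree$id)
  expect_equal(ped2$sex, d$pedigree$sex)
  expect_equal(ped2$observed, d$pedigree$observed)
  expect_equal(tab2$tsh, d$phenotypes$tsh, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$params$sigma2_g, d$truth$params$sigma2_g)
  expect_equal(truth$name, "knhanes_total")
})
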