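## Synthetic family data emulating a KNHANES-like household sample:
## many small families (pairs and trios), two correlated quantitative
## thyroid traits with additive-genetic + unique-environment structure,
## sex-specific genetic variances, and covariate effects.  Phenotypes are
## drawn directly from the model covariance per family block (matrix
## square root), built from the kinship matrix through the same
## covariance operations the fitters use.

#' Simulation scenario presets
#'
#' Named presets whose true parameters correspond to the headline
#' estimates of the emulated study (variances on the standardized latent
#' scale, total variance 1 per sex/trait):
#' \describe{
#'   \item{knhanes_total}{bivariate TSH/fT4, h2 = (0.54, 0.56),
#'     rho_g = -0.150, rho_e = -0.056; 1,115 families.}
#'   \item{knhanes_gxs}{sex-limitation TSH: sigma2_gF = 0.75,
#'     sigma2_gM = 0.41 (variance ratios), rho_gMF = 1.}
#'   \item{knhanes_bivariate_female}{female-only sibship design,
#'     rho_g = -0.347, rho_e = 0.367, h2 = (0.75, 0.52).}
#'   \item{null_gxs}{no genotype-by-sex interaction:
#'     sigma_gM = sigma_gF (h2 = 0.5), rho_gMF = 1.}
#'   \item{null_pleiotropy}{rho_g = rho_e = 0, h2 = (0.5, 0.5).}
#' }
#'
#' @param name preset name.
#' @param n_families override the preset's number of families.
#' @return a `sim_scenario` list; fields can be modified before use.
#' @export
scenario_presets <- function(name = c("knhanes_total", "knhanes_gxs",
                                      "knhanes_bivariate_female",
                                      "null_gxs", "null_pleiotropy"),
                             n_families = NULL) {
  name <- match.arg(name)
  base <- list(
    name = name,
    n_families = 1115,
    ## family-size mixture: mostly pairs, some trios (household survey)
    size_probs = c(`2` = 0.90, `3` = 0.08, `4` = 0.02),
    composition = "knhanes",
    p_male = 1201 / 2250,
    covariate_effects = list(age = 0.011, age2 = 2e-4, sex = 0.2, bmi = 0),
    trait_scale = list(
      tsh = list(type = "lognormal", meanlog = log(2.30), sdlog = 0.45),
      ft4 = list(type = "lognormal", meanlog = log(1.24), sdlog = 0.12)),
    include_excludable = FALSE)
  preset <- switch(name,
    knhanes_total = list(
      model = "bivariate",
      params = list(sigma2_g = c(0.54, 0.56), sigma2_e = c(0.46, 0.44),
                    rho_g = -0.150, rho_e = -0.056)),
    knhanes_gxs = list(
      model = "gxs",
      params = list(sigma2_gM = 0.41, sigma2_gF = 0.75,
                    sigma2_eM = 0.59, sigma2_eF = 0.25, rho_gMF = 1)),
    knhanes_bivariate_female = list(
      model = "bivariate", composition = "sibpair", p_male = 0,
      n_families = 520,
      params = list(sigma2_g = c(0.75, 0.52), sigma2_e = c(0.25, 0.48),
                    rho_g = -0.347, rho_e = 0.367)),
    null_gxs = list(
      model = "gxs",
      params = list(sigma2_gM = 0.5, sigma2_gF = 0.5,
                    sigma2_eM = 0.5, sigma2_eF = 0.5, rho_gMF = 1)),
    null_pleiotropy = list(
      model = "bivariate",
      params = list(sigma2_g = c(0.5, 0.5), sigma2_e = c(0.5, 0.5),
                    rho_g = 0, rho_e = 0)))
  sc <- utils::modifyList(base, preset)
  if (!is.null(n_families)) sc$n_families <- n_families
  stopifnot(abs(sum(sc$size_probs) - 1) < 1e-12)
  class(sc) <- "sim_scenario"
  sc
}

## run expr with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a pedigree of small families
#'
#' Families are drawn independently with sizes from the scenario's size
#' mixture. Under the `knhanes` composition, two-member families are
#' parent-offspring, full-sib or spouse pairs (45/35/20%), three-member
#' families nuclear trios or a parent with two children, four-member
#' families two parents with two children. Under `sibpair`, every family
#' is a sibship whose founder parents are carried in the pedigree but
#' flagged unobserved (they receive no phenotypes). Sexes not fixed by a
#' structural role (father, mother, spouse) are drawn with the
#' scenario's male fraction.
#'
#' @param scenario a `sim_scenario` (see [scenario_presets()]).
#' @param seed integer seed for this dataset's private RNG stream.
#' @return a validated [as_pedigree()] object.
#' @export
simulate_pedigrees <- function(scenario, seed) {
  with_seed(seed, {
    size_opts <- as.integer(names(scenario$size_probs))
    sizes <- size_opts[sample.int(length(size_opts), scenario$n_families,
                                  replace = TRUE,
                                  prob = scenario$size_probs)]
    rsex <- function(n) ifelse(runif(n) < scenario$p_male, "male", "female")
    rows <- vector("list", scenario$n_families)
    for (f in seq_len(scenario$n_families)) {
      fid <- sprintf("F%04d", f)
      id <- function(k) sprintf("%s_%d", fid, k)
      size <- sizes[f]
      type <- if (scenario$composition == "sibpair") {
        "sib"
      } else if (scenario$composition == "nuclear") {
        c(`2` = "po", `3` = "trio", `4` = "nuc22")[as.character(size)]
      } else {
        switch(as.character(size),
          `2` = sample(c("po", "sib", "spouse"), 1,
                       prob = c(0.45, 0.35, 0.20)),
          `3` = sample(c("trio", "po2"), 1, prob = c(0.6, 0.4)),
          `4` = "nuc22")
      }
      mk <- function(k, father = NA, mother = NA, sex = NULL, obs = TRUE) {
        data.frame(fid = fid, id = id(k),
                   father = if (is.na(father)) NA_character_ else id(father),
                   mother = if (is.na(mother)) NA_character_ else id(mother),
                   sex = if (is.null(sex)) rsex(1) else sex,
                   observed = obs, stringsAsFactors = FALSE)
      }
      rows[[f]] <- switch(type,
        po = {  # one observed parent, one child (other parent unobserved)
          p <- mk(1)
          q <- mk(2, sex = if (p$sex == "male") "female" else "male",
                  obs = FALSE)
          ch <- mk(3, father = if (p$sex == "male") 1 else 2,
                   mother = if (p$sex == "male") 2 else 1)
          rbind(p, q, ch)
        },
        po2 = {
          p <- mk(1)
          q <- mk(2, sex = if (p$sex == "male") "female" else "male",
                  obs = FALSE)
          fa <- if (p$sex == "male") 1 else 2
          mo <- if (p$sex == "male") 2 else 1
          rbind(p, q, mk(3, fa, mo), mk(4, fa, mo))
        },
        sib = {
          k <- if (scenario$composition == "sibpair") size else size
          founders <- rbind(mk(1, sex = "male", obs = FALSE),
                            mk(2, sex = "female", obs = FALSE))
          sibs <- do.call(rbind, lapply(seq_len(k), function(j)
            mk(2 + j, father = 1, mother = 2)))
          rbind(founders, sibs)
        },
        spouse = rbind(mk(1, sex = "male"), mk(2, sex = "female")),
        trio = {
          fa <- mk(1, sex = "male"); mo <- mk(2, sex = "female")
          rbind(fa, mo, mk(3, father = 1, mother = 2))
        },
        nuc22 = {
          fa <- mk(1, sex = "male"); mo <- mk(2, sex = "female")
          rbind(fa, mo, mk(3, father = 1, mother = 2),
                mk(4, father = 1, mother = 2))
        })
    }
    as_pedigree(do.call(rbind, rows))
  })
}

## analytic per-block covariance of observed members, latent scale
sim_block_cov <- function(kin2, sexes, scenario) {
  p <- scenario$params
  n <- nrow(kin2)
  if (scenario$model == "bivariate") {
    G <- matrix(c(p$sigma2_g[1],
                  p$rho_g * sqrt(p$sigma2_g[1] * p$sigma2_g[2]),
                  p$rho_g * sqrt(p$sigma2_g[1] * p$sigma2_g[2]),
                  p$sigma2_g[2]), 2, 2)
    E <- matrix(c(p$sigma2_e[1],
                  p$rho_e * sqrt(p$sigma2_e[1] * p$sigma2_e[2]),
                  p$rho_e * sqrt(p$sigma2_e[1] * p$sigma2_e[2]),
                  p$sigma2_e[2]), 2, 2)
    kin2 %x% G + diag(n) %x% E
  } else if (scenario$model == "gxs") {
    gpar <- list(sigma_gM = sqrt(p$sigma2_gM), sigma_gF = sqrt(p$sigma2_gF),
                 sigma_eM = sqrt(p$sigma2_eM), sigma_eF = sqrt(p$sigma2_eF),
                 rho_gMF = p$rho_gMF)
    S <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      S[i, j] <- gxs_covariance(sexes[i], sexes[j], kin2[i, j] / 2,
                                same_individual = (i == j), gpar)
    }
    S
  } else {  # univariate_ACE
    kin2 * p$sigma2_g + matrix(p$sigma2_c, n, n) + diag(n) * p$sigma2_e
  }
}

#' Simulate phenotypes on a pedigree
#'
#' Draws latent trait values per family block from a zero-mean Gaussian
#' with the scenario's exact model covariance (built from the kinship
#' matrix through the same covariance operations the fitters use), adds
#' fixed-effect contributions from simulated covariates (age uniform on
#' 10-80 years, BMI, sex), and maps traits to their observed scales
#' (lognormal by default, medians matching the emulated cohort).
#' Ancillary variables (urinary iodine and creatinine, TPOAb below the
#' positivity cut, smoking, menopausal status, history flags) are drawn
#' so the preparation stage is exercised; by default the sample emulates
#' the post-exclusion cohort, and `include_excludable = TRUE` adds rows
#' targeted by each exclusion rule.
#'
#' @param ped pedigree from [simulate_pedigrees()].
#' @param scenario `sim_scenario`.
#' @param seed integer seed (private stream).
#' @return phenotype data frame, one row per observed individual.
#' @export
simulate_phenotypes <- function(ped, scenario, seed) {
  with_seed(seed, {
    obs <- ped[ped$observed, , drop = FALSE]
    n <- nrow(obs)
    age <- runif(n, 10, 80)
    bmi <- rnorm(n, 23.5, 3.3)
    male <- obs$sex == "male"
    eff <- scenario$covariate_effects
    fixed <- eff$age * (age - 45) + eff$age2 * ((age - 45)^2 - 408) +
      eff$sex * male + eff$bmi * (bmi - 23.5)

    ## latent genetic + environmental draw, per family block
    two_traits <- scenario$model == "bivariate"
    lat <- matrix(NA_real_, n, if (two_traits) 2 else 1)
    for (fid in unique(obs$fid)) {
      fam_ped <- ped[ped$fid == fid, , drop = FALSE]
      class(fam_ped) <- c("pedigree", "data.frame")
      rows <- which(obs$fid == fid)
      kin2 <- 2 * kinship_matrix(fam_ped, ids = obs$id[rows])
      S <- sim_block_cov(kin2, obs$sex[rows], scenario)
      L <- t(chol(S))
      z <- L %*% rnorm(nrow(S))
      if (two_traits) {
        lat[rows, ] <- matrix(z, ncol = 2, byrow = TRUE)
      } else {
        lat[rows, 1] <- z
      }
    }
    lat <- lat + fixed  # same covariate effects on each trait

    to_scale <- function(latent, trait) {
      sc <- scenario$trait_scale[[trait]]
      if (is.null(sc) || sc$type == "identity") latent
      else exp(sc$meanlog + sc$sdlog * latent)
    }
    tsh <- to_scale(lat[, 1], "tsh")
    ft4 <- if (two_traits) to_scale(lat[, 2], "ft4") else rep(NA_real_, n)

    smoking <- ifelse(age < 12, "not-indicated",
               ifelse(runif(n) < ifelse(male, 0.31, 0.06), "current",
                      "former/never"))
    menopause <- ifelse(male, "no",
                 ifelse(age >= 50, ifelse(runif(n) < 0.9, "yes", "no"),
                 ifelse(runif(n) < 0.03, "yes", "no")))
    ucr <- rlnorm(n, log(1.2), 0.5)
    uicr <- rlnorm(n, log(181), 0.9)
    ui <- uicr * ucr / 100
    tpoab <- rlnorm(n, log(5), 0.8)
    tpoab[tpoab >= 34] <- 33.9  # emulates the post-exclusion sample

    tab <- data.frame(
      fid = obs$fid, id = obs$id, sex = obs$sex, age = age, bmi = bmi,
      smoking = smoking, menopause = menopause, ui = ui, ucr = ucr,
      tpoab = tpoab, tsh = tsh, ft4 = ft4,
      overt_dysfunction = FALSE, thyroid_treatment = FALSE,
      pregnant = FALSE, thyroid_history = FALSE, fhx_thyroid = FALSE,
      stringsAsFactors = FALSE)
    if (isTRUE(scenario$include_excludable)) {
      flip <- function(p) runif(n) < p
      hot <- flip(0.05)
      tab$tpoab[hot] <- rlnorm(sum(hot), log(60), 0.4)
      tab$overt_dysfunction <- flip(0.01)
      tab$thyroid_treatment <- flip(0.01)
      tab$pregnant <- flip(0.01) & !male
      tab$thyroid_history <- flip(0.02)
      tab$fhx_thyroid <- flip(0.04)
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate a complete dataset (pedigree + phenotypes + truth)
#'
#' @param scenario `sim_scenario` or a preset name.
#' @param seed integer seed; the pedigree and phenotype streams are
#'   derived deterministically from it.
#' @return list of class `sim_dataset` with `pedigree`, `phenotypes`,
#'   and `truth` (the generating scenario).
#' @export
simulate_dataset <- function(scenario, seed) {
  if (is.character(scenario)) scenario <- scenario_presets(scenario)
  ped <- simulate_pedigrees(scenario, seed)
  tab <- simulate_phenotypes(ped, scenario, seed + 500009L)
  structure(list(pedigree = ped, phenotypes = tab, truth = scenario),
            class = "sim_dataset")
}

#' Write a simulated dataset as delimited text + truth sidecar
#'
#' Writes `pedigree.tsv` and `phenotypes.tsv` in the formats the readers
#' consume, and `truth.json` with the generating parameters.
#'
#' @param dataset `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.tsv"))
  write.table(dataset$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phenotype table written by [write_dataset()]
#' @param path tab- or comma-delimited file with a named header.
#' @param na missing-value tokens.
#' @return data frame.
#' @export
read_phenotypes <- function(path, na = c("", "NA")) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, na.strings = na,
             stringsAsFactors = FALSE)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset (%s): %d families, %d phenotyped individuals\n",
              x$truth$name, length(unique(x$phenotypes$fid)),
              nrow(x$phenotypes)))
  invisible(x)
}
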