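## End-to-end orchestration: prepare -> univariate heritability
## (total / male / female) -> sex-limitation tests -> bivariate
## pleiotropy -> report bundle, deterministic given config + seed.

#' Pipeline configuration
#'
#' Exactly one of `preset` or `input` must be supplied.
#'
#' @param preset simulation preset name (see [scenario_presets()]).
#' @param input list with file paths `pedigree` and `phenotypes`.
#' @param traits trait column names to analyze.
#' @param covariate_set `"basic"` (age, age squared, sex) or
#'   `"extended"`.
#' @param mode exclusion mode, `"main"` or `"euthyroid"`.
#' @param stepwise screen the covariates by the forward-backward
#'   procedure (TRUE) or use the full set as-is.
#' @param p_enter,p_remove stepwise thresholds in (0, 1).
#' @param lrt_null null for the A/C-removal LRTs (`"auto"` = boundary
#'   mixture).
#' @param outdir optional directory: the report bundle is written there.
#' @param seed integer seed (drives simulation when `preset` is used).
#' @param n_families optional override of the preset's family count.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(preset = NULL, input = NULL,
                            traits = c("tsh", "ft4"),
                            covariate_set = c("basic", "extended"),
                            mode = c("main", "euthyroid"),
                            stepwise = TRUE,
                            p_enter = 0.10, p_remove = 0.10,
                            lrt_null = "auto",
                            outdir = NULL, seed = 1L, n_families = NULL) {
  if (is.null(preset) == is.null(input)) {
    stop("supply exactly one of `preset` or `input`")
  }
  stopifnot(p_enter > 0, p_enter < 1, p_remove > 0, p_remove < 1)
  structure(list(preset = preset, input = input, traits = traits,
                 covariate_set = match.arg(covariate_set),
                 mode = match.arg(mode), stepwise = stepwise,
                 p_enter = p_enter, p_remove = p_remove,
                 lrt_null = lrt_null, outdir = outdir,
                 seed = as.integer(seed), n_families = n_families),
            class = "run_config")
}

#' Run the full family analysis pipeline
#'
#' Stages: load or simulate the data; apply the exclusion cascade;
#' inverse-normal transform each trait; screen covariates; fit
#' ACE/AE/CE/E models per trait for the total sample and each sex; fit
#' the sex-limitation model with both constraint tests; fit the
#' bivariate model (total and per sex) with zero-constraint tests of
#' rho_g, rho_e, rho_p. Any stage failure aborts with a stage-tagged
#' error.
#'
#' @param config a [pipeline_config()] object.
#' @return a `report_bundle`: `heritability` (per trait x group AE
#'   estimates), `model_comparison` (ACE vs nested LRTs),
#'   `gxs` (sex-limitation tests), `correlations` (bivariate estimates
#'   and p-values), `exclusions`, `covariates` (selected per trait),
#'   `log`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  note <- function(stage, n_in, n_out, msg = "") {
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, message = msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- data ----------------------------------------------------------------
  dat <- stage("data", {
    if (!is.null(config$preset)) {
      sc <- scenario_presets(config$preset, n_families = config$n_families)
      simulate_dataset(sc, config$seed)
    } else {
      list(pedigree = read_pedigree(config$input$pedigree),
           phenotypes = read_phenotypes(config$input$phenotypes))
    }
  })
  ped <- dat$pedigree
  tab <- dat$phenotypes
  note("data", nrow(tab), nrow(tab))

  ## -- prepare -------------------------------------------------------------
  traits <- config$traits[config$traits %in% names(tab)]
  traits <- traits[vapply(traits, function(tr) any(!is.na(tab[[tr]])),
                          logical(1))]
  excl <- stage("prepare", apply_exclusions(tab, mode = config$mode))
  tab2 <- excl$table
  note("exclusions", nrow(tab), nrow(tab2),
       paste(names(excl$tally), excl$tally, sep = "=", collapse = ", "))
  for (tr in traits) {
    tab2[[paste0(tr, "_int")]] <- inverse_normal_transform(tab2[[tr]])
  }

  cand <- covariate_set(config$covariate_set)
  screens <- list()
  covs <- list()
  for (tr in traits) {
    if (config$stepwise) {
      scr <- stage("screen", screen_covariates(
        ped, tab2, paste0(tr, "_int"), cand,
        p_enter = config$p_enter, p_remove = config$p_remove))
      screens[[tr]] <- scr
      covs[[tr]] <- scr$selected
    } else {
      covs[[tr]] <- cand
    }
  }
  note("screen", nrow(tab2), nrow(tab2),
       paste(vapply(traits, function(tr)
         paste0(tr, ":{", paste(covs[[tr]], collapse = ","), "}"),
         character(1)), collapse = " "))

  ## -- univariate ----------------------------------------------------------
  groups <- list(Total = NULL, Male = quote(sex == "male"),
                 Female = quote(sex == "female"))
  herit <- NULL
  mcomp <- NULL
  fits_ae <- list()
  stage("univariate", for (tr in traits) {
    y <- paste0(tr, "_int")
    for (g in names(groups)) {
      sub <- if (is.null(groups[[g]])) NULL else
        eval(groups[[g]], tab2)
      ace <- fit_vc(ped, tab2, y, c("A", "C", "E"), covs[[tr]], subset = sub)
      ae <- fit_vc(ped, tab2, y, c("A", "E"), covs[[tr]], subset = sub)
      ce <- fit_vc(ped, tab2, y, c("C", "E"), covs[[tr]], subset = sub)
      e <- fit_vc(ped, tab2, y, "E", covs[[tr]], subset = sub, se = FALSE)
      p_A <- compare_models(ace, ce, null = config$lrt_null)$p_value
      p_C <- compare_models(ace, ae, null = config$lrt_null)$p_value
      p_h2 <- compare_models(ae, e, null = config$lrt_null)$p_value
      fits_ae[[paste(tr, g, sep = ".")]] <- ae
      herit <- rbind(herit, data.frame(
        trait = tr, group = g, n = ae$n_used, h2 = ae$h2, h2_se = ae$h2_se,
        p_value = p_h2))
      mcomp <- rbind(mcomp, data.frame(
        trait = tr, group = g,
        model = c("ACE", "AE", "CE", "E"),
        loglik = c(ace$loglik, ae$loglik, ce$loglik, e$loglik),
        h2 = c(ace$h2, ae$h2, ce$h2, e$h2),
        p_vs_ACE = c(NA, p_C, p_A,
                     compare_models(ace, e, null = "chi2")$p_value)))
    }
  })
  note("univariate", nrow(tab2), nrow(herit))

  ## -- sex-limitation ------------------------------------------------------
  gxs_tab <- NULL
  gxs_fits <- list()
  stage("gxs", for (tr in traits) {
    y <- paste0(tr, "_int")
    cv <- union(covs[[tr]], "sex")  # absorb sex-specific means
    full <- fit_gxs(ped, tab2, y, cv, constraint = "none")
    rho1 <- fit_gxs(ped, tab2, y, cv, constraint = "rho_eq_1")
    sgeq <- fit_gxs(ped, tab2, y, cv, constraint = "sigma_g_equal")
    t_rho <- test_gxs(full, rho1)
    t_sg <- test_gxs(full, sgeq)
    gxs_fits[[tr]] <- list(full = full, rho_eq_1 = rho1,
                           sigma_g_equal = sgeq)
    gxs_tab <- rbind(gxs_tab, data.frame(
      trait = tr,
      m2ll_full = -2 * full$loglik,
      m2ll_rho1 = -2 * rho1$loglik, chi2_rho1 = t_rho$statistic,
      p_rho1 = t_rho$p_value,
      m2ll_sgeq = -2 * sgeq$loglik, chi2_sgeq = t_sg$statistic,
      p_sgeq = t_sg$p_value,
      h2_M = full$h2_M, h2_F = full$h2_F))
  })
  note("gxs", nrow(tab2), if (is.null(gxs_tab)) 0 else nrow(gxs_tab))

  ## -- bivariate -----------------------------------------------------------
  cors <- NULL
  if (length(traits) == 2) {
    ys <- paste0(traits, "_int")
    cv <- union(covs[[traits[1]]], covs[[traits[2]]])
    stage("bivariate", for (g in names(groups)) {
      sub <- if (is.null(groups[[g]])) NULL else eval(groups[[g]], tab2)
      full <- fit_bivariate(ped, tab2, ys, cv, subset = sub)
      for (w in c("rho_g", "rho_e", "rho_p")) {
        tc <- test_correlation(ped, tab2, ys, cv, subset = sub,
                               which = w, full = full)
        cors <- rbind(cors, data.frame(
          group = g, quantity = w, estimate = tc$estimate,
          statistic = tc$lrt$statistic, p_value = tc$lrt$p_value,
          n = full$n_used))
      }
    })
    note("bivariate", nrow(tab2), nrow(cors))
  }

  bundle <- structure(list(
    heritability = herit, model_comparison = mcomp, gxs = gxs_tab,
    correlations = cors, exclusions = excl$log, covariates = covs,
    screens = screens, fits = list(ae = fits_ae, gxs = gxs_fits),
    log = do.call(rbind, log), config = config),
    class = "report_bundle")
  if (!is.null(config$outdir)) write_report_bundle(bundle, config$outdir)
  bundle
}

#' Write a report bundle as TSV tables + a JSON mirror
#' @param bundle `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("heritability", "model_comparison", "gxs", "correlations",
               "exclusions")) {
    if (!is.null(bundle[[nm]])) {
      write.table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  json <- list(heritability = bundle$heritability,
               model_comparison = bundle$model_comparison,
               gxs = bundle$gxs, correlations = bundle$correlations,
               exclusions = bundle$exclusions,
               covariates = bundle$covariates,
               seed = bundle$config$seed)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report bundle\n-- heritability (AE) --\n")
  print(transform(x$heritability, h2 = round(h2, 2),
                  h2_se = round(h2_se, 2), p_value = signif(p_value, 3)))
  if (!is.null(x$gxs)) {
    cat("-- sex-limitation tests --\n")
    print(transform(x$gxs, chi2_rho1 = round(chi2_rho1, 2),
                    p_rho1 = round(p_rho1, 3),
                    chi2_sgeq = round(chi2_sgeq, 2),
                    p_sgeq = round(p_sgeq, 3)))
  }
  if (!is.null(x$correlations)) {
    cat("-- bivariate correlations --\n")
    print(transform(x$correlations, estimate = round(estimate, 3),
                    p_value = signif(p_value, 3)))
  }
  invisible(x)
}

#' Cohort description by sex
#'
#' Medians (quartiles) for continuous variables with Mann-Whitney
#' (rank-sum) male/female comparison p-values, and counts (%) for
#' categorical variables with chi-square p-values over valid categories.
#'
#' @param tab phenotype data frame.
#' @param continuous,categorical columns to describe (defaults cover the
#'   standard thyroid-survey variables present in `tab`).
#' @return data frame with one row per variable (or category).
#' @export
describe_cohort <- function(tab,
                            continuous = c("age", "bmi", "uicr", "tsh", "ft4"),
                            categorical = c("smoking", "menopause",
                                            "fhx_thyroid")) {
  if (nrow(tab) == 0) stop("empty phenotype table")
  if (!"uicr" %in% names(tab) && all(c("ui", "ucr") %in% names(tab))) {
    tab$uicr <- compute_uicr(tab$ui, tab$ucr)
  }
  male <- tab$sex == "male"
  out <- NULL
  fmt <- function(x) sprintf("%.2f (%.2f, %.2f)",
                             median(x, na.rm = TRUE),
                             quantile(x, 0.25, na.rm = TRUE),
                             quantile(x, 0.75, na.rm = TRUE))
  for (v in intersect(continuous, names(tab))) {
    x <- tab[[v]]
    p <- if (length(unique(na.omit(x))) > 1) {
      suppressWarnings(wilcox.test(x[male], x[!male])$p.value)
    } else 1
    out <- rbind(out, data.frame(
      variable = v, level = "", total = fmt(x), male = fmt(x[male]),
      female = fmt(x[!male]), test = "rank-sum", p_value = p))
  }
  for (v in intersect(categorical, names(tab))) {
    x <- as.character(tab[[v]])
    valid <- !is.na(x) & !(x %in% c("missing", "unknown", "not-indicated"))
    p <- if (length(unique(x[valid])) > 1 && length(unique(male[valid])) > 1) {
      suppressWarnings(chisq.test(table(x[valid], male[valid]))$p.value)
    } else NA_real_
    cnt <- function(lv, sel) {
      k <- sum(x[sel] == lv, na.rm = TRUE)
      sprintf("%d (%.1f%%)", k, 100 * k / max(1, sum(sel)))
    }
    for (lv in sort(unique(na.omit(x)))) {
      out <- rbind(out, data.frame(
        variable = v, level = lv, total = cnt(lv, rep(TRUE, nrow(tab))),
        male = cnt(lv, male), female = cnt(lv, !male),
        test = "chi-square", p_value = p))
      p <- NA_real_  # report the test once per variable
    }
  }
  rownames(out) <- NULL
  out
}
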