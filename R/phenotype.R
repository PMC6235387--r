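## Phenotype/covariate preparation: derived variables, exclusion cascade,
## euthyroid subgroup, rank-based inverse normal transformation, and
## stepwise covariate screening inside the polygenic model.

#' Urinary iodine-to-creatinine ratio
#'
#' UICR (\eqn{\mu}g iodine per g creatinine) = urinary iodine divided by
#' urinary creatinine, times 100. Non-positive or missing creatinine
#' yields a missing value, never zero.
#'
#' @param ui urinary iodine concentration.
#' @param ucr urinary creatinine concentration.
#' @return numeric vector of the same length.
#' @examples compute_uicr(2, 1)  # 200
#' @export
compute_uicr <- function(ui, ucr) {
  out <- ifelse(!is.na(ucr) & ucr > 0 & !is.na(ui), ui / ucr * 100, NA_real_)
  as.numeric(out)
}

#' Rank-based inverse normal transformation
#'
#' Replaces each non-missing value by
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} where \eqn{r} is its rank
#' (average rank for ties), \eqn{n} the number of non-missing values and
#' \eqn{c} the Blom offset 3/8. Missing values stay missing; the
#' transform is monotone in the input.
#'
#' @param x numeric vector (may contain `NA`).
#' @param offset rank offset \eqn{c}; default the Blom constant 3/8.
#' @return transformed vector, same length and missingness as `x`.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) stop("inverse_normal_transform: all values missing")
  if (n == 1) stop("inverse_normal_transform: need >= 2 non-missing values")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Exclusion cascade for the analysis sample
#'
#' Applies the study's exclusion filters in order and tallies removals
#' per rule. In `main` mode the filters are: overt thyroid dysfunction,
#' prior treatment for thyroid disease, pregnancy, TPOAb at or above the
#' positivity cut (34.0 IU/mL), missing TSH/fT4/urinary iodine, and
#' finally restriction to families with at least `min_family` remaining
#' members. `euthyroid` mode additionally removes any prior or family
#' history of thyroid disease, TSH or fT4 outside the reference interval
#' (closed: boundary values are retained), and rows with missing
#' covariates, before the family-size restriction.
#'
#' Flag columns (`overt_dysfunction`, `thyroid_treatment`, `pregnant`,
#' `thyroid_history`, `fhx_thyroid`) are treated as all-negative when
#' absent.
#'
#' @param tab phenotype data frame with columns `fid`, `id`, `tsh`,
#'   `ft4`, `ui` (others optional).
#' @param mode `"main"` or `"euthyroid"`.
#' @param tpoab_cut TPOAb positivity threshold, IU/mL.
#' @param tsh_ref,ft4_ref closed reference intervals for the euthyroid
#'   subgroup (mIU/L; ng/dL).
#' @param min_family minimum family size kept.
#' @param covariate_cols columns whose missingness removes a row in
#'   euthyroid mode.
#' @return list with `table` (filtered rows), `tally` (named integer
#'   vector, application order) and `log` (data frame of rule, n removed,
#'   n remaining).
#' @export
apply_exclusions <- function(tab, mode = c("main", "euthyroid"),
                             tpoab_cut = 34.0,
                             tsh_ref = c(0.62, 6.86),
                             ft4_ref = c(0.89, 1.76),
                             min_family = 2,
                             covariate_cols = c("age", "sex", "bmi")) {
  mode <- match.arg(mode)
  flag <- function(col) {
    if (is.null(tab[[col]])) rep(FALSE, nrow(tab)) else {
      v <- tab[[col]]
      if (is.logical(v)) !is.na(v) & v else !is.na(v) & v %in% c(1, "1", "yes", "TRUE")
    }
  }
  rules <- list(
    overt_dysfunction = flag("overt_dysfunction"),
    thyroid_treatment = flag("thyroid_treatment"),
    pregnant = flag("pregnant"),
    tpoab_positive = !is.na(tab$tpoab) & tab$tpoab >= tpoab_cut,
    missing_assay = is.na(tab$tsh) | is.na(tab$ft4) | is.na(tab$ui)
  )
  if (mode == "euthyroid") {
    rules <- c(rules, list(
      thyroid_history = flag("thyroid_history") | flag("fhx_thyroid"),
      tsh_out_of_range = !is.na(tab$tsh) &
        (tab$tsh < tsh_ref[1] | tab$tsh > tsh_ref[2]),
      ft4_out_of_range = !is.na(tab$ft4) &
        (tab$ft4 < ft4_ref[1] | tab$ft4 > ft4_ref[2]),
      missing_covariate = Reduce(`|`, lapply(
        intersect(covariate_cols, names(tab)),
        function(cl) is.na(tab[[cl]])), rep(FALSE, nrow(tab)))
    ))
  }
  keep <- rep(TRUE, nrow(tab))
  tally <- integer(0)
  for (rn in names(rules)) {
    hit <- keep & rules[[rn]]
    tally[rn] <- sum(hit)
    keep <- keep & !hit
  }
  fam_sizes <- table(tab$fid[keep])
  small <- keep & (as.vector(fam_sizes[tab$fid]) < min_family)
  small[is.na(small)] <- FALSE
  tally["family_below_min"] <- sum(small, na.rm = TRUE)
  keep <- keep & !small
  log <- data.frame(rule = names(tally), removed = as.integer(tally),
                    remaining = nrow(tab) - cumsum(as.integer(tally)))
  list(table = tab[keep, , drop = FALSE], tally = tally, log = log)
}

## ---- covariate design -----------------------------------------------------

#' Build covariate design columns from a phenotype table
#'
#' Supported names: `age`, `age2` (age squared), `sex` (male = 1),
#' `bmi`, `smoking` (indicator of current smoking), `log_uicr`
#' (natural-log urinary iodine/creatinine ratio, computed from `ui` and
#' `ucr` if a `uicr` column is absent), `menopause` (males regarded as
#' not having menopausal status, i.e. coded no).
#'
#' @param tab phenotype data frame.
#' @param names character vector of covariate names.
#' @return numeric matrix with one column per covariate (rows with
#'   missing values yield `NA` and are dropped downstream by
#'   complete-case analysis).
#' @export
build_covariates <- function(tab, names) {
  n <- nrow(tab)
  col <- function(nm) {
    switch(nm,
      age = as.numeric(tab$age),
      age2 = as.numeric(tab$age)^2,
      sex = as.numeric(tab$sex == "male"),
      bmi = as.numeric(tab$bmi),
      smoking = {
        s <- as.character(tab$smoking)
        ifelse(is.na(s) | s %in% c("missing"), NA_real_,
               as.numeric(s == "current"))
      },
      log_uicr = {
        u <- if (!is.null(tab$uicr)) tab$uicr else compute_uicr(tab$ui, tab$ucr)
        ifelse(!is.na(u) & u > 0, log(u), NA_real_)
      },
      menopause = {
        m <- as.character(tab$menopause)
        v <- ifelse(is.na(m) | m %in% c("missing", "unknown"), NA_real_,
                    as.numeric(m == "yes"))
        v[tab$sex == "male"] <- 0  # males regarded as not menopausal
        v
      },
      stop("unknown covariate: ", nm)
    )
  }
  if (length(names) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  X <- vapply(names, col, numeric(n))
  if (n == 1) X <- matrix(X, nrow = 1, dimnames = list(NULL, names))
  colnames(X) <- names
  X
}

#' Candidate covariate sets
#'
#' `basic` = age, age squared, sex; `extended` = age, sex, BMI, current
#' smoking, log UICR, menopausal status.
#'
#' @param set `"basic"` or `"extended"`.
#' @return character vector of covariate names for [build_covariates()].
#' @export
covariate_set <- function(set = c("basic", "extended")) {
  switch(match.arg(set),
         basic = c("age", "age2", "sex"),
         extended = c("age", "sex", "bmi", "smoking", "log_uicr", "menopause"))
}

#' Stepwise (forward-backward) covariate screening in the polygenic model
#'
#' Screens fixed-effect covariates for a trait inside the additive
#' polygenic (AE) model: at each step the candidate with the smallest
#' likelihood-ratio p-value below `p_enter` is added, then any included
#' covariate whose removal p-value exceeds `p_remove` is dropped,
#' iterating to a fixpoint. Complete-case rows over all candidates are
#' used throughout so every compared fit sees the same data.
#'
#' @param ped pedigree object.
#' @param tab phenotype data frame (ids resolvable against `ped`).
#' @param trait trait column name (transformed or raw).
#' @param candidates candidate covariate names (see [build_covariates()]).
#' @param p_enter,p_remove entry/removal thresholds (default 0.10).
#' @return object of class `covariate_model`: `selected` (ordered names),
#'   `coefficients` (fixed effects of the final polygenic fit, including
#'   intercept), `screening_log` (one row per decision).
#' @export
screen_covariates <- function(ped, tab, trait, candidates,
                              p_enter = 0.10, p_remove = 0.10) {
  cand_X <- build_covariates(tab, candidates)
  y <- tab[[trait]]
  ok <- !is.na(y) & (if (ncol(cand_X)) complete.cases(cand_X) else TRUE)
  tab2 <- tab[ok, , drop = FALSE]
  cand_X <- cand_X[ok, , drop = FALSE]

  fit_with <- function(sel) {
    fit_vc(ped, tab2, trait = trait, components = c("A", "E"),
           covariates = sel, n_starts = 1)
  }
  selected <- character(0)
  log <- data.frame(step = integer(0), action = character(0),
                    covariate = character(0), statistic = numeric(0),
                    df = integer(0), p_value = numeric(0))
  step <- 0L
  base_fit <- fit_with(selected)
  repeat {
    changed <- FALSE
    ## forward
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      ps <- sapply(remaining, function(cv) {
        f <- tryCatch(fit_with(c(selected, cv)), error = function(e) NULL)
        if (is.null(f) || !f$converged) {
          warning("screening fit failed for candidate ", cv, "; skipped")
          return(c(NA, NA))
        }
        stat <- max(0, 2 * (f$loglik - base_fit$loglik))
        c(stat, pchisq(stat, df = 1, lower.tail = FALSE))
      })
      if (any(!is.na(ps[2, ]))) {
        best <- which.min(ps[2, ])
        step <- step + 1L
        if (!is.na(ps[2, best]) && ps[2, best] < p_enter) {
          selected <- c(selected, remaining[best])
          base_fit <- fit_with(selected)
          log <- rbind(log, data.frame(step = step, action = "add",
                                       covariate = remaining[best],
                                       statistic = ps[1, best], df = 1L,
                                       p_value = ps[2, best]))
          changed <- TRUE
        } else {
          log <- rbind(log, data.frame(step = step, action = "stop_forward",
                                       covariate = remaining[best],
                                       statistic = ps[1, best], df = 1L,
                                       p_value = ps[2, best]))
        }
      }
    }
    ## backward
    if (length(selected)) {
      ps <- sapply(selected, function(cv) {
        f <- tryCatch(fit_with(setdiff(selected, cv)), error = function(e) NULL)
        if (is.null(f)) return(c(NA, NA))
        stat <- max(0, 2 * (base_fit$loglik - f$loglik))
        c(stat, pchisq(stat, df = 1, lower.tail = FALSE))
      })
      worst <- which.max(ps[2, ])
      if (length(worst) == 1 && !is.na(ps[2, worst]) && ps[2, worst] > p_remove) {
        step <- step + 1L
        log <- rbind(log, data.frame(step = step, action = "remove",
                                     covariate = selected[worst],
                                     statistic = ps[1, worst], df = 1L,
                                     p_value = ps[2, worst]))
        selected <- setdiff(selected, selected[worst])
        base_fit <- fit_with(selected)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(selected = selected,
                 coefficients = base_fit$beta,
                 screening_log = log),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("stepwise covariate screen: selected {",
      paste(x$selected, collapse = ", "), "}\n")
  invisible(x)
}
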