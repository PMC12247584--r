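#' Build behavioral memory scores
#'
#' Narrative recall is the average of immediate and delayed story-detail
#' counts. The composite memory score is the mean of the z-scored narrative
#' and emotional recall scores, defined only for subjects with both;
#' z-scoring uses the sample mean and SD (n-1 denominator) of complete
#' cases.
#'
#' @param subjects data.frame with columns `immediate`, `delayed` and
#'   optionally `mem_emo` (NA where missing).
#' @return the input with columns `mem_narr` and (when emotional scores
#'   exist) `composite` added.
#' @export
build_scores <- function(subjects) {
  need <- c("immediate", "delayed")
  if (!all(need %in% names(subjects))) {
    stop("subjects table needs columns immediate and delayed", call. = FALSE)
  }
  if (any(stats::na.omit(c(subjects$immediate, subjects$delayed)) < 0)) {
    stop("recall counts must be non-negative", call. = FALSE)
  }
  subjects$mem_narr <- (subjects$immediate + subjects$delayed) / 2
  if ("mem_emo" %in% names(subjects) && any(!is.na(subjects$mem_emo))) {
    z_narr <- zscore(subjects$mem_narr, "mem_narr")
    z_emo <- zscore(subjects$mem_emo, "mem_emo")
    subjects$composite <- ifelse(!is.na(z_narr) & !is.na(z_emo),
                                 (z_narr + z_emo) / 2, NA_real_)
  }
  subjects
}

covariate_sets <- list(
  none = character(),
  motion_demographic = c("age", "sex", "fd"),
  full = c("age", "sex", "fd", "cattell", "acer")
)

#' Covariate-adjusted brain-behavior regression
#'
#' OLS of a behavior column on a connectivity summary column plus one of
#' three named covariate sets: `none`, `motion_demographic` (age, sex, mean
#' FD), or `full` (adding fluid intelligence and the cognitive screen).
#' All variables, including the binary sex indicator, are z-scored (sample
#' SD) so the reported coefficient on the summary is a standardized beta;
#' the raw-scale beta is reported alongside. Rows are restricted to cases
#' complete on the model's variables (listwise deletion).
#'
#' @param data data.frame holding `y`, `x` and the covariate columns.
#' @param y,x column names of the behavior and the connectivity summary.
#' @param covariates one of `"none"`, `"motion_demographic"`, `"full"`, or a
#'   character vector of column names.
#' @return data.frame row: `y`, `x`, `covariate_set`, `beta` (standardized),
#'   `raw_beta`, `se`, `t`, `df`, `p`, `n_used`.
#' @export
fit_brain_behavior <- function(data, y, x, covariates = "none") {
  if (length(covariates) == 1 && covariates %in% names(covariate_sets)) {
    set_id <- covariates
    covs <- covariate_sets[[covariates]]
  } else {
    set_id <- paste(covariates, collapse = "+")
    covs <- covariates
  }
  vars <- c(y, x, covs)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  p_pred <- length(covs) + 1
  if (nrow(d) < p_pred + 2) stop("too few complete cases for this model", call. = FALSE)

  zd <- as.data.frame(lapply(stats::setNames(vars, vars), function(v) zscore(d[[v]], v)))
  X <- as.matrix(cbind(1, zd[, c(x, covs), drop = FALSE]))
  colnames(X)[1] <- "(Intercept)"
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear predictor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, zd[[y]])
  dfres <- nrow(d) - p_pred - 1
  rss <- sum(fit$residuals^2)
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(rss / dfres * diag(XtX_inv))
  beta <- fit$coefficients[x]
  tval <- beta / se[which(colnames(X) == x)]
  pval <- 2 * stats::pt(-abs(tval), dfres)
  raw_beta <- beta * stats::sd(d[[y]]) / stats::sd(d[[x]])

  data.frame(y = y, x = x, covariate_set = set_id,
             beta = unname(beta), raw_beta = unname(raw_beta),
             se = unname(se[which(colnames(X) == x)]),
             t = unname(tval), df = dfres, p = unname(pval),
             n_used = nrow(d), stringsAsFactors = FALSE)
}

#' All brain-behavior models for a cohort
#'
#' One row per behavior x summary x covariate set: behaviors `mem_narr` and
#' (when present) `composite`; summaries `within`, `between`, `extra`,
#' `hipp`; covariate sets `none`, `motion_demographic`, `full`.
#'
#' Models that cannot be fit (e.g. too few complete cases for the composite
#' score in a small cohort) are skipped with a warning rather than aborting
#' the whole table.
#'
#' @param subjects behavior/covariate table (see [build_scores()]).
#' @param summaries per-subject network summaries (see [summarize_cohort()]).
#' @return tidy data.frame of [fit_brain_behavior()] rows.
#' @export
run_association_models <- function(subjects, summaries) {
  d <- merge(subjects, summaries, by = "subject_id")
  ys <- intersect(c("mem_narr", "composite"), names(d))
  xs <- intersect(c("within", "between", "extra", "hipp"), names(d))
  rows <- list()
  for (yv in ys) for (xv in xs) for (cs in names(covariate_sets)) {
    row <- tryCatch(fit_brain_behavior(d, yv, xv, cs), error = function(e) {
      warning(sprintf("skipping model %s ~ %s (%s): %s", yv, xv, cs, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no association model could be fit", call. = FALSE)
  do.call(rbind, rows)
}
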