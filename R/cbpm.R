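#' CBPM configuration
#'
#' Parameters of the connectome-based predictive modeling procedure.
#'
#' @param selection_alpha edge-selection p threshold (default 0.01).
#' @param covariates character vector of nuisance columns partialled out
#'   during edge selection (default age, sex, fd; `character()` for plain
#'   Pearson selection).
#' @param n_permutations null simulations for the permutation test (default
#'   100).
#' @param seed integer seed governing the permutations.
#' @param threshold_sweep alphas for the robustness sweep.
#' @param model_form `"combined_pos_neg"` (default: intercept + positive +
#'   negative summed strengths), `"pos_only"`, or `"neg_only"`.
#' @param permute_covariates_with_y permutation-scheme variant: when TRUE the
#'   covariate rows are permuted jointly with behavior instead of staying
#'   attached to the connectomes (default FALSE, matching random re-pairing
#'   of connectomes with behavior).
#' @return a `cbpm_config` list.
#' @export
cbpm_config <- function(selection_alpha = 0.01,
                        covariates = c("age", "sex", "fd"),
                        n_permutations = 100,
                        seed = 1L,
                        threshold_sweep = c(0.001, 0.005, 0.01, 0.05, 0.1),
                        model_form = c("combined_pos_neg", "pos_only", "neg_only"),
                        permute_covariates_with_y = FALSE) {
  model_form <- match.arg(model_form)
  if (!(selection_alpha > 0 && selection_alpha <= 1)) {
    stop("selection_alpha must lie in (0, 1]", call. = FALSE)
  }
  if (n_permutations < 1) stop("n_permutations must be at least 1", call. = FALSE)
  structure(list(selection_alpha = selection_alpha, covariates = covariates,
                 n_permutations = as.integer(n_permutations), seed = as.integer(seed),
                 threshold_sweep = threshold_sweep, model_form = model_form,
                 permute_covariates_with_y = permute_covariates_with_y),
            class = "cbpm_config")
}

# map model_form to the engine code
model_form_code <- function(form) {
  switch(form, combined_pos_neg = 0L, pos_only = 1L, neg_only = 2L)
}

# covariate matrix (possibly 0-column) from a data.frame or matrix
as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.character(covariates) && !length(covariates))) {
    return(matrix(0, n, 0))
  }
  m <- as.matrix(covariates)
  storage.mode(m) <- "double"
  if (nrow(m) != n) stop("covariate rows must match subjects", call. = FALSE)
  if (anyNA(m)) stop("missing values among covariates; apply listwise deletion first",
                     call. = FALSE)
  m
}

#' Per-subject edge matrix from a cohort of connectomes
#'
#' Stacks the lower-triangle edge vectors of per-subject generalized
#' connectomes (Pearson scale) into the subjects x edges matrix the CBPM
#' functions operate on.
#'
#' @param connectomes named list of [connectome()] objects.
#' @return numeric matrix, one row per subject, columns in
#'   [edge_index_map()] order; the map is attached as attribute
#'   `"edge_map"`.
#' @export
cohort_edge_matrix <- function(connectomes) {
  rows <- lapply(connectomes, function(cn) vectorize_connectome(cn)$values)
  X <- do.call(rbind, rows)
  rownames(X) <- names(connectomes)
  attr(X, "edge_map") <- edge_index_map(length(connectomes[[1]]$roi_ids))
  X
}

#' Nuisance-adjusted edge selection
#'
#' For each edge, the partial correlation with behavior given the covariates
#' (plain Pearson when there are none), with a two-sided p-value from the
#' exact t transform at df = n - 2 - c. Edges with `p < alpha` are split by
#' sign into disjoint positive and negative masks. Constant edges are
#' unselectable and reported in the `unselectable` attribute.
#'
#' @param X subjects x edges matrix.
#' @param y behavior vector.
#' @param covariates data.frame/matrix of nuisance columns, or NULL.
#' @param alpha selection threshold (default 0.01).
#' @return list with logical `pos_mask`, `neg_mask`, plus `r`, `p`, `df`.
#' @export
select_edges <- function(X, y, covariates = NULL, alpha = 0.01) {
  X <- as.matrix(X)
  n <- nrow(X)
  Zc <- as_covariate_matrix(covariates, n)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]", call. = FALSE)
  df <- n - 2 - ncol(Zc)
  if (df < 1) stop("too few subjects for the selection degrees of freedom", call. = FALSE)
  r <- as.numeric(cpp_partial_cor(X, as.numeric(y), Zc))
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  sel <- !is.na(p) & p < alpha
  out <- list(pos_mask = sel & r > 0, neg_mask = sel & r < 0,
              r = r, p = p, df = df)
  out$unselectable <- which(is.na(r))
  out
}

#' Summed positive/negative connection strengths
#'
#' @param X subjects x edges matrix (or a single subject's edge vector).
#' @param pos_mask,neg_mask logical edge masks from [select_edges()] on
#'   training data.
#' @return data.frame with columns `pos_sum`, `neg_sum` (0 for empty masks).
#' @export
summed_strengths <- function(X, pos_mask, neg_mask) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  data.frame(pos_sum = as.numeric(X %*% as.numeric(pos_mask)),
             neg_sum = as.numeric(X %*% as.numeric(neg_mask)))
}

#' Leave-one-out cross-validated CBPM
#'
#' For each held-out subject, edges are re-selected and the summed-strength
#' model re-fit on the remaining subjects only; the held-out subject's
#' behavior is predicted from that model. Folds selecting no usable edges
#' predict the training mean (logged in `fold_fallback`). Performance is the
#' Pearson correlation between predicted and observed behavior.
#'
#' @param X subjects x edges matrix.
#' @param y behavior vector.
#' @param covariates nuisance columns for selection (NULL for none).
#' @param config a [cbpm_config()].
#' @param keep_masks keep per-fold masks (needed for consensus; turned off
#'   inside permutation runs).
#' @return a `cbpm_result`: `predicted`, `observed`, `r_obs_pred` (NA with
#'   `status = "degenerate"` when the predictions have zero variance),
#'   per-fold `pos_masks`/`neg_masks` (edges x folds), consensus masks
#'   (selected in every fold), fold coefficients, fallback log.
#' @export
cbpm_loocv <- function(X, y, covariates = NULL, config = cbpm_config(),
                       keep_masks = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("CBPM requires at least 10 subjects", call. = FALSE)
  if (length(y) != n) stop("length of y must match rows of X", call. = FALSE)
  Zc <- as_covariate_matrix(covariates, n)
  eng <- cpp_cbpm_loocv(X, as.numeric(y), Zc, config$selection_alpha,
                        model_form_code(config$model_form), keep_masks)
  predicted <- as.numeric(eng$predicted)
  status <- "ok"
  r_obs_pred <- NA_real_
  if (stats::sd(predicted) == 0) {
    status <- "degenerate"        # r undefined, stays NA
  } else {
    r_obs_pred <- stats::cor(predicted, y)
    if (all(as.logical(eng$fallback))) status <- "degenerate"
  }
  res <- list(predicted = predicted, observed = as.numeric(y),
              r_obs_pred = r_obs_pred, status = status,
              fold_fallback = as.logical(eng$fallback),
              coefficients = eng$coefficients,
              config = config)
  if (keep_masks) {
    pos <- eng$pos_masks == 1
    neg <- eng$neg_masks == 1
    res$pos_masks <- pos
    res$neg_masks <- neg
    res$consensus_pos <- rowSums(pos) == n
    res$consensus_neg <- rowSums(neg) == n
  }
  class(res) <- "cbpm_result"
  res
}

#' @export
print.cbpm_result <- function(x, ...) {
  cat(sprintf("<cbpm_result> n = %d, r(observed, predicted) = %s, status = %s\n",
              length(x$observed),
              ifelse(is.na(x$r_obs_pred), "NA", sprintf("%.3f", x$r_obs_pred)),
              x$status))
  if (!is.null(x$consensus_pos)) {
    cat(sprintf("  consensus edges: %d positive, %d negative; fallback folds: %d\n",
                sum(x$consensus_pos), sum(x$consensus_neg), sum(x$fold_fallback)))
  }
  invisible(x)
}

#' Permutation test for CBPM performance
#'
#' Reruns the full leave-one-out procedure `n_permutations` times with the
#' behavior vector randomly re-paired with the connectomes (covariates stay
#' attached to the connectome side unless
#' `config$permute_covariates_with_y`). The permutation p-value is the plain
#' proportion of null runs whose prediction performance is at least as good
#' as observed (ties count as better, so p = 0 is attainable); the
#' conservative add-one estimator is reported alongside. Null runs with
#' degenerate (zero-variance) predictions count as not better and are
#' tallied.
#'
#' @inheritParams cbpm_loocv
#' @return list with `observed` (the [cbpm_loocv()] result), `null_r`,
#'   `p_perm`, `p_perm_add_one`, `n_null_degenerate`.
#' @export
cbpm_permutation_test <- function(X, y, covariates = NULL, config = cbpm_config()) {
  observed <- cbpm_loocv(X, y, covariates, config, keep_masks = TRUE)
  m <- config$n_permutations
  null_r <- rep(NA_real_, m)
  set.seed(derive_seed(config$seed, "cbpm_permutation"))
  n <- length(y)
  for (b in seq_len(m)) {
    ord <- sample.int(n)
    cov_b <- covariates
    if (config$permute_covariates_with_y && !is.null(covariates)) {
      cov_b <- as_covariate_matrix(covariates, n)[ord, , drop = FALSE]
    }
    nullfit <- cbpm_loocv(X, y[ord], cov_b, config, keep_masks = FALSE)
    null_r[b] <- nullfit$r_obs_pred
  }
  better <- !is.na(null_r) & !is.na(observed$r_obs_pred) & null_r >= observed$r_obs_pred
  list(observed = observed,
       null_r = null_r,
       p_perm = mean(better),
       p_perm_add_one = (sum(better) + 1) / (m + 1),
       n_null_degenerate = sum(is.na(null_r)))
}

#' Selection-threshold sweep
#'
#' Reruns LOOCV and the permutation test at each alpha in
#' `config$threshold_sweep`.
#'
#' @inheritParams cbpm_loocv
#' @return data.frame with one row per alpha: `alpha`, `r_obs_pred`,
#'   `p_perm`, `p_perm_add_one`, `n_consensus_pos`, `n_consensus_neg`.
#' @export
cbpm_threshold_sweep <- function(X, y, covariates = NULL, config = cbpm_config()) {
  rows <- lapply(config$threshold_sweep, function(a) {
    cfg <- config
    cfg$selection_alpha <- a
    pt <- cbpm_permutation_test(X, y, covariates, cfg)
    data.frame(alpha = a,
               r_obs_pred = pt$observed$r_obs_pred,
               p_perm = pt$p_perm,
               p_perm_add_one = pt$p_perm_add_one,
               n_consensus_pos = sum(pt$observed$consensus_pos),
               n_consensus_neg = sum(pt$observed$consensus_neg))
  })
  do.call(rbind, rows)
}

#' Computational lesion analysis
#'
#' For each atlas network, removes every edge incident to any of its ROIs
#' and reruns the full CBPM (LOOCV + permutation test) on the reduced edge
#' matrix. Networks whose ROIs carry the `DMN-C` or `Hipp` role are flagged
#' as memory networks.
#'
#' @inheritParams cbpm_loocv
#' @param atlas `atlas_labels` table matching the connectome the edge matrix
#'   came from.
#' @return data.frame with one row per network: `network`,
#'   `memory_network`, `n_rois`, `n_edges_removed`, `r_obs_pred`, `p_perm`,
#'   `p_perm_add_one`.
#' @export
cbpm_lesion_analysis <- function(X, y, covariates = NULL, atlas,
                                 config = cbpm_config()) {
  X <- as.matrix(X)
  map <- attr(X, "edge_map") %||% edge_index_map(nrow(atlas))
  if (nrow(map) != ncol(X)) {
    stop("edge matrix does not match the atlas ROI count", call. = FALSE)
  }
  networks <- unique(atlas$network)
  rows <- lapply(networks, function(net) {
    rois <- which(atlas$network == net)
    keep <- !(map$i %in% rois | map$j %in% rois)
    if (!any(keep)) {
      stop("lesioning network '", net, "' removes every edge", call. = FALSE)
    }
    pt <- cbpm_permutation_test(X[, keep, drop = FALSE], y, covariates, config)
    data.frame(network = net,
               memory_network = any(atlas$role[rois] %in% c("DMN-C", "Hipp")),
               n_rois = length(rois),
               n_edges_removed = sum(!keep),
               r_obs_pred = pt$observed$r_obs_pred,
               p_perm = pt$p_perm,
               p_perm_add_one = pt$p_perm_add_one,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
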