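#' Fisher z-transform of a correlation
#'
#' `atanh` with clipping just inside (-1, 1) so that correlations at the
#' boundary (e.g. a diagonal that leaked into an edge vector) do not map to
#' infinity.
#'
#' @param r correlations in \[-1, 1\].
#' @param clip magnitude at which correlations are clipped before `atanh`.
#' @return values on the Fisher-z scale.
#' @export
fisher_z <- function(r, clip = 1 - 1e-12) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Inverse Fisher z-transform
#'
#' @param z values on the Fisher-z scale.
#' @return correlations in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

# z-score with the sample (n-1) SD over non-missing entries; errors on zero
# variance because a standardized score is then undefined.
zscore <- function(x, what = "variable") {
  mu <- mean(x, na.rm = TRUE)
  sdev <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sdev) || sdev == 0) {
    stop("cannot standardize '", what, "': zero or undefined variance", call. = FALSE)
  }
  (x - mu) / sdev
}

# Derive a per-stage 32-bit seed from a master seed; keeps all randomness
# flowing from one integer while decoupling the streams of the stages.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
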