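## Element-wise significance of connectivity against null tractography:
## a one-tailed Poisson sum test and a paired one-tailed t-test, plus
## sensitivity/specificity of the resulting significance masks against the
## retinotopic connectivity pattern.  No multiple-testing correction is
## applied; masks are simply p < alpha.

#' Per-hemisphere mean null-count matrices
#'
#' Averages the count matrices of the null-tractography repeats of one
#' hemisphere into the per-hemisphere null mean matrix (kept as
#' non-integer means).
#'
#' @param repeat_counts List of count matrices, one per null repeat.
#' @return Numeric 18x18 matrix of means.
#' @export
null_mean_matrix <- function(repeat_counts) {
  group_average(repeat_counts)
}

#' One-tailed Poisson sum test against null tractography
#'
#' Under the null, the observed count of element (i, j) in hemisphere h is
#' Poisson with the mean of that hemisphere's null-tractography counts.
#' Since a sum of independent Poisson variables is Poisson with the summed
#' mean, the test sums counts and null means over hemispheres and computes
#' the one-tailed p-value `P(X >= S)` for `X ~ Poisson(M)` (inclusive of
#' the observed value).  When `M = 0`, p is 1 if `S = 0` and 0 otherwise.
#'
#' @param counts List of per-hemisphere observed count matrices.
#' @param nulls List of per-hemisphere null mean matrices (same length and
#'   order).
#' @return Matrix of p-values in \[0, 1\].
#' @export
poisson_test <- function(counts, nulls) {
  stopifnot(length(counts) == length(nulls), length(counts) >= 1)
  S <- Reduce(`+`, lapply(counts, unclass))
  M <- Reduce(`+`, lapply(nulls, unclass))
  if (any(S < 0) || any(M < 0)) stop("negative counts")
  p <- stats::ppois(S - 1, M, lower.tail = FALSE)
  dimnames(p) <- dimnames(S)
  p
}

#' Paired one-tailed t-test against null tractography
#'
#' For each matrix element, tests whether the mean over hemispheres of the
#' paired differences d_h = observed_h - null_mean_h exceeds zero
#' (alternative: mean > 0).  Degenerate cases are defined explicitly:
#' all-zero differences give p = 1; zero variance with positive mean gives
#' p = 0 (the limit of the t statistic), zero variance with negative mean
#' p = 1.
#'
#' @param counts List (length >= 2) of per-hemisphere observed count
#'   matrices.
#' @param nulls Matching list of per-hemisphere null mean matrices.
#' @return Matrix of p-values.
#' @export
paired_t_test <- function(counts, nulls) {
  stopifnot(length(counts) == length(nulls))
  n <- length(counts)
  if (n < 2) stop("paired t-test needs at least 2 hemispheres")
  d <- lapply(seq_len(n), function(h) unclass(counts[[h]]) - unclass(nulls[[h]]))
  mean_d <- Reduce(`+`, d) / n
  ss <- Reduce(`+`, lapply(d, function(x) (x - mean_d)^2))
  sd_d <- sqrt(ss / (n - 1))
  p <- matrix(NA_real_, nrow(mean_d), ncol(mean_d), dimnames = dimnames(mean_d))
  zero_var <- sd_d == 0
  p[zero_var & mean_d > 0] <- 0
  p[zero_var & mean_d <= 0] <- 1
  ok <- !zero_var
  tstat <- mean_d[ok] / (sd_d[ok] / sqrt(n))
  p[ok] <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  p
}

#' Significance mask at level alpha
#'
#' @param p Matrix of p-values.
#' @param alpha Significance level (default 0.05); an element is
#'   significant iff `p < alpha` (no multiple-testing correction).
#' @return Logical matrix.
#' @export
significance_mask <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  p < alpha
}

#' Sensitivity and specificity of a significance mask
#'
#' Against the retinotopic connectivity pattern: in a 6x6 inter-area block
#' the six diagonal elements are the expected (retinotopic) connections
#' and the thirty off-diagonal elements the non-retinotopic ones.
#' Sensitivity is the fraction of retinotopic elements detected as
#' significant; specificity the fraction of non-retinotopic elements that
#' are not significant.
#'
#' @param mask Logical 18x18 significance matrix.
#' @param scope An area pair such as `c("V1", "V2")` for one 6x6 block, or
#'   `"inter"` for all three inter-area blocks pooled.
#' @return List with `sensitivity`, `specificity`, and the underlying
#'   counts `n_retinotopic`, `n_nonretinotopic`.
#' @export
sensitivity_specificity <- function(mask, scope = "inter") {
  stopifnot(is.logical(mask), all(dim(mask) == 18))
  pairs <- if (identical(scope, "inter"))
    list(c("V1", "V2"), c("V2", "V3"), c("V1", "V3"))
  else list(scope)
  ret <- logical(0); nonret <- logical(0)
  for (p in pairs) {
    b <- subarea_block(mask, p[1], p[2])
    ret <- c(ret, diag(b))
    nonret <- c(nonret, b[row(b) != col(b)])
  }
  if (!length(ret)) stop("empty scope")
  list(sensitivity = mean(ret), specificity = mean(!nonret),
       n_retinotopic = length(ret), n_nonretinotopic = length(nonret))
}
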