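#' Watson's U2 test of circular uniformity (one sample)
#'
#' Classical one-sample Watson statistic. With \eqn{u_{(i)} =
#' \theta_{(i)}/2\pi} the sorted rescaled angles,
#' \deqn{U^2 = \sum_i \left(u_{(i)} - \frac{2i - 1}{2n}\right)^2
#'   - n\left(\bar u - \tfrac12\right)^2 + \frac{1}{12n}.}
#' Rotation-invariant in distribution; its minimum \eqn{1/(12n)} is attained
#' exactly on the regular grid \eqn{\theta_i = (i - 1/2) \cdot 2\pi/n}.
#'
#' @param theta numeric vector of angles (or [phase_series()]), n >= 2.
#' @return the U2 statistic (a single nonnegative number).
#' @examples
#' watson_u2(rvonmises(200, pi, 2, seed = 1)) # concentrated: large U2
#' @export
watson_u2 <- function(theta) {
  theta <- phase_values(theta)
  n <- length(theta)
  if (n < 2L) stop("watson_u2() needs n >= 2")
  u <- sort(wrap(theta)) / TWO_PI
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

# pooled-ECDF evaluation at distinct pooled order statistics; ties are a
# single evaluation point with both ECDFs stepped
pooled_ecdf_diff <- function(sorted_values, sorted_labels, n1, n2) {
  keep <- c(diff(sorted_values) != 0, TRUE)
  F1 <- cumsum(sorted_labels)[keep] / n1
  F2 <- cumsum(!sorted_labels)[keep] / n2
  list(F1 = F1, F2 = F2)
}

watson_u2_from_labels <- function(sorted_values, sorted_labels, n1, n2,
                                  variant) {
  fs <- pooled_ecdf_diff(sorted_values, sorted_labels, n1, n2)
  d <- fs$F1 - fs$F2
  n <- n1 + n2
  switch(variant,
    classical = n1 * n2 / n^2 * sum((d - mean(d))^2),
    scaled = n1 * n2 / n * sum((d - mean(d))^2),
    `scaled-literal` = {
      D <- n1 / n * fs$F1 + n2 / n * fs$F2
      n1 * n2 / n * sum((d - D)^2)
    },
    stop("unknown variant: ", variant))
}

#' Watson's two-sample U2 statistic
#'
#' Compares two circular samples through their pooled empirical distribution
#' functions. Three variants are exposed:
#' \describe{
#'   \item{`"classical"`}{\eqn{U^2 = \frac{n_1 n_2}{n^2} \sum_k (d_k -
#'     \bar d)^2} over the pooled order statistics, with \eqn{d_k =
#'     F_1(\theta_k) - F_2(\theta_k)}. Invariant to a common rotation of
#'     both samples and symmetric in its arguments.}
#'   \item{`"scaled"`}{the same mean-centered sum with the \eqn{n_1 n_2/n}
#'     prefactor, i.e. `classical` scaled by \eqn{n}.}
#'   \item{`"scaled-literal"`}{the centering term evaluated per observation
#'     as \eqn{D_k = \frac{n_1}{n}F_1(\theta_k) + \frac{n_2}{n}
#'     F_2(\theta_k)}; retained for auditability only, not recommended for
#'     inference.}
#' }
#' Ties across or within samples are treated as a single evaluation point at
#' which both ECDFs step.
#'
#' @param s1,s2 numeric angle vectors (or [phase_series()]), each n >= 2.
#' @param variant `"classical"` (default), `"scaled"` or `"scaled-literal"`.
#' @return an object of class `"watson_two_sample"`: list with `u2`, `n1`,
#'   `n2` and `variant`.
#' @examples
#' a <- rvonmises(50, pi / 4, 5, seed = 1)
#' b <- rvonmises(50, 3 * pi / 4, 5, seed = 2)
#' watson_u2_two_sample(a, b)
#' @export
watson_u2_two_sample <- function(s1, s2,
                                 variant = c("classical", "scaled",
                                             "scaled-literal")) {
  variant <- match.arg(variant)
  s1 <- phase_values(s1); s2 <- phase_values(s2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2L || n2 < 2L) stop("watson_u2_two_sample() needs n1, n2 >= 2")
  pooled <- c(wrap(s1), wrap(s2))
  lab <- rep(c(TRUE, FALSE), c(n1, n2))
  ord <- order(pooled)
  u2 <- watson_u2_from_labels(pooled[ord], lab[ord], n1, n2, variant)
  structure(list(u2 = u2, n1 = n1, n2 = n2, variant = variant),
            class = "watson_two_sample")
}

#' @export
print.watson_two_sample <- function(x, ...) {
  cat(sprintf("Watson two-sample U2 (%s): %.6g  (n1 = %d, n2 = %d)\n",
              x$variant, x$u2, x$n1, x$n2))
  invisible(x)
}

#' Permutation test for Watson's two-sample U2
#'
#' Builds the null distribution of the two-sample statistic by shuffling the
#' group labels of the pooled sample; the p-value uses the add-one
#' convention \eqn{p = (1 + \#\{U^2_{perm} \ge U^2_{obs}\}) / (n_{perm} +
#' 1)}, so it can never be exactly zero.
#'
#' @inheritParams watson_u2_two_sample
#' @param n_perm number of label permutations, >= 99 (smaller counts give
#'   unstable p-values).
#' @param seed optional integer seed.
#' @return an object of class `"perm_test"`: list with `observed`, `n_perm`,
#'   `p_value`, `seed`, `variant` and the permuted statistics `perm_stats`.
#' @examples
#' a <- rvonmises(100, pi / 4, 5, seed = 1)
#' b <- rvonmises(100, 3 * pi / 4, 5, seed = 2)
#' watson_permutation_test(a, b, n_perm = 199, seed = 3)$p_value
#' @export
watson_permutation_test <- function(s1, s2, n_perm = 999, seed = NULL,
                                    variant = c("classical", "scaled",
                                                "scaled-literal")) {
  variant <- match.arg(variant)
  if (n_perm < 99) stop("n_perm must be >= 99")
  s1 <- phase_values(s1); s2 <- phase_values(s2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2L || n2 < 2L) stop("watson_permutation_test() needs n1, n2 >= 2")
  if (!is.null(seed)) set.seed(seed)
  n_perm <- as.integer(n_perm)

  pooled <- c(wrap(s1), wrap(s2))
  lab <- rep(c(TRUE, FALSE), c(n1, n2))
  ord <- order(pooled)
  sv <- pooled[ord]
  observed <- watson_u2_from_labels(sv, lab[ord], n1, n2, variant)
  # the sorted pooled values are permutation-invariant: only labels shuffle
  perm_stats <- vapply(seq_len(n_perm), function(b) {
    watson_u2_from_labels(sv, sample(lab), n1, n2, variant)
  }, numeric(1L))
  p <- (1 + sum(perm_stats >= observed)) / (n_perm + 1)
  structure(list(observed = observed, n_perm = n_perm, p_value = p,
                 seed = seed, variant = variant, perm_stats = perm_stats,
                 n1 = n1, n2 = n2),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (Watson U2, %s)\n", x$variant))
  cat(sprintf("  observed U2 = %.6g, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}
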