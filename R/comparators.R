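# Classical multiplicity adjustments: the frequentist contrast class.
# Holm and Benjamini-Hochberg adjusted p-values are delegated to
# stats::p.adjust; Bonferroni is computed directly so that the family size
# m can exceed the number of supplied p-values (adjusting a published table
# "post hoc" for tests reported elsewhere, e.g. m = 8 + 16 = 24).

.check_p <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p
}

#' Bonferroni correction
#'
#' Adjusted p-values min(1, m p_j); rejection at level alpha exactly when
#' the adjusted p-value is at most alpha.  The family size m may exceed the
#' number of supplied p-values, penalizing the supplied tests for
#' unreported members of the family.
#'
#' @param p p-values in (0, 1].
#' @param alpha significance level; default 0.05.
#' @param m total family size; default \code{length(p)}.
#' @return a data.frame with columns \code{p}, \code{p_adjusted},
#'   \code{reject}.
#' @examples
#' bonferroni(0.04, m = 24)  # adjusted 0.96: no longer significant
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  p <- .check_p(p)
  if (m < length(p))
    stop(sprintf("family size m = %d is smaller than the %d supplied p-values",
                 m, length(p)))
  adj <- pmin(1, m * p)
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Holm step-down adjustment
#'
#' Uniformly more powerful than Bonferroni at the same FWER; its rejections
#' always contain Bonferroni's.
#'
#' @inheritParams bonferroni
#' @return a data.frame with columns \code{p}, \code{p_adjusted},
#'   \code{reject}.
#' @export
holm <- function(p, alpha = 0.05) {
  p <- .check_p(p)
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false discovery rate at level q for independent (or
#' positively dependent) p-values.
#'
#' @param p p-values in (0, 1].
#' @param q target FDR level; default 0.05.
#' @return a data.frame with columns \code{p}, \code{p_adjusted},
#'   \code{reject}.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  p <- .check_p(p)
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, reject = adj <= q)
}
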