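#' Cumulative-logit cell probabilities
#'
#' The proportional-odds model puts \eqn{P(\mathrm{level} \le c) =
#' \mathrm{logit}^{-1}(\kappa_c - \eta)} for ordered cutpoints \eqn{\kappa}
#' and a single linear predictor \eqn{\eta}; cell probabilities are the
#' successive differences, with \eqn{\kappa_0 = -\infty} and
#' \eqn{\kappa_{C} = +\infty}. This one function is shared by the synthetic
#' data generator, the fitted-model predictions and the poststratification
#' step, so the data-generating process and the likelihood agree by
#' construction.
#'
#' @param cutpoints strictly increasing numeric vector of length C-1.
#' @param eta numeric vector of linear predictors.
#' @return if \code{eta} has length 1, a probability vector of length C;
#'   otherwise a \code{length(eta) x C} matrix. Rows sum to 1.
#' @examples
#' cell_probabilities(stats::qlogis(c(.25, .5, .75)), 0)  # c(.25,.25,.25,.25)
#' @export
cell_probabilities <- function(cutpoints, eta) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1L || anyNA(cutpoints))
    stop("cutpoints must be a non-empty numeric vector")
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be strictly increasing")
  q <- stats::plogis(outer(-as.numeric(eta), cutpoints, `+`))
  p <- cbind(q, 1) - cbind(0, q)
  colnames(p) <- NULL
  if (length(eta) == 1L) drop(p) else p
}

#' Highest posterior density interval from draws
#'
#' The shortest contiguous interval over the sorted draws containing at least
#' \code{mass} of them (the Chen-Shao estimator). With \code{n} draws the
#' window spans \code{ceiling(mass * n)} points; ties in width are broken to
#' the lowest start index so the result is deterministic.
#'
#' @param samples numeric vector of at least 2 finite draws.
#' @param mass interval mass, default 0.95.
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
hpd <- function(samples, mass = 0.95) {
  x <- samples[is.finite(samples)]
  n <- length(x)
  if (n < 2L) stop("hpd needs at least 2 finite samples")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)  # which.min takes the first minimum: lowest start
  c(lower = x[i], upper = x[i + m])
}

.hpd_fmt <- function(x, digits = 3) {
  iv <- hpd(x)
  sprintf("%s [%s, %s]", signif(mean(x), digits),
          signif(iv[1], digits), signif(iv[2], digits))
}
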