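#' @export
print.ordmrp <- function(x, ...) {
  cat("Bayesian cumulative-logit multilevel model (ordmrp)\n")
  cat("  outcome:", x$outcome, "with", x$n_levels, "levels\n")
  cat("  records:", x$n_records, "aggregated to", x$n_patterns,
      "covariate patterns\n")
  cat("  fixed factors:", paste(x$factors, collapse = ", "), "\n")
  if (!is.null(x$covariate))
    cat("  numeric covariate:", x$covariate,
        sprintf("(posterior mean gamma = %.3f)", mean(x$draws$gamma_z)), "\n")
  if (!is.null(x$random))
    cat("  random deviations by:", x$random, "\n")
  cat("  draws:", x$draws$n_draws, sprintf("(%d chain(s) x %d, warmup %d)\n",
      x$mcmc$chains, x$mcmc$draws, x$mcmc$warmup))
  mx <- max(x$diagnostics$rhat, na.rm = TRUE)
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n", mx,
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary of a fitted ordinal MRP model
#'
#' Cutpoints on the latent scale and, for each fixed effect and the intent
#' slope, the posterior-mean odds ratio with its 95% highest posterior
#' density interval; a log-OR interval excluding zero is flagged.
#'
#' @param object an \code{\link{ordmrp}} fit.
#' @param ... unused.
#' @export
summary.ordmrp <- function(object, ...) {
  dr <- object$draws
  eff <- cbind(dr$beta,
               if (!is.null(dr$gamma_z)) `gamma_z` = dr$gamma_z)
  tab <- NULL
  if (!is.null(eff) && ncol(eff)) {
    tab <- do.call(rbind, lapply(colnames(eff), function(p) {
      o <- summarize_odds_ratio(object, p)
      data.frame(parameter = p, log_or = mean(eff[, p]), or = o$or,
                 hpd_low = o$hpd_low, hpd_high = o$hpd_high,
                 significant = o$hpd_low > 1 | o$hpd_high < 1)
    }))
  }
  kap <- apply(dr$kappa, 2, function(k) c(mean = mean(k), hpd(k)))
  out <- list(cutpoints = t(kap), effects = tab,
              diagnostics = object$diagnostics,
              sd_u = if (!is.null(dr$sd_u)) colMeans(dr$sd_u))
  class(out) <- "summary.ordmrp"
  out
}

#' @export
print.summary.ordmrp <- function(x, ...) {
  cat("Cutpoints (posterior mean [95% HPD]):\n")
  print(round(x$cutpoints, 3))
  if (!is.null(x$effects)) {
    cat("\nOdds ratios (posterior mean of exp(beta) [95% HPD]):\n")
    ef <- x$effects
    ef[-1] <- lapply(ef[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
    print(ef, row.names = FALSE)
  }
  if (!is.null(x$sd_u)) {
    cat("\nRegion random-effect SDs (posterior mean):\n")
    print(round(x$sd_u, 3))
  }
  cat(sprintf("\nmax split-Rhat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.ordmrp <- function(object, ...) {
  dr <- object$draws
  c(colMeans(dr$kappa),
    if (!is.null(dr$beta)) colMeans(dr$beta),
    if (!is.null(dr$gamma_z)) c(gamma_z = mean(dr$gamma_z)))
}

#' Posterior odds-ratio summary for one parameter
#'
#' @param fit an \code{\link{ordmrp}} fit.
#' @param parameter fixed-effect name (\code{"factor:level"}) or
#'   \code{"gamma_z"}.
#' @return list with \code{or} (posterior mean of the exponentiated draws),
#'   \code{hpd_low}, \code{hpd_high} (95% HPD of the exponentiated draws)
#'   and \code{log_or}.
#' @export
summarize_odds_ratio <- function(fit, parameter) {
  stopifnot(inherits(fit, "ordmrp"))
  dr <- fit$draws
  x <- if (identical(parameter, "gamma_z")) {
    if (is.null(dr$gamma_z)) stop("model has no gamma_z")
    dr$gamma_z
  } else if (!is.null(dr$beta) && parameter %in% colnames(dr$beta)) {
    dr$beta[, parameter]
  } else stop("unknown parameter: ", parameter)
  ex <- exp(x)
  if (stats::sd(ex) == 0) {
    iv <- c(lower = ex[1], upper = ex[1])
  } else iv <- hpd(ex)
  list(or = mean(ex), hpd_low = unname(iv[1]), hpd_high = unname(iv[2]),
       log_or = mean(x))
}

# per-draw cell probabilities from kappa draws (D x (C-1)) and eta draws (D)
.probs_from_draws <- function(kappa, eta) {
  q <- stats::plogis(kappa - eta)  # recycles eta down columns
  cbind(q, 1) - cbind(0, q)
}

#' Per-draw outcome probabilities for one stratum
#'
#' For each posterior draw, assembles the linear predictor of the given
#' stratum (and intent value, for Z-conditioned models) from that draw's
#' parameters and returns the cumulative-logit cell probabilities. No
#' averaging across draws.
#'
#' @param fit an \code{\link{ordmrp}} fit.
#' @param stratum one-row data.frame (or named list) with the model's factor
#'   columns.
#' @param z numeric intent value; required iff the model has the intent
#'   slope.
#' @return draws x C matrix of probabilities.
#' @export
cellwise_predict <- function(fit, stratum, z = NULL) {
  stopifnot(inherits(fit, "ordmrp"))
  if (!is.null(fit$covariate) && is.null(z))
    stop("model is conditioned on '", fit$covariate, "': supply z")
  if (is.null(fit$covariate) && !is.null(z))
    stop("model has no numeric covariate; z must be NULL")
  stratum <- as.data.frame(stratum, stringsAsFactors = FALSE)
  stopifnot(nrow(stratum) == 1L)
  eta <- .draw_etas(fit, stratum)[1, ]
  if (!is.null(z)) eta <- eta + fit$draws$gamma_z * as.numeric(z)
  .probs_from_draws(fit$draws$kappa, eta)
}

# linear predictors for every row of `data` under every draw: S x D matrix
# (excludes the gamma_z term)
.draw_etas <- function(fit, data) {
  dr <- fit$draws
  X <- .design_matrix(data[, fit$factors, drop = FALSE], fit$schemes)
  D <- dr$n_draws
  Eta <- if (ncol(X)) X %*% t(dr$beta[, colnames(X), drop = FALSE])
         else matrix(0, nrow(data), D)
  if (!is.null(fit$random) && !is.null(dr$u)) {
    ridx <- match(as.character(data[[fit$random]]),
                  fit$schemes[[fit$random]]$levels)
    Xr <- X[, fit$random_cols, drop = FALSE]
    for (j in seq_along(fit$random_cols)) {
      xj <- Xr[, j]
      nz <- which(xj != 0)
      if (length(nz))
        Eta[nz, ] <- Eta[nz, , drop = FALSE] +
          xj[nz] * t(dr$u[, ridx[nz], j, drop = FALSE][, , 1, drop = TRUE])
    }
  }
  Eta
}

#' Predict outcome probabilities for new strata
#'
#' @param object an \code{\link{ordmrp}} fit.
#' @param newdata data.frame with the model's factor columns (and the numeric
#'   covariate column for Z-conditioned models).
#' @param type \code{"mean"} for posterior-mean probabilities (rows x C
#'   matrix) or \code{"draws"} for a draws x C x rows array.
#' @param ... unused.
#' @export
predict.ordmrp <- function(object, newdata, type = c("mean", "draws"), ...) {
  type <- match.arg(type)
  Eta <- .draw_etas(object, newdata)
  if (!is.null(object$covariate)) {
    if (!object$covariate %in% names(newdata))
      stop("newdata lacks covariate column '", object$covariate, "'")
    Eta <- Eta + outer(as.numeric(newdata[[object$covariate]]),
                       object$draws$gamma_z)
  }
  C <- object$n_levels
  D <- object$draws$n_draws
  if (type == "draws") {
    out <- array(NA_real_, c(D, C, nrow(newdata)))
    for (i in seq_len(nrow(newdata)))
      out[, , i] <- .probs_from_draws(object$draws$kappa, Eta[i, ])
    return(out)
  }
  out <- matrix(NA_real_, nrow(newdata), C)
  for (i in seq_len(nrow(newdata)))
    out[i, ] <- colMeans(.probs_from_draws(object$draws$kappa, Eta[i, ]))
  out
}

#' Simulate ordinal outcomes from the posterior predictive
#'
#' Draws one outcome per row of \code{newdata} per simulation, using a
#' randomly chosen posterior draw for each simulation.
#'
#' @param object an \code{\link{ordmrp}} fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed integer seed.
#' @param newdata data.frame of strata rows (with covariate column if
#'   needed).
#' @param ... unused.
#' @return integer matrix, rows of \code{newdata} x \code{nsim}.
#' @export
simulate.ordmrp <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata, type = "draws")
  D <- dim(pr)[1]
  out <- matrix(NA_integer_, nrow(newdata), nsim)
  for (s in seq_len(nsim)) {
    d <- sample.int(D, 1)
    out[, s] <- .sample_ordinal(t(pr[d, , , drop = TRUE]))
  }
  out
}

#' Caterpillar plot of fixed-effect odds ratios
#'
#' @param x an \code{\link{ordmrp}} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.ordmrp <- function(x, ...) {
  sm <- summary(x)
  ef <- sm$effects
  if (is.null(ef)) {
    graphics::matplot(x$draws$kappa, type = "l", lty = 1,
                      ylab = "cutpoint draw", xlab = "iteration", ...)
    return(invisible(x))
  }
  n <- nrow(ef)
  graphics::plot(ef$or, seq_len(n), xlim = range(ef$hpd_low, ef$hpd_high, 1),
                 pch = 19, yaxt = "n", xlab = "odds ratio (95% HPD)",
                 ylab = "", log = "x",
                 panel.first = graphics::abline(v = 1, lty = 2, col = "grey"),
                 ...)
  graphics::segments(ef$hpd_low, seq_len(n), ef$hpd_high, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = ef$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}
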