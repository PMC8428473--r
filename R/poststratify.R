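#' Poststratify a fitted model over census strata
#'
#' For each posterior draw d, averages the stratum-level predictive
#' distributions with the census weights:
#' \deqn{P_d(\mathrm{level}) = \sum_s P_d(\mathrm{level} \mid s)\, P(S=s).}
#' Only unconditional models qualify; a model carrying the intent slope must
#' go through \code{\link{joint_distribution}} instead.
#'
#' @param fit an \code{\link{ordmrp}} fit without a numeric covariate.
#' @param strata strata table from \code{\link{enumerate_strata}} /
#'   \code{\link{read_census}}; its factor columns must cover the model's
#'   factors with identical levels.
#' @param chunk number of draws processed per block (memory control).
#' @return object of class \code{"ordmrp_poststrat"}: \code{per_draw}
#'   (draws x C probability matrix, rows sum to 1) plus a mean/HPD summary.
#' @export
poststratify <- function(fit, strata, chunk = 500) {
  stopifnot(inherits(fit, "ordmrp"))
  if (!is.null(fit$covariate))
    stop("model is conditioned on '", fit$covariate,
         "'; use joint_distribution()")
  .check_strata(fit, strata)
  C <- fit$n_levels
  D <- fit$draws$n_draws
  w <- strata$weight
  per <- matrix(NA_real_, D, C)
  Eta <- .draw_etas(fit, strata)
  for (ix in .chunks(D, chunk)) {
    kap <- fit$draws$kappa[ix, , drop = FALSE]
    E <- Eta[, ix, drop = FALSE]
    per[ix, ] <- .weighted_cells(kap, E, w)
  }
  colnames(per) <- paste0("level", seq_len(C))
  structure(list(per_draw = per, summary = .cells_summary(per),
                 outcome = fit$outcome, n_strata = nrow(strata)),
            class = "ordmrp_poststrat")
}

# weighted cell probabilities: kappa (d x C-1), Eta (S x d), weights (S)
# returns d x C
.weighted_cells <- function(kap, Eta, w) {
  d <- nrow(kap); S <- nrow(Eta); C <- ncol(kap) + 1L
  out <- matrix(NA_real_, d, C)
  qprev <- matrix(0, S, d)
  for (c in seq_len(C - 1)) {
    q <- stats::plogis(matrix(kap[, c], S, d, byrow = TRUE) - Eta)
    out[, c] <- drop(crossprod(w, q - qprev))
    qprev <- q
  }
  out[, C] <- drop(crossprod(w, 1 - qprev))
  out
}

.cells_summary <- function(per) {
  t(apply(per, 2, function(x) c(mean = mean(x), .hpd_or_point(x))))
}

# hpd() demands >= 2 draws; single-draw summaries degenerate to the point
.hpd_or_point <- function(x) {
  if (length(x) < 2L) return(c(lower = x[1], upper = x[1]))
  hpd(x)
}

.chunks <- function(n, size) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

.check_strata <- function(fit, strata) {
  fac <- .strata_factors(strata)
  miss <- setdiff(fit$factors, fac)
  if (length(miss))
    stop("strata table lacks factor column(s): ", paste(miss, collapse = ", "))
  for (f in fit$factors) {
    have <- if (is.factor(strata[[f]])) levels(strata[[f]])
            else unique(as.character(strata[[f]]))
    extra <- setdiff(unique(as.character(strata[[f]])), fit$schemes[[f]]$levels)
    if (length(extra))
      stop("strata factor '", f, "' has level(s) unknown to the model: ",
           paste(extra, collapse = ", "))
  }
  if (abs(sum(strata$weight) - 1) > 1e-9)
    stop("stratum weights do not sum to 1")
  invisible(TRUE)
}

#' @export
print.ordmrp_poststrat <- function(x, ...) {
  cat("Poststratified distribution of", x$outcome, "over", x$n_strata,
      "strata\n")
  print(round(100 * x$summary, 2))
  invisible(x)
}

#' Joint posterior-predictive distribution of change and baseline intent
#'
#' Composes the intent-conditioned change model and the baseline-intent model
#' into the population joint distribution, draw by draw:
#' \deqn{P_d(Y'=j, Z'=k) = \sum_s P_d(Y'=j \mid Z'=k, S=s)\,
#'   P_d(Z'=k \mid S=s)\, P(S=s),}
#' the chain-rule composition in which the change model is evaluated at each
#' intent level k. Draws of the two fits are paired by index. Entries are
#' percentages; every per-draw 5 x 4 matrix sums to 100.
#'
#' @param fit_y \code{\link{ordmrp}} fit of change in inclination given
#'   intent (must carry the intent slope).
#' @param fit_z \code{\link{ordmrp}} fit of baseline intent (no slope).
#' @param strata strata table; factor columns must cover both models.
#' @param variant label, \code{"domestic"} or \code{"international"}.
#' @param chunk draws per processing block.
#' @return object of class \code{"ordmrp_joint"}: \code{per_draw}
#'   (draws x C_y x C_z percentage array), mean and 95% HPD summaries.
#' @export
joint_distribution <- function(fit_y, fit_z, strata,
                               variant = c("domestic", "international"),
                               chunk = 200) {
  variant <- match.arg(variant)
  stopifnot(inherits(fit_y, "ordmrp"), inherits(fit_z, "ordmrp"))
  if (is.null(fit_y$covariate))
    stop("fit_y must be conditioned on baseline intent (numeric covariate)")
  if (!is.null(fit_z$covariate))
    stop("fit_z must be an unconditional intent model")
  D <- fit_y$draws$n_draws
  if (fit_z$draws$n_draws != D)
    stop("draw counts differ (", D, " vs ", fit_z$draws$n_draws,
         "); draws are paired by index")
  .check_strata(fit_y, strata)
  .check_strata(fit_z, strata)
  Cy <- fit_y$n_levels
  Cz <- fit_z$n_levels
  w <- strata$weight
  Eta_y <- .draw_etas(fit_y, strata)
  Eta_z <- .draw_etas(fit_z, strata)
  per <- array(NA_real_, c(D, Cy, Cz))
  for (ix in .chunks(D, chunk)) {
    kap_y <- fit_y$draws$kappa[ix, , drop = FALSE]
    kap_z <- fit_z$draws$kappa[ix, , drop = FALSE]
    gz <- fit_y$draws$gamma_z[ix]
    d <- length(ix); S <- nrow(strata)
    Ey0 <- Eta_y[, ix, drop = FALSE]
    Ez <- Eta_z[, ix, drop = FALSE]
    # P_d(Z=k|s) for all k: successive differences of the z-model logits
    qprev_z <- matrix(0, S, d)
    for (k in seq_len(Cz)) {
      Pz_k <- if (k < Cz) {
        qk <- stats::plogis(matrix(kap_z[, k], S, d, byrow = TRUE) - Ez)
        on <- qk - qprev_z; qprev_z <- qk; on
      } else 1 - qprev_z
      Ey <- Ey0 + matrix(gz * k, S, d, byrow = TRUE)
      qprev_y <- matrix(0, S, d)
      for (j in seq_len(Cy)) {
        Py_jk <- if (j < Cy) {
          qj <- stats::plogis(matrix(kap_y[, j], S, d, byrow = TRUE) - Ey)
          on <- qj - qprev_y; qprev_y <- qj; on
        } else 1 - qprev_y
        per[ix, j, k] <- 100 * drop(crossprod(w, Py_jk * Pz_k))
      }
    }
  }
  dimnames(per) <- list(NULL, paste0("y", seq_len(Cy)),
                        paste0("z", seq_len(Cz)))
  structure(list(per_draw = per,
                 summary = .joint_summary(per),
                 variant = variant, n_strata = nrow(strata)),
            class = "ordmrp_joint")
}

.joint_summary <- function(per) {
  dm <- dim(per)
  mean_ <- apply(per, c(2, 3), mean)
  lo <- apply(per, c(2, 3), function(x) .hpd_or_point(x)[1])
  hi <- apply(per, c(2, 3), function(x) .hpd_or_point(x)[2])
  list(mean = mean_, hpd_low = lo, hpd_high = hi)
}

#' @export
print.ordmrp_joint <- function(x, ...) {
  cat("Joint population distribution P(Y', Z') [%],", x$variant,
      "variant,", dim(x$per_draw)[1], "draws over", x$n_strata, "strata\n")
  cat("posterior means (rows: change in inclination; cols: baseline intent):\n")
  print(round(x$summary$mean, 2))
  invisible(x)
}

#' Row and column marginals of a joint distribution
#'
#' Row totals give the population distribution of change in inclination;
#' column totals give the baseline-intent distribution. Each per-draw set
#' sums to 100.
#'
#' @param joint an \code{\link{joint_distribution}} result, or a single
#'   C_y x C_z matrix of percentages.
#' @return list with per-draw matrices \code{rows} (draws x C_y) and
#'   \code{cols} (draws x C_z) and their mean/HPD summaries (for a single
#'   matrix: the totals themselves).
#' @export
marginals <- function(joint) {
  if (is.matrix(joint))
    return(list(rows = rowSums(joint), cols = colSums(joint)))
  stopifnot(inherits(joint, "ordmrp_joint"))
  rows <- apply(joint$per_draw, c(1, 2), sum)
  cols <- apply(joint$per_draw, c(1, 3), sum)
  list(rows = rows, cols = cols,
       rows_summary = .cells_summary(rows),
       cols_summary = .cells_summary(cols))
}
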