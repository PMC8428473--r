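#' Net shift in vaccination inclination for one baseline-intent group
#'
#' For intent group k, the decision-relevant net shift is the upward
#' inclination mass (levels above neutral, j > 3) minus the downward mass
#' (j < 3) in column k of the joint percentage matrix, with the upward term
#' suppressed for the "definitely accept" group (k = 4, who cannot be moved
#' higher in a way that changes their decision) and the downward term
#' suppressed for "definitely not" (k = 1):
#' \deqn{U_k = (1-\delta_{k4}) \sum_{j>3} P(Y'=j, Z'=k)
#'      - (1-\delta_{k1}) \sum_{j<3} P(Y'=j, Z'=k)}
#' (entries already scaled to percent). Hence U_1 >= 0 and U_4 <= 0 always.
#'
#' @param joint_cells C_y x C_z matrix of population percentages (rows:
#'   change in inclination, 5 levels with 3 neutral; cols: baseline intent).
#' @param k intent level, 1-4.
#' @return the net shift (percentage points).
#' @export
compute_uk <- function(joint_cells, k) {
  stopifnot(is.matrix(joint_cells))
  Cy <- nrow(joint_cells)
  Cz <- ncol(joint_cells)
  if (length(k) != 1L || is.na(k) || k < 1 || k > Cz || k != as.integer(k))
    stop("k must be a single intent level in 1..", Cz)
  mid <- (Cy + 1) / 2
  up <- sum(joint_cells[seq_len(Cy) > mid, k])
  down <- sum(joint_cells[seq_len(Cy) < mid, k])
  (k != Cz) * up - (k != 1) * down
}

#' Overall net shift S = sum of the per-group net shifts
#'
#' @inheritParams compute_uk
#' @return S in percentage points.
#' @export
compute_s <- function(joint_cells) {
  sum(vapply(seq_len(ncol(joint_cells)),
             function(k) compute_uk(joint_cells, k), numeric(1)))
}

#' Per-draw impact summary of a joint distribution
#'
#' Applies the net-shift statistics to every posterior draw of the joint
#' distribution and summarises each U_k and S by the posterior mean and 95%
#' HPD interval.
#'
#' @param joint an \code{\link{joint_distribution}} result.
#' @return object of class \code{"ordmrp_impact"}: \code{u} (draws x C_z),
#'   \code{s} (draws), \code{summary} data.frame, \code{variant}.
#' @export
impact_summary <- function(joint) {
  stopifnot(inherits(joint, "ordmrp_joint"))
  per <- joint$per_draw
  D <- dim(per)[1]; Cy <- dim(per)[2]; Cz <- dim(per)[3]
  mid <- (Cy + 1) / 2
  up <- apply(per[, seq_len(Cy) > mid, , drop = FALSE], c(1, 3), sum)
  down <- apply(per[, seq_len(Cy) < mid, , drop = FALSE], c(1, 3), sum)
  u <- matrix(NA_real_, D, Cz)
  for (k in seq_len(Cz))
    u[, k] <- (k != Cz) * up[, k] - (k != 1) * down[, k]
  colnames(u) <- paste0("U", seq_len(Cz))
  s <- rowSums(u)
  sm <- rbind(.impact_rows(u), .impact_rows(matrix(s, ncol = 1,
                                                   dimnames = list(NULL, "S"))))
  structure(list(u = u, s = s, summary = sm, variant = joint$variant),
            class = "ordmrp_impact")
}

.impact_rows <- function(m) {
  do.call(rbind, lapply(colnames(m), function(p) {
    iv <- .hpd_or_point(m[, p])
    data.frame(statistic = p, mean = mean(m[, p]),
               hpd_low = unname(iv[1]), hpd_high = unname(iv[2]))
  }))
}

#' @export
print.ordmrp_impact <- function(x, ...) {
  cat("Net-shift impact statistics,", x$variant, "variant:\n")
  sm <- x$summary
  sm[-1] <- lapply(sm[-1], round, 3)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' Domestic-minus-international impact contrast
#'
#' Per-draw differences S_DOM - S_INT (and per-group U_k differences) between
#' two index-paired impact summaries, with mean and 95% HPD.
#'
#' @param dom,intl \code{\link{impact_summary}} objects with equal draw
#'   counts.
#' @return object of class \code{"ordmrp_impact"} (variant
#'   \code{"difference"}).
#' @export
compute_delta_s <- function(dom, intl) {
  stopifnot(inherits(dom, "ordmrp_impact"), inherits(intl, "ordmrp_impact"))
  if (length(dom$s) != length(intl$s))
    stop("draw counts differ (", length(dom$s), " vs ", length(intl$s),
         "); draws are paired by index")
  u <- dom$u - intl$u
  s <- dom$s - intl$s
  sm <- rbind(.impact_rows(u),
              .impact_rows(matrix(s, ncol = 1, dimnames = list(NULL, "S"))))
  structure(list(u = u, s = s, summary = sm, variant = "difference"),
            class = "ordmrp_impact")
}

#' Poststratified agreement share for an attitude item
#'
#' Share of the population in the top-two agreement categories ("agree" +
#' "strongly agree") of a 5-level item, poststratified over the census
#' strata, per draw, with mean and 95% HPD.
#'
#' @param fit an \code{\link{ordmrp}} fit of the attitude item (5 levels, no
#'   intent slope).
#' @param strata strata table.
#' @param top number of top categories counted as agreement.
#' @return list with \code{per_draw} (percent agreeing per draw), \code{mean}
#'   and \code{hpd_low}/\code{hpd_high}.
#' @export
agreement_share <- function(fit, strata, top = 2) {
  ps <- poststratify(fit, strata)
  C <- ncol(ps$per_draw)
  agree <- 100 * rowSums(ps$per_draw[, (C - top + 1):C, drop = FALSE])
  iv <- hpd(agree)
  list(per_draw = agree, mean = mean(agree),
       hpd_low = unname(iv[1]), hpd_high = unname(iv[2]))
}
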