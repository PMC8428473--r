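#' Ground-truth parameters for the synthetic data-generating process
#'
#' Draws a complete set of true parameters for the ordered-logit process that
#' generates synthetic respondents: cutpoints for the 4-level baseline-intent
#' outcome Z and the 5-level change-in-inclination outcome Y, fixed-effect
#' coefficients for every non-baseline level of every factor, the slope
#' gamma_z of numeric baseline intent in the Y model, and region-level random
#' deviations of the non-region coefficients.
#'
#' Defaults emulate the study conditions of the UK passport survey: the Z
#' cutpoints put the no-covariate intent distribution near (4.5, 5.1, 11.7,
#' 78.7)%; \code{gamma_z = log(3.11)} matches the reported intent odds ratio;
#' the Y cutpoints place the change-in-inclination distribution of the
#' "definitely accept" group near its published shape; fixed effects of
#' magnitude ~0.2 on the log-odds scale mirror the reported socio-demographic
#' odds ratios (0.8-1.25), with smaller sub-national deviations.
#'
#' @param schemes named list of \code{\link{category_scheme}} objects
#'   (region first).
#' @param seed integer seed for the coefficient draws.
#' @param gamma_z slope of numeric Z (1-4) in the Y model.
#' @param effect_sd SD of the fixed-effect coefficient draws (log-odds).
#' @param region_effect_sd SD of region-level deviations.
#' @param cutpoints_z,cutpoints_y strictly increasing cutpoints for the
#'   4-level and 5-level outcomes.
#' @param random name of the random-effect grouping factor.
#' @return object of class \code{"ordmrp_params"}.
#' @export
true_params <- function(schemes, seed = 1, gamma_z = log(3.11),
                        effect_sd = 0.2, region_effect_sd = 0.15,
                        cutpoints_z = c(-3.05, -2.25, -1.31),
                        cutpoints_y = c(1.17, 1.79, 4.57, 5.26),
                        random = "region") {
  stopifnot(!is.unsorted(cutpoints_z, strictly = TRUE),
            !is.unsorted(cutpoints_y, strictly = TRUE),
            region_effect_sd >= 0)
  nm <- vapply(schemes, `[[`, "", "name")
  names(schemes) <- nm
  terms <- .fixed_terms(schemes)
  cols <- unlist(terms, use.names = FALSE)
  rcols <- .random_cols(schemes, random)
  regions <- if (random %in% nm) schemes[[random]]$levels else character(0)
  .with_seed(seed, {
    beta_z <- stats::setNames(stats::rnorm(length(cols), 0, effect_sd), cols)
    beta_y <- stats::setNames(stats::rnorm(length(cols), 0, effect_sd), cols)
    u_z <- u_y <- NULL
    if (length(rcols) && length(regions)) {
      u_z <- matrix(stats::rnorm(length(regions) * length(rcols), 0,
                                 region_effect_sd),
                    length(regions), length(rcols),
                    dimnames = list(regions, rcols))
      u_y <- matrix(stats::rnorm(length(regions) * length(rcols), 0,
                                 region_effect_sd),
                    length(regions), length(rcols),
                    dimnames = list(regions, rcols))
    }
    structure(list(schemes = schemes, random = random,
                   cutpoints_z = cutpoints_z, cutpoints_y = cutpoints_y,
                   beta_z = beta_z, beta_y = beta_y, gamma_z = gamma_z,
                   region_effect_sd = region_effect_sd,
                   region_effects_z = u_z, region_effects_y = u_y,
                   seed = seed),
              class = "ordmrp_params")
  })
}

#' @export
print.ordmrp_params <- function(x, ...) {
  cat("<ordmrp_params> ground truth over",
      paste(names(x$schemes), collapse = " x "), "\n")
  cat("  gamma_z =", signif(x$gamma_z, 4),
      "| region effect sd =", x$region_effect_sd, "\n")
  invisible(x)
}

# linear predictors for every row of a strata-like data.frame
.eta_rows <- function(data, schemes, beta, u, random) {
  X <- .design_matrix(data, schemes)
  eta <- if (ncol(X) && !is.null(beta))
    drop(X %*% beta[colnames(X)]) else numeric(nrow(data))
  if (!is.null(u)) {
    ridx <- match(as.character(data[[random]]), rownames(u))
    Xr <- X[, colnames(u), drop = FALSE]
    eta <- eta + rowSums(Xr * u[ridx, , drop = FALSE])
  }
  eta
}

# sample one ordinal outcome per row of a probability matrix
.sample_ordinal <- function(P) {
  n <- nrow(P)
  cum <- P
  for (j in seq_len(ncol(P))[-1]) cum[, j] <- cum[, j - 1] + P[, j]
  u <- stats::runif(n)
  1L + as.integer(rowSums(cum[, -ncol(P), drop = FALSE] < u))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic census strata table
#'
#' Draws stratum population counts from a symmetric Dirichlet-multinomial
#' over the full stratum enumeration: stratum probabilities from a symmetric
#' Dirichlet with the given concentration, then counts from a multinomial of
#' size \code{total}. Large concentrations approach a uniform census; small
#' ones give the heavy-tailed stratum sizes typical of a real cross.
#'
#' @param schemes named list of \code{\link{category_scheme}} objects.
#' @param total total census population.
#' @param concentration Dirichlet concentration (> 0).
#' @param seed integer seed.
#' @return strata table as from \code{\link{enumerate_strata}}.
#' @export
generate_census <- function(schemes, total = 100000, concentration = 1,
                            seed = 1) {
  stopifnot(concentration > 0, total >= 1)
  strata <- enumerate_strata(schemes)
  n <- nrow(strata)
  .with_seed(seed, {
    g <- stats::rgamma(n, shape = concentration, rate = 1)
    if (all(g == 0)) g <- rep(1, n)
    counts <- as.vector(stats::rmultinom(1, size = total, prob = g / sum(g)))
  })
  enumerate_strata(schemes, counts = counts)
}

#' Generate synthetic survey respondents from known ground truth
#'
#' Samples each respondent's stratum proportionally to the census weights,
#' then draws baseline intent Z from the cumulative-logit law with linear
#' predictor \eqn{\eta_z(s)}, the two change-in-inclination outcomes from
#' \eqn{\eta_y(s) + \gamma_Z z}, dose status independently, and (optionally)
#' seven attitude items from an ordered logit sharing \eqn{\eta_z(s)}, with a
#' small "prefer not to say" refusal probability. The generator and the
#' fitted model share \code{\link{cell_probabilities}}, so the ground truth
#' lives exactly on the model family.
#'
#' @param params \code{\link{true_params}} object.
#' @param strata strata table (weights used for sampling).
#' @param n number of respondents.
#' @param seed integer seed.
#' @param dose_probs named probabilities over
#'   \code{not_offered, offered_not_taken, one_dose, two_doses}; the default
#'   reproduces the study's observed two-dose share (1,984 of 16,527).
#' @param attitudes generate the seven attitude items?
#' @param pnts_prob per-item refusal ("prefer not to say") probability.
#' @return data.frame of respondent records (already recoded).
#' @export
generate_respondents <- function(params, strata, n, seed = 1,
                                 dose_probs = c(not_offered = 0.530,
                                                offered_not_taken = 0.050,
                                                one_dose = 0.300,
                                                two_doses = 0.120),
                                 attitudes = TRUE, pnts_prob = 0.03) {
  stopifnot(inherits(params, "ordmrp_params"), n >= 1)
  stopifnot(abs(sum(dose_probs) - 1) < 1e-8)
  schemes <- params$schemes
  fac <- .strata_factors(strata)
  stopifnot(identical(sort(fac), sort(names(schemes))))
  eta_z_s <- .eta_rows(strata, schemes, params$beta_z,
                       params$region_effects_z, params$random)
  eta_y_s <- .eta_rows(strata, schemes, params$beta_y,
                       params$region_effects_y, params$random)
  .with_seed(seed, {
    s_idx <- sample.int(nrow(strata), n, replace = TRUE,
                        prob = strata$weight)
    rec <- strata[s_idx, fac, drop = FALSE]
    rownames(rec) <- NULL
    rec <- cbind(data.frame(respondent_id = seq_len(n)), rec)
    rec$dose_status <- factor(
      sample(names(dose_probs), n, replace = TRUE, prob = dose_probs),
      levels = .dose_levels)
    ez <- eta_z_s[s_idx]
    rec$z <- .sample_ordinal(cell_probabilities(params$cutpoints_z, ez))
    ey <- eta_y_s[s_idx] + params$gamma_z * rec$z
    rec$y_dom <- .sample_ordinal(cell_probabilities(params$cutpoints_y, ey))
    rec$y_int <- .sample_ordinal(cell_probabilities(params$cutpoints_y, ey))
    if (attitudes) {
      Pa <- cell_probabilities(params$cutpoints_y, ez)
      for (i in 1:7) {
        v <- .sample_ordinal(Pa)
        v[stats::runif(n) < pnts_prob] <- NA_integer_
        rec[[paste0("att_", i)]] <- v
      }
    }
    rec
  })
}

#' Simulate a complete synthetic study to disk
#'
#' Writes a survey CSV, a census CSV and a JSON sidecar holding the ground
#' truth, all derived from one seed, in the formats read back by
#' \code{\link{load_survey}} and \code{\link{read_census}}.
#'
#' @param dir output directory (created if needed).
#' @param schemes named list of \code{\link{category_scheme}} objects.
#' @param n number of respondents.
#' @param seed integer master seed (census, truth and respondents use fixed
#'   offsets of it).
#' @param census_total,census_concentration forwarded to
#'   \code{\link{generate_census}}.
#' @param ... forwarded to \code{\link{true_params}}.
#' @return invisibly, a list with the file paths, the truth, the records and
#'   the strata.
#' @export
simulate_study <- function(dir, schemes = toy_schemes(), n = 5000, seed = 1,
                           census_total = 100000,
                           census_concentration = 5, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  strata <- generate_census(schemes, total = census_total,
                            concentration = census_concentration,
                            seed = seed + 1L)
  params <- true_params(schemes, seed = seed + 2L, ...)
  rec <- generate_respondents(params, strata, n = n, seed = seed + 3L)
  hdr <- sprintf("ordmrp simulate_study seed=%d n=%d", seed, n)
  survey_path <- file.path(dir, "survey.csv")
  census_path <- file.path(dir, "census.csv")
  params_path <- file.path(dir, "true_params.json")
  write_survey(rec, survey_path, header = hdr)
  write_census(strata, census_path, header = hdr)
  tp <- params
  tp$schemes <- lapply(params$schemes, unclass)
  jsonlite::write_json(unclass(tp), params_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(survey = survey_path, census = census_path,
                 params_file = params_path, params = params,
                 records = rec, strata = strata))
}
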