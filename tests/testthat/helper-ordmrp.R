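# shared fixtures and independent oracles for the test suite

quiet_exclude <- function(records) exclude_fully_vaccinated(records, quiet = TRUE)

# draw one ordinal outcome per linear-predictor value
.sample_y <- function(kappa, eta) {
  P <- cell_probabilities(kappa, eta)
  if (is.null(dim(P))) P <- matrix(P, 1)
  apply(P, 1, function(p) sample.int(length(p), 1, prob = p))
}

# tiny scheme sets built in code
scheme_2x3 <- function() {
  list(a = category_scheme("a", c("a1", "a2")),
       b = category_scheme("b", c("b1", "b2", "b3")))
}

# a fabricated ordmrp-shaped object with random draws, for oracle tests of
# the prediction / poststratification / joint composition path (no MCMC)
mock_fit <- function(schemes, n_levels, n_draws, with_z = FALSE,
                     random = if ("region" %in% names(schemes)) "region") {
  fcols <- unlist(lapply(schemes, function(s)
    paste0(s$name, ":", setdiff(s$levels, s$baseline))), use.names = FALSE)
  rcols <- if (!is.null(random))
    fcols[!startsWith(fcols, paste0(random, ":"))] else character(0)
  kappa <- t(apply(matrix(rnorm(n_draws * (n_levels - 1), 0, 1.5),
                          n_draws), 1, sort))
  beta <- matrix(rnorm(n_draws * length(fcols), 0, 0.5), n_draws,
                 dimnames = list(NULL, fcols))
  draws <- list(kappa = kappa, n_draws = n_draws)
  if (length(fcols)) draws$beta <- beta
  if (with_z) draws$gamma_z <- rnorm(n_draws, 0.8, 0.1)
  if (length(rcols)) {
    reg <- schemes[[random]]$levels
    draws$u <- array(rnorm(n_draws * length(reg) * length(rcols), 0, 0.2),
                     c(n_draws, length(reg), length(rcols)),
                     dimnames = list(NULL, reg, rcols))
    draws$sd_u <- matrix(0.2, n_draws, 1)
  }
  structure(list(outcome = "y", n_levels = n_levels, schemes = schemes,
                 factors = names(schemes),
                 covariate = if (with_z) "z", random = random,
                 random_cols = rcols, draws = draws,
                 n_records = 0L, n_patterns = 0L,
                 mcmc = list(chains = 1, warmup = 0, draws = n_draws,
                             thin = 1, seed = 0)),
            class = "ordmrp")
}

# oracle: linear predictor of one stratum under one draw, by explicit sums
oracle_eta <- function(fit, stratum, d) {
  dr <- fit$draws
  eta <- 0
  for (f in fit$factors) {
    lev <- as.character(stratum[[f]])
    cn <- paste0(f, ":", lev)
    if (!is.null(dr$beta) && cn %in% colnames(dr$beta))
      eta <- eta + dr$beta[d, cn]
  }
  if (!is.null(fit$random) && !is.null(dr$u)) {
    r <- as.character(stratum[[fit$random]])
    for (cn in fit$random_cols) {
      f <- sub(":.*$", "", cn)
      if (paste0(f, ":", as.character(stratum[[f]])) == cn)
        eta <- eta + dr$u[d, r, cn]
    }
  }
  eta
}

# oracle: joint distribution by a bare triple loop (draws x strata x cells)
oracle_joint <- function(fit_y, fit_z, strata) {
  D <- fit_y$draws$n_draws
  Cy <- fit_y$n_levels; Cz <- fit_z$n_levels
  out <- array(0, c(D, Cy, Cz))
  for (d in seq_len(D)) {
    for (s in seq_len(nrow(strata))) {
      st <- strata[s, , drop = FALSE]
      pz <- cell_probabilities(fit_z$draws$kappa[d, ],
                               oracle_eta(fit_z, st, d))
      for (k in seq_len(Cz)) {
        ey <- oracle_eta(fit_y, st, d) + fit_y$draws$gamma_z[d] * k
        py <- cell_probabilities(fit_y$draws$kappa[d, ], ey)
        for (j in seq_len(Cy))
          out[d, j, k] <- out[d, j, k] +
            100 * py[j] * pz[k] * strata$weight[s]
      }
    }
  }
  out
}

# oracle: poststratified univariate distribution by explicit loop
oracle_poststrat <- function(fit, strata) {
  D <- fit$draws$n_draws
  out <- matrix(0, D, fit$n_levels)
  for (d in seq_len(D))
    for (s in seq_len(nrow(strata)))
      out[d, ] <- out[d, ] + strata$weight[s] *
        cell_probabilities(fit$draws$kappa[d, ],
                           oracle_eta(fit, strata[s, , drop = FALSE], d))
  out
}

# oracle: net shift with explicit if-branches
oracle_uk <- function(m, k) {
  up <- 0; down <- 0
  for (j in seq_len(nrow(m))) {
    if (j > 3) up <- up + m[j, k]
    if (j < 3) down <- down + m[j, k]
  }
  val <- 0
  if (k != 4) val <- val + up
  if (k != 1) val <- val - down
  val
}

# oracle: exhaustive search over all contiguous sorted windows spanning
# ceiling(mass * n) gaps
oracle_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[1 + m])
  for (i in seq_len(n - m))
    if (x[i + m] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m])
  best
}
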