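# model-fitting checks against independent oracles (no MCMC inside oracles)

test_that("intercept-only cutpoints match empirical cumulative logits", {
  set.seed(5)
  n <- 2000
  ktrue <- c(-1.2, 0.1, 1.0)
  y <- .sample_y(ktrue, rep(0, n))
  dat <- data.frame(y = y)
  fit <- ordmrp(y ~ 1, dat, random = NULL, n_levels = 4, chains = 2,
                warmup = 300, draws = 800, seed = 2)
  emp <- qlogis(cumsum(tabulate(y, 4) / n)[1:3])
  expect_lt(max(abs(colMeans(fit$draws$kappa) - emp)), 0.1)
})

test_that("posterior matches dense-grid integration on a tiny model", {
  # n = 50, one binary factor, 3-level outcome; 3 free parameters
  set.seed(17)
  n <- 50
  x <- rbinom(n, 1, 0.5)
  ktrue <- c(-0.6, 0.8); btrue <- 0.9
  y <- .sample_y(ktrue, btrue * x)
  dat <- data.frame(y = y, g = factor(ifelse(x == 1, "g2", "g1"),
                                      levels = c("g1", "g2")))
  fit <- ordmrp(y ~ g, dat, random = NULL, n_levels = 3, chains = 2,
                warmup = 1000, draws = 8000, seed = 3)

  # independent oracle: grid integration in the centred parameterisation
  # (prior: sorted pair of N(0,5) cutpoints, N(0,2.5) coefficient)
  xbar <- mean(x)
  cnt <- table(factor(x, levels = 0:1), factor(y, levels = 1:3))
  ks <- seq(-4, 4, by = 0.08)
  bs <- seq(-3, 3, by = 0.06)
  grid <- expand.grid(k1 = ks, k2 = ks, b = bs)
  grid <- grid[grid$k1 < grid$k2, ]
  eta0 <- -xbar * grid$b
  eta1 <- (1 - xbar) * grid$b
  lp <- function(k1, k2, eta, c) {
    q1 <- plogis(k1 - eta); q2 <- plogis(k2 - eta)
    log(switch(c, q1, q2 - q1, 1 - q2))
  }
  ll <- 0
  for (c in 1:3) {
    ll <- ll + cnt[1, c] * lp(grid$k1, grid$k2, eta0, c) +
               cnt[2, c] * lp(grid$k1, grid$k2, eta1, c)
  }
  logpost <- ll + dnorm(grid$k1, 0, 5, log = TRUE) +
    dnorm(grid$k2, 0, 5, log = TRUE) + dnorm(grid$b, 0, 2.5, log = TRUE)
  wgt <- exp(logpost - max(logpost))
  wgt <- wgt / sum(wgt)
  b_grid <- sum(wgt * grid$b)
  k_grid <- c(sum(wgt * (grid$k1 + grid$b * xbar)),
              sum(wgt * (grid$k2 + grid$b * xbar)))

  expect_lt(abs(mean(fit$draws$beta[, "g:g2"]) - b_grid), 0.05)
  expect_lt(max(abs(colMeans(fit$draws$kappa) - k_grid)), 0.05)
})

test_that("log posterior likelihood is invariant to record order", {
  sc <- toy_schemes()
  st <- generate_census(sc, total = 2000, concentration = 2, seed = 1)
  pars <- true_params(sc, seed = 2)
  rec <- generate_respondents(pars, st, n = 300, seed = 3, attitudes = FALSE)
  ll <- ordmrp:::.loglik_records(
    kappa = pars$cutpoints_y, beta = pars$beta_y, gamma_z = pars$gamma_z,
    u = pars$region_effects_y, data = rec, schemes = sc,
    outcome = "y_dom", covariate = "z", random = "region")
  perm <- rec[sample(nrow(rec)), ]
  ll2 <- ordmrp:::.loglik_records(
    kappa = pars$cutpoints_y, beta = pars$beta_y, gamma_z = pars$gamma_z,
    u = pars$region_effects_y, data = perm, schemes = sc,
    outcome = "y_dom", covariate = "z", random = "region")
  expect_equal(ll, ll2, tolerance = 1e-12)
  expect_true(is.finite(ll))
})

test_that("stronger true gamma_z raises its posterior mean monotonically", {
  sc <- toy_schemes(n_regions = 2, factors = "sex")
  st <- generate_census(sc, total = 5000, concentration = 5, seed = 4)
  means <- vapply(c(0.3, 0.8, 1.3), function(g) {
    pars <- true_params(sc, seed = 11, gamma_z = g)
    rec <- generate_respondents(pars, st, n = 2500, seed = 12,
                                attitudes = FALSE)
    rec <- quiet_exclude(rec)
    fit <- ordmrp(y_dom ~ z + region + sex, rec, schemes = sc,
                  random = NULL, n_levels = 5, chains = 1, warmup = 300,
                  draws = 600, seed = 5)
    mean(fit$draws$gamma_z)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fits are deterministic given seed and settings", {
  set.seed(8)
  dat <- data.frame(y = sample(1:4, 300, TRUE),
                    g = factor(sample(c("g1", "g2"), 300, TRUE)))
  f1 <- ordmrp(y ~ g, dat, random = NULL, chains = 2, warmup = 100,
               draws = 200, seed = 42)
  f2 <- ordmrp(y ~ g, dat, random = NULL, chains = 2, warmup = 100,
               draws = 200, seed = 42)
  expect_identical(f1$draws$kappa, f2$draws$kappa)
  expect_identical(f1$draws$beta, f2$draws$beta)
  f3 <- ordmrp(y ~ g, dat, random = NULL, chains = 2, warmup = 100,
               draws = 200, seed = 43)
  expect_false(identical(f1$draws$kappa, f3$draws$kappa))
})

test_that("diagnostics cover every sampled parameter and pass on a clean fit", {
  sc <- toy_schemes()
  st <- generate_census(sc, total = 20000, concentration = 5, seed = 6)
  pars <- true_params(sc, seed = 7)
  rec <- generate_respondents(pars, st, n = 4000, seed = 8,
                              attitudes = FALSE)
  fit <- ordmrp(z ~ region + sex + age + education, rec, schemes = sc,
                random = NULL, n_levels = 4, chains = 4, warmup = 500,
                draws = 1000, seed = 9)
  d <- fit$diagnostics
  expect_setequal(d$parameter,
                  c(paste0("kappa[", 1:3, "]"), colnames(fit$draws$beta)))
  expect_true(all(is.finite(d$rhat)))
  expect_lt(max(d$rhat), 1.02)
  expect_gt(min(d$ess), 400)
})

test_that("degenerate inputs raise contract errors and warnings", {
  expect_error(ordmrp(y ~ g, data.frame(y = integer(0), g = character(0))),
               "empty data")
  dat <- data.frame(y = c(1, 2, 3, 2), g = factor("g1",
                    levels = c("g1", "g2")))
  expect_warning(
    ordmrp(y ~ g, dat, random = NULL, chains = 1, warmup = 50, draws = 50,
           seed = 1),
    "absent from data")
})

test_that("odds-ratio summaries follow the definition on degenerate draws", {
  fit <- mock_fit(scheme_2x3(), n_levels = 4, n_draws = 50)
  fit$draws$beta[, "a:a2"] <- 0
  o <- summarize_odds_ratio(fit, "a:a2")
  expect_equal(o$or, 1)
  expect_equal(c(o$hpd_low, o$hpd_high), c(1, 1))
  fit$draws$beta[, "b:b2"] <- log(2)
  o2 <- summarize_odds_ratio(fit, "b:b2")
  expect_equal(o2$or, 2, tolerance = 1e-12)
  expect_error(summarize_odds_ratio(fit, "nope"), "unknown parameter")
  # HPD of exponentiated normal draws equals the sorted-scan oracle
  set.seed(2)
  fit$draws$beta[, "b:b3"] <- rnorm(50)
  o3 <- summarize_odds_ratio(fit, "b:b3")
  ora <- oracle_hpd(exp(fit$draws$beta[, "b:b3"]))
  expect_equal(c(o3$hpd_low, o3$hpd_high), ora, tolerance = 1e-12)
})

test_that("posterior interval for gamma_z covers a known truth", {
  sc <- toy_schemes(n_regions = 2, factors = "sex")
  st <- generate_census(sc, total = 10000, concentration = 5, seed = 13)
  pars <- true_params(sc, seed = 14)
  rec <- quiet_exclude(generate_respondents(pars, st, n = 4000, seed = 15,
                                            attitudes = FALSE))
  fit <- ordmrp(y_dom ~ z + region + sex, rec, schemes = sc, random = NULL,
                n_levels = 5, chains = 2, warmup = 400, draws = 800,
                seed = 16)
  iv <- hpd(fit$draws$gamma_z)
  expect_lt(iv[1], pars$gamma_z)
  expect_gt(iv[2], pars$gamma_z)
})
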