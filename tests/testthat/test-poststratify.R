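# prediction and census-weighted composition, checked against loop oracles

test_that("cellwise prediction equals cell_probabilities composition", {
  set.seed(31)
  sc <- scheme_2x3()
  fit <- mock_fit(sc, n_levels = 4, n_draws = 20)
  st <- enumerate_strata(sc)[4, , drop = FALSE]
  pr <- cellwise_predict(fit, st)
  for (d in c(1, 7, 20)) {
    eta <- oracle_eta(fit, st, d)
    expect_equal(unname(pr[d, ]),
                 unname(cell_probabilities(fit$draws$kappa[d, ], eta)),
                 tolerance = 1e-12)
  }
  # degenerate draws: all parameters zero, symmetric cutpoints -> uniform
  fit0 <- mock_fit(sc, n_levels = 4, n_draws = 5)
  fit0$draws$kappa <- matrix(rep(qlogis(c(.25, .5, .75)), each = 5), 5)
  fit0$draws$beta[] <- 0
  pr0 <- cellwise_predict(fit0, st)
  expect_equal(unname(pr0), matrix(0.25, 5, 4), tolerance = 1e-12)
})

test_that("cellwise prediction enforces the z contract", {
  sc <- scheme_2x3()
  st <- enumerate_strata(sc)[1, , drop = FALSE]
  fit_z <- mock_fit(sc, n_levels = 4, n_draws = 5)
  fit_y <- mock_fit(sc, n_levels = 5, n_draws = 5, with_z = TRUE)
  expect_error(cellwise_predict(fit_y, st), "supply z")
  expect_error(cellwise_predict(fit_z, st, z = 2), "must be NULL")
  pr <- cellwise_predict(fit_y, st, z = 3)
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)
})

test_that("poststratification equals the explicit stratum loop", {
  set.seed(33)
  for (i in 1:5) {
    sc <- list(region = category_scheme("region", c("r1", "r2")),
               a = category_scheme("a", c("a1", "a2", "a3")))
    fit <- mock_fit(sc, n_levels = 4, n_draws = 15)
    st <- enumerate_strata(sc, counts = rgamma(6, 2))
    ps <- poststratify(fit, st)
    expect_equal(unname(ps$per_draw), oracle_poststrat(fit, st),
                 tolerance = 1e-10)
    expect_equal(rowSums(ps$per_draw), rep(1, 15), tolerance = 1e-10)
  }
})

test_that("poststratification identities: uniform and single stratum", {
  sc <- scheme_2x3()
  fit <- mock_fit(sc, n_levels = 4, n_draws = 10)
  # single stratum equals cellwise prediction
  st1 <- enumerate_strata(sc)[3, , drop = FALSE]
  st1$weight <- 1
  ps <- poststratify(fit, st1)
  expect_equal(unname(ps$per_draw), unname(cellwise_predict(fit, st1)),
               tolerance = 1e-12)
  # a Z-conditioned model is refused
  fit_y <- mock_fit(sc, n_levels = 5, n_draws = 10, with_z = TRUE)
  expect_error(poststratify(fit_y, enumerate_strata(sc)),
               "joint_distribution")
})

test_that("joint composition matches the hand-computed two-stratum product", {
  # one draw, two strata with hand-set parameters: pencil-and-paper oracle
  sc <- list(g = category_scheme("g", c("s1", "s2")))
  fit_z <- mock_fit(sc, n_levels = 4, n_draws = 1, random = NULL)
  fit_y <- mock_fit(sc, n_levels = 5, n_draws = 1, with_z = TRUE,
                    random = NULL)
  fit_z$draws$kappa <- matrix(qlogis(c(.2, .5, .8)), 1)
  fit_z$draws$beta[1, "g:s2"] <- 0.7
  fit_y$draws$kappa <- matrix(qlogis(c(.1, .3, .7, .9)), 1)
  fit_y$draws$beta[1, "g:s2"] <- -0.4
  fit_y$draws$gamma_z <- 0.5
  st <- enumerate_strata(sc, counts = c(3, 1))
  jt <- joint_distribution(fit_y, fit_z, st)
  manual <- matrix(0, 5, 4)
  for (s in 1:2) {
    w <- c(0.75, 0.25)[s]
    bz <- c(0, 0.7)[s]; by <- c(0, -0.4)[s]
    pz <- cell_probabilities(qlogis(c(.2, .5, .8)), bz)
    for (k in 1:4) {
      py <- cell_probabilities(qlogis(c(.1, .3, .7, .9)), by + 0.5 * k)
      manual[, k] <- manual[, k] + 100 * w * pz[k] * py
    }
  }
  expect_equal(unname(jt$per_draw[1, , ]), manual, tolerance = 1e-12)
})

test_that("a degenerate predictive concentrates the joint in one cell", {
  sc <- list(g = category_scheme("g", "only"))
  fit_z <- mock_fit(sc, n_levels = 4, n_draws = 3, random = NULL)
  fit_y <- mock_fit(sc, n_levels = 5, n_draws = 3, with_z = TRUE,
                    random = NULL)
  # z-model mass on k = 4, y-model mass on j = 3
  fit_z$draws$kappa <- matrix(rep(c(-60, -50, -40), each = 3), 3)
  fit_y$draws$kappa <- matrix(rep(c(-80, -70, 60, 70), each = 3), 3)
  fit_y$draws$gamma_z <- rep(0, 3)
  st <- enumerate_strata(sc)
  jt <- joint_distribution(fit_y, fit_z, st)
  expect_equal(unname(jt$per_draw[1, 3, 4]), 100, tolerance = 1e-6)
  expect_equal(sum(jt$per_draw[1, , ]), 100, tolerance = 1e-8)
  mg <- marginals(jt)
  expect_equal(unname(mg$rows[1, 3]), 100, tolerance = 1e-6)
})

test_that("joint equals the brute-force triple loop on random instances", {
  set.seed(35)
  for (i in 1:6) {
    sc <- list(region = category_scheme("region", c("r1", "r2")),
               a = category_scheme("a", c("a1", "a2")))
    fit_z <- mock_fit(sc, n_levels = 4, n_draws = 4)
    fit_y <- mock_fit(sc, n_levels = 5, n_draws = 4, with_z = TRUE)
    st <- enumerate_strata(sc, counts = rgamma(4, 1) + 0.1)
    jt <- joint_distribution(fit_y, fit_z, st)
    expect_equal(unname(jt$per_draw), oracle_joint(fit_y, fit_z, st),
                 tolerance = 1e-9)
    # conservation per draw
    expect_equal(apply(jt$per_draw, 1, sum), rep(100, 4), tolerance = 1e-8)
    # marginals equal brute-force sums and close to 100
    mg <- marginals(jt)
    expect_equal(unname(mg$rows), unname(t(apply(jt$per_draw, 1, rowSums))),
                 tolerance = 1e-10)
    expect_equal(unname(mg$cols), unname(t(apply(jt$per_draw, 1, colSums))),
                 tolerance = 1e-10)
  }
})

test_that("joint is mixture-consistent over a partition of the strata", {
  set.seed(36)
  sc <- list(region = category_scheme("region", c("r1", "r2")),
             a = category_scheme("a", c("a1", "a2", "a3")))
  fit_z <- mock_fit(sc, n_levels = 4, n_draws = 6)
  fit_y <- mock_fit(sc, n_levels = 5, n_draws = 6, with_z = TRUE)
  st <- enumerate_strata(sc, counts = rgamma(6, 2) + 0.05)
  idx <- c(1, 3, 5)
  stA <- st[idx, ]; stB <- st[-idx, ]
  wA <- sum(stA$weight); wB <- sum(stB$weight)
  stA$weight <- stA$weight / wA
  stB$weight <- stB$weight / wB
  jt <- joint_distribution(fit_y, fit_z, st)
  jtA <- joint_distribution(fit_y, fit_z, stA)
  jtB <- joint_distribution(fit_y, fit_z, stB)
  expect_equal(jt$per_draw, wA * jtA$per_draw + wB * jtB$per_draw,
               tolerance = 1e-9)
})

test_that("joint contract errors: draw mismatch and missing factors", {
  sc <- scheme_2x3()
  fit_z <- mock_fit(sc, n_levels = 4, n_draws = 5)
  fit_y <- mock_fit(sc, n_levels = 5, n_draws = 6, with_z = TRUE)
  st <- enumerate_strata(sc)
  expect_error(joint_distribution(fit_y, fit_z, st), "draw counts differ")
  fit_y2 <- mock_fit(sc, n_levels = 5, n_draws = 5)
  expect_error(joint_distribution(fit_y2, fit_z, st), "conditioned")
  fit_y3 <- mock_fit(sc, n_levels = 5, n_draws = 5, with_z = TRUE)
  expect_error(joint_distribution(fit_y3, fit_z, st[, -2]),
               "lacks factor column")
})
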