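test_that("census generation conserves totals and is seed-deterministic", {
  sc <- scheme_2x3()
  st1 <- generate_census(sc, total = 6000, concentration = 1, seed = 4)
  st2 <- generate_census(sc, total = 6000, concentration = 1, seed = 4)
  expect_equal(sum(st1$count), 6000)
  expect_identical(st1$count, st2$count)
  st3 <- generate_census(sc, total = 6000, concentration = 1, seed = 5)
  expect_false(identical(st1$count, st3$count))
})

test_that("large concentration approaches a uniform census", {
  sc <- scheme_2x3()
  st <- generate_census(sc, total = 6e5, concentration = 1e6, seed = 2)
  expect_lt(max(st$count) / min(st$count), 1.1)
})

test_that("generated categories are valid scheme levels", {
  sc <- toy_schemes()
  st <- generate_census(sc, total = 5000, concentration = 2, seed = 3)
  pars <- true_params(sc, seed = 5)
  rec <- generate_respondents(pars, st, n = 500, seed = 6)
  for (f in names(sc))
    expect_true(all(as.character(rec[[f]]) %in% sc[[f]]$levels))
  expect_true(all(rec$z %in% 1:4))
  expect_true(all(rec$y_dom %in% 1:5))
  expect_true(all(rec$y_int %in% 1:5))
  expect_true(all(rec$att_1 %in% c(1:5, NA)))
  expect_true(all(as.character(rec$dose_status) %in%
                  c("not_offered", "offered_not_taken", "one_dose",
                    "two_doses")))
})

test_that("null effects and symmetric cutpoints give uniform intent", {
  sc <- list(region = category_scheme("region", "only"))
  pars <- true_params(sc, seed = 1, gamma_z = 0, effect_sd = 0,
                      region_effect_sd = 0,
                      cutpoints_z = qlogis(c(.25, .5, .75)))
  st <- enumerate_strata(sc)
  rec <- generate_respondents(pars, st, n = 20000, seed = 2,
                              attitudes = FALSE)
  freq <- tabulate(rec$z, 4) / 20000
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
})

test_that("single-stratum frequencies match the closed-form cell law", {
  sc <- list(region = category_scheme("region", "only"))
  pars <- true_params(sc, seed = 1, gamma_z = 0.6, effect_sd = 0,
                      region_effect_sd = 0,
                      cutpoints_z = c(-1, 0.2, 1.4),
                      cutpoints_y = c(-0.5, 0.5, 2.5, 3.5))
  st <- enumerate_strata(sc)
  n <- 50000
  rec <- generate_respondents(pars, st, n = n, seed = 9, attitudes = FALSE)
  pz <- cell_probabilities(pars$cutpoints_z, 0)
  fz <- tabulate(rec$z, 4) / n
  expect_true(all(abs(fz - pz) < 3 * sqrt(pz * (1 - pz) / n)))
  # y within each z class follows the law at eta = gamma_z * z
  for (zz in 1:4) {
    idx <- rec$z == zz
    if (sum(idx) < 500) next
    py <- cell_probabilities(pars$cutpoints_y, 0.6 * zz)
    fy <- tabulate(rec$y_dom[idx], 5) / sum(idx)
    expect_true(all(abs(fy - py) < 3 * sqrt(py * (1 - py) / sum(idx)) + 1e-9))
  }
})

test_that("positive gamma_z induces positive rank correlation of z and y", {
  sc <- toy_schemes()
  st <- generate_census(sc, total = 20000, concentration = 3, seed = 1)
  pars <- true_params(sc, seed = 2, gamma_z = 2)
  rec <- generate_respondents(pars, st, n = 8000, seed = 3,
                              attitudes = FALSE)
  expect_gt(cor(rec$z, rec$y_dom, method = "spearman"), 0.1)
})

test_that("empirical stratum frequencies follow the census weights", {
  sc <- scheme_2x3()
  st <- enumerate_strata(sc, counts = c(10, 20, 5, 40, 15, 10))
  pars <- true_params(sc, seed = 4)
  rec <- generate_respondents(pars, st, n = 100000, seed = 8,
                              attitudes = FALSE)
  obs <- tabulate(match(paste(rec$a, rec$b), paste(st$a, st$b)),
                  nbins = nrow(st))
  gof <- suppressWarnings(chisq.test(obs, p = st$weight))
  expect_gt(gof$p.value, 0.01)
})

test_that("the generator and the model share one probability function", {
  # generator draws via cell_probabilities; the fitted-model prediction path
  # must evaluate the identical law pointwise
  set.seed(21)
  k <- sort(rnorm(4, 0, 2))
  for (eta in c(-2, -0.3, 0, 1.7)) {
    a <- cell_probabilities(k, eta)
    b <- ordmrp:::.probs_from_draws(matrix(k, 1), eta)
    expect_equal(unname(a), drop(b), tolerance = 1e-14)
  }
})

test_that("simulate_study writes loadable files with a truth sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(dir, schemes = toy_schemes(), n = 400, seed = 31)
  sc <- toy_schemes()
  rec <- load_survey(sim$survey, sc)
  expect_equal(nrow(rec), 400L)
  st <- read_census(sim$census, sc)
  expect_equal(st$count, sim$strata$count)
  truth <- jsonlite::read_json(sim$params_file, simplifyVector = TRUE)
  expect_equal(truth$gamma_z, sim$params$gamma_z, tolerance = 1e-12)
  # same seed reproduces byte-identical outputs
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_study(dir2, schemes = toy_schemes(), n = 400, seed = 31)
  expect_identical(readLines(sim$survey), readLines(sim2$survey))
  expect_identical(readLines(sim$census), readLines(sim2$census))
})
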