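#' Fit a Bayesian cumulative-logit multilevel model
#'
#' Fits the proportional-odds model
#' \deqn{P(y \le c \mid s) = \mathrm{logit}^{-1}(\kappa_c - \eta),\qquad
#'   \eta = \sum_f \beta_{f[\mathrm{level}]} + \gamma_Z z +
#'   u_{\mathrm{region}, p},}
#' with national fixed effects for every non-baseline level of every factor,
#' an optional slope \eqn{\gamma_Z} on a numeric covariate (baseline
#' vaccination intent, 1-4), and region-level random deviations of the
#' non-region coefficients with one shared SD per factor. Sampling is Gibbs
#' via JAGS; the likelihood is aggregated exactly to covariate-pattern
#' multinomial counts (all covariates are categorical), which makes the fit
#' independent of sample size given the pattern table.
#'
#' Priors: Normal(0, 2.5^2) on fixed effects and \eqn{\gamma_Z}; cutpoints as
#' the sorted transform of iid Normal(0, 5^2); half-Normal(0, 1) on each
#' random-effect SD.
#'
#' @param formula model formula, e.g. \code{y_dom ~ z + region + sex + age}.
#'   Factor terms become fixed effects (with scheme baselines); numeric terms
#'   become slope covariates (at most one, conventionally \code{z}).
#' @param data data.frame of recoded respondent records (two-dose records
#'   must already be excluded).
#' @param schemes named list of \code{\link{category_scheme}} objects for the
#'   factor terms; factors without a scheme use their observed levels with
#'   the first as baseline.
#' @param random name of the random-effect grouping factor (default
#'   \code{"region"} when present in the formula; \code{NULL} disables random
#'   effects).
#' @param n_levels number of outcome levels C (default: max observed).
#' @param chains,warmup,draws,thin MCMC settings. Defaults (4 chains, 500
#'   warm-up, 1000 kept draws each) satisfy the diagnostics contract on the
#'   bundled examples; scale \code{warmup}/\code{draws} up for production.
#' @param seed integer seed; together with the sampler settings it makes the
#'   draws reproducible.
#' @param quiet suppress JAGS progress output.
#' @return an object of class \code{"ordmrp"}; see
#'   \code{\link{summary.ordmrp}}, \code{\link{predict.ordmrp}},
#'   \code{\link{poststratify}}.
#' @export
ordmrp <- function(formula, data, schemes = NULL, random = "region",
                   n_levels = NULL, chains = 4, warmup = 500, draws = 1000,
                   thin = 1, seed = 1, quiet = TRUE) {
  cl <- match.call()
  if (!inherits(formula, "formula") || length(formula) != 3L)
    stop("formula must have the form outcome ~ terms")
  outcome <- all.vars(formula[[2]])
  vars <- all.vars(formula[[3]])
  if (!nrow(data)) stop("empty data")
  miss <- setdiff(c(outcome, vars), names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))

  y <- data[[outcome]]
  if (!is.numeric(y) || anyNA(y)) stop("outcome '", outcome,
                                       "' must be complete integers")
  y <- as.integer(y)
  C <- if (is.null(n_levels)) max(y) else as.integer(n_levels)
  if (C < 3L) stop("need at least 3 outcome levels")
  if (any(y < 1L | y > C)) stop("outcome values outside 1..", C)

  is_num <- vapply(vars, function(v) is.numeric(data[[v]]), TRUE)
  covars <- vars[is_num]
  if (length(covars) > 1L)
    stop("at most one numeric covariate supported (got: ",
         paste(covars, collapse = ", "), ")")
  factors <- vars[!is_num]
  used <- list()
  for (f in factors) {
    if (!is.null(schemes) && f %in% names(schemes)) {
      used[[f]] <- schemes[[f]]
    } else {
      lev <- if (is.factor(data[[f]])) levels(data[[f]])
             else sort(unique(as.character(data[[f]])))
      used[[f]] <- category_scheme(f, lev)
    }
    obs <- unique(as.character(data[[f]]))
    absent <- setdiff(used[[f]]$levels, obs)
    if (length(absent))
      warning("factor '", f, "': level(s) absent from data (posterior stays ",
              "at the prior): ", paste(absent, collapse = ", "))
  }
  if (!is.null(random) && !random %in% factors) random <- NULL

  X <- .design_matrix(data[, factors, drop = FALSE], used)
  zc <- if (length(covars)) as.numeric(data[[covars]]) else NULL
  rcols <- if (!is.null(random)) .random_cols(used, random) else character(0)
  regions <- if (!is.null(random)) used[[random]]$levels else character(0)

  # exact aggregation to covariate-pattern multinomial counts
  keydf <- data[, factors, drop = FALSE]
  if (!is.null(zc)) keydf$..z <- zc
  key <- if (ncol(keydf)) # intercept-only: one pattern holds everybody
    do.call(paste, c(lapply(keydf, as.character), sep = "\r"))
  else rep("", nrow(data))
  first <- !duplicated(key)
  gidx <- match(key, key[first])
  G <- sum(first)
  ycount <- matrix(0L, G, C)
  for (c in seq_len(C)) ycount[, c] <- tabulate(gidx[y == c], nbins = G)
  Xg <- X[first, , drop = FALSE]
  zg <- if (!is.null(zc)) zc[first] else NULL
  regg <- if (!is.null(random))
    match(as.character(data[[random]][first]), regions) else NULL

  jd <- list(ycount = ycount, ntot = rowSums(ycount), G = G, C = C)
  P <- ncol(Xg)
  has_z <- !is.null(zg)
  has_u <- length(rcols) > 0L && length(regions) > 0L
  # columns with region deviations are hierarchically centred: region
  # coefficients v[r,j] ~ N(br[j], tau) enter eta directly and the national
  # coefficient br[j] is their mean -- a pure reparameterisation of
  # "fixed + zero-mean deviation" with far better Gibbs mixing.
  fcols <- if (has_u) setdiff(colnames(Xg), rcols) else colnames(Xg)
  has_b0 <- length(fcols) > 0L
  # centre the non-hierarchical design columns (pattern means weighted by
  # pattern size) to decorrelate cutpoints from coefficients; undone
  # draw-by-draw below so reported parameters are on the raw scale
  wpat <- rowSums(ycount) / sum(ycount)
  xbar0 <- if (has_b0) drop(crossprod(wpat, Xg[, fcols, drop = FALSE]))
           else numeric(0)
  zbar <- if (has_z) sum(wpat * zg) else 0
  if (has_b0) {
    jd$X0 <- sweep(Xg[, fcols, drop = FALSE], 2, xbar0)
    jd$P0 <- length(fcols)
  }
  if (has_z) jd$zcov <- zg - zbar
  if (has_u) {
    rfac <- .random_col_factor(used, random)
    fl <- unique(rfac)
    jd$Xr <- Xg[, rcols, drop = FALSE]
    jd$reg <- regg
    jd$R <- length(regions)
    jd$PR <- length(rcols)
    jd$NF <- length(fl)
    jd$fidx <- match(rfac, fl)
  } else fl <- character(0)

  code <- .jags_code(C, has_b0, has_z, has_u)
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(.RNG.name = "base::Wichmann-Hill",
                .RNG.seed = (as.integer(seed) - 1L) %% 99999L * 101L + ch,
                kappa0 = stats::qlogis(seq_len(C - 1) / C))
    if (has_b0) ini$b0 <- rep(0, length(fcols))
    if (has_u) ini$br <- rep(0, length(rcols))
    if (has_z) ini$gz <- 0
    ini
  })
  monitors <- c("kappa", if (has_b0) "b0", if (has_z) "gz",
                if (has_u) c("br", "v", "sd_u"))
  jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                          n.chains = chains, quiet = quiet)
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors, n.iter = draws,
                              thin = thin, progress.bar = "none")

  dr <- .extract_draws(samp, C, colnames(Xg), fcols, has_z, has_u,
                       regions, rcols, fl)
  # undo the centring: kappa_raw = kappa_centred + b0.xbar0 + gamma*zbar
  shift <- numeric(dr$n_draws)
  if (has_b0) shift <- shift +
    drop(dr$beta[, fcols, drop = FALSE] %*% xbar0)
  if (has_z) shift <- shift + dr$gamma_z * zbar
  dr$kappa <- dr$kappa + shift
  diag <- .fit_diagnostics(samp)
  diag$parameter <- .rename_params(diag$parameter, fcols, rcols, regions, fl)
  structure(list(call = cl, formula = formula, outcome = outcome,
                 n_levels = C, schemes = used, factors = factors,
                 covariate = if (has_z) covars else NULL, random = random,
                 random_cols = rcols, draws = dr, diagnostics = diag,
                 n_records = nrow(data), n_patterns = G,
                 mcmc = list(chains = chains, warmup = warmup, draws = draws,
                             thin = thin, seed = as.integer(seed))),
            class = "ordmrp")
}

.jags_code <- function(C, has_b0, has_z, has_u) {
  eta <- c(if (has_b0) "inprod(X0[g,], b0[])",
           if (has_z) "gz * zcov[g]",
           if (has_u) "inprod(Xr[g,], v[reg[g],])")
  if (!length(eta)) eta <- "0"
  paste0(
    "model {\n",
    "  for (g in 1:G) {\n",
    "    eta[g] <- ", paste(eta, collapse = " + "), "\n",
    "    for (c in 1:(C-1)) { logit(q[g,c]) <- kappa[c] - eta[g] }\n",
    "    p[g,1] <- q[g,1]\n",
    if (C > 3) "    for (c in 2:(C-1)) { p[g,c] <- q[g,c] - q[g,c-1] }\n"
    else       "    p[g,2] <- q[g,2] - q[g,1]\n",
    "    p[g,C] <- 1 - q[g,C-1]\n",
    "    ycount[g,1:C] ~ dmulti(p[g,1:C], ntot[g])\n",
    "  }\n",
    if (has_b0) "  for (j in 1:P0) { b0[j] ~ dnorm(0, 0.16) }\n",
    if (has_z) "  gz ~ dnorm(0, 0.16)\n",
    "  for (c in 1:(C-1)) { kappa0[c] ~ dnorm(0, 0.04) }\n",
    "  kappa[1:(C-1)] <- sort(kappa0[1:(C-1)])\n",
    if (has_u) paste0(
      "  for (j in 1:PR) { br[j] ~ dnorm(0, 0.16) }\n",
      "  for (r in 1:R) { for (j in 1:PR) { v[r,j] ~ dnorm(br[j], tau_u[fidx[j]]) } }\n",
      "  for (f in 1:NF) {\n",
      "    sd_u[f] ~ dnorm(0, 1) T(0,)\n",
      "    tau_u[f] <- pow(sd_u[f], -2)\n",
      "  }\n"),
    "}\n")
}

.extract_draws <- function(samp, C, design_cols, fcols, has_z, has_u,
                           regions, rcols, rfactors) {
  m <- do.call(rbind, lapply(samp, as.matrix))
  D <- nrow(m)
  cn <- colnames(m)
  kap <- m[, paste0("kappa[", seq_len(C - 1), "]"), drop = FALSE]
  colnames(kap) <- paste0("kappa[", seq_len(C - 1), "]")
  out <- list(kappa = kap, n_draws = D)
  # coda drops the "[1]" suffix from length-1 monitored nodes
  col <- function(nm, base) if (nm %in% cn) m[, nm] else m[, base]
  if (length(design_cols)) {
    b <- matrix(NA_real_, D, length(design_cols),
                dimnames = list(NULL, design_cols))
    for (j in seq_along(fcols))
      b[, fcols[j]] <- col(sprintf("b0[%d]", j), "b0")
    if (has_u) for (j in seq_along(rcols))
      b[, rcols[j]] <- col(sprintf("br[%d]", j), "br")
    out$beta <- b
  }
  if (has_z) out$gamma_z <- m[, "gz"]
  if (has_u) {
    u <- array(NA_real_, c(D, length(regions), length(rcols)),
               dimnames = list(NULL, regions, rcols))
    for (r in seq_along(regions))
      for (j in seq_along(rcols)) # deviation = region coefficient - mean
        u[, r, j] <- col(sprintf("v[%d,%d]", r, j), "v") -
          out$beta[, rcols[j]]
    out$u <- u
    sdn <- grep("^sd_u", cn, value = TRUE)
    sd_u <- m[, sdn, drop = FALSE]
    colnames(sd_u) <- if (length(sdn) == length(rfactors)) rfactors else sdn
    out$sd_u <- sd_u
  }
  out
}

# user-facing names for the sampled JAGS nodes
.rename_params <- function(p, fcols, rcols, regions, rfactors) {
  out <- p
  for (j in seq_along(fcols))
    out[p == sprintf("b0[%d]", j) | (length(fcols) == 1 & p == "b0")] <-
      fcols[j]
  for (j in seq_along(rcols))
    out[p == sprintf("br[%d]", j) | (length(rcols) == 1 & p == "br")] <-
      rcols[j]
  for (f in seq_along(rfactors))
    out[p == sprintf("sd_u[%d]", f) |
          (length(rfactors) == 1 & p == "sd_u")] <-
      paste0("sd_u[", rfactors[f], "]")
  out[p == "gz"] <- "gamma_z"
  vm <- regmatches(p, regexec("^v\\[(\\d+),(\\d+)\\]$", p))
  for (i in seq_along(vm)) {
    if (length(vm[[i]]) == 3)
      out[i] <- paste0("v[", regions[as.integer(vm[[i]][2])], ",",
                       rcols[as.integer(vm[[i]][3])], "]")
  }
  out
}

# split-Rhat (each chain halved) and effective sample size per parameter
.fit_diagnostics <- function(samp) {
  halves <- list()
  for (ch in samp) {
    m <- as.matrix(ch)
    n2 <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(n2), , drop = FALSE],
                             m[nrow(m) - n2 + seq_len(n2), , drop = FALSE]))
  }
  params <- colnames(as.matrix(samp[[1]]))
  rhat <- vapply(params, function(p) {
    seqs <- vapply(halves, function(h) h[, p], numeric(nrow(halves[[1]])))
    n <- nrow(seqs); k <- ncol(seqs)
    mu <- colMeans(seqs)
    W <- mean(apply(seqs, 2, stats::var))
    B <- n * stats::var(mu)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(samp),
                  error = function(e) rep(NA_real_, length(params)))
  data.frame(parameter = params, rhat = unname(rhat),
             ess = unname(ess[params]), row.names = NULL)
}

# log-likelihood of recoded records at one parameter point (record order
# invariant; used by tests and the grid-integration oracle)
.loglik_records <- function(kappa, beta, gamma_z, u, data, schemes, outcome,
                            covariate = NULL, random = "region") {
  eta <- .eta_rows(data, schemes, beta, u, random)
  if (!is.null(covariate) && !is.null(gamma_z))
    eta <- eta + gamma_z * as.numeric(data[[covariate]])
  P <- cell_probabilities(kappa, eta)
  sum(log(P[cbind(seq_len(nrow(data)), as.integer(data[[outcome]]))]))
}
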