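# Shared design construction for the cumulative-logit linear predictor
#
#   eta = sum_f beta_f[level]  (+ gamma_z * z)  + u[region, p] over random cols
#
# Fixed effects are treatment-coded indicators of every non-baseline level of
# every factor (region included); random effects are region-specific
# deviations on the non-baseline columns of the non-region factors. The same
# builder serves the generator, the likelihood and prediction, so parameter
# ordering (factor order as supplied, levels in scheme order) is identical
# everywhere.

.fixed_terms <- function(schemes) {
  out <- list()
  for (s in schemes) {
    lev <- setdiff(s$levels, s$baseline)
    # keep scheme order
    lev <- s$levels[s$levels %in% lev]
    if (length(lev))
      out[[s$name]] <- paste0(s$name, ":", lev)
  }
  out
}

# X: n x P indicator matrix with columns named "factor:level"
.design_matrix <- function(data, schemes) {
  terms <- .fixed_terms(schemes)
  cols <- unlist(terms, use.names = FALSE)
  X <- matrix(0, nrow(data), length(cols), dimnames = list(NULL, cols))
  for (s in schemes) {
    v <- as.character(data[[s$name]])
    bad <- setdiff(unique(v), s$levels)
    if (length(bad))
      stop("level(s) not in scheme '", s$name, "': ",
           paste(bad, collapse = ", "))
    for (l in setdiff(s$levels, s$baseline)) {
      cn <- paste0(s$name, ":", l)
      if (cn %in% cols) X[, cn] <- as.numeric(v == l)
    }
  }
  X
}

# columns of X that receive region-level random deviations
.random_cols <- function(schemes, random = "region") {
  if (is.null(random) || !random %in% names(schemes)) return(character(0))
  terms <- .fixed_terms(schemes[setdiff(names(schemes), random)])
  unlist(terms, use.names = FALSE)
}

# map each random column to its factor (for per-factor random-effect SDs)
.random_col_factor <- function(schemes, random = "region") {
  cols <- .random_cols(schemes, random)
  sub(":.*$", "", cols)
}
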