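#' Enumerate census strata and attach poststratification weights
#'
#' Forms the full Cartesian product of the scheme levels, in a deterministic
#' order (factors in the order given, levels in scheme order, with the first
#' factor varying slowest), assigns stable integer stratum ids, and attaches
#' population counts and normalised weights P(S = s). The canonical UK
#' eight-factor cross has exactly 370,440 rows.
#'
#' @param schemes named list of \code{\link{category_scheme}} objects.
#' @param counts optional population counts: either a numeric vector in
#'   stratum-id order, or a data.frame with one column per factor plus a
#'   \code{count} column (strata absent from it get count 0). \code{NULL}
#'   gives a uniform table.
#' @return data.frame with columns \code{stratum_id}, one factor column per
#'   scheme, \code{count} and \code{weight}; weights sum to 1.
#' @export
enumerate_strata <- function(schemes, counts = NULL) {
  stopifnot(length(schemes) >= 1)
  nm <- vapply(schemes, `[[`, "", "name")
  names(schemes) <- nm
  lv <- lapply(schemes, `[[`, "levels")
  # first factor slowest: expand.grid varies the first argument fastest, so
  # feed factors reversed and reorder columns back
  grid <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(lv)), drop = FALSE]
  names(grid) <- nm
  for (f in nm) grid[[f]] <- factor(grid[[f]], levels = schemes[[f]]$levels)
  n <- nrow(grid)
  if (is.null(counts)) {
    cnt <- rep(1, n)
  } else if (is.data.frame(counts)) {
    miss <- setdiff(nm, names(counts))
    if (length(miss))
      stop("census table is missing stratum column(s): ",
           paste(miss, collapse = ", "))
    if (!"count" %in% names(counts)) stop("census table has no 'count' column")
    key_grid <- do.call(paste, c(lapply(grid, as.character), sep = "\r"))
    key_cnt <- do.call(paste, c(lapply(counts[nm], as.character), sep = "\r"))
    unknown <- setdiff(key_cnt, key_grid)
    if (length(unknown))
      stop("census table contains ", length(unknown),
           " row(s) with level combinations outside the scheme")
    cnt <- numeric(n)
    idx <- match(key_cnt, key_grid)
    cnt[idx] <- cnt[idx] + counts$count
  } else {
    if (length(counts) != n)
      stop("counts has length ", length(counts), ", expected ", n)
    cnt <- as.numeric(counts)
  }
  if (any(cnt < 0)) stop("negative census counts")
  tot <- sum(cnt)
  if (tot <= 0) stop("census counts sum to zero")
  out <- cbind(data.frame(stratum_id = seq_len(n)), grid)
  out$count <- cnt
  out$weight <- cnt / tot
  out
}

#' Read a census strata table from CSV
#'
#' The file must carry one column per scheme factor (raw labels are recoded
#' through the schemes) and a \code{count} column. Missing strata are kept
#' with count 0 so stratum ids stay stable.
#'
#' @param path CSV path.
#' @param schemes named list of \code{\link{category_scheme}} objects.
#' @return strata table as from \code{\link{enumerate_strata}}.
#' @export
read_census <- function(path, schemes) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  nm <- vapply(schemes, `[[`, "", "name")
  miss <- setdiff(c(nm, "count"), names(df))
  if (length(miss))
    stop("census file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  for (f in nm) df[[f]] <- recode_values(df[[f]], schemes[[match(f, nm)]],
                                         context = f)
  enumerate_strata(schemes, counts = df[, c(nm, "count")])
}

#' Write a strata table to CSV
#' @param strata strata table from \code{\link{enumerate_strata}}.
#' @param path output CSV path.
#' @param header optional character vector of \code{#}-prefixed header lines.
#' @export
write_census <- function(strata, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(strata[, setdiff(names(strata), c("stratum_id", "weight"))],
                   con, row.names = FALSE)
  invisible(path)
}

# factor columns of a strata table, in order
.strata_factors <- function(strata) {
  setdiff(names(strata), c("stratum_id", "count", "weight"))
}
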