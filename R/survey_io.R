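#' Load and recode a survey CSV
#'
#' Reads one row per respondent, recodes every socio-demographic column
#' through its \code{\link{category_scheme}}, and maps the ordinal responses
#' to integers: baseline vaccination intent \code{z} on 1-4 ("no, definitely
#' not" = 1 ... "yes, definitely" = 4), change in inclination \code{y_dom} /
#' \code{y_int} on 1-5 ("much less inclined" = 1 ... "much more inclined" =
#' 5, with "do not know / prefer not to say" folded into the neutral 3), and
#' any \code{att_1}..\code{att_7} agreement items on 1-5 with "prefer not to
#' say" as \code{NA}. Unknown labels raise an error naming the row and value;
#' they are never silently dropped. Recoding is idempotent, so a file written
#' by \code{\link{write_survey}} reloads identically.
#'
#' @param path CSV path (RFC 4180, UTF-8, header row mandatory; lines
#'   starting with \code{#} are treated as comments).
#' @param schemes named list of \code{\link{category_scheme}} objects; the
#'   file must have one column per scheme factor.
#' @param require list of required non-factor columns; by default
#'   \code{dose_status}, \code{z}, \code{y_dom}, \code{y_int}.
#' @return data.frame of recoded respondent records.
#' @export
load_survey <- function(path, schemes = uk_schemes(),
                        require = c("dose_status", "z", "y_dom", "y_int")) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  recode_survey(df, schemes = schemes, require = require)
}

#' Recode an in-memory survey data.frame
#' @inheritParams load_survey
#' @param df data.frame with raw or already-recoded columns.
#' @export
recode_survey <- function(df, schemes = uk_schemes(),
                          require = c("dose_status", "z", "y_dom", "y_int")) {
  nm <- vapply(schemes, `[[`, "", "name")
  miss <- setdiff(c(nm, require), names(df))
  if (length(miss))
    stop("survey schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  out <- df
  if (!"respondent_id" %in% names(out))
    out$respondent_id <- seq_len(nrow(out))
  for (i in seq_along(nm))
    out[[nm[i]]] <- recode_values(df[[nm[i]]], schemes[[i]], context = nm[i])
  if ("dose_status" %in% names(out)) {
    ds <- as.character(out$dose_status)
    bad <- which(!ds %in% .dose_levels)
    if (length(bad))
      stop("recode error in 'dose_status': unmapped label(s) ",
           paste0("'", unique(ds[utils::head(bad, 5)]), "'", collapse = ", "),
           " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    out$dose_status <- factor(ds, levels = .dose_levels)
  }
  if ("z" %in% names(out))
    out$z <- .recode_ordinal(df$z, .z_labels, 4L, "z")
  for (col in intersect(c("y_dom", "y_int"), names(out)))
    out[[col]] <- .recode_ordinal(df[[col]], .y_labels, 5L, col)
  for (col in grep("^att_[1-7]$", names(out), value = TRUE))
    out[[col]] <- .recode_ordinal(df[[col]], .att_labels, 5L, col)
  if ("z" %in% names(out) && anyNA(out$z))
    stop("recode error in 'z': missing baseline intent at row(s) ",
         paste(utils::head(which(is.na(out$z)), 5), collapse = ", "),
         " (z has no refusal option; recode explicitly before loading)")
  out
}

#' Write recoded survey records to CSV
#' @param records data.frame of recoded respondent records.
#' @param path output CSV path.
#' @param header optional character vector of \code{#}-prefixed header lines.
#' @export
write_survey <- function(records, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Drop respondents who have already received both vaccine doses
#'
#' Fully vaccinated respondents cannot change a future vaccination decision,
#' so they are excluded from every model fit. Order is preserved.
#'
#' @param records data.frame with a \code{dose_status} column.
#' @param quiet suppress the exclusion-count message.
#' @return the records with \code{dose_status != "two_doses"}.
#' @export
exclude_fully_vaccinated <- function(records, quiet = FALSE) {
  stopifnot("dose_status" %in% names(records))
  drop <- records$dose_status == "two_doses"
  if (!quiet)
    message("excluding ", sum(drop), " fully vaccinated respondent(s); ",
            sum(!drop), " remain")
  records[!drop, , drop = FALSE]
}

#' Resolve "prefer not to say" attitude responses
#'
#' @param records recoded records with \code{att_*} columns.
#' @param item attitude column name (e.g. \code{"att_6"}).
#' @param policy \code{"drop"} for complete-case removal (default) or
#'   \code{"neutral"} to recode refusals to the scale midpoint 3, the
#'   sensitivity variant.
#' @return records with the item resolved per policy.
#' @export
apply_pnts_policy <- function(records, item, policy = c("drop", "neutral")) {
  policy <- match.arg(policy)
  stopifnot(item %in% names(records))
  if (policy == "drop") {
    records[!is.na(records[[item]]), , drop = FALSE]
  } else {
    records[[item]][is.na(records[[item]])] <- 3L
    records
  }
}
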