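#' Define a categorical coding scheme for one survey factor
#'
#' A scheme fixes, for one socio-demographic factor, the ordered set of
#' modelled levels, the baseline level used in the ordinal regressions, and a
#' recode map from raw questionnaire labels to modelled levels. Level order is
#' part of the contract: stratum indices and parameter ordering are derived
#' from it, so identical schemes yield identical stratum ids across runs.
#'
#' @param name factor name (e.g. \code{"education"}).
#' @param levels character vector of modelled levels, in canonical order.
#' @param baseline baseline level; must be one of \code{levels}. Defaults to
#'   the first level.
#' @param recode optional named character vector mapping raw survey labels to
#'   modelled levels. Modelled levels always map to themselves, so recoding is
#'   idempotent.
#' @return an object of class \code{"category_scheme"}.
#' @export
category_scheme <- function(name, levels, baseline = levels[1], recode = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  levels <- as.character(levels)
  if (anyDuplicated(levels))
    stop("scheme '", name, "': duplicate level(s): ",
         paste(unique(levels[duplicated(levels)]), collapse = ", "))
  if (!baseline %in% levels)
    stop("scheme '", name, "': baseline '", baseline, "' is not a level")
  if (!is.null(recode)) {
    if (is.null(names(recode)) || any(!nzchar(names(recode))))
      stop("scheme '", name, "': recode map must be a named character vector")
    bad <- setdiff(unname(recode), levels)
    if (length(bad))
      stop("scheme '", name, "': recode targets not in levels: ",
           paste(unique(bad), collapse = ", "))
  }
  # self-maps make recoding idempotent
  map <- c(recode, stats::setNames(levels, levels))
  map <- map[!duplicated(names(map))]
  structure(list(name = name, levels = levels, baseline = baseline,
                 recode_map = map),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme> ", x$name, ": ", length(x$levels), " levels (baseline '",
      x$baseline, "')\n", sep = "")
  cat("  ", paste(x$levels, collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Recode raw labels to a scheme's modelled levels
#'
#' @param x character vector of raw labels (already-modelled levels pass
#'   through unchanged).
#' @param scheme a \code{\link{category_scheme}}.
#' @param context label used in error messages (e.g. a column name).
#' @return factor with the scheme's levels.
#' @export
recode_values <- function(x, scheme, context = scheme$name) {
  x <- as.character(x)
  out <- unname(scheme$recode_map[x])
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("recode error in '", context, "': unmapped label(s) ",
         paste0("'", unique(x[bad[seq_len(min(5, length(bad)))]]), "'",
                collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  factor(out, levels = scheme$levels)
}

#' Recode a raw education response to the three modelled attainment levels
#'
#' Collapses the nine questionnaire responses on highest educational
#' attainment into \code{none/other}, \code{level 1-3} (GCSE/O-level/A-level
#' equivalents) and \code{level 4} (degree or other professional
#' qualification).
#'
#' @param raw_label character vector of raw responses.
#' @return factor with levels \code{none/other}, \code{level 1-3},
#'   \code{level 4}.
#' @examples
#' recode_education("Apprenticeship")              # none/other
#' recode_education("2 + A levels or equivalents") # level 1-3
#' @export
recode_education <- function(raw_label) {
  recode_values(raw_label, uk_schemes()$education, context = "education")
}

#' The eight UK socio-demographic coding schemes
#'
#' Returns the factor schemes used for the UK vaccine-passport analysis:
#' region (12 NUTS1 units), sex (2), age group (7), education (3), work
#' status (7), religious affiliation (7), ethnicity (5) and primary language
#' (3), in that canonical order, with the questionnaire recode maps and the
#' regression baselines. Crossing all eight yields 370,440 census strata.
#'
#' @return named list of \code{\link{category_scheme}} objects.
#' @export
uk_schemes <- function() {
  list(
    region = category_scheme(
      "region",
      levels = c("North East", "North West", "Yorkshire and the Humber",
                 "East Midlands", "West Midlands", "East of England",
                 "London", "South East", "South West", "Wales", "Scotland",
                 "Northern Ireland"),
      baseline = "London"),
    sex = category_scheme("sex", levels = c("female", "male"),
                          baseline = "female"),
    age = category_scheme(
      "age",
      levels = c("18-24", "25-34", "35-44", "45-54", "55-64", "65-79", "80+"),
      baseline = "18-24"),
    education = category_scheme(
      "education",
      levels = c("none/other", "level 1-3", "level 4"),
      baseline = "level 1-3",
      recode = c(
        "No academic qualifications" = "none/other",
        "0-4 GCSE, O-levels, or equivalents" = "level 1-3",
        "5+ GCSE, O-levels, 1 A level, or equivalents" = "level 1-3",
        "2 + A levels or equivalents" = "level 1-3",
        "Undergraduate or postgraduate degree or other professional qualification" = "level 4",
        "Apprenticeship" = "none/other",
        "Other (e.g., vocational, foreign qualifications)" = "none/other",
        "Do not know" = "none/other",
        "Do not wish to answer" = "none/other")),
    work = category_scheme(
      "work",
      levels = c("full-time", "part-time", "unemployed", "student",
                 "looking after home", "retired / disabled",
                 "other work status"),
      baseline = "full-time",
      recode = c(
        "working full-time (including self-employed)" = "full-time",
        "part-time (including self-employed)" = "part-time",
        "looking after the home" = "looking after home",
        "retired" = "retired / disabled",
        "unable to work (e.g., short- or long-term disability)" = "retired / disabled",
        "do not wish to answer" = "other work status")),
    religion = category_scheme(
      "religion",
      levels = c("atheist/agnostic", "Christian", "Hindu", "Jewish", "Muslim",
                 "other religion", "not given"),
      baseline = "atheist/agnostic",
      recode = c(
        "Buddhist" = "other religion",
        "do not wish to answer" = "not given")),
    ethnicity = category_scheme(
      "ethnicity",
      levels = c("White", "mixed", "Black/Black British",
                 "Asian/Asian British", "other ethnicity"),
      baseline = "White",
      recode = c(
        "White: English/Welsh/Scottish/Northern Irish/British" = "White",
        "White: Irish" = "White",
        "White: Other white background" = "White",
        "White and Black Caribbean" = "mixed",
        "White and Black African" = "mixed",
        "White and Asian or White and Asian British" = "mixed",
        "Black, African, Caribbean or Black British" = "Black/Black British",
        "Asian or Asian British: Indian" = "Asian/Asian British",
        "Asian or Asian British: Pakistani" = "Asian/Asian British",
        "Asian or Asian British: Chinese" = "Asian/Asian British",
        "Asian or Asian British: Other" = "Asian/Asian British",
        "do not wish to answer" = "other ethnicity")),
    language = category_scheme(
      "language",
      levels = c("English or Welsh", "Polish", "other language"),
      baseline = "English or Welsh",
      recode = c(
        "Punjabi" = "other language",
        "Urdu" = "other language",
        "Bengali" = "other language",
        "Other" = "other language",
        "do not wish to answer" = "other language"))
  )
}

#' Small reduced schemes for examples and simulation studies
#'
#' A cut-down cross (a few regions, binary sex, three age groups, two
#' education levels by default) that exercises the full modelling path at a
#' fraction of the 370,440-stratum cost.
#'
#' @param n_regions number of regions to keep (2-12).
#' @param factors names of non-region factors to keep, subset of
#'   \code{c("sex", "age", "education")}.
#' @return named list of \code{\link{category_scheme}} objects.
#' @export
toy_schemes <- function(n_regions = 3,
                        factors = c("sex", "age", "education")) {
  full <- uk_schemes()
  out <- list(region = category_scheme(
    "region", levels = full$region$levels[seq_len(n_regions)],
    baseline = full$region$levels[1]))
  if ("sex" %in% factors) out$sex <- full$sex
  if ("age" %in% factors)
    out$age <- category_scheme("age", levels = c("18-24", "25-54", "55+"),
                               baseline = "18-24")
  if ("education" %in% factors)
    out$education <- category_scheme("education",
                                     levels = c("level 1-3", "level 4"),
                                     baseline = "level 1-3")
  out
}

# ordinal response label maps -------------------------------------------------

# change in inclination Y: 5 levels; "do not know / prefer not to say" folds
# into the neutral midpoint
.y_labels <- c(
  "much less inclined" = 1L,
  "somewhat less inclined" = 2L,
  "neither more nor less inclined" = 3L,
  "somewhat more inclined" = 4L,
  "much more inclined" = 5L,
  "do not know / prefer not to say" = 3L)

# baseline intent Z: 4 levels, no refusal option
.z_labels <- c(
  "no, definitely not" = 1L,
  "unsure, but leaning towards no" = 2L,
  "unsure, but leaning towards yes" = 3L,
  "yes, definitely" = 4L)

# attitude items: 5-point agreement; "prefer not to say" becomes NA and is
# resolved later by the chosen policy (complete-case or neutral recode)
.att_labels <- c(
  "strongly disagree" = 1L,
  "disagree" = 2L,
  "neither agree nor disagree" = 3L,
  "agree" = 4L,
  "strongly agree" = 5L,
  "prefer not to say" = NA_integer_)

.dose_levels <- c("not_offered", "offered_not_taken", "one_dose", "two_doses")

.recode_ordinal <- function(x, map, n_levels, context) {
  if (is.numeric(x)) {
    v <- as.integer(x)
    bad <- which(!is.na(v) & (v < 1L | v > n_levels | v != x))
    if (length(bad))
      stop("recode error in '", context, "': value(s) outside 1..", n_levels,
           " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    return(v)
  }
  x <- tolower(trimws(as.character(x)))
  v <- unname(map[x])
  # numeric strings pass through
  num <- suppressWarnings(as.integer(x))
  v[is.na(v) & !is.na(num)] <- num[is.na(v) & !is.na(num)]
  bad <- which(is.na(v) & !is.na(x) & !(x %in% names(map)[is.na(map)]))
  if (length(bad))
    stop("recode error in '", context, "': unmapped label(s) ",
         paste0("'", unique(x[utils::head(bad, 5)]), "'", collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  if (any(!is.na(v) & (v < 1L | v > n_levels)))
    stop("recode error in '", context, "': value outside 1..", n_levels)
  v
}
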