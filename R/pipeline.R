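#' Published joint-distribution panels (worked example)
#'
#' Loads the bundled national posterior-mean estimates of the joint
#' distribution of baseline COVID-19 vaccination intent and change in
#' inclination under vaccine passports (UK, April 2021 survey wave), one
#' 5 x 4 percentage panel per passport variant. These printed panels are the
#' package's headline worked example: applying \code{\link{compute_uk}} /
#' \code{\link{compute_s}} to them reproduces the published net-shift
#' estimates.
#'
#' @param path CSV with columns \code{variant}, \code{y}, \code{z1}..\code{z4};
#'   defaults to the bundled file.
#' @return named list of 5 x 4 matrices, one per variant.
#' @export
passport_joint_table <- function(path = system.file(
    "extdata", "uk_passport_joint_published.csv", package = "ordmrp")) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant", "y", paste0("z", 1:4))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("joint table is missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$variant), function(p) {
    p <- p[order(p$y), ]
    if (!identical(p$y, 1:5) && !identical(as.integer(p$y), 1:5))
      stop("each panel needs rows y = 1..5 (shape error)")
    m <- as.matrix(p[, paste0("z", 1:4)])
    dimnames(m) <- list(paste0("y", 1:5), paste0("z", 1:4))
    m
  })
  out[order(match(names(out), c("domestic", "international")))]
}

#' Net-shift point estimates from printed joint panels
#'
#' The worked example: reads the 5 x 4 joint percentage panels (domestic and
#' international) and emits the per-group net shifts U_1..U_4, their total S,
#' and — when both variants are present — the domestic-minus-international
#' difference row.
#'
#' @param path panels CSV (see \code{\link{passport_joint_table}}); defaults
#'   to the bundled published panels.
#' @param out optional path to write the estimates as CSV.
#' @return data.frame with columns \code{variant}, \code{U1}..\code{U4},
#'   \code{S}.
#' @export
net_shift_from_panels <- function(path = NULL, out = NULL) {
  panels <- if (is.null(path)) passport_joint_table()
            else passport_joint_table(path)
  rows <- lapply(names(panels), function(v) {
    m <- panels[[v]]
    u <- vapply(1:4, function(k) compute_uk(m, k), numeric(1))
    data.frame(variant = v, U1 = u[1], U2 = u[2], U3 = u[3], U4 = u[4],
               S = sum(u))
  })
  res <- do.call(rbind, rows)
  if (all(c("domestic", "international") %in% res$variant)) {
    d <- res[res$variant == "domestic", -1] -
         res[res$variant == "international", -1]
    res <- rbind(res, cbind(data.frame(variant = "difference"), d))
  }
  rownames(res) <- NULL
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Run the full MRP pipeline from survey and census inputs
#'
#' Orchestrates load, exclusion of fully vaccinated respondents, the
#' baseline-intent fit Z|S, the intent-conditioned change fits Y|Z,S per
#' passport variant, the joint population distribution, and the net-shift
#' impact statistics (with the domestic-international contrast when both
#' variants run). Every stage failure aborts naming the stage; convergence
#' failures (split-Rhat >= 1.01) raise a warning naming the parameters.
#'
#' @param survey survey CSV path or pre-recoded records data.frame.
#' @param census census CSV path or strata table.
#' @param schemes named list of \code{\link{category_scheme}} objects.
#' @param variants subset of \code{c("domestic", "international")}.
#' @param mcmc list of sampler settings: \code{chains}, \code{warmup},
#'   \code{draws}, \code{seed}.
#' @param out_dir optional directory; when given, published-panel-shaped joint CSVs,
#'   an impact-report CSV and a diagnostics CSV are written, each with
#'   a header comment embedding seed, config hash and draw counts.
#' @param quiet suppress progress messages.
#' @return list with \code{records}, \code{strata}, \code{fit_z},
#'   \code{fits_y}, \code{joints}, \code{impacts} (incl. \code{difference}),
#'   \code{diagnostics} and \code{files}.
#' @export
run_mrp_pipeline <- function(survey, census, schemes = uk_schemes(),
                             variants = c("domestic", "international"),
                             mcmc = list(chains = 4, warmup = 500,
                                         draws = 1000, seed = 1),
                             out_dir = NULL, quiet = TRUE) {
  variants <- match.arg(variants, several.ok = TRUE)
  mcmc <- utils::modifyList(list(chains = 4, warmup = 500, draws = 1000,
                                 seed = 1), mcmc)
  if (is.null(mcmc$seed)) stop("stage config: mcmc$seed is mandatory")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  records <- stage("load_survey", {
    if (is.character(survey)) load_survey(survey, schemes) else survey
  })
  strata <- stage("load_census", {
    if (is.character(census)) read_census(census, schemes) else census
  })
  n0 <- nrow(records)
  records <- stage("exclude_fully_vaccinated",
                   exclude_fully_vaccinated(records, quiet = quiet))
  if (!quiet)
    message("pipeline: ", n0, " records loaded, ", nrow(records),
            " modelled after two-dose exclusion")
  fnames <- names(schemes)
  f_z <- stats::reformulate(fnames, response = "z")
  fit_z <- stage("fit_z_given_s",
                 ordmrp(f_z, records, schemes = schemes, random = "region",
                        n_levels = 4, chains = mcmc$chains,
                        warmup = mcmc$warmup, draws = mcmc$draws,
                        seed = mcmc$seed, quiet = TRUE))
  outc <- c(domestic = "y_dom", international = "y_int")
  fits_y <- list(); joints <- list(); impacts <- list()
  for (v in variants) {
    f_y <- stats::reformulate(c("z", fnames), response = outc[[v]])
    fits_y[[v]] <- stage(paste0("fit_y_given_zs_", v),
                         ordmrp(f_y, records, schemes = schemes,
                                random = "region", n_levels = 5,
                                chains = mcmc$chains, warmup = mcmc$warmup,
                                draws = mcmc$draws, seed = mcmc$seed + 1L,
                                quiet = TRUE))
    joints[[v]] <- stage(paste0("joint_distribution_", v),
                         joint_distribution(fits_y[[v]], fit_z, strata,
                                            variant = v))
    impacts[[v]] <- stage(paste0("impact_", v), impact_summary(joints[[v]]))
  }
  if (length(variants) == 2L)
    impacts$difference <- compute_delta_s(impacts$domestic,
                                          impacts$international)
  diag <- do.call(rbind, c(
    list(cbind(model = "z_given_s", fit_z$diagnostics)),
    lapply(variants, function(v)
      cbind(model = paste0("y_given_zs_", v), fits_y[[v]]$diagnostics))))
  bad <- diag$parameter[!is.na(diag$rhat) & diag$rhat >= 1.01]
  if (length(bad))
    warning("convergence: split-Rhat >= 1.01 for ",
            paste(utils::head(bad, 10), collapse = ", "),
            "; rerun with more draws")
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .run_header(mcmc, fit_z$draws$n_draws, variants)
    files <- c(
      vapply(variants, function(v) {
        p <- file.path(out_dir, paste0("joint_", v, ".csv"))
        write_joint_csv(joints[[v]], p, header = hdr)
      }, ""),
      impact = write_impact_csv(impacts, file.path(out_dir, "impact.csv"),
                                header = hdr),
      diagnostics = {
        p <- file.path(out_dir, "diagnostics.csv")
        con <- file(p, "w"); writeLines(paste0("# ", hdr), con)
        utils::write.csv(diag, con, row.names = FALSE); close(con)
        p
      })
  }
  list(records = records, strata = strata, fit_z = fit_z, fits_y = fits_y,
       joints = joints, impacts = impacts, diagnostics = diag,
       files = files)
}

.run_header <- function(mcmc, n_draws, variants) {
  cfg <- paste(deparse(mcmc[order(names(mcmc))]), collapse = "")
  tf <- tempfile(); writeLines(cfg, tf)
  h <- unname(tools::md5sum(tf)); unlink(tf)
  sprintf("ordmrp run seed=%d config_hash=%s chains=%d warmup=%d draws=%d variants=%s",
          mcmc$seed, h, mcmc$chains, mcmc$warmup, n_draws,
          paste(variants, collapse = "+"))
}

#' Write a joint distribution as a panel-shaped CSV
#'
#' 5 inclination rows x 4 intent columns plus both marginals, each cell
#' "mean [hpd_low, hpd_high]" in percent to 3 significant figures.
#'
#' @param joint an \code{\link{joint_distribution}} result.
#' @param path output path.
#' @param header optional header comment line(s).
#' @return the path, invisibly.
#' @export
write_joint_csv <- function(joint, path, header = NULL) {
  stopifnot(inherits(joint, "ordmrp_joint"))
  sm <- joint$summary
  mg <- marginals(joint)
  fmt <- function(m, lo, hi)
    sprintf("%s [%s, %s]", signif(m, 3), signif(lo, 3), signif(hi, 3))
  cells <- matrix(fmt(sm$mean, sm$hpd_low, sm$hpd_high),
                  nrow(sm$mean), ncol(sm$mean))
  rowm <- fmt(mg$rows_summary[, "mean"], mg$rows_summary[, "lower"],
              mg$rows_summary[, "upper"])
  colm <- fmt(mg$cols_summary[, "mean"], mg$cols_summary[, "lower"],
              mg$cols_summary[, "upper"])
  df <- data.frame(change_in_inclination = c(paste0("y", 1:nrow(cells)),
                                             "total_intent"),
                   rbind(cbind(cells, rowm),
                         c(colm, "100")), check.names = FALSE)
  names(df)[-1] <- c(paste0("z", seq_len(ncol(cells))), "total_change")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste0("# joint distribution, ", joint$variant, " variant"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write impact summaries as an impact-report CSV
#'
#' One row per variant (plus the difference row when present), columns
#' U1..U4 and S, each "mean [hpd_low, hpd_high]".
#'
#' @param impacts named list of \code{\link{impact_summary}} /
#'   \code{\link{compute_delta_s}} objects.
#' @param path output path.
#' @param header optional header comment line(s).
#' @return the path, invisibly.
#' @export
write_impact_csv <- function(impacts, path, header = NULL) {
  rows <- lapply(names(impacts), function(v) {
    sm <- impacts[[v]]$summary
    vals <- sprintf("%s [%s, %s]", signif(sm$mean, 3),
                    signif(sm$hpd_low, 3), signif(sm$hpd_high, 3))
    stats::setNames(data.frame(v, as.list(vals), stringsAsFactors = FALSE),
                    c("variant", sm$statistic))
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
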