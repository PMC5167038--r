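#' Mast-cycle phase of a trapping year
#'
#' In a masting-driven rodent cycle the population peaks in the first summer
#' after a mast autumn (FSA) and crashes in the second (SSA). A year is FSA
#' when the previous autumn was a mast year, and SSA when the autumn two
#' years back was a mast year and the previous one was not.
#'
#' @param year trapping year(s), vectorised.
#' @param mast_years integer vector of mast autumn years.
#' @return Character vector `"FSA"` / `"SSA"`, `NA` where neither applies.
#' @examples
#' mast_phase(2010:2013, c(2009, 2011))  # FSA SSA FSA SSA
#' @export
mast_phase <- function(year, mast_years) {
  stopifnot(is.numeric(year), is.numeric(mast_years))
  ifelse((year - 1) %in% mast_years, "FSA",
         ifelse((year - 2) %in% mast_years, "SSA", NA_character_))
}

#' Assemble space-use records from per-session SECR estimates
#'
#' Joins per-session `(D, sigma)` estimates with the mast calendar into the
#' record table the mixed-model stage consumes: one row per
#' (site, year, month, sex) with a converged fit. Non-converged fits are
#' dropped with a message; a year the mast calendar cannot classify is an
#' error.
#'
#' @param fits data frame with columns `site`, `year`, `month`, `sex`,
#'   `D_hat`, `sigma_hat` and optionally `converged` (default `TRUE`).
#' @param mast_years mast autumn years (see [mast_phase()]).
#' @return Data frame of space-use records with a `phase` column; zero rows
#'   in, zero rows out.
#' @export
assemble_records <- function(fits, mast_years) {
  stopifnot(is.data.frame(fits))
  if (nrow(fits) == 0)
    return(data.frame(site = character(), year = integer(), month = integer(),
                      sex = character(), phase = character(),
                      D_hat = numeric(), sigma_hat = numeric()))
  need <- c("site", "year", "month", "sex", "D_hat", "sigma_hat")
  if (!all(need %in% names(fits)))
    stop("'fits' needs columns: ", paste(need, collapse = ", "))
  conv <- if ("converged" %in% names(fits)) fits$converged else TRUE
  if (any(!conv))
    message(sum(!conv), " non-converged fit(s) dropped")
  out <- fits[conv, need, drop = FALSE]
  out$phase <- mast_phase(out$year, mast_years)
  if (any(is.na(out$phase)))
    stop("mast calendar does not classify year(s): ",
         paste(unique(out$year[is.na(out$phase)]), collapse = ", "))
  stopifnot(all(out$D_hat > 0), all(out$sigma_hat > 0))
  rownames(out) <- NULL
  out[c("site", "year", "month", "sex", "phase", "D_hat", "sigma_hat")]
}

#' Gaussian mixed models for density and space use
#'
#' The two second-stage models, fitted by maximum likelihood with
#' [lme4::lmer()] and a random intercept per study site:
#' \describe{
#'   \item{`density_model`}{`log(D) ~ phase * sex + month_c + (1 | site)` —
#'     does density differ by mast-cycle phase and sex?}
#'   \item{`sigma_model`}{`log(sigma) ~ (log(D) + phase + sex)^2 + month_c +
#'     (1 | site)` — does space use, after controlling for density, differ
#'     by phase and sex?}
#' }
#' Month enters as a centred numeric covariate (June = 6 ... September = 9,
#' centred on its mean). Reference levels are phase = SSA and sex = female,
#' so the `phase` main effect reads as the FSA offset. Point estimates of
#' `D` and `sigma` are taken as data; their estimation uncertainty is not
#' propagated.
#'
#' Under constant within-phase overlap k the generating relation is
#' `log sigma = log(100 k_phase) - 0.5 log D`, so the sigma model's `log(D)`
#' coefficient has -0.5 as its reference value and its `phase` coefficient
#' measures `log(k_FSA / k_SSA)`.
#'
#' @param records data frame from [assemble_records()].
#' @param formula_id `"density_model"` or `"sigma_model"`.
#' @return An `lmm_result`: the `lmerMod` fit plus extracted fixed effects,
#'   covariance, variance components and a boundary flag (random-intercept
#'   variance estimated at zero).
#' @export
fit_lmm <- function(records, formula_id = c("density_model", "sigma_model")) {
  formula_id <- match.arg(formula_id)
  stopifnot(is.data.frame(records), nrow(records) >= 4)
  d <- records
  d$site <- factor(d$site)
  if (nlevels(d$site) < 2) stop("need >= 2 sites for a site random effect")
  d$phase <- stats::relevel(factor(d$phase), ref = "SSA")
  d$sex <- stats::relevel(factor(d$sex), ref = "female")
  d$month_c <- d$month - mean(d$month)
  d$logD <- log(d$D_hat)
  d$logsigma <- log(d$sigma_hat)
  fml <- switch(formula_id,
    density_model = logD ~ phase * sex + month_c + (1 | site),
    sigma_model = logsigma ~ (logD + phase + sex)^2 + month_c + (1 | site))
  fit <- lme4::lmer(fml, data = d, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  X <- stats::model.matrix(lme4::nobars(fml), data = d)
  if (qr(X)$rank < ncol(X)) {
    ali <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(ali, collapse = ", "))
  }
  vcs <- as.data.frame(lme4::VarCorr(fit))
  site_var <- vcs$vcov[vcs$grp == "site"]
  structure(list(model = fit, formula_id = formula_id,
                 coefficients = lme4::fixef(fit),
                 vcov = as.matrix(stats::vcov(fit)),
                 site_variance = site_var,
                 residual_variance = stats::sigma(fit)^2,
                 boundary = isTRUE(site_var < 1e-8),
                 data = d),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Gaussian mixed model (ML):", x$formula_id, "\n")
  cat(sprintf("  site variance %.4g%s, residual variance %.4g\n",
              x$site_variance, if (x$boundary) " (boundary)" else "",
              x$residual_variance))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Wald Type II tests of fixed-effect terms
#'
#' Type II Wald chi-square tests: each term is tested adjusted for all
#' others except higher-order terms that contain it, using the ML
#' fixed-effect covariance.
#'
#' @param fit an `lmm_result` from [fit_lmm()].
#' @param term optional term name (as printed in the table) to extract a
#'   single row; an unknown term is an error.
#' @return Data frame with columns `term`, `chisq`, `df`, `p` (all terms),
#'   or the single requested row.
#' @export
wald_type2 <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "lmm_result"))
  a <- car::Anova(fit$model, type = "II", test.statistic = "Chisq")
  out <- data.frame(term = rownames(a), chisq = a$Chisq, df = a$Df,
                    p = a[["Pr(>Chisq)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(term)) {
    i <- match(term, out$term)
    if (is.na(i)) stop("term not in model: ", term,
                       " (available: ", paste(out$term, collapse = ", "), ")")
    out <- out[i, , drop = FALSE]
  }
  out
}
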