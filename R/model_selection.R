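#' Candidate SECR model structures
#'
#' The default candidate set crosses density and spatial-scale structure
#' (constant vs. session-specific) with three baseline-hazard structures:
#' constant, session-specific, and constant with a global behavioural
#' response — 2 x 2 x 3 = 12 models in a fixed, deterministic order. This is
#' one reading of a "12 models, all combinations of three parameters"
#' design; a fully crossed 4-level lambda0 axis would give 16 and a 2-level
#' one 8, so the builder also accepts any user-supplied list of
#' [model_spec()]s wherever a model set is consumed.
#'
#' @return A list of 12 [model_spec()] objects, no duplicates.
#' @export
enumerate_models <- function() {
  out <- list()
  for (dd in c("constant", "session"))
    for (ss in c("constant", "session"))
      for (ll in list(c("constant", FALSE), c("session", FALSE),
                      c("constant", TRUE)))
        out[[length(out) + 1L]] <- model_spec(d = dd, sigma = ss,
                                              lambda0 = ll[[1]],
                                              behavioral = as.logical(ll[[2]]))
  out
}

#' Akaike's information criterion with small-sample correction
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param K number of estimated parameters (>= 1).
#' @param n effective sample size. For SECR fits the convention used
#'   throughout this package is the number of distinct individuals detected.
#' @return The AICc value; always `>= AIC`, converging to it as `n` grows.
#' @examples
#' aicc(-100, K = 3, n = 50)  # 206.5217
#' @export
aicc <- function(loglik, K, n) {
  stopifnot(is.numeric(loglik), is.numeric(K), is.numeric(n), K >= 1)
  if (n <= K + 1)
    stop("small-sample error: AICc requires n > K + 1 (n = ", n,
         ", K = ", K, ")")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`; interpretable as the weight of evidence
#' in favour of each model within the candidate set.
#'
#' @param aicc_values numeric vector of AICc (or AIC) values; `Inf` allowed,
#'   `NA` propagated as zero weight.
#' @return Weights summing to 1 over the finite entries.
#' @examples
#' round(akaike_weights(c(0, 3.60, 57.71, 100.32, 111.84)), 2)
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(is.numeric(aicc_values), length(aicc_values) >= 1)
  v <- ifelse(is.na(aicc_values), Inf, aicc_values)
  if (all(!is.finite(v))) stop("no finite AICc values")
  delta <- v - min(v)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Evidence ratio between two models
#'
#' The ratio of Akaike weights `w_i / w_j`, equal to
#' `exp((Delta_j - Delta_i) / 2)` when both come from the same table.
#'
#' @param w_i,w_j Akaike weights.
#' @return The ratio; `Inf` (with a warning) when `w_j` is zero.
#' @export
evidence_ratio <- function(w_i, w_j) {
  stopifnot(is.numeric(w_i), is.numeric(w_j), w_i >= 0, w_j >= 0)
  if (any(w_j == 0)) {
    warning("zero weight in denominator; evidence ratio is infinite")
  }
  w_i / w_j
}

#' AICc ranking table for a set of SECR fits
#'
#' Ranks fits by AICc and attaches delta-AICc and Akaike weights. Fits whose
#' effective sample size fails the AICc requirement `n > K + 1` are excluded
#' from the ranking with a warning. Ties are broken by fewer parameters,
#' then by input order.
#'
#' @param fits list of `secr_fit` objects (or any objects with `loglik`,
#'   `K_params`, `n_individuals`, `spec`, `converged` fields).
#' @param n effective sample size; defaults to each fit's own
#'   `n_individuals` (distinct detected animals).
#' @return A `model_table` data frame sorted by AICc: model label, structure
#'   columns, K, logLik, AICc, dAICc, weight.
#' @export
model_table <- function(fits, n = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ns <- if (is.null(n)) f$n_individuals else n
    data.frame(model = spec_label(f$spec),
               lambda0 = paste0(if (f$spec$lambda0 == "session") "session" else "(.)",
                                if (f$spec$behavioral) " + b" else ""),
               D = f$spec$d, sigma = f$spec$sigma,
               K = f$K_params, n = ns, logLik = f$loglik,
               converged = f$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$n > tab$K + 1
  if (any(!ok))
    warning(sum(!ok), " model(s) excluded from ranking: n <= K + 1")
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rankable models (all fail n > K + 1)")
  tab$AICc <- mapply(aicc, tab$logLik, tab$K, tab$n)
  ord <- order(tab$AICc, tab$K, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$AICc)
  rownames(tab) <- NULL
  structure(tab, class = c("model_table", "data.frame"))
}

#' Fit a set of candidate SECR model structures
#'
#' Convenience wrapper: fits every spec in `specs` to the same sessions and
#' returns the fits plus their [model_table()].
#'
#' @inheritParams fit_secr
#' @param specs list of [model_spec()]s; default [enumerate_models()].
#' @param ... passed to [fit_secr()].
#' @return List with elements `fits` and `table`.
#' @export
fit_model_set <- function(sessions, traps, mask, specs = enumerate_models(),
                          ...) {
  fits <- lapply(specs, function(sp)
    fit_secr(sessions, traps, mask, spec = sp, ...))
  list(fits = fits, table = model_table(fits))
}
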