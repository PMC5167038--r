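#' Capture session constructor
#'
#' One site-month trapping bout, treated by the likelihood as an independent
#' population sample: `K` occasions (trap-nights) over a fixed trap array,
#' with one record per capture. An animal can occupy at most one multi-catch
#' trap per occasion, so duplicate `(animal_id, occasion)` pairs are
#' rejected.
#'
#' @param session_id label, conventionally `"site-year-month"`.
#' @param n_occasions number of occasions (>= 1; study designs typically use
#'   5 consecutive nights).
#' @param records data frame with columns `animal_id`, `occasion` (1-based),
#'   `trap_id`. May have zero rows (no animals detected).
#' @return A `capture_session` object.
#' @export
capture_session <- function(session_id, n_occasions, records) {
  stopifnot(length(session_id) == 1L, is.numeric(n_occasions),
            n_occasions >= 1, is.data.frame(records))
  need <- c("animal_id", "occasion", "trap_id")
  if (!all(need %in% names(records)))
    stop("'records' needs columns: ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[need]
  if (nrow(records) > 0) {
    occ <- records$occasion
    if (any(occ != as.integer(occ)) || any(occ < 1) || any(occ > n_occasions))
      stop("occasion indices must be integers in 1..n_occasions")
    dup <- duplicated(records[c("animal_id", "occasion")])
    if (any(dup))
      stop("duplicate (animal_id, occasion) pairs: an animal occupies at ",
           "most one trap per occasion (rows ",
           paste(which(dup), collapse = ", "), ")")
  }
  structure(list(session_id = as.character(session_id),
                 n_occasions = as.integer(n_occasions),
                 records = records),
            class = "capture_session")
}

#' @export
print.capture_session <- function(x, ...) {
  cat(sprintf("Capture session %s: %d occasions, %d captures of %d animals\n",
              x$session_id, x$n_occasions, nrow(x$records),
              length(unique(x$records$animal_id))))
  invisible(x)
}

# Per-animal sufficient statistics of a session's capture histories.
# With the half-normal hazard shared across occasions, an animal's history
# likelihood at centre x depends only on: its per-trap capture counts, the
# occasion of first capture (u1 = occasions uncaught before it) and the
# post-first-capture split into c2 recaptures and u2 uncaught occasions.
session_comp <- function(session, traps) {
  stopifnot(inherits(session, "capture_session"), inherits(traps, "trap_array"))
  rec <- session$records
  K <- session$n_occasions
  if (nrow(rec) == 0)
    return(list(n = 0L, K = K))
  ti <- match(rec$trap_id, traps$trap_id)
  if (anyNA(ti))
    stop("session ", session$session_id, ": capture records reference ",
         "unknown traps: ", paste(unique(rec$trap_id[is.na(ti)]), collapse = ", "))
  ids <- unique(rec$animal_id)
  ai <- match(rec$animal_id, ids)
  n <- length(ids)
  Tn <- nrow(traps)
  # per-animal per-trap capture counts (an animal may reuse a trap)
  Nik <- matrix(tabulate(ai + n * (ti - 1L), nbins = n * Tn), n, Tn)
  f <- tapply(rec$occasion, ai, min)[as.character(seq_len(n))]
  f <- as.numeric(f)
  ctot <- rowSums(Nik)
  c2 <- ctot - 1
  u1 <- f - 1
  u2 <- (K - f) - c2
  stopifnot(all(u2 >= -1e-9))
  list(n = n, K = K, ids = ids, Nik = Nik, ctot = ctot, c2 = c2,
       u1 = u1, u2 = u2)
}

# Detection-field quantities shared by all sessions with the same
# (lambda0, sigma): log-hazard matrix over mask x traps and derived vectors.
# W = sum_k h_k * d_k^2 drives the sigma derivative of H.
hazard_field <- function(d2, lambda0, sigma, grad = FALSE) {
  logh <- log(lambda0) - d2 / (2 * sigma^2)
  hmat <- exp(logh)
  H <- pmax(rowSums(hmat), 1e-300)
  out <- list(logh = logh, H = H, logH = log(H), l1 = log(-expm1(-H)),
              lambda0 = lambda0, sigma = sigma)
  if (grad) {
    out$W <- rowSums(hmat * d2)
    out$g1 <- 1 / expm1(H)            # d l1 / dH = e^-H / (1 - e^-H)
  }
  out
}

# Negative log-likelihood of one session given precomputed pieces.
# Full (Poisson-n) form, including the log(n!) constant:
#   -log L = D*a - n*log D - sum_i log[ cell * sum_m Pr(w_i | x_m) ] + log n!
# with a = cell * sum_m (1 - exp(-K * H(x_m))).
session_nll_core <- function(comp, fld, cell, D, b) {
  pd <- -expm1(-comp$K * fld$H)
  a <- cell * sum(pd)
  n <- comp$n
  out <- D * a - n * log(D) + lgamma(n + 1)
  if (n == 0L) return(out)
  l1b <- if (b == 1) fld$l1 else log(-expm1(-b * fld$H))
  # log Pr(w_i | x_m): captures contribute log h_k - log H + log(1 - e^-H')
  # (H' naive at first capture, b*H after), uncaught occasions -H or -b*H
  A <- tcrossprod(comp$Nik, fld$logh)             # n x M: sum of log h over captures
  Cf <- cbind(-comp$ctot, rep(1, n), comp$c2, -(comp$u1 + b * comp$u2))
  V <- rbind(fld$logH, fld$l1, l1b, fld$H)
  A <- A + Cf %*% V
  mc <- max.col(A)
  rmax <- A[cbind(seq_len(n), mc)]
  lse <- rmax + log(rowSums(exp(A - rmax)))
  out - sum(lse) - n * log(cell)
}

# Negative log-likelihood of one session together with its gradient with
# respect to (D, sigma, lambda0, b) on the natural scale. Requires a field
# built with grad = TRUE and the squared-distance matrix used to build it.
session_nll_grad <- function(comp, fld, d2, cell, D, b) {
  H <- fld$H; K <- comp$K; n <- comp$n
  sig <- fld$sigma; lam <- fld$lambda0
  eKH <- exp(-K * H)
  a <- cell * sum(-expm1(-K * H))
  # d a / dH_m = cell * K * e^{-K H}; dH/dlam = H/lam; dH/dsig = W/sig^3
  daH <- cell * K * eKH
  da_lam <- sum(daH * H) / lam
  da_sig <- sum(daH * fld$W) / sig^3
  val <- D * a - n * log(D) + lgamma(n + 1)
  g <- c(D = a - n / D, sigma = D * da_sig, lambda0 = D * da_lam, b = 0)
  if (n == 0L) return(list(value = val, grad = g))
  g2 <- b / expm1(b * H)              # d l1b / dH
  l1b <- if (b == 1) fld$l1 else log(-expm1(-b * H))
  A <- tcrossprod(comp$Nik, fld$logh)
  Cf <- cbind(-comp$ctot, rep(1, n), comp$c2, -(comp$u1 + b * comp$u2))
  V <- rbind(fld$logH, fld$l1, l1b, H)
  A <- A + Cf %*% V
  mc <- max.col(A)
  rmax <- A[cbind(seq_len(n), mc)]
  E <- exp(A - rmax)
  rs <- rowSums(E)
  val <- val - sum(rmax + log(rs)) - n * log(cell)
  Wgt <- E / rs                       # n x M posterior weights over mask
  # common per-(i, m) factor multiplying dH: g1 + c2_i * g2 - (u1_i + b u2_i)
  Fcom <- outer(rep(1, n), fld$g1) + outer(comp$c2, g2) -
    (comp$u1 + b * comp$u2)
  # dA/dlam = Fcom * H / lam (the capture-count and logH terms cancel)
  g["lambda0"] <- g["lambda0"] - sum(Wgt * sweep(Fcom, 2, H / lam, "*"))
  # dA/dsig = [sum_k N d^2 - ctot * W / H] / sig^3 + Fcom * W / sig^3
  Nd2 <- tcrossprod(comp$Nik, d2)
  dA_sig <- (Nd2 - outer(comp$ctot, fld$W / H)) / sig^3 +
    sweep(Fcom, 2, fld$W / sig^3, "*")
  g["sigma"] <- g["sigma"] - sum(Wgt * dA_sig)
  # dA/db = c2_i * H * e^{-bH}/(1 - e^{-bH}) - u2_i * H = c2_i*H*g2/b - u2_i*H
  dA_b <- outer(comp$c2, H * g2 / b) - outer(comp$u2, H)
  g["b"] <- g["b"] - sum(Wgt * dA_b)
  list(value = val, grad = g)
}

#' SECR negative log-likelihood of one session
#'
#' Evaluates the full (Poisson) spatially explicit capture-recapture negative
#' log-likelihood for one session over a habitat mask, under a half-normal
#' multi-catch detection model with uniform-Poisson activity centres at
#' density `D`. Only detected animals appear in the data; the likelihood
#' integrates each capture history over the mask and thins the Poisson
#' intensity by the probability of at least one detection.
#'
#' The `-log(n!)` constant is included, so values are comparable across
#' model structures.
#'
#' @param session a [capture_session()].
#' @param traps the session's [trap_array()].
#' @param mask a [build_mask()] habitat mask.
#' @param D density in animals per hectare (> 0).
#' @param params a [detection_params()].
#' @return The negative log-likelihood (finite, including for n = 0, where
#'   it equals `D` times the effective sampled area).
#' @export
secr_nll <- function(session, traps, mask, D, params) {
  stopifnot(inherits(mask, "secr_mask"), inherits(params, "detection_params"))
  if (!is.numeric(D) || length(D) != 1L || D <= 0) stop("'D' must be > 0")
  if (nrow(mask) == 0) stop("empty mask")
  comp <- session_comp(session, traps)
  fld <- hazard_field(trap_dist2(mask, traps), params$lambda0, params$sigma)
  session_nll_core(comp, fld, attr(mask, "cell_area"), D, params$b_mult)
}

#' SECR model structure
#'
#' Which parameters are shared across sessions and which vary: density `D`,
#' spatial scale `sigma` and baseline hazard `lambda0` can each be constant
#' or session-specific, and `lambda0` can additionally carry a global
#' behavioural response (a multiplicative change after an animal's first
#' capture within a session).
#'
#' @param d,sigma,lambda0 `"constant"` or `"session"`.
#' @param behavioral logical; include the behavioural multiplier `b_mult`?
#' @return A `secr_model_spec` object.
#' @export
model_spec <- function(d = "constant", sigma = "constant",
                       lambda0 = "constant", behavioral = FALSE) {
  d <- match.arg(d, c("constant", "session"))
  sigma <- match.arg(sigma, c("constant", "session"))
  lambda0 <- match.arg(lambda0, c("constant", "session"))
  stopifnot(is.logical(behavioral), length(behavioral) == 1L)
  structure(list(d = d, sigma = sigma, lambda0 = lambda0,
                 behavioral = behavioral),
            class = "secr_model_spec")
}

#' @export
format.secr_model_spec <- function(x, ...) {
  lam <- if (x$lambda0 == "session") "session" else "(.)"
  if (x$behavioral) lam <- paste(lam, "+ b")
  sprintf("D ~ %s, sigma ~ %s, lambda0 ~ %s", x$d, x$sigma, lam)
}

#' @export
print.secr_model_spec <- function(x, ...) {
  cat("SECR model:", format(x), "\n")
  invisible(x)
}

spec_label <- function(spec) format(spec)

#' Fit a SECR model by maximum likelihood
#'
#' Maximises the summed session negative log-likelihoods over parameters
#' structured according to `spec`. All parameters are log-transformed
#' internally and optimised with BFGS; Wald standard errors come from the
#' inverse observed information (numerical Hessian at the optimum).
#'
#' Sessions are modelled as independent populations sharing parameters only
#' through the model structure; identities are not linked across sessions.
#'
#' @param sessions a [capture_session()] or list of them (one trap array and
#'   mask shared by all).
#' @param traps the [trap_array()].
#' @param mask a [build_mask()] habitat mask.
#' @param spec a [model_spec()].
#' @param start optional named list overriding starting values (`D`, `sigma`,
#'   `lambda0`, `b_mult`, natural scale).
#' @param control passed to [stats::optim()] (defaults: BFGS,
#'   `reltol = 1e-8`, `maxit = 500`).
#' @return A `secr_fit` object: log-scale estimates and SEs, per-session
#'   expansion of `(D, sigma, lambda0, b_mult)`, maximised log-likelihood,
#'   parameter count, number of detected individuals and a convergence flag.
#' @examples
#' \donttest{
#' tr <- make_grid(6, 6, 10)
#' msk <- build_mask(tr, buffer = 80, spacing = 20)
#' set.seed(1)
#' sim <- simulate_session(D = 20, detection_params(0.5, 12), tr, K = 5)
#' fit_secr(sim$session, tr, msk)
#' }
#' @export
fit_secr <- function(sessions, traps, mask, spec = model_spec(),
                     start = NULL, control = list()) {
  if (inherits(sessions, "capture_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1, inherits(mask, "secr_mask"),
            inherits(spec, "secr_model_spec"))
  S <- length(sessions)
  ids <- vapply(sessions, `[[`, "", "session_id")
  comps <- lapply(sessions, session_comp, traps = traps)
  nvec <- vapply(comps, `[[`, 0L, "n")
  if (spec$d == "session" && any(nvec == 0L))
    stop("degenerate session(s) with no detected animals under ",
         "session-specific D: ", paste(ids[nvec == 0L], collapse = ", "))
  if (sum(nvec) == 0L) stop("no detected animals in any session")

  d_idx <- if (spec$d == "session") seq_len(S) else rep(1L, S)
  s_idx <- if (spec$sigma == "session") seq_len(S) else rep(1L, S)
  l_idx <- if (spec$lambda0 == "session") seq_len(S) else rep(1L, S)
  nD <- max(d_idx); nSg <- max(s_idx); nL <- max(l_idx)
  nb <- as.integer(spec$behavioral)
  npar <- nD + nSg + nL + nb

  d2 <- trap_dist2(mask, traps)
  cell <- attr(mask, "cell_area")

  # starting values: sigma from half the mean recapture displacement
  # (fallback half the mask spacing), lambda0 = 0.3, and D from detected
  # counts over the effective sampled area those detection values imply --
  # starting from n / (total mask area) instead routinely lands BFGS in a
  # poor basin on sparse sessions
  sv <- list(D = NULL, sigma = NULL, lambda0 = 0.3, b_mult = 1)
  disp <- unlist(lapply(seq_len(S), function(s) {
    rec <- sessions[[s]]$records
    if (nrow(rec) < 2) return(numeric(0))
    sp <- split(rec$trap_id, rec$animal_id)
    unlist(lapply(sp, function(tid) {
      if (length(tid) < 2) return(numeric(0))
      i <- match(tid, traps$trap_id)
      sqrt(diff(traps$x[i])^2 + diff(traps$y[i])^2)
    }))
  }))
  sig0 <- if (length(disp) && mean(disp) > 0) mean(disp) / 2
          else 0.5 * attr(mask, "spacing")
  sv$sigma <- rep(sig0, nSg)
  sv$lambda0 <- rep(sv$lambda0, nL)
  Kbar <- round(mean(vapply(sessions, `[[`, 0L, "n_occasions")))
  esa0 <- cell * sum(pdot(as.matrix(mask[c("x", "y")]), traps,
                          detection_params(0.3, sig0), Kbar))
  sv$D <- vapply(seq_len(nD), function(g)
    max(mean(nvec[d_idx == g]), 0.5) / max(esa0, cell), 0)
  if (!is.null(start)) for (nm in names(start)) sv[[nm]] <- rep(start[[nm]],
    length.out = length(sv[[nm]]))
  par0 <- log(c(sv$D, sv$sigma, sv$lambda0, if (nb) sv$b_mult))

  split_par <- function(p) list(
    D = exp(p[seq_len(nD)]),
    sigma = exp(p[nD + seq_len(nSg)]),
    lambda0 = exp(p[nD + nSg + seq_len(nL)]),
    b = if (nb) exp(p[npar]) else 1)

  # sessions sharing a (sigma, lambda0) group share the hazard field;
  # value and analytic gradient are computed together and cached so optim's
  # fn/gr pair costs one evaluation
  combo <- interaction(s_idx, l_idx, drop = TRUE)
  combo_first <- match(levels(combo), combo)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    if (!is.null(cache$p) && identical(p, cache$p)) return(cache$res)
    th <- split_par(p)
    flds <- lapply(combo_first, function(s)
      hazard_field(d2, th$lambda0[l_idx[s]], th$sigma[s_idx[s]], grad = TRUE))
    val <- 0
    gr <- numeric(npar)
    for (s in seq_len(S)) {
      fld <- flds[[as.integer(combo[s])]]
      sg <- session_nll_grad(comps[[s]], fld, d2, cell, th$D[d_idx[s]], th$b)
      val <- val + sg$value
      # chain rule to the log scale: d/d log(theta) = theta * d/d theta
      gr[d_idx[s]] <- gr[d_idx[s]] + sg$grad["D"] * th$D[d_idx[s]]
      gr[nD + s_idx[s]] <- gr[nD + s_idx[s]] +
        sg$grad["sigma"] * th$sigma[s_idx[s]]
      gr[nD + nSg + l_idx[s]] <- gr[nD + nSg + l_idx[s]] +
        sg$grad["lambda0"] * th$lambda0[l_idx[s]]
      if (nb) gr[npar] <- gr[npar] + sg$grad["b"] * th$b
    }
    if (!is.finite(val)) {
      val <- 1e10
      gr <- rep(0, npar)
    }
    cache$p <- p
    cache$res <- list(value = val, grad = gr)
    cache$res
  }
  nll <- function(p) evaluate(p)$value
  nll_gr <- function(p) evaluate(p)$grad

  ctrl <- modifyList(list(reltol = 1e-8, maxit = 500), control)
  opt <- stats::optim(par0, nll, gr = nll_gr, method = "BFGS",
                      control = ctrl, hessian = TRUE)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, npar) else {
    dg <- diag(vc)
    ifelse(dg >= 0, sqrt(pmax(dg, 0)), NA_real_)
  }

  grp <- function(struct, idx) if (struct == "session") ids else "all"
  pnames <- c(paste0("D.", grp(spec$d, d_idx)),
              paste0("sigma.", grp(spec$sigma, s_idx)),
              paste0("lambda0.", grp(spec$lambda0, l_idx)),
              if (nb) "b_mult")
  est <- data.frame(parameter = c(rep("D", nD), rep("sigma", nSg),
                                  rep("lambda0", nL), if (nb) "b_mult"),
                    group = sub("^[^.]*\\.", "", sub("^b_mult$", "b_mult.all", pnames)),
                    log_estimate = opt$par, log_se = se,
                    estimate = exp(opt$par),
                    stringsAsFactors = FALSE)
  th <- split_par(opt$par)
  sess_est <- data.frame(session_id = ids, n = nvec,
                         D = th$D[d_idx], sigma = th$sigma[s_idx],
                         lambda0 = th$lambda0[l_idx],
                         b_mult = rep(th$b, S),
                         stringsAsFactors = FALSE)
  structure(list(estimates = est, session_estimates = sess_est,
                 loglik = -opt$value, K_params = npar,
                 n_individuals = sum(nvec),
                 converged = opt$convergence == 0L,
                 spec = spec, vcov_log = vc, optim = opt[c("convergence", "counts")]),
            class = "secr_fit")
}

#' @export
print.secr_fit <- function(x, ...) {
  cat("SECR fit:", format(x$spec), "\n")
  cat(sprintf("  %d sessions, %d individuals, logLik %.3f, %d parameters%s\n",
              nrow(x$session_estimates), x$n_individuals, x$loglik,
              x$K_params, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$estimates, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-session parameter estimates from a SECR fit
#'
#' @param fit a `secr_fit`.
#' @return Data frame with one row per session: `session_id`, `n` (animals
#'   detected), `D`, `sigma`, `lambda0`, `b_mult`.
#' @export
session_estimates <- function(fit) {
  stopifnot(inherits(fit, "secr_fit"))
  fit$session_estimates
}

#' Wald confidence intervals on the natural scale
#'
#' Log-scale Wald intervals, exponentiated, so bounds are always positive.
#'
#' @param fit a converged `secr_fit`.
#' @param level coverage (default 0.95).
#' @return Data frame: parameter, group, estimate, lower, upper.
#' @export
param_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "secr_fit"), level > 0, level < 1)
  if (!fit$converged) stop("fit did not converge; intervals not available")
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$estimates
  data.frame(parameter = est$parameter, group = est$group,
             estimate = est$estimate,
             lower = exp(est$log_estimate - z * est$log_se),
             upper = exp(est$log_estimate + z * est$log_se),
             stringsAsFactors = FALSE)
}
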