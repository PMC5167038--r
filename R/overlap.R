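#' Home-range overlap index k
#'
#' `k = sigma * sqrt(D)` in consistent units. With `D` in animals per
#' hectare and `sigma` in metres, `k = sigma * sqrt(D) / 100` (converting D
#' to animals per square metre), which makes `k` dimensionless: constant `k`
#' means home-range size scales with density as `sigma ~ D^-0.5`, i.e. a
#' fixed degree of overlap between neighbouring home ranges.
#'
#' @param D density in animals/ha (>= 0, vectorised).
#' @param sigma spatial scale of detection in metres (> 0, vectorised).
#' @return k (dimensionless), zero iff `D` is zero.
#' @examples
#' k_index(1, 100)        # 1: one animal/ha, 100-m scale
#' k_index(22.4, 11.4)    # ~0.54, a post-mast peak value
#' @export
k_index <- function(D, sigma) {
  stopifnot(is.numeric(D), is.numeric(sigma))
  if (any(D < 0)) stop("'D' must be non-negative")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  sigma * sqrt(D) / 100
}

#' Expected neighbours within a 95% home range
#'
#' `S95 = 6 * pi * k^2`: the expected number of individuals whose activity
#' centres fall inside one animal's 95% home-range area, under the
#' half-normal model (the 95% range is a circle of radius sqrt(6) * sigma).
#'
#' @param k overlap index from [k_index()] (>= 0, vectorised).
#' @return S95 (individuals), strictly increasing in `k`.
#' @examples
#' s95(1)     # 6 * pi
#' s95(0.54)  # ~5.5
#' @export
s95 <- function(k) {
  stopifnot(is.numeric(k))
  if (any(k < 0)) stop("'k' must be non-negative")
  6 * pi * k^2
}

#' Phase-level mean and standard error
#'
#' Arithmetic mean and standard error of the mean of session-level values
#' within each phase label (order-invariant).
#'
#' @param values numeric session-level values (e.g. per-session k).
#' @param phase phase label per value (e.g. `"FSA"` / `"SSA"`).
#' @return Data frame: phase, mean, se, n. SE requires >= 2 values per
#'   phase; empty phases are an error.
#' @export
phase_average <- function(values, phase) {
  stopifnot(is.numeric(values), length(values) == length(phase))
  phase <- as.character(phase)
  if (any(is.na(phase)) || length(values) == 0) stop("empty or missing phase labels")
  sp <- split(values, phase)
  out <- data.frame(phase = names(sp),
                    mean = vapply(sp, mean, 0),
                    se = vapply(sp, function(v)
                      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
                    n = lengths(sp), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-session overlap statistics with phase summaries
#'
#' Computes the overlap index `k` and neighbour count `S95` for each row of
#' per-session density/scale estimates, then phase-level summaries by sex.
#' Phase-level S95 is reported both ways: transformed from the phase-mean k
#' (`6 * pi * mean(k)^2`) and as the phase mean of per-session S95 values —
#' the two differ by a Jensen gap whenever k varies within a phase, so both
#' conventions are exposed.
#'
#' @param records data frame with columns `session_id` (or `site`, `year`,
#'   `month`), `sex`, `phase`, `D_hat`, `sigma_hat`.
#' @return A list: `per_session` (input plus `k`, `S95`), `phase_k`
#'   (mean +/- SE of k by phase and sex) and `phase_S95` (both conventions).
#' @export
overlap_stats <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sex", "phase", "D_hat", "sigma_hat") %in% names(records)))
  per <- records
  per$k <- k_index(per$D_hat, per$sigma_hat)
  per$S95 <- s95(per$k)
  grp <- interaction(per$phase, per$sex, sep = ":", drop = TRUE)
  phase_k <- do.call(rbind, lapply(split(per, grp), function(g)
    cbind(sex = g$sex[1], phase_average(g$k, g$phase))))
  phase_s95 <- do.call(rbind, lapply(split(per, grp), function(g) {
    pa <- phase_average(g$k, g$phase)
    data.frame(sex = g$sex[1], phase = pa$phase,
               S95_from_mean_k = s95(pa$mean),
               S95_session_mean = mean(s95(g$k)),
               n = pa$n, stringsAsFactors = FALSE)
  }))
  rownames(phase_k) <- rownames(phase_s95) <- NULL
  list(per_session = per, phase_k = phase_k, phase_S95 = phase_s95)
}
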