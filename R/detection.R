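#' Detection parameters for the half-normal hazard model
#'
#' Bundles the three parameters of the per-occasion detection process:
#' `lambda0`, the cumulative detection hazard for a trap placed exactly at an
#' animal's activity centre; `sigma`, the spatial scale of detection in
#' metres (a model-based index of home-range size); and `b_mult`, a global
#' multiplicative behavioural response applied to `lambda0` from the occasion
#' after an animal's first capture within a session (`b_mult > 1` =
#' trap-happy, `< 1` = trap-shy, `1` = none).
#'
#' `lambda0` is treated as a hazard, not a probability: per-occasion capture
#' probabilities are derived from the summed hazard over traps via
#' `1 - exp(-H)`, which is the only coherent way to allocate one animal among
#' several competing multi-catch traps. Field descriptions of `lambda0` as
#' the "probability of detection at the centre" correspond to small-hazard
#' behaviour, where `1 - exp(-lambda0)` is close to `lambda0`.
#'
#' @param lambda0 per-occasion detection hazard at distance zero (> 0).
#' @param sigma spatial scale of detection in metres (> 0).
#' @param b_mult multiplicative behavioural response (> 0, default 1).
#' @return An object of class `detection_params`.
#' @examples
#' detection_params(lambda0 = 0.5, sigma = 12)
#' @export
detection_params <- function(lambda0, sigma, b_mult = 1) {
  stopifnot(is.numeric(lambda0), length(lambda0) == 1L, is.finite(lambda0),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(b_mult), length(b_mult) == 1L, is.finite(b_mult))
  if (lambda0 <= 0) stop("'lambda0' must be > 0")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (b_mult <= 0) stop("'b_mult' must be > 0")
  structure(list(lambda0 = lambda0, sigma = sigma, b_mult = b_mult),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("Half-normal detection: lambda0 = %.4g, sigma = %.4g m, b_mult = %.4g\n",
              x$lambda0, x$sigma, x$b_mult))
  invisible(x)
}

#' Half-normal detection hazard
#'
#' The per-occasion hazard of detection at distance `d` between an animal's
#' activity centre and a trap: `lambda0 * exp(-d^2 / (2 * sigma^2))`.
#'
#' @param d distance(s) in metres, >= 0 (vectorised).
#' @param params a [detection_params()] object. The behavioural multiplier is
#'   not applied here; callers scale `lambda0` themselves where it applies.
#' @return Hazard value(s), same length as `d`.
#' @examples
#' hazard_halfnormal(0, detection_params(0.8, 12))   # 0.8
#' hazard_halfnormal(10, detection_params(1, 10))    # exp(-0.5)
#' @export
hazard_halfnormal <- function(d, params) {
  stopifnot(inherits(params, "detection_params"), is.numeric(d))
  if (any(d < 0)) stop("distances must be non-negative")
  params$lambda0 * exp(-d^2 / (2 * params$sigma^2))
}

#' Trap array constructor
#'
#' A detector layout: one row per trap with a unique label and planar
#' coordinates in metres.
#'
#' @param trap_id unique trap labels.
#' @param x,y planar coordinates in metres.
#' @return A `trap_array` data frame with columns `trap_id`, `x`, `y`.
#' @seealso [make_grid()] for regular trapping grids.
#' @export
trap_array <- function(trap_id, x, y) {
  trap_id <- as.character(trap_id)
  stopifnot(length(trap_id) >= 1L, length(x) == length(trap_id),
            length(y) == length(trap_id), is.numeric(x), is.numeric(y),
            all(is.finite(x)), all(is.finite(y)))
  if (anyDuplicated(trap_id)) stop("trap_ids must be unique")
  if (anyDuplicated(cbind(x, y))) stop("trap coordinates must be unique")
  structure(data.frame(trap_id = trap_id, x = x, y = y,
                       stringsAsFactors = FALSE),
            class = c("trap_array", "data.frame"))
}

#' Regular rectangular trapping grid
#'
#' Builds an `nx` by `ny` grid of traps with the given spacing, with the
#' origin at the grid corner. The default is the 8 x 8 grid at 10-m spacing
#' used by small-mammal live-trapping designs.
#'
#' @param nx,ny number of trap columns and rows.
#' @param spacing distance between adjacent trap stations in metres.
#' @return A [trap_array()].
#' @export
make_grid <- function(nx = 8, ny = 8, spacing = 10) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  trap_array(trap_id = sprintf("T%02d", seq_len(nrow(g))),
             x = (g$col - 1) * spacing, y = (g$row - 1) * spacing)
}

# squared distances between points (n x 2 matrix or data frame) and traps
trap_dist2 <- function(xy, traps) {
  xy <- as.matrix(xy)
  outer(xy[, 1], traps$x, "-")^2 + outer(xy[, 2], traps$y, "-")^2
}

#' Per-occasion multi-catch capture probabilities
#'
#' Competing-risks allocation of one animal among multi-catch traps in a
#' single occasion. With per-trap hazards `h_k` and total `H = sum(h_k)`, the
#' probability of capture in trap `k` is `(h_k / H) * (1 - exp(-H))` and the
#' probability of escaping capture is `exp(-H)`; the probabilities sum to 1.
#'
#' @param x activity-centre coordinates, length-2 numeric `(x, y)` in metres.
#' @param traps a [trap_array()].
#' @param lambda0_eff effective hazard scale for this occasion (the naive
#'   `lambda0`, or `lambda0 * b_mult` after a first capture).
#' @param sigma spatial scale of detection in metres.
#' @return A list with `trap` (per-trap capture probabilities, named by
#'   `trap_id`) and `none` (probability of no capture).
#' @examples
#' tr <- make_grid(2, 1, 10)
#' capture_probs(c(5, 0), tr, lambda0_eff = 0.5, sigma = 10)
#' @export
capture_probs <- function(x, traps, lambda0_eff, sigma) {
  stopifnot(inherits(traps, "trap_array"), nrow(traps) >= 1,
            length(x) == 2L, lambda0_eff > 0, sigma > 0)
  d2 <- drop(trap_dist2(rbind(x), traps))
  h <- lambda0_eff * exp(-d2 / (2 * sigma^2))
  H <- sum(h)
  if (H == 0) {
    p <- rep(0, nrow(traps))
  } else {
    p <- (h / H) * -expm1(-H)
  }
  names(p) <- traps$trap_id
  list(trap = p, none = exp(-H))
}

#' Probability of at least one detection over K occasions
#'
#' `1 - exp(-K * H(x))`, where `H(x)` is the total naive detection hazard of
#' the trap array at activity centre `x`. The behavioural multiplier never
#' applies: an animal is undetected until its first capture, so only the
#' naive `lambda0` governs the probability of being detected at all. This is
#' the thinning probability that defines the effective sampled area in the
#' SECR likelihood.
#'
#' @param x activity-centre coordinates, length-2 `(x, y)` in metres, or an
#'   n x 2 matrix of centres.
#' @param traps a [trap_array()].
#' @param params a [detection_params()].
#' @param K number of occasions (>= 1).
#' @return Probability (vector if `x` is a matrix).
#' @export
pdot <- function(x, traps, params, K) {
  stopifnot(inherits(traps, "trap_array"), inherits(params, "detection_params"))
  if (length(K) != 1L || !is.finite(K) || K < 1) stop("'K' must be >= 1")
  xy <- if (is.matrix(x) || is.data.frame(x)) as.matrix(x) else rbind(x)
  d2 <- trap_dist2(xy, traps)
  H <- rowSums(params$lambda0 * exp(-d2 / (2 * params$sigma^2)))
  unname(-expm1(-K * H))
}
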