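# Independent brute-force SECR likelihood: explicit loops over mask points,
# animals and occasions, competing-risks multinomial per occasion, naive
# hazard before an animal's first capture and b_mult-scaled after. Kept
# deliberately simple and separate from the package's vectorised code path.
oracle_nll <- function(session, traps, mask, D, params) {
  cell <- attr(mask, "cell_area")
  K <- session$n_occasions
  rec <- session$records
  ids <- unique(rec$animal_id)
  n <- length(ids)
  M <- nrow(mask)
  hfun <- function(x, lam)
    lam * exp(-((x[1] - traps$x)^2 + (x[2] - traps$y)^2) /
                (2 * params$sigma^2))
  pd <- numeric(M)
  integ <- matrix(0, max(n, 1L), M)
  for (m in seq_len(M)) {
    x <- c(mask$x[m], mask$y[m])
    Hn <- sum(hfun(x, params$lambda0))
    pd[m] <- 1 - exp(-K * Hn)
    for (i in seq_len(n)) {
      caught <- FALSE
      pr <- 1
      for (occ in seq_len(K)) {
        lam <- if (caught) params$lambda0 * params$b_mult else params$lambda0
        hh <- hfun(x, lam)
        HH <- sum(hh)
        row <- rec[rec$animal_id == ids[i] & rec$occasion == occ, ]
        if (nrow(row) == 1) {
          kk <- match(row$trap_id, traps$trap_id)
          pr <- pr * (hh[kk] / HH) * (1 - exp(-HH))
          caught <- TRUE
        } else {
          pr <- pr * exp(-HH)
        }
      }
      integ[i, m] <- pr
    }
  }
  ll <- -D * cell * sum(pd) + n * log(D) - lfactorial(n)
  if (n > 0) ll <- ll + sum(log(cell * rowSums(integ)))
  -ll
}

# hand-built tiny habitat mask (bypasses build_mask so oracle tests control
# the integration points exactly)
manual_mask <- function(x, y, cell_area = 0.01, spacing = 10) {
  structure(data.frame(x = x, y = y), cell_area = cell_area,
            buffer = NA_real_, spacing = spacing,
            class = c("secr_mask", "data.frame"))
}

# capture session from a compact matrix spec: rows of (animal, occasion, trap)
quick_session <- function(m, K, id = "toy") {
  capture_session(id, K, data.frame(animal_id = paste0("a", m[, 1]),
                                    occasion = m[, 2],
                                    trap_id = m[, 3]))
}

# scaled-down mast-cycle scenario used by the stochastic suites: 4 sites,
# one FSA year and one SSA year, June-September
small_scenario_config <- function(..., seed = NULL) {
  scenario_config(n_sites = 4, years = 2010:2011, mast_years = c(2009),
                  months = 6:9, seed = seed, ...)
}
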