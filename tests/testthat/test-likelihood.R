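test_that("capture sessions validate their records", {
  expect_error(capture_session("s", 5,
    data.frame(animal_id = c("a", "a"), occasion = c(2, 2),
               trap_id = c("t1", "t2"))), "at most one trap")
  expect_error(capture_session("s", 3,
    data.frame(animal_id = "a", occasion = 4, trap_id = "t1")),
    "1..n_occasions")
  s <- capture_session("s", 5,
    data.frame(animal_id = character(), occasion = integer(),
               trap_id = character()))
  expect_identical(nrow(s$records), 0L)
})

test_that("empty session gives -logL = D * effective sampled area", {
  tr <- make_grid(3, 3, 10)
  msk <- build_mask(tr, 50, 10)
  p <- detection_params(0.5, 12)
  s0 <- capture_session("empty", 5,
    data.frame(animal_id = character(), occasion = integer(),
               trap_id = character()))
  a <- attr(msk, "cell_area") *
    sum(pdot(as.matrix(msk[c("x", "y")]), tr, p, 5))
  expect_equal(secr_nll(s0, tr, msk, D = 10, p), 10 * a, tolerance = 1e-10)
})

test_that("vectorised likelihood equals the loop-based oracle on toy instances", {
  # all instances: <= 3 traps, <= 5 mask points, <= 3 occasions, <= 4 animals
  set.seed(101)
  for (i in 1:12) {
    nt <- sample(1:3, 1)
    tr <- trap_array(paste0("t", 1:nt),
                     runif(nt, 0, 30), runif(nt, 0, 30))
    nm <- sample(2:5, 1)
    msk <- manual_mask(runif(nm, -10, 40), runif(nm, -10, 40),
                       cell_area = runif(1, 0.005, 0.04))
    K <- sample(1:3, 1)
    b <- sample(c(1, 1, 1.6, 0.6), 1)
    p <- detection_params(runif(1, 0.2, 1.2), runif(1, 6, 18), b)
    na <- sample(1:4, 1)
    rec <- do.call(rbind, lapply(1:na, function(a) {
      occs <- sort(sample(1:K, sample(1:K, 1)))
      data.frame(animal_id = paste0("a", a), occasion = occs,
                 trap_id = sample(tr$trap_id, length(occs), replace = TRUE))
    }))
    s <- capture_session("toy", K, rec)
    D <- runif(1, 2, 60)
    expect_equal(secr_nll(s, tr, msk, D, p), oracle_nll(s, tr, msk, D, p),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to relabeling animals and traps", {
  set.seed(5)
  tr <- make_grid(3, 2, 12)
  msk <- build_mask(tr, 40, 15)
  p <- detection_params(0.6, 10, 1.4)
  sim <- simulate_session(40, p, tr, K = 4, buffer_sim = 40)
  s <- sim$session
  v <- secr_nll(s, tr, msk, 30, p)
  # shuffle record order and relabel animals
  rec <- s$records[sample(nrow(s$records)), ]
  relab <- setNames(sample(paste0("z", seq_along(unique(rec$animal_id)))),
                    unique(rec$animal_id))
  rec$animal_id <- relab[rec$animal_id]
  s2 <- capture_session("x", s$n_occasions, rec)
  expect_equal(secr_nll(s2, tr, msk, 30, p), v, tolerance = 1e-10)
  # relabel traps (permute rows of the trap array consistently)
  perm <- sample(nrow(tr))
  tr2 <- trap_array(tr$trap_id[perm], tr$x[perm], tr$y[perm])
  expect_equal(secr_nll(s, tr2, msk, 30, p), v, tolerance = 1e-10)
  # unknown trap reference is a data-integrity error
  rec$trap_id[1] <- "nope"
  expect_error(secr_nll(capture_session("x", 4, rec), tr, msk, 30, p),
               "unknown traps")
})

test_that("removing one animal changes the likelihood by its own terms", {
  set.seed(8)
  tr <- make_grid(3, 3, 10)
  msk <- build_mask(tr, 40, 10)
  p <- detection_params(0.5, 10)
  sim <- simulate_session(30, p, tr, K = 3, buffer_sim = 40)
  s <- sim$session
  ids <- unique(s$records$animal_id)
  skip_if(length(ids) < 2)
  D <- 20
  drop_id <- ids[1]
  s2 <- capture_session("x", 3, s$records[s$records$animal_id != drop_id, ])
  # difference = log D + log integral of the dropped animal - log(n) factor
  full <- secr_nll(s, tr, msk, D, p)
  red <- secr_nll(s2, tr, msk, D, p)
  n <- length(ids)
  # the dropped animal's integral term, via the oracle on a 1-animal session
  s1 <- capture_session("x", 3, s$records[s$records$animal_id == drop_id, ])
  esa_term <- secr_nll(capture_session("x", 3, s$records[0, ]), tr, msk, D, p)
  one <- oracle_nll(s1, tr, msk, D, p)
  log_int <- -(one - esa_term) - log(D)    # log(c * sum Pr(w|x))
  expect_equal(full - red, -log(D) - log_int + log(n), tolerance = 1e-8)
})

test_that("fitting two identical sessions reproduces the one-session fit", {
  set.seed(12)
  tr <- make_grid(5, 5, 10)
  msk <- build_mask(tr, 60, 15)
  sim <- simulate_session(25, detection_params(0.5, 12), tr, K = 5,
                          buffer_sim = 60)
  skip_if(nrow(sim$session$records) == 0)
  f1 <- fit_secr(sim$session, tr, msk)
  s2 <- capture_session("copy", 5, sim$session$records)
  f2 <- fit_secr(list(sim$session, s2), tr, msk, spec = model_spec())
  expect_equal(f2$estimates$estimate, f1$estimates$estimate, tolerance = 1e-3)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-4)
  expect_equal(f2$n_individuals, 2L * f1$n_individuals)
})

test_that("fit recovers simulated parameters and sits at a local maximum", {
  set.seed(99)
  tr <- make_grid(8, 8, 10)
  msk <- build_mask(tr, 100, 10)
  truth <- detection_params(0.5, 12)
  sim <- simulate_session(25, truth, tr, K = 5)
  fit <- fit_secr(sim$session, tr, msk)
  expect_true(fit$converged)
  est <- fit$estimates
  # estimates within 3 Wald SEs of truth (log scale)
  z <- (est$log_estimate - log(c(25, 12, 0.5))) / est$log_se
  expect_true(all(abs(z) < 3))
  # perturbing each parameter by +/- 2 SE lowers the log-likelihood
  for (j in seq_len(nrow(est))) {
    for (sgn in c(-2, 2)) {
      th <- est$estimate
      th[j] <- exp(est$log_estimate[j] + sgn * est$log_se[j])
      v <- secr_nll(sim$session, tr, msk, th[1],
                    detection_params(th[3], th[2]))
      expect_gt(v, -fit$loglik)
    }
  }
})

test_that("mask refinement changes the likelihood negligibly at study scale", {
  set.seed(3)
  tr <- make_grid(8, 8, 10)
  p <- detection_params(0.5, 12)
  sim <- simulate_session(25, p, tr, K = 5)
  v10 <- secr_nll(sim$session, tr, build_mask(tr, 100, 10), 25, p)
  v5 <- secr_nll(sim$session, tr, build_mask(tr, 100, 5), 25, p)
  expect_lt(abs(v10 - v5), 0.1)
})

test_that("session-specific D with an empty session is a degenerate error", {
  tr <- make_grid(3, 3, 10)
  msk <- build_mask(tr, 40, 15)
  s0 <- capture_session("void", 5,
    data.frame(animal_id = character(), occasion = integer(),
               trap_id = character()))
  set.seed(2)
  sim <- simulate_session(40, detection_params(0.6, 10), tr, K = 5,
                          buffer_sim = 40)
  expect_error(fit_secr(list(sim$session, s0), tr, msk,
                        spec = model_spec(d = "session")), "void")
})

test_that("Wald intervals exponentiate the log-scale interval", {
  fake <- structure(list(
    estimates = data.frame(parameter = "D", group = "all",
                           log_estimate = 0, log_se = 1, estimate = 1),
    converged = TRUE), class = "secr_fit")
  ci <- param_ci(fake, 0.95)
  expect_equal(ci$lower, exp(-qnorm(0.975)), tolerance = 1e-6)
  expect_equal(ci$upper, exp(qnorm(0.975)), tolerance = 1e-6)
  expect_equal(ci$lower, 0.1408635, tolerance = 1e-6)
  expect_equal(ci$upper, 7.099071, tolerance = 1e-6)
  # nested coverage levels nest the intervals; SE = 0 degenerates
  ci90 <- param_ci(fake, 0.90)
  expect_true(ci90$lower > ci$lower && ci90$upper < ci$upper)
  fake$estimates$log_se <- 0
  ci0 <- param_ci(fake)
  expect_equal(ci0$lower, ci0$upper)
  fake$converged <- FALSE
  expect_error(param_ci(fake), "converge")
})
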