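test_that("rate matrix columns sum to zero and off-diagonals are non-negative", {
  for (seed in 1:3) {
    ls <- random_landscape(canonical_landscape(), c(1.0, 2.2), c(4, 12),
                           seed = seed)
    K <- build_rate_matrix(enumerate_states(ls, 2))
    expect_lt(max(abs(colSums(unclass(K)))) / max(abs(K)), 1e-14)
    off <- unclass(K); diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("symmetric two-site toy gives the textbook generator and relaxation", {
  toy <- toy_two_site()
  sp <- enumerate_states(toy, 1)
  K <- build_rate_matrix(sp)   # no terminus roles: fully reversible
  k <- jortner_rate(0, 5, toy$rate_params)
  expect_equal(unclass(K), rbind(c(-k, k), c(k, -k)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # closed form: P1(t) = 1/2 + (P1(0) - 1/2) exp(-2kt)
  times <- c(0, 10^seq(-12, -6, length.out = 13))
  traj <- propagate(K, c(1, 0), times)
  expect_equal(traj$probabilities[, 1],
               0.5 + 0.5 * exp(-2 * k * times), tolerance = 1e-8)
  expect_equal(traj$probabilities[1, ], c(1, 0))  # e^0 is the identity
})

test_that("matrix-exponential and stiff-ODE propagation agree", {
  ls <- canonical_landscape()
  sp <- enumerate_states(ls, 2)
  K <- build_rate_matrix(sp)
  P0 <- numeric(nrow(sp$states))
  P0[state_index(sp, c("W1", "W2"))] <- 1
  times <- 10^seq(-9, 0, length.out = 19)
  a <- propagate(K, P0, times, method = "expm")
  b <- propagate(K, P0, times, method = "ode")
  expect_lt(max(abs(a$probabilities - b$probabilities)), 1e-6)
})

test_that("probability is conserved and non-negative along trajectories", {
  for (seed in 1:3) {
    ls <- random_landscape(canonical_landscape(), c(1.0, 2.2), c(4, 12),
                           seed = 10 + seed)
    sp <- enumerate_states(ls, 2)
    K <- build_rate_matrix(sp)
    P0 <- numeric(nrow(sp$states))
    P0[state_index(sp, c("W1", "W2"))] <- 1
    traj <- propagate(K, P0, default_time_grid(n = 20))
    expect_true(all(abs(rowSums(traj$probabilities) - 1) < 1e-9))
    expect_true(all(traj$probabilities > -1e-12))
  }
})

test_that("long-time distribution is stationary", {
  ls <- canonical_landscape()
  sp <- enumerate_states(ls, 2)
  K <- build_rate_matrix(sp)
  P0 <- numeric(nrow(sp$states))
  P0[state_index(sp, c("W1", "W2"))] <- 1
  Pinf <- propagate(K, P0, 1)$probabilities[1, ]
  # residual probability flux at 1 s, in absolute rate units
  expect_lt(max(abs(unclass(K) %*% Pinf)), 1e-2)
})

test_that("yield starts at zero and a blocked cold path abolishes bifurcation", {
  ls <- canonical_landscape()
  expect_equal(quantum_yield(ls, 0), 0)
  blocked <- ls
  up <- blocked$cofactors$id %in% c("WL1", "WL2", "Tcold")
  blocked$cofactors$potential[up] <- blocked$cofactors$potential[up] + 2
  expect_lt(quantum_yield(blocked, 1), 0.01)
})

test_that("arrival curves start at zero, rise monotonically and saturate", {
  cv <- arrival_curves(canonical_landscape(), times = c(0, default_time_grid()))
  expect_equal(cv$hot[1], 0)
  expect_equal(cv$cold[1], 0)
  expect_true(all(diff(cv$hot) > -1e-8))
  expect_true(all(diff(cv$cold) > -1e-8))
  expect_gt(tail(cv$hot, 1), 0.99)
  expect_gt(tail(cv$cold, 1), 0.99)
})

test_that("completion times are ordered in threshold and refined off-grid", {
  cv <- arrival_curves(canonical_landscape())
  t50 <- completion_time(cv, "cold", 0.5)
  t99 <- completion_time(cv, "cold", 0.99)
  expect_gt(t99, t50)
  # refinement is grid-independent: a coarser grid gives the same crossing
  cv2 <- arrival_curves(canonical_landscape(), times = default_time_grid(n = 15))
  expect_equal(completion_time(cv2, "cold", 0.5), t50, tolerance = 5e-3)
  # a horizon ending before the cold hole arrives is signalled distinctly
  early <- arrival_curves(canonical_landscape(),
                          times = default_time_grid(1e-9, 1e-6, 20))
  expect_warning(t_na <- completion_time(early, "cold", 0.5),
                 "never reaches")
  expect_true(is.na(t_na))
})

test_that("propagate rejects non-stochastic initial conditions", {
  K <- build_rate_matrix(enumerate_states(toy_two_site(), 1))
  expect_error(propagate(K, c(0.7, 0.7), 1e-9), "probability")
  expect_error(propagate(K, c(-0.5, 1.5), 1e-9), "probability")
})
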