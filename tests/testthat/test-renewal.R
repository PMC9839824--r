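test_that("kernel truncation bounds the neglected tail", {
  k <- sir_bench()$kernel
  # scalar tail integral beta exp(-alpha tau)/alpha = tail_tol at ~ 58.0
  tau_ref <- log(5e-4 / (0.25 * 1e-10)) / 0.25
  tm <- truncate_kernel(k, 1e-10)
  expect_equal(tm, tau_ref, tolerance = 1e-3)
  # grid alignment rounds up
  tmh <- truncate_kernel(k, 1e-10, h = 0.25)
  expect_gte(tmh, tm)
  expect_equal(tmh %% 0.25, 0, tolerance = 1e-9)
  # larger alpha gives a shorter kernel
  k2 <- compartment_kernel(5e-4, matrix(-0.5), 1)
  expect_lt(truncate_kernel(k2, 1e-10), tm)
  # contract: exact tail beyond tau_max is below tail_tol
  expect_lt(5e-4 * exp(-0.25 * tm) / 0.25, 1e-10 * (1 + 1e-6))
  expect_error(truncate_kernel(list(U = 1, Sigma = matrix(0), V = 1)), "integrable")
})

test_that("the renewal solver matches the ODE reduction and grows at the Euler-Lotka rate", {
  m <- sir_bench()
  psi <- build_psi(m)
  st <- seed_state(m, psi)
  re <- solve_re(m$kernel, psi, h = 0.02, t_end = 100, history = st$history)
  ode <- simulate_integrated(m, psi, t_end = 100, dt = 0.02)
  expect_lt(max(abs(re$w - ode$w)) / max(ode$w), 0.01)
  # early phase: log w affine with slope r
  sel <- re$w > 1e-6 & re$w < 1e-3
  slope <- unname(coef(lm(log(w) ~ time, data = re[sel, ]))[2])
  expect_equal(slope, st$r, tolerance = 1e-3)
  # zero Psi with zero history stays at zero
  re0 <- solve_re(m$kernel, psi_zero(), h = 0.1, t_end = 5, history = 0)
  expect_true(all(re0$w == 0))
})

test_that("the scheme is monotone and second-order on the SIR benchmark", {
  m <- sir_bench()
  psi <- build_psi(m)
  st <- seed_state(m, psi)
  ds <- vapply(c(0.04, 0.02), function(h) {
    re <- solve_re(m$kernel, psi, h = h, t_end = 100, history = st$history)
    expect_true(all(diff(re$w) >= 0))
    expect_true(all(re$w >= 0))
    ode <- simulate_integrated(m, psi, t_end = 100, dt = h)
    max(abs(re$w - ode$w)) / max(ode$w)
  }, numeric(1))
  expect_gt(ds[1] / ds[2], 3)
  expect_lt(ds[1] / ds[2], 5)
})

test_that("the multitype renewal system handles symmetry and degenerate arcs", {
  # all arcs absent: w identically zero
  arcs <- vector("list", 4); dim(arcs) <- c(2, 2)
  psis <- list(psi_homogeneous(1000), psi_homogeneous(1000))
  out <- solve_re_system(arcs, psis, h = 0.1, t_end = 2,
                         histories = list(function(t) 0 * t, function(t) 0 * t))
  expect_true(all(out$w_1 == 0) && all(out$w_2 == 0))

  # symmetric two-sex model: identical components for symmetric history
  mt <- two_sex_bench()
  res <- solve_re_multitype(mt, h = 0.05, t_end = 60)
  expect_lt(max(abs(res$w_1 - res$w_2)), 1e-12)

  # matches the multitype integrated reduction
  ti <- simulate_multitype_integrated(mt, t_end = 60, dt = 0.05)
  expect_lt(max(abs(res$w_1 - ti[[1]]$w)) / max(ti[[1]]$w), 0.01)
})
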