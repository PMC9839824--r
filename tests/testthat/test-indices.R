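test_that("R0, growth rate and generation time match scalar and two-stage algebra", {
  m <- sir_bench()
  expect_equal(r0(m), 2)
  expect_equal(growth_rate(m), 0.25, tolerance = 1e-12)
  expect_equal(generation_time(m$kernel), 4)

  # SEIR with N beta = 0.5, gamma = alpha = 0.25: r solves (l+g)(l+a) = N beta gamma
  m2 <- seir_bench()
  expect_equal(growth_rate(m2), -0.25 + sqrt(0.125), tolerance = 1e-10)
  expect_equal(generation_time(m2$kernel), 1 / 0.25 + 1 / 0.25)

  # threshold: R0 = 1 gives r = 0
  m1 <- sir_model(beta = 0.25 / 1000, alpha = 0.25, N = 1000)
  expect_equal(r0(m1), 1)
  expect_lt(abs(growth_rate(m1)), 1e-10)

  # subcritical: negative root
  msub <- sir_model(5e-4, 0.25, 400)
  expect_lt(growth_rate(msub), 0)
})

test_that("quarantine-model indices reproduce the printed closed forms", {
  # benchmark parameters: R0 = 0.5 * 0.3/0.2 + 0.5 * 0.3/0.3 = 1.25 at N = 1
  mq <- quarantine_bench(N = 1)
  expect_equal(r0(mq), 1.25, tolerance = 1e-12)

  # -Sigma^-1 entrywise (block form with 1/gamma_i and 1/removal_i)
  S <- mq$kernel$Sigma
  expect_equal(-solve(S),
               rbind(c(1 / 0.5, 0, 0, 0),
                     c(0, 1 / 0.5, 0, 0),
                     c(1 / 0.2, 0, 1 / 0.2, 0),
                     c(0, 1 / 0.3, 0, 1 / 0.3)),
               tolerance = 1e-12)

  # 20 random parameter draws: generic machinery vs closed forms to 1e-12
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1); g1 <- runif(1, 0.1, 1); g2 <- runif(1, 0.1, 1)
    a1 <- runif(1, 0.1, 1); a2 <- runif(1, 0.1, 1); th <- runif(1, 0, 0.5)
    b1 <- runif(1, 0.1, 1); b2 <- runif(1, 0.1, 1); N <- runif(1, 10, 1e4)
    mq <- quarantine_seir_model(p, g1, g2, a1, a2, th, b1, b2, N)
    R0_closed <- N * (p * b1 / a1 + (1 - p) * b2 / (a2 + th))
    T_closed <- (p * b1 / a1 * (1 / g1 + 1 / a1) +
                 (1 - p) * b2 / (a2 + th) * (1 / g2 + 1 / (a2 + th))) /
                (p * b1 / a1 + (1 - p) * b2 / (a2 + th))
    expect_equal(r0(mq), R0_closed, tolerance = 1e-12)
    expect_equal(generation_time(mq$kernel), T_closed, tolerance = 1e-12)
  }
})

test_that("heterogeneous R0 reduces to the homogeneous value when traits are trivial", {
  base <- sir_bench()
  same <- two_group_immunity_variant(base, 600, 400, eps1 = 1, eps2 = 1)
  expect_equal(r0(same), r0(base), tolerance = 1e-13)
})

test_that("final size and herd-immunity threshold match closed-form inversions", {
  # homogeneous R0 = 2
  m <- sir_bench()
  fs <- final_size(m)
  expect_equal(fs$w_inf, final_size_oracle(2), tolerance = 1e-10)
  expect_equal(fs$attack_rate, 1 - exp(-fs$w_inf), tolerance = 1e-12)
  expect_equal(herd_immunity_threshold(m), 0.5, tolerance = 1e-10)

  # Gamma p = 1, c constant, R0 = 2: w_inf = R0 - 1, attack = 1/2,
  # hit from Psi' ~ (1+w)^-2: w* = sqrt(2) - 1, hit = 1 - 2^-1/2
  mg <- sir_bench(trait = trait_gamma(1, "constant_one"))
  fsg <- final_size(mg)
  expect_equal(fsg$w_inf, 1, tolerance = 1e-10)
  expect_equal(fsg$attack_rate, 0.5, tolerance = 1e-10)
  expect_equal(herd_immunity_threshold(mg), 1 - 2^-0.5, tolerance = 1e-10)

  # heterogeneous HIT below homogeneous at equal R0
  for (p in c(0.5, 1, 2))
    expect_lt(herd_immunity_threshold(sir_bench(trait = trait_gamma(p))), 0.5)

  # subcritical gate
  msub <- sir_model(5e-4, 0.25, 400)
  expect_equal(final_size(msub), list(w_inf = 0, attack_rate = 0))
  expect_warning(h0 <- herd_immunity_threshold(msub), "R0 <= 1")
  expect_equal(h0, 0)
})

test_that("index consistency triangle holds on random fixtures", {
  for (i in 1:10) {
    mod <- random_model_fixture(n = 1 + (i %% 4), seed = 200 + i,
                                R0_target = 0.8 + 0.25 * i)
    k <- mod$kernel
    # R0 via linear solve vs N * quadrature of b
    q <- integrate(function(t) kernel_eval(k, t), 0, truncate_kernel(k, 1e-13),
                   rel.tol = 1e-10)$value
    expect_equal(r0(mod), mod$N * q, tolerance = 1e-6)
    # sign equivalence R0 - 1 <-> r
    r <- growth_rate(mod)
    expect_equal(r0(mod) > 1, r > 0)
    # generation time vs quadrature of tau b / b
    q1 <- integrate(function(t) t * kernel_eval(k, t), 0,
                    truncate_kernel(k, 1e-13), rel.tol = 1e-12)$value
    expect_equal(generation_time(k), q1 / q, tolerance = 1e-8)
  }
})
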