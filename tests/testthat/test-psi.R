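test_that("homogeneous Psi has the exponential-saturation form", {
  psi <- psi_homogeneous(1000)
  expect_equal(psi_eval(psi, 0), 0)
  expect_equal(psi_prime_eval(psi, 0), 1000)
  expect_equal(psi_eval(psi, 1), 1000 * (1 - exp(-1)))  # ~ 632.12
  expect_equal(psi$saturation, 1000)
  expect_error(psi_homogeneous(-1), "positive")
})

test_that("discrete Psi reproduces the two-group immunity forms", {
  # single reference atom: identical to the homogeneous Psi
  tr1 <- trait_discrete(1, a = 1, c_vals = 1)
  p1 <- psi_discrete(800, tr1)
  ph <- psi_homogeneous(800)
  w <- c(0, 0.5, 2)
  expect_equal(psi_eval(p1, w), psi_eval(ph, w), tolerance = 1e-14)

  # N1 = N2 = 500, eps1 = 0.5, eps2 = 2
  tr <- trait_discrete(c(0.5, 0.5), a = c(1, 0.5), c_vals = c(1, 2))
  psi <- psi_discrete(1000, tr)
  expect_equal(psi_eval(psi, 1), 500 * (1 - exp(-1)) + 1000 * (1 - exp(-0.5)))
  # Psi'(-log s) = N1 s + N2 eps1 eps2 s^eps1; at s = 1 this is N1 + N2 eps1 eps2
  expect_equal(psi_prime_eval(psi, 0), 500 + 500 * 0.5 * 2)
  s <- c(0.9, 0.5, 0.2)
  expect_equal(psi_prime_eval(psi, -log(s)), 500 * s + 500 * 0.5 * 2 * s^0.5,
               tolerance = 1e-13)

  expect_error(trait_discrete(c(0.6, 0.5), c(1, 1), c(1, 1)), "sum to 1")
  expect_error(trait_discrete(c(0.5, 0.5), c(2, 1), c(1, 1)), "reference")
})

test_that("Gamma Psi closed forms, Laplace transform, and the large-p limit", {
  expect_equal(gamma_laplace(2, 0), 1)
  expect_equal(gamma_laplace(1, 1), 0.5)
  # Laplace transform agrees with direct quadrature of the density
  q <- integrate(function(x) exp(-x) * dgamma(x, shape = 2, rate = 2), 0, Inf,
                 rel.tol = 1e-12)$value
  expect_equal(gamma_laplace(2, 1), q, tolerance = 1e-8)

  psi <- psi_gamma(1, 1, "constant_one")
  expect_equal(psi_eval(psi, 0), 0)
  expect_equal(psi_eval(psi, 1), 0.5)
  expect_equal(psi_gamma(1, 1, "proportional")$psi(1), 1 - 2^-2)

  # p -> Inf recovers the homogeneous form
  pbig <- psi_gamma(1, 1e6, "constant_one")
  w <- c(0.5, 1, 2)
  expect_lt(max(abs(psi_eval(pbig, w) - (1 - exp(-w)))), 1e-4)

  expect_error(psi_gamma(1, -1), "positive")
  expect_error(gamma_laplace(-1, 0), "positive")
})

test_that("quadrature Psi agrees with closed forms across trait dialects", {
  w <- c(0.1, 1, 3)
  # integrand independent of the trait: any density collapses to homogeneous
  tr <- trait_density(function(x) dgamma(x, 3, 3), function(x) rep(1, length(x)),
                      function(x) rep(1, length(x)), x_bar = 1)
  pq <- psi_quadrature(1, tr)
  expect_equal(psi_eval(pq, w), 1 - exp(-w), tolerance = 1e-10)

  # a constant, c arbitrary: Psi = E[c] * N (1 - exp(-w))
  tr2 <- trait_density(function(x) dgamma(x, 2, 2), function(x) rep(1, length(x)),
                       function(x) x, x_bar = 1)
  pq2 <- psi_quadrature(1, tr2)
  expect_equal(psi_eval(pq2, w), 1 - exp(-w), tolerance = 1e-9)  # E[c] = 1

  # Gamma density, a(x) = x, c = 1, p = 2: matches the closed form
  cf <- psi_gamma(1, 2, "constant_one")
  pq3 <- psi_quadrature(1, trait_gamma(2, "constant_one"))
  expect_equal(psi_eval(pq3, 1.5), psi_eval(cf, 1.5), tolerance = 1e-8)

  # full grid, both modes, p in {0.5, 1, 2, 5}
  wg <- seq(0, 10, by = 0.5)
  for (p in c(0.5, 1, 2, 5)) for (cm in c("constant_one", "proportional")) {
    cfp <- psi_gamma(1, p, cm)
    qp <- psi_quadrature(1, trait_gamma(p, cm))
    expect_lt(max(abs(psi_eval(cfp, wg) - psi_eval(qp, wg))), 1e-8)
    expect_lt(max(abs(psi_prime_eval(cfp, wg) - psi_prime_eval(qp, wg))), 1e-8)
  }
})

test_that("every builder yields a concave, saturating Psi with consistent derivative", {
  builders <- list(
    psi_homogeneous(1000),
    psi_discrete(1000, trait_discrete(c(0.3, 0.7), c(1, 0.6), c(1, 1.5), ref = 1)),
    psi_gamma(1000, 2, "constant_one"),
    psi_gamma(1000, 0.5, "proportional"),
    psi_quadrature(1000, trait_gamma(1, "constant_one")))
  wg <- seq(0, 10, by = 0.05)
  for (psi in builders) {
    v <- psi_eval(psi, wg)
    expect_equal(v[1], 0)
    expect_true(all(diff(v) >= -1e-10))
    expect_lt(max(diff(v, differences = 2)), 1e-10 * max(1, psi$n_scale))
    expect_true(all(psi_eval(psi, wg) <= psi$saturation * (1 + 1e-12)))
    d <- psi_prime_eval(psi, wg)
    expect_true(all(d >= 0))
    expect_true(all(diff(d) <= 1e-12 * max(1, psi$n_scale)))
    # central finite difference check at w in {0.1, 1, 5}
    for (w0 in c(0.1, 1, 5)) {
      hfd <- 1e-6
      fd <- (psi_eval(psi, w0 + hfd) - psi_eval(psi, w0 - hfd)) / (2 * hfd)
      expect_equal(psi_prime_eval(psi, w0), fd, tolerance = 1e-6)
    }
  }
  # saturation reached at w = 50 when min a >= 0.5 on the support
  for (psi in builders[1:2]) {
    expect_lt(abs(psi_eval(psi, 50) - psi$saturation), 1e-6 * psi$saturation)
  }
})
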