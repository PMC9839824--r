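Package: kmreduce
Title: Compartmental Epidemic Models via the Kermack-McKendrick Renewal
    Equation, with Separable Static Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codes a compartmental outbreak model as a matrix-exponential
    infectivity kernel b(tau) = U exp(tau * Sigma) V and reduces the
    Kermack-McKendrick renewal equation for the cumulative force of
    infection to a finite system of ordinary differential equations (the
    "integrated form"), together with the conventional "standard form".
    Separable static host heterogeneity - a trait distribution with
    relative susceptibility a(x) and relative infectiousness c(xi) - is
    incorporated by redefining a single scalar function Psi, with closed
    forms for Gamma-distributed susceptibility. Provides epidemic indices
    (basic reproduction number, intrinsic growth rate, generation time,
    final size, herd-immunity threshold), two-sex / host-vector multitype
    extensions, and a direct trapezoidal solver for the renewal equation
    that serves as an independent numerical cross-check of the ODE
    reductions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
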