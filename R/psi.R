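#' The Psi function
#'
#' `Psi(w)` is the infectiousness-weighted expected mass of no-longer-
#' susceptible individuals, given cumulative force of infection `w` at the
#' reference trait:
#' `Psi(w) = N * integral of c(xi) (1 - exp(-a(xi) w)) dPhi(xi)`.
#' It is the single object that changes when separable static heterogeneity
#' is added to a compartmental model. `Psi` is nondecreasing and concave with
#' `Psi(0) = 0` and saturation level `N * E[c]`; its derivative
#' `Psi'(w) = N * integral of c a exp(-a w) dPhi` enters the heterogeneous
#' standard form.
#'
#' A `km_psi` object carries `psi` and `psi_prime` (both vectorised),
#' `saturation`, and the embedded population size `n_scale`.
#'
#' @param psi,psi_prime vectorised functions of `w >= 0`.
#' @param saturation limit of `psi` at infinity.
#' @param n_scale the population size `N` embedded in `psi`.
#' @param label short description used in printing.
#' @return An object of class `km_psi`.
#' @name psi_function
#' @export
psi_function <- function(psi, psi_prime, saturation, n_scale, label = "psi") {
  stopifnot(is.function(psi), is.function(psi_prime))
  structure(list(psi = psi, psi_prime = psi_prime, saturation = saturation,
                 n_scale = n_scale, label = label), class = "km_psi")
}

#' Evaluate a Psi object or its derivative
#' @param psi a `km_psi`.
#' @param w nonnegative numeric vector.
#' @return Numeric vector.
#' @export
psi_eval <- function(psi, w) psi$psi(w)

#' @rdname psi_eval
#' @export
psi_prime_eval <- function(psi, w) psi$psi_prime(w)

#' Homogeneous Psi
#'
#' `Psi(w) = N (1 - exp(-w))`, the no-longer-susceptible count in a
#' homogeneous population of size `N`.
#'
#' @param N population size (> 0).
#' @return A `km_psi`.
#' @export
psi_homogeneous <- function(N) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  psi_function(
    psi = function(w) N * (1 - exp(-w)),
    psi_prime = function(w) N * exp(-w),
    saturation = N, n_scale = N, label = "homogeneous")
}

#' Discrete-heterogeneity Psi
#'
#' For atoms `(weight_k, a_k, c_k)`:
#' `Psi(w) = N sum_k weight_k c_k (1 - exp(-a_k w))`. The two-group immunity
#' case with weights `N1/N, N2/N`, `a = (1, eps1)`, `c = (1, eps2)` gives
#' `Psi(w) = N1 (1 - exp(-w)) + N2 eps2 (1 - exp(-eps1 w))` and
#' `Psi'(-log s) = N1 s + N2 eps1 eps2 s^eps1`.
#'
#' @param N population size (> 0).
#' @param trait a discrete `km_trait` (see [trait_discrete()]).
#' @return A `km_psi`.
#' @export
psi_discrete <- function(N, trait) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (!inherits(trait, "km_trait") || trait$type != "discrete")
    stop("trait must be a discrete km_trait", call. = FALSE)
  wk <- trait$weights; ak <- trait$a; ck <- trait$c_vals
  psi_function(
    psi = function(w)
      as.numeric((1 - exp(outer(w, ak, function(wi, ai) -wi * ai))) %*% (N * wk * ck)),
    psi_prime = function(w)
      as.numeric(exp(outer(w, ak, function(wi, ai) -wi * ai)) %*% (N * wk * ck * ak)),
    saturation = N * sum(wk * ck), n_scale = N, label = "discrete")
}

#' Laplace transform of the unit-mean Gamma distribution
#'
#' For the Gamma distribution with mean 1 and variance `1/p`,
#' `Phi_hat(lambda) = (lambda/p + 1)^(-p)`.
#'
#' @param p shape parameter (> 0).
#' @param lambda nonnegative argument (vectorised).
#' @return Numeric vector.
#' @export
gamma_laplace <- function(p, lambda) {
  if (p <= 0) stop("p must be positive", call. = FALSE)
  if (any(lambda / p + 1 <= 0)) stop("lambda/p + 1 must be positive", call. = FALSE)
  (lambda / p + 1)^(-p)
}

#' Gamma-heterogeneity Psi in closed form
#'
#' With `a(x) = x` and the unit-mean Gamma trait distribution of variance
#' `1/p`, the Psi integral is a Laplace transform and has closed forms:
#' * `c` identically 1: `Psi(w) = N (1 - (w/p + 1)^(-p))`;
#' * `c(x) = x` (proportional): `Psi(w) = N (1 - (w/p + 1)^(-p-1))`.
#' Both saturate at `N` (the Gamma mean is 1, so `E[c] = 1` in either mode).
#'
#' @param N population size (> 0).
#' @param p Gamma shape (> 0); trait variance is `1/p`.
#' @param c_mode `"constant_one"` or `"proportional"`.
#' @return A `km_psi`.
#' @export
psi_gamma <- function(N, p, c_mode = c("constant_one", "proportional")) {
  c_mode <- match.arg(c_mode)
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (p <= 0) stop("p must be positive", call. = FALSE)
  if (c_mode == "constant_one") {
    psi_function(
      psi = function(w) N * (1 - (w / p + 1)^(-p)),
      psi_prime = function(w) N * (w / p + 1)^(-p - 1),
      saturation = N, n_scale = N, label = "gamma (c = 1)")
  } else {
    psi_function(
      psi = function(w) N * (1 - (w / p + 1)^(-p - 1)),
      psi_prime = function(w) N * (1 + 1 / p) * (w / p + 1)^(-p - 2),
      saturation = N, n_scale = N, label = "gamma (c = x)")
  }
}

#' Psi by fixed-node quadrature over a trait model
#'
#' Evaluates `Psi(w) = N * integral of c(xi) (1 - exp(-a(xi) w)) dPhi(xi)` and
#' its derivative on fixed quadrature nodes. Discrete traits reduce exactly to
#' [psi_discrete()]; Gamma traits use generalized Gauss-Laguerre nodes (so
#' this path is an independent check of the [psi_gamma()] closed forms);
#' generic densities use transformed Gauss-Legendre nodes.
#'
#' @param N population size (> 0).
#' @param trait a `km_trait`.
#' @param n_nodes quadrature node count (default 200; ignored for discrete).
#' @return A `km_psi`.
#' @export
psi_quadrature <- function(N, trait, n_nodes = 200L) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (!inherits(trait, "km_trait")) stop("trait must be a km_trait", call. = FALSE)
  if (trait$type == "discrete") return(psi_discrete(N, trait))
  nodes <- trait_nodes(trait, n_nodes)
  mass <- sum(nodes$w)
  if (abs(mass - 1) > 1e-8)
    stop(sprintf("quadrature self-check failed: nodes integrate Phi to %.10g, not 1", mass),
         call. = FALSE)
  ac <- trait_ac(trait, nodes)
  wc <- N * nodes$w * ac$c
  wca <- wc * ac$a
  a <- ac$a
  psi_function(
    psi = function(w)
      as.numeric((1 - exp(outer(w, a, function(wi, ai) -wi * ai))) %*% wc),
    psi_prime = function(w)
      as.numeric(exp(outer(w, a, function(wi, ai) -wi * ai)) %*% wca),
    saturation = sum(wc), n_scale = N,
    label = sprintf("quadrature (%s, %d nodes)", trait$type, length(nodes$x)))
}

#' Build the Psi function of a model
#'
#' Dispatches on the model's trait block: homogeneous (`NULL` trait) to
#' [psi_homogeneous()], discrete atoms to [psi_discrete()], Gamma traits to
#' the [psi_gamma()] closed forms, and generic densities to
#' [psi_quadrature()].
#'
#' @param model a `km_model`.
#' @param n_nodes quadrature nodes for density traits.
#' @return A `km_psi`.
#' @export
build_psi <- function(model, n_nodes = 200L) {
  tr <- model$trait
  if (is.null(tr)) return(psi_homogeneous(model$N))
  switch(tr$type,
    discrete = psi_discrete(model$N, tr),
    gamma = psi_gamma(model$N, tr$p, tr$c_mode),
    density = psi_quadrature(model$N, tr, n_nodes))
}

#' A Psi that is identically zero
#'
#' The formal `N -> 0` limit; useful to probe the linear decay of the
#' integrated system.
#' @return A `km_psi` with `psi` and `psi_prime` identically 0.
#' @export
psi_zero <- function() {
  psi_function(function(w) 0 * w, function(w) 0 * w, saturation = 0,
               n_scale = 0, label = "zero")
}

#' @export
print.km_psi <- function(x, ...) {
  cat(sprintf("<km_psi> %s; saturation = %g, N = %g, Psi'(0) = %g\n",
              x$label, x$saturation, x$n_scale, x$psi_prime(0)))
  invisible(x)
}
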