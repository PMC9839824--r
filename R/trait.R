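#' Trait models for separable static heterogeneity
#'
#' Hosts carry a fixed trait `x` with distribution `Phi`; the transmission
#' kernel factorises as `a(x) b(tau) c(xi)`, where `a` is the relative
#' susceptibility of the receiver and `c` the relative infectiousness of the
#' transmitter. Both are normalised at a reference trait `x_bar`:
#' `a(x_bar) = c(x_bar) = 1`.
#'
#' Three dialects are supported:
#' * `trait_discrete()`: finitely many atoms with weights, `a`, `c` values;
#' * `trait_gamma()`: `a(x) = x` with `x ~ Gamma(mean 1, variance 1/p)` and
#'   `c` either identically 1 or `c(x) = x` (the two closed-form cases);
#' * `trait_density()`: a generic continuous density with callable `a`, `c`,
#'   integrated by fixed-node quadrature.
#'
#' @name trait_models
NULL

#' @describeIn trait_models Finite set of trait atoms. `weights`, `a`, `c`
#'   are equal-length numeric vectors; `weights` must sum to 1 (tolerance
#'   1e-10) and `a[ref]`, `c[ref]` must equal 1 (tolerance 1e-12).
#' @param weights probability weights of the atoms.
#' @param a relative susceptibility per atom (nonnegative).
#' @param c_vals relative infectiousness per atom (nonnegative).
#' @param ref index of the reference atom (default 1).
#' @export
trait_discrete <- function(weights, a, c_vals, ref = 1L) {
  weights <- as.numeric(weights); a <- as.numeric(a); c_vals <- as.numeric(c_vals)
  if (length(unique(c(length(weights), length(a), length(c_vals)))) != 1L)
    stop("weights, a, c_vals must have equal length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-10)
    stop("atom weights must sum to 1 (got ", sum(weights), ")", call. = FALSE)
  if (any(weights < 0) || any(a < 0) || any(c_vals < 0))
    stop("weights, a, c_vals must be nonnegative", call. = FALSE)
  if (abs(a[ref] - 1) > 1e-12 || abs(c_vals[ref] - 1) > 1e-12)
    stop("a and c must equal 1 at the reference atom", call. = FALSE)
  structure(list(type = "discrete", weights = weights, a = a, c_vals = c_vals,
                 ref = ref), class = "km_trait")
}

#' @describeIn trait_models Gamma-distributed relative susceptibility with
#'   mean 1 and variance `1/p`; density `p^p / Gamma(p) x^{p-1} e^{-p x}`.
#'   The reference trait is the mean, `x_bar = 1`.
#' @param p shape parameter (> 0); the trait variance is `1/p`.
#' @param c_mode `"constant_one"` (infectiousness unaffected by the trait) or
#'   `"proportional"` (`c(x) = x`).
#' @export
trait_gamma <- function(p, c_mode = c("constant_one", "proportional")) {
  c_mode <- match.arg(c_mode)
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("p must be a positive scalar", call. = FALSE)
  structure(list(type = "gamma", p = p, c_mode = c_mode),
            class = "km_trait")
}

#' @describeIn trait_models Generic continuous trait density on
#'   `[lower, upper]` (`upper` may be `Inf`; an infinite right endpoint is
#'   handled by the substitution `x = lower + scale * t / (1 - t)` in
#'   quadrature). `density`, `a`, `c_fun` are vectorised functions of the
#'   trait; the density must integrate to 1 within 1e-8 on the quadrature
#'   nodes, and `a(x_bar) = c_fun(x_bar) = 1` within 1e-12.
#' @param density vectorised density function of the trait.
#' @param a_fun vectorised relative-susceptibility function.
#' @param c_fun vectorised relative-infectiousness function.
#' @param lower,upper support interval of the density.
#' @param x_bar reference trait.
#' @param n_nodes number of quadrature nodes (default 200).
#' @param scale scale of the `t/(1-t)` transform for `upper = Inf`.
#' @export
trait_density <- function(density, a_fun, c_fun, lower = 0, upper = Inf,
                          x_bar = 1, n_nodes = 200L, scale = 1) {
  stopifnot(is.function(density), is.function(a_fun), is.function(c_fun))
  if (abs(a_fun(x_bar) - 1) > 1e-12 || abs(c_fun(x_bar) - 1) > 1e-12)
    stop("a and c must equal 1 at the reference trait x_bar", call. = FALSE)
  tr <- structure(list(type = "density", density = density, a_fun = a_fun,
                       c_fun = c_fun, lower = lower, upper = upper,
                       x_bar = x_bar, n_nodes = as.integer(n_nodes),
                       scale = scale), class = "km_trait")
  q <- trait_nodes(tr)
  mass <- sum(q$w)
  if (abs(mass - 1) > 1e-8)
    stop(sprintf("density does not integrate to 1 on the quadrature nodes (got %.10g)", mass),
         call. = FALSE)
  # renormalise residual quadrature error so downstream integrals are exact-in-mass
  tr$mass_correction <- 1 / mass
  tr
}

# Generalized Gauss-Laguerre rule for the weight x^a e^{-x} on (0, Inf),
# any a > -1, by Golub-Welsch: eigenvalues of the symmetric tridiagonal
# Jacobi matrix are the nodes, squared first eigenvector components times
# the total mass Gamma(a + 1) are the weights.
gauss_laguerre <- function(n, a) {
  stopifnot(n >= 1, a > -1)
  k <- seq_len(n) - 1
  diag_main <- 2 * k + a + 1
  off <- sqrt(seq_len(n - 1) * (seq_len(n - 1) + a))
  J <- diag(diag_main)
  if (n > 1) {
    J[cbind(1:(n - 1), 2:n)] <- off
    J[cbind(2:n, 1:(n - 1))] <- off
  }
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(x = eg$values[ord], w = gamma(a + 1) * eg$vectors[1, ord]^2)
}

# Quadrature nodes (x) and Phi-weights (w) such that integral f dPhi ~ sum(w * f(x)).
# Gamma traits use generalized Gauss-Laguerre (weight x^{p-1} e^{-x}), which
# absorbs the density's endpoint singularity exactly; generic densities use
# Gauss-Legendre after mapping to a bounded interval.
trait_nodes <- function(trait, n_nodes = NULL) {
  if (trait$type == "gamma") {
    n <- if (is.null(n_nodes)) 200L else n_nodes
    p <- trait$p
    gl <- gauss_laguerre(n, p - 1)
    list(x = gl$x / p, w = gl$w / gamma(p))
  } else if (trait$type == "density") {
    n <- if (is.null(n_nodes)) trait$n_nodes else n_nodes
    if (is.finite(trait$upper)) {
      gl <- pracma::gaussLegendre(n, trait$lower, trait$upper)
      x <- gl$x
      w <- gl$w * trait$density(x)
    } else {
      gl <- pracma::gaussLegendre(n, 0, 1)
      t1 <- gl$x
      x <- trait$lower + trait$scale * t1 / (1 - t1)
      jac <- trait$scale / (1 - t1)^2
      w <- gl$w * trait$density(x) * jac
    }
    if (!is.null(trait$mass_correction)) w <- w * trait$mass_correction
    list(x = x, w = w)
  } else if (trait$type == "discrete") {
    list(x = seq_along(trait$weights), w = trait$weights)
  } else stop("unknown trait type")
}

# a and c evaluated on the trait_nodes grid, as numeric vectors.
trait_ac <- function(trait, nodes = NULL) {
  if (trait$type == "discrete")
    return(list(a = trait$a, c = trait$c_vals))
  if (is.null(nodes)) nodes <- trait_nodes(trait)
  if (trait$type == "gamma") {
    a <- nodes$x
    cc <- if (trait$c_mode == "constant_one") rep(1, length(nodes$x)) else nodes$x
    list(a = a, c = cc)
  } else {
    list(a = trait$a_fun(nodes$x), c = trait$c_fun(nodes$x))
  }
}

#' Population susceptible fraction as a function of w
#'
#' For cumulative force of infection `w` at the reference trait, the fraction
#' of trait-`x` individuals still susceptible is `exp(-a(x) w)`, and the
#' population fraction is `s_tot(w) = integral of exp(-a(xi) w) dPhi(xi)`.
#' `stot_deriv` returns `-d s_tot / dw = integral of a exp(-a w) dPhi`.
#' With `trait = NULL` (homogeneous population) both reduce to `exp(-w)`.
#'
#' @param trait a `km_trait` or `NULL`.
#' @param w nonnegative scalar or vector.
#' @return Numeric vector, same length as `w`.
#' @export
stot_fraction <- function(trait, w) {
  if (is.null(trait)) return(exp(-w))
  if (trait$type == "gamma") return(gamma_laplace(trait$p, w))
  nodes <- trait_nodes(trait)
  ac <- trait_ac(trait, nodes)
  as.numeric(exp(outer(w, ac$a, function(wi, ai) -wi * ai)) %*% nodes$w)
}

#' @rdname stot_fraction
#' @export
stot_deriv <- function(trait, w) {
  if (is.null(trait)) return(exp(-w))
  if (trait$type == "gamma") {
    p <- trait$p
    return((w / p + 1)^(-p - 1))
  }
  nodes <- trait_nodes(trait)
  ac <- trait_ac(trait, nodes)
  as.numeric(exp(outer(w, ac$a, function(wi, ai) -wi * ai)) %*% (nodes$w * ac$a))
}

#' @export
print.km_trait <- function(x, ...) {
  switch(x$type,
    discrete = cat(sprintf("<km_trait> discrete, %d atoms\n", length(x$weights))),
    gamma = cat(sprintf("<km_trait> Gamma susceptibility, p = %g (variance %g), c_mode = %s\n",
                        x$p, 1 / x$p, x$c_mode)),
    density = cat(sprintf("<km_trait> continuous density on [%g, %g], %d nodes\n",
                          x$lower, x$upper, x$n_nodes)))
  invisible(x)
}

#' Model specification: population size, kernel, optional heterogeneity
#'
#' @param N total host population size (> 0).
#' @param kernel a `km_kernel`.
#' @param trait a `km_trait`, or `NULL` for a homogeneous population
#'   (`a` and `c` identically 1).
#' @return An object of class `km_model`.
#' @export
#' @examples
#' m <- sir_model(beta = 0.0005, alpha = 0.25, N = 1000)
#' r0(m)
model_spec <- function(N, kernel, trait = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N <= 0)
    stop("N must be a positive scalar", call. = FALSE)
  if (!inherits(kernel, "km_kernel")) stop("kernel must be a km_kernel", call. = FALSE)
  if (!is.null(trait) && !inherits(trait, "km_trait"))
    stop("trait must be a km_trait or NULL", call. = FALSE)
  structure(list(N = N, kernel = kernel, trait = trait), class = "km_model")
}

#' @export
print.km_model <- function(x, ...) {
  cat(sprintf("<km_model> N = %g, n = %d compartments, %s\n", x$N, x$kernel$n,
              if (is.null(x$trait)) "homogeneous" else paste0("heterogeneous (", x$trait$type, ")")))
  invisible(x)
}
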