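#' SIR model as a kernel triple
#'
#' Standard SIR (`dS/dt = -beta I S`, `dI/dt = -alpha I + beta I S`) coded as
#' `n = 1`, `U = beta`, `Sigma = -alpha`, `V = 1`; the infectivity kernel is
#' `b(tau) = beta exp(-alpha tau)` and the integrated form is
#' `dQ/dt = -alpha Q + Psi(beta Q)`.
#'
#' @param beta transmission rate per susceptible per infective (> 0).
#' @param alpha recovery rate (> 0).
#' @param N population size (> 0).
#' @param trait optional `km_trait`.
#' @return A `km_model`.
#' @export
#' @examples
#' epidemic_indices(sir_model(0.0005, 0.25, 1000))  # R0 = 2, r = 0.25, T = 4
sir_model <- function(beta, alpha, N, trait = NULL) {
  stopifnot(beta > 0, alpha > 0, N > 0)
  model_spec(N, compartment_kernel(U = beta, Sigma = matrix(-alpha), V = 1),
             trait)
}

#' SEIR model as a kernel triple
#'
#' Exposed stage with progression rate `gamma`, infectious stage with
#' recovery rate `alpha`: `n = 2`, `V = (1, 0)`, `U = (0, beta)`,
#' `Sigma = [[-gamma, 0], [gamma, -alpha]]`.
#'
#' @param beta transmission rate (> 0).
#' @param gamma progression rate out of the exposed stage (> 0).
#' @param alpha recovery rate (> 0).
#' @param N population size (> 0).
#' @param trait optional `km_trait`.
#' @return A `km_model`.
#' @export
seir_model <- function(beta, gamma, alpha, N, trait = NULL) {
  stopifnot(beta > 0, gamma > 0, alpha > 0, N > 0)
  Sigma <- matrix(c(-gamma, gamma, 0, -alpha), 2L, 2L)
  model_spec(N, compartment_kernel(U = c(0, beta), Sigma = Sigma, V = c(1, 0)),
             trait)
}

#' SEIR model with asymptomatic infection and quarantine
#'
#' Two infection routes: a fraction `p` of new infections is asymptomatic
#' (compartments `E1 -> I1`, progression `gamma1`, recovery `alpha1`,
#' transmission `beta1`) and a fraction `1 - p` symptomatic
#' (`E2 -> I2`, progression `gamma2`, recovery `alpha2`, transmission
#' `beta2`), with symptomatic infectives additionally removed into
#' quarantine at rate `theta`. Compartment ordering `(E1, E2, I1, I2)`,
#' `V = (p, 1-p, 0, 0)`, `U = (0, 0, beta1, beta2)`. The recovered and
#' quarantined compartments are not state variables (their contents is
#' irrelevant for the future dynamics).
#'
#' The closed-form indices are
#' `R0 = N (p beta1/alpha1 + (1-p) beta2/(alpha2 + theta))` and a
#' generation time that is the `R0`-weighted mixture of
#' `1/gamma_i + 1/(removal rate)_i`; both are reproduced by the generic
#' index machinery.
#'
#' @param p asymptomatic fraction, in `[0, 1]`.
#' @param gamma1,gamma2 progression rates (> 0).
#' @param alpha1,alpha2 recovery rates (> 0).
#' @param theta quarantine rate for symptomatic infectives (>= 0).
#' @param beta1,beta2 transmission rates (> 0).
#' @param N population size (> 0).
#' @param trait optional `km_trait`.
#' @return A `km_model` with `n = 4`.
#' @export
quarantine_seir_model <- function(p, gamma1, gamma2, alpha1, alpha2, theta,
                                  beta1, beta2, N, trait = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  stopifnot(gamma1 > 0, gamma2 > 0, alpha1 > 0, alpha2 > 0, theta >= 0,
            beta1 > 0, beta2 > 0, N > 0)
  Sigma <- rbind(c(-gamma1, 0,       0,       0),
                 c(0,       -gamma2, 0,       0),
                 c(gamma1,  0,       -alpha1, 0),
                 c(0,       gamma2,  0,       -(alpha2 + theta)))
  V <- c(p, 1 - p, 0, 0)
  U <- c(0, 0, beta1, beta2)
  # V components may include a zero when p is 0 or 1; kernel stays valid
  model_spec(N, compartment_kernel(U = U, Sigma = Sigma, V = V), trait)
}

#' Two-group partial-immunity variant of a model
#'
#' Splits the population into `N1` fully susceptible (type 1, the reference)
#' and `N2` partly immune individuals with relative susceptibility `eps1`
#' and relative infectiousness `eps2`. Attaches the discrete trait with
#' atoms `(N1/N, 1, 1)` and `(N2/N, eps1, eps2)`, so
#' `Psi(w) = N1 (1 - exp(-w)) + N2 eps2 (1 - exp(-eps1 w))`. With
#' `eps1 = eps2 = eps` the same model reads as a fraction `N2/N` reducing
#' social activity by a factor `eps`.
#'
#' @param base a homogeneous `km_model`.
#' @param N1,N2 subpopulation sizes; must sum to `base$N`.
#' @param eps1 relative susceptibility of the partly immune group (>= 0).
#' @param eps2 relative infectiousness of the partly immune group (>= 0).
#' @return A `km_model` with a discrete trait.
#' @export
two_group_immunity_variant <- function(base, N1, N2, eps1, eps2) {
  stopifnot(inherits(base, "km_model"), eps1 >= 0, eps2 >= 0)
  if (abs(N1 + N2 - base$N) > 1e-9 * base$N)
    stop("N1 + N2 must equal the base population size", call. = FALSE)
  tr <- trait_discrete(weights = c(N1, N2) / base$N,
                       a = c(1, eps1), c_vals = c(1, eps2), ref = 1L)
  model_spec(base$N, base$kernel, tr)
}

#' Two-sex (or host-vector) multitype model
#'
#' Builds the zero-diagonal two-type structure: type 1 (males / hosts)
#' infects type 2 and vice versa, each type described by its own kernel
#' triple and optional trait model (e.g. a Gamma-distributed promiscuity
#' trait per type).
#'
#' @param N1,N2 population sizes of the two types.
#' @param kernel1,kernel2 `km_kernel` describing infected individuals of
#'   type 1 and 2.
#' @param trait1,trait2 optional `km_trait` per type.
#' @return A `km_multitype`.
#' @export
#' @examples
#' k <- compartment_kernel(0.0005, matrix(-0.25), 1)
#' mt <- two_sex_model(1000, 1000, k, k)
#' multitype_r0(mt)   # 2
two_sex_model <- function(N1, N2, kernel1, kernel2,
                          trait1 = NULL, trait2 = NULL) {
  multitype_model(N = c(N1, N2), kernels = list(kernel1, kernel2),
                  traits = list(trait1, trait2))
}
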