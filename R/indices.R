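#' Basic reproduction number
#'
#' `R0 = Psi'(0) * integral of b = -Psi'(0) * U Sigma^-1 V`, computed by a
#' linear solve. For a homogeneous population `Psi'(0) = N`, recovering
#' `R0 = -N U Sigma^-1 V`; for heterogeneous models `Psi'(0)` replaces `N`
#' (the unique definition under which the Euler-Lotka root is 0 exactly at
#' `R0 = 1`).
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi` (default [build_psi()]).
#' @return Scalar `R0`.
#' @export
r0 <- function(model, psi = build_psi(model)) {
  kernel_mass(model$kernel) * psi_prime_eval(psi, 0)
}

#' Intrinsic growth rate (Euler-Lotka root)
#'
#' Solves `Psi'(0) * U (lambda I - Sigma)^-1 V = 1` for the unique real
#' `lambda` above the spectral abscissa of `Sigma`; the left side is strictly
#' decreasing there, so the root is found by bracketing plus Newton polish to
#' residual below 1e-12.
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi`.
#' @return The real root `r`; positive iff `R0 > 1`.
#' @export
growth_rate <- function(model, psi = build_psi(model)) {
  k <- model$kernel
  psip0 <- psi_prime_eval(psi, 0)
  if (psip0 <= 0) stop("Psi'(0) must be positive", call. = FALSE)
  n <- k$n
  I <- diag(n)
  f <- function(lam) psip0 * as.numeric(k$U %*% solve(lam * I - k$Sigma, k$V)) - 1
  fp <- function(lam) {
    x <- solve(lam * I - k$Sigma, k$V)
    -psip0 * as.numeric(k$U %*% solve(lam * I - k$Sigma, x))
  }
  absc <- max(Re(eigen(k$Sigma, only.values = TRUE)$values))
  R0 <- r0(model, psi)
  if (R0 <= 0) stop("R0 must be positive", call. = FALSE)
  # f(0) = R0 - 1; bracket to the appropriate side of 0
  if (abs(R0 - 1) < 1e-14) return(0)
  if (R0 > 1) {
    lo <- 0; hi <- max(1, -absc)
    tries <- 0L
    while (f(hi) > 0) {
      hi <- hi * 2
      tries <- tries + 1L
      if (tries > 10L) stop("failed to bracket the Euler-Lotka root", call. = FALSE)
    }
  } else {
    hi <- 0
    lo <- absc + 0.9 * (0 - absc)   # between abscissa and 0
    tries <- 0L
    while (f(lo) < 0) {
      lo <- absc + 0.5 * (lo - absc)
      tries <- tries + 1L
      if (tries > 60L) stop("failed to bracket the Euler-Lotka root", call. = FALSE)
    }
  }
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  for (i in 1:5) {                  # Newton polish with analytic derivative
    fr <- f(r)
    if (abs(fr) < 1e-13) break
    r <- r - fr / fp(r)
  }
  r
}

#' Generation time
#'
#' Mean time since infection weighted by the kernel:
#' `T = integral(tau b) / integral(b) = -(U Sigma^-2 V) / (U Sigma^-1 V)`,
#' via two linear solves.
#'
#' @param kernel a `km_kernel`.
#' @return Scalar generation time.
#' @export
generation_time <- function(kernel) {
  x1 <- solve(kernel$Sigma, kernel$V)
  x2 <- solve(kernel$Sigma, x1)
  -as.numeric(kernel$U %*% x2) / as.numeric(kernel$U %*% x1)
}

#' Final size of the outbreak
#'
#' The final cumulative force of infection at the reference trait, `w_inf`,
#' is the unique positive root of `w = (-U Sigma^-1 V) * Psi(w)` (the
#' time-integrated renewal equation); the attack rate is
#' `1 - integral of exp(-a(xi) w_inf) dPhi`. Subcritical models return
#' `(0, 0)`.
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi`.
#' @return A list with `w_inf` and `attack_rate`.
#' @export
final_size <- function(model, psi = build_psi(model)) {
  mass <- kernel_mass(model$kernel)
  if (r0(model, psi) <= 1) return(list(w_inf = 0, attack_rate = 0))
  g <- function(w) mass * psi_eval(psi, w) - w
  hi <- 1
  while (g(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e8) stop("failed to bracket the final-size root", call. = FALSE)
  }
  w_inf <- stats::uniroot(g, c(1e-12, hi), tol = 1e-15)$root
  list(w_inf = w_inf,
       attack_rate = 1 - stot_fraction(model$trait, w_inf))
}

#' Herd-immunity threshold
#'
#' Solves `(-U Sigma^-1 V) * Psi'(w*) = 1` (the depletion of susceptibility
#' at which the effective reproduction number crosses 1; `Psi'` is strictly
#' decreasing, so the root is unique) and returns the infected fraction at
#' that point, `1 - integral of exp(-a(xi) w*) dPhi`. Subcritical models
#' return 0 with a warning.
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi`.
#' @return Scalar threshold in `[0, 1)`.
#' @export
herd_immunity_threshold <- function(model, psi = build_psi(model)) {
  mass <- kernel_mass(model$kernel)
  if (r0(model, psi) <= 1) {
    warning("R0 <= 1: herd-immunity threshold is 0", call. = FALSE)
    return(0)
  }
  h <- function(w) mass * psi_prime_eval(psi, w) - 1
  hi <- 1
  while (h(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e8) stop("failed to bracket the herd-immunity root", call. = FALSE)
  }
  w_star <- stats::uniroot(h, c(0, hi), tol = 1e-15)$root
  1 - stot_fraction(model$trait, w_star)
}

#' All epidemic indices of a model
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi`.
#' @return A list with `R0`, `r` (intrinsic growth rate), `T` (generation
#'   time), `w_inf`, `attack_rate`, `hit` (herd-immunity threshold).
#' @export
#' @examples
#' epidemic_indices(sir_model(0.0005, 0.25, 1000))
epidemic_indices <- function(model, psi = build_psi(model)) {
  fs <- final_size(model, psi)
  R0 <- r0(model, psi)
  list(R0 = R0,
       r = growth_rate(model, psi),
       T = generation_time(model$kernel),
       w_inf = fs$w_inf,
       attack_rate = fs$attack_rate,
       hit = if (R0 > 1) herd_immunity_threshold(model, psi) else 0)
}
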