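#' Right-hand side of the integrated-form ODE
#'
#' The integrated form evolves `Q`, the time-integral of the compartment
#' contents, by `dQ/dt = Sigma Q + V Psi(U Q)`. The same construction serves
#' homogeneous and heterogeneous models: heterogeneity enters only through
#' `Psi`.
#'
#' @param kernel a `km_kernel`.
#' @param psi a `km_psi`.
#' @return A function `Q -> Sigma Q + V Psi(U Q)`.
#' @export
integrated_rhs <- function(kernel, psi) {
  U <- kernel$U; Sigma <- kernel$Sigma; V <- kernel$V
  function(Q) {
    if (length(Q) != length(U)) stop("Q has wrong dimension", call. = FALSE)
    as.numeric(Sigma %*% Q) + V * psi_eval(psi, sum(U * Q))
  }
}

#' Seeding specifications
#'
#' `seed_eigen(w0)` starts the outbreak on the linearized exponential ansatz:
#' the history is `w(t) = w0 exp(r t)` for `t <= 0` with `r` the Euler-Lotka
#' root, and the time-0 state is the matching point on that ray. This is the
#' unique finite-time initialisation consistent with both the ODE reductions
#' and the renewal equation posed on the infinite past, which makes the
#' cross-checks between the two well-posed. `seed_explicit(Q0)` supplies an
#' initial integrated state directly (no history; renewal-equation
#' comparisons then need a user history).
#'
#' @param w0 small positive initial cumulative force of infection at the
#'   reference trait (warn above 0.01).
#' @param Q0 numeric initial `Q` vector for explicit mode.
#' @return A seed-spec list.
#' @export
seed_eigen <- function(w0 = 1e-6) {
  if (w0 <= 0) stop("w0 must be positive", call. = FALSE)
  if (w0 > 0.01) warning("w0 > 0.01: the linearized seeding assumes w0 << 1", call. = FALSE)
  list(mode = "eigen", w0 = w0)
}

#' @rdname seed_eigen
#' @export
seed_explicit <- function(Q0) list(mode = "explicit", Q0 = as.numeric(Q0))

#' Initial state from a seed specification
#'
#' In eigen mode returns `Q(0) = Psi'(0) w0 (r I - Sigma)^-1 V`, which
#' satisfies `U Q(0) = w0` exactly because `r` solves the Euler-Lotka
#' equation; the matching standard-form state is `s_bar(0) = exp(-w0)`,
#' `Y(0) = r Q(0)` (the time derivative of the ansatz), and the renewal
#' history is `w(t) = w0 exp(r t)`.
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi`.
#' @param seed a seed spec from [seed_eigen()] or [seed_explicit()].
#' @return List with `Q0`, `Y0`, `w0`, `r` (eigen mode), `s_bar0`, and
#'   `history` (function of `t <= 0`).
#' @export
seed_state <- function(model, psi = build_psi(model), seed = seed_eigen()) {
  k <- model$kernel
  if (seed$mode == "explicit") {
    Q0 <- seed$Q0
    if (length(Q0) != k$n) stop("Q0 has wrong dimension", call. = FALSE)
    w0 <- sum(k$U * Q0)
    return(list(Q0 = Q0, Y0 = NULL, w0 = w0, r = NA_real_,
                s_bar0 = exp(-w0), history = NULL))
  }
  if (r0(model, psi) <= 1)
    stop("eigen seeding needs R0 > 1; use seed_explicit() for subcritical models",
         call. = FALSE)
  r <- growth_rate(model, psi)
  w0 <- seed$w0
  Q0 <- psi_prime_eval(psi, 0) * w0 *
    as.numeric(solve(r * diag(k$n) - k$Sigma, k$V))
  list(Q0 = Q0, Y0 = r * Q0, w0 = w0, r = r, s_bar0 = exp(-w0),
       history = function(t) w0 * exp(r * t))
}

# Assemble a km_trajectory data frame from a time grid, Q (and optionally Y),
# w, and the model. incidence = -dS/dt = N * stot_deriv(w) * dw/dt.
build_trajectory <- function(model, times, w, Q, Y = NULL, dwdt = NULL,
                             form = "integrated") {
  n <- model$kernel$n
  s_bar <- exp(-pmax(w, 0))
  s_tot <- stot_fraction(model$trait, w)
  S <- model$N * s_tot
  if (is.null(dwdt)) dwdt <- c(diff(w) / diff(times), NA_real_)
  incidence <- model$N * stot_deriv(model$trait, w) * dwdt
  df <- data.frame(time = times, w = w, s_bar = s_bar, s_tot = s_tot,
                   S = S, incidence = incidence)
  Q <- matrix(Q, ncol = n)
  colnames(Q) <- paste0("Q_", seq_len(n))
  df <- cbind(df, Q)
  if (!is.null(Y)) {
    Y <- matrix(Y, ncol = n)
    colnames(Y) <- paste0("Y_", seq_len(n))
    df <- cbind(df, Y)
  }
  structure(df, class = c("km_trajectory", "data.frame"),
            form = form, n = n, N = model$N)
}

# shared deSolve driver
ode_solve <- function(y0, times, rhs, rtol, atol) {
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms) list(rhs(y)),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE solver failed: ", paste(deSolve::diagnostics(sol), collapse = " "),
         call. = FALSE)
  sol
}

#' Simulate the integrated-form ODE
#'
#' Integrates `dQ/dt = Sigma Q + V Psi(U Q)` from the seed state and recovers
#' the observables: `w = U Q`, `s_bar = exp(-w)`, `s_tot`, `S = N s_tot`,
#' and incidence `-dS/dt`. For homogeneous runs `S = N exp(-w)`.
#'
#' @param model a `km_model`.
#' @param psi the model's `km_psi`.
#' @param seed a seed spec ([seed_eigen()] / [seed_explicit()]).
#' @param t_end end time (> 0).
#' @param dt output grid step (default `t_end / 2000`).
#' @param rtol,atol solver tolerances (defaults `1e-9`, `1e-12 * N`).
#' @return A `km_trajectory` data frame.
#' @export
#' @examples
#' m <- sir_model(0.0005, 0.25, 1000)
#' tr <- simulate_integrated(m, t_end = 100)
#' tail(tr$w, 1)   # approaches the final-size root
simulate_integrated <- function(model, psi = build_psi(model),
                                seed = seed_eigen(), t_end, dt = t_end / 2000,
                                rtol = 1e-9, atol = 1e-12 * model$N) {
  stopifnot(t_end > 0)
  k <- model$kernel
  st <- seed_state(model, psi, seed)
  rhs <- integrated_rhs(k, psi)
  times <- seq(0, t_end, by = dt)
  sol <- ode_solve(st$Q0, times, rhs, rtol, atol)
  Q <- unname(sol[, -1L, drop = FALSE])
  w <- as.numeric(Q %*% k$U)
  if (psi$n_scale > 0 && min(diff(w)) < -1e-8 * max(abs(w)))
    stop("invariant violation: w decreased along the trajectory", call. = FALSE)
  dwdt <- vapply(seq_len(nrow(Q)), function(i) sum(k$U * rhs(Q[i, ])), numeric(1))
  build_trajectory(model, times, w, Q, dwdt = dwdt, form = "integrated")
}

#' Simulate the standard-form ODE
#'
#' The heterogeneous standard form is
#' `ds_bar/dt = -(U Y) s_bar`, `dY/dt = Sigma Y + (U Y) Psi'(-log s_bar) V`;
#' for homogeneous models `Psi'(-log s_bar) = N s_bar`, recovering the
#' textbook system with `S = N s_bar`. Internally the susceptible fraction is
#' propagated in log space (the state is `w = -log s_bar`, so `dw/dt = U Y`),
#' which avoids underflow uniformly; the reported `s_bar = exp(-w)` is
#' clipped to `[0, 1]`. The cumulative state `Q(t) = Q(0) + integral of Y` is
#' carried as extra state so the integrated-form `Q` is recovered exactly.
#'
#' @inheritParams simulate_integrated
#' @return A `km_trajectory` with `Y_1..Y_n` columns in addition to `Q`.
#' @export
simulate_standard <- function(model, psi = build_psi(model),
                              seed = seed_eigen(), t_end, dt = t_end / 2000,
                              rtol = 1e-9, atol = 1e-12 * model$N) {
  stopifnot(t_end > 0)
  k <- model$kernel
  n <- k$n
  st <- seed_state(model, psi, seed)
  Y0 <- st$Y0
  if (is.null(Y0)) Y0 <- as.numeric(k$Sigma %*% st$Q0) +
    k$V * psi_eval(psi, st$w0)       # dQ/dt at 0 for explicit seeds
  y0 <- c(st$w0, Y0, st$Q0)
  rhs <- function(y) {
    w <- y[1L]; Y <- y[2:(n + 1L)]
    Fbar <- sum(k$U * Y)
    c(Fbar,
      as.numeric(k$Sigma %*% Y) + Fbar * psi_prime_eval(psi, w) * k$V,
      Y)
  }
  times <- seq(0, t_end, by = dt)
  sol <- ode_solve(y0, times, rhs, rtol, atol)
  w <- sol[, 2L]
  Y <- unname(sol[, 3:(n + 2L), drop = FALSE])
  Q <- unname(sol[, (n + 3L):(2L * n + 2L), drop = FALSE])
  dwdt <- as.numeric(Y %*% k$U)
  build_trajectory(model, times, w, Q, Y = Y, dwdt = dwdt, form = "standard")
}

#' Simulate the Gamma s_tot system
#'
#' For Gamma-distributed susceptibility the standard form can be written in
#' the total susceptible fraction instead of the reference-trait fraction:
#' `ds_tot/dt = -F_bar s_tot^(1 + 1/p)`,
#' `dY/dt = Sigma Y + F_bar H(s_tot) V`, `F_bar = U Y`, where
#' `H(s) = N s^(1 + 1/p)` when `c` is identically 1 and
#' `H(s) = N (1 + 1/p) s^(1 + 2/p)` when `c(x) = x`. The link to the
#' reference-trait form is `s_tot = Phi_hat(-log s_bar)` with `Phi_hat` the
#' Gamma Laplace transform.
#'
#' @inheritParams simulate_integrated
#' @return A `km_trajectory`; `w` is recovered as `p (s_tot^(-1/p) - 1)`.
#' @export
simulate_gamma_stot <- function(model, seed = seed_eigen(), t_end,
                                dt = t_end / 2000, rtol = 1e-9,
                                atol = 1e-12 * model$N) {
  tr <- model$trait
  if (is.null(tr) || tr$type != "gamma")
    stop("simulate_gamma_stot requires a Gamma trait model", call. = FALSE)
  p <- tr$p
  N <- model$N
  H <- if (tr$c_mode == "constant_one") {
    function(s) N * s^(1 + 1 / p)
  } else {
    function(s) N * (1 + 1 / p) * s^(1 + 2 / p)
  }
  psi <- build_psi(model)
  k <- model$kernel
  n <- k$n
  st <- seed_state(model, psi, seed)
  s0 <- gamma_laplace(p, st$w0)
  Y0 <- st$Y0
  if (is.null(Y0)) stop("explicit seeding is not supported for the s_tot form",
                        call. = FALSE)
  y0 <- c(s0, Y0)
  rhs <- function(y) {
    s <- max(y[1L], 0); Y <- y[2:(n + 1L)]
    Fbar <- sum(k$U * Y)
    c(-Fbar * s^(1 + 1 / p),
      as.numeric(k$Sigma %*% Y) + Fbar * H(s) * k$V)
  }
  times <- seq(0, t_end, by = dt)
  sol <- ode_solve(y0, times, rhs, rtol, atol)
  s_tot <- pmin(pmax(sol[, 2L], 0), 1)
  Y <- unname(sol[, 3:(n + 2L), drop = FALSE])
  w <- p * (s_tot^(-1 / p) - 1)
  df <- data.frame(time = times, w = w, s_bar = exp(-w), s_tot = s_tot,
                   S = N * s_tot,
                   incidence = N * stot_deriv(tr, w) * as.numeric(Y %*% k$U))
  Ym <- Y; colnames(Ym) <- paste0("Y_", seq_len(n))
  df <- cbind(df, Ym)
  structure(df, class = c("km_trajectory", "data.frame"),
            form = "gamma_stot", n = n, N = N)
}

#' @export
print.km_trajectory <- function(x, ...) {
  cat(sprintf("<km_trajectory> %s form, %d time points on [%g, %g]\n",
              attr(x, "form"), nrow(x), x$time[1L], x$time[nrow(x)]))
  cat(sprintf("  final w = %.6g, final susceptible fraction = %.6g\n",
              x$w[nrow(x)], x$s_tot[nrow(x)]))
  invisible(x)
}
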