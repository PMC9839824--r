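#' Multitype (two-sex / host-vector) model
#'
#' Cyclic transmission among `m` host types. An infected individual of type
#' `j` is described by its own kernel triple `(U_j, Sigma_j, V_j)`; the arc
#' structure says which types it infects (the two-sex and host-vector cases
#' have `m = 2` with a zero diagonal: type 1 infects only type 2 and vice
#' versa). Each type has its own population size `N_i` and optional trait
#' model, giving per-type `Psi_i`.
#'
#' @param N numeric vector of per-type population sizes.
#' @param kernels list of `m` `km_kernel` objects; `kernels[[j]]` describes
#'   an infected individual of type `j`.
#' @param arcs `m x m` logical matrix; `arcs[i, j]` is `TRUE` when type `j`
#'   transmits to type `i`. Default: the zero-diagonal two-type structure
#'   (requires `m = 2`).
#' @param traits optional list of `m` `km_trait` objects (or `NULL` entries
#'   for homogeneous types).
#' @return An object of class `km_multitype`.
#' @export
multitype_model <- function(N, kernels, arcs = NULL, traits = NULL) {
  m <- length(kernels)
  stopifnot(length(N) == m, all(N > 0))
  for (k in kernels) {
    rep <- validate_kernel(k)
    if (!rep$ok) stop("invalid arc kernel: ", paste(rep$violations, collapse = "; "),
                      call. = FALSE)
  }
  if (is.null(arcs)) {
    if (m != 2L) stop("default arc structure requires m = 2", call. = FALSE)
    arcs <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2L, 2L)
  }
  stopifnot(is.matrix(arcs), nrow(arcs) == m, ncol(arcs) == m)
  if (any(diag(arcs)))
    warning("nonzero diagonal arcs: not the two-sex/host-vector structure",
            call. = FALSE)
  # irreducibility of the cyclic structure (every type reachable)
  reach <- diag(m) > 0
  for (i in seq_len(m)) reach <- reach | (reach %*% arcs > 0)
  if (!all(reach))
    warning("arc structure is reducible; eigen seeding may fail", call. = FALSE)
  if (is.null(traits)) traits <- vector("list", m)
  models <- lapply(seq_len(m), function(i)
    model_spec(N[i], kernels[[i]], traits[[i]]))
  psis <- lapply(models, build_psi)
  structure(list(m = m, N = N, kernels = kernels, arcs = arcs,
                 traits = traits, models = models, psis = psis),
            class = "km_multitype")
}

#' @export
print.km_multitype <- function(x, ...) {
  cat(sprintf("<km_multitype> %d types, N = (%s)\n", x$m,
              paste(format(x$N), collapse = ", ")))
  invisible(x)
}

#' Multitype basic reproduction number
#'
#' Spectral radius of the next-generation matrix `K` with
#' `K[i, j] = Psi_j'(0) * (-U_j Sigma_j^-1 V_j)` on present arcs; for the
#' two-type zero-diagonal case this is `sqrt(K12 K21)`.
#'
#' @param mt a `km_multitype`.
#' @return Scalar spectral radius.
#' @export
multitype_r0 <- function(mt) {
  m <- mt$m
  K <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (mt$arcs[i, j])
    K[i, j] <- psi_prime_eval(mt$psis[[j]], 0) * kernel_mass(mt$kernels[[j]])
  max(Mod(eigen(K, only.values = TRUE)$values))
}

# Linearized integrated system: block matrix M with diagonal blocks Sigma_i
# and off blocks Psi_i'(0) V_i U_j on arcs (i, j).
multitype_linearization <- function(mt) {
  ns <- vapply(mt$kernels, function(k) k$n, integer(1))
  off <- c(0L, cumsum(ns))
  ntot <- sum(ns)
  M <- matrix(0, ntot, ntot)
  for (i in seq_len(mt$m)) {
    ri <- (off[i] + 1L):(off[i] + ns[i])
    M[ri, ri] <- mt$kernels[[i]]$Sigma
    for (j in seq_len(mt$m)) if (mt$arcs[i, j]) {
      cj <- (off[j] + 1L):(off[j] + ns[j])
      M[ri, cj] <- M[ri, cj] +
        psi_prime_eval(mt$psis[[i]], 0) * outer(mt$kernels[[i]]$V, mt$kernels[[j]]$U)
    }
  }
  list(M = M, ns = ns, off = off)
}

#' Multitype growth rate and eigen seed
#'
#' The leading eigenvalue of the linearized integrated system gives the
#' multitype intrinsic growth rate; its (Perron) eigenvector, scaled so the
#' type-1 cumulative force of infection equals `w0`, gives the seed state -
#' the multitype analogue of the scalar eigen ansatz.
#'
#' @param mt a `km_multitype`.
#' @param w0 initial cumulative force of infection on type 1.
#' @return List with `r`, per-type `Q0` (list), `w0_types` (initial `w_i`),
#'   and `histories` (list of functions `w0_i exp(r t)`).
#' @export
multitype_seed <- function(mt, w0 = 1e-6) {
  lin <- multitype_linearization(mt)
  eg <- eigen(lin$M)
  lead <- which.max(Re(eg$values))
  r <- Re(eg$values[lead])
  if (r <= 0) stop("eigen seeding needs a supercritical multitype model", call. = FALSE)
  v <- Re(eg$vectors[, lead])
  if (sum(v) < 0) v <- -v
  Qs <- lapply(seq_len(mt$m), function(i)
    v[(lin$off[i] + 1L):(lin$off[i] + lin$ns[i])])
  wv <- multitype_w(mt, Qs)
  scale <- w0 / wv[1L]
  Qs <- lapply(Qs, function(q) q * scale)
  wv <- wv * scale
  list(r = r, Q0 = Qs, w0_types = wv,
       histories = lapply(wv, function(wi) {
         force(wi); function(t) wi * exp(r * t)
       }))
}

# w_i = sum over arcs (i, j) of U_j Q_j
multitype_w <- function(mt, Qs) {
  vapply(seq_len(mt$m), function(i) {
    s <- 0
    for (j in seq_len(mt$m)) if (mt$arcs[i, j])
      s <- s + sum(mt$kernels[[j]]$U * Qs[[j]])
    s
  }, numeric(1))
}

# stack/unstack helpers
mt_unstack <- function(y, ns, off) lapply(seq_along(ns), function(i)
  y[(off[i] + 1L):(off[i] + ns[i])])

#' Simulate the multitype integrated form
#'
#' Integrates `dQ_i/dt = Sigma_i Q_i + Psi_i(w_i) V_i` with
#' `w_i = sum_j U_j Q_j` over present arcs (for the two-type case,
#' `w_1 = U_2 Q_2` and `w_2 = U_1 Q_1`).
#'
#' @param mt a `km_multitype`.
#' @param w0 eigen-seed size on type 1.
#' @param t_end end time.
#' @param dt output step.
#' @param rtol,atol solver tolerances.
#' @return A list of per-type `km_trajectory` data frames.
#' @export
simulate_multitype_integrated <- function(mt, w0 = 1e-6, t_end,
                                          dt = t_end / 2000, rtol = 1e-9,
                                          atol = 1e-12 * max(mt$N)) {
  sd <- multitype_seed(mt, w0)
  lin <- multitype_linearization(mt)
  ns <- lin$ns; off <- lin$off
  rhs <- function(y) {
    Qs <- mt_unstack(y, ns, off)
    wv <- multitype_w(mt, Qs)
    unlist(lapply(seq_len(mt$m), function(i)
      as.numeric(mt$kernels[[i]]$Sigma %*% Qs[[i]]) +
        mt$kernels[[i]]$V * psi_eval(mt$psis[[i]], wv[i])))
  }
  times <- seq(0, t_end, by = dt)
  sol <- ode_solve(unlist(sd$Q0), times, rhs, rtol, atol)
  Y <- unname(sol[, -1L, drop = FALSE])
  lapply(seq_len(mt$m), function(i) {
    wv <- vapply(seq_len(nrow(Y)), function(rw)
      multitype_w(mt, mt_unstack(Y[rw, ], ns, off))[i], numeric(1))
    Qi <- Y[, (off[i] + 1L):(off[i] + ns[i]), drop = FALSE]
    build_trajectory(mt$models[[i]], times, wv, Qi, form = "integrated")
  })
}

#' Simulate the multitype standard form
#'
#' Integrates, per type, `dw_i/dt = F_i`,
#' `dY_i/dt = Sigma_i Y_i + F_i Psi_i'(w_i) V_i` with
#' `F_i = sum_j U_j Y_j` over present arcs. For homogeneous types
#' `Psi_i'(w_i) = N_i exp(-w_i) = S_i`, recovering the two-sex standard form
#' `dS_i/dt = -F_i S_i`, `dY_i/dt = Sigma_i Y_i + F_i S_i V_i`; heterogeneous
#' types use the per-type `Psi_i'` analogue.
#'
#' @inheritParams simulate_multitype_integrated
#' @return A list of per-type `km_trajectory` data frames (with `Y` columns).
#' @export
simulate_multitype_standard <- function(mt, w0 = 1e-6, t_end,
                                        dt = t_end / 2000, rtol = 1e-9,
                                        atol = 1e-12 * max(mt$N)) {
  sd <- multitype_seed(mt, w0)
  lin <- multitype_linearization(mt)
  ns <- lin$ns; off <- lin$off
  m <- mt$m
  ntot <- sum(ns)
  Y0 <- lapply(sd$Q0, function(q) sd$r * q)
  y0 <- c(sd$w0_types, unlist(Y0), unlist(sd$Q0))
  rhs <- function(y) {
    wv <- y[seq_len(m)]
    Ys <- mt_unstack(y[m + seq_len(ntot)], ns, off)
    Fv <- vapply(seq_len(m), function(i) {
      s <- 0
      for (j in seq_len(m)) if (mt$arcs[i, j]) s <- s + sum(mt$kernels[[j]]$U * Ys[[j]])
      s
    }, numeric(1))
    dY <- unlist(lapply(seq_len(m), function(i)
      as.numeric(mt$kernels[[i]]$Sigma %*% Ys[[i]]) +
        Fv[i] * psi_prime_eval(mt$psis[[i]], wv[i]) * mt$kernels[[i]]$V))
    c(Fv, dY, unlist(Ys))
  }
  times <- seq(0, t_end, by = dt)
  sol <- ode_solve(y0, times, rhs, rtol, atol)
  out <- unname(sol[, -1L, drop = FALSE])
  lapply(seq_len(m), function(i) {
    wv <- out[, i]
    Yi <- out[, m + (off[i] + 1L):(off[i] + ns[i]), drop = FALSE]
    Qi <- out[, m + ntot + (off[i] + 1L):(off[i] + ns[i]), drop = FALSE]
    build_trajectory(mt$models[[i]], times, wv, Qi, Y = Yi, form = "standard")
  })
}

#' Renewal-equation solve of a multitype model
#'
#' Convenience wrapper assembling the arc kernels, per-type `Psi`, and eigen
#' histories of a `km_multitype` and calling [solve_re_system()].
#'
#' @inheritParams simulate_multitype_integrated
#' @param h renewal time step.
#' @param tail_tol neglected kernel tail mass.
#' @return Data frame from [solve_re_system()].
#' @export
solve_re_multitype <- function(mt, w0 = 1e-6, h, t_end, tail_tol = 1e-10) {
  sd <- multitype_seed(mt, w0)
  arcs <- vector("list", mt$m * mt$m)
  dim(arcs) <- c(mt$m, mt$m)
  for (i in seq_len(mt$m)) for (j in seq_len(mt$m)) if (mt$arcs[i, j])
    arcs[[i, j]] <- mt$kernels[[j]]
  solve_re_system(arcs, mt$psis, h, t_end, sd$histories, tail_tol)
}
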