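#' Kernel truncation point for the renewal solver
#'
#' Chooses the smallest grid-aligned `tau_max` whose neglected tail mass is
#' below `tail_tol`. For a matrix-exponential kernel the tail is available
#' exactly as `integral_{tau}^inf b = U (-Sigma^-1) exp(tau Sigma) V`, so the
#' truncation point is located by doubling and grid-aligned bisection on
#' that expression (no norm bound needed).
#'
#' @param kernel a `km_kernel`.
#' @param tail_tol neglected tail mass (default `1e-10`).
#' @param h grid step to align to (default: return the exact crossing).
#' @return Scalar `tau_max`.
#' @export
truncate_kernel <- function(kernel, tail_tol = 1e-10, h = NULL) {
  absc <- max(Re(eigen(kernel$Sigma, only.values = TRUE)$values))
  if (absc >= 0) stop("kernel not integrable: spectral abscissa >= 0", call. = FALSE)
  negSinv <- -solve(kernel$Sigma)
  tail <- function(tau)
    as.numeric(kernel$U %*% (negSinv %*% (mexp(tau * kernel$Sigma) %*% kernel$V)))
  hi <- 1
  while (tail(hi) >= tail_tol) {
    hi <- hi * 2
    if (hi > 1e6) stop("failed to locate kernel truncation point", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > 1e-6 * hi) {
    mid <- (lo + hi) / 2
    if (tail(mid) < tail_tol) hi <- mid else lo <- mid
  }
  if (!is.null(h)) hi <- ceiling(hi / h) * h
  hi
}

#' Solve the scalar renewal equation by trapezoidal marching
#'
#' Direct discretization of
#' `w(t) = integral_0^inf b(tau) Psi(w(t - tau)) dtau`,
#' independent of any ODE reduction: the kernel is truncated at `tau_max`
#' (see [truncate_kernel()]), tabulated on the uniform `tau`-grid, and the
#' convolution is marched forward with trapezoidal weights. The implicit
#' dependence on `Psi(w(t_k))` through the `tau = 0` node (weight
#' `h/2 b(0)`) is resolved by fixed-point iteration to relative machine
#' precision, which
#' contracts when `h/2 b(0) Psi'(0) < 1`; `h` is halved automatically (up to
#' 5 times) if that condition fails.
#'
#' @param kernel a `km_kernel`, or `NULL` if `b_table` is supplied.
#' @param psi a `km_psi`.
#' @param h time step.
#' @param t_end end time.
#' @param history function of `t <= 0` giving the prescribed past of `w`
#'   (e.g. the eigen ansatz `w0 exp(r t)` from [seed_state()]), or a single
#'   number treated as a constant history.
#' @param tail_tol neglected kernel tail mass.
#' @param b_table optional pre-tabulated kernel values on `tau = 0, h, ...`
#'   (overrides `kernel`/`tail_tol`).
#' @return A data frame with columns `time` and `w`; attribute `h` records
#'   the (possibly halved) step actually used.
#' @export
solve_re <- function(kernel, psi, h, t_end, history, tail_tol = 1e-10,
                     b_table = NULL) {
  if (!is.function(history)) {
    hval <- history; history <- function(t) rep(hval, length(t))
  }
  halvings <- 0L
  repeat {
    if (is.null(b_table)) {
      tau_max <- truncate_kernel(kernel, tail_tol, h = h)
      J <- as.integer(round(tau_max / h))
      b <- kernel_tabulate(kernel, h, J)
    } else {
      b <- b_table
      J <- length(b) - 1L
    }
    if ((h / 2) * b[1L] * psi_prime_eval(psi, 0) < 0.9) break
    halvings <- halvings + 1L
    if (halvings > 5L)
      stop("inner fixed-point iteration cannot contract; reduce h", call. = FALSE)
    h <- h / 2
    b_table <- NULL
  }
  K <- as.integer(round(t_end / h))
  wt <- h * b
  wt[1L] <- wt[1L] / 2
  wt[J + 1L] <- wt[J + 1L] / 2
  wt_rev <- rev(wt[-1L])              # weights for lags j = J..1
  c0 <- wt[1L]                        # implicit tau = 0 weight: h/2 * b(0)
  # P[m + J + 1] = Psi(w(m h)) for m = -J..K
  P <- numeric(K + J + 1L)
  w_hist <- history(seq(-J, 0) * h)
  P[1:(J + 1L)] <- psi_eval(psi, w_hist)
  w <- numeric(K + 1L)
  w[1L] <- w_hist[J + 1L]
  for (k in seq_len(K)) {
    base <- sum(wt_rev * P[(k + 1L):(k + J)])   # lags J..1
    wk <- w[k]                                # warm start
    for (it in 1:100) {
      wk_new <- base + c0 * psi_eval(psi, wk)
      done <- abs(wk_new - wk) <= 1e-15 * abs(wk_new)
      wk <- wk_new
      if (done) break
    }
    w[k + 1L] <- wk
    P[k + J + 1L] <- psi_eval(psi, wk)
  }
  structure(data.frame(time = seq(0, K) * h, w = w), h = h)
}

#' Solve a system of renewal equations (multitype)
#'
#' Componentwise trapezoidal marching for
#' `w_i(t) = sum_m integral b_im(tau) Psi_m(w_m(t - tau)) dtau`,
#' the cyclic-transmission (two-sex / host-vector) analogue of [solve_re()].
#' The implicit diagonal contribution is resolved by vector fixed-point
#' iteration.
#'
#' @param arcs an `m x m` list-matrix; entry `[i, m]` is a `km_kernel`
#'   (the kernel `b_m` of transmitters of type `m` infecting type `i`) or
#'   `NULL` for an absent arc.
#' @param psis list of `m` `km_psi` objects, one per transmitter type.
#' @param h time step.
#' @param t_end end time.
#' @param histories list of `m` history functions of `t <= 0`.
#' @param tail_tol neglected kernel tail mass.
#' @return A data frame with columns `time`, `w_1`, ..., `w_m`.
#' @export
solve_re_system <- function(arcs, psis, h, t_end, histories, tail_tol = 1e-10) {
  m <- nrow(arcs)
  stopifnot(ncol(arcs) == m, length(psis) == m, length(histories) == m)
  present <- !vapply(arcs, is.null, logical(1))
  dim(present) <- c(m, m)
  if (!any(present)) {
    K <- as.integer(round(t_end / h))
    out <- data.frame(time = seq(0, K) * h)
    for (i in seq_len(m)) out[[paste0("w_", i)]] <- rep(0, K + 1L)
    return(out)
  }
  tau_max <- max(vapply(arcs[present], truncate_kernel, numeric(1),
                        tail_tol = tail_tol, h = h))
  J <- as.integer(round(tau_max / h))
  K <- as.integer(round(t_end / h))
  # tabulated, trapezoid-weighted arc kernels
  WT <- vector("list", m * m); dim(WT) <- c(m, m)
  C0 <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (present[i, j]) {
    wt <- h * kernel_tabulate(arcs[[i, j]], h, J)
    wt[1L] <- wt[1L] / 2
    wt[J + 1L] <- wt[J + 1L] / 2
    C0[i, j] <- wt[1L]
    WT[[i, j]] <- rev(wt[-1L])
  }
  # P[[j]][m + J + 1] = Psi_j(w_j(m h))
  P <- vector("list", m)
  w <- matrix(0, K + 1L, m)
  for (j in seq_len(m)) {
    P[[j]] <- numeric(K + J + 1L)
    w_hist <- histories[[j]](seq(-J, 0) * h)
    P[[j]][1:(J + 1L)] <- psi_eval(psis[[j]], w_hist)
    w[1L, j] <- w_hist[J + 1L]
  }
  for (k in seq_len(K)) {
    base <- numeric(m)
    for (i in seq_len(m)) for (j in seq_len(m)) if (present[i, j])
      base[i] <- base[i] + sum(WT[[i, j]] * P[[j]][(k + 1L):(k + J)])
    wk <- w[k, ]
    for (it in 1:100) {
      pv <- vapply(seq_len(m), function(j) psi_eval(psis[[j]], wk[j]), numeric(1))
      wk_new <- base + as.numeric(C0 %*% pv)
      done <- max(abs(wk_new - wk)) <= 1e-15 * max(abs(wk_new))
      wk <- wk_new
      if (done) break
    }
    w[k + 1L, ] <- wk
    for (j in seq_len(m)) P[[j]][k + J + 1L] <- psi_eval(psis[[j]], wk[j])
  }
  out <- data.frame(time = seq(0, K) * h)
  for (i in seq_len(m)) out[[paste0("w_", i)]] <- w[, i]
  out
}
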