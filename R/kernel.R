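#' Compartmental kernel triple (V, Sigma, U)
#'
#' A compartmental outbreak model with `n` infected compartments is coded by
#' the triple (V, Sigma, U): `V` is the probability distribution of the
#' state-at-infection (length-`n`, nonnegative, summing to at most 1), `Sigma`
#' is the `n x n` transition-rate matrix among infected states (subgenerator:
#' nonnegative off-diagonal entries, eigenvalues with strictly negative real
#' part), and `U` holds the per-compartment contribution rates to the force of
#' infection. The scalar infectivity kernel is `b(tau) = U exp(tau Sigma) V`.
#'
#' `Sigma[i, j]` is the rate from compartment `j` into compartment `i`
#' (column-to-row convention, matching `dQ/dt = Sigma Q`).
#'
#' @param U numeric vector, length `n`, nonnegative, at least one positive.
#'   Units 1/(time x individual).
#' @param Sigma numeric `n x n` matrix of transition rates (1/time).
#' @param V numeric vector, length `n`, nonnegative, `sum(V)` in (0, 1].
#' @param validate logical; check invariants on construction (default `TRUE`).
#'
#' @return An object of class `km_kernel` with fields `n`, `U`, `Sigma`, `V`.
#' @seealso [validate_kernel()], [kernel_eval()], [sir_model()]
#' @export
#' @examples
#' k <- compartment_kernel(U = 0.0005, Sigma = matrix(-0.25), V = 1)
#' kernel_eval(k, c(0, 1, 4))
compartment_kernel <- function(U, Sigma, V, validate = TRUE) {
  if (is.vector(Sigma) && length(Sigma) == 1L) Sigma <- matrix(Sigma, 1L, 1L)
  if (!is.matrix(Sigma) || nrow(Sigma) != ncol(Sigma))
    stop("Sigma must be a square matrix", call. = FALSE)
  n <- nrow(Sigma)
  U <- as.numeric(U)
  V <- as.numeric(V)
  if (length(U) != n || length(V) != n)
    stop(sprintf("dimension mismatch: Sigma is %dx%d but length(U)=%d, length(V)=%d",
                 n, n, length(U), length(V)), call. = FALSE)
  if (!all(is.finite(U)) || !all(is.finite(Sigma)) || !all(is.finite(V)))
    stop("U, Sigma, V must be finite", call. = FALSE)
  k <- structure(list(n = n, U = U, Sigma = Sigma, V = V), class = "km_kernel")
  if (validate) {
    rep <- validate_kernel(k)
    if (!rep$ok)
      stop("invalid kernel: ", paste(rep$violations, collapse = "; "), call. = FALSE)
    if (sum(V) < 1 - 1e-12)
      warning("sum(V) < 1: the deficit is interpreted as infections that never contribute",
              call. = FALSE)
  }
  k
}

#' Validate a compartmental kernel triple
#'
#' Checks the subgenerator structure of `Sigma` (nonnegative off-diagonal,
#' nonpositive diagonal, all eigenvalues with real part below `-1e-12`), the
#' sign and normalisation conditions on `U` and `V`. Structural defects
#' (non-square `Sigma`, length mismatches) raise an error in
#' [compartment_kernel()] instead; this function reports invariant failures.
#'
#' @param kernel a `km_kernel` (or a bare list with fields `U`, `Sigma`, `V`).
#' @return A list with `ok` (logical) and `violations` (character vector).
#' @export
validate_kernel <- function(kernel) {
  U <- kernel$U; Sigma <- kernel$Sigma; V <- kernel$V
  n <- nrow(Sigma)
  bad <- character(0)
  offdiag <- Sigma; diag(offdiag) <- 0
  if (any(offdiag < 0)) bad <- c(bad, "off-diagonal entry of Sigma is negative")
  if (any(diag(Sigma) > 0)) bad <- c(bad, "diagonal entry of Sigma is positive")
  ev <- eigen(Sigma, only.values = TRUE)$values
  if (max(Re(ev)) > -1e-12)
    bad <- c(bad, "eigenvalue real part not negative")
  if (any(V < 0)) bad <- c(bad, "entry of V is negative")
  sv <- sum(V)
  if (!(sv > 0 && sv <= 1 + 1e-12)) bad <- c(bad, "sum(V) not in (0, 1]")
  if (any(U < 0)) bad <- c(bad, "entry of U is negative")
  if (!any(U > 0)) bad <- c(bad, "U has no positive entry")
  list(ok = length(bad) == 0L, violations = bad)
}

#' Evaluate the infectivity kernel b(tau) = U exp(tau Sigma) V
#'
#' Dense matrix exponential (scaling-and-squaring); vectorised over a grid of
#' nonnegative `tau` values.
#'
#' @param kernel a `km_kernel`.
#' @param tau nonnegative scalar or vector of times since infection.
#' @return Numeric vector `b(tau)`, same length as `tau`.
#' @export
kernel_eval <- function(kernel, tau) {
  if (any(tau < 0)) stop("tau must be nonnegative", call. = FALSE)
  vapply(tau, function(t1) {
    as.numeric(kernel$U %*% (mexp(t1 * kernel$Sigma) %*% kernel$V))
  }, numeric(1))
}

# dense matrix exponential, accurate to near machine precision
#' @importFrom Matrix expm Matrix
mexp <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

#' Tabulate b(tau) on a uniform grid
#'
#' Computes `b(j h)` for `j = 0..J` by repeated multiplication with the single
#' step matrix `exp(h Sigma)`; for a subgenerator the step matrix is
#' substochastic-like (norm <= 1), so the accumulated rounding stays near
#' machine precision even for long grids.
#'
#' @param kernel a `km_kernel`.
#' @param h grid step (> 0).
#' @param J number of steps; the grid is `0, h, ..., J h`.
#' @return Numeric vector of length `J + 1`.
#' @keywords internal
#' @export
kernel_tabulate <- function(kernel, h, J) {
  stopifnot(h > 0, J >= 0)
  Eh <- mexp(h * kernel$Sigma)
  b <- numeric(J + 1L)
  Ucur <- kernel$U              # row vector propagated: U e^{jh Sigma}
  b[1L] <- sum(Ucur * kernel$V)
  if (J >= 1L) for (j in seq_len(J)) {
    Ucur <- as.numeric(Ucur %*% Eh)
    b[j + 1L] <- sum(Ucur * kernel$V)
  }
  b
}

#' Total kernel mass and first moment
#'
#' `kernel_mass` returns the integral of b over (0, Inf), computed as
#' `-U Sigma^-1 V` by a linear solve. `kernel_first_moment` returns the
#' integral of `tau b(tau)`, equal to `U Sigma^-2 V`.
#'
#' @param kernel a `km_kernel`.
#' @return A scalar.
#' @keywords internal
#' @export
kernel_mass <- function(kernel) {
  -as.numeric(kernel$U %*% solve(kernel$Sigma, kernel$V))
}

#' @rdname kernel_mass
#' @export
kernel_first_moment <- function(kernel) {
  x1 <- solve(kernel$Sigma, kernel$V)
  as.numeric(kernel$U %*% solve(kernel$Sigma, x1))
}

#' Random valid kernel triples for testing
#'
#' Deterministic-in-seed generator of valid subgenerator triples: nonnegative
#' off-diagonal `Sigma` entries with diagonals making every column sum
#' strictly negative, nonnegative `U`, and a probability vector `V`. The RNG
#' state of the session is left untouched.
#'
#' @param n number of compartments (>= 1).
#' @param seed integer seed.
#' @return A valid `km_kernel`.
#' @export
random_kernel_fixture <- function(n, seed) {
  stopifnot(n >= 1)
  out <- local_rng(seed, {
    Sigma <- matrix(stats::runif(n * n, 0, 1), n, n)
    diag(Sigma) <- 0
    # make each column strictly diagonally dominant (negative column sums)
    diag(Sigma) <- -(colSums(Sigma) + stats::runif(n, 0.2, 1.5))
    U <- stats::runif(n, 0, 1)
    V <- stats::runif(n, 0.05, 1)
    V <- V / sum(V)
    list(U = U, Sigma = Sigma, V = V)
  })
  compartment_kernel(out$U, out$Sigma, out$V)
}

#' Random supercritical model fixture
#'
#' Builds a random kernel with [random_kernel_fixture()], optionally attaches
#' a trait model, and rescales `U` so that the basic reproduction number
#' equals `R0_target` exactly.
#'
#' @param n number of compartments.
#' @param seed integer seed.
#' @param N population size.
#' @param R0_target desired basic reproduction number (> 0).
#' @param trait optional `km_trait` heterogeneity model.
#' @return A `km_model` (see [model_spec()]).
#' @export
random_model_fixture <- function(n, seed, N = 1000, R0_target = 2, trait = NULL) {
  k <- random_kernel_fixture(n, seed)
  m0 <- model_spec(N, k, trait)
  scale <- R0_target / r0(m0)
  k2 <- compartment_kernel(k$U * scale, k$Sigma, k$V)
  model_spec(N, k2, trait)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.km_kernel <- function(x, ...) {
  cat(sprintf("<km_kernel> n = %d compartments\n", x$n))
  cat("  U:", format(x$U, digits = 4), "\n")
  cat("  V:", format(x$V, digits = 4), "\n")
  cat("  b(0) =", format(sum(x$U * x$V), digits = 6),
      " mass =", format(kernel_mass(x), digits = 6), "\n")
  invisible(x)
}
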