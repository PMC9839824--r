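# Shared benchmark models and small utilities for the suite.

# SIR benchmark: R0 = 2, r = 0.25, T = 4
sir_bench <- function(trait = NULL) sir_model(beta = 5e-4, alpha = 0.25, N = 1000,
                                              trait = trait)

# SEIR benchmark with equal stage rates (defective Sigma on purpose)
seir_bench <- function() seir_model(beta = 5e-4, gamma = 0.25, alpha = 0.25, N = 1000)

# quarantine-SEIR parameter set used in closed-form cross-checks
quarantine_bench <- function(N = 1) quarantine_seir_model(
  p = 0.5, gamma1 = 0.5, gamma2 = 0.5, alpha1 = 0.2, alpha2 = 0.2,
  theta = 0.1, beta1 = 0.3, beta2 = 0.3, N = N)

# two-sex SIR-like benchmark: multitype R0 = 2
two_sex_bench <- function() {
  k <- compartment_kernel(U = 5e-4, Sigma = matrix(-0.25), V = 1)
  two_sex_model(1000, 1000, k, k)
}

# positive root of w = R0 (1 - exp(-w)), by bisection (independent oracle)
final_size_oracle <- function(R0) {
  stopifnot(R0 > 1)
  uniroot(function(w) R0 * (1 - exp(-w)) - w, c(1e-9, 50), tol = 1e-15)$root
}

# mixed homogeneous/heterogeneous fixture battery used by equivalence tests
fixture_models <- function(k = 5) {
  traits <- list(NULL,
                 trait_gamma(1, "constant_one"),
                 trait_discrete(c(0.5, 0.5), a = c(1, 0.5), c_vals = c(1, 2)),
                 NULL,
                 trait_gamma(2, "proportional"))
  lapply(seq_len(k), function(i)
    random_model_fixture(n = 2 + (i %% 3), seed = 100 + i, N = 1000,
                         R0_target = 1.5 + 0.3 * i,
                         trait = traits[[1 + (i - 1) %% length(traits)]]))
}

# slope of log w on the early (linear) phase of a trajectory
early_slope <- function(traj, lo = 1e-7, hi = 1e-4) {
  sel <- traj$w > lo & traj$w < hi
  stopifnot(sum(sel) > 10)
  unname(coef(lm(log(w) ~ time, data = traj[sel, ]))[2])
}
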