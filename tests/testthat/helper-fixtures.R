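## Shared fixtures: the reference strain (Table-style defaults) and its
## periodic solutions, computed once per test run.

fix_div <- division_params()
fix_kin <- kinetic_params(gamma = fix_div$gamma_M)
fix_kin_weak <- kinetic_params(rho = 0.87, gamma = fix_div$gamma_M)

fix_ps_mother <- find_periodic_solutions("MOTHER", fix_kin, fix_div)
fix_ps_daughter <- find_periodic_solutions("DAUGHTER", fix_kin, fix_div)

fp_states <- function(set) t(sapply(set, function(p) p$state))
fp_stabilities <- function(set) vapply(set, function(p) p$stability, "")

stable_prion_state <- function(set) {
  S <- vapply(set, function(p) p$state[["S"]], 0)
  st <- fp_stabilities(set)
  ix <- which(st == "STABLE" & S > 1e-3)
  if (!length(ix)) return(NULL)
  set[[ix[which.max(S[ix])]]]$state
}

## Independent fixed-step RK4 integrator of the same vector field, used as
## the reference for the adaptive integration.
rk4_oracle <- function(state, kin, gamma, duration, h = 1e-4) {
  f <- function(y) {
    V <- y[1]; S <- y[2]
    fs <- if (S > 0) S^kin$n / (kin$K^kin$n + S^kin$n) else 0
    r <- kin$rho * V * fs
    c(kin$lam - gamma * V - r, r - gamma * S)
  }
  n <- round(duration / h)
  y <- as.numeric(state)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
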