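# Shared fixtures, built in code.

# dX/dt = 1 - X : the minimal relaxation model with closed-form solution.
fix_relax <- function(x0 = 2) {
  gma_model(
    variable_spec("X", "dependent", x0),
    list(X = list(power_law_term(1, numeric(0), +1L, flux_id = "vin"),
                  power_law_term(1, c(X = 1), -1L, flux_id = "vout"))))
}

# two-pool linear cascade: X1' = k0 - k1 X1 ; X2' = k1 X1 - k2 X2
fix_cascade <- function(k1 = 1, k2 = 2, k0 = 1) {
  gma_model(
    variable_spec(c("X1", "X2"), c("dependent", "dependent"),
                  c(k0 / k1, k0 / k2)),
    list(X1 = list(power_law_term(k0, numeric(0), +1L, flux_id = "v0"),
                   power_law_term(k1, c(X1 = 1), -1L, flux_id = "v1")),
         X2 = list(power_law_term(k1, c(X1 = 1), +1L, flux_id = "v1"),
                   power_law_term(k2, c(X2 = 1), -1L, flux_id = "v2"))))
}

# single pool fed by an independent source: dX/dt = a XI^g - b X^h
fix_single <- function(a = 1, b = 1, g = 1, h = 2, xi = 5) {
  xstar <- (a * xi^g / b)^(1 / h)
  gma_model(
    variable_spec(c("X", "XI"), c("dependent", "independent"), c(xstar, xi)),
    list(X = list(power_law_term(a, c(XI = g), +1L, flux_id = "vin"),
                  power_law_term(b, c(X = h), -1L, flux_id = "vout"))))
}

# central finite-difference Jacobian of the GMA right-hand side
fd_jacobian <- function(model, state = basal_state(model, "dependent"),
                        rel_h = 1e-6) {
  dep <- dependent_names(model)
  indep <- basal_state(model, "independent")
  n <- length(dep)
  J <- matrix(0, n, n, dimnames = list(dep, dep))
  for (j in seq_len(n)) {
    h <- rel_h * state[j]
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (gma_derivatives(model, c(up, indep)) -
               gma_derivatives(model, c(dn, indep))) / (2 * h)
  }
  J
}

# seeds used by the fixture-sweep property tests
PROPERTY_SEEDS <- 1:20
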