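test_that("aggregating single-term equations is the identity", {
  m <- fix_single(a = 2, b = 3, g = 0.5, h = 1.2, xi = 2)
  ss <- as_ssystem(m)
  expect_equal(unname(ss$alpha), 2)
  expect_equal(unname(ss$beta), 3)
  expect_equal(ss$G["X", "XI"], 0.5)
  expect_equal(ss$H["X", "X"], 1.2)
})

test_that("aggregation flux-weights the kinetic orders", {
  # two influxes at the operating point X1=1, X2=1: v1 = 2 (order 1 in X2),
  # v2 = 2 (order 0) -> alpha = 4, g(X2) = (2*1 + 2*0)/4 = 0.5
  m <- gma_model(
    variable_spec(c("X1", "X2"), c("dependent", "independent"), c(1, 1)),
    list(X1 = list(power_law_term(2, c(X2 = 1), +1L, flux_id = "v1"),
                   power_law_term(2, numeric(0), +1L, flux_id = "v2"),
                   power_law_term(4, c(X1 = 1), -1L, flux_id = "v3"))))
  ss <- as_ssystem(m)
  expect_equal(unname(ss$alpha), 4)
  expect_equal(ss$G["X1", "X2"], 0.5)
  expect_equal(unname(ss$Vin), unname(ss$Vout))
  expect_error(as_ssystem(gma_model(
    variable_spec("X", "dependent", 1),
    list(X = list(power_law_term(1, c(X = 1), -1L))))), "no influx")
})

test_that("SL-E aggregation is consistent at the balanced basal state", {
  ss <- as_ssystem(sle_model("balanced"))
  expect_lt(max(abs(ss$Vin - ss$Vout) / ss$Vin), 1e-9)
  # and the aggregated steady state recovers the basal dependents
  st <- steady_state_log(ss)
  basal <- ss$operating_point[ss$dependent]
  expect_lt(max(abs(st - basal) / basal), 1e-3)
})

test_that("log-space steady state matches closed forms", {
  m <- fix_single(a = 1, b = 1, g = 1, h = 1, xi = 1)
  expect_equal(unname(steady_state_log(as_ssystem(m))), 1)
  # dX/dt = XI - X^2 with XI = 5: X* = sqrt(5)
  m2 <- fix_single(a = 1, b = 1, g = 1, h = 2, xi = 5)
  expect_equal(unname(steady_state_log(as_ssystem(m2))), sqrt(5),
               tolerance = 1e-12)
  # substituting back gives zero net rate
  ss <- as_ssystem(m2)
  st <- steady_state_log(ss)
  rate <- ssystem_rates(ss, c(st, XI = 5))
  expect_lt(abs(rate) / ss$Vin, 1e-9)
})

test_that("singular aggregate systems are reported with diagnostics", {
  # two pools with identical kinetic dependence -> A_D singular
  m <- gma_model(
    variable_spec(c("A", "B", "E"), c("dependent", "dependent", "independent"),
                  c(1, 1, 1)),
    list(A = list(power_law_term(1, c(E = 1), +1L),
                  power_law_term(1, c(A = 1, B = -1), -1L)),
         B = list(power_law_term(1, c(E = 1), +1L),
                  power_law_term(1, c(A = 1, B = -1), -1L))))
  expect_error(steady_state_log(as_ssystem(m)), "singular|rank")
})

test_that("stability eigenvalues match analytic Jacobians", {
  expect_equal(as.numeric(stability_eigenvalues(as_ssystem(fix_relax(1)))),
               -1)
  ev <- sort(Re(stability_eigenvalues(as_ssystem(fix_cascade(1, 2)))))
  expect_equal(ev, c(-2, -1), tolerance = 1e-10)
})

test_that("S-system Jacobian agrees with finite differences of the GMA rhs", {
  m <- sle_model("balanced")
  ss <- as_ssystem(m)
  steady <- basal_state(m, "dependent")
  x <- c(steady, ss$operating_point[ss$independent])
  Vstar <- ss$alpha * exp(as.numeric(ss$G[, names(x)] %*% log(x)))
  AD <- (ss$G - ss$H)[, ss$dependent]
  J <- diag(Vstar) %*% AD %*% diag(1 / steady)
  Jfd <- fd_jacobian(m)
  scale <- max(abs(Jfd))
  expect_lt(max(abs(J - Jfd)) / scale, 1e-5)
})

test_that("log gains and rate-constant sensitivities verify against theory", {
  # single equation: L(X, XI) = g/h
  m <- fix_single(a = 1, b = 1, g = 1.2, h = 0.8, xi = 2)
  rep <- sensitivity_report(as_ssystem(m))
  expect_equal(rep$log_gains_metabolites["X", "XI"], 1.2 / 0.8)
  m2 <- fix_single(g = 0.9, h = 0.9)
  rep2 <- sensitivity_report(as_ssystem(m2))
  expect_equal(rep2$log_gains_metabolites["X", "XI"], 1.0)
  # antisymmetry S(X, alpha) = -S(X, beta)
  expect_equal(rep$rc_sensitivities_metabolites$alpha,
               -rep$rc_sensitivities_metabolites$beta)
})

test_that("sensitivities match brute-force perturbation of the steady state", {
  # 1% multiplicative perturbation, central differences in log space, with
  # the steady state re-found by long-time integration of the GMA system
  # (independent of the linear-algebra path)
  for (seed in c(3, 11, 19)) {
    m <- generate_gma(synth_spec(n_dependent = 6, n_independent = 2,
                                 seed = seed))
    ss <- as_ssystem(m)
    rep <- sensitivity_report(ss)
    ind <- independent_names(m)[1]
    settle <- function(model) {
      tr <- simulate_gma(model, t_end = 4000, times = c(0, 4000),
                         rtol = 1e-10, atol = 1e-12)
      tr$values[nrow(tr$values), ]
    }
    h <- log(1.01)
    up <- m; up$variables$value[up$variables$name == ind] <-
      up$variables$value[up$variables$name == ind] * exp(h)
    dn <- m; dn$variables$value[dn$variables$name == ind] <-
      dn$variables$value[dn$variables$name == ind] * exp(-h)
    L_fd <- (log(settle(up)) - log(settle(dn))) / (2 * h)
    L_an <- rep$log_gains_metabolites[, ind]
    expect_equal(L_an, L_fd[names(L_an)], tolerance = 1e-3)
  }
})

test_that("log gains are scale invariant; eigenvalues scale with rate", {
  m <- fix_cascade(1.3, 0.6)
  scale_all <- function(model, c_fac) {
    for (nm in names(model$equations))
      for (k in seq_along(model$equations[[nm]]))
        model$equations[[nm]][[k]]$gamma <-
          model$equations[[nm]][[k]]$gamma * c_fac
    model
  }
  m2 <- scale_all(m, 4)
  r1 <- sensitivity_report(as_ssystem(m))
  r2 <- sensitivity_report(as_ssystem(m2))
  expect_equal(r1$log_gains_metabolites, r2$log_gains_metabolites)
  expect_equal(sort(Re(r2$eigenvalues)), 4 * sort(Re(r1$eigenvalues)),
               tolerance = 1e-10)
})

test_that("top log-gain ranking applies the magnitude-above-one filter", {
  rep <- list(log_gains_metabolites =
                matrix(c(2, 0.5, 0.9, 0.2), 2, 2,
                       dimnames = list(c("X5", "X9"), c("E1", "E2"))))
  expect_equal(as.character(top_loggain_ranking(rep)), "X5")
  rep0 <- list(log_gains_metabolites =
                 matrix(0.4, 2, 2, dimnames = list(c("A", "B"), c("E", "F"))))
  expect_length(top_loggain_ranking(rep0), 0)
  # ties break by declaration order
  rept <- list(log_gains_metabolites =
                 matrix(c(1.5, 1.5), 2, 1,
                        dimnames = list(c("X2", "X1"), "E")))
  expect_equal(as.character(top_loggain_ranking(rept)), c("X2", "X1"))
})

test_that("S-system steady state equals the long-time GMA limit on fixtures", {
  for (seed in PROPERTY_SEEDS) {
    m <- generate_gma(synth_spec(n_dependent = 8, n_independent = 3,
                                 seed = seed))
    ss <- as_ssystem(m)
    st <- steady_state_log(ss)
    # start away from the steady state and let the GMA system settle
    m_off <- m
    dep_rows <- m_off$variables$role == "dependent"
    m_off$variables$value[dep_rows] <- m_off$variables$value[dep_rows] * 1.25
    tr <- simulate_gma(m_off, t_end = 10000, times = c(0, 10000))
    lim <- tr$values[nrow(tr$values), ]
    expect_lt(max(abs(lim - st[names(lim)]) / st[names(lim)]), 1e-3)
  }
})
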