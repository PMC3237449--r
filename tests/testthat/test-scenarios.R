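# Scenario runs are the slowest tests; reuse one model build where possible.

test_that("a zero-amount bolus leaves every labeled pool at zero", {
  m <- sle_model("dynamic")
  tr <- run_bolus(0, t_end = 30, model = m)
  expect_equal(max(abs(tr$L)), 0)
})

test_that("the acetate bolus enters at the published uptake rate", {
  m <- sle_model("dynamic")
  tr <- run_bolus(125, t_end = 5, dt = 0.5, model = m)
  # at t = 1+ the labeled uptake flux is 0.0022 * 0.93 * 125 uM/min; the
  # labeled internal-acetate pool grows at that rate initially
  k <- which(tr$times == 1)[length(which(tr$times == 1))]
  l38_rate <- unname(tr$L[k + 1, "X38"] - tr$L[k, "X38"]) /
    (tr$times[k + 1] - tr$times[k])
  expect_equal(l38_rate, 0.0022 * 0.93 * 125, tolerance = 0.02)
})

test_that("pulse-chase washes external label out at the chase time", {
  m <- sle_model("dynamic")
  tr <- run_pulse_chase(125, pulse_len = 30, t_end = 60, model = m)
  k_pre <- max(which(tr$times < 31))
  expect_gt(tr$L[k_pre, "X125"], 0)
  k_post <- max(which(tr$times == 31))
  expect_equal(unname(tr$L[k_post, "X125"]), 0)
  # external total is restored to the medium concentration, unlabeled
  expect_equal(unname(tr$U[k_post, "X125"]), 125)
  expect_error(run_pulse_chase(pulse_len = 0), "pulse_len")
  expect_error(run_bolus(-1), "label_amount")
})

test_that("a fraction-1 knockdown is identical to its control", {
  m <- sle_model("dynamic")
  kd <- run_knockdown("X157", 1, "pulse_chase", t_end = 40, model = m)
  expect_equal(kd$perturbed$values, kd$control$values, tolerance = 1e-10)
  expect_equal(kd$perturbed$L, kd$control$L, tolerance = 1e-10)
  expect_error(run_knockdown("X157", 0, t_end = 10, model = m), "fraction")
  expect_error(run_knockdown("X32", 0.5, t_end = 10, model = m),
               "independent")
})

test_that("wild-type total-mass fold changes are exactly one", {
  mb <- sle_model("balanced")
  tab <- total_mass_table(list(), times = c(60), model = mb)
  wt <- tab$raw[tab$raw$condition == "wild type", ]
  expect_equal(wt$fold, rep(1, nrow(wt)), tolerance = 1e-9)
})

test_that("knockdown fold-change tables have the expected directions", {
  mb <- sle_model("balanced")
  tab <- total_mass_table(
    list("1% SPT" = list(enzyme = "X157", fraction = 0.01)),
    times = c(60), model = mb)
  raw <- tab$raw
  g <- function(pool) raw$fold[raw$pool == pool & raw$condition == "1% SPT"]
  # raft/CS-associated ergosterol falls; free sub-populations rise;
  # complex sphingolipids fall
  expect_lt(g("X37"), 1)
  expect_gt(g("X36"), 1)
  expect_gt(g("X39"), 1)
  expect_lt(g("CS"), 1)
  expect_lt(g("IPC"), 1)
})

test_that("scenario runs are deterministic at reporting precision", {
  mb <- sle_model("balanced")
  conds <- list("1% IPC synthase" = list(enzyme = "X133", fraction = 0.01))
  t1 <- total_mass_table(conds, times = 60, model = mb)
  t2 <- total_mass_table(conds, times = 60, model = mb)
  expect_identical(t1$ergosterol_subpops, t2$ergosterol_subpops)
})

test_that("declarative YAML scenarios run through the same machinery", {
  f <- system.file("scenarios", "total_mass.yaml", package = "sleBST")
  expect_true(nzchar(f))
  sc <- yaml::read_yaml(f)
  expect_equal(sc$kind, "total_mass")
  # run a reduced inline copy to keep the suite fast
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "reduced", kind = "total_mass",
                        times = list(60),
                        conditions = list(
                          "12.5% Ceramide synthase" =
                            list(enzyme = "X134", fraction = 0.125))), tmp)
  out <- run_scenario(tmp)
  expect_true(is.data.frame(out$ergosterol_subpops))
  expect_equal(out$ergosterol_subpops$time, c(60, 60))
})
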