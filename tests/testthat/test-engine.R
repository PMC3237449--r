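test_that("simulation matches the closed-form relaxation solution", {
  m <- fix_relax(x0 = 2)
  tr <- simulate_gma(m, t_end = 20)
  expect_equal(unname(tr$values[tr$times == 0, "X"]), 2)
  expect_equal(unname(tr$values[tr$times == 20, "X"]), 1 + exp(-20),
               tolerance = 1e-8)
  mid <- unname(tr$values[tr$times == 5, "X"])
  expect_equal(mid, 1 + exp(-5), tolerance = 1e-8)
})

test_that("interventions restart the trajectory as discontinuities", {
  m <- fix_relax(x0 = 2)
  tr <- simulate_gma(m, list(intervention(5, "set_value", "X", 2)),
                     t_end = 15)
  # post-event value at t = 5 is the reset value
  expect_equal(unname(tr$values[tr$times == 5, "X"]), 2)
  expect_equal(unname(tr$values[tr$times == 10, "X"]), 1 + exp(-5),
               tolerance = 1e-7)
  # scale and bolus semantics
  tr2 <- simulate_gma(m, list(intervention(0, "add_bolus", "X", 3)),
                      t_end = 1)
  expect_equal(unname(tr2$values[1, "X"]), 5)
  # scaling an independent changes the flux from that segment on
  ms <- fix_single(a = 1, b = 1, g = 1, h = 1, xi = 1)   # X* = 1
  tr3 <- simulate_gma(ms, list(intervention(2, "scale_value", "XI", 2)),
                      t_end = 60)
  expect_equal(unname(tr3$values[tr3$times == 60, "X"]), 2,
               tolerance = 1e-6)
})

test_that("unforced SL-E simulation holds every pool at basal", {
  m <- sle_model("dynamic")
  tr <- simulate_gma(m, t_end = 120)
  basal <- basal_state(m, "dependent")
  dev <- apply(tr$values, 1, function(row) max(abs(row - basal) / basal))
  expect_lt(max(dev), 1e-3)   # within 0.1% of basal over 120 min
})

test_that("halving integrator tolerances leaves reported values unchanged", {
  m <- sle_model("dynamic")
  iv <- list(intervention(0, "scale_value", "X157", 0.01))
  a <- simulate_gma(m, iv, t_end = 60, dt = 30, rtol = 1e-8, atol = 1e-10)
  b <- simulate_gma(m, iv, t_end = 60, dt = 30, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$values - b$values) / abs(b$values)), 1e-3)
})

test_that("maximal amplitude is the largest relative excursion", {
  fake <- structure(list(times = 0:2,
                         values = cbind(X = c(1, 1.5, 1.2))),
                    class = "gma_trajectory")
  expect_equal(maximal_amplitude(fake, "X"), 0.5)
  flat <- structure(list(times = 0:5, values = cbind(X = rep(2, 6))),
                    class = "gma_trajectory")
  expect_equal(maximal_amplitude(flat, "X"), 0)
  dip <- structure(list(times = 0:3, values = cbind(X = c(2, 1.5, 0.5, 1.8))),
                   class = "gma_trajectory")
  expect_equal(maximal_amplitude(dip, "X"), (0.5 - 2) / 2)
  expect_error(maximal_amplitude(fake, "X", window = c(10, 20)), "empty window")
})

test_that("pool aggregation is an element-wise sum", {
  m <- fix_cascade()
  tr <- simulate_gma(m, t_end = 5)
  expect_equal(aggregate_pools(tr, "X1"), unname(tr$values[, "X1"]))
  expect_equal(aggregate_pools(tr, c("X1", "X2")),
               unname(tr$values[, "X1"] + tr$values[, "X2"]))
  expect_error(aggregate_pools(tr, "nope"), "unknown variable")
})

test_that("trajectory exports and provenance are consistent", {
  m <- fix_cascade()
  tr <- simulate_gma(m, t_end = 3)
  expect_equal(tr$model_hash, model_hash(m))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(back$X1, unname(tr$values[, "X1"]))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), length(tr$times) * 2)
})
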