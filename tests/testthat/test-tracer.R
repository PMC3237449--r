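test_that("labeling maps must cover every flux and name declared donors", {
  m <- fix_cascade()
  expect_error(labeling_map(m, list(v0 = "unlabeled")), "unassigned")
  expect_error(labeling_map(m, list(v0 = "unlabeled", v1 = "Z", v2 = "X2")),
               "undeclared donor")
  map <- labeling_map(m, list(v0 = "unlabeled", v1 = "X1", v2 = "X2"))
  expect_s3_class(map, "labeling_map")
})

test_that("zero initial label stays zero and totals reproduce the base model", {
  ch <- generate_labeled_chain(length = 3, rates = c(0.5, 1, 2))
  lm0 <- split_labels(ch$model, ch$map)          # nothing labeled
  tr <- simulate_labeled(lm0, t_end = 20)
  expect_equal(max(abs(tr$L)), 0)
  base <- simulate_gma(ch$model, t_end = 20)
  expect_lt(max(abs(tr$values - base$values)), 1e-7)
})

test_that("label fractions follow the closed-form chain solutions", {
  # single product, rate k, source fraction 1: f(t) = 1 - exp(-k t)
  k <- 0.7
  ch <- generate_labeled_chain(length = 1, rates = k)
  tr <- simulate_labeled(ch$lmodel, t_end = 10, dt = 0.5)
  f <- label_fraction(tr, "P1")
  expect_equal(f, 1 - exp(-k * tr$times), tolerance = 1e-6,
               ignore_attr = TRUE)
  # source held at fraction 0.5: product converges to 0.5 at its turnover
  ch2 <- generate_labeled_chain(length = 1, rates = k, source_fraction = 0.5)
  tr2 <- simulate_labeled(ch2$lmodel, t_end = 12, dt = 0.5)
  f2 <- label_fraction(tr2, "P1")
  expect_equal(f2, 0.5 * (1 - exp(-k * tr2$times)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # multi-pool convolution formula, distinct rates
  ch3 <- generate_labeled_chain(length = 3, rates = c(0.3, 0.9, 1.7))
  tr3 <- simulate_labeled(ch3$lmodel, t_end = 15, dt = 1)
  f3 <- label_fraction(tr3, "P3")
  expect_equal(f3, ch3$closed_form(tr3$times, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("fully labeled source saturates every downstream fraction to 1", {
  ch <- generate_labeled_chain(length = 4, rates = c(2, 1, 0.5, 0.25))
  tr <- simulate_labeled(ch$lmodel, t_end = 80, dt = 2)
  for (p in c("P1", "P2", "P3", "P4")) {
    f <- label_fraction(tr, p)
    expect_true(all(diff(f) > -1e-9))          # monotone saturation
    expect_gt(f[length(f)], 0.99)
  }
})

test_that("label bookkeeping conserves mass on seeded chain fixtures", {
  for (seed in PROPERTY_SEEDS) {
    set.seed(seed)
    len <- sample(2:5, 1)
    rates <- exp(stats::runif(len, -1.5, 1))
    frac <- stats::runif(1)
    ch <- generate_labeled_chain(length = len, rates = rates,
                                 source_fraction = frac)
    tr <- simulate_labeled(ch$lmodel, t_end = 30, dt = 5)
    base <- simulate_gma(ch$model, t_end = 30, dt = 5)
    rel <- abs(tr$values - base$values) / base$values
    expect_lt(max(rel), 1e-6)
    f <- sapply(colnames(tr$L), function(p) label_fraction(tr, p))
    expect_true(all(f >= 0 & f <= 1 + 1e-12))
  }
})

test_that("blocked fluxes move mass but discard the label", {
  # source fully labeled; transfer flux blocked -> product stays unlabeled
  ch <- generate_labeled_chain(length = 2, rates = c(1, 1.5))
  blocked <- ch$map$assignments
  blocked[["v1"]] <- "blocked"
  lm <- split_labels(ch$model, labeling_map(ch$model, blocked),
                     c(S = 1))
  tr <- simulate_labeled(lm, t_end = 20)
  expect_equal(max(label_fraction(tr, "P2")), 0)
  expect_gt(max(label_fraction(tr, "P1")), 0.9)     # upstream still labels
  base <- simulate_gma(ch$model, t_end = 20)
  expect_lt(max(abs(tr$values - base$values) / base$values), 1e-6)
})

test_that("labeled aggregate series and refinement agree", {
  ch <- generate_labeled_chain(length = 2, rates = c(0.4, 0.8))
  a <- simulate_labeled(ch$lmodel, t_end = 25, dt = 5)
  b <- simulate_labeled(ch$lmodel, t_end = 25, dt = 5,
                        rtol = 5e-9, atol = 5e-11)
  expect_equal(label_fraction(a, "P2"), label_fraction(b, "P2"),
               tolerance = 1e-4)
  expect_equal(labeled_series(a, c("P1", "P2")),
               unname(a$L[, "P1"] + a$L[, "P2"]))
})

test_that("ester count correction applies 27/43 only in acyl-donor mode", {
  expect_equal(cpm_corrected_esters(43, acyl_labeled = TRUE), 27)
  expect_equal(cpm_corrected_esters(0, acyl_labeled = TRUE), 0)
  sig <- c(1.2, 3.4)
  expect_identical(cpm_corrected_esters(sig, acyl_labeled = FALSE), sig)
})

test_that("labeling map YAML serialization round-trips", {
  ch <- generate_labeled_chain(length = 2)
  f <- tempfile(fileext = ".yaml")
  write_labeling_yaml(ch$map, f)
  back <- read_labeling_yaml(ch$model, f)
  expect_equal(back$assignments[order(names(back$assignments))],
               ch$map$assignments[order(names(ch$map$assignments))])
})
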