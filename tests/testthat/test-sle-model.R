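test_that("the SL-E roster and basal state honor the published constraints", {
  m <- sle_model("dynamic")
  basal <- basal_state(m)
  # dependent pools X1..X40 present; key independent enzymes declared
  expect_true(all(sprintf("X%d", 25:40) %in% dependent_names(m)))
  expect_true(all(c("X133", "X134", "X157", "X171", "X179", "X181", "X182",
                    "X183", "X186") %in% independent_names(m)))
  # basal sterol distribution (percent of wild-type total sterols)
  pct <- percent_total_sterols(basal[c("X32", "X36", "X37", "X39")])
  expect_equal(unname(pct), c(9.51, 4.75, 42.80, 47.55))
  # 9:1 free-sterol : raft split on the outer leaflet (X37 >> X36)
  expect_equal(basal[["X37"]] / (basal[["X37"]] + basal[["X36"]]), 0.9,
               tolerance = 0.001)
  # 10:1 lipid-particle ergosteryl-ester sub-pools
  expect_equal(basal[["X35"]] / basal[["X40"]], 10)
  # acetate uptake: rate constant 0.0022 on undissociated external acetate
  up <- Filter(function(tm) identical(tm$flux_id, "v125,38"),
               m$equations$X38)[[1]]
  expect_equal(up$gamma, 0.0022)
  expect_equal(up$factors, c(X125 = 1, X126 = 1))
  expect_equal(basal[["X126"]], 0.93)
  expect_equal(evaluate_flux(up, basal), 0.0022 * 125 * 0.93)
})

test_that("pool aggregates reproduce the published wild-type reference rows", {
  basal <- basal_state(sle_model("dynamic"))
  pools <- sle_pools()
  pct <- function(v) sum(percent_total_sterols(basal[v]))
  expect_equal(pct(pools$pm_ergosterol), 95.1)
  expect_equal(pct(pools$total_ergosterol), 104.61)
  expect_equal(pct(pools$total_erg_esters), 45.7)
  expect_equal(pct(pools$total_sterols), 112.91)
  expect_equal(pct(pools$total_steryl_esters), 62.2)
  # complex sphingolipid classes in mol%
  expect_equal(sum(basal[pools$IPC]), 1.02)
  expect_equal(sum(basal[pools$MIPC]), 1.40)
  expect_equal(sum(basal[pools$MIP2C]), 0.085)
  expect_equal(sum(basal[pools$CS]), 2.505)
  # fixed denominator: doubling every sterol pool doubles every entry
  expect_equal(percent_total_sterols(2 * basal[pools$total_sterols]),
               2 * percent_total_sterols(basal[pools$total_sterols]))
})

test_that("both variants are exact steady states and pass their checklists", {
  for (variant in c("dynamic", "balanced")) {
    m <- sle_model(variant)
    basal <- basal_state(m, "dependent")
    expect_lt(max(abs(gma_derivatives(m)) / basal), 1e-9)
    expect_true(validate_sle_structure(m, variant))
  }
  # the Yeh2p ester hydrolysis flux exists only in the dynamic variant
  ids <- function(m) unique(unlist(lapply(m$equations, function(tl)
    vapply(tl, `[[`, "", "flux_id"))))
  expect_true("v40,39" %in% ids(sle_model("dynamic")))
  expect_false("v40,39" %in% ids(sle_model("balanced")))
})

test_that("flux balancing equalizes pairs, is idempotent, and keeps steadiness", {
  m <- sle_model("dynamic")
  b <- balance_fluxes(m, sle_balance_pairs(), zero_fluxes = "v40,39")
  basal <- basal_state(b)
  fx <- gma_fluxes(b, basal)
  for (pr in sle_balance_pairs())
    expect_equal(fx[[pr[1]]], fx[[pr[2]]], tolerance = 1e-12)
  # balancing an already balanced model changes nothing
  b2 <- balance_fluxes(b, sle_balance_pairs())
  expect_true(gma_equal(b, b2))
  # a pair with forward = 2 x backward: the backward gamma is doubled and
  # the slack fluxes at both pools re-absorb the residuals
  toy <- gma_model(
    variable_spec(c("A", "B"), c("dependent", "dependent"), c(1, 1)),
    list(A = list(power_law_term(1.5, numeric(0), +1L, flux_id = "vin"),
                  power_law_term(1, c(B = 1), +1L, flux_id = "vb"),
                  power_law_term(2, c(A = 1), -1L, flux_id = "vf"),
                  power_law_term(0.5, c(A = 1), -1L, flux_id = "va.out",
                                 tag = "slack")),
         B = list(power_law_term(2, c(A = 1), +1L, flux_id = "vf"),
                  power_law_term(1, numeric(0), +1L, flux_id = "vb.in"),
                  power_law_term(1, c(B = 1), -1L, flux_id = "vb"),
                  power_law_term(2, c(B = 1), -1L, flux_id = "vsink",
                                 tag = "slack"))))
  expect_lt(max(abs(gma_derivatives(toy))), 1e-12)
  bt <- balance_fluxes(toy, list(c("vf", "vb")))
  expect_equal(Filter(function(tm) identical(tm$flux_id, "vb"),
                      bt$equations$A)[[1]]$gamma, 2)
  expect_lt(max(abs(gma_derivatives(bt))), 1e-12)
})

test_that("the shipped model files load, validate, and equal the constructors", {
  for (variant in c("dynamic", "balanced")) {
    loaded <- load_sle(variant)
    expect_true(gma_equal(loaded, sle_model(variant), tol = 1e-10))
  }
})

test_that("balanced-variant diagnostics: stable with oscillatory modes", {
  ev <- stability_eigenvalues(as_ssystem(sle_model("balanced")))
  expect_true(all(Re(ev) < 0))
  expect_gt(sum(Im(ev) != 0), 0)
})
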