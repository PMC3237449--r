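#' @name sle
#' @title Synthetic sphingolipid-ergosterol (SL-E) network model
#'
#' @description
#' A synthetic reconstruction of the integrated sphingolipid-ergosterol
#' pathway of *S. cerevisiae* in GMA power-law form: de novo sphingolipid
#' synthesis from palmitoyl-CoA and serine through ceramides to the complex
#' sphingolipids (IPC, MIPC, M(IP)2C) in Golgi and plasma membrane; the
#' mevalonate/ergosterol route from acetyl-CoA through squalene, lanosterol
#' and zymosterol to an ER ergosterol pool; ergosterol sub-populations in the
#' plasma membrane (inner leaflet, free outer leaflet, and a raft/DIM pool
#' associated with complex sphingolipids); steryl-ester sub-pools in bulk and
#' PM-associated lipid particles; acetate uptake; and the end-product feedback
#' of ergosterol on the acetoacetyl-CoA thiolase step.
#'
#' The network topology, the pool roster (X1--X40 dependent; enzyme activities
#' and the undissociated-acetate fraction independent) and every published
#' numerical constraint honored here (basal sterol distribution, the 9:1
#' free-vs-raft outer-leaflet split, the 10:1 lipid-particle ester split, the
#' acetate uptake rate constant 0.0022 acting on the 93% undissociated
#' external acetate, a fractal kinetic order on the raft-association flux
#' v36,37, Yeh2p ester hydrolysis routed wholly to the inner-leaflet pool,
#' first-order mass-action vesicular and non-vesicular transport) are fixed at
#' construction. Kinetic orders follow BST conventions (substrates 0.5,
#' enzymes 1, transport 1, raft association 0.67, feedback -0.5) and rate
#' constants are solved so the declared basal state is an exact steady state.
#' The parameterization is synthetic: it reproduces the published basal state
#' and qualitative behaviour, not any particular published rate constant
#' except where noted.
#'
#' Two variants are provided: `"dynamic"` (net forward transport toward the
#' plasma membrane and lipid particles plus growth-dilution effluxes, used for
#' tracer simulations) and `"balanced"` (bidirectional PM/LP fluxes
#' equilibrated, growth fluxes and the Yeh2p flux v40,39 removed; used for
#' total-mass experiments and for stability/sensitivity diagnostics).
NULL

# ---------------------------------------------------------------------------
# Variable roster: name, role, basal value, unit, description
sle_variable_table <- function() {
  d <- function(name, value, unit, desc)
    data.frame(name = name, role = "dependent", value = value, unit = unit,
               description = desc, stringsAsFactors = FALSE)
  i <- function(name, value, desc)
    data.frame(name = name, role = "independent", value = value,
               unit = "relative", description = desc, stringsAsFactors = FALSE)
  ester_total <- 45.7            # total ergosteryl esters, % total sterols
  rbind(
    d("X1",  0.2,  "uM",   "3-keto-sphinganine (KDHS)"),
    d("X2",  0.5,  "uM",   "sphinganine (DHS)"),
    d("X3",  0.5,  "uM",   "dihydroceramide"),
    d("X4",  0.1,  "uM",   "sphinganine-1-phosphate (DHS-P)"),
    d("X5",  0.5,  "uM",   "4-OH-sphinganine / phytosphingosine (PHS)"),
    d("X6",  0.1,  "uM",   "phytosphingosine-1-phosphate (PHS-P)"),
    d("X7",  1.0,  "uM",   "phytoceramide"),
    d("X8",  0.20, "molpct", "IPC, Golgi"),
    d("X9",  2.0,  "uM",   "CDP-diacylglycerol"),
    d("X10", 5.0,  "uM",   "phosphatidylserine"),
    d("X11", 5.0,  "uM",   "phosphatidic acid"),
    d("X12", 10.0, "uM",   "palmitoyl-CoA"),
    d("X13", 500,  "uM",   "serine"),
    d("X14", 5.0,  "uM",   "sn-1,2-diacylglycerol"),
    d("X15", 10.0, "uM",   "phosphatidylinositol"),
    d("X16", 100,  "uM",   "inositol"),
    d("X17", 1.0,  "uM",   "CDP-ethanolamine"),
    d("X18", 0.20, "molpct", "MIPC, Golgi"),
    d("X19", 0.015, "molpct", "M(IP)2C, Golgi"),
    d("X20", 0.82, "molpct", "IPC, plasma membrane"),
    d("X21", 1.20, "molpct", "MIPC, plasma membrane"),
    d("X22", 0.07, "molpct", "M(IP)2C, plasma membrane"),
    d("X23", 2.0,  "uM",   "very long chain fatty acyl-CoA (C26-CoA)"),
    d("X24", 10.0, "uM",   "malonyl-CoA"),
    d("X25", 50.0, "uM",   "acetyl-CoA"),
    d("X26", 1.0,  "pctTS", "HMG-CoA"),
    d("X27", 5.0,  "pctTS", "mevalonate"),
    d("X28", 1.0,  "pctTS", "farnesyl pyrophosphate"),
    d("X29", 2.0,  "pctTS", "squalene"),
    d("X30", 4.15, "pctTS", "lanosterol"),
    d("X31", 4.15, "pctTS", "zymosterol"),
    d("X32", 9.51, "pctTS", "ergosterol, endoplasmic reticulum"),
    d("X33", 8.25, "pctTS", "steryl lanosterol, lipid particles"),
    d("X34", 8.25, "pctTS", "steryl zymosterol, lipid particles"),
    d("X35", ester_total * 10 / 11, "pctTS",
      "steryl ergosterol, bulk lipid particles (sub-pool 1)"),
    d("X36", 4.75, "pctTS", "ergosterol, PM outer leaflet, free"),
    d("X37", 42.80, "pctTS", "ergosterol, PM outer leaflet, raft/DIM (CS-associated)"),
    d("X38", 300,  "uM",   "internal acetate"),
    d("X39", 47.55, "pctTS", "ergosterol, PM inner leaflet"),
    d("X40", ester_total / 11, "pctTS",
      "steryl ergosterol, PM-associated lipid particles (sub-pool 2)"),
    d("X125", 125, "uM",  "external acetate"),
    i("X126", 0.93, "undissociated fraction of external acetate"),
    i("X133", 1, "IPC synthase activity (Aur1p)"),
    i("X134", 1, "ceramide synthase activity"),
    i("X157", 1, "serine palmitoyltransferase activity (SPT, Lcb1/2p)"),
    i("X171", 1, "acetoacetyl-CoA thiolase / HMG-CoA synthase activity"),
    i("X172", 1, "HMG-CoA reductase activity"),
    i("X179", 1, "farnesyltransferase activity"),
    i("X181", 1, "steryl-ester synthase activity (Are1p)"),
    i("X182", 1, "steryl-ester hydrolase activity, PM (Yeh2p)"),
    i("X183", 1, "steryl-ester synthase activity (Are2p)"),
    i("X186", 1, "ER-to-organelle ergosterol translocation capacity"))
}

# ---------------------------------------------------------------------------
# Flux table. Each row: one physical flux with its basal value (solved into a
# rate constant against the basal state), the pools it consumes/produces, its
# kinetic orders, its label donors and an optional tag ("growth" fluxes are
# removed when the model is balanced). Basal values are chosen so every pool
# is exactly balanced; the constructor asserts this.
sle_flux_table <- function() {
  fl <- function(id, from, to, orders, flux, donors, tag = "")
    list(id = id, from = from, to = to, orders = orders, flux = flux,
         donors = donors, tag = tag)
  list(
    # --- acetate supply and activation ------------------------------------
    fl("v_feed125", character(0), "X125", c(), 1.25575, "unlabeled"),
    fl("v125,out", "X125", character(0), c(X125 = 1), 1.0, "X125"),
    fl("v125,38", "X125", "X38", c(X125 = 1, X126 = 1), 0.25575, "X125"),
    fl("v_prod38", character(0), "X38", c(), 5.0, "unlabeled"),
    fl("v38,25", "X38", "X25", c(X38 = 0.5), 5.25575, "X38"),
    fl("v25,24", "X25", "X24", c(X25 = 0.5), 3.4, "X25"),
    fl("v25,26", "X25", "X26", c(X25 = 0.5, X171 = 1, X32 = -0.5), 1.0, "X25"),
    fl("v25,out", "X25", character(0), c(X25 = 1), 0.85575, "X25"),
    fl("v24,12", "X24", "X12", c(X24 = 0.5, X25 = 0.3), 3.2, "X24"),
    fl("v_el", c("X12", "X24"), "X23", c(X12 = 0.3, X24 = 0.3), 0.2, "X12"),
    fl("v23,out", "X23", character(0), c(X23 = 0.5), 0.04, "X23"),
    # --- de novo sphingolipid synthesis -----------------------------------
    fl("v_ser_in", character(0), "X13", c(), 5.0, "unlabeled"),
    fl("v13,out", "X13", character(0), c(X13 = 1), 4.8, "X13"),
    fl("v12,1", c("X12", "X13"), "X1", c(X12 = 0.5, X13 = 0.5, X157 = 1),
       0.2, "X12"),
    fl("v1,2", "X1", "X2", c(X1 = 0.5), 0.2, "X1"),
    fl("v2,5", "X2", "X5", c(X2 = 0.5), 0.1, "X2"),
    fl("v2,3", c("X2", "X23"), "X3", c(X2 = 0.5, X23 = 0.5, X134 = 1),
       0.08, "X2"),
    fl("v2,4", "X2", "X4", c(X2 = 0.5), 0.02, "X2"),
    fl("v4,out", "X4", character(0), c(X4 = 0.5), 0.02, "X4"),
    fl("v5,7", c("X5", "X23"), "X7", c(X5 = 0.5, X23 = 0.5, X134 = 1),
       0.08, "X5"),
    fl("v5,6", "X5", "X6", c(X5 = 0.5), 0.02, "X5"),
    fl("v6,out", "X6", character(0), c(X6 = 0.5), 0.02, "X6"),
    fl("v3,7", "X3", "X7", c(X3 = 0.5), 0.04, "X3"),
    fl("v3,8", c("X3", "X15"), "X8", c(X3 = 0.5, X15 = 0.5, X133 = 1),
       0.04, "X3"),
    fl("v7,8", c("X7", "X15"), "X8", c(X7 = 0.5, X15 = 0.5, X133 = 1),
       0.10, "X7"),
    fl("v7,out", "X7", character(0), c(X7 = 0.5), 0.02, "X7"),
    # --- complex sphingolipid maturation and transport --------------------
    fl("v8,18", "X8", "X18", c(X8 = 0.5), 0.09, "X8"),
    fl("v8,20", "X8", "X20", c(X8 = 1), 0.05, "X8"),
    fl("v18,19", "X18", "X19", c(X18 = 0.5), 0.01, "X18"),
    fl("v18,21", "X18", "X21", c(X18 = 1), 0.08, "X18"),
    fl("v19,22", "X19", "X22", c(X19 = 1), 0.01, "X19"),
    fl("v20,out", "X20", character(0), c(X20 = 0.5), 0.045, "X20", "slack"),
    fl("v20,dil", "X20", character(0), c(X20 = 1), 0.005, "X20", "growth"),
    fl("v21,out", "X21", character(0), c(X21 = 0.5), 0.072, "X21", "slack"),
    fl("v21,dil", "X21", character(0), c(X21 = 1), 0.008, "X21", "growth"),
    fl("v22,out", "X22", character(0), c(X22 = 0.5), 0.009, "X22", "slack"),
    fl("v22,dil", "X22", character(0), c(X22 = 1), 0.001, "X22", "growth"),
    # --- glycerolipids -----------------------------------------------------
    fl("v12,11", "X12", "X11", c(X12 = 0.5), 1.6, "X12"),
    fl("v11,9", "X11", "X9", c(X11 = 0.5), 0.8, "X11"),
    fl("v11,14", "X11", "X14", c(X11 = 0.5), 0.8, "X11"),
    fl("v14,out", "X14", character(0), c(X14 = 0.5), 0.8, "X14"),
    fl("v9,10", "X9", "X10", c(X9 = 0.5), 0.3, "X9"),
    fl("v9,15", c("X9", "X16"), "X15", c(X9 = 0.5, X16 = 0.5), 0.5, "X9"),
    fl("v10,out", "X10", character(0), c(X10 = 0.5), 0.3, "X10"),
    fl("v15,out", "X15", character(0), c(X15 = 0.5), 0.36, "X15"),
    fl("v_ino_in", character(0), "X16", c(), 0.55, "unlabeled"),
    fl("v16,out", "X16", character(0), c(X16 = 1), 0.05, "X16"),
    fl("v_eth_in", character(0), "X17", c(), 0.1, "unlabeled"),
    fl("v17,out", "X17", character(0), c(X17 = 0.5), 0.1, "X17"),
    # --- mevalonate / ergosterol biosynthesis -----------------------------
    fl("v26,27", "X26", "X27", c(X26 = 0.5, X172 = 1), 1.0, "X26"),
    fl("v27,28", "X27", "X28", c(X27 = 0.5), 1.0, "X27"),
    fl("v28,29", "X28", "X29", c(X28 = 0.5), 0.85, "X28"),
    fl("v28,out", "X28", character(0), c(X28 = 0.5, X179 = 1), 0.15, "X28"),
    fl("v29,30", "X29", "X30", c(X29 = 0.5), 0.85, "X29"),
    fl("v30,31", "X30", "X31", c(X30 = 0.5), 0.84, "X30", "slack"),
    fl("v31,32", "X31", "X32", c(X31 = 0.5), 0.83, "X31", "slack"),
    # --- steryl-ester cycles ----------------------------------------------
    fl("v30,33", c("X30", "X12"), "X33", c(X30 = 0.5, X12 = 0.3, X181 = 1),
       0.30, "X30"),
    fl("v33,30", "X33", "X30", c(X33 = 0.5), 0.29, "X33"),
    fl("v33,dil", "X33", character(0), c(X33 = 1), 0.01, "X33", "growth"),
    fl("v31,34", c("X31", "X12"), "X34", c(X31 = 0.5, X12 = 0.3, X181 = 1),
       0.30, "X31"),
    fl("v34,31", "X34", "X31", c(X34 = 0.5), 0.29, "X34"),
    fl("v34,dil", "X34", character(0), c(X34 = 1), 0.01, "X34", "growth"),
    fl("v32,35", c("X32", "X12"), "X35", c(X32 = 0.5, X12 = 0.3, X183 = 1),
       0.60, "X32"),
    fl("v35,32", "X35", "X32", c(X35 = 0.5), 0.55, "X35"),
    fl("v35,40", "X35", "X40", c(X35 = 1), 0.33, "X35"),
    fl("v40,35", "X40", "X35", c(X40 = 1), 0.30, "X40"),
    fl("v35,dil", "X35", character(0), c(X35 = 1), 0.02, "X35", "growth"),
    fl("v40,39", "X40", "X39", c(X40 = 0.5, X182 = 1), 0.02, "X40"),
    fl("v40,dil", "X40", character(0), c(X40 = 1), 0.01, "X40", "growth"),
    # --- ergosterol transport and PM sub-pools ----------------------------
    fl("v32,37", "X32", "X37", c(X32 = 1), 0.10, "X32"),
    fl("v37,32", "X37", "X32", c(X37 = 1), 0.08, "X37"),
    fl("v32,39", "X32", "X39", c(X32 = 1), 4.5, "X32"),
    fl("v39,32", "X39", "X32", c(X39 = 1), 4.4, "X39"),
    fl("v36,37", "X36", "X37", c(X36 = 0.67, X20 = 0.5), 2.0, "X36"),
    fl("v37,36", "X37", "X36", c(X37 = 1), 1.99, "X37"),
    fl("v39,36", "X39", "X36", c(X39 = 1), 3.0, "X39"),
    fl("v36,39", "X36", "X39", c(X36 = 1), 2.97, "X36"),
    fl("v32,186", "X32", character(0), c(X32 = 0.5, X186 = 1), 0.63, "X32",
       "slack"),
    fl("v32,dil", "X32", character(0), c(X32 = 1), 0.03, "X32", "growth"),
    fl("v36,dil", "X36", character(0), c(X36 = 1), 0.02, "X36", "growth"),
    fl("v37,dil", "X37", character(0), c(X37 = 1), 0.03, "X37", "growth"),
    fl("v39,dil", "X39", character(0), c(X39 = 1), 0.09, "X39", "growth"))
}

# Bidirectional flux pairs equilibrated by the balanced variant: vesicular
# and non-vesicular ER<->PM ergosterol exchange, the PM flip-flop and raft
# association/dissociation, the ester/hydrolysis cycles and the LP sub-pool
# exchange.
#' Bidirectional flux pairs of the SL-E model
#'
#' Each c(forward, backward) pair is assumed to be in equilibrium in the
#' balanced model variant.
#' @return list of length-2 character vectors.
#' @export
sle_balance_pairs <- function() {
  list(c("v32,37", "v37,32"), c("v32,39", "v39,32"),
       c("v36,37", "v37,36"), c("v39,36", "v36,39"),
       c("v32,35", "v35,32"), c("v30,33", "v33,30"),
       c("v31,34", "v34,31"), c("v35,40", "v40,35"))
}

# Build a gma_model from the flux table (gamma solved against basal state).
build_from_flux_table <- function(vars, fluxes) {
  basal <- stats::setNames(vars$value, vars$name)
  dep <- vars$name[vars$role == "dependent"]
  eqs <- stats::setNames(vector("list", length(dep)), dep)
  for (f in fluxes) {
    ord <- if (length(f$orders)) unlist(f$orders) else numeric(0)
    gamma <- f$flux / prod(basal[names(ord)]^ord)
    for (p in f$from)
      eqs[[p]] <- c(eqs[[p]], list(power_law_term(gamma, ord, -1L,
                                                  flux_id = f$id, tag = f$tag)))
    for (p in f$to)
      eqs[[p]] <- c(eqs[[p]], list(power_law_term(gamma, ord, +1L,
                                                  flux_id = f$id, tag = f$tag)))
  }
  gma_model(vars, eqs)
}

#' Construct the synthetic SL-E model
#'
#' Builds the model in code from the internal flux table; see [load_sle()] to
#' read the shipped plain-text copies instead. The basal state is an exact
#' steady state of both variants (asserted at construction).
#'
#' @param variant `"dynamic"` (growth fluxes and net forward transport; used
#'   for tracer dynamics) or `"balanced"` (equilibrated bidirectional fluxes,
#'   growth and Yeh2p v40,39 fluxes removed; used for total-mass experiments
#'   and diagnostics).
#' @return a [gma_model()].
#' @export
sle_model <- function(variant = c("dynamic", "balanced")) {
  variant <- match.arg(variant)
  m <- build_from_flux_table(sle_variable_table(), sle_flux_table())
  if (variant == "balanced")
    m <- balance_fluxes(m, sle_balance_pairs(), zero_fluxes = "v40,39")
  r <- gma_derivatives(m)
  if (max(abs(r) / basal_state(m, "dependent")) > 1e-9)
    stop("internal error: SL-E ", variant,
         " basal state is not a steady state", call. = FALSE)
  m
}

#' Equilibrate bidirectional fluxes for total-mass experiments
#'
#' Rescales each pair's backward rate constant so forward and backward fluxes
#' are equal at the basal state, removes growth-dilution fluxes (terms tagged
#' `"growth"`) and any explicitly listed fluxes, then absorbs the remaining
#' per-pool residuals into each pool's designated slack flux (terms tagged
#' `"slack"`), sweeping until the basal state is again an exact steady state.
#'
#' @param model a [gma_model()] whose terms carry `growth`/`slack` tags.
#' @param pairs list of c(forward, backward) flux-id pairs.
#' @param zero_fluxes flux ids to remove entirely (e.g. the Yeh2p ester
#'   hydrolysis flux when Yeh1p is taken as the only active hydrolase).
#' @param drop_growth remove terms tagged `"growth"` (default TRUE).
#' @param tol residual tolerance (relative to basal values).
#' @param max_sweeps cap on slack-absorption sweeps.
#' @return the balanced [gma_model()].
#' @export
balance_fluxes <- function(model, pairs, zero_fluxes = character(0),
                           drop_growth = TRUE, tol = 1e-12, max_sweeps = 100) {
  basal <- basal_state(model)
  all_ids <- unique(unlist(lapply(model$equations, function(tl)
    vapply(tl, `[[`, "", "flux_id"))))
  for (pr in pairs) {
    missing_id <- setdiff(pr, all_ids)
    if (length(missing_id))
      stop("pair flux not in model: ", paste(missing_id, collapse = ", "),
           call. = FALSE)
  }
  # map: flux id -> multiply gamma by factor (applied across all equations)
  scale_gamma <- function(m, id, fac) {
    for (nm in names(m$equations))
      for (k in seq_along(m$equations[[nm]]))
        if (identical(m$equations[[nm]][[k]]$flux_id, id))
          m$equations[[nm]][[k]]$gamma <- m$equations[[nm]][[k]]$gamma * fac
    m
  }
  drop_flux <- function(m, ids) {
    for (nm in names(m$equations)) {
      keep <- vapply(m$equations[[nm]], function(tm)
        !(tm$flux_id %in% ids), TRUE)
      m$equations[[nm]] <- m$equations[[nm]][keep]
    }
    m
  }
  flux_at_basal <- function(m, id) {
    for (nm in names(m$equations)) for (tm in m$equations[[nm]])
      if (identical(tm$flux_id, id)) return(evaluate_flux(tm, basal))
    NA_real_
  }
  m <- model
  for (pr in pairs) {
    vf <- flux_at_basal(m, pr[1]); vb <- flux_at_basal(m, pr[2])
    if (!is.na(vb) && vb == 0 && vf != 0 && !(pr[2] %in% zero_fluxes))
      stop("cannot balance pair (", pr[1], ", ", pr[2],
           "): backward flux is structurally zero", call. = FALSE)
    if (vb != vf) m <- scale_gamma(m, pr[2], vf / vb)
  }
  growth_ids <- character(0)
  if (drop_growth) {
    growth_ids <- unique(unlist(lapply(m$equations, function(tl)
      vapply(tl[vapply(tl, function(tm) identical(tm$tag, "growth"), TRUE)],
             `[[`, "", "flux_id"))))
  }
  m <- drop_flux(m, c(growth_ids, zero_fluxes))
  # absorb residuals into slack effluxes, pool by pool
  dep <- dependent_names(m)
  for (sweep in seq_len(max_sweeps)) {
    r <- gma_derivatives(m, basal)
    if (max(abs(r) / basal[dep]) < tol) return(validate_gma(m))
    worst <- order(-abs(r))
    progressed <- FALSE
    for (i in worst) {
      if (abs(r[i]) / basal[dep[i]] < tol) next
      terms <- m$equations[[dep[i]]]
      slack_k <- which(vapply(terms, function(tm)
        identical(tm$tag, "slack") && tm$sign < 0, TRUE))
      if (!length(slack_k)) next
      tm <- terms[[slack_k[1]]]
      v_old <- evaluate_flux(tm, basal)
      v_new <- v_old + r[i]          # residual > 0 means excess influx
      if (v_new <= 0)
        stop("slack flux ", tm$flux_id, " cannot absorb residual at ",
             dep[i], call. = FALSE)
      m <- scale_gamma(m, tm$flux_id, v_new / v_old)
      progressed <- TRUE
    }
    if (!progressed)
      stop("flux balancing stalled; residual pools without slack: ",
           paste(dep[abs(r) / basal[dep] >= tol], collapse = ", "),
           call. = FALSE)
  }
  stop("flux balancing did not converge in ", max_sweeps, " sweeps",
       call. = FALSE)
}

#' Canonical pool aggregates of the SL-E model
#'
#' Named variable sets used by all reporting: total sterols, total
#' steryl-esters, PM ergosterol, total ergosterol, ergosteryl esters, and the
#' complex sphingolipid classes (Golgi + PM).
#'
#' @return named list of character vectors.
#' @export
sle_pools <- function() {
  list(total_sterols = c("X30", "X31", "X32", "X36", "X37", "X39"),
       total_steryl_esters = c("X33", "X34", "X35", "X40"),
       pm_ergosterol = c("X36", "X37", "X39"),
       total_ergosterol = c("X32", "X36", "X37", "X39"),
       total_erg_esters = c("X35", "X40"),
       IPC = c("X8", "X20"),
       MIPC = c("X18", "X21"),
       MIP2C = c("X19", "X22"),
       CS = c("X8", "X18", "X19", "X20", "X21", "X22"))
}

# The fixed reporting denominator: the wild-type total sterol amount.
# Sterol pools are parameterized on a scale where this reference equals 100,
# so basal sterol values read directly as % of total sterols.
sle_wt_total_sterol_reference <- function() 100

#' Express sterol pools as percent of the wild-type total sterol amount
#'
#' The denominator is the *fixed* wild-type reference, never re-normalized
#' per condition, so values under perturbations (and aggregates like total
#' sterols) may exceed 100.
#'
#' @param state named state vector (or a named subset of sterol pools).
#' @return named numeric, same names as `state`, in % of wild-type total
#'   sterols.
#' @export
percent_total_sterols <- function(state) {
  100 * state / sle_wt_total_sterol_reference()
}

#' Label donor map of the SL-E model
#'
#' Carbon-skeleton donors per flux. The acyl co-substrate of the steryl-ester
#' synthases (palmitoyl-CoA, X12) does not deliver label in the default mode
#' (`acyl = "blocked"`, matching experiments in which ester counts are
#' corrected down to the sterol moiety); with `acyl = "donor"` the ester
#' fluxes also carry the acyl label.
#'
#' @param model the SL-E model the map is built for.
#' @param acyl `"blocked"` (default) or `"donor"`.
#' @return a [labeling_map()].
#' @export
sle_labeling <- function(model = sle_model("dynamic"),
                         acyl = c("blocked", "donor")) {
  acyl <- match.arg(acyl)
  tab <- sle_flux_table()
  a <- stats::setNames(lapply(tab, `[[`, "donors"), vapply(tab, `[[`, "", "id"))
  if (acyl == "donor")
    for (id in c("v30,33", "v31,34", "v32,35"))
      a[[id]] <- c(a[[id]], "X12")
  present <- unique(unlist(lapply(model$equations, function(tl)
    vapply(tl, `[[`, "", "flux_id"))))
  labeling_map(model, a[names(a) %in% present])
}

#' Structural checklist for an SL-E model
#'
#' Verifies the committed structural assumptions: the ergosterol end-product
#' feedback onto the thiolase step; the fractal (non-integer, non-half)
#' kinetic order on the raft association flux v36,37; the Yeh2p flux routed
#' entirely to the inner-leaflet pool X39; first-order mass-action vesicular
#' transport v32,37/v37,32; and, for the balanced variant, the removed
#' v40,39 and growth fluxes.
#'
#' @param model a [gma_model()].
#' @param variant which variant's checklist to apply.
#' @return TRUE invisibly; stops with a named structural error otherwise.
#' @export
validate_sle_structure <- function(model, variant = c("dynamic", "balanced")) {
  variant <- match.arg(variant)
  find_term <- function(id) {
    for (nm in names(model$equations)) for (tm in model$equations[[nm]])
      if (identical(tm$flux_id, id)) return(tm)
    NULL
  }
  tm <- find_term("v25,26")
  if (is.null(tm) || is.na(tm$factors["X32"]) || tm$factors["X32"] >= 0)
    stop("structural error: missing ergosterol feedback on the thiolase step",
         call. = FALSE)
  tm <- find_term("v36,37")
  if (is.null(tm) || tm$factors["X36"] %% 0.5 == 0)
    stop("structural error: raft association flux v36,37 lacks its fractal ",
         "kinetic order", call. = FALSE)
  for (id in c("v32,37", "v37,32")) {
    tm <- find_term(id)
    if (is.null(tm) || length(tm$factors) != 1L || tm$factors[[1]] != 1)
      stop("structural error: vesicular transport ", id,
           " must be first-order mass action", call. = FALSE)
  }
  yeh <- find_term("v40,39")
  if (variant == "dynamic") {
    if (is.null(yeh)) stop("structural error: Yeh2p flux v40,39 missing",
                           call. = FALSE)
    if (!"v40,39" %in% vapply(model$equations[["X39"]], `[[`, "", "flux_id"))
      stop("structural error: Yeh2p product not routed to X39", call. = FALSE)
  } else {
    if (!is.null(yeh))
      stop("structural error: balanced variant must have v40,39 removed",
           call. = FALSE)
    tags <- unlist(lapply(model$equations, function(tl)
      vapply(tl, `[[`, "", "tag")))
    if (any(tags == "growth"))
      stop("structural error: balanced variant retains growth fluxes",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a shipped SL-E model file
#'
#' Parses the plain-text copy under `inst/extdata` (written by
#' [write_plas()] from [sle_model()]) and runs the structural checklist.
#'
#' @param variant `"dynamic"` or `"balanced"`.
#' @return a [gma_model()].
#' @export
load_sle <- function(variant = c("dynamic", "balanced")) {
  variant <- match.arg(variant)
  f <- system.file("extdata",
                   sprintf("sle_synthetic_%s.plas", variant),
                   package = "sleBST", mustWork = TRUE)
  m <- parse_plas(file = f)
  validate_sle_structure(m, variant)
  m
}
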