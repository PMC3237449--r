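#' Specification for a random GMA fixture model
#'
#' Describes the statistical character of the generated networks: pool and
#' enzyme counts, how many variables enter each flux, the kinetic-order range,
#' and the rate-constant scale.
#'
#' @param n_dependent,n_independent counts (>= 1).
#' @param connectivity mean number of extra regulator variables per flux
#'   beyond the primary substrate (default 0.8).
#' @param order_range kinetic-order range for regulators (default c(-1, 2)).
#' @param self_order_range kinetic-order range for a pool's own efflux order
#'   (kept positive so degradation grows with the pool).
#' @param log_gamma_range natural-log range of provisional rate constants.
#' @param seed integer seed; the seed fully reproduces the model.
#' @param max_tries rejection budget for the stable-model redraw loop.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_dependent = 12, n_independent = 4, connectivity = 0.8,
                       order_range = c(-1, 2), self_order_range = c(0.3, 1.2),
                       log_gamma_range = c(-1, 1), seed = 1L,
                       max_tries = 200L) {
  stopifnot(n_dependent >= 1, n_independent >= 1)
  structure(list(n_dependent = n_dependent, n_independent = n_independent,
                 connectivity = connectivity, order_range = order_range,
                 self_order_range = self_order_range,
                 log_gamma_range = log_gamma_range, seed = as.integer(seed),
                 max_tries = as.integer(max_tries)),
            class = "synth_spec")
}

#' Generate a random stable GMA model with a designated steady state
#'
#' Construction: draw a random network (every dependent pool gets one influx
#' driven by independents/other pools and one self-dependent efflux, plus
#' random regulators), draw a positive target state, then solve the rate
#' constants so that the target state is an *exact* steady state
#' (influx scaled to match efflux per pool). Candidates whose S-system
#' Jacobian has any eigenvalue with non-negative real part are rejected and
#' redrawn, so every returned fixture sits in the stable regime.
#'
#' @param spec a [synth_spec()].
#' @return a [gma_model()] whose declared basal values are the designated
#'   steady state; the number of redraws is attached as attribute `"tries"`.
#' @export
generate_gma <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  nd <- spec$n_dependent; ni <- spec$n_independent
  dep <- sprintf("X%d", seq_len(nd))
  ind <- sprintf("E%d", seq_len(ni))
  for (try in seq_len(spec$max_tries)) {
    xstar <- stats::setNames(exp(stats::runif(nd, -1, 2)), dep)
    istar <- stats::setNames(exp(stats::runif(ni, -0.5, 0.5)), ind)
    equations <- list()
    ok <- TRUE
    for (i in seq_len(nd)) {
      # efflux: own pool plus possible regulators
      h <- stats::setNames(stats::runif(1, spec$self_order_range[1],
                                        spec$self_order_range[2]), dep[i])
      n_extra <- stats::rpois(1, spec$connectivity / 2)
      if (n_extra > 0) {
        reg <- sample(setdiff(c(dep, ind), dep[i]), min(n_extra, 2))
        h[reg] <- stats::runif(length(reg), spec$order_range[1],
                               spec$order_range[2])
      }
      # influx: driven by an independent source and possibly other pools
      g <- stats::setNames(stats::runif(1, 0.2, 1), sample(ind, 1))
      n_extra <- stats::rpois(1, spec$connectivity)
      if (n_extra > 0) {
        reg <- sample(setdiff(c(dep, ind), names(g)), min(n_extra, 2))
        g[reg] <- stats::runif(length(reg), spec$order_range[1],
                               spec$order_range[2])
      }
      full <- c(xstar, istar)
      gam_out <- exp(stats::runif(1, spec$log_gamma_range[1],
                                  spec$log_gamma_range[2]))
      v_out <- gam_out * prod(full[names(h)]^h)
      gam_in <- v_out / prod(full[names(g)]^g)  # exact steady state
      equations[[dep[i]]] <- list(
        power_law_term(gam_in, g, +1L, flux_id = sprintf("vin%d", i)),
        power_law_term(gam_out, h, -1L, flux_id = sprintf("vout%d", i)))
    }
    vars <- variable_spec(c(dep, ind),
                          c(rep("dependent", nd), rep("independent", ni)),
                          c(xstar, istar))
    model <- gma_model(vars, equations)
    ev <- tryCatch(stability_eigenvalues(as_ssystem(model)),
                   error = function(e) NULL)
    if (!is.null(ev) && all(Re(ev) < 0)) {
      attr(model, "tries") <- try
      return(model)
    }
  }
  stop("rejection budget exhausted after ", spec$max_tries,
       " draws without a stable candidate; relax the spec (connectivity ",
       spec$connectivity, ", orders [", spec$order_range[1], ", ",
       spec$order_range[2], "])", call. = FALSE)
}

#' Linear labeled-chain fixture with closed-form label dynamics
#'
#' A precursor -> ... -> product chain fed by an independent source `S` held
#' at constant concentration. Pool `i` has efflux rate constant `rates[i]`
#' (first-order), basal value `flux/rates[i]`, and all transfer fluxes equal
#' `flux` at the steady state, so each pool's turnover is `rates[i]` and the
#' label fractions obey \eqn{df_i/dt = k_i (f_{i-1} - f_i)}. For a chain of
#' length 2 with source fraction 1, the product fraction is the closed form
#' \eqn{1 - e^{-k t}}.
#'
#' @param length number of chain pools downstream of the source.
#' @param rates per-pool turnover rates (recycled to `length`).
#' @param flux common chain flux (default 1).
#' @param source_fraction initial/held label fraction of the source.
#' @return list with `model`, `map` ([labeling_map()]), `lmodel`
#'   (the split system with the source held at `source_fraction`), and
#'   `closed_form(t, i)` giving pool i's label fraction under a source held
#'   at `source_fraction` since t = 0.
#' @export
generate_labeled_chain <- function(length = 2, rates = 1, flux = 1,
                                   source_fraction = 1) {
  stopifnot(length >= 1)
  k <- rep_len(rates, length)
  dep <- sprintf("P%d", seq_len(length))
  xstar <- flux / k
  # The source is modeled as a dependent pool with a constant feed so its
  # label fraction can be held by initial condition (its in/outflux match).
  vars <- variable_spec(c("S", dep), c("dependent", rep("dependent", length)),
                        c(1, xstar))
  eqs <- list(S = list(
    power_law_term(flux, numeric(0), +1L, flux_id = "vfeed"),
    power_law_term(flux, c(S = 1), -1L, flux_id = "v0")))
  prev <- "S"
  for (i in seq_len(length)) {
    vin <- sprintf("v%d", i - 1L)
    vout <- sprintf("v%d", i)
    eqs[[dep[i]]] <- list(
      power_law_term(if (i == 1) flux else k[i - 1], stats::setNames(1, prev),
                     +1L, flux_id = vin),
      power_law_term(k[i], stats::setNames(1, dep[i]), -1L, flux_id = vout))
    prev <- dep[i]
  }
  model <- gma_model(vars, eqs)
  # the feed re-delivers the source's own label fraction, so a source set to
  # `source_fraction` at t = 0 is *held* there (its in/outflux cancel in L)
  assign_list <- c(list(vfeed = "S"),
                   stats::setNames(as.list(c("S", dep)),
                                   sprintf("v%d", 0:length)))
  map <- labeling_map(model, assign_list)
  lmodel <- split_labels(model, map,
                         stats::setNames(source_fraction, "S"))
  closed_form <- function(t, i = length) {
    # f_i(t) for constant source fraction; distinct-rate convolution formula
    ki <- k[seq_len(i)]
    if (anyDuplicated(ki))
      stop("closed form implemented for distinct rates only", call. = FALSE)
    acc <- 0
    for (j in seq_along(ki)) {
      num <- prod(ki[-j]); den <- prod(ki[-j] - ki[j])
      acc <- acc + (num / den) * exp(-ki[j] * t)
    }
    source_fraction * (1 - acc)
  }
  list(model = model, map = map, lmodel = lmodel, rates = k,
       closed_form = closed_form)
}
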