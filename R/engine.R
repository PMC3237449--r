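#' Timed intervention on a simulation
#'
#' @param time minutes (>= 0) at which the intervention fires.
#' @param kind `"set_value"` (replace a variable's value), `"scale_value"`
#'   (multiply by `amount`, which must be positive), or `"add_bolus"` (add
#'   `amount` to a state variable).
#' @param target variable name (dependent state or independent parameter; for
#'   labeled models also `L_<name>` / `U_<name>`).
#' @param amount numeric.
#' @return object of class `bst_intervention`.
#' @export
intervention <- function(time, kind = c("set_value", "scale_value", "add_bolus"),
                         target, amount) {
  kind <- match.arg(kind)
  if (time < 0) stop("intervention time must be >= 0", call. = FALSE)
  if (kind == "scale_value" && amount <= 0)
    stop("scale_value amount must be positive", call. = FALSE)
  structure(list(time = time, kind = kind, target = target, amount = amount),
            class = "bst_intervention")
}

# Internal: apply one intervention to (state, params); returns both.
apply_intervention <- function(iv, state, params) {
  tgt <- iv$target
  place <- if (tgt %in% names(state)) "state"
           else if (tgt %in% names(params)) "params"
           else stop("intervention target not found: ", tgt, call. = FALSE)
  cur <- if (place == "state") state[tgt] else params[tgt]
  new <- switch(iv$kind,
                set_value = iv$amount,
                scale_value = cur * iv$amount,
                add_bolus = cur + iv$amount)
  if (place == "state") state[tgt] <- new else params[tgt] <- new
  list(state = state, params = params)
}

# Internal: piecewise stiff integration shared by the plain and labeled
# engines. rhs_factory(params) must return function(t, y) -> list(dy).
# `applier` lets the labeled engine expand interventions on total pools.
integrate_piecewise <- function(y0, params, interventions, t_end, dt, times,
                                rhs_factory, rtol, atol, method, floor_vec,
                                applier = apply_intervention,
                                warn_clamp = TRUE) {
  if (is.null(times)) times <- seq(0, t_end, by = dt)
  if (any(diff(times) <= 0)) stop("output times must be strictly increasing",
                                  call. = FALSE)
  t_end <- max(times)
  iv_times <- vapply(interventions, `[[`, 0, "time")
  if (length(iv_times)) {
    o <- order(iv_times)
    interventions <- interventions[o]; iv_times <- iv_times[o]
    if (any(iv_times > t_end))
      warning("interventions after t_end are ignored")
  }
  brk <- sort(unique(c(0, iv_times[iv_times <= t_end], t_end)))
  clamped <- FALSE
  state <- y0
  # fire t = 0 interventions before the first segment
  for (iv in interventions[iv_times == 0]) {
    r <- applier(iv, state, params); state <- r$state; params <- r$params
  }
  rows <- list(); row_t <- numeric(0)
  record <- function(tt, st) { rows[[length(rows) + 1L]] <<- st
                               row_t <<- c(row_t, tt) }
  record(0, state)
  for (seg in seq_len(length(brk) - 1L)) {
    t0 <- brk[seg]; t1 <- brk[seg + 1L]
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    rhs <- rhs_factory(params)
    func <- function(t, y, p) {
      low <- y < floor_vec
      if (any(low)) { y[low] <- floor_vec[low]; clamped <<- TRUE }
      rhs(t, y)
    }
    sol <- deSolve::ode(y = state, times = seg_times, func = func, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure; last valid time ", max(sol[, 1]), call. = FALSE)
    for (k in seq_len(nrow(sol))[-1]) {
      tt <- sol[k, 1]
      if (tt %in% times || tt == t1) record(tt, pmax(sol[k, -1], floor_vec))
    }
    state <- pmax(sol[nrow(sol), -1], floor_vec)
    if (t1 < t_end)
      for (iv in interventions[iv_times == t1]) {
        r <- applier(iv, state, params)
        state <- r$state; params <- r$params
        record(t1, state)  # post-event value at the same time point
      }
  }
  if (clamped && warn_clamp)
    warning("state dipped below the positivity floor and was clamped")
  # keep the *last* record at each time (post-event values supersede)
  keep <- !duplicated(row_t, fromLast = TRUE)
  vals <- do.call(rbind, rows)[keep, , drop = FALSE]
  list(times = unname(row_t[keep]), values = vals, params = params)
}

#' Simulate a GMA model
#'
#' Integrates the stiff ODE system piecewise between intervention times; each
#' intervention is applied as a state/parameter discontinuity and the
#' integrator is restarted (no interpolation across discontinuities). States
#' that dip below `1e-12 x basal` are clamped to that floor with a warning
#' (power laws with negative exponents are undefined at zero; concentrations
#' cannot be negative).
#'
#' @param model a [gma_model()].
#' @param interventions list of [intervention()] objects.
#' @param t_end horizon in minutes.
#' @param dt output grid resolution in minutes (default 1).
#' @param times explicit strictly-increasing output grid (overrides
#'   `t_end`/`dt`).
#' @param rtol,atol integrator tolerances; `atol` is scaled per state by its
#'   basal value.
#' @param method deSolve method (default `"lsoda"`, stiff-capable).
#' @return a `gma_trajectory`: list with `times`, `values` (time x variable
#'   matrix over dependent variables), `independents`, `model_hash`,
#'   `interventions`.
#' @export
simulate_gma <- function(model, interventions = list(), t_end = 100, dt = 1,
                         times = NULL, rtol = 1e-8, atol = 1e-10,
                         method = "lsoda") {
  if (inherits(interventions, "bst_intervention"))
    interventions <- list(interventions)
  cm <- compile_gma(model)
  y0 <- basal_state(model, "dependent")
  if (any(y0 <= 0)) stop("initial state must be positive", call. = FALSE)
  params <- basal_state(model, "independent")
  floor_vec <- 1e-12 * y0
  atol_vec <- atol * pmax(y0, 1e-6)
  rhs_factory <- function(p) {
    function(t, y) {
      full <- c(y, p)
      v <- compiled_fluxes(cm, full)
      list(as.numeric(cm$S %*% v))
    }
  }
  res <- integrate_piecewise(y0, params, interventions, t_end, dt, times,
                             rhs_factory, rtol, atol_vec, method, floor_vec)
  colnames(res$values) <- names(y0)
  structure(list(times = res$times, values = res$values,
                 independents = params,
                 model_hash = model_hash(model),
                 interventions = interventions),
            class = "gma_trajectory")
}

#' @export
print.gma_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points (%g..%g min), %d variables\n",
              length(x$times), min(x$times), max(x$times), ncol(x$values)))
  invisible(x)
}

#' Tidy data.frame view of a trajectory
#'
#' @param x a `gma_trajectory`.
#' @param row.names,optional,... standard [as.data.frame()] arguments (unused).
#' @return data.frame with columns time, variable, value.
#' @export
as.data.frame.gma_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                         ...) {
  data.frame(time = rep(x$times, ncol(x$values)),
             variable = rep(colnames(x$values), each = length(x$times)),
             value = as.numeric(x$values))
}

#' One variable's series from a trajectory
#' @param traj a `gma_trajectory`.
#' @param var variable name.
#' @export
trajectory_series <- function(traj, var) {
  if (!var %in% colnames(traj$values))
    stop("unknown variable: ", var, call. = FALSE)
  stats::setNames(traj$values[, var], traj$times)
}

#' Element-wise sum of a set of pools
#'
#' @param traj a `gma_trajectory`.
#' @param pool_def character vector of variable names.
#' @return numeric series along `traj$times`.
#' @export
aggregate_pools <- function(traj, pool_def) {
  missing_v <- setdiff(pool_def, colnames(traj$values))
  if (length(missing_v))
    stop("unknown variable(s): ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  rowSums(traj$values[, pool_def, drop = FALSE])
}

#' Maximal amplitude of an excursion
#'
#' The signed relative excursion \eqn{(extremum - x_0)/x_0}, where `x_0` is
#' the value at the window start and the extremum is the point of largest
#' absolute deviation from `x_0` inside the window.
#'
#' @param traj a `gma_trajectory` (or any object with `times` and a series via
#'   `var`).
#' @param var variable name, or a numeric series along `traj$times`.
#' @param window length-2 numeric c(start, end) in minutes; defaults to the
#'   full span.
#' @return signed fraction (e.g. +0.5 for a 50\% rise).
#' @export
maximal_amplitude <- function(traj, var, window = range(traj$times)) {
  series <- if (is.character(var)) trajectory_series(traj, var) else var
  idx <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(idx)) stop("empty window", call. = FALSE)
  s <- series[idx]
  x0 <- s[1]
  dev <- s - x0
  ext <- s[which.max(abs(dev))]
  unname((ext - x0) / x0)
}

#' Export a trajectory as CSV
#'
#' @param traj a `gma_trajectory`.
#' @param file path.
#' @param wide write one column per variable (default) or tidy long format.
#' @export
write_trajectory_csv <- function(traj, file, wide = TRUE) {
  if (wide) {
    df <- data.frame(time = traj$times, traj$values, check.names = FALSE)
  } else df <- as.data.frame(traj)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Stable content hash of a model
#'
#' Provenance tag stored on trajectories so a scenario plus model hash fully
#' determines an output.
#'
#' @param model a `gma_model`.
#' @return character scalar.
#' @export
model_hash <- function(model) {
  txt <- paste(write_plas(model), collapse = "\n")
  # simple polynomial rolling hash (avoids a digest dependency)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
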