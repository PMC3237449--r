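#' Power-law flux term
#'
#' A single flux in the generalized mass action (GMA) representation:
#' \eqn{v = \gamma \prod_j X_j^{f_j}}. The kinetic order \eqn{f_j} quantifies
#' the strength and direction of the influence of variable \eqn{X_j} on the
#' flux; the rate constant \eqn{\gamma} sets its turnover scale.
#'
#' @param gamma positive rate constant.
#' @param factors named numeric vector of kinetic orders (may be empty for a
#'   constant flux).
#' @param sign +1 for an influx term, -1 for an efflux term.
#' @param flux_id character label of the physical flux (e.g. `"v32,37"`).
#'   Terms sharing a `flux_id` across equations describe one physical flux and
#'   must agree in `gamma` and `factors`.
#' @param coef positive stoichiometric coefficient applied to the flux in the
#'   equation holding this term (default 1).
#' @param tag free-form tag (e.g. `"growth"` for dilution fluxes that are
#'   removed when a model is flux-balanced, `"slack"` for the flux that absorbs
#'   balancing residuals at its pool).
#' @return An object of class `power_law_term`.
#' @export
power_law_term <- function(gamma, factors = numeric(0), sign = 1L,
                           flux_id = NA_character_, coef = 1, tag = "") {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single positive number", call. = FALSE)
  if (length(factors) && is.null(names(factors)))
    stop("'factors' must be a named numeric vector", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("'sign' must be +1 or -1", call. = FALSE)
  if (coef <= 0) stop("'coef' must be positive", call. = FALSE)
  structure(list(gamma = as.numeric(gamma),
                 factors = if (length(factors))
                   factors[order(names(factors))] else numeric(0),
                 sign = as.integer(sign),
                 flux_id = as.character(flux_id),
                 coef = as.numeric(coef),
                 tag = as.character(tag)),
            class = "power_law_term")
}

#' @export
print.power_law_term <- function(x, ...) {
  fac <- if (length(x$factors))
    paste(sprintf("%s^%g", names(x$factors), x$factors), collapse = " ") else "1"
  cat(sprintf("%s%g %s  [%s]\n", if (x$sign > 0) "+" else "-", x$gamma, fac,
              x$flux_id))
  invisible(x)
}

#' Variable roster for a GMA model
#'
#' @param name character vector of variable names.
#' @param role `"dependent"` or `"independent"` per variable.
#' @param value basal (operating-point) value per variable; must be positive
#'   for any variable that appears with a non-zero kinetic order, because
#'   power laws with negative exponents are undefined at zero.
#' @param unit unit string per variable (recycled).
#' @param description free text per variable (recycled).
#' @return data.frame with one row per variable.
#' @export
variable_spec <- function(name, role, value, unit = "", description = "") {
  stopifnot(length(name) == length(role), length(name) == length(value))
  if (anyDuplicated(name)) stop("variable names must be unique: ",
                                paste(name[duplicated(name)], collapse = ", "),
                                call. = FALSE)
  role <- match.arg(role, c("dependent", "independent"), several.ok = TRUE)
  data.frame(name = as.character(name), role = role,
             value = as.numeric(value),
             unit = rep_len(as.character(unit), length(name)),
             description = rep_len(as.character(description), length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a GMA model
#'
#' Bundles a variable roster with one differential equation per dependent
#' variable, each a signed sum of [power_law_term()]s. Terms with a shared
#' `flux_id` record a stoichiometric coupling: one physical flux entering
#' several equations.
#'
#' @param variables data.frame from [variable_spec()].
#' @param equations named list (dependent variable -> list of terms).
#' @param check validate invariants (default TRUE).
#' @return object of class `gma_model`.
#' @export
gma_model <- function(variables, equations, check = TRUE) {
  m <- structure(list(variables = variables, equations = equations),
                 class = "gma_model")
  if (check) validate_gma(m)
  m
}

#' Validate a GMA model's structural invariants
#'
#' Checks: unique declared names; every referenced symbol declared; every
#' dependent variable has an equation with at least one term; terms sharing a
#' `flux_id` agree in rate constant and kinetic orders; basal values positive
#' wherever a non-zero kinetic order touches them.
#'
#' @param model a `gma_model`.
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_gma <- function(model) {
  v <- model$variables
  if (anyDuplicated(v$name))
    stop("duplicate variable declarations: ",
         paste(unique(v$name[duplicated(v$name)]), collapse = ", "), call. = FALSE)
  dep <- v$name[v$role == "dependent"]
  eq_names <- names(model$equations)
  if (anyDuplicated(eq_names))
    stop("duplicate equation for: ",
         paste(unique(eq_names[duplicated(eq_names)]), collapse = ", "), call. = FALSE)
  missing_eq <- setdiff(dep, eq_names)
  if (length(missing_eq))
    stop("dependent variable(s) without an equation: ",
         paste(missing_eq, collapse = ", "), call. = FALSE)
  extra_eq <- setdiff(eq_names, dep)
  if (length(extra_eq))
    stop("equation(s) for undeclared/independent variable(s): ",
         paste(extra_eq, collapse = ", "), call. = FALSE)
  seen <- new.env(parent = emptyenv())
  for (nm in eq_names) {
    terms <- model$equations[[nm]]
    if (!length(terms)) stop("equation for ", nm, " has no terms", call. = FALSE)
    for (tm in terms) {
      undecl <- setdiff(names(tm$factors), v$name)
      if (length(undecl))
        stop("undeclared variable(s) referenced in equation for ", nm, ": ",
             paste(undecl, collapse = ", "), call. = FALSE)
      for (fv in names(tm$factors)) {
        bv <- v$value[v$name == fv]
        if (tm$factors[[fv]] != 0 && (!is.finite(bv) || bv <= 0))
          stop("variable ", fv, " has non-positive basal value but a non-zero ",
               "kinetic order in equation for ", nm, call. = FALSE)
      }
      if (!is.na(tm$flux_id) && nzchar(tm$flux_id)) {
        prev <- get0(tm$flux_id, envir = seen)
        if (is.null(prev)) assign(tm$flux_id, tm, envir = seen)
        else if (!isTRUE(all.equal(prev$gamma, tm$gamma)) ||
                 !isTRUE(all.equal(prev$factors, tm$factors)))
          stop("flux '", tm$flux_id, "' appears with inconsistent rate ",
               "constant or kinetic orders across equations", call. = FALSE)
      }
    }
  }
  invisible(model)
}

#' @export
print.gma_model <- function(x, ...) {
  nd <- sum(x$variables$role == "dependent")
  ni <- sum(x$variables$role == "independent")
  nt <- sum(lengths(x$equations))
  cat(sprintf("GMA model: %d dependent, %d independent variables, %d terms\n",
              nd, ni, nt))
  invisible(x)
}

#' Basal (declared) state of a model
#'
#' @param model a `gma_model`.
#' @param role which variables to include.
#' @return named numeric vector of basal values.
#' @export
basal_state <- function(model, role = c("all", "dependent", "independent")) {
  role <- match.arg(role)
  v <- model$variables
  if (role != "all") v <- v[v$role == role, , drop = FALSE]
  stats::setNames(v$value, v$name)
}

#' Names of the dependent variables, in declaration order
#' @param model a `gma_model`.
#' @export
dependent_names <- function(model)
  model$variables$name[model$variables$role == "dependent"]

#' Names of the independent variables, in declaration order
#' @param model a `gma_model`.
#' @export
independent_names <- function(model)
  model$variables$name[model$variables$role == "independent"]

#' Evaluate one power-law flux
#'
#' Returns \eqn{\gamma \prod_j state_j^{f_j}} (without the sign or
#' stoichiometric coefficient). A constant flux (empty factor map) evaluates
#' to its rate constant.
#'
#' @param term a [power_law_term()].
#' @param state named numeric vector covering all factor variables.
#' @return the (strictly positive) flux value.
#' @export
evaluate_flux <- function(term, state) {
  if (!length(term$factors)) return(term$gamma)
  vals <- state[names(term$factors)]
  if (anyNA(vals))
    stop("state does not cover: ",
         paste(names(term$factors)[is.na(vals)], collapse = ", "), call. = FALSE)
  bad <- vals <= 0 & term$factors != 0
  if (any(bad))
    stop("non-positive state for variable(s) with non-zero kinetic order: ",
         paste(names(term$factors)[bad], collapse = ", "), call. = FALSE)
  term$gamma * prod(vals^term$factors)
}

#' All flux values of a model at a state
#'
#' One value per distinct `flux_id` (terms without an id are keyed by
#' position).
#'
#' @param model a `gma_model`.
#' @param state named state vector (defaults to the basal state).
#' @return named numeric vector of fluxes.
#' @export
gma_fluxes <- function(model, state = basal_state(model)) {
  out <- c(); k <- 0L
  for (nm in names(model$equations)) for (tm in model$equations[[nm]]) {
    k <- k + 1L
    id <- if (!is.na(tm$flux_id) && nzchar(tm$flux_id)) tm$flux_id
          else sprintf("term%03d", k)
    if (!id %in% names(out)) out[id] <- evaluate_flux(tm, state)
  }
  out
}

#' Time derivatives of the dependent variables
#'
#' \eqn{dX_i/dt = \sum_k s_k c_k v_k} over the equation's terms: the exact
#' signed sum of [evaluate_flux()] results.
#'
#' @param model a `gma_model`.
#' @param state named state vector over all variables (defaults to basal).
#' @return named numeric vector of rates, one per dependent variable.
#' @export
gma_derivatives <- function(model, state = basal_state(model)) {
  dep <- dependent_names(model)
  out <- stats::setNames(numeric(length(dep)), dep)
  for (nm in dep) {
    s <- 0
    for (tm in model$equations[[nm]])
      s <- s + tm$sign * tm$coef * evaluate_flux(tm, state)
    out[nm] <- s
  }
  out
}

#' Stoichiometric couplings of a model
#'
#' Physical fluxes whose `flux_id` appears in more than one equation, with the
#' signed coefficient they carry in each.
#'
#' @param model a `gma_model`.
#' @return named list: flux_id -> named numeric (variable -> signed coef).
#' @export
flux_couplings <- function(model) {
  acc <- list()
  for (nm in names(model$equations)) for (tm in model$equations[[nm]]) {
    if (is.na(tm$flux_id) || !nzchar(tm$flux_id)) next
    acc[[tm$flux_id]] <- c(acc[[tm$flux_id]],
                           stats::setNames(tm$sign * tm$coef, nm))
  }
  acc[vapply(acc, length, 1L) > 1L]
}

# Internal: compiled representation for fast vectorised evaluation.
# E: n_term x n_var exponent matrix; S: n_dep x n_term signed-coef matrix;
# gamma: n_term vector. deriv(state) = S %*% (gamma * exp(E %*% log(state))).
compile_gma <- function(model) {
  vn <- model$variables$name
  dep <- dependent_names(model)
  terms <- list(); target <- integer(0); sgn <- numeric(0)
  for (nm in names(model$equations)) for (tm in model$equations[[nm]]) {
    terms[[length(terms) + 1L]] <- tm
    target <- c(target, match(nm, dep))
    sgn <- c(sgn, tm$sign * tm$coef)
  }
  nt <- length(terms)
  E <- matrix(0, nt, length(vn), dimnames = list(NULL, vn))
  gam <- numeric(nt)
  for (k in seq_len(nt)) {
    tm <- terms[[k]]
    gam[k] <- tm$gamma
    if (length(tm$factors)) E[k, names(tm$factors)] <- tm$factors
  }
  S <- matrix(0, length(dep), nt)
  S[cbind(target, seq_len(nt))] <- sgn
  list(E = E, S = S, gamma = gam, var_names = vn, dep = dep,
       terms = terms, target = target)
}

# Internal: flux vector for a compiled model at a full positive state.
compiled_fluxes <- function(cm, state) {
  as.numeric(cm$gamma * exp(cm$E %*% log(state[cm$var_names])))
}
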