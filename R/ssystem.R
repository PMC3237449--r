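#' Aggregate a GMA model into an S-system at an operating point
#'
#' Collapses every dependent pool's influx terms into one aggregate power law
#' \eqn{\alpha_i \prod_j X_j^{g_{ij}}} (and the effluxes into
#' \eqn{\beta_i \prod_j X_j^{h_{ij}}}) by flux-weighted averaging of the
#' kinetic orders at the operating point:
#' \eqn{g_{ij} = \sum_k v_{ik} f_{ikj} / \sum_k v_{ik}} over the influx
#' terms, and likewise for the effluxes. \eqn{\alpha_i} is chosen so the
#' aggregate influx matches the GMA influx sum at the operating point.
#'
#' @param model a [gma_model()].
#' @param operating_point named positive state over all variables (defaults to
#'   the basal state).
#' @return object of class `ssystem`: alpha, beta, kinetic-order matrices G
#'   and H (dependent rows, all-variable columns), the operating point, and
#'   the aggregate influx/efflux values `Vin`, `Vout` there.
#' @export
as_ssystem <- function(model, operating_point = basal_state(model)) {
  if (any(operating_point <= 0))
    stop("operating point must be strictly positive", call. = FALSE)
  dep <- dependent_names(model)
  vn <- model$variables$name
  nd <- length(dep)
  G <- H <- matrix(0, nd, length(vn), dimnames = list(dep, vn))
  alpha <- beta <- Vin <- Vout <- stats::setNames(numeric(nd), dep)
  for (i in seq_along(dep)) {
    nm <- dep[i]
    terms <- model$equations[[nm]]
    sg <- vapply(terms, `[[`, 1L, "sign")
    if (!any(sg > 0) || !any(sg < 0))
      stop("S-system undefined: dependent variable ", nm,
           if (!any(sg > 0)) " has no influx term" else " has no efflux term",
           call. = FALSE)
    v <- vapply(terms, function(tm)
      tm$coef * evaluate_flux(tm, operating_point), 0)
    for (side in c(1, -1)) {
      sel <- which(sg == side)
      V <- sum(v[sel])
      ord <- stats::setNames(numeric(length(vn)), vn)
      for (k in sel) {
        f <- terms[[k]]$factors
        if (length(f)) ord[names(f)] <- ord[names(f)] + v[k] * f
      }
      ord <- ord / V
      a <- V / prod(operating_point[vn]^ord)
      if (side == 1) { G[i, ] <- ord; alpha[i] <- a; Vin[i] <- V }
      else           { H[i, ] <- ord; beta[i] <- a; Vout[i] <- V }
    }
  }
  structure(list(alpha = alpha, beta = beta, G = G, H = H,
                 operating_point = operating_point[vn],
                 dependent = dep,
                 independent = setdiff(vn, dep),
                 Vin = Vin, Vout = Vout),
            class = "ssystem")
}

#' @export
print.ssystem <- function(x, ...) {
  cat(sprintf("S-system: %d dependent, %d independent variables\n",
              length(x$dependent), length(x$independent)))
  r <- max(abs(x$Vin - x$Vout) / x$Vin)
  cat(sprintf("max |influx-efflux|/influx at operating point: %.3g\n", r))
  invisible(x)
}

# Internal: A = G - H partitioned into dependent / independent columns.
ssystem_A <- function(ss) {
  A <- ss$G - ss$H
  list(AD = A[, ss$dependent, drop = FALSE],
       AI = A[, ss$independent, drop = FALSE])
}

# Internal: solve with AD, with a diagnostic error when singular.
solve_AD <- function(AD, rhs) {
  qrA <- qr(AD)
  if (qrA$rank < ncol(AD)) {
    sv <- svd(AD)
    null_vec <- round(sv$v[, ncol(AD)], 6)
    stop("singular dependent kinetic-order matrix A_D (rank ", qrA$rank,
         " of ", ncol(AD), "); null-space direction: ",
         paste(sprintf("%s:%g", colnames(AD), null_vec)[null_vec != 0],
               collapse = ", "), call. = FALSE)
  }
  solve(qrA, rhs)
}

#' S-system steady state via the logarithmic coordinate system
#'
#' In log coordinates an S-system steady state is the linear system
#' \eqn{A_D y_D = b - A_I y_I} with \eqn{A = G - H},
#' \eqn{b_i = \ln(\beta_i/\alpha_i)} and \eqn{y = \ln X}.
#'
#' @param ss an [as_ssystem()] result.
#' @param independent_values named values for the independent variables
#'   (defaults to the operating point).
#' @return named vector of steady-state concentrations for the dependent
#'   variables.
#' @export
steady_state_log <- function(ss, independent_values = NULL) {
  yI <- if (is.null(independent_values)) log(ss$operating_point[ss$independent])
        else log(independent_values[ss$independent])
  if (anyNA(yI)) stop("independent_values must cover all independents",
                      call. = FALSE)
  p <- ssystem_A(ss)
  b <- log(ss$beta / ss$alpha)
  yD <- solve_AD(p$AD, b - as.numeric(p$AI %*% yI))
  exp(stats::setNames(as.numeric(yD), ss$dependent))
}

#' Net rates of an S-system at a state (diagnostic)
#'
#' @param ss an `ssystem`.
#' @param state named values over all variables.
#' @return named numeric: alpha_i prod X^g - beta_i prod X^h per pool.
#' @export
ssystem_rates <- function(ss, state) {
  x <- state[c(ss$dependent, ss$independent)]
  lx <- log(x)
  vin <- ss$alpha * exp(as.numeric(ss$G[, names(x)] %*% lx))
  vout <- ss$beta * exp(as.numeric(ss$H[, names(x)] %*% lx))
  stats::setNames(vin - vout, ss$dependent)
}

#' Eigenvalues of the S-system Jacobian at steady state
#'
#' \eqn{J_{ij} = V_i^* (g_{ij} - h_{ij}) / X_j^*} with \eqn{V_i^*} the common
#' influx/efflux value at the steady state. All-negative real parts mean the
#' steady state is locally asymptotically stable; non-zero imaginary parts
#' permit (damped) oscillations.
#'
#' @param ss an `ssystem`.
#' @param steady named dependent steady state (defaults to the solution of
#'   [steady_state_log()] at the operating-point independents).
#' @return complex vector of eigenvalues.
#' @export
stability_eigenvalues <- function(ss, steady = NULL) {
  if (is.null(steady)) steady <- steady_state_log(ss)
  x <- c(steady[ss$dependent], ss$operating_point[ss$independent])
  lx <- log(x)
  Vstar <- ss$alpha * exp(as.numeric(ss$G[, names(x)] %*% lx))
  AD <- ssystem_A(ss)$AD
  n <- length(Vstar)
  J <- diag(Vstar, nrow = n) %*% AD %*% diag(1 / steady[ss$dependent], nrow = n)
  eigen(J, only.values = TRUE)$values
}

#' Logarithmic gains and rate-constant sensitivities of an S-system
#'
#' Closed forms at the steady state:
#' \itemize{
#'   \item metabolite log gains \eqn{L(X, X_I) = -A_D^{-1} A_I}
#'     (\eqn{\partial \ln X_i / \partial \ln X_{Ij}});
#'   \item rate-constant sensitivities \eqn{S(X, \beta) = A_D^{-1}} and
#'     \eqn{S(X, \alpha) = -A_D^{-1}};
#'   \item flux log gains \eqn{L(V, X_I) = G_I + G_D L};
#'   \item flux rate-constant sensitivities
#'     \eqn{S(V, \alpha) = I + G_D S(X,\alpha)},
#'     \eqn{S(V, \beta) = G_D S(X,\beta)}.
#' }
#'
#' @param ss an `ssystem`.
#' @return object of class `sensitivity_report` with the matrices, the
#'   eigenvalues and a `summary` list (fraction of magnitudes below 1, the
#'   maximum magnitude, per-variable aggregates).
#' @export
sensitivity_report <- function(ss) {
  p <- ssystem_A(ss)
  n <- length(ss$dependent)
  ADinv <- solve_AD(p$AD, diag(n))
  dimnames(ADinv) <- list(ss$dependent, ss$dependent)
  L <- -ADinv %*% p$AI
  GD <- ss$G[, ss$dependent, drop = FALSE]
  GI <- ss$G[, ss$independent, drop = FALSE]
  LV <- GI + GD %*% L
  S_beta <- ADinv
  S_alpha <- -ADinv
  SV_alpha <- diag(n) + GD %*% S_alpha
  SV_beta <- GD %*% S_beta
  dimnames(SV_alpha) <- dimnames(SV_beta) <- list(ss$dependent, ss$dependent)
  ev <- stability_eigenvalues(ss)
  all_mag <- abs(c(L, LV, S_alpha, S_beta, SV_alpha, SV_beta))
  summ <- list(
    n_entries = length(all_mag),
    fraction_below_one = mean(all_mag < 1),
    max_magnitude = max(all_mag),
    loggain_fraction_below_one = mean(abs(c(L, LV)) < 1),
    per_variable_sum_above_one = sort(apply(abs(L), 1, function(r)
      sum(r[r > 1])), decreasing = TRUE))
  structure(list(eigenvalues = ev,
                 log_gains_metabolites = L,
                 log_gains_fluxes = LV,
                 rc_sensitivities_metabolites = list(alpha = S_alpha,
                                                     beta = S_beta),
                 rc_sensitivities_fluxes = list(alpha = SV_alpha,
                                                beta = SV_beta),
                 summary = summ),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity report: %d entries, %.1f%% below 1 in magnitude, max %.3g\n",
              x$summary$n_entries, 100 * x$summary$fraction_below_one,
              x$summary$max_magnitude))
  re <- Re(x$eigenvalues)
  cat(sprintf("eigenvalues: max real part %.4g; %d with non-zero imaginary part\n",
              max(re), sum(Im(x$eigenvalues) != 0)))
  invisible(x)
}

#' Rank dependent variables by summed large logarithmic gains
#'
#' Per dependent variable, sums the magnitudes of its metabolite log gains
#' that exceed 1, sorts descending; ties break by variable declaration order.
#' Variables whose gains are all below 1 are omitted.
#'
#' @param report a [sensitivity_report()].
#' @param k how many variables to return (default all qualifying).
#' @return character vector of variable names (ranked), with the sums as a
#'   `"scores"` attribute.
#' @export
top_loggain_ranking <- function(report, k = Inf) {
  L <- report$log_gains_metabolites
  sums <- apply(abs(L), 1, function(r) sum(r[r > 1]))
  keep <- which(sums > 0)
  if (!length(keep)) return(character(0))
  ord <- keep[order(-sums[keep], keep)]
  ord <- ord[seq_len(min(k, length(ord)))]
  structure(rownames(L)[ord], scores = unname(sums[ord]))
}

#' Export a sensitivity report
#'
#' Writes the matrices as CSV files and a JSON summary (eigenvalues, counts,
#' fractions) into a directory.
#'
#' @param report a `sensitivity_report`.
#' @param dir output directory (created if needed).
#' @export
write_sensitivity_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.csv(as.data.frame(m),
                                        file.path(dir, f), row.names = TRUE)
  wr(report$log_gains_metabolites, "log_gains_metabolites.csv")
  wr(report$log_gains_fluxes, "log_gains_fluxes.csv")
  wr(report$rc_sensitivities_metabolites$alpha, "rc_sens_metabolites_alpha.csv")
  wr(report$rc_sensitivities_metabolites$beta, "rc_sens_metabolites_beta.csv")
  wr(report$rc_sensitivities_fluxes$alpha, "rc_sens_fluxes_alpha.csv")
  wr(report$rc_sensitivities_fluxes$beta, "rc_sens_fluxes_beta.csv")
  jsonlite::write_json(
    list(eigenvalues = data.frame(re = Re(report$eigenvalues),
                                  im = Im(report$eigenvalues)),
         summary = report$summary[c("n_entries", "fraction_below_one",
                                    "max_magnitude",
                                    "loggain_fraction_below_one")]),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
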