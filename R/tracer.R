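#' Labeling map for tracer simulation
#'
#' Assigns, for every physical flux of a model, where the label carried by
#' that flux comes from:
#' \itemize{
#'   \item one or more donor variable names: material arriving through the
#'     flux is labeled with probability \eqn{1 - \prod_d (1 - f_d)} where
#'     \eqn{f_d} is each donor's current label fraction (a single
#'     carbon-skeleton donor is the usual case);
#'   \item `"unlabeled"`: the flux never delivers label (e.g. fresh medium
#'     inflow);
#'   \item `"blocked"`: label transfer is suppressed -- the total mass flow is
#'     unchanged but the material is delivered unlabeled (the donor still
#'     loses label through its own efflux bookkeeping).
#' }
#'
#' @param model a [gma_model()].
#' @param assignments named list: flux_id -> character vector of donors, or
#'   `"unlabeled"` / `"blocked"`.
#' @return object of class `labeling_map`.
#' @export
labeling_map <- function(model, assignments) {
  ids <- unique(unlist(lapply(model$equations, function(tl)
    vapply(tl, `[[`, "", "flux_id"))))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  missing_f <- setdiff(ids, names(assignments))
  if (length(missing_f))
    stop("labeling map incomplete; unassigned flux(es): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  vn <- model$variables$name
  for (id in names(assignments)) {
    a <- assignments[[id]]
    if (length(a) == 1L && a %in% c("unlabeled", "blocked")) next
    bad <- setdiff(a, vn)
    if (length(bad))
      stop("labeling map for ", id, " names undeclared donor(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(assignments = assignments), class = "labeling_map")
}

#' Split a GMA model into labeled/unlabeled twin pools
#'
#' Every dependent pool \eqn{X_i} becomes a labeled part \eqn{L_i} and an
#' unlabeled part \eqn{U_i} with \eqn{X_i = L_i + U_i}. Kinetics are always
#' evaluated on the total pools, so the twin system's summed dynamics are
#' term-by-term identical to the base model; the label bookkeeping only
#' partitions each flux. Mass leaving a pool carries that pool's label
#' fraction; mass arriving is labeled according to the flux's donors (see
#' [labeling_map()]).
#'
#' @param model base [gma_model()]; every flux must carry a `flux_id`.
#' @param map a [labeling_map()].
#' @param initially_labeled named numeric vector of label fractions in
#'   `[0, 1]` at t = 0 (pools not named start fully unlabeled).
#' @return object of class `labeled_model`.
#' @export
split_labels <- function(model, map, initially_labeled = numeric(0)) {
  stopifnot(inherits(map, "labeling_map"))
  bad <- initially_labeled[initially_labeled < 0 | initially_labeled > 1]
  if (length(bad)) stop("initial label fractions must lie in [0, 1]",
                        call. = FALSE)
  dep <- dependent_names(model)
  unknown <- setdiff(names(initially_labeled), dep)
  if (length(unknown))
    stop("initially_labeled names unknown pools: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  frac0 <- stats::setNames(numeric(length(dep)), dep)
  frac0[names(initially_labeled)] <- initially_labeled
  structure(list(base = model, map = map, frac0 = frac0),
            class = "labeled_model")
}

#' @export
print.labeled_model <- function(x, ...) {
  cat("labeled twin system over", length(dependent_names(x$base)),
      "pools (L + U per pool)\n")
  invisible(x)
}

#' Simulate a labeled twin system
#'
#' Integrates the split system. State names are `L_<pool>` and `U_<pool>`;
#' interventions may target those, the independents, or a total pool name
#' (interpreted as acting proportionally on both halves for `set_value` /
#' `scale_value`, and as an unlabeled addition for `add_bolus`).
#'
#' @param lmodel a [split_labels()] result.
#' @param interventions list of [intervention()]s.
#' @inheritParams simulate_gma
#' @return a `labeled_trajectory`: times, `L` and `U` matrices, and the total
#'   `values` matrix (L + U).
#' @export
simulate_labeled <- function(lmodel, interventions = list(), t_end = 100,
                             dt = 1, times = NULL, rtol = 1e-8, atol = 1e-10,
                             method = "lsoda") {
  if (inherits(interventions, "bst_intervention"))
    interventions <- list(interventions)
  model <- lmodel$base
  cm <- compile_gma(model)
  dep <- cm$dep
  nd <- length(dep)
  tot0 <- basal_state(model, "dependent")
  L0 <- tot0 * lmodel$frac0
  y0 <- c(stats::setNames(L0, paste0("L_", dep)),
          stats::setNames(tot0 - L0, paste0("U_", dep)))
  params <- basal_state(model, "independent")

  # rewrite interventions on total pools into split-space interventions
  interventions <- lapply(interventions, function(iv) {
    if (iv$target %in% dep) iv$target <- paste0("TOTAL_", iv$target)
    iv
  })

  # per-term routing info
  nt <- length(cm$terms)
  donor_single <- rep(NA_integer_, nt)   # index into dep for 1-donor fluxes
  donor_multi <- vector("list", nt)      # indices for multi-donor fluxes
  for (k in seq_len(nt)) {
    id <- cm$terms[[k]]$flux_id
    if (is.na(id) || !nzchar(id))
      stop("every flux needs a flux_id for label routing", call. = FALSE)
    a <- lmodel$map$assignments[[id]]
    if (is.null(a)) stop("flux ", id, " missing from labeling map", call. = FALSE)
    if (length(a) == 1L && a %in% c("unlabeled", "blocked")) next
    di <- match(a, dep)
    if (anyNA(di)) {
      # donors that are independent variables never carry label
      di <- di[!is.na(di)]
      if (!length(di)) next
    }
    if (length(di) == 1L) donor_single[k] <- di else donor_multi[[k]] <- di
  }
  multi_idx <- which(lengths(donor_multi) > 0)
  Spos <- pmax(cm$S, 0)   # influx routing  (ndep x nterm)
  Sneg <- -pmin(cm$S, 0)  # efflux routing
  floor_tot <- 1e-12 * tot0

  rhs_factory <- function(p) {
    function(t, y) {
      L <- y[seq_len(nd)]; U <- y[nd + seq_len(nd)]
      tot <- pmax(L + U, floor_tot)
      full <- c(stats::setNames(tot, dep), p)
      v <- compiled_fluxes(cm, full)
      f <- pmin(pmax(L / tot, 0), 1)
      f[L + U <= 0] <- 0                       # no label in nothing
      alpha <- ifelse(is.na(donor_single), 0, f[donor_single])
      alpha[is.na(alpha)] <- 0
      for (k in multi_idx) alpha[k] <- 1 - prod(1 - f[donor_multi[[k]]])
      f_eq <- f[cm$target]                     # efflux carries own fraction
      dL <- as.numeric(Spos %*% (v * alpha) - Sneg %*% (v * f_eq))
      dU <- as.numeric(Spos %*% (v * (1 - alpha)) - Sneg %*% (v * (1 - f_eq)))
      list(c(dL, dU))
    }
  }

  # TOTAL_* targets are expanded here rather than in apply_intervention
  expand_total <- function(iv, state) {
    pool <- sub("^TOTAL_", "", iv$target)
    li <- paste0("L_", pool); ui <- paste0("U_", pool)
    tot <- state[li] + state[ui]
    switch(iv$kind,
           set_value = { r <- if (tot > 0) state[li] / tot else 0
                         state[li] <- iv$amount * r
                         state[ui] <- iv$amount * (1 - r) },
           scale_value = { state[li] <- state[li] * iv$amount
                           state[ui] <- state[ui] * iv$amount },
           add_bolus = state[ui] <- state[ui] + iv$amount)
    state
  }
  apply_one <- function(iv, state, params) {
    if (grepl("^TOTAL_", iv$target))
      list(state = expand_total(iv, state), params = params)
    else apply_intervention(iv, state, params)
  }
  # the label halves may legitimately touch zero; clamping them there is
  # bookkeeping, not a kinetic pathology, so no warning is raised
  res <- integrate_piecewise(y0, params, interventions, t_end, dt, times,
                             rhs_factory, rtol,
                             atol * pmax(c(tot0, tot0), 1e-6), method,
                             rep(0, 2 * nd), applier = apply_one,
                             warn_clamp = FALSE)
  L <- res$values[, seq_len(nd), drop = FALSE]
  U <- res$values[, nd + seq_len(nd), drop = FALSE]
  colnames(L) <- colnames(U) <- dep
  structure(list(times = res$times, L = L, U = U, values = L + U,
                 independents = res$params,
                 model_hash = model_hash(model),
                 interventions = interventions),
            class = c("labeled_trajectory", "gma_trajectory"))
}

#' Label fraction series of a pool
#'
#' \eqn{L/(L+U)} with the 0/0 -> 0 convention.
#'
#' @param ltraj a [simulate_labeled()] trajectory.
#' @param pool pool name.
#' @return numeric series in `[0, 1]` along `ltraj$times`.
#' @export
label_fraction <- function(ltraj, pool) {
  if (!pool %in% colnames(ltraj$L)) stop("unknown pool: ", pool, call. = FALSE)
  tot <- ltraj$L[, pool] + ltraj$U[, pool]
  out <- ifelse(tot > 0, ltraj$L[, pool] / tot, 0)
  pmin(pmax(out, 0), 1)
}

#' Labeled series of a pool (or an aggregate of pools)
#'
#' @param ltraj a labeled trajectory.
#' @param pools character vector of pool names.
#' @return summed labeled amounts along the time grid.
#' @export
labeled_series <- function(ltraj, pools) {
  missing_v <- setdiff(pools, colnames(ltraj$L))
  if (length(missing_v)) stop("unknown pool(s): ",
                              paste(missing_v, collapse = ", "), call. = FALSE)
  rowSums(ltraj$L[, pools, drop = FALSE])
}

#' Counts-per-minute correction for steryl-ester label signals
#'
#' Experimental steryl-ester counts include label in the acyl moiety; the
#' classical correction multiplies the counts by 27/43 (27 sterol carbons of
#' 43 total with a C16 acyl chain). In a simulation where acyl-label
#' incorporation into esters is suppressed (`acyl_labeled = FALSE`, the
#' default simulation mode) the signal is already sterol-only and the
#' correction is an identity.
#'
#' @param signal numeric labeled steryl-ester series.
#' @param acyl_labeled whether the simulated ester label includes the acyl
#'   moiety.
#' @return corrected series.
#' @export
cpm_corrected_esters <- function(signal, acyl_labeled = FALSE) {
  if (acyl_labeled) signal * 27 / 43 else signal
}

#' Serialize / read a labeling map as YAML
#'
#' @param map a [labeling_map()].
#' @param file path.
#' @export
write_labeling_yaml <- function(map, file) {
  yaml::write_yaml(map$assignments, file)
  invisible(file)
}

#' @rdname write_labeling_yaml
#' @param model model the map belongs to (for validation).
#' @export
read_labeling_yaml <- function(model, file) {
  labeling_map(model, yaml::read_yaml(file))
}
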