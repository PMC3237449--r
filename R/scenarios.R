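#' In-silico tracer and inhibition experiments on the SL-E model
#'
#' @description
#' The computational experiments are thin, declarative drivers over
#' [simulate_labeled()] / [simulate_gma()]: a radioactive acetate bolus, a
#' pulse-chase (labeled medium for a fixed window, then washout with
#' unlabeled medium of equal concentration), enzyme knockdowns applied one
#' minute before the tracer perturbation, and total-mass fold-change tables.
#'
#' Timing convention: enzyme activities are scaled at t = 0 and the tracer
#' perturbation fires at t = 1 min, i.e. the inhibitor is assumed to reach
#' its target one minute before labeling starts.
#'
#' @name sle-scenarios
NULL

# internal: knockdown interventions at t = 0
knockdown_interventions <- function(model, enzyme, fraction) {
  if (is.null(enzyme)) return(list())
  if (!enzyme %in% independent_names(model))
    stop("knockdown target must be an independent variable: ", enzyme,
         call. = FALSE)
  if (fraction <= 0)
    stop("fraction must be > 0 (a full knockout is singular for power-law ",
         "kinetics; use 0.01 for a 99% activity decrease)", call. = FALSE)
  if (fraction > 1) stop("fraction must be <= 1", call. = FALSE)
  list(intervention(0, "scale_value", enzyme, fraction))
}

#' Radioactive acetate bolus experiment
#'
#' At t = 1 min the external acetate pool's unlabeled content is replaced by
#' `label_amount` of labeled acetate (replacement up to the current total;
#' any excess over the current total raises the total). Uptake kinetics are
#' unchanged: labeling never alters mass flow.
#'
#' @param label_amount labeled external acetate in uM (>= 0).
#' @param t_end horizon in minutes (default 1000).
#' @param enzyme,fraction optional knockdown (independent variable scaled at
#'   t = 0).
#' @param acyl `"blocked"` or `"donor"`: whether the steryl-ester synthases
#'   incorporate acyl label (see [sle_labeling()]).
#' @param model dynamic-variant SL-E model (built fresh by default).
#' @param dt output resolution (min).
#' @param ... passed to [simulate_labeled()].
#' @return a `labeled_trajectory`.
#' @export
run_bolus <- function(label_amount = 125, t_end = 1000, enzyme = NULL,
                      fraction = 1, acyl = "blocked",
                      model = sle_model("dynamic"), dt = 1, ...) {
  if (label_amount < 0) stop("label_amount must be >= 0", call. = FALSE)
  lm <- split_labels(model, sle_labeling(model, acyl = acyl))
  total0 <- basal_state(model)[["X125"]]
  iv <- c(knockdown_interventions(model, enzyme, fraction),
          list(intervention(1, "set_value", "L_X125", label_amount),
               intervention(1, "set_value", "U_X125",
                            max(total0 - label_amount, 0))))
  simulate_labeled(lm, iv, t_end = t_end, dt = dt, ...)
}

#' Pulse-chase labeling experiment
#'
#' As [run_bolus()], but after `pulse_len` minutes of labeling the external
#' label is replaced by unlabeled acetate of equal concentration (washout:
#' total uptake kinetics unchanged).
#'
#' @inheritParams run_bolus
#' @param pulse_len labeling window in minutes (> 0; default 30).
#' @return a `labeled_trajectory`.
#' @export
run_pulse_chase <- function(label_amount = 125, pulse_len = 30, t_end = 1000,
                            enzyme = NULL, fraction = 1, acyl = "blocked",
                            model = sle_model("dynamic"), dt = 1, ...) {
  if (pulse_len <= 0) stop("pulse_len must be > 0", call. = FALSE)
  if (label_amount < 0) stop("label_amount must be >= 0", call. = FALSE)
  lm <- split_labels(model, sle_labeling(model, acyl = acyl))
  total0 <- basal_state(model)[["X125"]]
  t_chase <- 1 + pulse_len
  # washout with fresh unlabeled medium: external label -> 0, external total
  # restored to the medium concentration
  iv <- c(knockdown_interventions(model, enzyme, fraction),
          list(intervention(1, "set_value", "L_X125", label_amount),
               intervention(1, "set_value", "U_X125",
                            max(total0 - label_amount, 0)),
               intervention(t_chase, "set_value", "L_X125", 0),
               intervention(t_chase, "set_value", "U_X125", total0)))
  simulate_labeled(lm, iv, t_end = t_end, dt = dt, ...)
}

#' Enzyme knockdown with paired control
#'
#' Scales an independent enzyme activity at t = 0, applies the base
#' scenario's tracer perturbation at t = 1 min, and returns both the
#' perturbed and the control (fraction 1) run for paired comparison.
#'
#' @param enzyme independent variable name (e.g. `"X157"` for SPT, `"X133"`
#'   for IPC synthase, `"X134"` for ceramide synthase).
#' @param fraction remaining activity in (0, 1]; use 0.01 for a 99% decrease.
#' @param base_scenario `"pulse_chase"` (default) or `"bolus"`.
#' @param t_end horizon (min).
#' @param model dynamic-variant SL-E model.
#' @param ... passed to the base scenario runner.
#' @return list with elements `perturbed` and `control` (labeled
#'   trajectories).
#' @export
run_knockdown <- function(enzyme, fraction,
                          base_scenario = c("pulse_chase", "bolus"),
                          t_end = 1000, model = sle_model("dynamic"), ...) {
  base_scenario <- match.arg(base_scenario)
  runner <- switch(base_scenario, pulse_chase = run_pulse_chase,
                   bolus = run_bolus)
  list(perturbed = runner(enzyme = enzyme, fraction = fraction, t_end = t_end,
                          model = model, ...),
       control = runner(t_end = t_end, model = model, ...))
}

#' Total-mass fold-change tables under enzyme inhibition
#'
#' For each condition the balanced model is integrated with the enzyme scaled
#' at t = 0 (no tracer; total masses only), pools are read at the requested
#' times and divided by their basal values. Output mirrors the three-table
#' layout used for such experiments: ergosterol sub-populations (X32, X36,
#' X37, X39), sterol/ester aggregates, and complex sphingolipid classes.
#'
#' @param conditions named list: condition label -> list(enzyme =, fraction =).
#'   The wild type (no intervention) is always included as reference.
#' @param times evaluation times in minutes (default c(60, 120)).
#' @param model balanced-variant SL-E model.
#' @param digits rounding applied to the formatted fold changes (2, matching
#'   the table convention); raw values are returned alongside.
#' @return list of data.frames `ergosterol_subpops`, `sterol_aggregates`,
#'   `complex_sphingolipids` (rounded) plus `raw` (unrounded long format).
#' @export
total_mass_table <- function(conditions,
                             times = c(60, 120),
                             model = sle_model("balanced"),
                             digits = 2) {
  basal <- basal_state(model, "dependent")
  pools <- sle_pools()
  agg_defs <- list(
    ergosterol_subpops = list(X32 = "X32", X36 = "X36", X37 = "X37",
                              X39 = "X39"),
    sterol_aggregates = list(pm_ergosterol = pools$pm_ergosterol,
                             total_ergosterol = pools$total_ergosterol,
                             total_erg_esters = pools$total_erg_esters,
                             total_sterols = pools$total_sterols,
                             total_steryl_esters = pools$total_steryl_esters),
    complex_sphingolipids = list(IPC = pools$IPC, MIPC = pools$MIPC,
                                 MIP2C = pools$MIP2C, CS = pools$CS))
  conditions <- c(list("wild type" = list(enzyme = NULL, fraction = 1)),
                  conditions)
  rows <- list()
  for (cond in names(conditions)) {
    cfg <- conditions[[cond]]
    iv <- knockdown_interventions(model, cfg$enzyme, cfg$fraction)
    traj <- simulate_gma(model, iv, t_end = max(times), dt = 1)
    for (tt in times) {
      k <- which(traj$times == tt)
      if (!length(k)) stop("time ", tt, " not on the output grid", call. = FALSE)
      state <- traj$values[max(k), ]
      for (tab in names(agg_defs)) for (nm in names(agg_defs[[tab]])) {
        vars <- agg_defs[[tab]][[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          table = tab, condition = cond, time = tt, pool = nm,
          fold = sum(state[vars]) / sum(basal[vars]),
          stringsAsFactors = FALSE)
      }
    }
  }
  raw <- do.call(rbind, rows)
  shape <- function(tab) {
    d <- raw[raw$table == tab, ]
    out <- stats::reshape(
      d[, c("condition", "time", "pool", "fold")],
      idvar = c("condition", "time"), timevar = "pool", direction = "wide")
    names(out) <- sub("^fold\\.", "", names(out))
    out[, -(1:2)] <- round(out[, -(1:2)], digits)
    rownames(out) <- NULL
    out
  }
  list(ergosterol_subpops = shape("ergosterol_subpops"),
       sterol_aggregates = shape("sterol_aggregates"),
       complex_sphingolipids = shape("complex_sphingolipids"),
       raw = raw)
}

#' Read and run a declarative scenario file
#'
#' Scenario YAML fields: `name`; `variant` (dynamic/balanced); `kind`
#' (`bolus`, `pulse_chase`, `total_mass`); `label_amount`; `pulse_len`;
#' `t_end`; `enzyme`; `fraction`; `conditions`/`times` (total_mass).
#'
#' @param file YAML path.
#' @return for tracer kinds a labeled trajectory (knockdowns return the
#'   paired list); for `total_mass` the table list.
#' @export
run_scenario <- function(file) {
  sc <- yaml::read_yaml(file)
  kind <- match.arg(sc$kind, c("bolus", "pulse_chase", "total_mass"))
  if (kind == "total_mass") {
    conds <- lapply(sc$conditions, function(cc)
      list(enzyme = cc$enzyme, fraction = cc$fraction))
    return(total_mass_table(conds, times = unlist(sc$times)))
  }
  args <- list(label_amount = sc$label_amount %||% 125,
               t_end = sc$t_end %||% 1000)
  if (kind == "pulse_chase") args$pulse_len <- sc$pulse_len %||% 30
  if (!is.null(sc$enzyme)) {
    do.call(run_knockdown,
            c(list(enzyme = sc$enzyme, fraction = sc$fraction,
                   base_scenario = kind, t_end = args$t_end),
              args[setdiff(names(args), "t_end")]))
  } else do.call(switch(kind, bolus = run_bolus,
                        pulse_chase = run_pulse_chase), args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
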