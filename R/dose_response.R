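#' @name protocols
#' @title Perifusion protocols
#'
#' @description
#' A protocol is an ordered sequence of bath conditions applied to the imaged
#' cell: a glucose concentration, an optional acute treatment, and a duration.
#' Washout steps are part of the recording but excluded from rate analysis.
#'
#' Supported treatments:
#' * `"none"` - glucose only;
#' * `"arginine_10mM"` - 10 mM arginine, a depolarising secretagogue that
#'   triggers release even at inhibitory (11 mM) glucose;
#' * `"mannoheptulose_10mM"` - classic glucokinase inhibitor; ineffective in
#'   rat alpha cells, which lack the GLUT2 transporter needed for its uptake;
#' * `"deoxyglucose_10mM"`, `"thioglucose_10mM"` - glycolysis inhibitors
#'   (glucose-6-phosphate isomerase / glucose transport), which lower the
#'   metabolic flux so that normally inhibitory 4 mM glucose stimulates;
#' * `"GKA"` - small-molecule glucokinase activator (e.g. RO0281675) at
#'   `gka_conc_uM` micromolar; raises phosphorylating flux so that normally
#'   stimulatory 3 mM glucose inhibits;
#' * `"washout"` - drug washout period, flagged and excluded from analysis.
NULL

.treatments <- c("none", "arginine_10mM", "mannoheptulose_10mM",
                 "deoxyglucose_10mM", "thioglucose_10mM", "GKA", "washout")

#' @rdname protocols
#' @param glucose_mM Bath glucose concentration in mM (>= 0).
#' @param treatment One of the treatment names listed below.
#' @param duration_s Step duration in seconds (> 0).
#' @param gka_conc_uM Glucokinase-activator concentration in micromolar;
#'   required when `treatment = "GKA"`.
#' @param label Optional step label; defaults to a compact description.
#' @return `protocol_step()`: a `protocol_step` object.
#' @export
protocol_step <- function(glucose_mM, treatment = "none", duration_s,
                          gka_conc_uM = NA_real_, label = NULL) {
  if (!is.numeric(glucose_mM) || length(glucose_mM) != 1L ||
      !is.finite(glucose_mM) || glucose_mM < 0) {
    stop("glucose_mM must be a single non-negative number", call. = FALSE)
  }
  treatment <- match.arg(treatment, .treatments)
  stop_if_not_scalar_pos(duration_s, "duration_s")
  if (treatment == "GKA" && (!is.finite(gka_conc_uM) || gka_conc_uM <= 0)) {
    stop("GKA steps need a positive gka_conc_uM", call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0(format(glucose_mM), "mM")
    if (treatment == "GKA") label <- paste0(label, "+GKA", format(gka_conc_uM), "uM")
    else if (treatment != "none") label <- paste0(label, "+", treatment)
  }
  structure(
    list(glucose_mM = glucose_mM, treatment = treatment,
         duration_s = duration_s, gka_conc_uM = gka_conc_uM,
         washout = treatment == "washout", label = label),
    class = "protocol_step")
}

#' @rdname protocols
#' @param steps List of `protocol_step` objects.
#' @return `protocol()`: a `protocol` object (fields `steps`, `label`,
#'   `total_duration_s`).
#' @export
protocol <- function(steps, label = "protocol") {
  stopifnot(length(steps) >= 0, all(vapply(steps, inherits, TRUE, "protocol_step")))
  structure(
    list(steps = steps, label = label,
         total_duration_s = sum(vapply(steps, `[[`, 0, "duration_s"))),
    class = "protocol")
}

#' @rdname protocols
#' @param glucose_levels_mM Glucose concentrations applied sequentially.
#' @param step_duration_s Duration of each ramp step (default 3 min).
#' @return `protocol_ramp()`: the descending glucose ramp protocol
#'   (11, 5, 4, 3, 2, 1, 0 mM for 3 min each by default).
#' @export
protocol_ramp <- function(glucose_levels_mM = c(11, 5, 4, 3, 2, 1, 0),
                          step_duration_s = 180) {
  protocol(lapply(glucose_levels_mM, protocol_step,
                  treatment = "none", duration_s = step_duration_s),
           label = "glucose ramp")
}

#' @rdname protocols
#' @param inhibitor One of the inhibitor treatments
#'   (`"mannoheptulose_10mM"`, `"deoxyglucose_10mM"`, `"thioglucose_10mM"`).
#' @return `protocol_inhibitor()`: the 4 mM / 4 mM + inhibitor / washout /
#'   3 mM design (4 min each, washout excluded from analysis).
#' @export
protocol_inhibitor <- function(inhibitor = c("mannoheptulose_10mM",
                                             "deoxyglucose_10mM",
                                             "thioglucose_10mM"),
                               step_duration_s = 240) {
  inhibitor <- match.arg(inhibitor)
  protocol(list(
    protocol_step(4, "none", step_duration_s),
    protocol_step(4, inhibitor, step_duration_s),
    protocol_step(4, "washout", step_duration_s),
    protocol_step(3, "none", step_duration_s)
  ), label = paste0("glycolysis inhibitor (", inhibitor, ")"))
}

#' Glucose dose-response model of glucagon release
#'
#' Maps a protocol step (glucose + treatment) to a true exocytosis rate in
#' events per 100 um^2 per minute. The wildtype model is a two-level switch:
#' hypoglycaemic glucose inside `stim_range_mM` stimulates at `r_stim`,
#' normo-/hyperglycaemic glucose inhibits at `r_inhib`, and glucose-free
#' buffer collapses metabolic flux (low ATP/ADP) and suppresses release back
#' to `r_inhib` when `zero_glucose_suppressed` is `TRUE`. The default 2:1
#' ratio of `r_stim` to `r_inhib` encodes the observed two-fold stimulation
#' at 1-3 mM glucose. Glucokinase knockdown cells lose glucose control and
#' release at the flat intermediate rate `r_kd` at every concentration.
#'
#' @param r_inhib Rate under inhibitory glucose (events/100 um^2/min).
#' @param r_stim Rate under stimulatory glucose; must exceed `r_inhib`.
#' @param stim_range_mM Closed interval `c(low, high)` of stimulatory
#'   glucose concentrations.
#' @param zero_glucose_suppressed If `TRUE`, glucose below `stim_range_mM[1]`
#'   (including 0 mM) releases at `r_inhib` rather than `r_stim`.
#' @param genotype `"wildtype"` or `"gk_knockdown"`.
#' @param r_kd Flat knockdown rate; must satisfy `r_inhib < r_kd < r_stim`.
#' @return A `dose_response_model` object.
#' @examples
#' m <- dose_response_model()
#' event_rate_at(m, protocol_step(3, "none", 180))  # stimulated: 2
#' event_rate_at(m, protocol_step(0, "none", 180))  # suppressed: 1
#' @export
dose_response_model <- function(r_inhib = 1.0, r_stim = 2.0,
                                stim_range_mM = c(1, 3),
                                zero_glucose_suppressed = TRUE,
                                genotype = c("wildtype", "gk_knockdown"),
                                r_kd = 1.5) {
  genotype <- match.arg(genotype)
  stop_if_not_scalar_pos(r_inhib, "r_inhib")
  stop_if_not_scalar_pos(r_stim, "r_stim")
  if (r_stim <= r_inhib) stop("r_stim must exceed r_inhib", call. = FALSE)
  stopifnot(length(stim_range_mM) == 2L, stim_range_mM[1] <= stim_range_mM[2])
  if (genotype == "gk_knockdown" && !(r_inhib < r_kd && r_kd < r_stim)) {
    stop("knockdown rate must satisfy r_inhib < r_kd < r_stim", call. = FALSE)
  }
  structure(
    list(r_inhib = r_inhib, r_stim = r_stim, stim_range_mM = stim_range_mM,
         zero_glucose_suppressed = zero_glucose_suppressed,
         genotype = genotype, r_kd = r_kd),
    class = "dose_response_model")
}

#' True event rate for one protocol step
#'
#' Applies the dose-response model to a (non-washout) protocol step,
#' including treatment modifiers:
#' arginine stimulates regardless of glucose; mannoheptulose has no effect
#' (no uptake in rat alpha cells); the glycolysis inhibitors 2-deoxy-glucose
#' and 5-thio-glucose make metabolisable glucose act stimulatory (their
#' effect at 4 mM matches 3 mM glucose alone); a glucokinase activator at
#' >= 0.1 uM lowers the stimulation threshold by one tested step, so 3 mM
#' glucose becomes inhibitory while 4 mM stays inhibitory. Knockdown cells
#' return the flat `r_kd` under all conditions.
#'
#' @param model A [dose_response_model()].
#' @param step A [protocol_step()]; must not be a washout step.
#' @return Event rate in events per 100 um^2 per minute.
#' @export
event_rate_at <- function(model, step) {
  stopifnot(inherits(model, "dose_response_model"),
            inherits(step, "protocol_step"))
  if (step$washout) stop("washout steps have no analysable rate", call. = FALSE)
  if (step$glucose_mM < 0) stop("negative glucose concentration", call. = FALSE)
  if (!step$treatment %in% .treatments) stop("unknown treatment", call. = FALSE)
  if (model$genotype == "gk_knockdown") return(model$r_kd)

  g <- step$glucose_mM
  lo <- model$stim_range_mM[1]
  hi <- model$stim_range_mM[2]
  base_rate <- function(g, hi) {
    if (g < lo) {
      # metabolic collapse regime (0 mM and below the stimulatory band)
      if (model$zero_glucose_suppressed) model$r_inhib else model$r_stim
    } else if (g <= hi) model$r_stim else model$r_inhib
  }
  switch(step$treatment,
    none = base_rate(g, hi),
    washout = model$r_inhib,
    arginine_10mM = model$r_stim,
    mannoheptulose_10mM = base_rate(g, hi),
    deoxyglucose_10mM = if (g >= lo) model$r_stim else base_rate(g, hi),
    thioglucose_10mM = if (g >= lo) model$r_stim else base_rate(g, hi),
    GKA = {
      if (step$gka_conc_uM >= 0.1) base_rate(g, hi - 1) else base_rate(g, hi)
    })
}

# Rate used by the simulator for every step, including washouts
# (basal secretion continues during washout at the inhibited rate).
simulated_rate <- function(model, step) {
  if (step$washout) {
    if (model$genotype == "gk_knockdown") model$r_kd else model$r_inhib
  } else {
    event_rate_at(model, step)
  }
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("protocol '%s': %d steps, %.0f s total\n",
              x$label, length(x$steps), x$total_duration_s))
  for (s in x$steps) {
    cat(sprintf("  %-18s %5.1f mM  %4.0f s%s\n", s$label, s$glucose_mM,
                s$duration_s, if (s$washout) "  [washout]" else ""))
  }
  invisible(x)
}
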