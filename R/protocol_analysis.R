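#' Segment a movie into protocol condition windows
#'
#' Converts the ordered protocol steps into half-open frame windows
#' `[frame_start, frame_end)`. Step durations are floored to whole frames;
#' window k starts at the cumulative frame count of the preceding steps.
#'
#' @param protocol A [protocol()].
#' @param acquisition An [acquisition_params()].
#' @param n_frames Number of frames in the recording; the protocol must fit.
#' @return Data frame: `label`, `glucose_mM`, `treatment`, `washout`,
#'   `frame_start`, `frame_end` (0-based half-open), `duration_min`.
#' @examples
#' w <- segment_conditions(protocol_ramp(), acquisition_params(), 14000)
#' w[w$glucose_mM == 3, c("frame_start", "frame_end")]  # 6000, 8000
#' @export
segment_conditions <- function(protocol, acquisition, n_frames) {
  stopifnot(inherits(protocol, "protocol"),
            inherits(acquisition, "acquisition_params"))
  steps <- protocol$steps
  if (length(steps) == 0) {
    return(data.frame(label = character(), glucose_mM = numeric(),
                      treatment = character(), washout = logical(),
                      frame_start = integer(), frame_end = integer(),
                      duration_min = numeric()))
  }
  nf <- vapply(steps, function(s) {
    floor_div(s$duration_s, acquisition$frame_interval_s)
  }, 0L)
  if (sum(nf) > n_frames) {
    stop("protocol is longer than the movie", call. = FALSE)
  }
  start <- cumsum(c(0L, nf[-length(nf)]))
  data.frame(
    label = vapply(steps, `[[`, "", "label"),
    glucose_mM = vapply(steps, `[[`, 0, "glucose_mM"),
    treatment = vapply(steps, `[[`, "", "treatment"),
    washout = vapply(steps, `[[`, TRUE, "washout"),
    frame_start = start,
    frame_end = start + nf,
    duration_min = nf * acquisition$frame_interval_s / 60)
}

#' Per-condition event rates
#'
#' Assigns detected events to condition windows by frame membership
#' (half-open ranges) and normalizes counts to events per 100 um^2 per
#' minute. Washout windows are excluded from the returned records; their
#' events, and any events outside all windows, are tallied separately.
#'
#' @param events Detected events data frame (needs a `frame` column).
#' @param windows Output of [segment_conditions()].
#' @param area_um2 Cell footprint area in um^2.
#' @return Data frame of [normalize_rate()] records, one per non-washout
#'   window (in protocol order), with additional columns `glucose_mM` and
#'   `treatment`; attributes `n_washout_events` and `n_unassigned`. A
#'   warning is emitted if events fall outside every window.
#' @export
rates_per_condition <- function(events, windows, area_um2) {
  assigned <- rep(NA_integer_, nrow(events))
  for (w in seq_len(nrow(windows))) {
    inw <- events$frame >= windows$frame_start[w] &
      events$frame < windows$frame_end[w]
    assigned[inw & is.na(assigned)] <- w
  }
  n_unassigned <- sum(is.na(assigned))
  if (n_unassigned > 0) {
    warning(sprintf("%d event(s) outside all condition windows", n_unassigned))
  }
  live <- which(!windows$washout)
  recs <- do.call(rbind, lapply(live, function(w) {
    r <- normalize_rate(sum(assigned == w, na.rm = TRUE), area_um2,
                        windows$duration_min[w] * 60, windows$label[w])
    r$glucose_mM <- windows$glucose_mM[w]
    r$treatment <- windows$treatment[w]
    r
  }))
  attr(recs, "n_washout_events") <-
    sum(windows$washout[assigned[!is.na(assigned)]])
  attr(recs, "n_unassigned") <- n_unassigned
  recs
}

#' Fold change between stimulatory and inhibitory conditions
#'
#' Ratio of the mean rate over the stimulatory condition labels to the mean
#' rate over the inhibitory labels (e.g. 1-3 mM vs 4-11 mM glucose in the
#' ramp).
#'
#' @param records Rate records (columns `condition` and
#'   `rate_per_100um2_min`), possibly pooled over cells.
#' @param stim_labels,inhib_labels Disjoint, non-empty sets of condition
#'   labels.
#' @return List with `ratio` (NA when the inhibitory mean is 0),
#'   `stim_mean`, `inhib_mean` and `undefined` flag.
#' @export
fold_change <- function(records, stim_labels, inhib_labels) {
  if (!length(stim_labels) || !length(inhib_labels)) {
    stop("label sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(stim_labels, inhib_labels))) {
    stop("label sets must be disjoint", call. = FALSE)
  }
  sm <- mean(records$rate_per_100um2_min[records$condition %in% stim_labels])
  im <- mean(records$rate_per_100um2_min[records$condition %in% inhib_labels])
  if (is.nan(sm) || is.nan(im)) stop("labels not found in records", call. = FALSE)
  if (im == 0) {
    list(ratio = NA_real_, stim_mean = sm, inhib_mean = im, undefined = TRUE)
  } else {
    list(ratio = sm / im, stim_mean = sm, inhib_mean = im, undefined = FALSE)
  }
}

#' Detect the glucose threshold of stimulation
#'
#' The dose-response analysis behind the "threshold between 4 and 3 mM"
#' conclusion. Takes per-cell rates at each tested glucose level, runs a
#' one-way ANOVA across levels (repeated measures with cell as block by
#' default, since each cell traverses the whole ramp), then Scheffe
#' post-hoc comparisons of every level against the reference (highest)
#' glucose concentration. A level is stimulatory iff its comparison with
#' the reference is significant and its mean rate is higher. The threshold
#' is reported as the bracketing interval between the highest stimulatory
#' level and the lowest non-stimulatory level above it, never interpolated.
#' `regulated` is `FALSE` when the omnibus ANOVA is non-significant (as in
#' glucokinase knockdown cells).
#'
#' @param rates Numeric matrix, cells x glucose levels (column names or
#'   `glucose_mM` give the concentrations), each entry a per-cell rate in
#'   events/100 um^2/min.
#' @param glucose_mM Glucose concentration per column; defaults to numeric
#'   column names.
#' @param reference_mM Reference (inhibitory) concentration; defaults to the
#'   highest tested level.
#' @param alpha Significance level (default 0.05).
#' @param method `"repeated"` (cell as block, default) or `"oneway"`.
#' @return A `threshold_result` list: `stimulatory_set` (descending),
#'   `threshold_interval_mM` (`c(low, high)` = (highest stimulatory, lowest
#'   non-stimulatory above it), `NA` when unregulated), `regulated`,
#'   `anova` (`F`, `df1`, `df2`, `p`) and `scheffe` (data frame of
#'   comparisons vs the reference).
#' @export
detect_threshold <- function(rates, glucose_mM = NULL, reference_mM = NULL,
                             alpha = 0.05, method = c("repeated", "oneway")) {
  method <- match.arg(method)
  rates <- as.matrix(rates)
  if (is.null(glucose_mM)) glucose_mM <- as.numeric(colnames(rates))
  if (anyNA(glucose_mM)) stop("glucose_mM could not be determined", call. = FALSE)
  if (ncol(rates) < 2) stop("need at least 2 glucose levels", call. = FALSE)
  if (nrow(rates) < 2) stop("need at least 2 cells", call. = FALSE)
  if (is.null(reference_mM)) reference_mM <- max(glucose_mM)
  ref <- which(glucose_mM == reference_mM)
  if (length(ref) != 1) stop("reference level not among tested levels", call. = FALSE)

  if (method == "repeated") {
    an <- rm_one_way_anova(rates)
  } else {
    an <- one_way_anova(lapply(seq_len(ncol(rates)), function(j) rates[, j]))
  }
  sch <- scheffe_posthoc(lapply(seq_len(ncol(rates)), function(j) rates[, j]),
                         ms_within = an$ms_within, df_within = an$df[2],
                         alpha = alpha, labels = as.character(glucose_mM))
  vs_ref <- sch[sch$i == ref | sch$j == ref, , drop = FALSE]
  other <- ifelse(vs_ref$i == ref, vs_ref$j, vs_ref$i)
  means <- colMeans(rates)
  elevated <- means[other] > means[ref]
  stim <- sort(glucose_mM[other[vs_ref$significant & elevated]],
               decreasing = TRUE)

  regulated <- is.finite(an$p) && an$p < alpha
  if (!regulated) stim <- numeric(0)
  interval <- c(NA_real_, NA_real_)
  if (length(stim)) {
    above <- sort(glucose_mM[glucose_mM > max(stim)])
    if (length(above)) interval <- c(max(stim), above[1])
  }
  structure(
    list(stimulatory_set = stim, threshold_interval_mM = interval,
         regulated = regulated,
         anova = list(F = an$statistic, df1 = an$df[1], df2 = an$df[2],
                      p = an$p),
         scheffe = vs_ref),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("glucose regulation: %s (ANOVA F(%d,%d) = %.2f, p = %.3g)\n",
              if (x$regulated) "present" else "absent",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  if (length(x$stimulatory_set)) {
    cat("stimulatory glucose:", paste(x$stimulatory_set, collapse = ", "),
        "mM\n")
    cat(sprintf("release threshold between %g and %g mM\n",
                x$threshold_interval_mM[2], x$threshold_interval_mM[1]))
  }
  invisible(x)
}
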