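# The assay's defined analysis: compression-expansion cycle segmentation,
# per-cycle minimum surface tension extraction, baseline QC, inhibition
# calling, replicate aggregation, and inhibitory-dose estimation.

#' Assay acceptance and inhibition criteria
#'
#' The thresholds of the bioassay, kept as configuration so the decision
#' rules are auditable rather than hard-coded. Defaults: baseline minimum
#' surface tension must be strictly below 5 mN/m with compression strictly
#' below 30 percent for data acceptance; inhibition is a minimum surface
#' tension at or above 10 mN/m for three or more consecutive cycle minima; a
#' chemical is called inhibitory when at least half of its QC-passing
#' replicates are inhibited.
#'
#' @param baseline_max_st Baseline acceptance limit for the minimum surface
#'   tension, mN/m (strict).
#' @param inhibition_st Inhibition threshold on per-cycle minima, mN/m
#'   (inclusive).
#' @param max_compression Baseline acceptance limit on the compression
#'   ratio (strict).
#' @param run_length Minimum number of consecutive qualifying minima.
#' @param replicate_rule Minimum fraction of QC-passing replicates that must
#'   be inhibited for an inhibitory chemical call.
#' @param n_baseline_cycles Number of leading complete cycles forming the
#'   baseline.
#' @return A named list of class \code{assay_criteria}.
#' @export
assay_criteria <- function(baseline_max_st = 5, inhibition_st = 10,
                           max_compression = 0.30, run_length = 3L,
                           replicate_rule = 0.5, n_baseline_cycles = 5L) {
  stopifnot(baseline_max_st > 0, inhibition_st > 0, max_compression > 0,
            run_length >= 1, replicate_rule > 0, replicate_rule <= 1,
            n_baseline_cycles >= 1)
  structure(list(baseline_max_st = baseline_max_st,
                 inhibition_st = inhibition_st,
                 max_compression = max_compression,
                 run_length = as.integer(run_length),
                 replicate_rule = replicate_rule,
                 n_baseline_cycles = as.integer(n_baseline_cycles)),
            class = "assay_criteria")
}

#' Segment a trace into compression-expansion cycles
#'
#' Cycles are delimited by successive local maxima of the area signal
#' (prominence-filtered: peaks must rise above the midline of the area range
#' and be separated by at least half the dominant period, estimated from the
#' area spectrum). A boundary sample that is itself a one-sided maximum
#' counts as a delimiter, so a trace starting at full expansion has no
#' discarded partial leading cycle; genuinely partial leading/trailing
#' cycles are discarded.
#'
#' @param trace A trace data frame with columns \code{time_s},
#'   \code{gamma_mN_per_m}, \code{area_mm2}.
#' @return Data frame with \code{cycle} (1-based), \code{start}, \code{end}:
#'   half-open sample index ranges [start, end).
#' @export
segment_cycles <- function(trace) {
  area <- trace$area_mm2
  n <- length(area)
  rng <- range(area)
  if (n < 3 || diff(rng) < 1e-9 * max(abs(rng), 1))
    stop_cdsurf("no compression-expansion cycle found in the area signal",
                "segmentation_error")
  mid <- rng[1] + 0.5 * diff(rng)

  # dominant period (samples) from the discrete spectrum
  sp <- Mod(stats::fft(area - mean(area)))[2:max(2, floor(n / 2))]
  period <- n / which.max(sp)
  min_dist <- max(2, floor(0.5 * period))

  pk <- pracma::findpeaks(area, minpeakheight = mid,
                          minpeakdistance = min_dist)
  peaks <- if (is.null(pk)) integer(0) else sort(pk[, 2])
  if (area[1] >= area[2] && area[1] >= mid &&
      (length(peaks) == 0 || peaks[1] > min_dist))
    peaks <- c(1L, peaks)
  if (area[n] >= area[n - 1] && area[n] >= mid &&
      (length(peaks) == 0 || n - peaks[length(peaks)] > min_dist))
    peaks <- c(peaks, as.integer(n))
  if (length(peaks) < 2)
    stop_cdsurf("no complete compression-expansion cycle found",
                "segmentation_error")
  k <- length(peaks) - 1
  data.frame(cycle = seq_len(k), start = peaks[-length(peaks)],
             end = peaks[-1])
}

#' Per-cycle summaries
#'
#' For each segmented cycle, extracts the minimum surface tension (the
#' minimum gamma sample within the cycle), the time and area at that sample,
#' the area extremes, and the compression ratio
#' \eqn{(A_{max} - A_{min}) / A_{max}}.
#'
#' @param trace Trace data frame.
#' @param ranges Output of \code{\link{segment_cycles}}.
#' @return Data frame with one row per cycle: \code{cycle},
#'   \code{min_surface_tension}, \code{time_at_min_s}, \code{area_at_min},
#'   \code{max_area}, \code{min_area}, \code{compression_ratio}.
#' @export
summarize_cycles <- function(trace, ranges) {
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    idx <- seq.int(ranges$start[i], ranges$end[i] - 1L)
    if (length(idx) < 2)
      stop_cdsurf("cycle range with fewer than 2 samples", "empty_range_error")
    g <- trace$gamma_mN_per_m[idx]
    a <- trace$area_mm2[idx]
    j <- which.min(g)
    data.frame(cycle = ranges$cycle[i],
               min_surface_tension = g[j],
               time_at_min_s = trace$time_s[idx[j]],
               area_at_min = a[j],
               max_area = max(a), min_area = min(a),
               compression_ratio = (max(a) - min(a)) / max(a))
  })
  do.call(rbind, out)
}

#' Baseline quality control
#'
#' Applies the data-acceptance criteria over the leading baseline cycles:
#' the lowest per-cycle minimum surface tension must be strictly below the
#' baseline limit and the mean compression ratio strictly below the
#' compression limit. Values exactly at a threshold fail.
#'
#' @param summaries Output of \code{\link{summarize_cycles}}.
#' @param criteria An \code{\link{assay_criteria}} object.
#' @return List of class \code{qc_result}: \code{baseline_min_st},
#'   \code{baseline_compression}, \code{passed}, \code{reasons} (failure
#'   codes, empty when passed).
#' @export
qc_baseline <- function(summaries, criteria = assay_criteria()) {
  nb <- criteria$n_baseline_cycles
  if (nrow(summaries) < nb)
    stop_cdsurf(sprintf("need at least %d cycles for the baseline", nb),
                "insufficient_baseline_error")
  base <- summaries[seq_len(nb), ]
  bmin <- min(base$min_surface_tension)
  bcomp <- mean(base$compression_ratio)
  reasons <- character(0)
  if (!(bmin < criteria$baseline_max_st))
    reasons <- c(reasons, "baseline_min_st_not_below_limit")
  if (!(bcomp < criteria$max_compression))
    reasons <- c(reasons, "compression_not_below_limit")
  structure(list(baseline_min_st = bmin, baseline_compression = bcomp,
                 passed = length(reasons) == 0, reasons = reasons),
            class = "qc_result")
}

#' Detect inhibition of lung surfactant function
#'
#' Inhibition is called when the per-cycle minimum surface tension is at or
#' above the threshold for at least \code{run_length} consecutive cycles.
#' The onset cycle is the first cycle of the earliest qualifying run.
#'
#' @param x Either the output of \code{\link{summarize_cycles}} or a bare
#'   numeric vector of per-cycle minima (then onset time is NA).
#' @param criteria An \code{\link{assay_criteria}} object.
#' @return List of class \code{inhibition_call}: \code{inhibited},
#'   \code{onset_cycle} (NA when not inhibited), \code{onset_time_s} (time
#'   of the onset cycle's minimum-gamma sample, NA when unavailable).
#' @export
detect_inhibition <- function(x, criteria = assay_criteria()) {
  if (is.data.frame(x)) {
    minima <- x$min_surface_tension
    times <- x$time_at_min_s
  } else {
    minima <- as.numeric(x)
    times <- rep(NA_real_, length(minima))
  }
  if (length(minima) < criteria$run_length)
    stop_cdsurf(sprintf("need at least %d cycle minima", criteria$run_length),
                "insufficient_data_error")
  qual <- minima >= criteria$inhibition_st
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= criteria$run_length)
  if (length(hit) == 0) {
    call <- list(inhibited = FALSE, onset_cycle = NA_integer_,
                 onset_time_s = NA_real_)
  } else {
    oc <- starts[hit[1]]
    call <- list(inhibited = TRUE, onset_cycle = as.integer(oc),
                 onset_time_s = times[oc])
  }
  structure(call, class = "inhibition_call")
}

#' Classify a chemical from replicate inhibition calls
#'
#' Aggregates QC-passing replicates: the chemical is labeled inhibitory when
#' the fraction of inhibited replicates is at least the replicate rule
#' (default 0.5). Discordant replicate sets are flagged.
#'
#' @param calls List of \code{inhibition_call} objects (or a logical vector
#'   of inhibited flags) from QC-passing replicates.
#' @param criteria An \code{\link{assay_criteria}} object.
#' @return List of class \code{chemical_call}: \code{inhibitory},
#'   \code{n_replicates}, \code{fraction_inhibited}, \code{agreement}
#'   (fraction of replicates agreeing with the call), \code{discordant}.
#' @export
classify_chemical <- function(calls, criteria = assay_criteria()) {
  inhibited <- if (is.logical(calls)) calls
               else vapply(calls, function(cl) isTRUE(cl$inhibited), logical(1))
  n <- length(inhibited)
  if (n == 0)
    stop_cdsurf("no QC-passing replicates: no call possible", "no_call_error")
  if (n < 3 || n > 5)
    warning(sprintf("%d QC-passing replicates (expected 3 to 5)", n))
  frac <- mean(inhibited)
  inhibitory <- frac >= criteria$replicate_rule
  structure(list(inhibitory = inhibitory, n_replicates = n,
                 fraction_inhibited = frac,
                 agreement = if (inhibitory) frac else 1 - frac,
                 discordant = frac > 0 && frac < 1),
            class = "chemical_call")
}

#' Estimate the inhibitory dose
#'
#' Deposited mass per area at inhibition onset: deposition flux times time at
#' inhibition; total deposited mass follows from the average drop area. Not
#' estimable for highly volatile chemicals, whose deposited-mass measurement
#' is unreliable.
#'
#' @param deposition_flux Deposition flux measured at the drop position,
#'   ng/cm^2/min (> 0).
#' @param call An \code{inhibition_call} with \code{inhibited = TRUE}.
#' @param mean_drop_area Average area of the cycling drop, mm^2.
#' @param volatile Is the chemical highly volatile? Then the deposited-mass
#'   measurement is unreliable and no dose is estimated.
#' @return List: \code{estimable}; when estimable,
#'   \code{dose_per_area_ng_cm2} and \code{total_mass_ng}; otherwise
#'   \code{reason}.
#' @export
estimate_inhibitory_dose <- function(deposition_flux, call, mean_drop_area,
                                     volatile = FALSE) {
  if (volatile)
    return(list(estimable = FALSE,
                reason = "volatile chemical: deposited-mass measurement unreliable"))
  if (!isTRUE(call$inhibited))
    stop_cdsurf("no inhibition detected: inhibitory dose undefined",
                "no_dose_error")
  if (!is.finite(deposition_flux) || deposition_flux <= 0)
    stop_cdsurf("deposition flux must be positive", "parameter_error")
  if (!is.finite(call$onset_time_s))
    stop_cdsurf("inhibition call carries no onset time", "parameter_error")
  dose <- deposition_flux * call$onset_time_s / 60
  list(estimable = TRUE,
       dose_per_area_ng_cm2 = dose,
       total_mass_ng = dose * mean_drop_area / 100)  # mm^2 -> cm^2
}

#' Full single-trace analysis
#'
#' Convenience pipeline: segmentation, per-cycle summaries, baseline QC and
#' inhibition call for one trace.
#'
#' @param trace Trace data frame.
#' @param criteria An \code{\link{assay_criteria}} object.
#' @return List: \code{summaries}, \code{qc}, \code{call} (the inhibition
#'   call; computed regardless of QC so failed replicates remain auditable).
#' @export
analyze_trace <- function(trace, criteria = assay_criteria()) {
  ranges <- segment_cycles(trace)
  summaries <- summarize_cycles(trace, ranges)
  qc <- qc_baseline(summaries, criteria)
  call <- detect_inhibition(summaries, criteria)
  list(summaries = summaries, qc = qc, call = call)
}

#' Replicate-level bioassay evaluation of one chemical
#'
#' Analyses each replicate trace, discards replicates failing baseline QC
#' (the declared handling of unacceptable baselines), and aggregates the
#' remaining inhibition calls into the chemical-level call.
#'
#' @param traces List of replicate trace data frames.
#' @param criteria An \code{\link{assay_criteria}} object.
#' @return List: \code{call} (the \code{chemical_call}), \code{replicates}
#'   (per-replicate analyses), \code{n_qc_passed}.
#' @export
assay_chemical <- function(traces, criteria = assay_criteria()) {
  reps <- lapply(traces, analyze_trace, criteria = criteria)
  passed <- vapply(reps, function(r) r$qc$passed, logical(1))
  call <- classify_chemical(lapply(reps[passed], `[[`, "call"), criteria)
  list(call = call, replicates = reps, n_qc_passed = sum(passed))
}
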