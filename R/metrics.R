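#' Spike tables
#'
#' A spike table is the common exchange format for simulated and recorded
#' windup data: one row per action potential, with the neuron it came from,
#' the 1-based index of the stimulus it followed, and its latency from the
#' stimulation artifact in ms (>= 0 and below the protocol period).
#'
#' @param x data.frame with columns neuron_id, stim_index, latency_ms.
#' @param n_stims number of stimuli in the protocol.
#' @param period inter-stimulus interval, ms (default 1000).
#' @return the table with class \code{spike_table} and protocol metadata
#'   attached.
#' @export
as_spike_table <- function(x, n_stims, period = 1000) {
  need <- c("neuron_id", "stim_index", "latency_ms")
  if (!all(need %in% names(x)))
    stop("spike table needs columns ", paste(need, collapse = ", "))
  if (any(x$latency_ms < 0)) stop("negative latencies")
  if (any(x$latency_ms >= period)) stop("latencies must be < period")
  structure(x, class = c("spike_table", class(x)),
            n_stims = as.integer(n_stims), period = period)
}

#' Latency-window classification of spikes
#'
#' Labels every spike by the conventional post-stimulus latency windows:
#' A-beta 0-20 ms, A-delta 20-90 ms, C 90-350 ms and post-discharge
#' 350-1000 ms after the stimulation artifact; later spikes are labeled
#' "other".  Windows are half-open [lo, hi) so every latency maps to exactly
#' one class.
#'
#' @param table a \code{\link{as_spike_table}} (or plain data.frame with the
#'   same columns).
#' @return the table with an added factor column \code{window}.
#' @export
classify_spikes <- function(table) {
  if (any(table$latency_ms < 0)) stop("negative latencies")
  br <- c(0, 20, 90, 350, 1000, Inf)
  lab <- c("Abeta", "Adelta", "C", "postdischarge", "other")
  table$window <- cut(table$latency_ms, breaks = br, labels = lab,
                      right = FALSE)
  table
}

#' Latency window boundaries
#' @return data.frame with window, lo_ms, hi_ms (half-open [lo, hi)).
#' @export
latency_windows <- function() {
  data.frame(window = c("Abeta", "Adelta", "C", "postdischarge"),
             lo_ms = c(0, 20, 90, 350), hi_ms = c(20, 90, 350, 1000))
}

#' Windup curve from a labeled spike table
#'
#' Counts, for each stimulus, the spikes in the C plus post-discharge
#' windows (the windup measure); missing stimuli count zero.  The result
#' carries the first-stimulus count ("input"), the total and the area under
#' the curve as attributes.
#'
#' @param labeled output of \code{\link{classify_spikes}}.
#' @param n_stims number of stimuli (default: from table metadata).
#' @return object of class \code{windup_curve}: data.frame (stim, n_spikes)
#'   with attributes \code{input}, \code{total}, \code{auc}.
#' @export
windup_curve <- function(labeled, n_stims = attr(labeled, "n_stims")) {
  if (is.null(n_stims)) stop("n_stims not given and not in table metadata")
  keep <- labeled$window %in% c("C", "postdischarge")
  idx <- labeled$stim_index[keep]
  counts <- tabulate(idx, nbins = n_stims)
  out <- data.frame(stim = seq_len(n_stims), n_spikes = counts)
  class(out) <- c("windup_curve", "data.frame")
  attr(out, "input") <- counts[1]
  attr(out, "total") <- sum(counts)
  attr(out, "auc") <- windup_auc(counts)
  out
}

#' Area under the windup curve
#'
#' Trapezoidal area of the per-stimulus counts above the baseline, the
#' baseline being the count at the first stimulation.  By default only the
#' positive excess contributes (area above baseline, the convention of the
#' standard analysis software); \code{clip = FALSE} gives the signed area.
#'
#' @param counts per-stimulus counts, or a \code{windup_curve}.
#' @param clip clip the excess at zero before integrating?
#' @return AUC in spike x stimulus units (>= 0 when clipped).
#' @export
windup_auc <- function(counts, clip = TRUE) {
  if (inherits(counts, "windup_curve")) counts <- counts$n_spikes
  if (length(counts) < 2) stop("need at least two stimuli")
  excess <- counts - counts[1]
  if (clip) excess <- pmax(excess, 0)
  sum((excess[-1] + excess[-length(excess)]) / 2)
}

#' Percent inhibition between paired conditions
#'
#' \eqn{100 (1 - drug/control)} computed separately from the total number of
#' C + post-discharge spikes and from the windup AUC.  Zero control
#' denominators yield \code{NA} (undefined), not an error.
#'
#' @param control,drug \code{windup_curve} objects (paired conditions).
#' @return list with \code{pct_total} and \code{pct_auc} (percent).
#' @export
percent_inhibition <- function(control, drug) {
  ct <- attr(control, "total"); dt_ <- attr(drug, "total")
  ca <- attr(control, "auc"); da <- attr(drug, "auc")
  list(pct_total = if (is.null(ct) || ct <= 0) NA_real_
                   else 100 * (1 - dt_ / ct),
       pct_auc = if (is.null(ca) || ca <= 0) NA_real_
                 else 100 * (1 - da / ca))
}

#' Peristimulus time histogram
#'
#' Mean spike count per latency bin across neurons (and across the selected
#' stimuli), e.g. the mean number of APs per 20 ms at stimulus 1 versus
#' stimulus 15.
#'
#' @param table a spike table.
#' @param binwidth bin width, ms (default 20).
#' @param stims stimulus indices to pool (default: all in the table).
#' @param n_neurons number of neurons the mean is taken over (default: the
#'   number of distinct neuron_id values present).
#' @param t_max histogram extent, ms (default: the protocol period, or 1000).
#' @return object of class \code{psth}: data.frame (t_lo, t_hi, mean_count)
#'   with the binning recorded in attributes.
#' @export
psth <- function(table, binwidth = 20, stims = NULL, n_neurons = NULL,
                 t_max = NULL) {
  stopifnot(binwidth > 0)
  if (is.null(t_max)) t_max <- attr(table, "period")
  if (is.null(t_max)) t_max <- 1000
  if (is.null(stims)) stims <- sort(unique(table$stim_index))
  if (is.null(n_neurons)) n_neurons <- max(length(unique(table$neuron_id)), 1)
  sel <- table[table$stim_index %in% stims, , drop = FALSE]
  breaks <- seq(0, t_max, by = binwidth)
  if (breaks[length(breaks)] < t_max) breaks <- c(breaks, t_max)
  bin <- findInterval(sel$latency_ms, breaks, left.open = FALSE)
  bin <- bin[bin >= 1 & bin <= length(breaks) - 1]
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  denom <- n_neurons * max(length(stims), 1)
  out <- data.frame(t_lo = breaks[-length(breaks)], t_hi = breaks[-1],
                    mean_count = counts / denom)
  structure(out, class = c("psth", "data.frame"),
            binwidth = binwidth, t_max = t_max)
}

#' Root-mean-square distance between two PSTHs
#'
#' Symmetric comparison of two identically binned histograms; zero iff they
#' are identical.  Used to score a model's post-stimulus spiking profile
#' against a reference profile.
#'
#' @param model,reference \code{\link{psth}} objects with identical binning.
#' @return RMS distance (spikes per bin).
#' @export
compare_psth <- function(model, reference) {
  if (nrow(model) != nrow(reference) ||
      any(model$t_lo != reference$t_lo) ||
      any(model$t_hi != reference$t_hi))
    stop("PSTH binning mismatch")
  sqrt(mean((model$mean_count - reference$mean_count)^2))
}

#' Read / write spike tables as CSV
#'
#' Plain-CSV interchange for spike tables (columns neuron_id, stim_index,
#' latency_ms).
#'
#' @param table a spike table.
#' @param file path.
#' @param n_stims,period protocol metadata to attach on read.
#' @return \code{read_spike_table} returns a \code{spike_table};
#'   \code{write_spike_table} returns the path invisibly.
#' @export
write_spike_table <- function(table, file) {
  utils::write.csv(as.data.frame(table)[, c("neuron_id", "stim_index",
                                            "latency_ms")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(file, n_stims, period = 1000) {
  as_spike_table(utils::read.csv(file), n_stims = n_stims, period = period)
}
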