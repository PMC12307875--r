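#' Reference-normalized dF/F0 trace
#'
#' The indicator is divided by the reference channel at every timepoint
#' (cancelling shared factors such as photobleaching or focus drift), then
#' converted to a relative change from the first timepoint:
#' `R(t) = indicator(t) / reference(t)`, `dF/F0(t) = (R(t) - R(0)) / R(0)`.
#' The first value is exactly 0.
#'
#' @param pair Data frame with numeric columns `time` (strictly increasing),
#'   `indicator` and `reference` (all the same length >= 2), e.g. from
#'   [sim_calcium_traces()].
#' @return Data frame with columns `time` and `dff0`.
#' @export
dff0 <- function(pair) {
  need <- c("time", "indicator", "reference")
  miss <- setdiff(need, names(pair))
  if (length(miss))
    stop_param("pair lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(pair)
  if (n < 2) stop_param("at least 2 timepoints are required")
  if (any(diff(pair$time) <= 0))
    stop_param("time must be strictly increasing")
  bad <- which(pair$reference <= 0)
  if (length(bad))
    stop_param("reference is non-positive at timepoint ", bad[1],
               " (t = ", pair$time[bad[1]], ")")
  r <- pair$indicator / pair$reference
  if (r[1] <= 0)
    stop_param("indicator/reference ratio at time 0 is non-positive; ",
               "dF/F0 undefined")
  data.frame(time = pair$time, dff0 = (r - r[1]) / r[1])
}

#' Pointwise mean and SEM of a set of dF/F0 traces
#'
#' @param traces List of data frames with identical `time` columns and a
#'   `dff0` column ([dff0()] outputs).
#' @return Data frame: `time`, `n`, `mean_dff0`, `sem_dff0`.
#' @export
summarize_traces <- function(traces) {
  if (!is.list(traces) || length(traces) == 0)
    stop_param("traces must be a non-empty list")
  t0 <- traces[[1]]$time
  for (tr in traces)
    if (!isTRUE(all.equal(tr$time, t0)))
      stop_param("all traces must share one timebase")
  mat <- vapply(traces, function(tr) tr$dff0, numeric(length(t0)))
  mat <- matrix(mat, nrow = length(t0))
  data.frame(time = t0, n = ncol(mat),
             mean_dff0 = rowMeans(mat),
             sem_dff0 = apply(mat, 1, sem))
}

#' Fit a first-order decay rate from a dF/F0 trace
#'
#' For an efflux trace with constant reference, `1 + dF/F0 = exp(-k t)`, so
#' the rate constant is recovered as minus the slope of a log-linear
#' regression of `log(1 + dF/F0)` on time.
#'
#' @param ntrace [dff0()] output.
#' @return Estimated rate constant k (1/s).
#' @export
fit_decay_rate <- function(ntrace) {
  y <- 1 + ntrace$dff0
  ok <- y > 0
  if (sum(ok) < 2) stop_param("too few positive points to fit a decay")
  -unname(coef(lm(log(y[ok]) ~ ntrace$time[ok]))[2])
}

#' Flow-cytometry summary: MFI, dye ratio and fold change vs control
#'
#' Computes the arithmetic mean fluorescence intensity (MFI) per channel and
#' sample, the potential-to-mass ratio `MFI[ratio_channels[1]] /
#' MFI[ratio_channels[2]]` (e.g. TMRM / MitoTracker Green), and fold changes
#' of each quantity against the control-group mean (so the control-group
#' mean fold change is 1).
#'
#' @param events Data frame with columns `sample_id`, `group` and one
#'   numeric column per channel (e.g. from [sim_flow_events()]).
#' @param channels Channel columns to summarize.
#' @param ratio_channels Length-2 channel pair for the ratio (numerator,
#'   denominator); `NULL` skips the ratio.
#' @param control_group Label of the reference group.
#' @return Data frame with one row per sample: `n_events`, `mfi_<channel>`,
#'   `ratio`, and `fold_<quantity>` columns.
#' @export
flow_summary <- function(events, channels = c("TMRM", "MTG"),
                         ratio_channels = channels[1:2],
                         control_group = "control") {
  need <- c("sample_id", "group", channels)
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop_param("events lacks column(s): ", paste(miss, collapse = ", "))
  samples <- unique(events[, c("sample_id", "group")])
  out <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    sub <- events[events$sample_id == samples$sample_id[i] &
                    events$group == samples$group[i], ]
    row <- data.frame(sample_id = samples$sample_id[i],
                      group = samples$group[i], n_events = nrow(sub),
                      stringsAsFactors = FALSE)
    for (ch in channels) row[[paste0("mfi_", ch)]] <- mean(sub[[ch]])
    row
  }))
  if (!is.null(ratio_channels)) {
    num <- out[[paste0("mfi_", ratio_channels[1])]]
    den <- out[[paste0("mfi_", ratio_channels[2])]]
    out$ratio <- num / den
  }
  ctrl <- out$group == control_group
  if (!any(ctrl))
    stop_param("control group '", control_group, "' has no samples")
  for (col in c(paste0("mfi_", channels),
                if (!is.null(ratio_channels)) "ratio")) {
    out[[paste0("fold_", col)]] <- out[[col]] / mean(out[[col]][ctrl])
  }
  rownames(out) <- NULL
  out
}
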