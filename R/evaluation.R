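#' Metric configuration
#'
#' Settings of the benchmarking protocol: downsampling factor, the native
#' acquisition interval, and the Victor-Purpura move cost.
#'
#' @param bin_factor integer downsampling factor (default 4, turning the
#'   native 10 ms sampling into 40 ms bins).
#' @param native_dt native acquisition interval in seconds (default 0.010).
#' @param vp_shift_cost_per_step cost of moving a spike by one native
#'   timestep in the Victor-Purpura distance (default 1).
#' @return Object of class `metric_config`.
#' @export
metric_config <- function(bin_factor = 4L, native_dt = 0.010,
                          vp_shift_cost_per_step = 1.0) {
  stopifnot(is.numeric(bin_factor), bin_factor >= 1L,
            is.numeric(native_dt), native_dt > 0,
            is.numeric(vp_shift_cost_per_step),
            vp_shift_cost_per_step >= 0)
  structure(list(bin_factor = as.integer(bin_factor),
                 native_dt = native_dt,
                 vp_shift_cost_per_step = vp_shift_cost_per_step),
            class = "metric_config")
}

#' Downsample a signal or spike train into coarser bins
#'
#' For a [time_series()] of rates, each bin holds the rate mass
#' `sum(s * dt)` (expected spike count) over `factor` consecutive samples.
#' For a [spike_train()], each bin holds the spike count over a window of
#' `factor * native_dt` seconds. A trailing partial bin is dropped with a
#' warning.
#'
#' @param series a [time_series()] or [spike_train()].
#' @param factor integer downsampling factor (> 0).
#' @param native_dt grid interval used to size spike-train bins; defaults
#'   to the series' own `dt` for time series.
#' @return Numeric vector of per-bin mass (time series) or integer counts
#'   (spike trains).
#' @export
#' @examples
#' bin_downsample(time_series(c(1, 1, 1, 1, 2, 2, 2, 2), dt = 1), 4)
bin_downsample <- function(series, factor, native_dt = 0.010) {
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (inherits(series, "time_series")) {
    v <- series$values * series$dt
    nb <- length(v) %/% factor
    if (nb < 1L) stop("series shorter than one bin")
    if (length(v) %% factor)
      warning("dropping trailing partial bin of ",
              length(v) %% factor, " sample(s)")
    v <- v[seq_len(nb * factor)]
    return(as.numeric(colSums(matrix(v, nrow = factor))))
  }
  if (inherits(series, "spike_train")) {
    width <- factor * native_dt
    n_steps <- floor(series$duration / native_dt + 1e-9)
    nb <- n_steps %/% factor
    if (nb < 1L) stop("train duration shorter than one bin")
    if (n_steps %% factor)
      warning("dropping trailing partial bin of ",
              n_steps %% factor, " step(s)")
    return(spike_counts(series, bin_width = width, n_bins = nb))
  }
  stop("`series` must be a time_series or spike_train")
}

#' Pearson correlation between two binned signals
#'
#' Standard sample correlation (via [stats::cor()]): invariant under
#' positive affine rescaling of either argument, so normalizing rates to
#' `[0, 1]` for display never changes the score.
#'
#' @param a,b equal-length numeric vectors, each with nonzero variance and
#'   at least 2 elements.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 2L) stop("need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined metric: zero variance input")
  stats::cor(a, b)
}

#' Victor-Purpura spike-train distance
#'
#' Edit distance between two spike trains: inserting or deleting a spike
#' costs 1, moving a spike by `dt` seconds costs `q * dt` with
#' `q = vp_shift_cost_per_step / native_dt`, so a shift of one native
#' timestep costs exactly `vp_shift_cost_per_step`. Computed by the classic
#' dynamic program; symmetric, zero on identical trains, and bounded by the
#' total spike count. Lower is better.
#'
#' @param t1,t2 [spike_train()] objects (or numeric vectors of spike times).
#' @param cfg a [metric_config()].
#' @return Nonnegative distance.
#' @export
#' @examples
#' a <- spike_train(0.100, duration = 1)
#' b <- spike_train(0.110, duration = 1)
#' victor_purpura(a, b)  # one-timestep shift: distance 1
victor_purpura <- function(t1, t2, cfg = metric_config()) {
  a <- if (inherits(t1, "spike_train")) t1$times else as.numeric(t1)
  b <- if (inherits(t2, "spike_train")) t2$times else as.numeric(t2)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  q <- cfg$vp_shift_cost_per_step / cfg$native_dt
  na <- length(a); nb <- length(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  # D[i+1, j+1] = distance between a[1..i] and b[1..j]
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1L)
    cur[1L] <- i
    shift <- q * abs(a[i] - b)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1,
                         cur[j] + 1,
                         prev[j] + shift[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Convert an inferred rate trace to discrete spikes
#'
#' The Victor-Purpura distance needs discrete events. Per 40 ms bin (or
#' whatever `bin_factor` gives), the expected count `sum(s * dt)` is rounded
#' (half to even) and that many spikes are emitted at the bin center.
#'
#' @param s_hat a [time_series()] of nonnegative rates (Hz).
#' @param cfg a [metric_config()].
#' @return A [spike_train()].
#' @export
rates_to_spikes <- function(s_hat, cfg = metric_config()) {
  stopifnot(inherits(s_hat, "time_series"))
  if (any(s_hat$values < 0)) stop("`s_hat` must be nonnegative")
  mass <- bin_downsample(s_hat, cfg$bin_factor, cfg$native_dt)
  counts <- round(mass)
  width <- cfg$bin_factor * s_hat$dt
  centers <- s_hat$t0 + (seq_along(counts) - 0.5) * width
  spike_train(rep(centers, counts),
              duration = s_hat$t0 + length(s_hat$values) * s_hat$dt)
}

#' Summarize per-neuron scores by dataset
#'
#' Per-group mean, median and sample standard deviation, plus a pooled row
#' across all groups (the sigma_all convention of benchmark tables). Groups
#' of a single score report `sd = 0` and are flagged as degenerate; empty
#' groups are skipped with a warning.
#'
#' @param scores numeric vector of per-neuron scores.
#' @param group grouping labels (e.g. dataset ids), same length as
#'   `scores`.
#' @return A data.frame with columns `group`, `n`, `mean`, `median`, `sd`,
#'   `degenerate`; the final row (`group = "all"`) pools every score.
#' @export
summarize_scores <- function(scores, group) {
  stopifnot(is.numeric(scores), length(scores) == length(group))
  keep <- is.finite(scores)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " non-finite score(s)")
    scores <- scores[keep]; group <- group[keep]
  }
  if (!length(scores)) stop("no scores to summarize")
  gs <- split(scores, as.character(group))
  empty <- vapply(gs, function(v) length(v) == 0L, logical(1L))
  if (any(empty)) {
    warning("skipping empty group(s): ",
            paste(names(gs)[empty], collapse = ", "))
    gs <- gs[!empty]
  }
  row <- function(name, v) {
    data.frame(group = name, n = length(v), mean = mean(v),
               median = stats::median(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               degenerate = length(v) < 2L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(Map(row, names(gs), gs),
                          list(row("all", scores))))
  rownames(out) <- NULL
  out
}
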