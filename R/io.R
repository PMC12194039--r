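#' Read spikefinder-style recordings
#'
#' Reads a calcium CSV (columns = neurons, rows = uniformly sampled 10 ms
#' timesteps, NaN padding for unequal lengths) and, optionally, the matching
#' ground-truth spike CSV of per-timestep spike counts. A first unnamed
#' (or `"X"`) integer index column is ignored. Leading/trailing NaN padding
#' is stripped per column; interior NaNs are linearly interpolated with a
#' warning. When both files are given, each neuron's calcium and spike
#' columns are truncated to their common length with a warning.
#'
#' @param calcium_path path to the fluorescence/calcium CSV.
#' @param spikes_path optional path to the spike-count CSV.
#' @param native_dt sampling interval in seconds (default 0.010).
#' @param dataset_id label stored on each recording (defaults to the
#'   calcium file name).
#' @return A list of recordings; each is a list with `dataset_id`,
#'   `neuron_id`, `calcium` (a [time_series()]) and `spikes` (a
#'   [spike_train()] or `NULL`).
#' @export
read_recordings <- function(calcium_path, spikes_path = NULL,
                            native_dt = 0.010, dataset_id = NULL) {
  cal <- read_trace_csv(calcium_path)
  if (is.null(dataset_id)) dataset_id <- basename(calcium_path)
  spk <- if (!is.null(spikes_path)) read_trace_csv(spikes_path) else NULL
  if (!is.null(spk) && length(spk) != length(cal))
    stop("format error: calcium file has ", length(cal),
         " neuron column(s) but spike file has ", length(spk))
  lapply(seq_along(cal), function(j) {
    cv <- strip_pad(cal[[j]], calcium_path, j)
    spikes <- NULL
    if (!is.null(spk)) {
      sv <- strip_pad(spk[[j]], spikes_path, j)
      m <- min(length(cv), length(sv))
      if (length(cv) != length(sv)) {
        warning("neuron ", j, ": calcium (", length(cv),
                ") and spike (", length(sv),
                ") lengths differ; truncating to ", m)
        cv <- cv[seq_len(m)]
        sv <- sv[seq_len(m)]
      }
      counts <- round(sv)
      spikes <- spike_train(
        rep((which(counts > 0L) - 0.5) * native_dt, counts[counts > 0L]),
        duration = m * native_dt)
    }
    list(dataset_id = dataset_id, neuron_id = names(cal)[j],
         calcium = time_series(cv, dt = native_dt), spikes = spikes)
  })
}

read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!nrow(df) || !ncol(df)) stop("input error: empty file ", path)
  first <- names(df)[1L]
  if (first %in% c("", "X", "index")) {
    idx <- suppressWarnings(as.numeric(df[[1L]]))
    if (all(is.finite(idx)) && all(diff(idx) > 0)) df <- df[-1L]
  }
  if (!ncol(df)) stop("input error: no neuron columns in ", path)
  out <- lapply(seq_along(df), function(j) {
    raw <- trimws(df[[j]])
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(is.na(raw) | raw == "" |
                                toupper(raw) %in% c("NA", "NAN")))
    if (length(bad))
      stop("format error in ", path, ": non-numeric value \"",
           raw[bad[1L]], "\" at row ", bad[1L], ", column ", j)
    v
  })
  names(out) <- names(df)
  out
}

strip_pad <- function(v, path, col) {
  ok <- is.finite(v)
  if (!any(ok)) stop("input error: column ", col, " of ", path,
                     " holds no finite samples")
  v <- v[min(which(ok)):max(which(ok))]
  if (anyNA(v)) {
    warning("interior NaN(s) in column ", col, " of ", basename(path),
            "; linearly interpolating")
    idx <- seq_along(v)
    v <- stats::approx(idx[is.finite(v)], v[is.finite(v)], xout = idx,
                       rule = 2)$y
  }
  v
}

#' Write inference results and a run manifest
#'
#' Writes the inferred rates and simulated indicator traces in the same
#' column-per-neuron CSV layout the readers accept (columns NaN-padded to
#' equal length), plus a key=value run manifest recording the controller
#' and filter settings, seeds and package version — enough to re-run the
#' inference bit-identically.
#'
#' @param results list of `inference_result` objects (from
#'   [infer_rates()] / [spike_inference()]).
#' @param path output directory (created if needed).
#' @param config optional named list merged into the manifest (e.g. seed,
#'   input paths).
#' @param mpc_cfg the [mpc_config()] used (defaults recorded when omitted).
#' @param filter_cfg the [filter_config()] used.
#' @return Invisibly, the paths written (`rates`, `ci_sim`, `manifest`).
#' @export
write_results <- function(results, path, config = list(),
                          mpc_cfg = mpc_config(),
                          filter_cfg = filter_config()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pad_cbind <- function(cols) {
    n <- if (length(cols)) max(vapply(cols, length, integer(1L))) else 0L
    as.data.frame(lapply(cols, function(v) c(v, rep(NaN, n - length(v)))),
                  check.names = FALSE, optional = TRUE)
  }
  grab <- function(field) {
    cols <- lapply(results, function(r) r[[field]]$values)
    names(cols) <- if (length(results))
      as.character(seq_along(results) - 1L) else character()
    cols
  }
  rates_path <- file.path(path, "rates.csv")
  ci_path <- file.path(path, "ci_sim.csv")
  utils::write.csv(pad_cbind(grab("s_hat")), rates_path, row.names = FALSE)
  utils::write.csv(pad_cbind(grab("ci_sim")), ci_path, row.names = FALSE)
  manifest <- c(
    list(package = "spikempc",
         version = as.character(utils::packageVersion("spikempc")),
         n_neurons = length(results),
         h_used = paste(vapply(results, function(r) {
           h <- r$diagnostics$h_used
           if (is.null(h)) NA_real_ else h
         }, numeric(1L)), collapse = ",")),
    unclass(mpc_cfg)[c("n", "r", "dt", "s_min", "s_max",
                       "terminal_weight", "solver_tol", "max_iter",
                       "substeps", "discretization", "reset_state")],
    unclass(filter_cfg),
    config)
  manifest_path <- file.path(path, "manifest.txt")
  writeLines(paste0(names(manifest), "=",
                    vapply(manifest, function(v)
                      paste(format(v, digits = 17), collapse = ","),
                      character(1L))),
             manifest_path)
  invisible(list(rates = rates_path, ci_sim = ci_path,
                 manifest = manifest_path))
}

#' Write or read a key=value parameter file
#'
#' The flat parameter format exchanged between the `calibrate` and `infer`
#' command-line steps.
#'
#' @param params a [cell_params()] object.
#' @param path file path.
#' @return `write_params` invisibly returns `path`; `read_params` returns
#'   a [cell_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cell_params"))
  fp <- flatten_params(params)
  writeLines(paste0(names(fp), "=", format(unlist(fp), digits = 17)), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(p) as.numeric(trimws(p[2L])), numeric(1L)),
    vapply(kv, function(p) trimws(p[1L]), character(1L)))
  need <- c("k_f", "k_r", "L", "alpha", "gamma")
  if (!all(need %in% names(vals)))
    stop("parameter file must define: ", paste(need, collapse = ", "))
  cell_params(indicator_params(vals[["k_f"]], vals[["k_r"]], vals[["L"]]),
              alpha = vals[["alpha"]], gamma = vals[["gamma"]])
}
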