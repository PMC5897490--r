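#' Construct an episodic recording object
#'
#' @param sweeps Numeric matrix, sweeps x samples, currents in pA.
#' @param protocol A `voltage_protocol`; sweep count and sample count must
#'   match the matrix.
#' @param meta Named list of metadata (construct label, cell line, free
#'   Ca2+ in uM, cell id, seed, transfected flag, ...).
#' @return Object of class `recording` with elements `sweeps`, `time_ms`,
#'   `protocol`, `meta`.
#' @export
recording <- function(sweeps, protocol, meta = list()) {
  sweeps <- as.matrix(sweeps)
  tb <- time_base(protocol)
  if (nrow(sweeps) != protocol$n_sweeps)
    stop("sweep count (", nrow(sweeps), ") does not match protocol (",
         protocol$n_sweeps, ")")
  if (ncol(sweeps) != length(tb))
    stop("sample count (", ncol(sweeps), ") does not match protocol (",
         length(tb), ")")
  structure(list(sweeps = sweeps, time_ms = tb, protocol = protocol,
                 meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$sweeps), " sweeps x ", ncol(x$sweeps),
      " samples (", x$protocol$rate_kHz, " kHz, ", x$protocol$kind,
      " protocol)\n", sep = "")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# full-precision numeric formatting so CSV round trips are bit-exact
.fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a recording container
#'
#' The on-disk container is a directory holding `meta.json` (protocol plus
#' metadata, explicit units) and `sweeps.csv` (first column `time_ms`, one
#' column per sweep, currents in pA). Numeric values are written at full
#' precision so that `read_recording(write_recording(x))` reproduces the
#' sweep matrix bit-exactly. Readers tolerate comment lines starting with
#' `#` and trailing newlines.
#'
#' @param rec A [recording()].
#' @param path Directory to create/read.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(container = "anophys-recording", version = 1L,
               units = list(current = "pA", voltage = "mV", time = "ms"),
               protocol = unclass(rec$protocol), meta = rec$meta,
               n_sweeps = nrow(rec$sweeps), n_samples = ncol(rec$sweeps))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  m <- cbind(rec$time_ms, t(rec$sweeps))
  colnames(m) <- c("time_ms", paste0("sweep_", seq_len(nrow(rec$sweeps)) - 1))
  txt <- apply(m, 1, function(r) paste(.fmt_full(r), collapse = ","))
  writeLines(c(paste(colnames(m), collapse = ","), txt),
             file.path(path, "sweeps.csv"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "meta.json")
  sf <- file.path(path, "sweeps.csv")
  if (!file.exists(mf)) stop("container format error: missing meta.json")
  if (!file.exists(sf)) stop("container format error: missing sweeps.csv")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (fld in c("protocol", "n_sweeps", "n_samples"))
    if (is.null(meta[[fld]]))
      stop("container format error: meta.json missing field '", fld, "'")
  pr <- meta$protocol
  proto <- if (identical(pr$kind, "step")) {
    build_step_protocol(pr$holding_mV, pr$start_mV, pr$stop_mV,
                        pr$increment_mV, pr$step_ms, pr$tail_mV, pr$tail_ms,
                        pr$baseline_ms, pr$rate_kHz)
  } else if (identical(pr$kind, "tail")) {
    build_tail_protocol(pr$holding_mV, pr$prepulse_mV, pr$prepulse_ms,
                        pr$start_mV, pr$stop_mV, pr$increment_mV, pr$tail_ms,
                        pr$baseline_ms, pr$rate_kHz)
  } else stop("container format error: unknown protocol kind '", pr$kind, "'")
  tab <- utils::read.csv(sf, comment.char = "#", check.names = FALSE)
  if (ncol(tab) != meta$n_sweeps + 1)
    stop("container format error: sweeps.csv has ", ncol(tab) - 1,
         " sweep columns but meta.json declares ", meta$n_sweeps)
  if (nrow(tab) != meta$n_samples)
    stop("container format error: sweeps.csv has ", nrow(tab),
         " samples but meta.json declares ", meta$n_samples)
  rec_meta <- meta$meta
  if (is.null(rec_meta)) rec_meta <- list()
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  recording(m, proto, as.list(rec_meta))
}

#' Construct a fluorescence time-course object
#'
#' @param time_min Time points, minutes, strictly increasing.
#' @param f_raw Raw ROI-integrated fluorescence intensity, a.u.
#' @param f_background Background level, a.u. (scalar or per-sample).
#' @param meta Named metadata list (cell id, transfected flag, seed, ...).
#' @param f_norm Optional normalized fluorescence change (set by
#'   [delta_f_norm()]).
#' @return Object of class `fluor_trace`.
#' @export
fluor_trace <- function(time_min, f_raw, f_background = 0, meta = list(),
                        f_norm = NULL) {
  if (length(time_min) != length(f_raw))
    stop("time and fluorescence vectors differ in length")
  if (any(diff(time_min) <= 0)) stop("time_min must be strictly increasing")
  structure(list(time_min = time_min, f_raw = f_raw,
                 f_background = f_background, f_norm = f_norm, meta = meta),
            class = "fluor_trace")
}

#' Write / read a fluorescence trace container
#'
#' Directory with `meta.json` and `fluor.csv` (columns `time_min`, `F_raw`,
#' `F_background`).
#'
#' @param trace A [fluor_trace()].
#' @param path Directory.
#' @export
write_fluor <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(container = "anophys-fluor", version = 1L,
                            units = list(time = "min", fluorescence = "a.u."),
                            meta = trace$meta,
                            n_samples = length(trace$time_min)),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bg <- rep_len(trace$f_background, length(trace$time_min))
  txt <- paste(.fmt_full(trace$time_min), .fmt_full(trace$f_raw),
               .fmt_full(bg), sep = ",")
  writeLines(c("time_min,F_raw,F_background", txt),
             file.path(path, "fluor.csv"))
  invisible(path)
}

#' @rdname write_fluor
#' @export
read_fluor <- function(path) {
  mf <- file.path(path, "meta.json")
  ff <- file.path(path, "fluor.csv")
  if (!file.exists(mf)) stop("container format error: missing meta.json")
  if (!file.exists(ff)) stop("container format error: missing fluor.csv")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  tab <- utils::read.csv(ff, comment.char = "#")
  if (!is.null(meta$n_samples) && nrow(tab) != meta$n_samples)
    stop("container format error: fluor.csv has ", nrow(tab),
         " samples but meta.json declares ", meta$n_samples)
  m <- meta$meta
  if (is.null(m)) m <- list()
  fluor_trace(as.numeric(tab$time_min), as.numeric(tab$F_raw),
              as.numeric(tab$F_background), as.list(m))
}
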