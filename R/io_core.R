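# Domain containers and file I/O: multi-coil raw acquisitions, trigger series,
# physiological waveforms.
#
# The acquisition container is a single plain-text file: a JSON header carrying
# scalars, dimensions and coil roles, followed by named numeric blocks written
# with 17 significant digits so every stored double round-trips bit-exactly.

ACQ_MAGIC <- "haptic-acquisition-v1"

#' Construct a multi-coil raw acquisition set
#'
#' Bundles per-readout complex samples with their timing, spiral-arm angles,
#' k-space trajectory and coil roles, and validates the container invariants.
#'
#' @param samples Complex array `[n_lines, n_coils, n_samples]` of raw readout
#'   samples (hybrid k-space, one row per TR).
#' @param line_time Numeric vector of start-of-readout times in seconds,
#'   strictly increasing. Navigator sample `k` is timestamped `line_time[k]`.
#' @param arm_angle Spiral-arm starting angle per line, radians in `[0, 2*pi)`.
#' @param dwell_time Seconds per readout sample (`> 0`).
#' @param TR Repetition time in seconds (`> 0`); sets the navigator sampling
#'   period.
#' @param f_off_nominal Nominal pilot-tone offset from the imaging center
#'   frequency, Hz.
#' @param coil_role Character vector, one of `"imaging"` or `"sniffer"` per
#'   coil; at least one imaging coil is required.
#' @param trajectory Optional k-space coordinates `[n_lines, n_samples, 2]`
#'   in cycles per FOV unit.
#' @return An object of class `haptic_acq`.
#' @export
acquisition_set <- function(samples, line_time, arm_angle, dwell_time, TR,
                            f_off_nominal, coil_role, trajectory = NULL) {
  acq <- structure(list(
    samples = samples, line_time = as.numeric(line_time),
    arm_angle = as.numeric(arm_angle), dwell_time = dwell_time, TR = TR,
    f_off_nominal = f_off_nominal, coil_role = as.character(coil_role),
    trajectory = trajectory), class = "haptic_acq")
  validate_acquisitions(acq)
  acq
}

#' Validate an acquisition set against its invariants
#'
#' @param acq A `haptic_acq` object.
#' @return `acq`, invisibly, if valid; otherwise an error naming the violated
#'   invariant.
#' @export
validate_acquisitions <- function(acq) {
  if (!is.array(acq$samples) || length(dim(acq$samples)) != 3L)
    stopf("samples must be a 3-d array [n_lines x n_coils x n_samples]")
  d <- dim(acq$samples)
  if (d[1] < 1L) stopf("n_lines must be >= 1")
  if (length(acq$line_time) != d[1])
    stopf("line_time length (%d) != n_lines (%d)", length(acq$line_time), d[1])
  if (d[1] > 1L && any(diff(acq$line_time) <= 0))
    stopf("line_time must be strictly increasing")
  if (length(acq$arm_angle) != d[1])
    stopf("arm_angle length (%d) != n_lines (%d)", length(acq$arm_angle), d[1])
  if (any(acq$arm_angle < 0 | acq$arm_angle >= 2 * pi))
    stopf("arm_angle must lie in [0, 2*pi)")
  if (!is_scalar_num(acq$TR) || acq$TR <= 0) stopf("TR must be > 0")
  if (!is_scalar_num(acq$dwell_time) || acq$dwell_time <= 0)
    stopf("dwell_time must be > 0")
  if (length(acq$coil_role) != d[2])
    stopf("coil_role length (%d) != n_coils (%d)", length(acq$coil_role), d[2])
  if (!all(acq$coil_role %in% c("imaging", "sniffer")))
    stopf("coil_role entries must be 'imaging' or 'sniffer'")
  if (!any(acq$coil_role == "imaging")) stopf("at least one imaging coil required")
  if (!is.null(acq$trajectory)) {
    td <- dim(acq$trajectory)
    if (is.null(td) || length(td) != 3L || td[1] != d[1] || td[2] != d[3] ||
        td[3] != 2L)
      stopf("trajectory must have dimensions [n_lines x n_samples x 2]")
  }
  invisible(acq)
}

#' @export
print.haptic_acq <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "<haptic_acq> %d lines x %d coils (%d imaging, %d sniffer) x %d samples\n",
    d[1], d[2], sum(x$coil_role == "imaging"), sum(x$coil_role == "sniffer"),
    d[3]))
  cat(sprintf("  TR = %.4g ms, dwell = %.4g us, nominal PT offset = %.4g kHz\n",
              1e3 * x$TR, 1e6 * x$dwell_time, 1e-3 * x$f_off_nominal))
  cat(sprintf("  duration = %.3g s%s\n",
              utils::tail(x$line_time, 1) - x$line_time[1] + x$TR,
              if (is.null(x$trajectory)) ", no trajectory" else ""))
  invisible(x)
}

n_lines <- function(acq) dim(acq$samples)[1]
n_coils <- function(acq) dim(acq$samples)[2]
n_samples <- function(acq) dim(acq$samples)[3]
imaging_idx <- function(acq) which(acq$coil_role == "imaging")
sniffer_idx <- function(acq) which(acq$coil_role == "sniffer")

write_block <- function(con, name, x) {
  x <- as.numeric(x)
  writeLines(sprintf("@%s %d", name, length(x)), con)
  # chunked to keep memory bounded for large payloads
  step <- 200000L
  i <- 1L
  while (i <= length(x)) {
    j <- min(i + step - 1L, length(x))
    writeLines(paste(fmt_exact(x[i:j]), collapse = " "), con)
    i <- j + 1L
  }
}

read_block <- function(con, name, n) {
  hdr <- readLines(con, n = 1L)
  expect <- sprintf("@%s %d", name, n)
  if (!identical(hdr, expect))
    stopf("acquisition file format error: expected block '%s', found '%s'",
          expect, hdr %||% "<eof>")
  scan(con, what = double(), n = n, quiet = TRUE)
}

#' Write an acquisition set to a single-file container
#'
#' Plain-text container: a JSON header (dimensions, timing scalars, coil
#' roles) followed by numeric blocks stored at 17 significant digits, so
#' `read_acquisitions(write_acquisitions(a))` reproduces every numeric field
#' bit-for-bit.
#'
#' @param acq A validated `haptic_acq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_acquisitions <- function(acq, path) {
  validate_acquisitions(acq)
  con <- tryCatch(file(path, open = "w"), error = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  d <- dim(acq$samples)
  header <- list(n_lines = d[1], n_coils = d[2], n_samples = d[3],
                 dwell_time = acq$dwell_time, TR = acq$TR,
                 f_off_nominal = acq$f_off_nominal,
                 coil_role = acq$coil_role,
                 has_trajectory = !is.null(acq$trajectory))
  writeLines(ACQ_MAGIC, con)
  writeLines(as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                           digits = NA)), con)
  write_block(con, "line_time", acq$line_time)
  write_block(con, "arm_angle", acq$arm_angle)
  write_block(con, "samples_re", Re(acq$samples))
  write_block(con, "samples_im", Im(acq$samples))
  if (!is.null(acq$trajectory)) write_block(con, "trajectory", acq$trajectory)
  invisible(path)
}

#' Read an acquisition set from a container file
#'
#' @param path Path to a file written by [write_acquisitions()].
#' @return A validated `haptic_acq`.
#' @export
read_acquisitions <- function(path) {
  if (!file.exists(path)) stopf("acquisition file '%s' does not exist", path)
  con <- file(path, open = "r")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, ACQ_MAGIC))
    stopf("'%s' is not a %s file", path, ACQ_MAGIC)
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  for (f in c("n_lines", "n_coils", "n_samples", "dwell_time", "TR",
              "f_off_nominal", "coil_role"))
    if (is.null(header[[f]]))
      stopf("acquisition file format error: missing header field '%s'", f)
  L <- header$n_lines; C <- header$n_coils; S <- header$n_samples
  line_time <- read_block(con, "line_time", L)
  arm_angle <- read_block(con, "arm_angle", L)
  re <- read_block(con, "samples_re", L * C * S)
  im <- read_block(con, "samples_im", L * C * S)
  samples <- array(complex(real = re, imaginary = im), dim = c(L, C, S))
  trajectory <- NULL
  if (isTRUE(header$has_trajectory))
    trajectory <- array(read_block(con, "trajectory", L * S * 2), c(L, S, 2))
  acquisition_set(samples, line_time, arm_angle, header$dwell_time, header$TR,
                  header$f_off_nominal, header$coil_role, trajectory)
}

#' Construct a trigger series
#'
#' @param event_time Event times in seconds, strictly increasing,
#'   non-negative.
#' @param source One of `"PT"`, `"ECG"`, `"truth"`.
#' @return A `haptic_triggers` object.
#' @export
trigger_series <- function(event_time, source = c("PT", "ECG", "truth")) {
  source <- match.arg(source)
  event_time <- as.numeric(event_time)
  if (any(!is.finite(event_time))) stopf("trigger times must be finite")
  if (any(event_time < 0)) stopf("trigger times must be non-negative")
  if (length(event_time) > 1L && any(diff(event_time) <= 0))
    stopf("trigger times must be strictly increasing")
  structure(list(event_time = event_time, source = source),
            class = "haptic_triggers")
}

#' @export
print.haptic_triggers <- function(x, ...) {
  cat(sprintf("<haptic_triggers> %d %s events", length(x$event_time),
              x$source))
  if (length(x$event_time) > 1)
    cat(sprintf(", span %.2f s, median interval %.3f s",
                diff(range(x$event_time)), stats::median(diff(x$event_time))))
  cat("\n")
  invisible(x)
}

#' Write a trigger series as CSV
#'
#' Columns `time_s,source`; times stored at 17 significant digits.
#'
#' @param trig A `haptic_triggers` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_triggers <- function(trig, path) {
  stopifnot(inherits(trig, "haptic_triggers"))
  lines <- c("time_s,source",
             sprintf("%s,%s", fmt_exact(trig$event_time), trig$source))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trigger series from CSV
#'
#' @param path CSV with header `time_s,source`, one event per row.
#' @return A validated `haptic_triggers`.
#' @export
read_triggers <- function(path) {
  if (!file.exists(path)) stopf("trigger file '%s' does not exist", path)
  lines <- readLines(path)
  if (length(lines) < 1L || !grepl("^time_s", lines[1]))
    stopf("trigger file must start with a 'time_s,source' header")
  if (length(lines) == 1L) return(trigger_series(numeric(0), "PT"))
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  times <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1]), 0))
  bad <- which(!is.finite(times))
  if (length(bad))
    stopf("trigger file parse error: non-numeric time on line %d", bad[1] + 1L)
  src <- unique(vapply(parts, function(p) p[2] %||% "PT", ""))
  if (length(src) != 1L) stopf("trigger file mixes sources: %s",
                               paste(src, collapse = ", "))
  trigger_series(times, src)
}

#' Write navigator waveforms as CSV
#'
#' @param nav A `haptic_nav` object (see [extract_navigators()]).
#' @param path Output CSV path with columns `t,resp,card`.
#' @return `path`, invisibly.
#' @export
write_navigators <- function(nav, path) {
  stopifnot(inherits(nav, "haptic_nav"))
  lines <- c("t,resp,card",
             sprintf("%s,%s,%s", fmt_exact(nav$t), fmt_exact(nav$resp),
                     fmt_exact(nav$card)))
  writeLines(lines, path)
  invisible(path)
}

#' Read navigator waveforms from CSV
#'
#' @param path CSV written by [write_navigators()].
#' @return A `haptic_nav` object.
#' @export
read_navigators <- function(path) {
  df <- utils::read.csv(path)
  for (f in c("t", "resp", "card"))
    if (is.null(df[[f]])) stopf("navigator CSV missing column '%s'", f)
  structure(list(t = df$t, resp = df$resp, card = df$card,
                 resp_channels = NA_integer_, card_channels = NA_integer_),
            class = "haptic_nav")
}
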