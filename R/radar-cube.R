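#' Radar frame cube
#'
#' An IR-UWB radar record is a complex matrix indexed
#' `[fast_time_bin, slow_time_frame]`. Fast time is proportional to time of
#' arrival, hence to range: bin `k` (0-based) sits at range
#' `range_start + k * bin_spacing` metres, with bin 0 the direct-path
#' reference bin. Slow time is ordinary time sampled at the frame rate:
#' frame `t` (0-based) has timestamp `t0 + t / fps` seconds.
#'
#' @param frames complex matrix, fast-time bins in rows, slow-time frames in
#'   columns. At least 2 x 2; real input is promoted to complex.
#' @param fps frames per second (Hz), > 0.
#' @param range_start range of bin 0 in metres.
#' @param bin_spacing metres per fast-time bin, > 0.
#' @param t0 acquisition start time in seconds.
#' @return an object of class `radar_cube`.
#' @seealso [acquisition_config()], [write_cube()], [read_cube()]
#' @export
radar_cube <- function(frames, fps, range_start = 0.4,
                       bin_spacing = default_bin_spacing(), t0 = 0) {
  if (!is.matrix(frames)) stop("`frames` must be a matrix", call. = FALSE)
  if (is.numeric(frames)) storage.mode(frames) <- "complex"
  if (!is.complex(frames)) stop("`frames` must be numeric or complex", call. = FALSE)
  if (nrow(frames) < 2L || ncol(frames) < 2L)
    stop("`frames` needs at least 2 fast-time bins and 2 slow-time frames", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (!is.numeric(bin_spacing) || bin_spacing <= 0)
    stop("`bin_spacing` must be positive", call. = FALSE)
  structure(
    list(frames = frames, fps = as.numeric(fps),
         range_start = as.numeric(range_start),
         bin_spacing = as.numeric(bin_spacing), t0 = as.numeric(t0)),
    class = "radar_cube")
}

#' Default fast-time bin spacing
#'
#' Bin spacing implied by a 23.328 GHz fast-time sampling rate:
#' `c / (2 * 23.328e9)` metres.
#' @return bin spacing in metres (about 6.43 mm).
#' @export
default_bin_spacing <- function() 299792458 / (2 * 23.328e9)

#' Acquisition configuration
#'
#' Defaults match a seated-subject monitoring setup: 250 frames per second
#' (4 ms slow-time resolution), start range 0.4 m (the direct-path reference
#' bin), maximum range 1.5 m, 5-minute evaluation window.
#'
#' @param fps frames per second.
#' @param range_start_m start range in metres.
#' @param range_max_m maximum range in metres; must exceed `range_start_m`.
#' @param window_s evaluation window length in seconds.
#' @param bin_spacing_m metres per fast-time bin.
#' @return a list of class `acquisition_config` with an additional
#'   `frame_interval_s` field equal to `1 / fps`.
#' @export
acquisition_config <- function(fps = 250, range_start_m = 0.4,
                               range_max_m = 1.5, window_s = 300,
                               bin_spacing_m = default_bin_spacing()) {
  if (range_max_m <= range_start_m)
    stop("`range_max_m` must exceed `range_start_m`", call. = FALSE)
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  structure(
    list(fps = fps, range_start_m = range_start_m, range_max_m = range_max_m,
         window_s = window_s, bin_spacing_m = bin_spacing_m,
         frame_interval_s = 1 / fps),
    class = "acquisition_config")
}

#' @export
print.radar_cube <- function(x, ...) {
  cat(sprintf("<radar_cube> %d fast-time bins x %d frames @ %g FPS\n",
              nrow(x$frames), ncol(x$frames), x$fps))
  cat(sprintf("  range %.3f..%.3f m (%.2f mm/bin), t0 = %g s, %.1f s record\n",
              x$range_start,
              x$range_start + (nrow(x$frames) - 1L) * x$bin_spacing,
              1000 * x$bin_spacing, x$t0, ncol(x$frames) / x$fps))
  invisible(x)
}

#' Fast-time bin ranges and slow-time frame timestamps
#'
#' @param cube a [radar_cube()].
#' @return `bin_ranges()`: range in metres of each fast-time bin;
#'   `frame_times()`: timestamp in seconds of each slow-time frame.
#' @export
bin_ranges <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  cube$range_start + (seq_len(nrow(cube$frames)) - 1L) * cube$bin_spacing
}

#' @rdname bin_ranges
#' @export
frame_times <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  cube$t0 + (seq_len(ncol(cube$frames)) - 1L) / cube$fps
}

#' Cube duration in seconds
#' @param cube a [radar_cube()].
#' @return number of frames divided by `fps`.
#' @export
cube_duration <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  ncol(cube$frames) / cube$fps
}

# ---- on-disk container ------------------------------------------------------
# ".rcube" = JSON sidecar "<path>.json" + raw little-endian float64 payload,
# bin-fastest (column-major over [bin, frame]), re/im interleaved per sample.
# Doubles keep the write/read round trip bit-exact for any R complex matrix.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a radar cube
#'
#' The container is a raw binary payload (little-endian float64, interleaved
#' real/imaginary, bin index varying fastest) plus a JSON sidecar
#' `<path>.json` holding `n_bins`, `n_frames`, `fps`, `range_start`,
#' `bin_spacing`, `t0` and `frame_interval_s`. `read_cube(write_cube(x))`
#' reproduces `x` bit-exactly.
#'
#' @param cube a [radar_cube()]; non-finite amplitudes are an error.
#' @param path file path, conventionally with extension `.rcube`.
#' @return `write_cube()`: `path`, invisibly. `read_cube()`: a [radar_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "radar_cube"))
  fr <- cube$frames
  if (any(!is.finite(Re(fr))) || any(!is.finite(Im(fr))))
    stop("cube contains non-finite amplitudes", call. = FALSE)
  meta <- list(
    format = "rcube-v1", n_bins = nrow(fr), n_frames = ncol(fr),
    fps = cube$fps, range_start = cube$range_start,
    bin_spacing = cube$bin_spacing, t0 = cube$t0,
    frame_interval_s = 1 / cube$fps,
    byte_order = "little", sample_type = "float64-interleaved-reim",
    sample_order = "bin-fastest")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  v <- as.vector(t(cbind(Re(as.vector(fr)), Im(as.vector(fr)))))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(v, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar: ", sp, call. = FALSE)
  if (!file.exists(path)) stop("missing payload: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("n_bins", "n_frames", "fps", "range_start", "bin_spacing", "t0"))
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f, call. = FALSE)
  n <- meta$n_bins * meta$n_frames
  v <- readBin(path, "double", n = 2L * n, size = 8, endian = "little")
  if (length(v) != 2L * n)
    stop("payload size does not match sidecar dimensions", call. = FALSE)
  fr <- matrix(complex(real = v[seq(1L, 2L * n, by = 2L)],
                       imaginary = v[seq(2L, 2L * n, by = 2L)]),
               nrow = meta$n_bins, ncol = meta$n_frames)
  radar_cube(fr, fps = meta$fps, range_start = meta$range_start,
             bin_spacing = meta$bin_spacing, t0 = meta$t0)
}

#' Export one slow-time trace as CSV
#'
#' Debug helper: writes `t_s`, `re`, `im` for a single fast-time bin.
#'
#' @param cube a [radar_cube()].
#' @param bin 0-based fast-time bin index.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(cube, bin, path) {
  stopifnot(inherits(cube, "radar_cube"))
  if (bin < 0 || bin >= nrow(cube$frames)) stop("bin out of range", call. = FALSE)
  s <- cube$frames[bin + 1L, ]
  utils::write.csv(
    data.frame(t_s = frame_times(cube), re = Re(s), im = Im(s)),
    path, row.names = FALSE)
  invisible(path)
}
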