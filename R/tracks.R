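#' Single-cell fluorescence track
#'
#' Time series of fluorescence and centroid position for one cell on a
#' uniform sampling grid (default 15-min spacing over up to 46 h).
#'
#' @param cell_id cell identifier (string).
#' @param times sampling times in hours, strictly increasing and uniformly
#'   spaced (tolerance 1e-6 h).
#' @param fluor numeric matrix (timepoints x channels) or vector of
#'   fluorescence values (arbitrary units).
#' @param centroids two-column matrix of (x, y) centroid coordinates (um),
#'   one row per timepoint.
#' @param channel_labels character vector naming the fluorescence channels.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(cell_id, times, fluor, centroids,
                       channel_labels = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(fluor))) fluor <- matrix(as.numeric(fluor), ncol = 1L)
  fluor <- as.matrix(fluor)
  centroids <- as.matrix(centroids)
  n <- length(times)
  if (n < 1L) stop("empty track for cell ", cell_id)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing for cell ", cell_id)
  if (n > 2L) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6)
      stop("non-uniform time grid for cell ", cell_id)
  }
  if (nrow(fluor) != n || nrow(centroids) != n || ncol(centroids) != 2L)
    stop("fluor/centroids length mismatch for cell ", cell_id)
  if (any(!is.finite(fluor)))
    stop("non-finite fluorescence for cell ", cell_id)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(fluor)
    if (is.null(channel_labels))
      channel_labels <- paste0("ch", seq_len(ncol(fluor)))
  }
  colnames(fluor) <- channel_labels
  colnames(centroids) <- c("x", "y")
  structure(list(cell_id = as.character(cell_id), times = times,
                 fluor = fluor, centroids = centroids,
                 channel_labels = channel_labels),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> %s: %d timepoints, %d channel(s), t in [%g, %g] h\n",
              x$cell_id, length(x$times), ncol(x$fluor),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Collection of cell tracks sharing a time grid
#'
#' @param tracks list of [cell_track()] objects, all on the same grid, with
#'   unique cell ids.
#' @param background list of numeric vectors (background traces on the same
#'   grid), or an empty list together with `zero_background = TRUE`.
#' @param metadata named list; conventional entries: `stage` (one of
#'   "E18.5", "P1.5", "Adult", "synthetic"), `treatment`, `field` (length-4
#'   rectangle `c(xmin, xmax, ymin, ymax)` in um).
#' @param zero_background set `TRUE` to declare explicitly that no
#'   background correction is needed.
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, background = list(), metadata = list(),
                      zero_background = FALSE) {
  stopifnot(length(tracks) >= 1L)
  ids <- vapply(tracks, function(tr) tr$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell ids")
  ref <- tracks[[1]]$times
  for (tr in tracks)
    if (length(tr$times) != length(ref) || any(abs(tr$times - ref) > 1e-9))
      stop("all tracks must share one time grid (cell ", tr$cell_id, ")")
  if (length(background) == 0L && !zero_background)
    stop("need >= 1 background trace or an explicit zero_background flag")
  for (bg in background)
    if (length(bg) != length(ref)) stop("background trace off the time grid")
  structure(list(tracks = tracks, background = background,
                 metadata = metadata, times = ref),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d cells, %d timepoints, %d background trace(s)\n",
              length(x$tracks), length(x$times), length(x$background)))
  if (!is.null(x$metadata$stage)) cat("  stage:", x$metadata$stage, "\n")
  invisible(x)
}

track_ids <- function(ts) vapply(ts$tracks, function(tr) tr$cell_id, character(1))

#' Fluorescence matrix of a track set
#'
#' @param ts a [track_set()].
#' @param channel channel index or label.
#' @return numeric matrix, timepoints x cells, columns named by cell id.
#' @export
fluor_matrix <- function(ts, channel = 1L) {
  m <- vapply(ts$tracks, function(tr) tr$fluor[, channel], numeric(length(ts$times)))
  colnames(m) <- track_ids(ts)
  m
}

#' Kinetic parameters of the reporter network
#'
#' @param delta_m mRNA degradation rate (per hour).
#' @param delta_p protein degradation rate (per hour).
#' @param alpha translation rate (per mRNA per hour).
#' @param kappa fluorescence per protein molecule (a.u.).
#' @param sigma2 measurement noise variance (a.u.^2).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(delta_m = 0.7, delta_p = 0.35, alpha = 5,
                           kappa = 1, sigma2 = 25) {
  vals <- c(delta_m, delta_p, alpha, kappa, sigma2)
  if (any(!is.finite(vals)) || any(vals[1:4] <= 0) || sigma2 < 0)
    stop("kinetic parameters must be strictly positive (sigma2 >= 0)")
  structure(list(delta_m = delta_m, delta_p = delta_p, alpha = alpha,
                 kappa = kappa, sigma2 = sigma2),
            class = "kinetic_params")
}

#' Load tracks from a tidy CSV file
#'
#' Expects columns `cell_id`, `time_h`, `x_um`, `y_um` and at least one
#' fluorescence column.  Background traces carry the reserved cell-id prefix
#' `"bg_"`; their coordinates are ignored.
#'
#' @param path CSV file path (comma-separated, header row, '.' decimal).
#' @param fluor_cols names of the fluorescence column(s); default: every
#'   column not among the reserved ones.
#' @param gap_tolerance if > 0, up to this many consecutive missing
#'   fluorescence values per cell are filled by linear interpolation (and
#'   reported via a message); otherwise missing values are an error.
#' @param metadata passed to [track_set()].
#' @return A [track_set()].
#' @export
load_tracks <- function(path, fluor_cols = NULL, gap_tolerance = 0,
                        metadata = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "time_h", "x_um", "y_um")
  if (!all(req %in% names(df)))
    stop("tracks CSV must have columns ", paste(req, collapse = ", "))
  if (is.null(fluor_cols))
    fluor_cols <- setdiff(names(df), req)
  if (length(fluor_cols) < 1L) stop("no fluorescence columns found")

  if (anyDuplicated(df[, c("cell_id", "time_h")]))
    stop("duplicate (cell_id, time) rows")

  is_bg <- startsWith(df$cell_id, "bg_")
  cells <- unique(df$cell_id[!is_bg])
  bg_ids <- unique(df$cell_id[is_bg])
  grid <- sort(unique(df$time_h))

  interp_gaps <- function(v, id) {
    if (!anyNA(v)) return(v)
    runs <- rle(is.na(v))
    if (max(runs$lengths[runs$values]) > gap_tolerance || gap_tolerance <= 0)
      stop("missing fluorescence for cell ", id,
           if (gap_tolerance > 0) " (gap exceeds tolerance)" else
             " (set gap_tolerance to interpolate)")
    if (is.na(v[1]) || is.na(v[length(v)]))
      stop("missing fluorescence at track boundary for cell ", id)
    filled <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                            xout = seq_along(v))$y
    message(sum(is.na(v)), " fluorescence value(s) interpolated for cell ", id)
    filled
  }

  build <- function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    if (nrow(sub) != length(grid) || any(abs(sub$time_h - grid) > 1e-9))
      stop("ragged time grid for cell ", id)
    fl <- as.matrix(sub[, fluor_cols, drop = FALSE])
    for (j in seq_len(ncol(fl))) fl[, j] <- interp_gaps(fl[, j], id)
    cell_track(id, sub$time_h, fl, cbind(sub$x_um, sub$y_um),
               channel_labels = fluor_cols)
  }

  tracks <- lapply(cells, build)
  background <- lapply(bg_ids, function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    if (nrow(sub) != length(grid)) stop("ragged time grid for ", id)
    sub[[fluor_cols[1]]]
  })
  track_set(tracks, background, metadata = metadata,
            zero_background = length(background) == 0L)
}

#' Write a track set to a tidy CSV file
#'
#' Inverse of [load_tracks()]; a write-read round trip is lossless to
#' numerical precision.
#'
#' @param ts a [track_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  rows <- lapply(ts$tracks, function(tr) {
    data.frame(cell_id = tr$cell_id, time_h = tr$times,
               x_um = tr$centroids[, 1], y_um = tr$centroids[, 2],
               tr$fluor, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  if (length(ts$background)) {
    for (i in seq_along(ts$background)) {
      bg <- data.frame(cell_id = sprintf("bg_%03d", i), time_h = ts$times,
                       x_um = 0, y_um = 0)
      fl <- matrix(ts$background[[i]],
                   ncol = ncol(ts$tracks[[1]]$fluor),
                   nrow = length(ts$times))
      colnames(fl) <- colnames(ts$tracks[[1]]$fluor)
      df <- rbind(df, cbind(bg, fl))
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Median cell positions
#'
#' Per-cell position summarised as the componentwise median of the centroid
#' over the time course, which is robust to transient tracking excursions
#' and invariant to time reversal.
#'
#' @param ts a [track_set()].
#' @return data.frame with columns `cell_id`, `x`, `y` (um).
#' @export
median_positions <- function(ts) {
  data.frame(
    cell_id = track_ids(ts),
    x = vapply(ts$tracks, function(tr) stats::median(tr$centroids[, 1]), numeric(1)),
    y = vapply(ts$tracks, function(tr) stats::median(tr$centroids[, 2]), numeric(1)),
    stringsAsFactors = FALSE)
}
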