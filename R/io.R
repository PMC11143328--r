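#' Read a multi-page TIFF frame stack
#'
#' Loads an acquisition time series into a `rows x cols x frames` array,
#' preserving page order and stored integer values.
#'
#' @param path Path to a (multi-page) TIFF file.
#' @return Numeric array `rows x cols x frames`.
#' @export
read_stack <- function(path) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("cannot read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), d))
      stop("corrupt stack '", path, "': page ", k,
           " has a different frame shape")
  }
  array(unlist(pages), c(d[1], d[2], length(pages)))
}

#' Write a frame stack as a multi-page TIFF
#'
#' Stores non-negative integer-valued frames at the stated bit depth.
#' Reading the file back with [read_stack()] reproduces the values exactly.
#'
#' @param stack Array `rows x cols x frames` of integers in
#'   `[0, 2^bits - 1]`.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(length(dim(stack)) == 3, bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  if (any(stack < 0) || any(stack > mx) || any(stack != round(stack)))
    stop("stack values must be integers in [0, ", mx, "]")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) stack[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Build and validate a session manifest
#'
#' The manifest carries everything the pipeline needs beyond the pixels:
#' frame rate, trial boundaries (half-open frame intervals), per-trial
#' stimulus times, intensities and condition labels, the stimulation
#' modality and the genotype/regime label.
#'
#' @param frame_rate Frames per second.
#' @param trials data.frame with columns `start_frame`, `end_frame`
#'   (0-based, half-open `[start, end)`), `stim_time` (s from trial start),
#'   `stim_intensity`, and `condition` (each one of `pre`, `early_post`,
#'   `late_post`).
#' @param modality One of `"PF"`, `"tactile"`, `"CF"`, `"WM"`.
#' @param regime Free-text genotype / regime label.
#' @param pixel_size Micrometres per pixel.
#' @return A list of class `session_manifest`.
#' @export
session_manifest <- function(frame_rate, trials, modality = "PF",
                             regime = "control", pixel_size = 1) {
  need <- c("start_frame", "end_frame", "stim_time", "stim_intensity",
            "condition")
  if (!all(need %in% names(trials)))
    stop("trials must have columns: ", paste(need, collapse = ", "))
  if (any(trials$end_frame <= trials$start_frame))
    stop("trial boundaries must satisfy start < end")
  if (is.unsorted(trials$start_frame, strictly = TRUE) ||
      any(trials$start_frame[-1] < trials$end_frame[-nrow(trials)]))
    stop("trial boundaries must be ascending and non-overlapping")
  if (!all(trials$condition %in% c("pre", "early_post", "late_post")))
    stop("every trial needs a condition label in ",
         "{pre, early_post, late_post}")
  if (!modality %in% c("PF", "tactile", "CF", "WM"))
    stop("unknown modality")
  structure(list(frame_rate = frame_rate, trials = trials,
                 modality = modality, regime = regime,
                 pixel_size = pixel_size),
            class = "session_manifest")
}

#' Write a session manifest to JSON or YAML
#'
#' @param manifest A `session_manifest`.
#' @param path Output path; `.json` or `.yaml`/`.yml` selects the format.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "session_manifest"))
  obj <- unclass(manifest)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read a session manifest from JSON or YAML
#'
#' @param path Manifest path.
#' @return A validated `session_manifest`.
#' @export
read_manifest <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  session_manifest(frame_rate = obj$frame_rate,
                   trials = as.data.frame(obj$trials),
                   modality = obj$modality, regime = obj$regime,
                   pixel_size = obj$pixel_size)
}

#' Extract per-ROI fluorescence traces from a frame stack
#'
#' The raw trace of an ROI is the mean pixel value over its mask, frame by
#' frame.
#'
#' @param stack Array `rows x cols x frames`.
#' @param rois Named list of logical masks (matrices matching the frame
#'   shape), or a single integer label matrix where 0 is background and
#'   each positive label is one ROI.
#' @return Numeric matrix `frames x rois` with ROI names as column names.
#' @export
extract_roi_traces <- function(stack, rois) {
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  if (is.matrix(rois) && !is.logical(rois)) {
    labs <- sort(setdiff(unique(as.vector(rois)), 0))
    rois <- stats::setNames(lapply(labs, function(l) rois == l),
                            paste0("roi", labs))
  }
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  flat <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  traces <- vapply(names(rois), function(id) {
    mask <- rois[[id]]
    stopifnot(identical(dim(mask), d[1:2]))
    if (!any(mask)) stop("ROI '", id, "' has an empty mask")
    colMeans(flat[as.vector(mask), , drop = FALSE])
  }, numeric(d[3]))
  traces
}

#' Rasterize a polygon ROI onto the imaging grid
#'
#' Even-odd fill: a pixel belongs to the ROI when a ray from its centre
#' crosses the polygon boundary an odd number of times. Coordinates are
#' 0-based `(y, x)` with pixel centres at integer positions.
#'
#' @param vertices Two-column matrix of polygon vertices, `(y, x)`.
#' @param nrow,ncol Size of the imaging grid.
#' @return Logical mask matrix.
#' @export
rasterize_polygon <- function(vertices, nrow, ncol) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  mask <- matrix(FALSE, nrow, ncol)
  vy <- vertices[, 1]; vx <- vertices[, 2]
  nv <- length(vy)
  for (i in seq_len(nrow)) {
    py <- i - 1
    j1 <- nv
    crossings_x <- numeric(0)
    for (j in seq_len(nv)) {
      y1 <- vy[j1]; y2 <- vy[j]
      if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
        x <- vx[j1] + (py - y1) / (y2 - y1) * (vx[j] - vx[j1])
        crossings_x <- c(crossings_x, x)
      }
      j1 <- j
    }
    if (length(crossings_x)) {
      px <- seq_len(ncol) - 1
      cnt <- vapply(px, function(x) sum(crossings_x > x), numeric(1))
      mask[i, ] <- cnt %% 2 == 1
    }
  }
  mask
}

#' Export a synthetic session to disk
#'
#' Writes the per-trial dF/F traces of an `rf_session` as a tidy CSV (one
#' row per trial and frame), the trial table with its ground-truth flags as
#' a JSON manifest companion, and the ground-truth event list as JSON — the
#' on-disk mirror of a processed experimental session.
#'
#' @param session An `rf_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "rf_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- do.call(rbind, lapply(seq_along(session$traces), function(i) {
    v <- session$traces[[i]]
    data.frame(trial = i, frame = seq_along(v), dff = v)
  }))
  p1 <- file.path(dir, "traces.csv")
  utils::write.csv(traces, p1, row.names = FALSE)
  p2 <- file.path(dir, "trials.json")
  jsonlite::write_json(session$trials, p2, auto_unbox = TRUE, digits = NA)
  p3 <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(session$ground_truth, p3, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(traces = p1, trials = p2, ground_truth = p3))
}
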