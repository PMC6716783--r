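# Tabular IO: trajectory tables (including an adapter for deposited
# single-molecule coordinate tables with arbitrary column headers and
# units), plate-reader spectra and kinetic traces, and tidy result
# writing with a JSON run manifest. Dialect: comma-separated, UTF-8,
# header row, '.' decimal. Readers never silently drop rows.

#' Read a trajectory table
#'
#' Reads a CSV of tracked positions (one row per localization) and
#' splits it into per-track [Trajectory-class] objects. Because deposited
#' tables use varying headers and units, the caller supplies a column map
#' and the coordinate unit; coordinates are converted to micrometres and
#' rows sorted by frame within each track. Tracks with missing frames
#' inside their span are flagged (`gapFraction() > 0`), not interpolated.
#'
#' @param path CSV file path.
#' @param columnMap named character vector resolving the required roles,
#'   e.g. `c(id = "track_id", frame = "frame", x = "x", y = "y")`.
#' @param unit coordinate unit in the file: `"um"`, `"nm"` or `"pixel"`.
#' @param dt frame interval in seconds.
#' @param pixelSize micrometres per pixel; required when `unit = "pixel"`.
#' @return named list of [Trajectory-class], one per track id.
#' @export
readTrajectories <- function(path,
                             columnMap = c(id = "track_id",
                                           frame = "frame", x = "x",
                                           y = "y"),
                             unit = c("um", "nm", "pixel"), dt,
                             pixelSize = NULL) {
  unit <- match.arg(unit)
  .assertNumber(dt, "dt", lower = 0, closedLower = FALSE)
  if (!file.exists(path)) stop("file not found: ", path)
  needed <- c("id", "frame", "x", "y")
  if (!all(needed %in% names(columnMap)))
    stop("'columnMap' must name columns for: ",
         paste(needed, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missingCols <- setdiff(unname(columnMap[needed]), names(df))
  if (length(missingCols))
    stop("columns not found in ", path, ": ",
         paste(missingCols, collapse = ", "), "; available headers: ",
         paste(names(df), collapse = ", "))
  id <- df[[columnMap[["id"]]]]
  frame <- df[[columnMap[["frame"]]]]
  dup <- duplicated(data.frame(id, frame))
  if (any(dup))
    stop("duplicate (track, frame) pair at row ", which(dup)[1L],
         ": track '", id[which(dup)[1L]], "', frame ",
         frame[which(dup)[1L]])
  scale <- switch(unit, um = 1, nm = 1e-3, pixel = {
    if (is.null(pixelSize))
      stop("pixel-unit input requires 'pixelSize' (um per pixel)")
    .assertNumber(pixelSize, "pixelSize", lower = 0, closedLower = FALSE)
    pixelSize
  })
  x <- df[[columnMap[["x"]]]] * scale
  y <- df[[columnMap[["y"]]]] * scale
  out <- lapply(split(seq_len(nrow(df)), id), function(rows) {
    o <- rows[order(frame[rows])]
    Trajectory(cbind(x[o], y[o]), dt = dt, frames = frame[o])
  })
  out[order(names(out))]
}

#' Write trajectories to a CSV trajectory table
#'
#' Inverse of [readTrajectories()] in the package's canonical dialect
#' (`track_id`, `frame`, `x`, `y`; micrometres).
#'
#' @param trajectories named list of [Trajectory-class]; unnamed lists
#'   get sequential ids.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTrajectories <- function(trajectories, path) {
  ids <- names(trajectories)
  if (is.null(ids)) ids <- sprintf("track%04d", seq_along(trajectories))
  rows <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    cc <- coords(tr)
    data.frame(track_id = ids[i], frame = frames(tr), x = cc[, 1L],
               y = cc[, 2L])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate spectra
#'
#' Reads a CSV with columns `well`, `wavelength`, `intensity` (and an
#' optional logical `blank` column flagging blank wells) into one
#' [EmissionSpectrum-class] per well. All wells must share one wavelength
#' grid.
#'
#' @param path CSV file path.
#' @return named list of [EmissionSpectrum-class]; blank wells are named
#'   in attribute `blankWells`. An empty file yields an empty list.
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "wavelength", "intensity")
  if (!all(need %in% names(df)))
    stop("spectra file needs columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  if (nrow(df) == 0L) {
    out <- list()
    attr(out, "blankWells") <- character()
    return(out)
  }
  wells <- split(df, df$well)
  grids <- lapply(wells, function(w) sort(w$wavelength))
  if (length(unique(vapply(grids, paste, character(1L),
                           collapse = ","))) != 1L)
    stop("all wells on a plate must share one wavelength grid")
  out <- lapply(wells, function(w) {
    o <- order(w$wavelength)
    EmissionSpectrum(w$wavelength[o], w$intensity[o])
  })
  blanks <- if ("blank" %in% names(df))
    unique(df$well[as.logical(df$blank)]) else character()
  attr(out, "blankWells") <- blanks
  out
}

#' Write plate spectra
#'
#' @param spectra named list of [EmissionSpectrum-class].
#' @param path output CSV path.
#' @param blankWells wells to flag as blanks.
#' @return the path, invisibly.
#' @export
writeSpectra <- function(spectra, path, blankWells = character()) {
  rows <- do.call(rbind, lapply(names(spectra), function(wl) {
    data.frame(well = wl, wavelength = wavelengths(spectra[[wl]]),
               intensity = intensities(spectra[[wl]]),
               blank = wl %in% blankWells)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read kinetic plate traces
#'
#' Reads a CSV with columns `well`, `time_s`, `channel_nm`, `intensity`
#' into one [KineticTrace-class] per well. Times must be non-decreasing
#' within each well and channel.
#'
#' @param path CSV file path.
#' @param baselineWindow optional `c(t0, tStim)` applied to every well.
#' @return named list of [KineticTrace-class].
#' @export
readTraces <- function(path, baselineWindow = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_s", "channel_nm", "intensity")
  if (!all(need %in% names(df)))
    stop("trace file needs columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$well), function(w) {
    chans <- split(w, w$channel_nm)
    times <- unique(w$time_s)
    mat <- vapply(chans, function(ch) {
      if (any(diff(ch$time_s) < 0))
        stop("well ", w$well[1L], ": times are not non-decreasing")
      if (!isTRUE(all.equal(ch$time_s, times)))
        stop("well ", w$well[1L], ": channels must share one time grid")
      ch$intensity
    }, numeric(length(times)))
    colnames(mat) <- names(chans)
    KineticTrace(times, mat, baselineWindow = baselineWindow,
                 well = as.character(w$well[1L]))
  })
}

#' Write kinetic traces
#'
#' @param traces named list of [KineticTrace-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTraces <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    grid <- expand.grid(time_s = traceTimes(tr),
                        channel_nm = colnames(tr@channels))
    data.frame(well = tr@well, time_s = grid$time_s,
               channel_nm = grid$channel_nm,
               intensity = tr@channels[cbind(
                 match(grid$time_s, traceTimes(tr)),
                 match(grid$channel_nm, colnames(tr@channels)))])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tidy result table with a JSON run manifest
#'
#' Writes `<name>.csv` plus `<name>_manifest.json` recording the inputs
#' (with checksums), configuration, seed and package version, so a run
#' can be re-executed and compared byte for byte.
#'
#' @param results data.frame of results.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param config list echoed into the manifest.
#' @param seed seed used for stochastic stages (NA for deterministic
#'   ones).
#' @param inputs character vector of input file paths to checksum.
#' @return invisible list with the two paths.
#' @export
writeResults <- function(results, dir, name, config = list(),
                         seed = NA_integer_, inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csvPath <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(results, csvPath, row.names = FALSE, quote = FALSE)
  manifest <- list(
    name = name,
    config = config,
    seed = seed,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    package = "nanodyn",
    version = as.character(utils::packageVersion("nanodyn"))
  )
  jsonPath <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv = csvPath, manifest = jsonPath))
}
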