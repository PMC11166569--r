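#' Read and write cell-record tables
#'
#' CSV with columns `cell_id`, `treatment`, `force_nN`, `p_crit_mbar`,
#' `censored`, `seed`.
#'
#' @param records cell-record data.frame.
#' @param path file path.
#' @return `read_cell_records` returns the data.frame;
#'   `write_cell_records` returns `path` invisibly.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "treatment", "force_nN", "p_crit_mbar", "censored")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df$censored <- as.logical(df$censored)
  df
}

#' Read and write TCSPC histograms
#'
#' Decay histograms are stored as two-column CSV (`time_ns`, `counts`);
#' the IRF goes to a companion CSV on the same time grid.
#'
#' @param h a `tcspc_histogram`.
#' @param path decay CSV path.
#' @param irf_path IRF CSV path; default `<path>` with an `_irf` suffix.
#' @return `read_tcspc` returns a `tcspc_histogram`.
#' @export
write_tcspc <- function(h, path, irf_path = sub("(\\.csv)?$", "_irf.csv",
                                                path)) {
  utils::write.csv(data.frame(time_ns = h$time_ns, counts = h$counts),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(time_ns = h$time_ns, counts = h$irf),
                   irf_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tcspc
#' @export
read_tcspc <- function(path, irf_path = sub("(\\.csv)?$", "_irf.csv", path)) {
  d <- utils::read.csv(path)
  irf <- utils::read.csv(irf_path)
  structure(list(time_ns = d$time_ns, counts = d$counts, irf = irf$counts,
                 dt_ns = d$time_ns[2L] - d$time_ns[1L]),
            class = "tcspc_histogram")
}

#' Read and write image stacks as long-format CSV with a JSON sidecar
#'
#' Plain-text stand-in for multi-page TIFF: one row per voxel
#' (`frame`, `y`, `x`, `value`, `channel`), metadata (pixel size, frame
#' interval, channel names, origin) in a JSON sidecar.
#'
#' @param movie a `calcium_movie` (or any list of named `frames x ny x nx`
#'   arrays plus metadata).
#' @param path CSV path; sidecar is `<path>.json`.
#' @return `read_movie_csv` returns a `calcium_movie`-shaped list.
#' @export
write_movie_csv <- function(movie, path) {
  chans <- intersect(c("green", "red"), names(movie))
  rows <- lapply(chans, function(ch) {
    arr <- movie[[ch]]
    d <- dim(arr)
    data.frame(channel = ch,
               frame = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
               y = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
               x = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
               value = as.vector(arr))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(pixel_size_um = movie$pixel_size_um,
               frame_interval_s = movie$frame_interval_s,
               origin = movie$origin, channels = chans,
               dim = dim(movie[[chans[1L]]]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_movie_csv
#' @export
read_movie_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  out <- list(pixel_size_um = meta$pixel_size_um,
              frame_interval_s = meta$frame_interval_s,
              origin = meta$origin)
  for (ch in meta$channels) {
    sub <- df[df$channel == ch, ]
    arr <- array(0, meta$dim)
    arr[cbind(sub$frame, sub$y, sub$x)] <- sub$value
    out[[ch]] <- arr
  }
  class(out) <- "calcium_movie"
  out
}

#' Write a sigmoid fit (or list of fits) to JSON
#'
#' @param fits a `sigmoid_fit` or named list of them.
#' @param path output JSON path.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "sigmoid_fit")) fits <- list(fit = fits)
  out <- lapply(fits, function(f)
    lapply(unclass(f), function(v) if (is.infinite(v)) "Inf" else v))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write force curves
#'
#' Two-column CSV (`position_um`, `force_nN`).
#'
#' @param curve a `force_curve` data.frame.
#' @param path CSV path.
#' @export
write_force_curve <- function(curve, path) {
  utils::write.csv(curve[, c("position_um", "force_nN")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("force_curve", class(df))
  df
}

#' Serialize a membrane system to CSV + JSON
#'
#' Vertices, edges and anchors as CSV files sharing a stem, scalar
#' configuration as JSON.
#'
#' @param sys a `membrane_system`.
#' @param stem path stem; writes `<stem>_vertices.csv`, `<stem>_edges.csv`,
#'   `<stem>_meta.json`.
#' @export
write_membrane_system <- function(sys, stem) {
  utils::write.csv(data.frame(x = sys$X[, 1L], y = sys$X[, 2L],
                              z = sys$X[, 3L],
                              boundary = seq_len(nrow(sys$X)) %in% sys$boundary,
                              anchor = seq_len(nrow(sys$X)) %in% sys$anchors),
                   paste0(stem, "_vertices.csv"), row.names = FALSE)
  utils::write.csv(data.frame(v1 = sys$edges[, 1L], v2 = sys$edges[, 2L],
                              rest_len = sys$rest_len),
                   paste0(stem, "_edges.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(sys$config), paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
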