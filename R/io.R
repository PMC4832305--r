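# On-disk formats: multi-page 16-bit TIFF movies with a JSON parameter
# sidecar, ground-truth and track CSVs. Counts survive the TIFF round trip
# bit-identically (16-bit storage, integer counts).

#' Write / read a simulated movie
#'
#' The movie goes to a multi-page unsigned 16-bit TIFF (one page per frame);
#' all parameters, the seed and the photon scale go to a JSON sidecar
#' (`<path>.json`), and the ground truth to `<path>.truth.csv`.
#'
#' @param movie an `mt_movie`.
#' @param path TIFF file path.
#' @return `write_movie`: the path, invisibly. `read_movie`: an `mt_movie`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "mt_movie"))
  pages <- lapply(movie$frames, function(f) pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(cfg = flatten_cfg(movie$cfg), seed = movie$seed,
               photon_scale = movie$photon_scale, snr_first = movie$snr_first)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_truth(movie$truth, paste0(path, ".truth.csv"))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) round(p * 65535))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(mt_config, c(list(seed = meta$seed),
                              as.list(meta$cfg[setdiff(names(meta$cfg), "seed")])))
  truth_path <- paste0(path, ".truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path) else NULL
  structure(list(frames = frames, truth = truth, cfg = cfg,
                 seed = meta$seed, photon_scale = meta$photon_scale,
                 snr_first = meta$snr_first),
            class = "mt_movie")
}

flatten_cfg <- function(cfg) {
  c(unclass(cfg$lattice), unclass(cfg$growth), unclass(cfg$imaging),
    unclass(cfg$tracker), unclass(cfg$geometry))
}

#' Write / read ground truth and track tables as CSV
#'
#' Plain comma-separated files with a header row and `.` decimal marks;
#' track tables carry positions in both px and nm.
#'
#' @param truth,tracks data frames (`mt_movie$truth`, `mt_track$tracks`).
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "mt_track")) tracks <- tracks$tracks
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_tracks <- function(path) utils::read.csv(path)
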