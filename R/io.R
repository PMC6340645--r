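#' Write a video as a directory of ASCII PGM frames
#'
#' One plain-text PGM (P2) file per frame, `frame_0000.pgm` onward, with
#' intensities scaled from `[0, 1]` to 16-bit, plus a `meta.json` holding
#' the frame rate and shape.  PGM is used because it is a plain-text
#' image format with universal tooling; the frame rate travels in the
#' JSON sidecar since PGM has no rate field.
#'
#' @param video An `echo_video`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "echo_video"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  maxval <- 65535L
  for (t in seq_len(video$n_frames)) {
    img <- get_frame(video, t)
    q <- round(pmin(pmax(img, 0), 1) * maxval)
    f <- file.path(path, sprintf("frame_%04d.pgm", t - 1L))
    con <- file(f, "w")
    writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)),
                 as.character(maxval)), con)
    write(t(q), con, ncolumns = ncol(q))
    close(con)
  }
  jsonlite::write_json(
    list(fps = video$fps, n_frames = video$n_frames,
         shape = as.integer(video$shape), maxval = maxval),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop_echogate("%s: only plain (P2) PGM is supported", path)
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc)
    stop_echogate("%s: expected %d pixels, got %d", path, nr * nc, length(vals))
  matrix(vals, nr, nc, byrow = TRUE) / maxval
}

#' Read a video from a directory of PGM frames
#'
#' Frames are read in lexicographic filename order and scaled to
#' `[0, 1]`.  The frame rate comes from `meta.json` when present,
#' otherwise the `fps` argument is required.
#'
#' @param path Directory containing `*.pgm` frames (and optionally
#'   `meta.json`).
#' @param fps Frame-rate override; required when no metadata exists.
#' @return An `echo_video`.
#' @export
read_video <- function(path, fps = NULL) {
  if (!dir.exists(path)) stop_echogate("no such video directory: %s", path)
  meta_file <- file.path(path, "meta.json")
  if (is.null(fps)) {
    if (!file.exists(meta_file))
      stop_echogate("frame rate unknown: no meta.json in %s and no fps given", path)
    fps <- jsonlite::read_json(meta_file)$fps
  }
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) < 2) stop_echogate("found %d PGM frames in %s; need >= 2",
                                       length(files), path)
  frames <- lapply(files, read_pgm)
  shapes <- unique(vapply(frames, function(f) paste(dim(f), collapse = "x"),
                          character(1)))
  if (length(shapes) != 1)
    stop_echogate("inconsistent frame shapes in %s: %s", path,
                  paste(shapes, collapse = ", "))
  video_sequence(frames, fps)
}

#' Write a phase track as CSV
#'
#' Columns `frame_index` (0-based, the on-disk convention), and the
#' phases with full double precision.
#'
#' @param phases An `echo_phases`.
#' @param path Output CSV path.
#' @export
write_phases_csv <- function(phases, path) {
  stopifnot(inherits(phases, "echo_phases"))
  df <- data.frame(frame_index = seq_along(phases$cardiac_phase) - 1L,
                   cardiac_phase = sprintf("%.9f", phases$cardiac_phase),
                   resp_phase = sprintf("%.9f", phases$resp_phase))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read simulation ground truth as CSV
#'
#' `frame_index` is 0-based on disk.
#'
#' @param truth The `truth` element of [simulate_video()].
#' @param path Ground-truth CSV path.
#' @param rpeaks_path Optional path for a separate R-peak CSV
#'   (column `frame_index`, 0-based).
#' @export
write_truth_csv <- function(truth, path, rpeaks_path = NULL) {
  df <- data.frame(frame_index = seq_along(truth$cardiac_phase) - 1L,
                   cardiac_phase = sprintf("%.9f", truth$cardiac_phase),
                   resp_phase = sprintf("%.9f", truth$resp_phase))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(rpeaks_path))
    utils::write.csv(data.frame(frame_index = truth$r_peak_frames - 1L),
                     rpeaks_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @return `read_truth_csv`: list with `cardiac_phase`, `resp_phase`.
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  list(cardiac_phase = as.numeric(df$cardiac_phase),
       resp_phase = as.numeric(df$resp_phase))
}

#' Read R-peak frame annotations (CSV column `frame_index`, 0-based)
#' @param path CSV path.
#' @return 1-based integer frame indices.
#' @export
read_rpeaks_csv <- function(path) {
  as.integer(utils::read.csv(path)$frame_index) + 1L
}

#' Serialize / deserialize a gating result as JSON
#'
#' Frame indices are 0-based on disk.  The LOWESS model is stored as its
#' training pairs and parameters and refitted on load, so the round trip
#' reproduces the same predictor.
#'
#' @param gating An `echo_gating`.
#' @param path JSON path.
#' @export
gating_to_json <- function(gating, path) {
  stopifnot(inherits(gating, "echo_gating"))
  jsonlite::write_json(list(
    f_cutoff = gating$f_cutoff - 1L, f_resp = gating$f_resp - 1L,
    sigma_L = gating$sigma_L, c = gating$c, k = gating$k,
    one_sided = gating$one_sided, n_frames = gating$n_frames,
    residuals = gating$residuals,
    lowess = list(phase = gating$lowess_model$phase,
                  value = gating$lowess_model$value,
                  span = gating$lowess_model$span,
                  iters = gating$lowess_model$iters)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gating_to_json
#' @return `gating_from_json`: an `echo_gating`.
#' @export
gating_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- lowess_fit(j$lowess$phase, j$lowess$value,
                      span = j$lowess$span, iters = j$lowess$iters)
  structure(list(f_cutoff = as.integer(j$f_cutoff) + 1L,
                 f_resp = as.integer(j$f_resp) + 1L,
                 lowess_model = model, sigma_L = j$sigma_L, c = j$c, k = j$k,
                 one_sided = j$one_sided, residuals = j$residuals,
                 respiratory = sort(union(as.integer(j$f_cutoff) + 1L,
                                          as.integer(j$f_resp) + 1L)),
                 n_frames = j$n_frames),
            class = "echo_gating")
}

#' Write / read a simulation config as JSON
#' @param config A [sim_config()].
#' @param path JSON path.
#' @export
sim_config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname sim_config_to_json
#' @export
sim_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, j)
}

#' Export the selected decomposition signals as CSV
#' @param decomp An `echo_decomp`.
#' @param path CSV path (columns t, u_hat, tau_resp, r_heart; t 0-based).
#' @export
write_decomp_csv <- function(decomp, path) {
  df <- data.frame(t = seq_along(decomp$u_hat) - 1L,
                   u_hat = decomp$u_hat, tau_resp = decomp$tau_resp,
                   r_heart = decomp$r_heart)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
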