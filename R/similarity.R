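#' Normalized correlation between two frames
#'
#' Pearson correlation of the flattened pixel intensity vectors — the
#' default inter-frame similarity metric.  It is invariant to a global
#' affine intensity transform `a*I + b` with `a > 0`.
#'
#' @param frame_a,frame_b Numeric matrices of identical shape.
#' @return A similarity value in `[-1, 1]`.
#' @export
normalized_correlation <- function(frame_a, frame_b) {
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  if (!identical(dim(frame_a), dim(frame_b)))
    stop_echogate("frames have different shapes (%s vs %s)",
                  paste(dim(frame_a), collapse = "x"),
                  paste(dim(frame_b), collapse = "x"))
  a <- as.numeric(frame_a); b <- as.numeric(frame_b)
  if (stats::sd(a) == 0) stop_echogate("frame_a has zero intensity variance")
  if (stats::sd(b) == 0) stop_echogate("frame_b has zero intensity variance")
  stats::cor(a, b)
}

#' Inter-frame similarity matrix
#'
#' The N x N symmetric matrix `S` with `S[i, j]` the similarity between
#' frames `i` and `j`.  Each row of `S`, read as a time series, is a
#' univariate signal that preserves the cardiorespiratory periodicity of
#' the video; downstream stages operate on these rows.
#'
#' @param video An `echo_video`.
#' @param metric Similarity metric; only `"ncorr"` (normalized
#'   correlation) is built in, but any function `(frame_a, frame_b) ->
#'   scalar` may be supplied.
#' @return An object of class `echo_similarity`: list with `values`
#'   (N x N matrix, symmetric, unit diagonal for ncorr), `metric_name`
#'   and `fps`.
#' @export
similarity_matrix <- function(video, metric = "ncorr") {
  stopifnot(inherits(video, "echo_video"))
  n <- video$n_frames
  if (is.function(metric)) {
    S <- matrix(1, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- tryCatch(metric(get_frame(video, i), get_frame(video, j)),
                      error = function(e) stop_echogate(
                        "similarity metric failed on frame pair (%d, %d): %s",
                        i, j, conditionMessage(e)))
        S[i, j] <- s; S[j, i] <- s
      }
    }
    name <- "custom"
  } else if (identical(metric, "ncorr")) {
    X <- frame_matrix(video)
    Xc <- X - rowMeans(X)
    norms <- sqrt(rowSums(Xc^2))
    bad <- which(norms == 0)
    if (length(bad))
      stop_echogate("frame %d has zero intensity variance", bad[1])
    S <- tcrossprod(Xc / norms)
    S <- (S + t(S)) / 2                  # exact symmetry
    S[S > 1] <- 1; S[S < -1] <- -1       # clamp rounding overshoot
    diag(S) <- 1
    name <- "ncorr"
  } else {
    stop_echogate("unsupported similarity metric '%s'", as.character(metric))
  }
  structure(list(values = S, metric_name = name, fps = video$fps),
            class = "echo_similarity")
}

#' @export
print.echo_similarity <- function(x, ...) {
  cat(sprintf("<echo_similarity> %dx%d (%s), range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$metric_name,
              min(x$values), max(x$values)))
  invisible(x)
}
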