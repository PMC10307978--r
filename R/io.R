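# Artifact writers/readers: grayscale PNG for single frames, a flat
# little-endian float64 container plus JSON sidecar for sequences and
# parameter checkpoints.

#' Write a frame or scene as a grayscale PNG
#'
#' Lossless single-channel export. Values are stored as-is if inside
#' \[0, 1\], else linearly rescaled (recorded in the sidecar-free PNG as
#' a best effort; use [save_sequence()] for exact round-trips).
#'
#' @param image numeric matrix.
#' @param path output file path.
#' @export
write_frame_png <- function(image, path) {
  img <- image
  if (min(img) < 0 || max(img) > 1) img <- rescale01(img)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read a grayscale PNG frame
#' @param path PNG file path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Save a stimulus sequence
#'
#' Frames go to `<path>.bin` (concatenated column-major float64) with a
#' JSON sidecar `<path>.json` holding kind, frame shape and metadata.
#'
#' @param sequence an `stec_sequence`.
#' @param path base path (without extension).
#' @export
save_sequence <- function(sequence, path) {
  d <- dim(sequence$frames[[1]])
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (f in sequence$frames)
    writeBin(as.vector(f), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(kind = sequence$kind, n_frames = length(sequence$frames),
         rows = d[1], cols = d[2], metadata = sequence$metadata),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a stimulus sequence written by [save_sequence()]
#' @param path base path (without extension).
#' @return An `stec_sequence`.
#' @export
load_sequence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$rows * meta$cols
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  frames <- lapply(seq_len(meta$n_frames), function(i)
    matrix(readBin(con, "double", n, size = 8, endian = "little"),
           meta$rows, meta$cols))
  new_sequence(frames, meta$kind, as.list(meta$metadata))
}

param_shapes <- function(params) {
  lapply(PARAM_LEAVES, function(nm) {
    leaf <- params[[nm]]
    if (is.list(leaf)) lapply(leaf, function(m) dim(m) %||% length(m))
    else dim(leaf) %||% length(leaf)
  }) |> stats::setNames(PARAM_LEAVES)
}

#' Save a parameter checkpoint
#'
#' Weights to `<path>.bin` (float64), metadata (architecture, objective
#' preset and lambda, seed, iterations) to `<path>.json`. The loader
#' validates all matrix shapes against the recorded architecture.
#'
#' @param fit an `stec_fit` from [train_network()], or bare `stec_params`
#'   (then `meta` supplies the metadata).
#' @param path base path (without extension).
#' @param meta optional extra metadata list.
#' @export
save_params <- function(fit, path, meta = list()) {
  params <- if (inherits(fit, "stec_fit")) fit$params else fit
  check_params(params)
  if (inherits(fit, "stec_fit"))
    meta <- utils::modifyList(list(
      preset = fit$objective$preset, lambda = fit$objective$lambda,
      seed = fit$training$seed,
      iterations = fit$training$iterations * fit$training$repetitions), meta)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (nm in PARAM_LEAVES) {
    leaf <- params[[nm]]
    if (is.list(leaf)) for (m in leaf) writeBin(as.vector(m), con, size = 8,
                                               endian = "little")
    else writeBin(as.vector(leaf), con, size = 8, endian = "little")
  }
  jsonlite::write_json(c(list(sizes = params$sizes), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a parameter checkpoint written by [save_params()]
#' @param path base path (without extension).
#' @return An `stec_params` with attribute `meta`.
#' @export
load_params <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sizes <- as.integer(meta$sizes)
  template <- init_params(input_size = sizes[1], hidden = sizes[-1], seed = 0L)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  fill <- function(m) {
    v <- readBin(con, "double", length(m), size = 8, endian = "little")
    if (length(v) != length(m)) stop("checkpoint truncated", call. = FALSE)
    if (is.matrix(m)) matrix(v, nrow(m), ncol(m)) else v
  }
  for (nm in PARAM_LEAVES) {
    leaf <- template[[nm]]
    template[[nm]] <- if (is.list(leaf)) lapply(leaf, fill) else fill(leaf)
  }
  if (length(readBin(con, "double", 1, size = 8)) != 0)
    stop("checkpoint has trailing data (shape mismatch)", call. = FALSE)
  attr(template, "meta") <- meta
  template
}
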