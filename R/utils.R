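#' Run code under a fixed, restored RNG state
#'
#' All generators in the package route their randomness through this helper:
#' the global RNG state is saved, the given seed installed (Mersenne-Twister,
#' inversion normals), and the previous state restored on exit, so repeated
#' calls with the same seed are bit-identical and never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Deterministic seed fan-out
#'
#' Derives child seeds from one master seed so pipeline stages get
#' independent but reproducible streams. Kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
fanOutSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Quantise a [0, 255] intensity matrix to integer 8-bit values.
quantise8 <- function(m) {
  storage.mode(m) <- "double"
  matrix(as.integer(round(clamp(m, 0, 255))), nrow(m), ncol(m))
}

#' Write a grayscale image to TIFF or PNG
#'
#' @param pixels Integer matrix of 8-bit intensities (rows = y, cols = x).
#' @param path Output file; format chosen from the extension
#'   (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(pixels, path) {
  img <- pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read a grayscale image written by [writeGrayImage()]
#'
#' @param path TIFF or PNG file.
#' @return Integer matrix of 8-bit intensities.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
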