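# Texture feature extraction: gray-level co-occurrence matrices, the 13
# classical Haralick statistics, and patch-wise bag-of-features extraction
# mapped onto the simplex.

#' Read a grayscale image from disk
#'
#' Supports PNG and TIFF; colour images are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B). Pixel values are returned in `[0, 1]`.
#'
#' @param path image file path.
#' @return numeric matrix of pixel intensities.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' (PNG and TIFF are supported)", ext),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img
}

# Quantise an image to integer levels 0..G-1 by linear binning over the
# observed min-max range (adding a constant to the image leaves the result
# unchanged).
quantize_image <- function(image, levels) {
  image <- as.matrix(image)
  rng <- range(image)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(image), ncol(image))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantised pixel levels at a fixed spatial offset
#' `(dy, dx)` over all valid pixel pairs, optionally symmetrised by adding
#' the transpose, and normalises to a probability distribution.
#'
#' @param image numeric matrix of pixel intensities (any range; quantised
#'   internally by linear binning over the observed min-max).
#' @param levels number of gray levels `G >= 2`.
#' @param offset integer pair `(dy, dx)`.
#' @param symmetric if `TRUE` (default) count both orderings of each pair.
#' @return object of class `"glcm"`: list with `matrix` (`G x G`,
#'   sums to 1), `levels`, `offset`, `symmetric`.
#' @export
glcm <- function(image, levels = 8L, offset = c(0L, 1L), symmetric = TRUE) {
  stopifnot(levels >= 2L, length(offset) == 2L)
  q <- quantize_image(image, levels)
  nr <- nrow(q); nc <- ncol(q)
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  rows <- seq_len(nr - abs(dy))
  if (dy < 0) rows <- rows + abs(dy)
  cols <- if (dx >= 0) seq_len(nc - dx) else seq.int(1L - dx, nc)
  if (!length(rows) || !length(cols)) {
    stop("image smaller than the offset in the traversal direction", call. = FALSE)
  }
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + dy, cols + dx, drop = FALSE]
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 0:(levels - 1L)),
               factor(b, levels = 0:(levels - 1L)))
  counts <- counts + as.matrix(tab)
  if (symmetric) counts <- counts + t(counts)
  structure(list(matrix = counts / sum(counts), levels = levels,
                 offset = c(dy, dx), symmetric = symmetric),
            class = "glcm")
}

# Entropy helper, log base 2 with 0 * log 0 := 0.
h2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' The 13 classical Haralick texture statistics
#'
#' Computes, from a normalised co-occurrence matrix: angular second moment
#' (energy), contrast, correlation, variance, inverse difference moment
#' (homogeneity), sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, and the two information
#' measures of correlation. Entropies use log base 2 with `0 log 0 := 0`;
#' correlation is defined as 0 when a marginal is degenerate.
#'
#' @param g a [glcm()] object (or a plain non-negative matrix summing to 1).
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(g) {
  p <- if (inherits(g, "glcm")) g$matrix else as.matrix(g)
  G <- nrow(p)
  stopifnot(ncol(p) == G, all(p >= 0), abs(sum(p) - 1) < 1e-6)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  asm <- sum(p^2)
  contrast <- sum(p * (i - j)^2)
  correlation <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))

  # diagonal-sum and diagonal-difference marginals
  psum <- tapply(as.vector(p), as.vector(i + j), sum)          # k = 2..2G
  pdif <- tapply(as.vector(p), as.vector(abs(i - j)), sum)     # k = 0..G-1
  ks <- as.numeric(names(psum)); kd <- as.numeric(names(pdif))
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- h2(psum)
  entropy <- h2(p)
  dif_avg <- sum(kd * pdif)
  dif_var <- sum((kd - dif_avg)^2 * pdif)
  dif_ent <- h2(pdif)

  hx <- h2(px); hy <- h2(py)
  pxy <- outer(px, py)
  pos <- p > 0 & pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- h2(pxy)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))

  c(energy = asm, contrast = contrast, correlation = correlation,
    variance = variance, homogeneity = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    imc1 = imc1, imc2 = imc2)
}

#' Turn a grayscale image into a bag of simplex-valued texture descriptors
#'
#' Slides (by default non-overlapping) patches over the image; for each
#' patch computes the 13 Haralick statistics averaged over the configured
#' co-occurrence offsets, and maps the resulting descriptor onto the
#' simplex with [project_to_simplex()]. The bag is the set of per-patch
#' compositions (`D = 13`).
#'
#' @param image numeric matrix of pixel intensities, or a file path readable
#'   by [read_gray_image()].
#' @param image_id identifier for the resulting bag (defaults to the file
#'   name, or `"image"`).
#' @param patch_size square patch side in pixels.
#' @param stride step between patch origins (default `patch_size`:
#'   non-overlapping tiling).
#' @param levels gray levels for the co-occurrence matrices.
#' @param offsets list of `(dy, dx)` offsets averaged per patch.
#' @param epsilon simplex-projection constant.
#' @return a [feature_bag()].
#' @export
image_to_bag <- function(image, image_id = NULL, patch_size = 16L,
                         stride = patch_size, levels = 8L,
                         offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                         epsilon = 1e-6) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_gray_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  image <- as.matrix(image)
  if (nrow(image) < patch_size || ncol(image) < patch_size) {
    stop(sprintf("image '%s' smaller than one patch", image_id), call. = FALSE)
  }
  r0 <- seq.int(1L, nrow(image) - patch_size + 1L, by = stride)
  c0 <- seq.int(1L, ncol(image) - patch_size + 1L, by = stride)
  desc <- list()
  for (r in r0) for (cc in c0) {
    patch <- image[r:(r + patch_size - 1L), cc:(cc + patch_size - 1L)]
    feats <- rowMeans(vapply(offsets, function(off) {
      haralick_features(glcm(patch, levels = levels, offset = off))
    }, numeric(13L)))
    desc[[length(desc) + 1L]] <- feats
  }
  if (!length(desc)) stop(sprintf("no descriptors extracted from '%s'", image_id),
                          call. = FALSE)
  V <- do.call(rbind, desc)
  feature_bag(image_id, project_to_simplex(V, epsilon = epsilon))
}
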