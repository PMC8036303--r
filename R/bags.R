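#' Bags of compositional feature vectors
#'
#' A feature bag is the set of descriptor vectors extracted from one image:
#' the unit the generative kernels compare. Every vector lies on the unit
#' simplex (see [project_to_simplex()]).
#'
#' @param image_id character scalar identifying the image.
#' @param vectors `N x D` matrix of compositions, `N >= 1`.
#' @return an object of class `"feature_bag"`.
#' @export
feature_bag <- function(image_id, vectors) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 1L || ncol(vectors) < 2L) {
    stop_dim("a bag needs at least one vector of dimension D >= 2")
  }
  vectors <- as_simplex_matrix(vectors, ncol(vectors))
  vectors <- vectors / rowSums(vectors)
  structure(list(image_id = image_id, vectors = vectors), class = "feature_bag")
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("FeatureBag '%s': %d vectors of dimension %d\n",
              x$image_id, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Read / write feature bags as delimited text
#'
#' The on-disk format is a TSV (or CSV) with a header row: an `image_id`
#' column followed by `D` feature columns. Consecutive rows with the same
#' `image_id` form one bag.
#'
#' @param path file path.
#' @param sep field separator; tab by default.
#' @return `read_bags()` returns a named list of [feature_bag()] objects,
#'   in file order.
#' @export
read_bags <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"image_id" %in% names(df)) stop("missing 'image_id' column", call. = FALSE)
  ids <- as.character(df$image_id)
  M <- as.matrix(df[setdiff(names(df), "image_id")])
  storage.mode(M) <- "double"
  split_idx <- split(seq_len(nrow(M)), factor(ids, levels = unique(ids)))
  bags <- lapply(names(split_idx), function(id) {
    feature_bag(id, M[split_idx[[id]], , drop = FALSE])
  })
  names(bags) <- names(split_idx)
  bags
}

#' @rdname read_bags
#' @param bags named list of [feature_bag()] objects.
#' @export
write_bags <- function(bags, path, sep = "\t") {
  stopifnot(length(bags) >= 1L)
  D <- ncol(bags[[1]]$vectors)
  rows <- lapply(bags, function(b) {
    data.frame(image_id = b$image_id, b$vectors, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("image_id", paste0("f", seq_len(D)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write image class labels
#'
#' Labels are a two-column TSV `image_id`, `class` with a header row.
#'
#' @param path file path.
#' @return named character vector of class labels, names are image ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df$class), as.character(df$image_id))
}

#' @rdname read_labels
#' @param labels named character vector (names = image ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(image_id = names(labels), class = unname(labels)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an SSD mixture to JSON
#'
#' Schema: `{dim, weights, components: [{alpha, beta, b}, ...]}`.
#'
#' @param model an [ssd_mixture()].
#' @param path output file.
#' @export
write_ssd_model <- function(model, path) {
  stopifnot(inherits(model, "ssd_mixture"))
  obj <- list(
    dim = model$dim,
    weights = model$weights,
    components = lapply(model$components, function(th) {
      list(alpha = th$alpha, beta = th$beta, b = th$b)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ssd_model
#' @export
read_ssd_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- obj$components
  if (is.data.frame(comps)) {
    comps <- lapply(seq_len(nrow(comps)), function(i) as.list(comps[i, ]))
  }
  components <- lapply(comps, function(cm) {
    ssd_params(alpha = unlist(cm$alpha), beta = unlist(cm$beta), b = cm$b)
  })
  ssd_mixture(weights = unlist(obj$weights), components = components)
}
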