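#' Cortical map
#'
#' Per-vertex scalar values on the source space: either a non-negative
#' activation map or a binary map (the irritative zone and the resection mask
#' are binary maps). Vertex coordinates are shared with the forward model
#' that produced the map.
#'
#' @param values numeric vector, one value per vertex.
#' @param vertex_coords `n_vertices x 3` coordinate matrix, millimetres.
#' @param kind `"activation"` (values `>= 0`) or `"binary"` (values in
#'   `{0, 1}`).
#' @return An object of class `"cortical_map"`.
#' @export
cortical_map <- function(values, vertex_coords, kind = c("activation", "binary")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  vertex_coords <- as.matrix(vertex_coords)
  if (length(values) != nrow(vertex_coords)) {
    abort("values must have one entry per vertex")
  }
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    abort("binary maps may contain only 0/1")
  }
  if (kind == "activation" && any(values < 0)) {
    abort("activation maps must be non-negative")
  }
  structure(list(values = values, vertex_coords = vertex_coords, kind = kind),
            class = "cortical_map")
}

#' @export
print.cortical_map <- function(x, ...) {
  cat(sprintf("<cortical_map: %s> %d vertices, %d active\n",
              x$kind, length(x$values), sum(x$values > 0)))
  invisible(x)
}

#' Binarize an activation map at a fraction of its maximum
#'
#' Vertices at or above `frac * max(values)` become 1. The result is
#' invariant to positive rescaling of the activation.
#'
#' @param map an activation [cortical_map()].
#' @param frac threshold fraction of the maximum (default 0.5).
#' @return A binary [cortical_map()].
#' @export
binarize_map <- function(map, frac = 0.5) {
  stopifnot(inherits(map, "cortical_map"))
  mx <- max(map$values)
  if (mx <= 0) abort("cannot binarize an all-zero activation map")
  cortical_map(as.numeric(map$values >= frac * mx), map$vertex_coords, "binary")
}

# indices of vertices within radius_mm of any of the given coordinates
vertices_within <- function(vertex_coords, centers, radius_mm) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
  hits <- rep(FALSE, nrow(vertex_coords))
  for (i in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(vertex_coords, 2L, centers[i, ])^2)
    hits <- hits | d2 <= radius_mm^2
  }
  which(hits)
}

# binary dilation by Euclidean radius on the vertex cloud
smooth_binary_map <- function(map, radius_mm) {
  act <- which(map$values > 0)
  if (!length(act)) return(map)
  idx <- vertices_within(map$vertex_coords, map$vertex_coords[act, , drop = FALSE],
                         radius_mm)
  vals <- numeric(length(map$values))
  vals[idx] <- 1
  cortical_map(vals, map$vertex_coords, "binary")
}

#' Write / read a cortical map as JSON
#'
#' Full-precision JSON holding values, coordinates and the map kind, so the
#' round trip is lossless.
#'
#' @param map a [cortical_map()].
#' @param path file path (`.json`).
#' @export
write_cortical_map <- function(map, path) {
  jsonlite::write_json(
    list(kind = map$kind, values = map$values,
         vertex_coords = map$vertex_coords),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cortical_map
#' @export
read_cortical_map <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cortical_map(m$values, m$vertex_coords, m$kind)
}
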