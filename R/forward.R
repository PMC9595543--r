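#' Forward model (leadfield plus source space)
#'
#' A leadfield matrix mapping cortical sources to sensors, together with the
#' source-space vertex coordinates. With free orientations
#' (`n_orient = 3`) the leadfield has three consecutive columns per vertex.
#' Coordinates are millimetres in a single head-coordinate frame; every
#' distance used by the pipeline (resection margin, smoothing radius, hull
#' distance) is Euclidean in this frame.
#'
#' @param leadfield numeric matrix, `n_channels x (n_vertices * n_orient)`.
#' @param vertex_coords numeric matrix, `n_vertices x 3`, millimetres.
#' @param n_orient 1 (fixed orientation) or 3 (free).
#' @param channel_names optional channel names aligned with a recording.
#' @return An object of class `"forward_model"`.
#' @export
forward_model <- function(leadfield, vertex_coords, n_orient = 1,
                          channel_names = NULL) {
  leadfield <- as.matrix(leadfield)
  vertex_coords <- as.matrix(vertex_coords)
  if (!n_orient %in% c(1, 3)) abort("n_orient must be 1 or 3")
  if (ncol(vertex_coords) != 3L) abort("vertex_coords must be n x 3")
  if (ncol(leadfield) != nrow(vertex_coords) * n_orient) {
    abort("leadfield column count must equal n_vertices * n_orient")
  }
  if (!all(is.finite(vertex_coords)) || !all(is.finite(leadfield))) {
    abort("leadfield and vertex_coords must be finite")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("CH%03d", seq_len(nrow(leadfield)))
  }
  structure(
    list(leadfield = leadfield, vertex_coords = vertex_coords,
         n_orient = as.integer(n_orient),
         channel_names = as.character(channel_names)),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d channels, %d vertices, n_orient=%d\n",
              nrow(x$leadfield), nrow(x$vertex_coords), x$n_orient))
  invisible(x)
}

n_vertices <- function(fwd) nrow(fwd$vertex_coords)

# leadfield columns of one vertex (matrix n_channels x n_orient)
vertex_leadfield <- function(fwd, j) {
  idx <- ((j - 1L) * fwd$n_orient + 1L):(j * fwd$n_orient)
  fwd$leadfield[, idx, drop = FALSE]
}

#' Write / read a forward model (TSV + JSON manifest)
#'
#' @param fwd a [forward_model()].
#' @param path path prefix (no extension).
#' @export
write_forward <- function(fwd, path) {
  data.table::fwrite(data.table::as.data.table(fwd$leadfield),
                     paste0(path, "_leadfield.tsv"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(fwd$vertex_coords),
                     paste0(path, "_vertices.tsv"), sep = "\t",
                     col.names = FALSE)
  jsonlite::write_json(
    list(leadfield_file = paste0(basename(path), "_leadfield.tsv"),
         vertices_file = paste0(basename(path), "_vertices.tsv"),
         n_orient = fwd$n_orient, channel_names = fwd$channel_names),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forward
#' @export
read_forward <- function(path) {
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lf <- as.matrix(data.table::fread(
    file.path(dirname(path), m$leadfield_file), sep = "\t", header = FALSE))
  vc <- as.matrix(data.table::fread(
    file.path(dirname(path), m$vertices_file), sep = "\t", header = FALSE))
  dimnames(lf) <- dimnames(vc) <- NULL
  forward_model(lf, vc, m$n_orient, m$channel_names)
}
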