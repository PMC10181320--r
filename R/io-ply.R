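# PLY interchange for visualisation tools. Coordinates are stored as float32
# (hence round-trips are exact only to single precision); labels, when
# present, as an int32 vertex property named "label". The writer emits
# binary_little_endian; the reader also accepts ascii.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Export a point cloud to PLY
#'
#' @param cloud a `point_cloud`.
#' @param path output file; binary little-endian PLY with float32 vertex
#'   coordinates and, when labels are present, an int32 `label` property.
#' @export
export_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$coords)
  has_lab <- !is.null(cloud$labels)
  header <- c(
    "ply",
    "format binary_little_endian 1.0",
    "comment written by ffnet",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_lab) "property int label",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  co <- t(cloud$coords)                       # xyz interleaved per vertex
  if (has_lab) {
    # mixed float/int records: build the raw stream per vertex
    fl <- writeBin(as.numeric(co), raw(), size = 4L, endian = "little")
    lb <- writeBin(as.integer(cloud$labels), raw(), size = 4L, endian = "little")
    rec <- raw(16L * n)
    pos <- rep((seq_len(n) - 1L) * 16L, each = 12L)
    rec[pos + rep(1:12, n)] <- fl
    posl <- rep((seq_len(n) - 1L) * 16L, each = 4L)
    rec[posl + rep(13:16, n)] <- lb
    writeBin(rec, con)
  } else {
    writeBin(as.numeric(co), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Import a point cloud from PLY
#'
#' Accepts ascii and binary_little_endian PLY with a vertex element holding
#' numeric `x`, `y`, `z` properties and an optional integer `label` property.
#'
#' @param path PLY file.
#' @param plant_id,day metadata for the returned cloud.
#' @return a `point_cloud`; labels are absent when the file has no `label`
#'   property.
#' @export
import_ply <- function(path, plant_id = NULL, day = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L, warn = FALSE)
  if (length(first) == 0L || trimws(first) != "ply")
    stop("not a PLY file (missing 'ply' magic): ", path)
  fmt <- NULL; n_vertex <- NULL
  props <- character(); prop_types <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unterminated PLY header in ", path)
    tk <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (tk[1L] == "format") {
      fmt <- tk[2L]
    } else if (tk[1L] == "element") {
      in_vertex <- identical(tk[2L], "vertex")
      if (in_vertex) n_vertex <- as.integer(tk[3L])
    } else if (tk[1L] == "property" && in_vertex) {
      if (tk[2L] == "list") stop("list properties on vertices are unsupported")
      prop_types <- c(prop_types, tk[2L])
      props <- c(props, tk[3L])
    } else if (tk[1L] == "end_header") break
  }
  if (is.null(n_vertex)) stop("PLY file has no vertex element: ", path)
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n_vertex * length(props),
                 quiet = TRUE)
    m <- matrix(vals, ncol = length(props), byrow = TRUE)
  } else {
    sizes <- ply_type_size[prop_types]
    if (anyNA(sizes)) stop("unknown PLY property type")
    stride <- sum(sizes)
    blob <- readBin(con, raw(), n = n_vertex * stride)
    if (length(blob) < n_vertex * stride) stop("truncated PLY payload: ", path)
    offs <- c(0L, cumsum(sizes))[seq_along(props)]
    m <- matrix(0, n_vertex, length(props))
    for (j in seq_along(props)) {
      sel <- rep((seq_len(n_vertex) - 1L) * stride + offs[j], each = sizes[j]) +
        rep(seq_len(sizes[j]), n_vertex)
      tp <- prop_types[j]
      what <- if (tp %in% c("float", "float32", "double", "float64")) numeric()
              else integer()
      m[, j] <- readBin(blob[sel], what, n = n_vertex, size = sizes[j],
                        endian = "little",
                        signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }
  coords <- m[, match(c("x", "y", "z"), props), drop = FALSE]
  labels <- if ("label" %in% props) as.integer(m[, match("label", props)])
            else NULL
  if (is.null(plant_id))
    plant_id <- tools::file_path_sans_ext(basename(path))
  point_cloud(coords, labels,
              if (!is.null(labels) && all(labels <= 2L)) semantic_classes(),
              plant_id, day, path)
}
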