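# HDF5 bundle layout: one group per cloud under /clouds, keyed
# "<plant>_day<day>", holding `coords` (N x 3 double, bit-exact round-trip)
# and optionally `labels` (N int). Root-level datasets `split_plant` /
# `split_subset` carry the plant-level train/test table; `provenance` and
# `class_names` are stored alongside.

#' Write a dataset bundle to an HDF5 file
#'
#' @param bundle a `dataset_bundle`.
#' @param path output `.h5` file (overwritten if present).
#' @export
write_bundle_hdf <- function(bundle, path) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "clouds")
  for (cl in bundle$clouds) {
    key <- sprintf("clouds/%s_day%d", cl$plant_id, cl$day)
    rhdf5::h5createGroup(path, key)
    rhdf5::h5write(cl$coords, path, paste0(key, "/coords"))
    if (!is.null(cl$labels))
      rhdf5::h5write(as.integer(cl$labels), path, paste0(key, "/labels"))
    rhdf5::h5write(cl$plant_id, path, paste0(key, "/plant_id"))
    rhdf5::h5write(as.integer(cl$day), path, paste0(key, "/day"))
    rhdf5::h5write(as.character(cl$source), path, paste0(key, "/source"))
    rhdf5::h5write(if (is.null(cl$class_names)) character(0) else cl$class_names,
                   path, paste0(key, "/class_names"))
  }
  rhdf5::h5write(names(bundle$split), path, "split_plant")
  rhdf5::h5write(unname(bundle$split), path, "split_subset")
  rhdf5::h5write(as.character(bundle$provenance), path, "provenance")
  invisible(path)
}

#' Read a dataset bundle from an HDF5 file
#'
#' @param path a bundle written by [write_bundle_hdf()].
#' @return a `dataset_bundle`; coordinates round-trip bit-exactly.
#' @export
read_bundle_hdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  top <- ls$name[ls$group == "/"]
  for (req in c("clouds", "split_plant", "split_subset"))
    if (!req %in% top)
      stop("malformed bundle file (missing '", req, "'): ", path)
  keys <- sort(ls$name[ls$group == "/clouds"])
  clouds <- lapply(keys, function(key) {
    members <- ls$name[ls$group == paste0("/clouds/", key)]
    for (req in c("coords", "plant_id", "day"))
      if (!req %in% members)
        stop("malformed bundle file (missing 'clouds/", key, "/", req, "')")
    rd <- function(nm) rhdf5::h5read(path, sprintf("clouds/%s/%s", key, nm))
    coords <- as.matrix(rd("coords"))
    labels <- if ("labels" %in% members) as.integer(rd("labels")) else NULL
    cn <- if ("class_names" %in% members) as.character(rd("class_names"))
          else character(0)
    point_cloud(coords, labels, if (length(cn) > 0L) cn else NULL,
                as.character(rd("plant_id")), as.integer(rd("day")),
                if ("source" %in% members) as.character(rd("source")) else "")
  })
  split <- stats::setNames(as.character(rhdf5::h5read(path, "split_subset")),
                           as.character(rhdf5::h5read(path, "split_plant")))
  prov <- if ("provenance" %in% top)
    as.character(rhdf5::h5read(path, "provenance")) else ""
  dataset_bundle(clouds, split, prov)
}
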