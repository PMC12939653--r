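# Persistence of toolkit artifacts in portable text/standard formats:
# images to NIfTI, graphs to GraphML, diagrams/masks/logs to CSV, configs
# and reports to JSON.

#' Write an image volume to NIfTI
#'
#' @param img an [image_volume()] (magnitude written for complex values).
#' @param path output file path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(img, path) {
  arr <- Mod(img$values)
  nif <- RNifti::asNifti(arr, pixdim = c(img$voxel_size_mm, img$voxel_size_mm))
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Write a vascular graph to GraphML
#'
#' Edge attributes `length_mm`, `diameter_mm`, `confidence`, `conductance`
#' and node attributes `x_mm`, `y_mm`, `kind` are preserved.
#'
#' @param g a [vascular_graph()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graph_graphml <- function(g, path) {
  ig <- igraph::graph_from_data_frame(
    d = g$edges, directed = FALSE,
    vertices = data.frame(name = g$nodes$id, x_mm = g$nodes$x_mm,
                          y_mm = g$nodes$y_mm, kind = g$nodes$kind))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a vascular graph from GraphML
#'
#' @param path GraphML file written by [write_graph_graphml()].
#' @return a [vascular_graph()] (without centerline polylines).
#' @export
read_graph_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr(ig)
  eat <- igraph::edge_attr(ig)
  el <- igraph::as_edgelist(ig, names = TRUE)
  nodes <- data.frame(id = as.integer(vat$name), x_mm = vat$x_mm,
                      y_mm = vat$y_mm, kind = vat$kind)
  edges <- data.frame(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                      length_mm = eat$length_mm, diameter_mm = eat$diameter_mm,
                      confidence = eat$confidence, conductance = eat$conductance)
  vascular_graph(nodes, edges)
}

#' Write persistence diagrams to CSV
#'
#' Columns: `dim`, `birth`, `death`, `essential` (death is empty for
#' essential classes).
#'
#' @param diagrams list with elements `dim0`, `dim1`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_diagram_csv <- function(diagrams, path) {
  rows <- lapply(diagrams, function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(dim = attr(d, "homdim"), birth = d$birth,
               death = ifelse(d$essential, NA_real_, d$death),
               essential = d$essential)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(dim = integer(), birth = numeric(),
                      death = numeric(), essential = logical())
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read persistence diagrams from CSV
#'
#' @param path CSV written by [write_diagram_csv()].
#' @return list with `dim0` and `dim1` [persistence_diagram()] objects.
#' @export
read_diagram_csv <- function(path) {
  tab <- utils::read.csv(path)
  mk <- function(dd, dim) {
    sub <- tab[tab$dim == dim, , drop = FALSE]
    persistence_diagram(sub$birth,
                        ifelse(sub$essential, -Inf, sub$death), dim = dim)
  }
  list(dim0 = mk(tab, 0), dim1 = mk(tab, 1))
}

#' Write a sampling mask to CSV
#'
#' Long format (`row`, `col`) of sampled locations with a JSON-encoded
#' header comment carrying acceleration and center-band metadata.
#'
#' @param mask a [sampling_mask()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  idx <- which(mask$mask, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- jsonlite::toJSON(list(shape = dim(mask$mask),
                                acceleration = mask$acceleration,
                                center_fraction = mask$center_fraction,
                                seed = mask$seed), auto_unbox = TRUE)
  writeLines(paste0("# ", meta), con)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2]), con,
                   row.names = FALSE)
  invisible(path)
}

#' Read a sampling mask from CSV
#'
#' @param path CSV written by [write_mask_csv()].
#' @return a [sampling_mask()].
#' @export
read_mask_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^# ", "", hdr))
  tab <- utils::read.csv(path, comment.char = "#")
  m <- matrix(FALSE, meta$shape[1], meta$shape[2])
  m[cbind(tab$row, tab$col)] <- TRUE
  sampling_mask(m, meta$center_fraction,
                if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write sensor streams to CSV with a JSON sidecar
#'
#' @param streams list of `sensor_stream` objects.
#' @param dir output directory (created if missing).
#' @return vector of written file paths, invisibly.
#' @export
write_streams_csv <- function(streams, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(streams, function(s) {
    p <- file.path(dir, paste0("stream_", s$channel, ".csv"))
    utils::write.csv(data.frame(timestamp_s = s$t, value = s$values), p,
                     row.names = FALSE)
    side <- file.path(dir, paste0("stream_", s$channel, ".json"))
    jsonlite::write_json(list(channel = s$channel, rate_hz = s$rate_hz,
                              noise_sd = s$noise_sd), side, auto_unbox = TRUE)
    p
  }, "")
  invisible(paths)
}

#' Write an experiment report to JSON
#'
#' @param report named list (data.frames are converted to row lists).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
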