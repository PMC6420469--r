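#' Read / write a per-vertex map as CSV
#'
#' Columns `vertex_id` (0-based) and `value`.
#'
#' @param path file path.
#' @return numeric per-vertex vector.
#' @export
read_map_csv <- function(path) {
  d <- utils::read.csv(path)
  d <- d[order(d$vertex_id), ]
  d$value
}

#' @param values numeric per-vertex vector.
#' @rdname read_map_csv
#' @export
write_map_csv <- function(values, path) {
  utils::write.csv(data.frame(vertex_id = seq_along(values) - 1L,
                              value = as.numeric(values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a one-column framewise-displacement CSV
#' @param path file with a single column `fd_mm` (header optional).
#' @return numeric FD vector.
#' @export
read_fd_csv <- function(path) {
  d <- utils::read.csv(path)
  as.numeric(d[[1]])
}

#' Read / write a time-series matrix as CSV
#'
#' Vertices as rows, timepoints as columns, no header/rownames.
#'
#' @param path file path.
#' @return numeric matrix vertices x timepoints.
#' @export
read_timeseries_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @param ts numeric matrix.
#' @rdname read_timeseries_csv
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.table(ts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records what a pipeline run did: the command label, the parameter/config
#' snapshot, the seed, md5 checksums of input files, package version and a
#' timestamp, so deterministic outputs can be reproduced bit-identically.
#'
#' @param path output JSON path.
#' @param command short label of the run.
#' @param params named list of parameters.
#' @param seed integer seed of the run (NULL if deterministic).
#' @param inputs character vector of input file paths to checksum.
#' @param extra named list of additional fields (e.g. skip counts).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, command, params = list(), seed = NULL,
                           inputs = character(0), extra = list()) {
  checks <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(command = command,
                     params = params,
                     seed = seed,
                     input_md5 = checks,
                     package_version =
                       as.character(utils::packageVersion("geograd")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        "%Y-%m-%dT%H:%M:%SZ")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# ---- GIFTI ------------------------------------------------------------
# Minimal GIFTI (.gii) support: enough to exchange surfaces, label maps and
# per-vertex metrics with standard neuroimaging tools. Reads ASCII,
# Base64Binary and GZipBase64Binary encodings; writes ASCII. Only the
# little-endian byte order produced by the common tools is handled.

gifti_decode_data <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  ord <- xml2::xml_attr(node, "ArrayIndexingOrder")
  dat <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(dat)
  if (identical(enc, "ASCII")) {
    vals <- scan(text = txt, quiet = TRUE)
  } else {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary"))
      raw <- memDecompress(raw, type = "gzip")
    endian <- xml2::xml_attr(node, "Endian")
    e <- if (identical(endian, "BigEndian")) "big" else "little"
    vals <- switch(dtype,
      "NIFTI_TYPE_FLOAT32" = readBin(raw, "double", size = 4,
                                     n = length(raw) / 4, endian = e),
      "NIFTI_TYPE_FLOAT64" = readBin(raw, "double", size = 8,
                                     n = length(raw) / 8, endian = e),
      "NIFTI_TYPE_INT32" = readBin(raw, "integer", size = 4,
                                   n = length(raw) / 4, endian = e),
      "NIFTI_TYPE_UINT8" = as.integer(raw),
      stop("unsupported GIFTI data type: ", dtype))
  }
  if (length(dims) == 2L) {
    matrix(vals, nrow = dims[1], ncol = dims[2],
           byrow = !identical(ord, "ColumnMajorOrder"))
  } else vals
}

gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # tolerate files with or without the GIFTI xmlns
  nodes <- xml2::xml_find_all(doc, "//DataArray")
  lapply(nodes, function(nd)
    list(intent = xml2::xml_attr(nd, "Intent"),
         data = gifti_decode_data(nd)))
}

#' Read a GIFTI surface
#'
#' Expects one pointset array (vertex coordinates, mm) and one triangle
#' array (0-based indices), the layout of `.surf.gii` files.
#'
#' @param path file path.
#' @return a [triangle_mesh()].
#' @export
read_gifti_surface <- function(path) {
  arrs <- gifti_arrays(path)
  pts <- NULL; tri <- NULL
  for (a in arrs) {
    if (identical(a$intent, "NIFTI_INTENT_POINTSET")) pts <- a$data
    if (identical(a$intent, "NIFTI_INTENT_TRIANGLE")) tri <- a$data
  }
  if (is.null(pts) || is.null(tri))
    stop("not a surface GIFTI: needs POINTSET and TRIANGLE arrays")
  triangle_mesh(pts, matrix(as.integer(tri), ncol = 3) + 1L)
}

#' Read per-vertex values from a GIFTI metric/label file
#' @param path file path.
#' @return numeric (or integer, for label intents) per-vertex vector of the
#'   first data array.
#' @export
read_gifti_metric <- function(path) {
  arrs <- gifti_arrays(path)
  if (!length(arrs)) stop("no data arrays in ", path)
  as.numeric(arrs[[1]]$data)
}

gifti_array_xml <- function(data, intent, dtype) {
  fmt <- function(x) if (dtype == "NIFTI_TYPE_INT32")
    sprintf("%d", as.integer(x)) else sprintf("%.17g", x)
  if (is.matrix(data)) {
    dims <- sprintf('Dim0="%d" Dim1="%d" Dimensionality="2"',
                    nrow(data), ncol(data))
    vals <- apply(data, 1L, function(r) paste(fmt(r), collapse = " "))
  } else {
    dims <- sprintf('Dim0="%d" Dimensionality="1"', length(data))
    vals <- fmt(data)
  }
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder" Encoding="ASCII" ',
         'Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="" ',
         dims, '>\n<Data>', paste(vals, collapse = "\n"),
         '</Data>\n</DataArray>')
}

#' Write a surface or per-vertex map as GIFTI (ASCII encoding)
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @export
write_gifti_surface <- function(mesh, path) {
  body <- paste0(
    gifti_array_xml(mesh$vertices, "NIFTI_INTENT_POINTSET",
                    "NIFTI_TYPE_FLOAT32"),
    "\n",
    gifti_array_xml(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                    "NIFTI_TYPE_INT32"))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<GIFTI Version="1.0" NumberOfDataArrays="2">', body,
               '</GIFTI>'), path)
  invisible(path)
}

#' @param values numeric per-vertex vector.
#' @rdname write_gifti_surface
#' @export
write_gifti_metric <- function(values, path) {
  body <- gifti_array_xml(as.numeric(values), "NIFTI_INTENT_NONE",
                          "NIFTI_TYPE_FLOAT32")
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<GIFTI Version="1.0" NumberOfDataArrays="1">', body,
               '</GIFTI>'), path)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Mesh (CSV dialect and GIFTI), labels, per-subject/scan time series and FD,
#' tracer tables, and a ground-truth JSON (anchors, gradient parameters,
#' seed), plus a run manifest.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_surface_csv(sim$mesh, fp("vertices.csv"), fp("faces.csv"))
  write_gifti_surface(sim$mesh, fp("surface.surf.gii"))
  write_labels_csv(sim$parc, fp("labels.csv"), fp("label_names.csv"))
  if (!is.null(sim$timeseries)) {
    for (s in seq_along(sim$timeseries)) {
      subj <- sim$timeseries[[s]]
      for (sc in seq_along(subj$scans)) {
        write_timeseries_csv(subj$scans[[sc]],
                             fp(sprintf("ts_sub%02d_scan%d.csv", s, sc)))
        utils::write.csv(data.frame(fd_mm = subj$fd[[sc]]),
                         fp(sprintf("fd_sub%02d_scan%d.csv", s, sc)),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(sim$records))
    write_tracer_csv(sim$records, fp("tracer_counts.csv"),
                     fp("injection_sites.csv"))
  jsonlite::write_json(sim$ground_truth, fp("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(fp("manifest.json"), "simulate",
                 params = unclass(sim$config), seed = sim$config$seed)
  invisible(dir)
}
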