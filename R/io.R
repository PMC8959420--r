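## File formats. GIFTI files are written/read in ASCII encoding (the GIFTI
## standard's text encoding): one XML <DataArray> per map with whitespace-
## separated values. Plain-matrix fallbacks are whitespace-delimited tables.

gifti_data_array <- function(doc_root, data, intent, datatype) {
  da <- xml2::xml_add_child(doc_root, "DataArray",
    Intent = intent, DataType = datatype, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dim(data)) %||% 1L),
    Encoding = "ASCII", Endian = "LittleEndian", ExternalFileName = "",
    ExternalFileOffset = "")
  dims <- dim(data) %||% length(data)
  for (d in seq_along(dims)) {
    xml2::xml_set_attr(da, paste0("Dim", d - 1L), as.character(dims[d]))
  }
  vals <- if (is.matrix(data)) as.vector(t(data)) else data
  txt <- paste(format(vals, scientific = FALSE, trim = TRUE, digits = 10),
               collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  da
}

#' Write a surface mesh as an ASCII GIFTI surface file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path (conventionally `.surf.gii`).
#' @return `path`, invisibly. The cortex mask is stored alongside in the
#'   file's metadata as a 0/1 vector under a shape data array.
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "3")
  gifti_data_array(doc, mesh$coordinates, "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT32")
  gifti_data_array(doc, mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32")
  gifti_data_array(doc, as.integer(mesh$cortex_mask), "NIFTI_INTENT_SHAPE",
                   "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write per-vertex integer labels as an ASCII GIFTI label file
#'
#' @param labels integer vector (or [parcellation_map()] / [group_atlas()]).
#' @param path output path (conventionally `.label.gii`).
#' @export
write_gifti_labels <- function(labels, path) {
  if (inherits(labels, c("parcellation_map", "group_atlas"))) labels <- labels$labels
  labels <- as.integer(labels)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (k in sort(unique(labels))) {
    xml2::xml_add_child(lt, "Label", Key = as.character(k),
                        sprintf("parcel_%d", k))
  }
  gifti_data_array(doc, labels, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a vertices x timepoints matrix as an ASCII GIFTI functional file
#'
#' One data array per timepoint (column), following the one-map-per-array
#' convention of `.func.gii`.
#'
#' @param data numeric matrix (vertices x timepoints) or [session_ts()].
#' @param path output path (conventionally `.func.gii`).
#' @export
write_gifti_func <- function(data, path) {
  if (inherits(data, "session_ts")) data <- data$data
  data <- as.matrix(data)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(data)))
  for (j in seq_len(ncol(data))) {
    gifti_data_array(doc, data[, j], "NIFTI_INTENT_TIME_SERIES",
                     "NIFTI_TYPE_FLOAT32")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_gifti_array <- function(da) {
  txt <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
  vals <- scan(text = txt, what = numeric(), quiet = TRUE)
  dim_attrs <- paste0("Dim", 0:5)
  dims <- suppressWarnings(as.integer(
    vapply(dim_attrs, function(a) xml2::xml_attr(da, a) %||% NA_character_,
           character(1))))
  dims <- dims[!is.na(dims)]
  if (length(vals) != prod(dims)) {
    stop_input("GIFTI data array has %d values but dims %s", length(vals),
               paste(dims, collapse = "x"))
  }
  if (length(dims) > 1L) {
    vals <- matrix(vals, nrow = dims[1L], byrow = TRUE)  # RowMajorOrder
  }
  list(intent = xml2::xml_attr(da, "Intent"),
       datatype = xml2::xml_attr(da, "DataType"), data = vals)
}

#' Read an ASCII GIFTI file
#'
#' Supports the ASCII encoding of surface (`.surf.gii`), label
#' (`.label.gii`) and functional (`.func.gii`) files as written by this
#' package's writers (and other tools using ASCII encoding).
#'
#' @param path file path.
#' @return List of parsed data arrays (`intent`, `datatype`, `data`).
#' @export
read_gifti <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_input("cannot parse GIFTI XML in %s: %s",
                                                 path, conditionMessage(e)))
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(das) == 0L) stop_input("no DataArray elements in %s", path)
  enc <- unique(xml2::xml_attr(das, "Encoding"))
  if (!all(enc == "ASCII")) {
    stop_input("only ASCII-encoded GIFTI is supported (found %s)",
               paste(setdiff(enc, "ASCII"), collapse = ", "))
  }
  lapply(das, parse_gifti_array)
}

read_gifti_surface <- function(path) {
  arrs <- read_gifti(path)
  intents <- vapply(arrs, `[[`, character(1), "intent")
  pts <- arrs[[match("NIFTI_INTENT_POINTSET", intents)]]$data
  tri <- arrs[[match("NIFTI_INTENT_TRIANGLE", intents)]]$data + 1L
  mask <- if ("NIFTI_INTENT_SHAPE" %in% intents) {
    as.logical(arrs[[match("NIFTI_INTENT_SHAPE", intents)]]$data)
  } else NULL
  surface_mesh(pts, tri, mask)
}

#' Load per-vertex data from a file, dispatching on extension
#'
#' `.surf.gii` gives a [surface_mesh()]; `.label.gii` an integer label
#' vector; `.func.gii` a vertices x timepoints matrix; `.txt`/`.tsv`/`.csv`
#' a plain numeric matrix or vector (whitespace/comma delimited, no header).
#'
#' @param path file path.
#' @param expected_n optional expected vertex count; mismatch is an error.
#' @return The loaded object with attribute `source` set to `path`.
#' @export
load_vertex_data <- function(path, expected_n = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lower <- tolower(path)
  out <- if (grepl("\\.surf\\.gii$", lower)) {
    read_gifti_surface(path)
  } else if (grepl("\\.label\\.gii$", lower)) {
    as.integer(read_gifti(path)[[1L]]$data)
  } else if (grepl("\\.(func|shape)\\.gii$", lower)) {
    arrs <- read_gifti(path)
    do.call(cbind, lapply(arrs, `[[`, "data"))
  } else if (grepl("\\.(txt|tsv)$", lower)) {
    as.matrix(utils::read.table(path, header = FALSE))
  } else if (grepl("\\.csv$", lower)) {
    as.matrix(utils::read.table(path, header = FALSE, sep = ","))
  } else {
    stop_input(paste0("unsupported extension in %s; supported: .surf.gii, ",
                      ".label.gii, .func.gii, .shape.gii, .txt, .tsv, .csv"),
               path)
  }
  n <- if (inherits(out, "surface_mesh")) nrow(out$coordinates) else NROW(out)
  if (!is.null(expected_n) && n != expected_n) {
    stop_input("%s has %d vertices but %d expected", path, n, expected_n)
  }
  if (is.matrix(out) && ncol(out) == 1L) out <- drop(out)
  attr(out, "source") <- path
  out
}

#' Write a plain numeric matrix (no header, whitespace delimited)
#'
#' @param m matrix or vector.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(as.matrix(m), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a trained model checkpoint
#'
#' Self-describing JSON archive: layer shapes and orders, flattened
#' coefficients, bias vectors, architecture hyperparameters and seed, plus a
#' content hash for manifests.
#'
#' @param model an [msgcn_model()].
#' @param path output path (`.json`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "msgcn_model"))
  ser <- list(
    format = "gcnparcel-checkpoint-1",
    n_features = model$n_features, n_hidden = model$n_hidden,
    n_classes = model$n_classes, order = model$order,
    dropout_rate = model$dropout_rate, bias = model$bias, seed = model$seed,
    layers = lapply(model$layers, function(l) list(
      n_in = l$n_in, n_out = l$n_out, order = l$order,
      theta = lapply(l$theta, function(th) as.vector(th)),
      bias = l$bias)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path.
#' @return An [msgcn_model()] with the stored parameters.
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(ser$format, "gcnparcel-checkpoint-1")) {
    stop_input("%s is not a gcnparcel checkpoint", path)
  }
  model <- msgcn_model(ser$n_features, ser$n_classes, ser$n_hidden,
                       ser$order, ser$dropout_rate, isTRUE(ser$bias),
                       seed = ser$seed)
  for (l in 1:2) {
    li <- ser$layers[[l]]
    theta <- lapply(li$theta, function(v) matrix(v, li$n_in, li$n_out))
    b <- if (isTRUE(ser$bias)) as.numeric(li$bias) else NULL
    model$layers[[l]] <- cheb_layer(theta, b)
  }
  model
}

#' Write a reproducibility manifest next to an artifact
#'
#' Records the generating seed, a hash of the configuration, and the package
#' version, sufficient to re-run the producing command bit-identically.
#'
#' @param path the artifact path (manifest goes to `<path>.manifest.json`).
#' @param config the configuration list used.
#' @param seed the run seed.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    artifact = basename(path),
    seed = seed,
    config_hash = config_hash(config),
    package = "gcnparcel",
    version = as.character(utils::packageVersion("gcnparcel")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# order-independent hash of a (nested) config list
config_hash <- function(config) {
  flat <- unlist(config)
  flat <- flat[order(names(flat))]
  txt <- paste(names(flat), vapply(flat, format, character(1)),
               collapse = ";", sep = "=")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2^31
  sprintf("%08x", h)
}
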