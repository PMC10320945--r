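## Case-bundle persistence. A bundle is a directory holding one JSON
## manifest plus one gzipped little-endian float64 blob per named array --
## a lightweight hierarchical array container with a schema version and a
## bit-exact round trip.

bundleSchemaVersion <- 1L

writeArrayBin <- function(x, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.numeric(x)), con, size = 8L, endian = "little")
}

readArrayBin <- function(path, dims) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(dims), size = 8L, endian = "little")
  if (length(x) != prod(dims))
    stop("array blob '", basename(path), "' is truncated")
  array(x, dim = dims)
}

gridToList <- function(g) list(dims = g@dims, spacing = g@spacing,
                               origin = g@origin)
gridFromList <- function(l)
  gridSpec(l$dims[1], l$dims[2], l$dims[3], l$spacing, l$origin)
beamsToList <- function(b) list(
  gantryAngles = b@gantryAngles, sad = b@sad, planeRows = b@planeRows,
  planeCols = b@planeCols, planePitch = b@planePitch)
beamsFromList <- function(l)
  beamGeometry(l$gantryAngles, l$sad, l$planeRows, l$planeCols, l$planePitch)

#' Save a case bundle
#'
#' Writes all arrays and metadata of a \code{PatientCase} into a bundle
#' directory. \code{loadCase(saveCase(x))} is bit-exact.
#'
#' @param case a \code{PatientCase}.
#' @param path bundle directory (created; must be empty or absent).
#' @return invisibly, \code{path}.
#' @export
saveCase <- function(case, path) {
  methods::validObject(case)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrays <- c(list(ct = case@ct, ptvDose = case@ptvDose, dose = case@dose,
                   fluence = case@fluence),
              stats::setNames(case@ptvMasks,
                              paste0("ptv.", names(case@ptvMasks))),
              stats::setNames(case@oarMasks,
                              paste0("oar.", names(case@oarMasks))))
  manifest <- list(
    schemaVersion = bundleSchemaVersion,
    type = "PatientCase",
    grid = gridToList(case@grid),
    beams = beamsToList(case@beams),
    prescriptions = as.list(case@prescriptions),
    seed = case@seed,
    arrays = lapply(arrays, function(a)
      list(dims = if (is.null(dim(a))) length(a) else dim(a))))
  for (nm in names(arrays))
    writeArrayBin(arrays[[nm]], file.path(path, paste0(nm, ".bin.gz")))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a case bundle
#'
#' Reads a bundle written by \code{\link{saveCase}}; the schema version is
#' checked (an unknown version is refused, never silently reinterpreted)
#' and the result is validated against all \code{PatientCase} invariants.
#'
#' @param path bundle directory.
#' @return a \code{PatientCase}.
#' @export
loadCase <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a case bundle: missing manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schemaVersion), bundleSchemaVersion))
    stop("unsupported bundle schema version ", manifest$schemaVersion,
         " (this build reads version ", bundleSchemaVersion, ")")
  if (!identical(manifest$type, "PatientCase"))
    stop("bundle does not contain a PatientCase")
  readArr <- function(nm) {
    meta <- manifest$arrays[[nm]]
    if (is.null(meta)) stop("bundle is missing array '", nm, "'")
    f <- file.path(path, paste0(nm, ".bin.gz"))
    if (!file.exists(f)) stop("bundle is missing array file '", nm, "'")
    readArrayBin(f, unlist(meta$dims))
  }
  grid <- gridFromList(manifest$grid)
  beams <- beamsFromList(manifest$beams)
  ptv <- stats::setNames(
    lapply(ptvNames(), function(nm) readArr(paste0("ptv.", nm))), ptvNames())
  oar <- stats::setNames(
    lapply(oarNames(), function(nm) readArr(paste0("oar.", nm))), oarNames())
  case <- new("PatientCase", grid = grid, beams = beams,
              ct = readArr("ct"), ptvDose = readArr("ptvDose"),
              ptvMasks = ptv, oarMasks = oar, dose = readArr("dose"),
              fluence = readArr("fluence"),
              prescriptions = unlist(manifest$prescriptions),
              seed = as.integer(manifest$seed))
  methods::validObject(case)
  case
}

#' Save / load a projection operator
#'
#' Serializes the sparse matrix as coordinate triplets (i, j, value)
#' alongside the geometry metadata; the round trip is bit-exact.
#'
#' @param op a \code{ProjectionOperator}.
#' @param path bundle directory.
#' @return invisibly, \code{path}.
#' @export
saveProjection <- function(op, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  trip <- Matrix::summary(op@P)
  writeArrayBin(trip$i, file.path(path, "i.bin.gz"))
  writeArrayBin(trip$j, file.path(path, "j.bin.gz"))
  writeArrayBin(trip$x, file.path(path, "x.bin.gz"))
  manifest <- list(
    schemaVersion = bundleSchemaVersion, type = "ProjectionOperator",
    beamIndex = op@beamIndex, gantryAngle = op@gantryAngle,
    dims = dim(op@P), nnz = length(trip$x),
    grid = gridToList(op@grid), beams = beamsToList(op@beam),
    sliceRange = op@sliceRange, rowRange = op@rowRange,
    truncated = op@truncated)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveProjection
#' @export
loadProjection <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schemaVersion), bundleSchemaVersion))
    stop("unsupported bundle schema version ", manifest$schemaVersion)
  if (!identical(manifest$type, "ProjectionOperator"))
    stop("bundle does not contain a ProjectionOperator")
  nnz <- manifest$nnz
  P <- Matrix::sparseMatrix(
    i = as.integer(readArrayBin(file.path(path, "i.bin.gz"), nnz)),
    j = as.integer(readArrayBin(file.path(path, "j.bin.gz"), nnz)),
    x = as.vector(readArrayBin(file.path(path, "x.bin.gz"), nnz)),
    dims = manifest$dims)
  new("ProjectionOperator", beamIndex = as.integer(manifest$beamIndex),
      gantryAngle = manifest$gantryAngle, P = P,
      grid = gridFromList(manifest$grid),
      beam = beamsFromList(manifest$beams),
      sliceRange = as.integer(manifest$sliceRange),
      rowRange = as.integer(manifest$rowRange),
      truncated = manifest$truncated)
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundle holds the model configuration as JSON and every
#' named parameter array as a binary blob. Loading verifies each
#' parameter's shape against the configuration's layer table: a mismatch
#' is an error, never a silent reshape.
#'
#' @param model a \code{SharedEncoderModel}.
#' @param path bundle directory.
#' @param extra optional named list stored verbatim in the manifest
#'   (e.g. training history or config).
#' @return invisibly, \code{path}.
#' @export
saveCheckpoint <- function(model, path, extra = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schemaVersion = bundleSchemaVersion, type = "SharedEncoderModel",
    config = model@config,
    params = lapply(model@params, function(p)
      list(dims = if (is.null(dim(p))) length(p) else dim(p))),
    extra = extra)
  for (nm in names(model@params))
    writeArrayBin(model@params[[nm]],
                  file.path(path, paste0(gsub("[^A-Za-z0-9.]", "_", nm),
                                         ".bin.gz")))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schemaVersion), bundleSchemaVersion))
    stop("unsupported checkpoint schema version ", manifest$schemaVersion)
  if (!identical(manifest$type, "SharedEncoderModel"))
    stop("bundle does not contain a model checkpoint")
  config <- manifest$config
  config$in_channels <- as.integer(config$in_channels)
  config$base_channels <- as.integer(config$base_channels)
  config$fluence_channels <- as.integer(config$fluence_channels)
  layers <- modelLayers(config)
  params <- list()
  for (nm in names(manifest$params)) {
    dims <- unlist(manifest$params[[nm]]$dims)
    p <- readArrayBin(
      file.path(path, paste0(gsub("[^A-Za-z0-9.]", "_", nm), ".bin.gz")),
      dims)
    if (length(dims) == 1L) p <- as.vector(p)
    params[[nm]] <- p
  }
  ref <- buildModel(config, seed = 1)
  if (!identical(sort(names(params)), sort(names(ref@params))))
    stop("checkpoint parameter set does not match the configuration")
  for (nm in names(params)) {
    want <- dim(ref@params[[nm]])
    have <- dim(params[[nm]])
    if (!identical(as.integer(want %||% length(ref@params[[nm]])),
                   as.integer(have %||% length(params[[nm]]))))
      stop("checkpoint parameter '", nm,
           "' does not match the configuration (shape mismatch)")
  }
  new("SharedEncoderModel", config = config, params = params[names(ref@params)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ingest a DICOM-RT directory (optional extra)
#'
#' Mapping a CT series, RTSTRUCT, RTDOSE and RTPLAN onto a
#' \code{PatientCase} requires a DICOM reader, which this build does not
#' bundle; the function exists as the documented integration point and
#' raises an informative error. All core functionality operates on
#' synthetic phantoms and case bundles instead.
#'
#' @param directory path containing the DICOM series.
#' @return never returns; raises an error.
#' @export
ingestDicom <- function(directory) {
  stop("DICOM ingest is an optional extra that needs a DICOM reader; ",
       "this installation has none. Generate phantom cases with ",
       "generateCase() or load a case bundle with loadCase() instead.")
}
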