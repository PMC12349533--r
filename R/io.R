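## Volume, image and run-configuration IO.
##
## Axis convention for all volume formats: array dimension k is world axis k,
## world position of voxel (i, j, k) (0-based) = origin + spacing * c(i, j, k).
## For NIfTI the spacing comes from pixdim and the origin from the xform
## translation; any rotational part of the xform is ignored (noted when
## verbose).

.metaTypeTable <- list(
    MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
    MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
    MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
    MET_INT = list(what = "integer", size = 4, signed = TRUE),
    MET_UINT = list(what = "integer", size = 4, signed = TRUE),
    MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

.parseMetaHeader <- function(lines) {
    lines <- lines[nzchar(trimws(lines))]
    kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
    keys <- vapply(kv, function(x) trimws(x[1]), character(1))
    vals <- vapply(kv, function(x) trimws(x[2]), character(1))
    setNames(as.list(vals), keys)
}

.readMetaVolume <- function(path) {
    if (grepl("\\.mha$", tolower(path))) {
        bytes <- readBin(path, "raw", file.size(path))
        tagAt <- grepRaw("ElementDataFile", bytes)
        if (!length(tagAt)) stop("malformed MetaImage header: no ElementDataFile")
        nl <- grepRaw("\n", bytes, offset = tagAt[1])
        header <- .parseMetaHeader(strsplit(rawToChar(bytes[1:(nl - 1)]),
                                            "\n")[[1]])
        dataBytes <- bytes[(nl + 1):length(bytes)]
    } else {
        header <- .parseMetaHeader(readLines(path, warn = FALSE))
        dataBytes <- NULL
    }
    if (!is.null(header$NDims) && as.integer(header$NDims) != 3)
        stop("only 3D MetaImage volumes are supported")
    if (isTRUE(toupper(header$CompressedData %||% "FALSE") == "TRUE"))
        stop("compressed MetaImage data are not supported")
    dims <- as.integer(strsplit(header$DimSize, "\\s+")[[1]])
    if (length(dims) != 3 || any(is.na(dims)))
        stop("malformed MetaImage header: bad DimSize")
    spacing <- as.numeric(strsplit(
        header$ElementSpacing %||% header$ElementSize %||% "1 1 1",
        "\\s+")[[1]])
    origin <- as.numeric(strsplit(
        header$Offset %||% header$Origin %||% header$Position %||% "0 0 0",
        "\\s+")[[1]])
    tinfo <- .metaTypeTable[[header$ElementType %||% "MET_FLOAT"]]
    if (is.null(tinfo))
        stop("unsupported MetaImage ElementType: ", header$ElementType)
    endian <- if (toupper(header$ElementByteOrderMSB %||% "FALSE") == "TRUE")
        "big" else "little"
    n <- prod(dims)
    vals <- if (is.null(dataBytes)) {
        dataFile <- header$ElementDataFile
        if (is.null(dataFile) || toupper(dataFile) == "LOCAL")
            stop("malformed .mhd header: ElementDataFile must name a raw file")
        rawPath <- file.path(dirname(path), dataFile)
        if (!file.exists(rawPath)) stop("raw data file not found: ", rawPath)
        readBin(rawPath, tinfo$what, n = n, size = tinfo$size,
                signed = tinfo$signed, endian = endian)
    } else {
        readBin(dataBytes, tinfo$what, n = n, size = tinfo$size,
                signed = tinfo$signed, endian = endian)
    }
    if (length(vals) != n) stop("MetaImage data block is truncated")
    CTVolume(array(as.numeric(vals), dims), spacing = spacing, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readNiftiVolume <- function(path) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3) stop("only 3D NIfTI volumes are supported")
    arr <- array(as.numeric(img), dim(img))
    spacing <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    if (max(abs(xf[1:3, 1:3] - diag(as.numeric(spacing)))) > 1e-6)
        .dprMessage("NIfTI xform has a non-trivial rotation/flip; ",
                    "only its translation is honored")
    CTVolume(arr, spacing = as.numeric(spacing),
             origin = as.numeric(xf[1:3, 4]))
}

.readRawJsonVolume <- function(path) {
    meta <- jsonlite::fromJSON(path)
    need <- c("dim", "spacing", "origin", "dataFile")
    if (!all(need %in% names(meta)))
        stop("raw-volume JSON sidecar must define: ",
             paste(need, collapse = ", "))
    dims <- as.integer(meta$dim)
    rawPath <- file.path(dirname(path), meta$dataFile)
    if (!file.exists(rawPath)) stop("raw data file not found: ", rawPath)
    dtype <- meta$dtype %||% "double"
    size <- switch(dtype, double = 8, float = 4,
                   stop("unsupported raw dtype: ", dtype))
    vals <- readBin(rawPath, "numeric", n = prod(dims), size = size,
                    endian = meta$byteOrder %||% "little")
    if (length(vals) != prod(dims)) stop("raw data block is truncated")
    CTVolume(array(vals, dims), spacing = as.numeric(meta$spacing),
             origin = as.numeric(meta$origin))
}

#' Read a CT volume
#'
#' Supports MetaImage (`.mhd` + raw file, or `.mha` with a LOCAL data block),
#' NIfTI (`.nii`, `.nii.gz`) and a raw + JSON-sidecar fallback (pass the
#' `.json` path). Header spacing and origin are honored.
#'
#' @param path volume file path.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lower <- tolower(path)
    if (grepl("\\.mhd$|\\.mha$", lower)) .readMetaVolume(path)
    else if (grepl("\\.nii$|\\.nii\\.gz$", lower)) .readNiftiVolume(path)
    else if (grepl("\\.json$", lower)) .readRawJsonVolume(path)
    else stop("unsupported volume format: ", basename(path))
}

#' Write a CT volume
#'
#' MetaImage output writes `.mhd` plus a sibling `.raw` file, or a
#' self-contained `.mha`; both store MET_DOUBLE so round trips are lossless.
#' NIfTI goes through RNifti; `.json` writes the raw + sidecar pair.
#'
#' @param volume a [CTVolume-class].
#' @param path output path (`.mhd`, `.mha`, `.nii`, `.nii.gz` or `.json`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "CTVolume"))
    lower <- tolower(path)
    d <- dim(volume@voxels)
    if (grepl("\\.mhd$|\\.mha$", lower)) {
        local <- grepl("\\.mha$", lower)
        dataFile <- if (local) "LOCAL"
                    else paste0(sub("\\.mhd$", "", basename(path),
                                    ignore.case = TRUE), ".raw")
        header <- paste0(
            "ObjectType = Image\n",
            "NDims = 3\n",
            "BinaryData = True\n",
            "BinaryDataByteOrderMSB = False\n",
            "ElementByteOrderMSB = False\n",
            "CompressedData = False\n",
            "DimSize = ", paste(d, collapse = " "), "\n",
            "ElementSpacing = ", paste(volume@spacing, collapse = " "), "\n",
            "Offset = ", paste(volume@origin, collapse = " "), "\n",
            "ElementType = MET_DOUBLE\n",
            "ElementDataFile = ", dataFile, "\n")
        if (local) {
            con <- file(path, "wb")
            on.exit(close(con))
            writeBin(charToRaw(header), con)
            writeBin(as.numeric(volume@voxels), con, size = 8,
                     endian = "little")
        } else {
            writeLines(sub("\n$", "", header), path)
            writeBin(as.numeric(volume@voxels),
                     file.path(dirname(path), dataFile), size = 8,
                     endian = "little")
        }
    } else if (grepl("\\.nii$|\\.nii\\.gz$", lower)) {
        img <- RNifti::asNifti(volume@voxels)
        RNifti::pixdim(img) <- volume@spacing
        xf <- diag(4)
        diag(xf)[1:3] <- volume@spacing
        xf[1:3, 4] <- volume@origin
        RNifti::sform(img) <- structure(xf, code = 2L)
        RNifti::writeNifti(img, path)
    } else if (grepl("\\.json$", lower)) {
        dataFile <- paste0(sub("\\.json$", "", basename(path),
                               ignore.case = TRUE), ".raw")
        jsonlite::write_json(
            list(dim = d, spacing = volume@spacing, origin = volume@origin,
                 dtype = "double", byteOrder = "little", dataFile = dataFile),
            path, auto_unbox = FALSE, digits = NA)
        writeBin(as.numeric(volume@voxels),
                 file.path(dirname(path), dataFile), size = 8,
                 endian = "little")
    } else stop("unsupported volume format: ", basename(path))
    invisible(path)
}

#' Read a grayscale radiograph
#'
#' 8- or 16-bit PNG/TIFF, returned on the \[0, 255\] grayscale regardless of
#' bit depth. Color images are rejected rather than silently converted.
#'
#' @param path image path.
#' @param pixelSpacing detector pixel pitch in mm (not stored by PNG).
#' @return A [Radiograph-class].
#' @export
readRadiograph <- function(path, pixelSpacing = 1) {
    if (!file.exists(path)) stop("file not found: ", path)
    lower <- tolower(path)
    px <- if (grepl("\\.png$", lower)) png::readPNG(path)
          else if (grepl("\\.tif$|\\.tiff$", lower)) tiff::readTIFF(path)
          else stop("unsupported image format: ", basename(path))
    if (length(dim(px)) == 3) {
        if (dim(px)[3] == 2) px <- px[, , 1] # gray + alpha: drop alpha
        else stop("color images are not supported; provide grayscale input")
    }
    Radiograph(px * 255, pixelSpacing = pixelSpacing)
}

#' Write a radiograph
#'
#' Pixels must lie in \[0, 255\]; PNG stores 8 or 16 bits, TIFF 16 bits.
#'
#' @param image a [Radiograph-class].
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @param bitDepth 8 or 16.
#' @return `path`, invisibly.
#' @export
writeRadiograph <- function(image, path, bitDepth = 8) {
    stopifnot(is(image, "Radiograph"), bitDepth %in% c(8, 16))
    px <- image@pixels
    if (min(px) < 0 || max(px) > 255)
        stop("pixels must lie in [0, 255]; normalize first (see toGrayscale)")
    lower <- tolower(path)
    if (grepl("\\.png$", lower))
        png::writePNG(px / 255, path, dpi = 25.4 / image@pixelSpacing)
    else if (grepl("\\.tif$|\\.tiff$", lower))
        tiff::writeTIFF(px / 255, path, bits.per.sample = bitDepth)
    else stop("unsupported image format: ", basename(path))
    invisible(path)
}

## ---- run configuration -------------------------------------------------------

.runConfigDefaults <- function() list(
    seed = 1,
    geometry = list(sourceToIso = 1000, isoToDetector = 200,
                    detectorSize = c(256, 256), pixelSpacing = 1,
                    stepSize = NA),
    similarity = list(aBand = 1, bBand = 3, w1 = 0.8, w2 = 0.5,
                      cannySigma = 1, cannyLow = NA, cannyHigh = NA),
    weights = list(wf = 0.6, wl = 0.4),
    optimizer = list(NP = 10, Gmax = 50, fFirst = 0.5, fSecond = 0.8,
                     crFirst = 0.9, crSecond = 0.3,
                     fScale = c(1, 1, 0.8, 1, 1, 1)),
    registration = list(mode = "dual", halfWidths = rep(10, 6),
                        includeInitial = TRUE, aggregateSuccess = FALSE,
                        initialPose = rep(0, 6)),
    phantom = list(noiseSd = 0, pixelNoiseSd = 2),
    transMat = transformAsVector(defaultTransMat()))

.mergeConfig <- function(defaults, user, path = character(0)) {
    for (key in names(user)) {
        here <- paste(c(path, key), collapse = ".")
        if (!key %in% names(defaults))
            stop("unknown configuration key '", here, "'", call. = FALSE)
        if (is.list(defaults[[key]]) && !is.list(user[[key]]))
            stop("configuration key '", here, "' must be a section",
                 call. = FALSE)
        if (is.list(defaults[[key]]))
            defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                            c(path, key))
        else {
            v <- user[[key]]
            if (length(v) != length(defaults[[key]]))
                stop("configuration key '", here, "' must have length ",
                     length(defaults[[key]]), call. = FALSE)
            defaults[[key]] <- v
        }
    }
    defaults
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON, rejects unknown keys (reported with their full key
#' path), materializes all defaults and checks the cross-field constraints
#' (frontal weight above lateral, phased CR schedule, band ordering) by
#' constructing the corresponding parameter objects. An empty file yields the
#' all-defaults configuration.
#'
#' @param path YAML/JSON file, or `NULL` for the defaults.
#' @return A [RunConfig-class] with every default materialized.
#' @examples
#' cfg <- loadRunConfig(NULL)
#' configValues(cfg)$weights
#' @export
loadRunConfig <- function(path = NULL) {
    user <- list()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("file not found: ", path)
        user <- if (grepl("\\.json$", tolower(path)))
            jsonlite::fromJSON(path, simplifyVector = TRUE)
        else yaml::read_yaml(path)
        if (is.null(user)) user <- list()
        if (!is.list(user)) stop("configuration must be a mapping")
    }
    vals <- .mergeConfig(.runConfigDefaults(), user)
    ## cross-field constraints via the parameter-object validators
    CompositeWeights(vals$weights$wf, vals$weights$wl)
    SimilarityBands(vals$similarity$aBand, vals$similarity$bBand,
                    vals$similarity$w1, vals$similarity$w2)
    DEConfig(NP = max(vals$optimizer$NP, 6), D = 6, Gmax = vals$optimizer$Gmax,
             lower = rep(0, 6), upper = rep(1, 6),
             fFirst = vals$optimizer$fFirst, fSecond = vals$optimizer$fSecond,
             crFirst = vals$optimizer$crFirst,
             crSecond = vals$optimizer$crSecond)
    transformFromVector(vals$transMat)
    new("RunConfig", values = vals)
}

#' Build registration inputs from a run configuration
#'
#' Expands a [RunConfig-class] into the `(config, geometry, transMat)`
#' triple consumed by [registerPose()].
#'
#' @param runConfig a [RunConfig-class].
#' @return `list(config = RegistrationConfig, geometry = ProjectionGeometry,
#'   transMat = RigidTransform)`.
#' @export
configToRegistration <- function(runConfig) {
    stopifnot(is(runConfig, "RunConfig"))
    v <- runConfig@values
    transMat <- transformFromVector(v$transMat)
    geometry <- makeDefaultGeometry(
        "frontal", sourceToIso = v$geometry$sourceToIso,
        isoToDetector = v$geometry$isoToDetector,
        detectorSize = v$geometry$detectorSize,
        pixelSpacing = v$geometry$pixelSpacing,
        stepSize = as.numeric(v$geometry$stepSize), transMat = transMat)
    config <- RegistrationConfig(
        mode = v$registration$mode,
        initialPose = poseFromVector(v$registration$initialPose),
        halfWidths = v$registration$halfWidths,
        bands = SimilarityBands(v$similarity$aBand, v$similarity$bBand,
                                v$similarity$w1, v$similarity$w2),
        weights = CompositeWeights(v$weights$wf, v$weights$wl),
        NP = v$optimizer$NP, Gmax = v$optimizer$Gmax,
        fFirst = v$optimizer$fFirst, fSecond = v$optimizer$fSecond,
        crFirst = v$optimizer$crFirst, crSecond = v$optimizer$crSecond,
        fScale = v$optimizer$fScale, cannySigma = v$similarity$cannySigma,
        cannyLow = as.numeric(v$similarity$cannyLow),
        cannyHigh = as.numeric(v$similarity$cannyHigh),
        includeInitial = v$registration$includeInitial,
        aggregateSuccess = v$registration$aggregateSuccess,
        seed = v$seed)
    list(config = config, geometry = geometry, transMat = transMat)
}

#' Write the effective configuration as YAML
#'
#' Serializes a [RunConfig-class] (all defaults materialized) so a run can be
#' reconstructed from its logged configuration.
#'
#' @param runConfig a [RunConfig-class].
#' @param path output YAML path, or `NULL` to return the YAML string.
#' @return The YAML string, invisibly when written to a file.
#' @export
writeRunConfig <- function(runConfig, path = NULL) {
    stopifnot(is(runConfig, "RunConfig"))
    txt <- yaml::as.yaml(runConfig@values)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Save a fixture case to disk
#'
#' Writes the phantom volume (MetaImage), the frontal/lateral reference
#' images (PNG) and a JSON record of the ground truth pose, geometry and
#' seeds.
#'
#' @param fixture a [FixtureCase-class].
#' @param dir output directory (created if needed).
#' @param name base name of the files.
#' @return The JSON record path, invisibly.
#' @export
saveFixtureCase <- function(fixture, dir, name = "fixture") {
    stopifnot(is(fixture, "FixtureCase"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeVolume(fixture@volume, file.path(dir, paste0(name, ".mhd")))
    writeRadiograph(fixture@frontal,
                    file.path(dir, paste0(name, "_frontal.png")))
    writeRadiograph(fixture@lateral,
                    file.path(dir, paste0(name, "_lateral.png")))
    g <- fixture@geometry
    rec <- list(
        truePose = poseAsVector(truePose(fixture)),
        transMat = transformAsVector(fixture@transMat),
        geometry = list(source = g@source, detectorCenter = g@detectorCenter,
                        detectorU = g@detectorU, detectorV = g@detectorV,
                        detectorSize = g@detectorSize,
                        pixelSpacing = g@pixelSpacing, stepSize = g@stepSize),
        noiseSd = fixture@noiseSd, seed = fixture@seed)
    out <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(rec, out, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
    invisible(out)
}
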