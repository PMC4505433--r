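# File adapters: a minimal multipage TIFF writer/reader (uncompressed,
# little-endian, 32-bit float or 16-bit unsigned grayscale - written by hand
# because no TIFF package is available in the target library), a JSON
# sidecar carrying scene ground truth (specs plus run-length-encoded masks),
# and ELISA plate CSV round-trip.

## ---- TIFF ------------------------------------------------------------------

TIFF_TAGS <- c(width = 256L, length = 257L, bps = 258L, compression = 259L,
               photometric = 262L, stripOffsets = 273L, rowsPerStrip = 278L,
               stripByteCounts = 279L, sampleFormat = 339L)

#' Write matrices as a multipage TIFF
#'
#' Uncompressed little-endian grayscale TIFF, one page per matrix; 32-bit
#' IEEE float by default (\code{bits = 16} writes unsigned 16-bit after
#' rounding and clamping to [0, 65535]).
#'
#' @param pages A numeric matrix or list of matrices (equal dimensions not
#'   required).
#' @param path Output path.
#' @param bits 32 (float) or 16 (unsigned integer).
#' @return \code{path}, invisibly.
#' @export
writeTiff <- function(pages, path, bits = 32L) {
    if (is.matrix(pages)) pages <- list(pages)
    stopifnot(bits %in% c(16L, 32L))
    con <- file(path, "wb")
    on.exit(close(con))
    w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
    w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
    ## header: II, 42, offset of first IFD (filled as we go)
    writeBin(charToRaw("II"), con)
    w2(42L)
    bytesPerPx <- bits / 8L
    nEntries <- length(TIFF_TAGS)
    pos <- 8L                       # next free offset after header
    ifdOffsets <- integer(length(pages))
    dataOffsets <- integer(length(pages))
    for (k in seq_along(pages)) {
        nbytes <- nrow(pages[[k]]) * ncol(pages[[k]]) * bytesPerPx
        dataOffsets[k] <- pos
        ifdOffsets[k] <- pos + nbytes
        pos <- ifdOffsets[k] + 2L + nEntries * 12L + 4L
    }
    w4(ifdOffsets[1])
    entry <- function(tag, type, count, value) {
        w2(tag); w2(type); w4(count)
        if (type == 3L) { w2(value); w2(0L) } else w4(value)
    }
    for (k in seq_along(pages)) {
        m <- pages[[k]]
        ## pixel data, row-major
        v <- as.vector(t(m))
        if (bits == 32L) {
            writeBin(as.numeric(v), con, size = 4, endian = "little")
        } else {
            v <- pmin(pmax(round(v), 0), 65535)
            hi <- v %/% 256L; lo <- v %% 256L
            writeBin(as.raw(rbind(lo, hi)), con)
        }
        ## IFD
        w2(nEntries)
        entry(TIFF_TAGS["width"], 3L, 1L, ncol(m))
        entry(TIFF_TAGS["length"], 3L, 1L, nrow(m))
        entry(TIFF_TAGS["bps"], 3L, 1L, bits)
        entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
        entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
        entry(TIFF_TAGS["stripOffsets"], 4L, 1L, dataOffsets[k])
        entry(TIFF_TAGS["rowsPerStrip"], 3L, 1L, nrow(m))
        entry(TIFF_TAGS["stripByteCounts"], 4L, 1L,
              nrow(m) * ncol(m) * bytesPerPx)
        entry(TIFF_TAGS["sampleFormat"], 3L, 1L, if (bits == 32L) 3L else 1L)
        w4(if (k < length(pages)) ifdOffsets[k + 1L] else 0L)
    }
    invisible(path)
}

#' Read a multipage TIFF written by \code{\link{writeTiff}}
#'
#' Supports uncompressed little-endian grayscale pages (8/16-bit unsigned or
#' 32-bit float, single strip per page as written by this package);
#' anything else raises a descriptive error.
#'
#' @param path TIFF path.
#' @return List of numeric matrices (one per page).
#' @export
readTiff <- function(path) {
    raw <- readBin(path, "raw", n = file.info(path)$size)
    rd <- function(at, size) {
        sum(as.integer(raw[at + seq_len(size)]) * 256^(0:(size - 1)))
    }
    if (rawToChar(raw[1:2]) != "II")
        stop("only little-endian ('II') TIFF is supported")
    if (rd(2, 2) != 42L) stop("not a TIFF file")
    offset <- rd(4, 4)
    pages <- list()
    while (offset != 0L) {
        n <- rd(offset, 2)
        tags <- list()
        for (e in seq_len(n)) {
            at <- offset + 2L + (e - 1L) * 12L
            tag <- rd(at, 2); type <- rd(at + 2, 2)
            val <- if (type == 3L) rd(at + 8, 2) else rd(at + 8, 4)
            tags[[as.character(tag)]] <- val
        }
        need <- function(tag, default = NULL) {
            v <- tags[[as.character(tag)]]
            if (is.null(v)) {
                if (is.null(default)) stop("missing TIFF tag ", tag)
                default
            } else v
        }
        wd <- need(256L); ht <- need(257L)
        bits <- need(258L, 8L)
        if (need(259L, 1L) != 1L) stop("compressed TIFF is not supported")
        fmt <- need(339L, 1L)
        dataAt <- need(273L)
        nbytes <- need(279L, wd * ht * bits / 8L)
        if (nbytes != wd * ht * bits / 8L)
            stop("multi-strip TIFF is not supported")
        bytes <- raw[dataAt + seq_len(nbytes)]
        v <- if (bits == 32L && fmt == 3L)
            readBin(bytes, "numeric", n = wd * ht, size = 4,
                    endian = "little")
        else if (bits == 16L && fmt == 1L)
            readBin(bytes, "integer", n = wd * ht, size = 2, signed = FALSE,
                    endian = "little")
        else if (bits == 8L && fmt == 1L)
            as.integer(bytes)
        else stop("unsupported TIFF sample format (bits = ", bits,
                  ", format = ", fmt, ")")
        pages[[length(pages) + 1L]] <- matrix(v, nrow = ht, ncol = wd,
                                              byrow = TRUE)
        offset <- rd(offset + 2L + n * 12L, 4)
    }
    pages
}

## ---- scene persistence -----------------------------------------------------

#' Write a rendered scene to disk
#'
#' Channels go to a multipage TIFF (one page per channel, 32-bit float) and
#' the ground truth (scene spec, per-cell specs, run-length-encoded masks)
#' to a JSON sidecar next to it.
#'
#' @param scene A \linkS4class{Scene}.
#' @param prefix Output path prefix; writes \code{<prefix>.tif} and
#'   \code{<prefix>.json}.
#' @return Named character vector of the two paths, invisibly.
#' @export
writeScene <- function(scene, prefix) {
    tifPath <- paste0(prefix, ".tif")
    jsonPath <- paste0(prefix, ".json")
    writeTiff(scene@channels, tifPath)
    sp <- scene@spec
    side <- list(
        channels = names(scene@channels),
        spec = list(imageShape = sp@imageShape, pixelSize = sp@pixelSize,
                    backgroundLevel = sp@backgroundLevel,
                    noiseGaussianSd = sp@noiseGaussianSd,
                    noisePoisson = sp@noisePoisson, seed = sp@seed),
        cells = lapply(sp@cells, function(cs) list(
            center = cs@center, radius = cs@radius,
            membraneThickness = cs@membraneThickness,
            membraneFraction = cs@membraneFraction,
            nucleusRadius = cs@nucleusRadius, totalSignal = cs@totalSignal,
            erFraction = cs@erFraction, transfected = cs@transfected,
            swellingAreaRatio = cs@swellingAreaRatio)),
        masks = lapply(scene@masks, function(mk)
            lapply(mk[c("cell", "ring", "interior", "nucleus", "er")],
                   rleMask)))
    jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(c(tif = tifPath, json = jsonPath))
}

#' Read a scene written by \code{\link{writeScene}}
#'
#' @param prefix Path prefix used when writing.
#' @return A \linkS4class{Scene}.
#' @export
readScene <- function(prefix) {
    pages <- readTiff(paste0(prefix, ".tif"))
    side <- jsonlite::read_json(paste0(prefix, ".json"))
    channels <- stats::setNames(pages, unlist(side$channels))
    cells <- lapply(side$cells, function(cs) {
        cellSpec(center = unlist(cs$center), radius = cs$radius,
                 membraneThickness = cs$membraneThickness,
                 membraneFraction = cs$membraneFraction,
                 nucleusRadius = cs$nucleusRadius,
                 totalSignal = cs$totalSignal, erFraction = cs$erFraction,
                 transfected = cs$transfected,
                 swellingAreaRatio = cs$swellingAreaRatio)
    })
    spec <- sceneSpec(cells,
                      imageShape = as.integer(unlist(side$spec$imageShape)),
                      pixelSize = side$spec$pixelSize,
                      backgroundLevel = side$spec$backgroundLevel,
                      noiseGaussianSd = side$spec$noiseGaussianSd,
                      noisePoisson = side$spec$noisePoisson,
                      seed = side$spec$seed)
    masks <- lapply(seq_along(cells), function(i) {
        mk <- lapply(side$masks[[i]], unrleMask)
        mk$spec <- cells[[i]]
        mk
    })
    new("Scene", channels = channels, masks = masks, spec = spec)
}

## ---- ELISA plate CSV -------------------------------------------------------

#' Write / read an ELISA plate as CSV
#'
#' Columns: well, row, col, condition, repeat_id, replicate, absorbance
#' (plus protein_scale when present); blank wells carry condition "blank".
#'
#' @param plate An \linkS4class{ElisaPlate}.
#' @param path CSV path.
#' @return \code{writePlateCsv}: the path, invisibly; \code{readPlateCsv}:
#'   an \linkS4class{ElisaPlate}.
#' @export
writePlateCsv <- function(plate, path) {
    utils::write.csv(plateWells(plate), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writePlateCsv
#' @export
readPlateCsv <- function(path) {
    w <- utils::read.csv(path, stringsAsFactors = FALSE)
    new("ElisaPlate", wells = w, truth = NULL)
}
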