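#' @import methods
NULL

## ---------------------------------------------------------------------------
## CellSpec: ground truth for one synthetic cell
## ---------------------------------------------------------------------------

#' CellSpec: ground-truth parameters of one synthetic cell
#'
#' Describes a single circular cell in a synthetic scene: geometry (in
#' micrometres), how the tagged protein is partitioned between the plasma
#' membrane ring and the rest of the cell, and how much the cell swells after
#' hypotonic challenge.
#'
#' The tagged-protein model places a uniform density carrying
#' \code{(1 - membraneFraction) * totalSignal} over the whole cell footprint
#' (so at \code{membraneFraction = 0} ring and interior have identical
#' intensity: the "even distribution" reference state), plus an extra
#' \code{membraneFraction * totalSignal} spread uniformly over the membrane
#' ring. The nucleus is rendered at 20\% of the cytoplasmic density.
#'
#' @slot center Numeric length-2: (x, y) pixel coordinates (0-based, pixel
#'   centred) of the cell centre.
#' @slot radius Cell radius in micrometres.
#' @slot membraneThickness Membrane ring thickness in micrometres.
#' @slot membraneFraction Fraction of the total tagged-protein signal placed
#'   in the membrane ring, in [0, 1].
#' @slot nucleusRadius Nucleus radius in micrometres (must leave cytoplasm
#'   between nucleus and ring).
#' @slot totalSignal Integrated tagged-protein intensity (a.u.).
#' @slot erFraction Fraction of the intracellular signal relocated into ER
#'   puncta, in [0, 1].
#' @slot transfected Logical: does this cell express the tagged protein?
#' @slot swellingAreaRatio Post/pre cross-sectional area ratio (>= 0).
#' @export
setClass("CellSpec", representation(
    center = "numeric",
    radius = "numeric",
    membraneThickness = "numeric",
    membraneFraction = "numeric",
    nucleusRadius = "numeric",
    totalSignal = "numeric",
    erFraction = "numeric",
    transfected = "logical",
    swellingAreaRatio = "numeric"))

setValidity("CellSpec", function(object) {
    msg <- character()
    if (length(object@center) != 2L || any(!is.finite(object@center)))
        msg <- c(msg, "'center' must be two finite pixel coordinates")
    if (object@radius <= 0) msg <- c(msg, "'radius' must be > 0")
    if (object@membraneThickness <= 0 ||
        object@membraneThickness >= object@radius)
        msg <- c(msg, "'membraneThickness' must be in (0, radius)")
    if (object@membraneFraction < 0 || object@membraneFraction > 1)
        msg <- c(msg, "'membraneFraction' must be in [0, 1]")
    if (object@nucleusRadius < 0)
        msg <- c(msg, "'nucleusRadius' must be >= 0")
    if (object@nucleusRadius >= object@radius - object@membraneThickness)
        msg <- c(msg, "'nucleusRadius' must be < radius - membraneThickness")
    if (object@totalSignal < 0) msg <- c(msg, "'totalSignal' must be >= 0")
    if (object@erFraction < 0 || object@erFraction > 1)
        msg <- c(msg, "'erFraction' must be in [0, 1]")
    if (object@swellingAreaRatio < 0)
        msg <- c(msg, "'swellingAreaRatio' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a CellSpec
#'
#' @param center (x, y) pixel coordinates of the cell centre (0-based).
#' @param radius Cell radius, micrometres.
#' @param membraneThickness Ring thickness, micrometres.
#' @param membraneFraction Fraction of total signal in the ring, [0, 1].
#' @param nucleusRadius Nucleus radius, micrometres (0 = no nucleus).
#' @param totalSignal Integrated tagged-protein intensity, a.u.
#' @param erFraction Fraction of intracellular signal in ER puncta, [0, 1].
#' @param transfected Logical.
#' @param swellingAreaRatio Post/pre area ratio.
#' @return A \linkS4class{CellSpec}.
#' @examples
#' cellSpec(center = c(64, 64), membraneFraction = 0.5)
#' @export
cellSpec <- function(center, radius = 8, membraneThickness = 0.6,
                     membraneFraction = 0, nucleusRadius = 3,
                     totalSignal = 2e5, erFraction = 0,
                     transfected = TRUE, swellingAreaRatio = 1) {
    new("CellSpec", center = as.numeric(center), radius = radius,
        membraneThickness = membraneThickness,
        membraneFraction = membraneFraction, nucleusRadius = nucleusRadius,
        totalSignal = totalSignal, erFraction = erFraction,
        transfected = transfected, swellingAreaRatio = swellingAreaRatio)
}

## ---------------------------------------------------------------------------
## SceneSpec
## ---------------------------------------------------------------------------

#' SceneSpec: ground-truth parameters of a synthetic scene
#'
#' @slot imageShape Integer length-2 (rows, cols) in pixels.
#' @slot pixelSize Micrometres per pixel.
#' @slot cells List of \linkS4class{CellSpec}.
#' @slot backgroundLevel Background intensity (a.u.).
#' @slot noiseGaussianSd Additive Gaussian noise SD (a.u., 0 = off).
#' @slot noisePoisson Logical: apply Poisson (shot) noise before Gaussian.
#' @slot seed Integer RNG seed used for every random element of the render.
#' @export
setClass("SceneSpec", representation(
    imageShape = "integer",
    pixelSize = "numeric",
    cells = "list",
    backgroundLevel = "numeric",
    noiseGaussianSd = "numeric",
    noisePoisson = "logical",
    seed = "integer"))

setValidity("SceneSpec", function(object) {
    msg <- character()
    if (length(object@imageShape) != 2L || any(object@imageShape <= 0L))
        msg <- c(msg, "'imageShape' must be two positive integers")
    if (object@pixelSize <= 0) msg <- c(msg, "'pixelSize' must be > 0")
    if (object@noiseGaussianSd < 0)
        msg <- c(msg, "'noiseGaussianSd' must be >= 0")
    if (!all(vapply(object@cells, is, logical(1), "CellSpec")))
        msg <- c(msg, "'cells' must be a list of CellSpec")
    for (cs in object@cells) {
        rpx <- cs@radius / object@pixelSize
        if (cs@center[1] - rpx < 0 || cs@center[2] - rpx < 0 ||
            cs@center[1] + rpx > object@imageShape[2] - 1 ||
            cs@center[2] + rpx > object@imageShape[1] - 1)
            msg <- c(msg, "cell footprint extends outside the image")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' @param cells List of \linkS4class{CellSpec} (or a single CellSpec).
#' @param imageShape (rows, cols) in pixels.
#' @param pixelSize Micrometres per pixel.
#' @param backgroundLevel Background intensity, a.u.
#' @param noiseGaussianSd Additive Gaussian noise SD (0 = noise-free).
#' @param noisePoisson Apply Poisson noise.
#' @param seed Integer seed.
#' @return A \linkS4class{SceneSpec}.
#' @examples
#' sceneSpec(cellSpec(center = c(64, 64), membraneFraction = 1))
#' @export
sceneSpec <- function(cells, imageShape = c(128L, 128L), pixelSize = 0.2,
                      backgroundLevel = 10, noiseGaussianSd = 0,
                      noisePoisson = FALSE, seed = 1L) {
    if (is(cells, "CellSpec")) cells <- list(cells)
    new("SceneSpec", imageShape = as.integer(imageShape),
        pixelSize = pixelSize, cells = cells,
        backgroundLevel = backgroundLevel,
        noiseGaussianSd = noiseGaussianSd, noisePoisson = noisePoisson,
        seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Scene: rendered channels plus ground-truth masks
## ---------------------------------------------------------------------------

#' Scene: rendered synthetic micrograph with ground truth
#'
#' Channels are numeric matrices named \code{"protein"},
#' \code{"membrane_dye"} and (when ER puncta are present) \code{"er_marker"}.
#' Per-cell truth masks are logical matrices: whole cell, membrane ring,
#' interior (cell minus ring), nucleus and ER puncta.
#'
#' @slot channels Named list of numeric matrices.
#' @slot masks List (one element per cell) of named lists of logical matrices
#'   with entries \code{cell}, \code{ring}, \code{interior}, \code{nucleus},
#'   \code{er}.
#' @slot spec The generating \linkS4class{SceneSpec}.
#' @export
setClass("Scene", representation(
    channels = "list", masks = "list", spec = "SceneSpec"))

setValidity("Scene", function(object) {
    msg <- character()
    dims <- lapply(object@channels, dim)
    if (length(unique(dims)) > 1L)
        msg <- c(msg, "all channels must share one dimension")
    for (mk in object@masks) {
        if (any(mk$ring & mk$nucleus))
            msg <- c(msg, "membrane ring and nucleus masks must be disjoint")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Scene-class Retrieve one channel by name.
#' @param x,name Scene and channel name.
#' @export
setMethod("$", "Scene", function(x, name) x@channels[[name]])

#' Accessors for Scene objects
#'
#' \code{channelNames} lists rendered channels, \code{getChannel} extracts one
#' as a matrix, \code{sceneMasks} returns the per-cell truth masks and
#' \code{sceneSpecOf} the generating spec.
#'
#' @param scene A \linkS4class{Scene}.
#' @param name Channel name.
#' @return See individual descriptions.
#' @export
channelNames <- function(scene) names(scene@channels)

#' @rdname channelNames
#' @export
getChannel <- function(scene, name) {
    if (!name %in% names(scene@channels))
        stop("channel '", name, "' not present; available: ",
             paste(names(scene@channels), collapse = ", "))
    scene@channels[[name]]
}

#' @rdname channelNames
#' @export
sceneMasks <- function(scene) scene@masks

#' @rdname channelNames
#' @export
sceneSpecOf <- function(scene) scene@spec

setMethod("show", "Scene", function(object) {
    cat("Scene:", paste(dim(object@channels[[1]]), collapse = " x "),
        "px,", length(object@masks), "cell(s), channels:",
        paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "SceneSpec", function(object) {
    cat("SceneSpec:", paste(object@imageShape, collapse = " x "), "px @",
        object@pixelSize, "um/px,", length(object@cells), "cell(s), seed",
        object@seed, "\n")
})

## ---------------------------------------------------------------------------
## LineProfile
## ---------------------------------------------------------------------------

#' LineProfile: intensity samples along a segment crossing a cell
#'
#' @slot endpoints Numeric length-4 (x0, y0, x1, y1), 0-based pixel coords.
#' @slot positions Sample distances along the segment, micrometres, strictly
#'   increasing.
#' @slot intensities Sampled intensities (a.u.).
#' @slot cellId Integer cell label.
#' @export
setClass("LineProfile", representation(
    endpoints = "numeric", positions = "numeric",
    intensities = "numeric", cellId = "integer"))

setValidity("LineProfile", function(object) {
    msg <- character()
    if (length(object@endpoints) != 4L)
        msg <- c(msg, "'endpoints' must be (x0, y0, x1, y1)")
    if (length(object@positions) != length(object@intensities))
        msg <- c(msg, "'positions' and 'intensities' lengths differ")
    if (any(diff(object@positions) <= 0))
        msg <- c(msg, "'positions' must be strictly increasing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LineProfile", function(object) {
    cat("LineProfile: cell", object@cellId, ",",
        length(object@positions), "samples over",
        sprintf("%.2f", diff(range(object@positions))), "um\n")
})

## ---------------------------------------------------------------------------
## ElisaTruth / ElisaPlate
## ---------------------------------------------------------------------------

#' ElisaTruth: ground truth for a simulated biotinylation-ELISA plate
#'
#' @slot conditions Character condition labels.
#' @slot levels True surface-expression levels per condition (a.u., > 0).
#' @slot control Name of the control condition (fold reference).
#' @slot cv Multiplicative noise coefficient of variation (>= 0).
#' @slot nReplicateWells Technical replicate wells per lysate (default 3).
#' @slot nRepeats Biological repeats (independent lysates) per condition.
#' @slot blankLevel Blank absorbance (a.u.).
#' @slot seed Integer RNG seed.
#' @export
setClass("ElisaTruth", representation(
    conditions = "character", levels = "numeric", control = "character",
    cv = "numeric", nReplicateWells = "integer", nRepeats = "integer",
    blankLevel = "numeric", seed = "integer"))

setValidity("ElisaTruth", function(object) {
    msg <- character()
    if (length(object@levels) != length(object@conditions))
        msg <- c(msg, "'levels' must match 'conditions'")
    if (any(object@levels <= 0)) msg <- c(msg, "'levels' must be > 0")
    if (object@cv < 0) msg <- c(msg, "'cv' must be >= 0")
    if (object@nReplicateWells < 1L)
        msg <- c(msg, "'nReplicateWells' must be >= 1")
    if (object@nRepeats < 1L) msg <- c(msg, "'nRepeats' must be >= 1")
    if (length(object@control) == 1L && !is.na(object@control) &&
        !object@control %in% object@conditions)
        msg <- c(msg, "'control' must be one of 'conditions'")
    if (length(msg)) msg else TRUE
})

#' Construct an ElisaTruth
#'
#' @param conditions Character labels.
#' @param levels True levels (a.u.), same length.
#' @param control Control condition label (default: first condition).
#' @param cv Multiplicative noise CV.
#' @param nReplicateWells Wells per lysate.
#' @param nRepeats Biological repeats.
#' @param blankLevel Blank absorbance.
#' @param seed Integer seed.
#' @return An \linkS4class{ElisaTruth}.
#' @examples
#' elisaTruth(c("iso_340", "hypo_85"), c(1, 2.7), cv = 0.1)
#' @export
elisaTruth <- function(conditions, levels, control = conditions[1],
                       cv = 0.1, nReplicateWells = 3L, nRepeats = 3L,
                       blankLevel = 0.05, seed = 1L) {
    new("ElisaTruth", conditions = conditions, levels = levels,
        control = control, cv = cv,
        nReplicateWells = as.integer(nReplicateWells),
        nRepeats = as.integer(nRepeats), blankLevel = blankLevel,
        seed = as.integer(seed))
}

#' ElisaPlate: well absorbances with layout
#'
#' Wells live in a data frame with columns \code{well} (e.g. "A1"),
#' \code{row}, \code{col}, \code{condition} ("blank" for blank wells),
#' \code{repeat_id} (biological lysate index), \code{replicate} (technical
#' well index within lysate), \code{absorbance} and optionally
#' \code{protein_scale}.
#'
#' @slot wells data.frame as described.
#' @slot truth The generating \linkS4class{ElisaTruth}, or NULL for plates
#'   read from file.
#' @export
setClass("ElisaPlate", representation(wells = "data.frame", truth = "ANY"))

setValidity("ElisaPlate", function(object) {
    need <- c("well", "condition", "repeat_id", "replicate", "absorbance")
    miss <- setdiff(need, names(object@wells))
    msg <- character()
    if (length(miss))
        msg <- c(msg, paste("missing well columns:",
                            paste(miss, collapse = ", ")))
    else {
        if (any(object@wells$absorbance < 0))
            msg <- c(msg, "absorbance must be >= 0")
        nonblank <- object@wells[object@wells$condition != "blank", ]
        key <- paste(nonblank$condition, nonblank$repeat_id,
                     nonblank$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "replicate indices must be unique within lysate")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname channelNames
#' @param plate An \linkS4class{ElisaPlate}.
#' @export
plateWells <- function(plate) plate@wells

setMethod("show", "ElisaPlate", function(object) {
    w <- object@wells
    conds <- unique(w$condition[w$condition != "blank"])
    cat("ElisaPlate:", nrow(w), "wells,", length(conds), "condition(s) (",
        paste(conds, collapse = ", "), "),",
        sum(w$condition == "blank"), "blank(s)\n")
})

## ---------------------------------------------------------------------------
## RMETimeSeries
## ---------------------------------------------------------------------------

#' RMETimeSeries: RME as a function of time, with kinetic fit
#'
#' @slot times Seconds, strictly increasing.
#' @slot rme RME values per frame.
#' @slot condition Condition label.
#' @slot rho Ring/interior area ratio estimated from the frame-0 geometry
#'   (the RME/membrane-fraction calibration; NA when unknown).
#' @slot fit List with the fitted kinetics (see \code{\link{fitTimescale}}),
#'   or an empty list before fitting.
#' @export
setClass("RMETimeSeries", representation(
    times = "numeric", rme = "numeric", condition = "character",
    rho = "numeric", fit = "list"),
    prototype(rho = NA_real_))

setValidity("RMETimeSeries", function(object) {
    msg <- character()
    if (length(object@times) != length(object@rme))
        msg <- c(msg, "'times' and 'rme' lengths differ")
    if (any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly increasing")
    if (length(object@fit) && isTRUE(object@fit$response) &&
        is.finite(object@fit$tau) && object@fit$tau <= 0)
        msg <- c(msg, "fitted tau must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RMETimeSeries", function(object) {
    cat("RMETimeSeries:", length(object@times), "frames over",
        sprintf("%.0f s", diff(range(object@times))))
    if (length(object@fit)) {
        if (isTRUE(object@fit$response))
            cat(sprintf(", tau = %.1f s", object@fit$tau))
        else cat(", no response")
    }
    cat("\n")
})
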