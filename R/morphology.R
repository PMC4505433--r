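# Cell segmentation, pre/post matching and cross-sectional area change
# (the swelling readout). Percent change follows the convention of the
# source tables: post area as a percent of pre area, 100 = no change.

MIN_PARTICLE_PX <- 50L

#' Segment cells in a single channel
#'
#' Global Otsu threshold, hole filling, 8-connected component labelling and
#' removal of components smaller than \code{minSize} pixels. Labels are
#' stable across calls: components are numbered by centroid in row-major
#' order. The natural input is a membrane-dye channel (which marks every
#' cell, transfected or not); thresholding the bright ring and filling its
#' hole recovers the full cell footprint.
#'
#' @param image Numeric matrix.
#' @param minSize Minimum component size in pixels (default 50).
#' @return A list: \code{labels} (integer matrix, 0 = background) and
#'   \code{table} (data.frame with \code{cell_id}, \code{area_px},
#'   \code{centroid_x}, \code{centroid_y}).
#' @examples
#' sc <- renderScene(sceneSpec(cellSpec(center = c(64, 64))))
#' segmentCells(getChannel(sc, "membrane_dye"))$table
#' @export
segmentCells <- function(image, minSize = MIN_PARTICLE_PX) {
    th <- otsuThreshold(image)
    mask <- image > th
    if (!any(mask))
        return(list(labels = matrix(0L, nrow(image), ncol(image)),
                    table = data.frame(cell_id = integer(),
                                       area_px = integer(),
                                       centroid_x = numeric(),
                                       centroid_y = numeric())))
    mask <- fillHoles(mask)
    lab <- labelComponents(mask, 8L)
    ids <- setdiff(sort(unique(as.integer(lab))), 0L)
    keep <- ids[vapply(ids, function(i) sum(lab == i), integer(1)) >= minSize]
    out <- matrix(0L, nrow(image), ncol(image))
    tabs <- list()
    for (k in seq_along(keep)) {
        sel <- lab == keep[k]
        out[sel] <- k
        ij <- which(sel, arr.ind = TRUE)
        tabs[[k]] <- data.frame(cell_id = k, area_px = nrow(ij),
                                centroid_x = mean(ij[, 2] - 1),
                                centroid_y = mean(ij[, 1] - 1))
    }
    tab <- if (length(tabs)) do.call(rbind, tabs)
           else data.frame(cell_id = integer(), area_px = integer(),
                           centroid_x = numeric(), centroid_y = numeric())
    list(labels = out, table = tab)
}

#' Match cells between pre- and post-challenge segmentations
#'
#' Greedy nearest-neighbour matching of centroids, closest pairs first, with
#' a maximum displacement of 25\% of the mean cell diameter; unmatched cells
#' are dropped with a warning.
#'
#' @param segPre,segPost Outputs of \code{\link{segmentCells}} for the same
#'   field of view.
#' @return data.frame with columns \code{cell_id} (pre label),
#'   \code{cell_id_post}, \code{area_px_pre}, \code{area_px_post},
#'   \code{displacement_px}.
#' @export
matchCells <- function(segPre, segPost) {
    a <- segPre$table; b <- segPost$table
    if (nrow(a) == 0L || nrow(b) == 0L)
        return(data.frame(cell_id = integer(), cell_id_post = integer(),
                          area_px_pre = integer(), area_px_post = integer(),
                          displacement_px = numeric()))
    meanDiam <- mean(2 * sqrt(c(a$area_px, b$area_px) / pi))
    maxDisp <- 0.25 * meanDiam
    d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j)
        sqrt((a$centroid_x[i] - b$centroid_x[j])^2 +
             (a$centroid_y[i] - b$centroid_y[j])^2)))
    pairs <- list()
    usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
    ord <- order(d)
    for (k in ord) {
        if (d[k] > maxDisp) break
        i <- (k - 1) %% nrow(a) + 1; j <- (k - 1) %/% nrow(a) + 1
        if (usedA[i] || usedB[j]) next
        usedA[i] <- TRUE; usedB[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
            cell_id = a$cell_id[i], cell_id_post = b$cell_id[j],
            area_px_pre = a$area_px[i], area_px_post = b$area_px[j],
            displacement_px = d[k])
    }
    nDrop <- sum(!usedA) + sum(!usedB)
    if (nDrop > 0L)
        warning(nDrop, " unmatched cell(s) dropped from area statistics")
    if (length(pairs)) do.call(rbind, pairs)
    else data.frame(cell_id = integer(), cell_id_post = integer(),
                    area_px_pre = integer(), area_px_post = integer(),
                    displacement_px = numeric())
}

#' Classify a cell as transfected from the protein channel
#'
#' A cell is transfected when the mean protein intensity inside its mask is
#' strictly greater than the background mode plus three background standard
#' deviations (ties break to non-transfected).
#'
#' @param cellMask Logical matrix for one cell.
#' @param proteinChannel Numeric matrix.
#' @param backgroundMask Logical matrix of background pixels (outside all
#'   cells); when NULL, the complement of \code{cellMask} dilated by 2 px.
#' @return Logical.
#' @export
classifyTransfected <- function(cellMask, proteinChannel,
                                backgroundMask = NULL) {
    if (is.null(backgroundMask)) backgroundMask <- !dilateDisk(cellMask, 2L)
    bg <- proteinChannel[backgroundMask]
    thr <- intensityMode(bg) + 3 * stats::sd(bg)
    mean(proteinChannel[cellMask]) > thr
}

#' Percent area change per group
#'
#' Computes each matched cell's post area as a percent of its pre area and
#' averages within transfected / non-transfected groups; the \code{increase}
#' column is \code{mean - 100} (so the headline swelling readouts are the
#' transfected-vs-non-transfected increases).
#'
#' @param pairs data.frame from \code{\link{matchCells}} with an added
#'   logical column \code{transfected}; areas may be in px or micrometres
#'   squared (the percent change is unit-free).
#' @return data.frame with one row per present group: \code{transfected},
#'   \code{n}, \code{mean_pct}, \code{sem}, \code{increase}.
#' @export
areaChange <- function(pairs) {
    stopifnot(all(c("area_px_pre", "area_px_post", "transfected") %in%
                      names(pairs)))
    if (any(pairs$area_px_pre <= 0)) stop("pre areas must be > 0")
    pairs$pct <- 100 * pairs$area_px_post / pairs$area_px_pre
    out <- do.call(rbind, lapply(split(pairs, pairs$transfected),
        function(g) data.frame(transfected = g$transfected[1], n = nrow(g),
                               mean_pct = mean(g$pct), sem = semOf(g$pct),
                               increase = mean(g$pct) - 100)))
    rownames(out) <- NULL
    out
}

#' Segment, match and measure swelling for a pre/post scene pair
#'
#' Convenience wrapper for synthetic or real two-channel images: segments
#' both frames (membrane-dye channel when present, else protein), matches
#' cells, classifies transfection from the pre-frame protein channel and
#' returns per-cell and per-group area changes in micrometre units.
#'
#' @param scenePre,scenePost \linkS4class{Scene} objects (or lists with
#'   \code{channels} and \code{spec}).
#' @return List with \code{pairs} (per-cell data.frame, areas also in um^2)
#'   and \code{groups} (output of \code{\link{areaChange}}).
#' @export
measureSwelling <- function(scenePre, scenePost) {
    chn <- channelNames(scenePre)
    segCh <- if ("membrane_dye" %in% chn) "membrane_dye" else "protein"
    segPre <- segmentCells(getChannel(scenePre, segCh))
    segPost <- segmentCells(getChannel(scenePost, segCh))
    pairs <- matchCells(segPre, segPost)
    if (nrow(pairs) == 0L) return(list(pairs = pairs, groups = NULL))
    protein <- getChannel(scenePre, "protein")
    allCells <- segPre$labels > 0L
    bgMask <- !dilateDisk(allCells, 2L)
    pairs$transfected <- vapply(pairs$cell_id, function(id)
        classifyTransfected(segPre$labels == id, protein, bgMask),
        logical(1))
    px <- scenePre@spec@pixelSize
    pairs$area_um2_pre <- pairs$area_px_pre * px^2
    pairs$area_um2_post <- pairs$area_px_post * px^2
    list(pairs = pairs, groups = areaChange(pairs))
}
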