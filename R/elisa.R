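# Biotinylation-ELISA quantification: triplicate aggregation, blank
# subtraction, per-condition levels, fold changes and percent-of-reference.

#' Quantify surface expression from an ELISA plate
#'
#' Each lysate's value is the mean of its replicate wells minus the blank
#' mean (dedicated blank wells when present, else a configured scalar);
#' an optional \code{protein_scale} column divides each lysate value (total
#' protein normalization). Negative blank-subtracted values are floored at 0
#' with a warning. The per-condition level is the mean over biological
#' repeats with SEM across repeats.
#'
#' @param plate An \linkS4class{ElisaPlate}.
#' @param blank Scalar blank level used when the plate has no blank wells.
#' @return List: \code{perRepeat} (condition, repeat_id, value) and
#'   \code{summary} (condition, level, sem, n).
#' @examples
#' tr <- elisaTruth(c("ctl", "hypo"), c(0.3, 0.81), cv = 0, blankLevel = 0.02)
#' quantifyPlate(simulateElisaPlate(tr))$summary
#' @export
quantifyPlate <- function(plate, blank = NULL) {
    w <- plateWells(plate)
    blanks <- w[w$condition == "blank", ]
    if (nrow(blanks) > 0L) blankMean <- mean(blanks$absorbance)
    else if (!is.null(blank)) blankMean <- blank
    else stop("no blank wells present and no 'blank' level configured")
    s <- w[w$condition != "blank", ]
    key <- interaction(s$condition, s$repeat_id, drop = TRUE)
    perRepeat <- do.call(rbind, lapply(split(s, key), function(g) {
        val <- mean(g$absorbance) - blankMean
        if (!is.null(g$protein_scale)) val <- val / g$protein_scale[1]
        data.frame(condition = g$condition[1], repeat_id = g$repeat_id[1],
                   value = val)
    }))
    rownames(perRepeat) <- NULL
    if (any(perRepeat$value < 0)) {
        warning("negative blank-subtracted value(s) floored at 0")
        perRepeat$value <- pmax(perRepeat$value, 0)
    }
    summary <- do.call(rbind, lapply(split(perRepeat, perRepeat$condition),
        function(g) data.frame(condition = g$condition[1],
                               level = mean(g$value), sem = semOf(g$value),
                               n = nrow(g))))
    rownames(summary) <- NULL
    list(perRepeat = perRepeat, summary = summary)
}

#' Surface-expression fold change versus a control condition
#'
#' Default estimate: fold computed per biological repeat (pairing repeats by
#' index) and averaged, with SEM across repeats. Also reported: the
#' ratio-of-means estimate with a first-order (delta-method) SEM propagated
#' from repeat-level variability of numerator and denominator.
#'
#' @param quant Output of \code{\link{quantifyPlate}}.
#' @param control Control condition label.
#' @return data.frame per condition: \code{fold} (per-repeat mean),
#'   \code{fold_sem}, \code{fold_of_means}, \code{fold_of_means_sem},
#'   \code{n}.
#' @export
foldChange <- function(quant, control) {
    pr <- quant$perRepeat
    if (!control %in% pr$condition)
        stop("control condition '", control, "' not present")
    ctl <- pr[pr$condition == control, ]
    ctl <- ctl[order(ctl$repeat_id), ]
    if (mean(ctl$value) <= 0) stop("control level must be > 0")
    out <- do.call(rbind, lapply(split(pr, pr$condition), function(g) {
        g <- g[order(g$repeat_id), ]
        m <- min(nrow(g), nrow(ctl))
        ratios <- g$value[seq_len(m)] / ctl$value[seq_len(m)]
        num <- mean(g$value); den <- mean(ctl$value)
        fom <- num / den
        vNum <- stats::var(g$value) / nrow(g)
        vDen <- stats::var(ctl$value) / nrow(ctl)
        fomSem <- if (is.finite(vNum) && is.finite(vDen))
            fom * sqrt(vNum / num^2 + vDen / den^2) else NA_real_
        data.frame(condition = g$condition[1], fold = mean(ratios),
                   fold_sem = semOf(ratios), fold_of_means = fom,
                   fold_of_means_sem = fomSem, n = m)
    }))
    rownames(out) <- NULL
    out
}

#' Percent of a reference condition
#'
#' \code{100 * level / reference level} per condition (the normalization used
#' for constitutive surface expression of mutants relative to wild type);
#' conditions with level 0 are reported as 0\% and flagged low-expression.
#'
#' @param quant Output of \code{\link{quantifyPlate}}.
#' @param reference Reference condition label.
#' @return data.frame per condition: \code{pct_of_reference}, \code{sem},
#'   \code{low_expression}.
#' @export
pctOfReference <- function(quant, reference) {
    s <- quant$summary
    if (!reference %in% s$condition)
        stop("reference condition '", reference, "' not present")
    ref <- s$level[s$condition == reference]
    if (ref <= 0) stop("reference level must be > 0")
    data.frame(condition = s$condition,
               pct_of_reference = 100 * s$level / ref,
               sem = 100 * s$sem / ref,
               low_expression = s$level <= 0)
}
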