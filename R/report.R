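# Assembly of the translocation report: one row per condition/arm with
# isotonic RME, hypotonic RME, percent area change, significance and the
# yes/no translocation call. A row is called "Yes" if and only if the paired
# hypotonic-vs-isotonic test is significant after correction AND the
# hypotonic mean exceeds the isotonic mean; the ANOVA gate, when it fails,
# blocks every "Yes".

#' Build a translocation report table
#'
#' @param rows A list; each element describes one experimental arm with
#'   fields: \code{label}; \code{iso}, \code{hypo} (numeric repeat-vectors of
#'   RME, equal length); optionally \code{areaPct} (repeat-vector of percent
#'   area change, post as \% of pre) and \code{surfacePct} (repeat-vector of
#'   constitutive surface expression as \% of the reference) with
#'   \code{surfaceRefSignificant} (logical: is its difference from 100\%
#'   significant).
#' @param m Bonferroni multiplier: the number of planned comparisons in the
#'   design (default: number of rows).
#' @param gate Optional output of \code{\link{anovaGate}}; when it fails, all
#'   comparisons are reported non-significant and every call is "No".
#' @return data.frame of class \code{"translocationReport"}: per row the
#'   means and SEMs, test columns, the \code{translocation} call and an
#'   \code{anomalous} flag for significant decreases.
#' @export
buildReport <- function(rows, m = length(rows), gate = NULL) {
    gateFails <- !is.null(gate) && !isTRUE(gate$pass)
    out <- lapply(rows, function(r) {
        stopifnot(!is.null(r$label), !is.null(r$iso), !is.null(r$hypo))
        tt <- pairedT(r$iso, r$hypo, label = r$label, m = m)
        sig <- tt$significant && !gateFails
        isoM <- mean(r$iso); hypoM <- mean(r$hypo)
        call <- sig && hypoM > isoM
        anomalous <- sig && hypoM < isoM
        areaM <- areaS <- NA_real_
        if (!is.null(r$areaPct) && length(r$areaPct)) {
            areaM <- mean(r$areaPct); areaS <- semOf(r$areaPct)
        }
        surfM <- surfS <- NA_real_; surfSig <- FALSE
        if (!is.null(r$surfacePct) && length(r$surfacePct)) {
            surfM <- mean(r$surfacePct); surfS <- semOf(r$surfacePct)
            surfSig <- isTRUE(r$surfaceRefSignificant)
        }
        data.frame(label = r$label,
                   iso_rme = isoM, iso_sem = semOf(r$iso),
                   hypo_rme = hypoM, hypo_sem = semOf(r$hypo),
                   area_pct = areaM, area_sem = areaS,
                   statistic = tt$statistic, p_raw = tt$p_raw,
                   p_corrected = tt$p_corrected,
                   p_display = tt$p_display,
                   significant = sig,
                   translocation = ifelse(call, "Yes", "No"),
                   anomalous = anomalous,
                   surface_pct = surfM, surface_sem = surfS,
                   surface_significant = surfSig)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    attr(out, "m") <- m
    attr(out, "gate") <- gate
    class(out) <- c("translocationReport", class(out))
    out
}

fmtCell <- function(mean, sem, star = FALSE) {
    if (!is.finite(mean)) return("NA")
    s <- if (is.finite(sem)) sprintf("%.2f (%.2f)", mean, sem)
         else sprintf("%.2f (NA)", mean)
    if (star) paste0(s, "*") else s
}

#' Format a translocation report as aligned text
#'
#' Means to 2 decimal places with the SEM in parentheses and '*' marking
#' entries whose test is significant after correction; the Bonferroni m is
#' recorded in the footer for auditability.
#'
#' @param report Output of \code{\link{buildReport}}.
#' @return Character vector of lines (also printed by \code{print}).
#' @export
formatReport <- function(report) {
    hasSurf <- any(is.finite(report$surface_pct))
    hdr <- c("Condition", "Isotonic RME (+/- S.E.)",
             "Hypotonic RME (+/- S.E.)", "Mean % of area change (+/- S.E.)",
             "Translocation")
    if (hasSurf) hdr <- c(hdr, "Constitutive surface expression (% of ref)")
    rows <- lapply(seq_len(nrow(report)), function(i) {
        r <- report[i, ]
        cells <- c(r$label,
                   fmtCell(r$iso_rme, r$iso_sem),
                   fmtCell(r$hypo_rme, r$hypo_sem, star = r$significant),
                   fmtCell(r$area_pct, r$area_sem, star = r$significant &&
                               is.finite(r$area_pct)),
                   r$translocation)
        if (hasSurf)
            cells <- c(cells, fmtCell(r$surface_pct, r$surface_sem,
                                      star = r$surface_significant))
        cells
    })
    tab <- rbind(hdr, do.call(rbind, rows))
    widths <- apply(nchar(tab), 2, max)
    lines <- apply(tab, 1, function(rw)
        paste(mapply(formatC, rw, width = widths, flag = "-"),
              collapse = "  "))
    c(lines, sprintf("Bonferroni m = %d; * p < 0.05 after correction",
                     attr(report, "m")))
}

#' @export
print.translocationReport <- function(x, ...) {
    cat(paste(formatReport(x), collapse = "\n"), "\n")
    invisible(x)
}

#' Write / read a translocation report as CSV
#'
#' The CSV rendering round-trips: reading it back recovers identical numbers
#' at the stored precision.
#'
#' @param report Output of \code{\link{buildReport}}.
#' @param path File path.
#' @return \code{writeReportCsv} the path, invisibly; \code{readReportCsv}
#'   the data.frame.
#' @export
writeReportCsv <- function(report, path) {
    df <- as.data.frame(report)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReportCsv
#' @export
readReportCsv <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
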