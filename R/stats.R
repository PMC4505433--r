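# Statistical decision machinery: ANOVA gate, paired/unpaired t-tests,
# Bonferroni correction with the display convention of rounding corrected
# p-values UP to one significant figure, and the p < 0.05 significance rule.

#' Round a p-value up to one significant figure
#'
#' Ceiling on the leading digit (0.00102 -> 0.002), the display convention
#' for post-correction p-values.
#'
#' @param p Numeric vector in [0, 1].
#' @return Numeric vector, each element >= its input.
#' @examples
#' roundUpP(c(0.00102, 0.0009, 0.034))
#' @export
roundUpP <- function(p) {
    vapply(p, function(x) {
        if (!is.finite(x)) return(NA_real_)
        if (x <= 0) return(0)
        if (x >= 1) return(1)
        e <- floor(log10(x))
        d <- ceiling(round(x / 10^e, 9))
        if (d == 10) { d <- 1; e <- e + 1 }
        min(1, d * 10^e)
    }, numeric(1))
}

#' Bonferroni correction
#'
#' \code{p_corrected = min(1, m * p_raw)} with m the number of planned
#' comparisons; the display value rounds the corrected p up to one
#' significant figure.
#'
#' @param pRaw Numeric vector of raw p-values.
#' @param m Number of planned comparisons (must be at least
#'   \code{length(pRaw)}).
#' @return data.frame: \code{p_raw}, \code{p_corrected}, \code{p_display}.
#' @examples
#' bonferroni(0.0003, m = 3)  # corrected 0.0009
#' @export
bonferroni <- function(pRaw, m) {
    if (m < length(pRaw))
        stop("'m' must be >= the number of comparisons made")
    pc <- pmin(1, m * pRaw)
    data.frame(p_raw = pRaw, p_corrected = pc, p_display = roundUpP(pc))
}

tResultFrame <- function(label, statistic, pRaw, n, paired, m = 1L,
                         degenerate = FALSE) {
    pc <- min(1, m * pRaw)
    data.frame(comparison = label, statistic = statistic, p_raw = pRaw,
               p_corrected = pc, p_display = roundUpP(pc), n = n,
               paired = paired, significant = is.finite(pc) && pc < 0.05,
               degenerate = degenerate)
}

#' Two-sided paired t-test
#'
#' For experiments in which the same cells are measured before and after a
#' treatment. Zero variance of the differences is degenerate: p = 1 when all
#' differences are 0 (no change at all), otherwise the result is flagged and
#' p is NA.
#'
#' @param before,after Numeric vectors of equal length (>= 2), one value per
#'   experimental repeat.
#' @param label Comparison label.
#' @param m Bonferroni multiplier applied to the raw p (default 1 = none).
#' @return One-row data.frame: \code{comparison}, \code{statistic},
#'   \code{p_raw}, \code{p_corrected}, \code{p_display}, \code{n},
#'   \code{paired}, \code{significant}, \code{degenerate}.
#' @export
pairedT <- function(before, after, label = "after vs before", m = 1L) {
    if (length(before) != length(after))
        stop("'before' and 'after' must have equal length")
    if (length(before) < 2L) stop("paired t-test needs n >= 2")
    d <- after - before
    if (stats::sd(d) == 0) {
        if (all(d == 0))
            return(tResultFrame(label, 0, 1, length(d), TRUE, m))
        ## identical nonzero shift in every pair: t is unbounded; report the
        ## limit (p -> 0) and flag the degenerate variance
        return(tResultFrame(label, sign(mean(d)) * Inf, 0, length(d), TRUE,
                            m, degenerate = TRUE))
    }
    tt <- stats::t.test(after, before, paired = TRUE)
    tResultFrame(label, unname(tt$statistic), tt$p.value, length(d), TRUE, m)
}

#' Two-sided unpaired t-test (Welch by default)
#'
#' For experiments in which different cells receive different treatments.
#'
#' @param groupA,groupB Numeric vectors (each n >= 2).
#' @param label Comparison label.
#' @param varEqual Use the equal-variance (Student) form.
#' @param m Bonferroni multiplier.
#' @return One-row data.frame as \code{\link{pairedT}}.
#' @export
unpairedT <- function(groupA, groupB, label = "A vs B", varEqual = FALSE,
                      m = 1L) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("unpaired t-test needs n >= 2 in each group")
    if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
        if (mean(groupA) == mean(groupB))
            return(tResultFrame(label, 0, 1,
                                length(groupA) + length(groupB), FALSE, m))
        return(tResultFrame(label, sign(mean(groupA) - mean(groupB)) * Inf,
                            0, length(groupA) + length(groupB), FALSE, m,
                            degenerate = TRUE))
    }
    tt <- stats::t.test(groupA, groupB, var.equal = varEqual)
    tResultFrame(label, unname(tt$statistic), tt$p.value,
                 length(groupA) + length(groupB), FALSE, m)
}

#' One-way repeated-measures ANOVA gate
#'
#' Multiple treatments of the same cells are first screened by one-way
#' repeated-measures ANOVA (subject = repeat index); pairwise tests should
#' only be interpreted when the gate passes (p < 0.05). Unbalanced input
#' falls back to ordinary one-way ANOVA with a warning. Two groups are an
#' error (use a t-test directly).
#'
#' @param groups List of at least 3 numeric repeat-vectors (each n >= 2).
#' @return List: \code{pass}, \code{F}, \code{p}, \code{df},
#'   \code{repeated} (whether the within-subject form was used).
#' @examples
#' anovaGate(list(c(10, 11, 12), c(10, 11, 12), c(30, 31, 32)))$pass
#' @export
anovaGate <- function(groups) {
    if (length(groups) < 3L)
        stop("ANOVA gate needs >= 3 groups; use a t-test for 2")
    if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
    ns <- lengths(groups)
    k <- length(groups)
    y <- unlist(groups, use.names = FALSE)
    g <- rep(seq_len(k), ns)
    balanced <- length(unique(ns)) == 1L
    if (balanced) {
        n <- ns[1]
        subj <- rep(seq_len(n), k)
        gm <- mean(y)
        ssTreat <- n * sum((tapply(y, g, mean) - gm)^2)
        ssSubj <- k * sum((tapply(y, subj, mean) - gm)^2)
        ssTot <- sum((y - gm)^2)
        ssErr <- ssTot - ssTreat - ssSubj
        dfT <- k - 1L; dfE <- (k - 1L) * (n - 1L)
        Fv <- if (ssTreat == 0) 0
              else if (ssErr <= 1e-12) Inf
              else (ssTreat / dfT) / (ssErr / dfE)
        p <- if (ssTreat == 0) 1
             else if (!is.finite(Fv)) 0
             else stats::pf(Fv, dfT, dfE, lower.tail = FALSE)
        repeated <- TRUE
        df <- c(dfT, dfE)
    } else {
        warning("unbalanced groups: falling back to ordinary one-way ANOVA")
        fit <- stats::anova(stats::lm(y ~ factor(g)))
        Fv <- fit$`F value`[1]; p <- fit$`Pr(>F)`[1]
        repeated <- FALSE
        df <- fit$Df
    }
    list(pass = is.finite(p) && p < 0.05, F = Fv, p = p, df = df,
         repeated = repeated)
}
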