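# Simulated biotinylation-ELISA plates. Wells mirror a 96-well layout
# (rows A-H, columns 1-12); each biological repeat (lysate) of each condition
# occupies nReplicateWells consecutive wells.

#' Simulate a biotinylation-ELISA plate
#'
#' Generates well absorbances
#' \code{absorbance = blankLevel + level * exp(eps)}, with
#' \code{eps ~ Normal(0, cv)} independently per well, for every biological
#' repeat (lysate) of every condition; blank wells carry
#' \code{blankLevel * exp(eps)}. The layout (well ids, rows, columns) mirrors
#' a 96-well plate filled row-major. Output is deterministic given the seed.
#'
#' @param truth An \linkS4class{ElisaTruth}.
#' @param nBlankWells Number of blank wells (default 3).
#' @return An \linkS4class{ElisaPlate}.
#' @examples
#' tr <- elisaTruth(c("iso_340", "hypo_85"), c(1, 2.7), cv = 0)
#' plateWells(simulateElisaPlate(tr))
#' @export
simulateElisaPlate <- function(truth, nBlankWells = 3L) {
    validObject(truth)
    rows <- LETTERS[1:8]
    wellId <- function(i) {
        r <- (i - 1L) %/% 12L + 1L; c <- (i - 1L) %% 12L + 1L
        if (r > 8L) stop("plate layout exceeds 96 wells")
        c(paste0(rows[r], c), r, c)
    }
    recs <- list(); i <- 0L
    for (ci in seq_along(truth@conditions)) {
        for (rep_id in seq_len(truth@nRepeats)) {
            for (tech in seq_len(truth@nReplicateWells)) {
                i <- i + 1L
                w <- wellId(i)
                recs[[length(recs) + 1L]] <- data.frame(
                    well = w[1], row = as.integer(w[2]), col = as.integer(w[3]),
                    condition = truth@conditions[ci], repeat_id = rep_id,
                    replicate = tech, level = truth@levels[ci],
                    stringsAsFactors = FALSE)
            }
        }
    }
    for (b in seq_len(nBlankWells)) {
        i <- i + 1L
        w <- wellId(i)
        recs[[length(recs) + 1L]] <- data.frame(
            well = w[1], row = as.integer(w[2]), col = as.integer(w[3]),
            condition = "blank", repeat_id = b, replicate = 1L,
            level = 0, stringsAsFactors = FALSE)
    }
    wells <- do.call(rbind, recs)
    wells$absorbance <- withSeed(truth@seed, {
        eps <- stats::rnorm(nrow(wells), 0, truth@cv)
        ifelse(wells$condition == "blank",
               truth@blankLevel * exp(eps),
               truth@blankLevel + wells$level * exp(eps))
    })
    wells$level <- NULL
    new("ElisaPlate", wells = wells, truth = truth)
}
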