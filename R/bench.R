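#' Species discrimination ratio of barcoded reads
#'
#' For each species s: the fraction of reads assigned to species-s genes
#' that carry a barcode of species s, among all species-s reads with any
#' accepted barcode. A species with zero mapped reads is reported as NA.
#'
#' @param assignments data.frame from [assignTranscripts()] (needs
#'   \code{species}, \code{status}).
#' @param parsed matching data.frame from [parseReads()] (needs
#'   \code{barcode_id}).
#' @param speciesOfBarcode named character vector mapping barcode_id ->
#'   species.
#' @return named numeric vector of per-species fractions, with attributes
#'   \code{n} (denominators per species).
#' @export
discriminationRatio <- function(assignments, parsed, speciesOfBarcode) {
    stopifnot(identical(assignments$read_id, parsed$read_id))
    keep <- assignments$status == "assigned" & !is.na(assignments$species) &
        parsed$barcode_id %in% names(speciesOfBarcode)
    sp <- assignments$species[keep]
    bcsp <- unname(speciesOfBarcode[parsed$barcode_id[keep]])
    speciesSet <- sort(unique(unname(speciesOfBarcode)))
    out <- setNames(rep(NA_real_, length(speciesSet)), speciesSet)
    ns <- setNames(integer(length(speciesSet)), speciesSet)
    for (s in speciesSet) {
        den <- sp == s
        ns[s] <- sum(den)
        if (ns[s] > 0L) out[s] <- sum(den & bcsp == s) / ns[s]
    }
    attr(out, "n") <- ns
    out
}

#' Summarize discrimination across replicates
#'
#' @param ratios list of per-replicate vectors from
#'   [discriminationRatio()].
#' @return data.frame species, mean, sd, n_replicates.
#' @export
discriminationSummary <- function(ratios) {
    m <- do.call(rbind, lapply(ratios, as.numeric))
    colnames(m) <- names(ratios[[1L]])
    data.frame(species = colnames(m),
               mean = colMeans(m, na.rm = TRUE),
               sd = apply(m, 2L, sd, na.rm = TRUE),
               n_replicates = colSums(!is.na(m)), row.names = NULL)
}

#' Pseudo-bulk pooling of single-cell counts
#'
#' Pools the counts of all cells whose type is in \code{include} and not in
#' \code{exclude}, emulating a bulk measurement of the selected
#' populations; also returns the per-cell mean (pooled / number of pooled
#' cells).
#'
#' @param counts matrix, genes x cells.
#' @param cellTypes character vector of cell-type labels, one per column.
#' @param include cell types to pool.
#' @param exclude cell types to drop even if listed in \code{include}
#'   (e.g. a subtype whose cell bodies lie outside the barcoded layer).
#' @return list with \code{pooled} (named numeric per gene),
#'   \code{per_cell_mean} and \code{n_cells}.
#' @export
pseudobulk <- function(counts, cellTypes, include, exclude = character(0)) {
    if (length(cellTypes) != ncol(counts))
        stop("'cellTypes' must have one label per column of 'counts'")
    sel <- cellTypes %in% include & !(cellTypes %in% exclude)
    if (!any(sel)) stop("no cells selected: empty included set")
    pooled <- rowSums(counts[, sel, drop = FALSE])
    list(pooled = pooled, per_cell_mean = pooled / sum(sel),
         n_cells = sum(sel))
}

#' Expected transcript count from an smFISH reference
#'
#' Average puncta per cell for the gene over all non-excluded cells, scaled
#' by the estimated number of cells in the sequenced population.
#'
#' @param smfish long-form reference data.frame (\code{cell_id},
#'   \code{subtype}, \code{gene}, \code{count}), as from
#'   [simulateSmFISHReference()] or read from TSV.
#' @param gene gene to evaluate (must be present).
#' @param nCells estimated cells in the sequenced population (> 0).
#' @param excludeSubtypes subtype labels removed before averaging
#'   (e.g. "BC1B").
#' @return expected transcript count.
#' @export
expectedTranscripts <- function(smfish, gene, nCells,
                                excludeSubtypes = character(0)) {
    if (nCells <= 0) stop("'nCells' must be > 0")
    rows <- smfish[!(smfish$subtype %in% excludeSubtypes), , drop = FALSE]
    sel <- rows[rows$gene == gene, , drop = FALSE]
    if (!nrow(sel)) stop("gene '", gene, "' absent from the smFISH reference")
    mean(sel$count) * nCells
}

#' Detection sensitivity relative to an smFISH expectation
#'
#' Reported as a percentage, observed / expected * 100 by default (the
#' orientation consistent with sensitivities of a few percent). The
#' inverted ratio expected / observed is available behind \code{invert}.
#'
#' @param observed observed deduplicated molecule count(s) for the gene.
#' @param expected expected transcript count(s) (> 0).
#' @param invert report expected / observed instead.
#' @return sensitivity in percent (vectorized).
#' @examples
#' sensitivity(43, 1000)  # 4.3
#' @export
sensitivity <- function(observed, expected, invert = FALSE) {
    if (any(expected <= 0)) stop("'expected' must be > 0")
    r <- if (invert) expected / observed else observed / expected
    100 * r
}

#' Layer marker sets from pairwise differential-expression tables
#'
#' A gene is a marker of region R iff, in both of R's pairwise comparisons,
#' its adjusted p-value is below \code{alpha} and the fold-change direction
#' favors R. Adjusted p-values are consumed, not computed. Marker sets are
#' disjoint by construction.
#'
#' @param deTables named list of pairwise tables; names are
#'   \code{"A_vs_B"} and each table has \code{gene_id}, \code{log2fc}
#'   (positive = enriched in A) and \code{padj}.
#' @param regions the three (or more) region names.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return named list of marker gene-id vectors, one per region.
#' @export
layerMarkers <- function(deTables, regions, alpha = 0.05) {
    parseName <- function(nm) strsplit(nm, "_vs_", fixed = TRUE)[[1L]]
    pairs <- lapply(names(deTables), parseName)
    universe <- Reduce(intersect, lapply(deTables, function(t) t$gene_id))
    if (any(vapply(deTables, nrow, 0L) != length(universe)))
        warning("inconsistent gene universes; restricting to intersection")
    out <- list()
    for (R in regions) {
        enriched <- NULL
        found <- 0L
        for (i in seq_along(deTables)) {
            ab <- pairs[[i]]
            if (!(R %in% ab)) next
            found <- found + 1L
            t <- deTables[[i]]
            t <- t[t$gene_id %in% universe, , drop = FALSE]
            dirOk <- if (ab[1L] == R) t$log2fc > 0 else t$log2fc < 0
            g <- t$gene_id[dirOk & t$padj < alpha]
            enriched <- if (is.null(enriched)) g else intersect(enriched, g)
        }
        if (found < length(regions) - 1L)
            stop("missing pairwise table(s) for region '", R, "'")
        out[[R]] <- sort(enriched)
    }
    out
}

#' Gene body coverage profile over percentile bins
#'
#' Maps each read's transcript position to the percentile bin
#' \code{floor(100 * pos / length)} (0-based position in [0, length)) and
#' normalizes the binned profile to a maximum of 1. Internal priming yields
#' a flat profile; 3'-anchored capture concentrates mass at one end.
#'
#' @param positions 0-based read positions along their transcripts.
#' @param lengths matching transcript lengths.
#' @return numeric vector of 100 bin heights (max 1; all zero for empty
#'   input); attribute \code{"rejected"} counts positions >= length.
#' @export
geneBodyCoverage <- function(positions, lengths) {
    if (length(positions) != length(lengths))
        stop("'positions' and 'lengths' must align")
    bad <- positions >= lengths | positions < 0
    nrej <- sum(bad)
    positions <- positions[!bad]; lengths <- lengths[!bad]
    bins <- floor(100 * positions / lengths)
    prof <- tabulate(bins + 1L, nbins = 100L)
    if (max(prof) > 0L) prof <- prof / max(prof)
    structure(as.numeric(prof), rejected = nrej)
}

#' Chimeric pair fraction
#'
#' Among read pairs whose mates both received a unique gene assignment, the
#' fraction assigned to different genes. With no doubly assigned pairs the
#' fraction is undefined (NA, flagged with a warning).
#'
#' @param assignR1,assignR2 assignment data.frames for Read 1 and Read 2
#'   (paired by \code{read_id}).
#' @return fraction in [0, 1] (or NA); attribute \code{"n_pairs"}.
#' @export
chimericPairFraction <- function(assignR1, assignR2) {
    m <- merge(assignR1[assignR1$status == "assigned",
                        c("read_id", "gene_id")],
               assignR2[assignR2$status == "assigned",
                        c("read_id", "gene_id")],
               by = "read_id", suffixes = c("_r1", "_r2"))
    if (!nrow(m)) {
        warning("no pairs with both mates assigned; fraction undefined")
        return(structure(NA_real_, n_pairs = 0L))
    }
    structure(mean(m$gene_id_r1 != m$gene_id_r2), n_pairs = nrow(m))
}

#' Pairwise replicate correlation of normalized expression
#'
#' Pearson correlation between replicate columns of a log2(TPM + 1)
#' matrix, on all shared genes and on the top \code{topN} genes by mean
#' expression. Zero-variance vectors give NA for that pair.
#'
#' @param logTpm matrix, genes x replicates, of log2(TPM + 1) values.
#' @param topN number of top expressed genes for the focused correlation
#'   (default 200, capped at the gene count).
#' @return data.frame with one row per replicate pair: \code{rep_a},
#'   \code{rep_b}, \code{r_all}, \code{r_top}.
#' @export
replicateCorrelation <- function(logTpm, topN = 200L) {
    if (ncol(logTpm) < 2L) stop("need at least two replicates")
    topN <- min(topN, nrow(logTpm))
    top <- order(rowMeans(logTpm), decreasing = TRUE)[seq_len(topN)]
    cp <- utils::combn(ncol(logTpm), 2L)
    safeCor <- function(a, b) {
        if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
        cor(a, b)
    }
    data.frame(
        rep_a = colnames(logTpm)[cp[1L, ]] %||% cp[1L, ],
        rep_b = colnames(logTpm)[cp[2L, ]] %||% cp[2L, ],
        r_all = apply(cp, 2L, function(p)
            safeCor(logTpm[, p[1L]], logTpm[, p[2L]])),
        r_top = apply(cp, 2L, function(p)
            safeCor(logTpm[top, p[1L]], logTpm[top, p[2L]])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
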