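#' Collapse a UMI multiset to a molecule count (directional adjacency)
#'
#' Reimplements the directional-adjacency deduplication rule: build a
#' directed edge u -> v between UMIs at Hamming distance 1 whenever
#' count(u) >= 2 * count(v) - 1, then count the clusters formed by
#' breadth-first absorption starting from the most abundant unvisited UMI
#' (ties broken lexicographically, so the result is independent of input
#' order). Each cluster is one molecule.
#'
#' @param umis character vector of observed UMIs (with repeats), or a named
#'   integer vector of counts per unique UMI.
#' @return integer molecule count.
#' @examples
#' dedupUMIs(c(rep("AAAA", 10), "AAAT"))  # 1
#' dedupUMIs(c(rep("AAAA", 5), rep("TTTT", 5)))  # 2
#' @export
dedupUMIs <- function(umis) {
    if (!length(umis)) return(0L)
    if (!is.null(names(umis)) && is.numeric(umis)) {
        cnt <- as.integer(umis)
        names(cnt) <- names(umis)
    } else {
        tab <- table(umis)
        cnt <- as.integer(tab)
        names(cnt) <- names(tab)
    }
    u <- names(cnt)
    if (length(unique(nchar(u))) > 1L)
        stop("UMIs must all have the same length")
    n <- length(u)
    if (n == 1L) return(1L)
    # order by count desc, then lexicographic, for order independence
    ord <- order(-cnt, u)
    cnt <- cnt[ord]; u <- u[ord]
    w <- nchar(u[1L])
    chars <- matrix(utf8ToInt(paste(u, collapse = "")), nrow = w)
    # adjacency: Hamming distance 1
    adj <- vector("list", n)
    for (i in seq_len(n - 1L)) {
        d <- colSums(chars[, (i + 1L):n, drop = FALSE] != chars[, i])
        nb <- which(d == 1L) + i
        adj[[i]] <- c(adj[[i]], nb)
        for (j in nb) adj[[j]] <- c(adj[[j]], i)
    }
    visited <- rep(FALSE, n)
    clusters <- 0L
    for (root in seq_len(n)) {
        if (visited[root]) next
        clusters <- clusters + 1L
        queue <- root
        visited[root] <- TRUE
        while (length(queue)) {
            node <- queue[[1L]]; queue <- queue[-1L]
            for (nb in adj[[node]]) {
                if (!visited[nb] && cnt[node] >= 2L * cnt[nb] - 1L) {
                    visited[nb] <- TRUE
                    queue <- c(queue, nb)
                }
            }
        }
    }
    clusters
}

#' Deduplicated gene x barcode molecule counts
#'
#' Groups accepted, uniquely assigned reads by (gene, barcode) and collapses
#' each group's UMI multiset with [dedupUMIs()]. Genes whose unique UMI
#' count trips the saturation guard are dropped (and reported), mirroring
#' the exclusion of rRNA-like genes whose mapped reads approach the UMI
#' diversity.
#'
#' @param assignments data.frame from [assignTranscripts()] /
#'   [rescueReads()].
#' @param parsed matching data.frame from [parseReads()].
#' @param umiLen UMI length in nt (for the saturation guard).
#' @param saturationThreshold fraction of 4^umiLen at which a (gene,
#'   barcode) group is dropped; NULL disables the guard.
#' @return a [UMICountMatrix-class]; attribute \code{"dropped"} lists the
#'   guard decisions (data.frame gene, barcode, unique_umis, limit).
#' @export
countMolecules <- function(assignments, parsed, umiLen = 8L,
                           saturationThreshold = 0.9) {
    stopifnot(identical(assignments$read_id, parsed$read_id))
    keep <- assignments$status == "assigned"
    df <- data.frame(gene = assignments$gene_id[keep],
                     barcode = parsed$barcode_id[keep],
                     umi = parsed$umi[keep], stringsAsFactors = FALSE)
    genes <- sort(unique(df$gene))
    bars <- sort(unique(df$barcode))
    counts <- matrix(0L, length(genes), length(bars),
                     dimnames = list(genes, bars))
    dropped <- list()
    if (nrow(df)) {
        grp <- split(df$umi, list(df$gene, df$barcode), drop = TRUE,
                     sep = "\r")
        for (g in names(grp)) {
            parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
            uniq <- length(unique(grp[[g]]))
            if (!is.null(saturationThreshold)) {
                guard <- saturationGuard(parts[1L], uniq, umiLen,
                                         saturationThreshold)
                if (guard) {
                    dropped[[length(dropped) + 1L]] <- data.frame(
                        gene = parts[1L], barcode = parts[2L],
                        unique_umis = uniq,
                        limit = attr(guard, "limit"))
                    next
                }
            }
            counts[parts[1L], parts[2L]] <- dedupUMIs(grp[[g]])
        }
    }
    out <- UMICountMatrix(counts)
    attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
        else NULL
    out
}

#' UMI saturation guard
#'
#' Drops a gene when its unique UMI count comes close to or exceeds the
#' number of possible UMIs (which stalls deduplication): drop iff
#' \code{uniqueUMIs >= floor(fractionThreshold * 4^umiLen)} (the limit is
#' an integer count of UMIs). The decision and both numbers are attached
#' as attributes.
#'
#' @param geneId gene identifier (for the log message).
#' @param uniqueUMIs observed unique UMI count.
#' @param umiLen UMI length in nt.
#' @param fractionThreshold fraction of saturation in (0, 1] at which to
#'   drop (default 0.9).
#' @return logical: TRUE = drop; attributes \code{limit} and
#'   \code{unique_umis}.
#' @examples
#' saturationGuard("rRNA1", 65000, 8, 0.9)  # TRUE: 65000 >= 58982
#' @export
saturationGuard <- function(geneId, uniqueUMIs, umiLen = 8L,
                            fractionThreshold = 0.9) {
    if (fractionThreshold <= 0 || fractionThreshold > 1)
        stop("'fractionThreshold' must be in (0, 1]")
    limit <- floor(fractionThreshold * 4^umiLen)
    drop <- uniqueUMIs >= limit
    if (drop)
        message("saturation guard: dropping '", geneId, "' (",
                uniqueUMIs, " unique UMIs >= ", format(limit), ")")
    structure(drop, limit = limit, unique_umis = uniqueUMIs)
}

#' log2(TPM + 1) normalization
#'
#' Transcripts per million: per-gene counts are divided by gene length in
#' kilobases, scaled so each sample sums to one million, then
#' log2-transformed with a pseudocount of 1. TPM columns sum to 10^6
#' exactly (up to floating point) unless a sample is all zero, which
#' returns zeros with a warning.
#'
#' @param counts matrix (genes x samples) or vector of counts.
#' @param lengthsNt gene lengths in nt, aligned with rows.
#' @return matrix (or vector) of log2(TPM + 1) values.
#' @export
log2Tpm <- function(counts, lengthsNt) {
    vec <- is.null(dim(counts))
    m <- as.matrix(counts)
    if (length(lengthsNt) != nrow(m))
        stop("'lengthsNt' must align with rows of 'counts'")
    if (any(lengthsNt <= 0)) stop("gene lengths must be > 0")
    rate <- m / (lengthsNt / 1000)
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero)) {
        warning("all-zero sample(s): ",
                paste(which(zero), collapse = ", "))
        tot[zero] <- 1
    }
    tpm <- sweep(rate, 2L, tot, "/") * 1e6
    out <- log2(tpm + 1)
    if (vec) out[, 1L] else out
}

#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM = count / (length_nt / 1000) / (total / 10^6)}: read counts
#' divided by transcript length in kilobases and again by the
#' per-condition total scaled to millions.
#'
#' @param count read count(s) for the transcript(s).
#' @param lengthNt transcript length(s) in nt (> 0).
#' @param totalReads total reads in the condition (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(100, 2000, 1e6)  # 50
#' @export
rpkm <- function(count, lengthNt, totalReads) {
    if (any(lengthNt <= 0)) stop("'lengthNt' must be > 0")
    if (any(totalReads <= 0)) stop("'totalReads' must be > 0")
    count / (lengthNt / 1000) / (totalReads / 1e6)
}

#' UMIs per unit barcoded area
#'
#' Normalizes a barcode's total deduplicated UMI count to the 10 x 10 um^2
#' unit area, making yields comparable across arbitrarily sized ROIs.
#'
#' @param totalUMIs total molecules for the barcode.
#' @param barcodedAreaUm2 barcoded area in um^2 (> 0), from
#'   [maskArea()] or an external measurement.
#' @param unitAreaUm2 the unit area (default 100 um^2).
#' @return UMIs per unit area.
#' @examples
#' umisPerUnitArea(1e5, 1e4)  # 1000
#' @export
umisPerUnitArea <- function(totalUMIs, barcodedAreaUm2, unitAreaUm2 = 100) {
    if (any(barcodedAreaUm2 <= 0)) stop("'barcodedAreaUm2' must be > 0")
    totalUMIs * unitAreaUm2 / barcodedAreaUm2
}

#' Arclength-scaled cell count estimate
#'
#' Scales a nuclei count made over a small portion of a layer's arclength
#' to the full barcoded arclength:
#' \code{total = arcTotal * cellsSmall / arcSmall}. Optionally the result
#' is multiplied by the bipolar fraction (72% of DAPI-stained nuclei in the
#' bipolar cell layer are bipolar cells) when the estimate should count
#' only that population. The fractional result is returned unrounded;
#' round half-up only at report time.
#'
#' @param arcTotal full arclength in um.
#' @param arcSmall measured sub-arclength in um (> 0).
#' @param cellsSmall nuclei counted along \code{arcSmall}.
#' @param applyBipolarFraction multiply by \code{bipolarFraction}.
#' @param bipolarFraction default 0.72.
#' @return estimated cell count (fractional).
#' @examples
#' estimateCells(1000, 200, 60)        # 300
#' estimateCells(1000, 200, 60, TRUE)  # 216
#' @export
estimateCells <- function(arcTotal, arcSmall, cellsSmall,
                          applyBipolarFraction = FALSE,
                          bipolarFraction = 0.72) {
    if (arcSmall <= 0) stop("'arcSmall' must be > 0")
    if (arcSmall > arcTotal) stop("'arcSmall' cannot exceed 'arcTotal'")
    total <- arcTotal * cellsSmall / arcSmall
    if (applyBipolarFraction) total <- total * bipolarFraction
    total
}
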