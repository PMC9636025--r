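#' Parse barcoded Read 1 sequences and demultiplex by exact barcode match
#'
#' Extracts barcode, UMI and mappable cDNA from fixed-layout Read 1
#' sequences. The first \code{barcodeLen} bases are compared to the
#' whitelist by exact string equality only (no mismatch tolerance, unless
#' the optional correction mode is enabled); the next \code{umiLen} bases
#' are the UMI. The junction remnant is trimmed adaptively: 7 bases are
#' always skipped, and an 8th is skipped iff it equals the A-tail extension
#' base, resolving the 7-vs-8 nt junction ambiguity at parse time (a
#' misresolved A shifts the cDNA by 1 nt, which downstream k-mer assignment
#' tolerates). The remainder is truncated to \code{cdnaMapLen}.
#'
#' Parsing is pure and order-independent: chunked and whole-file runs agree
#' exactly.
#'
#' @param reads named character vector (or [Biostrings::DNAStringSet]) of
#'   Read 1 sequences; names are read ids.
#' @param layout a [ReadLayout-class].
#' @param whitelist whitelist data.frame with \code{barcode_id} and
#'   \code{sequence}.
#' @param correctBarcodes if TRUE, additionally accept barcodes at Hamming
#'   distance 1 from exactly one whitelist entry (off by default; the
#'   default pipeline demultiplexes by exact matches only).
#' @return data.frame with one row per read: \code{read_id},
#'   \code{barcode_id} (or \code{"REJECTED"}), \code{umi}, \code{cdna},
#'   \code{accepted}, \code{reason} ("" / "length" / "barcode").
#' @examples
#' wl <- data.frame(barcode_id = "BC1", sequence = strrep("A", 12))
#' parseReads(c(r1 = paste0(strrep("A", 12), strrep("C", 8),
#'                          "TCAGGTC", "GATTACA")), ReadLayout(), wl)
#' @export
parseReads <- function(reads, layout = ReadLayout(), whitelist,
                       correctBarcodes = FALSE) {
    stopifnot(is(layout, "ReadLayout"))
    if (is(reads, "XStringSet")) reads <- setNames(as.character(reads),
                                                   names(reads))
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%08d", seq_along(reads))
    n <- length(reads)
    bl <- layout@barcodeLen; ul <- layout@umiLen
    jl <- nchar(layout@junctionSeq)
    minLen <- bl + ul + jl + 1L + 1L   # barcode+UMI+max junction+1 cDNA base
    len <- nchar(reads)
    tooShort <- len < minLen
    bc <- substr(reads, 1L, bl)
    hit <- match(bc, whitelist$sequence)
    if (correctBarcodes && anyNA(hit)) {
        miss <- which(is.na(hit) & !tooShort)
        for (i in miss) {
            d <- mismatchCount(rep(bc[i], nrow(whitelist)),
                               whitelist$sequence)
            if (sum(d <= 1L) == 1L) hit[i] <- which(d <= 1L)
        }
    }
    noBarcode <- is.na(hit) & !tooShort
    accepted <- !tooShort & !is.na(hit)
    umi <- ifelse(accepted, substr(reads, bl + 1L, bl + ul), "")
    # adaptive junction trim: always 7, plus the 8th iff it is the A-tail base
    eighth <- substr(reads, bl + ul + jl + 1L, bl + ul + jl + 1L)
    skip <- jl + (eighth == layout@junctionExtensionBase)
    cdnaStart <- bl + ul + skip + 1L
    cdna <- ifelse(accepted,
                   substr(reads, cdnaStart,
                          pmin(len, cdnaStart + layout@cdnaMapLen - 1L)), "")
    accepted <- accepted & nchar(cdna) > 0L
    reason <- rep("", n)
    reason[tooShort] <- "length"
    reason[noBarcode] <- "barcode"
    reason[!tooShort & !noBarcode & !accepted] <- "length"
    out <- data.frame(
        read_id = ids,
        barcode_id = ifelse(accepted, whitelist$barcode_id[hit], "REJECTED"),
        umi = umi, cdna = cdna, accepted = accepted, reason = reason,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Demultiplexing summary of a parsed read stream
#'
#' Tallies accepted reads per barcode and rejected reads per reason. Counts
#' always sum to the input size and are conserved across chunked
#' processing.
#'
#' @param parsed data.frame from [parseReads()] (or several chunks
#'   \code{rbind}-ed together).
#' @return list with \code{per_barcode} (data.frame \code{barcode_id},
#'   \code{accepted}), \code{rejected_by_reason} (named integer vector) and
#'   \code{total}.
#' @export
demuxStats <- function(parsed) {
    acc <- parsed[parsed$accepted, , drop = FALSE]
    rej <- parsed[!parsed$accepted, , drop = FALSE]
    tab <- table(acc$barcode_id)
    per_barcode <- data.frame(barcode_id = names(tab),
                              accepted = as.integer(tab),
                              stringsAsFactors = FALSE)
    rr <- table(rej$reason)
    list(per_barcode = per_barcode,
         rejected_by_reason = setNames(as.integer(rr), names(rr)),
         total = nrow(parsed))
}

#' Trim the leading A-tail T-run from Read 2 sequences
#'
#' Read 2 enters the cDNA from the A-tailed end, so it begins with a run of
#' T bases; this strips the run so the remainder can be assigned like a
#' Read 1 fragment.
#'
#' @param reads named character vector of Read 2 sequences.
#' @return named character vector with the leading T-run removed.
#' @export
trimAtail <- function(reads) {
    sub("^T+", "", reads)
}
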