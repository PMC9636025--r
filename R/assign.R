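#' Build a transcript index for deterministic fragment assignment
#'
#' Indexes transcript sequences and their reverse complements for
#' k-mer-seeded substring search. Because the reference is synthetic and
#' unspliced, a deterministic exact-seed search with bounded-mismatch
#' verification replaces a spliced genome aligner.
#'
#' @param transcriptome a [TranscriptomeModel-class].
#' @param k seed length in nt (default 12).
#' @return an opaque index list used by [assignTranscripts()].
#' @export
buildTranscriptIndex <- function(transcriptome, k = 12L) {
    stopifnot(is(transcriptome, "TranscriptomeModel"))
    fwd <- transcriptSeqs(transcriptome)
    rev <- Biostrings::reverseComplement(fwd)
    subjects <- c(fwd, rev)
    gene <- rep(geneInfo(transcriptome)$gene_id, 2L)
    strand <- rep(c("+", "-"), each = length(fwd))
    # concatenate subjects with N spacers (no ACGT seed can match a spacer)
    spacer <- strrep("N", 64L)
    chunks <- as.character(subjects)
    widths <- nchar(chunks)
    starts <- cumsum(c(1L, head(widths + 64L, -1L)))
    catChar <- paste(chunks, collapse = spacer)
    list(catDNA = Biostrings::DNAString(catChar), catChar = catChar,
         starts = starts, ends = starts + widths - 1L,
         gene = gene, strand = strand, k = as.integer(k),
         species = setNames(geneInfo(transcriptome)$species,
                            geneInfo(transcriptome)$gene_id))
}

#' Assign cDNA fragments to transcripts, uniquely or not at all
#'
#' Seeds each fragment with exact k-mers at fixed offsets (pigeonhole
#' coverage of the allowed mismatches), verifies every candidate placement
#' over the full fragment allowing at most 1 mismatch per 20 nt, and then
#' applies the unique-mapping rule: a verified hit in exactly one gene
#' assigns the read; hits in two or more genes are discarded as
#' multimapped; no hit leaves the read unassigned (eligible for rescue).
#' Both strands are searched; the hit strand is recorded but unused
#' downstream.
#'
#' @param parsed data.frame from [parseReads()] (rejected rows pass through
#'   as unassigned) or any data.frame with \code{read_id} and \code{cdna}.
#' @param index from [buildTranscriptIndex()].
#' @return data.frame: \code{read_id}, \code{gene_id} (NA unless assigned),
#'   \code{status} in \code{assigned}/\code{multimapped}/\code{unassigned},
#'   \code{strand}, \code{species}, \code{rescue} (FALSE here).
#' @export
assignTranscripts <- function(parsed, index) {
    k <- index$k
    cdna <- parsed$cdna
    n <- length(cdna)
    status <- rep("unassigned", n)
    gene <- rep(NA_character_, n)
    strand <- rep(NA_character_, n)
    usable <- which(!is.na(cdna) & nchar(cdna) >= k &
                    (is.null(parsed$accepted) | parsed$accepted))
    if (length(usable)) {
        len <- nchar(cdna[usable])
        maxmm <- pmax(1L, len %/% 20L)
        # seed offsets 1, 1+k, 1+2k... clipped into the fragment
        nOff <- max((max(len) - 1L) %/% k + 1L, 1L)
        cand <- list()
        for (oi in seq_len(nOff)) {
            o <- pmin((oi - 1L) * k + 1L, len - k + 1L)
            seeds <- substr(cdna[usable], o, o + k - 1L)
            pd <- Biostrings::PDict(seeds)
            m <- Biostrings::matchPDict(pd, index$catDNA)
            cnt <- S4Vectors::elementNROWS(m)
            if (!sum(cnt)) next
            pat <- rep(seq_along(cnt), cnt)
            st <- unlist(Biostrings::startIndex(m)[cnt > 0L],
                         use.names = FALSE)
            s <- findInterval(st, index$starts)
            alnStart <- st - (o[pat] - 1L)
            # full fragment must stay inside the seed's subject
            ok <- alnStart >= index$starts[s] &
                alnStart + len[pat] - 1L <= index$ends[s]
            if (!any(ok)) next
            cand[[length(cand) + 1L]] <- data.frame(
                q = pat[ok], s = s[ok], start = alnStart[ok])
        }
        if (length(cand)) {
            cand <- unique(do.call(rbind, cand))
            ref <- substring(index$catChar, cand$start,
                             cand$start + len[cand$q] - 1L)
            mm <- mismatchCount(cdna[usable][cand$q], ref)
            good <- cand[mm <= maxmm[cand$q], , drop = FALSE]
            if (nrow(good)) {
                good$gene <- index$gene[good$s]
                good$strand <- index$strand[good$s]
                gq <- unique(good[, c("q", "gene")])
                nPerQ <- table(gq$q)
                uniq <- as.integer(names(nPerQ)[nPerQ == 1L])
                multi <- as.integer(names(nPerQ)[nPerQ > 1L])
                status[usable[multi]] <- "multimapped"
                if (length(uniq)) {
                    status[usable[uniq]] <- "assigned"
                    gene[usable[uniq]] <- gq$gene[match(uniq, gq$q)]
                    firstRow <- match(uniq, good$q)
                    strand[usable[uniq]] <- good$strand[firstRow]
                }
            }
        }
    }
    data.frame(read_id = parsed$read_id, gene_id = gene, status = status,
               strand = strand,
               species = unname(index$species[gene]),
               rescue = FALSE, stringsAsFactors = FALSE)
}

#' Best local Smith-Waterman alignment score
#'
#' Affine-gap local alignment score under [SWParams-class] scoring, with
#' the striped-SW gap convention: a gap of length L costs
#' \code{gapOpen + (L - 1) * gapExtend}. Scores are clamped at 0 (the empty
#' local alignment). Vectorized over queries.
#'
#' @param query character vector of query sequences.
#' @param reference a single reference sequence.
#' @param params an [SWParams-class].
#' @return numeric vector of scores, one per query.
#' @examples
#' swScore("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")  # 40
#' @export
swScore <- function(query, reference, params = SWParams()) {
    stopifnot(is(params, "SWParams"))
    if (!length(query)) return(numeric(0))
    subMat <- Biostrings::nucleotideSubstitutionMatrix(
        match = params@match, mismatch = params@mismatch, baseOnly = TRUE)
    sc <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(query),
        Biostrings::DNAString(as.character(reference)),
        type = "local", substitutionMatrix = subMat,
        gapOpening = params@gapOpen - params@gapExtend,
        gapExtension = params@gapExtend, scoreOnly = TRUE)
    pmax(0, sc)
}

#' Rescue unassigned reads against a designated rescue sequence
#'
#' Reads left unassigned by [assignTranscripts()] are compared with the
#' rescue sequence (both strands) by local Smith-Waterman alignment and
#' attributed to it iff the score reaches \code{acceptThreshold} and the
#' read's UMI has not already been seen among rescued reads of the same
#' barcode (first occurrence in input order wins). The canonical use is
#' attributing transgene reads (e.g. eGFP) absent from the reference.
#'
#' @param assignments data.frame from [assignTranscripts()].
#' @param parsed matching data.frame from [parseReads()] (supplies
#'   \code{cdna}, \code{umi}, \code{barcode_id}).
#' @param rescueSeq the rescue transcript sequence (character or
#'   [Biostrings::DNAString]).
#' @param rescueGeneId gene id recorded for rescued reads.
#' @param rescueSpecies species tag recorded for rescued reads.
#' @param params an [SWParams-class].
#' @return the assignments data.frame with rescued rows set to
#'   \code{status = "assigned"}, \code{rescue = TRUE} and a \code{sw_score}
#'   column for the reads that were evaluated.
#' @export
rescueReads <- function(assignments, parsed, rescueSeq,
                        rescueGeneId = "rescue", rescueSpecies = NA_character_,
                        params = SWParams()) {
    stopifnot(identical(assignments$read_id, parsed$read_id))
    out <- assignments
    out$sw_score <- NA_real_
    idx <- which(out$status == "unassigned" & parsed$accepted &
                 nchar(parsed$cdna) > 0L)
    if (!length(idx)) return(out)
    ref <- as.character(rescueSeq)
    sc <- pmax(swScore(parsed$cdna[idx], ref, params),
               swScore(parsed$cdna[idx], revComp(ref), params))
    out$sw_score[idx] <- sc
    pass <- sc >= params@acceptThreshold
    # UMI uniqueness within each barcode, input order deterministic
    key <- paste(parsed$barcode_id[idx], parsed$umi[idx], sep = "\r")
    take <- idx[pass][!duplicated(key[pass])]
    out$status[take] <- "assigned"
    out$gene_id[take] <- rescueGeneId
    out$species[take] <- rescueSpecies
    out$rescue[take] <- TRUE
    out
}
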