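#' Generate a synthetic tissue phantom
#'
#' Seeds non-overlapping circular cells into rectangular regions, emulating
#' the co-cultured cell fields and layered tissue sections that
#' light-directed barcoding targets. Placement is rejection sampling with
#' bounded retries; per-region counts are exact and a fixed seed reproduces
#' the phantom bit-for-bit.
#'
#' @param regions data.frame with one row per region and columns
#'   \code{region}, \code{xmin}, \code{xmax}, \code{ymin}, \code{ymax} (um),
#'   \code{n_cells}, \code{species}, \code{cell_type} and optionally
#'   \code{radius_um} (default 5).
#' @param boundsUm field size (width, height) in microns; defaults to the
#'   union extent of the regions.
#' @param seed RNG seed.
#' @param maxTries placement retries per cell before failing.
#' @return a [TissuePhantom-class].
#' @examples
#' reg <- data.frame(region = c("A", "B"), xmin = c(0, 60), xmax = c(40, 100),
#'                   ymin = 0, ymax = 40, n_cells = c(25, 25),
#'                   species = c("human", "mouse"),
#'                   cell_type = c("HEK", "3T3"))
#' makeTissue(reg, seed = 1)
#' @export
makeTissue <- function(regions, boundsUm = NULL, seed = 1L, maxTries = 1000L) {
    need <- c("region", "xmin", "xmax", "ymin", "ymax", "n_cells", "species",
              "cell_type")
    if (!all(need %in% names(regions)))
        stop("'regions' must have columns: ", paste(need, collapse = ", "))
    if (is.null(regions$radius_um)) regions$radius_um <- 5
    if (is.null(boundsUm))
        boundsUm <- c(max(regions$xmax), max(regions$ymax))
    set.seed(seed)
    rows <- vector("list", nrow(regions))
    idx <- 0L
    for (r in seq_len(nrow(regions))) {
        n <- regions$n_cells[r]
        if (n == 0L) { rows[[r]] <- NULL; next }
        rad <- regions$radius_um[r]
        xs <- ys <- numeric(n)
        placed <- 0L
        while (placed < n) {
            ok <- FALSE
            for (t in seq_len(maxTries)) {
                x <- runif(1L, regions$xmin[r] + rad, regions$xmax[r] - rad)
                y <- runif(1L, regions$ymin[r] + rad, regions$ymax[r] - rad)
                if (placed == 0L ||
                    all((xs[seq_len(placed)] - x)^2 +
                        (ys[seq_len(placed)] - y)^2 >= (2 * rad)^2)) {
                    ok <- TRUE; break
                }
            }
            if (!ok)
                stop("could not place ", n, " non-overlapping cells in ",
                     "region '", regions$region[r], "'")
            placed <- placed + 1L
            xs[placed] <- x; ys[placed] <- y
        }
        rows[[r]] <- data.frame(
            cell_id = sprintf("cell%04d", idx + seq_len(n)),
            x_um = xs, y_um = ys, radius_um = rad,
            species = regions$species[r], cell_type = regions$cell_type[r],
            region = regions$region[r], stringsAsFactors = FALSE)
        idx <- idx + n
    }
    cellsDf <- do.call(rbind, rows)
    if (is.null(cellsDf))
        cellsDf <- data.frame(cell_id = character(0), x_um = numeric(0),
                              y_um = numeric(0), radius_um = numeric(0),
                              species = character(0), cell_type = character(0),
                              region = character(0))
    rownames(cellsDf) <- NULL
    new("TissuePhantom", cells = cellsDf, bounds = as.numeric(boundsUm))
}

#' Generate a synthetic (merged two-species) transcriptome
#'
#' Random gene sequences with per-(cell type, gene) mean expression,
#' emulating mapping against a merged multi-species reference. Each cell
#' type expresses its own species' genes; means are drawn log-normally.
#' Optionally the first gene of each species is flagged as rRNA-like and
#' given a very high mean, to exercise the UMI saturation guard.
#'
#' @param genesPerSpecies named integer vector, e.g.
#'   \code{c(human = 30, mouse = 30)}.
#' @param cellTypes named character vector mapping cell type -> species,
#'   e.g. \code{c(HEK = "human", `3T3` = "mouse")}.
#' @param lengthRange transcript length range in nt.
#' @param meanLog,sdLog log-normal parameters of expression means
#'   (transcripts per cell).
#' @param rrnaBoost multiplier applied to the rRNA-flagged gene's mean
#'   (0 disables the flagging).
#' @param seed RNG seed.
#' @return a [TranscriptomeModel-class].
#' @export
makeTranscriptome <- function(genesPerSpecies = c(human = 25L, mouse = 25L),
                              cellTypes = c(HEK = "human", `3T3` = "mouse"),
                              lengthRange = c(500L, 2000L),
                              meanLog = log(5), sdLog = 0.6,
                              rrnaBoost = 0, seed = 1L) {
    set.seed(seed)
    species <- rep(names(genesPerSpecies), genesPerSpecies)
    n <- length(species)
    gene_id <- sprintf("%s_g%03d", species,
                       unlist(lapply(genesPerSpecies, seq_len)))
    len <- sample(seq(lengthRange[1L], lengthRange[2L]), n, replace = TRUE)
    seqs <- Biostrings::DNAStringSet(randomDNA(n, max(len)))
    seqs <- Biostrings::subseq(seqs, 1L, len)
    names(seqs) <- gene_id
    biotype <- rep("protein_coding", n)
    expr <- matrix(0, nrow = length(cellTypes), ncol = n,
                   dimnames = list(names(cellTypes), gene_id))
    for (ct in names(cellTypes)) {
        own <- species == cellTypes[[ct]]
        expr[ct, own] <- exp(rnorm(sum(own), meanLog, sdLog))
    }
    if (rrnaBoost > 0) {
        for (sp in unique(species)) {
            first <- which(species == sp)[1L]
            biotype[first] <- "rRNA"
            expr[, first] <- expr[, first] * rrnaBoost
        }
    }
    genes <- data.frame(gene_id = gene_id, species = species,
                        length_nt = as.integer(len), biotype = biotype,
                        stringsAsFactors = FALSE)
    new("TranscriptomeModel", sequences = seqs, genes = genes,
        expression = expr)
}

#' Generate a barcode whitelist
#'
#' Random barcodes at the given length with a minimum pairwise Hamming
#' distance, one barcode per illumination round.
#'
#' @param nBarcodes number of barcodes / rounds.
#' @param barcodeLen barcode length in nt (default 12).
#' @param minDist minimum pairwise Hamming distance (default 4, so the
#'   optional single-mismatch correction mode stays unambiguous).
#' @param seed RNG seed.
#' @return data.frame with columns \code{barcode_id}, \code{sequence},
#'   \code{fluor}, \code{round}.
#' @export
barcodeWhitelist <- function(nBarcodes, barcodeLen = 12L, minDist = 4L,
                             seed = 1L) {
    set.seed(seed)
    seqs <- character(0)
    while (length(seqs) < nBarcodes) {
        cand <- randomDNA(1L, barcodeLen)
        if (!length(seqs) ||
            all(mismatchCount(rep(cand, length(seqs)), seqs) >= minDist))
            seqs <- c(seqs, cand)
    }
    fluors <- rep(c("Cy3", "FITC", "Cy5", "A647"), length.out = nBarcodes)
    data.frame(barcode_id = sprintf("BC%d", seq_len(nBarcodes)),
               sequence = seqs, fluor = fluors, round = seq_len(nBarcodes),
               stringsAsFactors = FALSE)
}

#' Simulate iterative light-directed barcoding of cDNA molecules
#'
#' Draws per-cell molecule pools from the transcriptome (Poisson per gene),
#' then runs the barcoding rounds in order. In round r a molecule whose
#' cell's scatter-blurred dose reaches the crosslink threshold is
#' crosslinked with barcode r; otherwise a residual uncrosslinked barcode
#' survives the washes with probability \code{carryoverRate}. A molecule's
#' dock is occupied by the first barcode it receives, so molecules never
#' carry two barcodes. Optionally a fraction of barcoded molecules is
#' swapped to a different round's barcode, modelling unexplained
#' misassignment.
#'
#' @param tissue a [TissuePhantom-class].
#' @param transcriptome a [TranscriptomeModel-class].
#' @param mask a [LabelMask-class] whose labels are the round ids and whose
#'   physical extent equals the tissue bounds.
#' @param scatter a [ScatterModel-class].
#' @param swapRate probability a barcoded molecule's round label is swapped
#'   uniformly to another round.
#' @param seed RNG seed.
#' @return list with \code{molecules} (data.frame: \code{molecule_id},
#'   \code{cell_id}, \code{gene_id}, \code{barcode_round} (0 = none),
#'   \code{noise_flag} in clean/scatter/carryover/swap) and \code{doses}
#'   (cells x rounds dose matrix).
#' @export
simulateBarcoding <- function(tissue, transcriptome, mask,
                              scatter = ScatterModel(), swapRate = 0,
                              seed = 1L) {
    stopifnot(is(tissue, "TissuePhantom"), is(mask, "LabelMask"),
              is(transcriptome, "TranscriptomeModel"),
              is(scatter, "ScatterModel"))
    px <- pixels(mask)
    dims_um <- c(ncol(px), nrow(px)) * umPerPixel(mask)
    if (any(abs(dims_um - bounds(tissue)) > umPerPixel(mask) / 2))
        stop("mask physical extent (", dims_um[1L], " x ", dims_um[2L],
             " um) does not match tissue bounds")
    set.seed(seed)
    cl <- cells(tissue)
    rounds <- maskLabels(mask)
    # pixel index of each centroid (half-open pixel convention)
    ci <- pmin(nrow(px), floor(cl$y_um / umPerPixel(mask)) + 1L)
    cj <- pmin(ncol(px), floor(cl$x_um / umPerPixel(mask)) + 1L)
    doses <- matrix(0, nrow(cl), length(rounds),
                    dimnames = list(cl$cell_id, as.character(rounds)))
    trueRoi <- px[cbind(ci, cj)]
    for (k in seq_along(rounds)) {
        d <- scatterDose(mask, rounds[k], scatter)
        doses[, k] <- d[cbind(ci, cj)]
    }
    # molecule pools: Poisson(mean expression) per cell per gene
    expr <- expressionMeans(transcriptome)
    genes <- geneInfo(transcriptome)$gene_id
    mols <- vector("list", nrow(cl))
    for (i in seq_len(nrow(cl))) {
        mu <- expr[cl$cell_type[i], ]
        counts <- rpois(length(mu), mu)
        if (sum(counts) == 0L) next
        mols[[i]] <- data.frame(cell_id = cl$cell_id[i],
                                gene_id = rep(genes, counts),
                                stringsAsFactors = FALSE)
    }
    mols <- do.call(rbind, mols)
    if (is.null(mols))
        mols <- data.frame(cell_id = character(0), gene_id = character(0))
    nmol <- nrow(mols)
    assigned <- integer(nmol)
    flag <- rep("none", nmol)
    cellRow <- match(mols$cell_id, cl$cell_id)
    for (k in seq_along(rounds)) {
        open <- assigned == 0L
        if (!any(open)) break
        hot <- doses[cellRow, k] >= scatter@crosslinkThreshold
        take <- open & hot
        assigned[take] <- rounds[k]
        flag[take] <- ifelse(trueRoi[cellRow[take]] == rounds[k],
                             "clean", "scatter")
        if (scatter@carryoverRate > 0) {
            cold <- open & !hot
            spur <- cold & runif(nmol) < scatter@carryoverRate
            assigned[spur] <- rounds[k]
            flag[spur] <- "carryover"
        }
    }
    if (swapRate > 0 && length(rounds) > 1L) {
        bar <- which(assigned > 0L)
        sw <- bar[runif(length(bar)) < swapRate]
        if (length(sw)) {
            assigned[sw] <- vapply(assigned[sw], function(r) {
                others <- setdiff(rounds, r)
                others[sample.int(length(others), 1L)]
            }, numeric(1))
            flag[sw] <- "swap"
        }
    }
    molecules <- data.frame(molecule_id = sprintf("mol%07d", seq_len(nmol)),
                            cell_id = mols$cell_id, gene_id = mols$gene_id,
                            barcode_round = as.integer(assigned),
                            noise_flag = flag, stringsAsFactors = FALSE)
    list(molecules = molecules, doses = doses)
}

#' Simulate sequencing reads from barcoded molecules
#'
#' For each barcoded molecule that survives capture, reverse transcription
#' primes at a position drawn uniformly over the sites that leave a full
#' mappable fragment (internal priming with a degenerate primer). Read 1 is
#' \code{[barcode][UMI][junction remnant of 7 or 8 nt][cDNA]}, read 5'->3'
#' from the synthesized strand (the cDNA segment is therefore the reverse
#' complement of the transcript up to the priming site). Substitution
#' errors are i.i.d. over the whole read; PCR duplicates replicate a
#' molecule with the same UMI and fragment but independent errors. Read 2,
#' when emitted, reads from the A-tail end: a leading T-run followed by the
#' reverse complement of the Read 1 cDNA segment (or, at the chimera rate,
#' a fragment of an unrelated transcript).
#'
#' @param barcoding result of [simulateBarcoding()].
#' @param transcriptome a [TranscriptomeModel-class].
#' @param layout a [ReadLayout-class].
#' @param whitelist whitelist data.frame from [barcodeWhitelist()].
#' @param tissue a [TissuePhantom-class] (species/cell annotation of truth).
#' @param captureRate probability a barcoded molecule is captured into the
#'   library (end-to-end efficiency of RT, extraction and stitching).
#' @param errorRate per-base substitution rate.
#' @param pcrDupRate probability mass of PCR duplication; each read gains
#'   geometric(1 - rate) extra copies.
#' @param depth if non-NULL, sample this many reads with replacement from
#'   the captured molecules instead of one read per molecule.
#' @param readLen total Read 1 length in nt.
#' @param emitR2 emit Read 2.
#' @param chimeraRate fraction of Read 2 fragments drawn from a different
#'   transcript (library chimeras).
#' @param seed RNG seed.
#' @return list with \code{r1} (named character vector of Read 1
#'   sequences), \code{r2} (or NULL), and \code{truth} data.frame:
#'   \code{read_id}, \code{molecule_id}, \code{cell_id}, \code{gene_id},
#'   \code{barcode_round}, \code{barcode_id}, \code{noise_flag},
#'   \code{priming_pos}, \code{umi}, \code{junction_len}, \code{cdna},
#'   \code{chimera}, \code{r2_gene_id}.
#' @export
simulateReads <- function(barcoding, transcriptome, layout = ReadLayout(),
                          whitelist, tissue, captureRate = 1, errorRate = 0,
                          pcrDupRate = 0, depth = NULL, readLen = 80L,
                          emitR2 = FALSE, chimeraRate = 0, seed = 1L) {
    stopifnot(is(layout, "ReadLayout"), is(transcriptome, "TranscriptomeModel"))
    set.seed(seed)
    mol <- barcoding$molecules
    mol <- mol[mol$barcode_round > 0L, , drop = FALSE]
    if (captureRate < 1 && nrow(mol))
        mol <- mol[runif(nrow(mol)) < captureRate, , drop = FALSE]
    emptyRes <- function() {
        warning("no barcoded molecules captured; empty FASTQ")
        list(r1 = setNames(character(0), character(0)), r2 = NULL,
             truth = data.frame())
    }
    if (!nrow(mol)) return(emptyRes())
    # one UMI per molecule
    mol$umi <- randomDNA(nrow(mol), layout@umiLen)
    jlen0 <- nchar(layout@junctionSeq)
    fragLen <- readLen - layout@barcodeLen - layout@umiLen - jlen0 - 1L
    fragLen <- min(fragLen, layout@cdnaMapLen)
    if (fragLen < 1L) stop("readLen too short for the layout")
    glen <- setNames(geneInfo(transcriptome)$length_nt,
                     geneInfo(transcriptome)$gene_id)
    # reads: sampled molecules (depth) or one per molecule, plus PCR copies
    ridx <- if (is.null(depth)) seq_len(nrow(mol)) else
        sample.int(nrow(mol), depth, replace = TRUE)
    if (pcrDupRate > 0)
        ridx <- rep(ridx, times = 1L + rgeom(length(ridx), 1 - pcrDupRate))
    rd <- mol[ridx, , drop = FALSE]
    n <- nrow(rd)
    L <- glen[rd$gene_id]
    flen <- pmin(fragLen, L)
    # priming position: uniform over sites leaving a full fragment
    p <- flen + floor(runif(n) * (L - flen + 1))
    # duplicate copies of a molecule share the priming position of the
    # first copy (one first-strand synthesis event per molecule)
    firstOf <- match(ridx, ridx)
    p <- p[firstOf]
    rd$priming_pos <- as.integer(p)
    seqs <- transcriptSeqs(transcriptome)[rd$gene_id]
    frag <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(seqs, start = p - flen + 1L, end = p)))
    jext <- runif(n) < layout@junctionExtendProb
    jext <- jext[firstOf]
    junction <- paste0(layout@junctionSeq,
                       ifelse(jext, layout@junctionExtensionBase, ""))
    bseq <- setNames(whitelist$sequence, as.character(whitelist$round))
    r1 <- paste0(bseq[as.character(rd$barcode_round)], rd$umi, junction, frag)
    r1 <- substr(r1, 1L, readLen)
    r1 <- injectSubstitutions(r1, errorRate)
    read_id <- sprintf("read%08d", seq_len(n))
    names(r1) <- read_id
    cl <- cells(tissue)
    truth <- data.frame(
        read_id = read_id, molecule_id = rd$molecule_id,
        cell_id = rd$cell_id, gene_id = rd$gene_id,
        barcode_round = rd$barcode_round,
        barcode_id = whitelist$barcode_id[
            match(rd$barcode_round, whitelist$round)],
        noise_flag = rd$noise_flag, priming_pos = rd$priming_pos,
        umi = rd$umi, junction_len = jlen0 + as.integer(jext),
        cdna = substr(frag, 1L, layout@cdnaMapLen),
        chimera = FALSE, r2_gene_id = rd$gene_id,
        stringsAsFactors = FALSE)
    truth$species <- cl$species[match(truth$cell_id, cl$cell_id)]
    r2 <- NULL
    if (emitR2) {
        chim <- runif(n) < chimeraRate
        r2gene <- rd$gene_id
        r2frag <- revComp(frag)
        if (any(chim)) {
            others <- vapply(rd$gene_id[chim], function(g)
                sample(setdiff(names(glen), g), 1L), character(1))
            L2 <- glen[others]
            fl2 <- pmin(fragLen, L2)
            p2 <- fl2 + floor(runif(sum(chim)) * (L2 - fl2 + 1))
            s2 <- Biostrings::subseq(transcriptSeqs(transcriptome)[others],
                                     start = p2 - fl2 + 1L, end = p2)
            r2frag[chim] <- as.character(s2)
            r2gene[chim] <- others
        }
        atail <- layout@atailMin +
            floor(runif(n) * (layout@atailMax - layout@atailMin + 1L))
        r2 <- paste0(strrep("T", atail), r2frag)
        r2 <- substr(r2, 1L, readLen)
        r2 <- injectSubstitutions(r2, errorRate)
        names(r2) <- read_id
        truth$chimera <- chim
        truth$r2_gene_id <- r2gene
    }
    list(r1 = r1, r2 = r2, truth = truth)
}

#' Generate a synthetic smFISH reference of per-cell puncta counts
#'
#' Emulates a quantitative smFISH survey of a mixed cell population:
#' subtypes are drawn at fixed mixture weights and each cell's puncta count
#' per gene is Poisson around its subtype mean. One subtype can play the
#' role of a population excluded from downstream expectations (displaced
#' cell bodies outside the barcoded layer).
#'
#' @param means numeric matrix of mean puncta per cell, subtypes x genes
#'   (dimnames required).
#' @param weights mixture weights over subtypes (recycled/normalized).
#' @param nCells number of surveyed cells.
#' @param seed RNG seed.
#' @return data.frame in long form: \code{cell_id}, \code{subtype},
#'   \code{gene}, \code{count}.
#' @export
simulateSmFISHReference <- function(means, weights = NULL, nCells = 200L,
                                    seed = 1L) {
    stopifnot(is.matrix(means), !is.null(rownames(means)),
              !is.null(colnames(means)))
    set.seed(seed)
    if (is.null(weights)) weights <- rep(1, nrow(means))
    weights <- weights / sum(weights)
    sub <- sample(rownames(means), nCells, replace = TRUE, prob = weights)
    counts <- matrix(rpois(nCells * ncol(means), means[sub, , drop = FALSE]),
                     nrow = nCells)
    data.frame(cell_id = rep(sprintf("fish%05d", seq_len(nCells)),
                             times = ncol(means)),
               subtype = rep(sub, times = ncol(means)),
               gene = rep(colnames(means), each = nCells),
               count = as.integer(counts), stringsAsFactors = FALSE)
}
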