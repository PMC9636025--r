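# Shared fixture builders: a two-species field barcoded in two rounds,
# one region per species, whole-region ROIs.

twoSpeciesSetup <- function(seed = 1L, nCells = c(25L, 25L),
                            meanLog = log(40), nGenes = c(25L, 25L)) {
    reg <- data.frame(
        region = c("left", "right"),
        xmin = c(0, 120), xmax = c(100, 220), ymin = 0, ymax = 100,
        n_cells = nCells, species = c("human", "mouse"),
        cell_type = c("HEK", "3T3"))
    tissue <- makeTissue(reg, boundsUm = c(220, 100), seed = seed)
    tx <- makeTranscriptome(
        genesPerSpecies = c(human = nGenes[1L], mouse = nGenes[2L]),
        meanLog = meanLog, seed = seed + 1L)
    wl <- barcodeWhitelist(2L, seed = seed + 2L)
    mask <- polygonToMask(
        list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
             cbind(c(120, 220, 220, 120), c(0, 0, 100, 100))),
        labels = 1:2, umPerPixel = 2, widthUm = 220, heightUm = 100)
    list(tissue = tissue, tx = tx, wl = wl, mask = mask,
         speciesOfBarcode = setNames(c("human", "mouse"), wl$barcode_id))
}

# run simulate -> parse -> assign on a setup; returns all intermediates
runPipeline <- function(setup, scatter = ScatterModel(), swapRate = 0,
                        errorRate = 0, captureRate = 1, depth = NULL,
                        seed = 10L, ...) {
    bc <- simulateBarcoding(setup$tissue, setup$tx, setup$mask,
                            scatter = scatter, swapRate = swapRate,
                            seed = seed)
    sim <- simulateReads(bc, setup$tx, ReadLayout(), setup$wl, setup$tissue,
                         errorRate = errorRate, captureRate = captureRate,
                         depth = depth, seed = seed + 1L, ...)
    parsed <- parseReads(sim$r1, ReadLayout(), setup$wl)
    index <- buildTranscriptIndex(setup$tx)
    assignments <- assignTranscripts(parsed, index)
    list(barcoding = bc, sim = sim, parsed = parsed, index = index,
         assignments = assignments)
}
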