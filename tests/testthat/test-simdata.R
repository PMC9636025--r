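test_that("makeTissue places exact per-region counts, reproducibly", {
    setup <- twoSpeciesSetup(seed = 1)
    cl <- cells(setup$tissue)
    expect_equal(nrow(cl), 50L)
    expect_equal(as.integer(table(cl$region)[c("left", "right")]), c(25L, 25L))
    expect_false(anyDuplicated(cl$cell_id) > 0)
    # same seed twice -> identical phantom
    setup2 <- twoSpeciesSetup(seed = 1)
    expect_identical(cells(setup2$tissue), cl)
    # cells stay inside their region and never overlap
    left <- cl[cl$region == "left", ]
    expect_true(all(left$x_um >= 0 & left$x_um <= 100))
    dmat <- as.matrix(dist(cl[, c("x_um", "y_um")]))
    diag(dmat) <- Inf
    expect_true(min(dmat) >= 2 * min(cl$radius_um) - 1e-9)
    # zero cells is a valid phantom
    reg0 <- data.frame(region = "e", xmin = 0, xmax = 50, ymin = 0, ymax = 50,
                       n_cells = 0L, species = "human", cell_type = "HEK")
    expect_equal(nrow(cells(makeTissue(reg0, seed = 1))), 0L)
    # impossible packing errors out naming the region
    regX <- data.frame(region = "tight", xmin = 0, xmax = 22, ymin = 0,
                       ymax = 22, n_cells = 25L, species = "human",
                       cell_type = "HEK")
    expect_error(makeTissue(regX, seed = 1), "tight")
})

test_that("makeTranscriptome builds a merged reference with valid lengths", {
    tx <- makeTranscriptome(genesPerSpecies = c(human = 10L, mouse = 8L),
                            rrnaBoost = 50, seed = 3)
    g <- geneInfo(tx)
    expect_equal(nrow(g), 18L)
    expect_false(anyDuplicated(g$gene_id) > 0)
    expect_identical(unname(Biostrings::width(transcriptSeqs(tx))),
                     g$length_nt)
    expect_equal(sum(g$biotype == "rRNA"), 2L)
    expr <- expressionMeans(tx)
    # each cell type expresses only its own species' genes
    expect_true(all(expr["HEK", g$species == "mouse"] == 0))
    expect_true(all(expr["3T3", g$species == "human"] == 0))
    expect_true(all(expr >= 0))
})

test_that("barcode whitelist respects length and minimum distance", {
    wl <- barcodeWhitelist(4L, barcodeLen = 12L, minDist = 4L, seed = 9)
    expect_equal(nchar(wl$sequence), rep(12L, 4L))
    for (i in 1:3) for (j in (i + 1):4)
        expect_gte(sum(strsplit(wl$sequence[i], "")[[1L]] !=
                       strsplit(wl$sequence[j], "")[[1L]]), 4L)
    expect_equal(wl$round, 1:4)
})

test_that("noise-free barcoding labels every in-ROI molecule correctly", {
    setup <- twoSpeciesSetup(seed = 5, meanLog = log(10))
    bc <- simulateBarcoding(setup$tissue, setup$tx, setup$mask,
                            ScatterModel(), seed = 6)
    mol <- bc$molecules
    cl <- cells(setup$tissue)
    expect_true(all(mol$noise_flag == "clean"))
    # region left = round 1, right = round 2
    round_of <- setNames(ifelse(cl$region == "left", 1L, 2L), cl$cell_id)
    expect_equal(mol$barcode_round, unname(round_of[mol$cell_id]))
    # molecules never carry two barcodes: single integer per molecule
    expect_true(all(mol$barcode_round %in% 1:2))
    # scale mismatch between mask and tissue bounds errors
    badMask <- polygonToMask(list(cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))),
                             1L, 1, 10, 10)
    expect_error(simulateBarcoding(setup$tissue, setup$tx, badMask,
                                   ScatterModel(), seed = 1), "bounds")
})

test_that("a cell outside every ROI yields nothing without carryover", {
    reg <- data.frame(region = "gap", xmin = 101, xmax = 119, ymin = 0,
                      ymax = 100, n_cells = 5L, species = "human",
                      cell_type = "HEK", radius_um = 3)
    setupMask <- twoSpeciesSetup(seed = 2)$mask
    tissue <- makeTissue(reg, boundsUm = c(220, 100), seed = 3)
    tx <- makeTranscriptome(seed = 4)
    bc <- simulateBarcoding(tissue, tx, setupMask, ScatterModel(), seed = 5)
    expect_true(all(bc$molecules$barcode_round == 0L))
})

test_that("carryover rate is recovered within its binomial 99% CI", {
    reg <- data.frame(region = "gap", xmin = 102, xmax = 118, ymin = 2,
                      ymax = 98, n_cells = 8L, species = "human",
                      cell_type = "HEK", radius_um = 3)
    tissue <- makeTissue(reg, boundsUm = c(220, 100), seed = 3)
    tx <- makeTranscriptome(genesPerSpecies = c(human = 20L, mouse = 2L),
                            meanLog = log(80), seed = 4)
    mask <- twoSpeciesSetup(seed = 2)$mask
    bc <- simulateBarcoding(tissue, tx, mask,
                            ScatterModel(carryoverRate = 0.05), seed = 6)
    mol <- bc$molecules
    expect_gte(nrow(mol), 5000)
    # two rounds of exposure: P(barcoded) = 1 - (1 - 0.05)^2
    p <- 1 - 0.95^2
    frac <- mean(mol$barcode_round > 0L)
    z <- qnorm(0.995)
    half <- z * sqrt(p * (1 - p) / nrow(mol))
    expect_lt(abs(frac - p), half)
    expect_true(all(mol$noise_flag[mol$barcode_round > 0L] == "carryover"))
})

test_that("simulated reads follow the declared layout exactly", {
    setup <- twoSpeciesSetup(seed = 11, meanLog = log(15))
    bc <- simulateBarcoding(setup$tissue, setup$tx, setup$mask,
                            ScatterModel(), seed = 12)
    layout <- ReadLayout()
    sim <- simulateReads(bc, setup$tx, layout, setup$wl, setup$tissue,
                         seed = 13)
    expect_equal(length(sim$r1), nrow(sim$truth))   # one truth row per read
    # every R1 begins with an exact whitelist barcode (error rate 0)
    expect_true(all(substr(sim$r1, 1, 12) %in% setup$wl$sequence))
    # UMI sits right after the barcode
    expect_equal(unname(substr(sim$r1, 13, 20)), sim$truth$umi)
    # junction remnant is the junction domain, A-extended per truth
    jl <- sim$truth$junction_len
    expect_true(all(substr(sim$r1, 21, 27) == layout@junctionSeq))
    expect_true(all(substr(sim$r1, 28, 28) == "A" |
                    substr(sim$r1, 28, 28) == substr(sim$truth$cdna, 1, 1)))
    expect_true(all(substr(sim$r1, 21 + jl, 20 + jl + 40) == sim$truth$cdna))
    # length accounting
    expect_true(all(nchar(sim$r1) >= 12 + 8 + 7 + 1))
    # forcing 7-nt junctions only
    lay7 <- ReadLayout(junctionExtendProb = 0)
    sim7 <- simulateReads(bc, setup$tx, lay7, setup$wl, setup$tissue,
                          seed = 14)
    expect_true(all(sim7$truth$junction_len == 7L))
})

test_that("priming positions are uniform over the valid range", {
    # one long transcript, one cell on it
    reg <- data.frame(region = "a", xmin = 0, xmax = 50, ymin = 0, ymax = 50,
                      n_cells = 1L, species = "human", cell_type = "HEK")
    tissue <- makeTissue(reg, boundsUm = c(50, 50), seed = 1)
    seqs <- Biostrings::DNAStringSet(setNames(
        paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""),
        "human_g001"))
    tx <- new("TranscriptomeModel", sequences = seqs,
              genes = data.frame(gene_id = "human_g001", species = "human",
                                 length_nt = 1000L,
                                 biotype = "protein_coding"),
              expression = matrix(10000, 1, 1,
                                  dimnames = list("HEK", "human_g001")))
    mask <- polygonToMask(list(cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))),
                          1L, 1, 50, 50)
    bc <- simulateBarcoding(tissue, tx, mask, ScatterModel(), seed = 2)
    sim <- simulateReads(bc, tx, ReadLayout(), barcodeWhitelist(1, seed = 3),
                         tissue, seed = 4)
    p <- sim$truth$priming_pos
    expect_gte(length(p), 9000)
    expect_true(all(p >= 40 & p <= 1000))
    # chi-square uniformity over 10 bins at alpha = 0.01
    bins <- cut(p, breaks = seq(40, 1000, length.out = 11),
                include.lowest = TRUE)
    cs <- suppressWarnings(chisq.test(table(bins)))
    expect_gt(cs$p.value, 0.01)
})

test_that("PCR duplicates replicate molecules and depth resamples them", {
    setup <- twoSpeciesSetup(seed = 21, meanLog = log(5))
    bc <- simulateBarcoding(setup$tissue, setup$tx, setup$mask,
                            ScatterModel(), seed = 22)
    sim <- simulateReads(bc, setup$tx, ReadLayout(), setup$wl, setup$tissue,
                         pcrDupRate = 0.4, seed = 23)
    tt <- sim$truth
    expect_gt(nrow(tt), length(unique(tt$molecule_id)))
    # duplicate copies of a molecule share UMI, position and junction form
    sp <- split(tt[, c("umi", "priming_pos", "junction_len")],
                tt$molecule_id)
    multi <- sp[vapply(sp, nrow, 0L) > 1L]
    expect_true(all(vapply(multi, function(d) nrow(unique(d)) == 1L, TRUE)))
    # explicit depth: exactly that many reads
    sim2 <- simulateReads(bc, setup$tx, ReadLayout(), setup$wl, setup$tissue,
                          depth = 500L, seed = 24)
    expect_equal(length(sim2$r1), 500L)
    # zero barcoded molecules -> warning + empty output
    bc0 <- bc
    bc0$molecules$barcode_round <- 0L
    expect_warning(
        sim0 <- simulateReads(bc0, setup$tx, ReadLayout(), setup$wl,
                              setup$tissue, seed = 25),
        "no barcoded molecules")
    expect_equal(length(sim0$r1), 0L)
})

test_that("Read 2 carries a T-run then the reverse-complement fragment", {
    setup <- twoSpeciesSetup(seed = 31, meanLog = log(5))
    bc <- simulateBarcoding(setup$tissue, setup$tx, setup$mask,
                            ScatterModel(), seed = 32)
    sim <- simulateReads(bc, setup$tx, ReadLayout(), setup$wl, setup$tissue,
                         emitR2 = TRUE, seed = 33)
    expect_equal(names(sim$r2), names(sim$r1))
    expect_true(all(substr(sim$r2, 1, 5) == "TTTTT"))
    nonchim <- !sim$truth$chimera
    trimmed <- trimAtail(sim$r2[nonchim])
    rcf <- LightSeqKit:::revComp(sim$truth$cdna[nonchim])
    # after trimming the T-run, R2 is a suffix of revcomp(cDNA) (the trim
    # can eat genuine leading Ts of the fragment)
    hit <- vapply(seq_along(trimmed), function(i)
        grepl(paste0(substr(trimmed[i], 1, 60), "$"),
              paste0("TTTTTTTTTTTTTTTT", rcf[i]), fixed = FALSE),
        TRUE)
    expect_true(all(hit))
})

test_that("smFISH reference simulation honors subtype means and weights", {
    means <- matrix(c(10, 2, 30, 6), 2, 2,
                    dimnames = list(c("BCa", "BC1B"), c("g1", "g2")))
    ref <- simulateSmFISHReference(means, weights = c(0.8, 0.2),
                                   nCells = 4000, seed = 7)
    expect_equal(nrow(ref), 8000L)   # long form: cells x genes
    frac <- mean(ref$subtype[!duplicated(ref$cell_id)] == "BC1B")
    expect_lt(abs(frac - 0.2), 0.03)
    m1 <- mean(ref$count[ref$gene == "g1" & ref$subtype == "BCa"])
    expect_lt(abs(m1 - 10), 0.5)
    expect_true(all(ref$count >= 0 & ref$count == floor(ref$count)))
})
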