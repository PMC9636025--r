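test_that("discrimination is perfect on a noise-free simulation", {
    setup <- twoSpeciesSetup(seed = 111, meanLog = log(10))
    run <- runPipeline(setup, seed = 112)
    dr <- discriminationRatio(run$assignments, run$parsed,
                              setup$speciesOfBarcode)
    expect_equal(unname(dr[c("human", "mouse")]), c(1, 1))
    # a species with zero mapped reads is reported missing
    hOnly <- run$assignments$species == "human" & !is.na(run$assignments$species)
    drH <- discriminationRatio(run$assignments[hOnly, ], run$parsed[hOnly, ],
                               setup$speciesOfBarcode)
    expect_true(is.na(drH[["mouse"]]))
    expect_equal(drH[["human"]], 1)
})

test_that("an injected barcode swap shows up as its binomial complement", {
    setup <- twoSpeciesSetup(seed = 121, meanLog = log(20))
    run <- runPipeline(setup, swapRate = 0.10, seed = 122)
    dr <- discriminationRatio(run$assignments, run$parsed,
                              setup$speciesOfBarcode)
    ns <- attr(dr, "n")
    z <- qnorm(0.995)
    for (s in c("human", "mouse")) {
        half <- z * sqrt(0.9 * 0.1 / ns[[s]])
        expect_lt(abs(dr[[s]] - 0.9), half,
                  label = paste("swap recovery", s))
    }
    summ <- discriminationSummary(list(dr, dr))
    expect_equal(summ$mean, unname(as.numeric(dr)))
    expect_equal(summ$sd, c(0, 0))
})

test_that("pseudobulk pools exactly the selected cell types", {
    cnt <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 1,
                  dimnames = list("g1", NULL))
    types <- c("rod", "rod", "rod", "BC", "BC", "BC1B")
    pb <- pseudobulk(cnt, types, include = "rod")
    expect_equal(unname(pb$pooled), 6)
    expect_equal(unname(pb$per_cell_mean), 2)
    # excluding a type removes exactly its contribution
    pbAll <- pseudobulk(cnt, types, include = c("BC", "BC1B"))
    pbEx <- pseudobulk(cnt, types, include = c("BC", "BC1B"),
                       exclude = "BC1B")
    expect_equal(unname(pbAll$pooled - pbEx$pooled), 30)
    expect_error(pseudobulk(cnt, types, include = "none"), "empty")
    # brute-force double-loop oracle on a random matrix
    set.seed(31)
    m <- matrix(rpois(200, 5), 10, 20)
    rownames(m) <- sprintf("g%02d", 1:10)
    ty <- sample(c("a", "b", "c"), 20, TRUE)
    pb2 <- pseudobulk(m, ty, include = c("a", "c"), exclude = "c")
    brute <- numeric(10)
    for (i in 1:10) for (j in 1:20)
        if (ty[j] == "a") brute[i] <- brute[i] + m[i, j]
    expect_equal(unname(pb2$pooled), brute)
})

test_that("expected transcripts honor subtype exclusion semantics", {
    ref <- data.frame(cell_id = rep(c("c1", "c2", "c3"), 2),
                      subtype = rep(c("BCa", "BCa", "BC1B"), 2),
                      gene = rep(c("g1", "g2"), each = 3),
                      count = c(5, 5, 5, 2, 4, 90))
    expect_equal(expectedTranscripts(ref, "g1", 100), 500)
    # the excluded subtype carries most of g2's signal
    expect_equal(expectedTranscripts(ref, "g2", 100,
                                     excludeSubtypes = "BC1B"), 300)
    expect_equal(expectedTranscripts(ref, "g2", 100), 3200)
    expect_error(expectedTranscripts(ref, "gX", 10), "gX")
    expect_error(expectedTranscripts(ref, "g1", 0), "nCells")
})

test_that("expected counts equal the analytic mixture mean", {
    means <- matrix(c(12, 3, 40, 8, 1, 2), 3, 2,
                    dimnames = list(c("A", "B", "BC1B"), c("g1", "g2")))
    w <- c(0.5, 0.3, 0.2)
    ref <- simulateSmFISHReference(means, w, nCells = 30000, seed = 17)
    # analytic mixture over the non-excluded subtypes
    wk <- w[1:2] / sum(w[1:2])
    mix <- drop(wk %*% means[1:2, ])
    for (g in c("g1", "g2"))
        expect_lt(abs(expectedTranscripts(ref, g, 50, "BC1B") -
                      mix[[g]] * 50) / (mix[[g]] * 50), 0.03)
})

test_that("sensitivity ratio and its inverted form behave as documented", {
    expect_equal(sensitivity(43, 1000), 4.3)
    expect_equal(sensitivity(100, 100), 100)
    expect_equal(sensitivity(50, 1000, invert = TRUE), 2000)
    expect_error(sensitivity(5, 0), "expected")
    expect_equal(sensitivity(c(10, 20), c(100, 100)), c(10, 20))
})

test_that("layer markers require enrichment against both other layers", {
    de <- function(g, fc, p) data.frame(gene_id = g, log2fc = fc, padj = p)
    tabs <- list(
        ONL_vs_BCL = de(c("a", "b", "c"), c(2, 2, -1), c(0.01, 0.01, 0.2)),
        ONL_vs_GCL = de(c("a", "b", "c"), c(2, -2, 1), c(0.01, 0.01, 0.3)),
        BCL_vs_GCL = de(c("a", "b", "c"), c(-1, -3, 2), c(0.5, 0.01, 0.01)))
    mk <- layerMarkers(tabs, c("ONL", "BCL", "GCL"))
    expect_equal(mk$ONL, "a")     # enriched in both ONL comparisons
    expect_equal(mk$BCL, character(0))
    expect_equal(mk$GCL, "b")     # favored in ONL_vs_GCL and BCL_vs_GCL
    # disjoint by construction
    expect_equal(length(intersect(mk$ONL, mk$GCL)), 0L)
    # brute-force predicate oracle on random tables
    set.seed(47)
    genes <- sprintf("g%02d", 1:40)
    rt <- function() de(genes, rnorm(40), runif(40, 0, 0.2))
    tabs2 <- list(R1_vs_R2 = rt(), R1_vs_R3 = rt(), R2_vs_R3 = rt())
    mk2 <- layerMarkers(tabs2, c("R1", "R2", "R3"), alpha = 0.05)
    for (g in genes) {
        r1 <- tabs2$R1_vs_R2
        r2 <- tabs2$R1_vs_R3
        want <- r1$log2fc[r1$gene_id == g] > 0 & r1$padj[r1$gene_id == g] < 0.05 &
                r2$log2fc[r2$gene_id == g] > 0 & r2$padj[r2$gene_id == g] < 0.05
        expect_equal(g %in% mk2$R1, unname(want), label = g)
    }
    expect_error(layerMarkers(tabs[1:2], c("ONL", "BCL", "GCL")), "missing")
})

test_that("gene body coverage bins positions and normalizes to max 1", {
    # all reads at the transcript start: all mass in bin 0
    prof <- geneBodyCoverage(rep(0, 50), rep(1000, 50))
    expect_equal(prof[1L], 1)
    expect_equal(sum(prof), 1)
    # empty input -> zero profile
    expect_equal(geneBodyCoverage(numeric(0), numeric(0)), rep(0, 100),
                 ignore_attr = TRUE)
    # out-of-range positions are rejected and counted
    p2 <- geneBodyCoverage(c(0, 500, 1000), rep(1000, 3))
    expect_equal(attr(p2, "rejected"), 1L)
    # uniform positions give a flat profile within multinomial tolerance
    set.seed(61)
    pos <- sample(0:999, 20000, TRUE)
    prof3 <- geneBodyCoverage(pos, rep(1000, 20000))
    counts <- prof3 / sum(prof3) * 20000
    expect_gt(suppressWarnings(chisq.test(
        tabulate(floor(pos / 10) + 1, 100))$p.value), 0.001)
    expect_gt(min(prof3), 0.5)
})

test_that("chimeric pair fraction counts doubly mapped discordant pairs", {
    a1 <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                     gene_id = c("g1", "g2", "g3", NA),
                     status = c("assigned", "assigned", "assigned",
                                "unassigned"))
    a2same <- a1
    expect_equal(as.numeric(chimericPairFraction(a1, a2same)), 0)
    a2 <- a1
    a2$gene_id[2] <- "g9"
    f <- chimericPairFraction(a1, a2)
    expect_equal(as.numeric(f), 1 / 3)
    expect_equal(attr(f, "n_pairs"), 3L)
    # no doubly assigned pairs -> NA with a warning
    a2none <- a1; a2none$status <- "unassigned"
    expect_warning(fna <- chimericPairFraction(a1, a2none), "undefined")
    expect_true(is.na(fna))
})

test_that("replicate correlation separates shared signal from noise", {
    set.seed(71)
    mu <- exp(rnorm(1000, 4, 1))
    mkrep <- function() rpois(1000, mu)
    counts <- cbind(r1 = mkrep(), r2 = mkrep(), r3 = mkrep())
    lt <- log2Tpm(counts, rep(1000, 1000))
    rc <- replicateCorrelation(lt)
    expect_equal(nrow(rc), 3L)
    expect_true(all(rc$r_all > 0.9))
    expect_true(all(rc$r_top > 0.9))
    # identical replicates: r = 1
    rci <- replicateCorrelation(cbind(a = lt[, 1], b = lt[, 1]))
    expect_equal(rci$r_all, 1)
    # independent random replicates: |r| small
    ind <- cbind(a = log2Tpm(rpois(1000, exp(rnorm(1000, 4, 1))),
                             rep(1000, 1000)),
                 b = log2Tpm(rpois(1000, exp(rnorm(1000, 4, 1))),
                             rep(1000, 1000)))
    rcn <- replicateCorrelation(ind)
    expect_lt(abs(rcn$r_all), 0.1)
    # zero-variance vector -> NA
    z <- cbind(a = rep(1, 10), b = seq_len(10))
    expect_true(is.na(replicateCorrelation(z, topN = 5)$r_all))
})
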