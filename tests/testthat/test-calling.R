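test_that("amplicon assignment tolerates primer mismatches up to the budget", {
    mp <- toyPanel()
    panel <- mp$panel
    amps <- amplicons(panel)
    fwd <- S4Vectors::mcols(amps)$fwdPrimer[1]
    rev <- S4Vectors::mcols(amps)$revPrimer[1]
    pad <- function(p) paste0(p, randomDnaStr(60))

    set.seed(420)
    expect_equal(assignAmplicon(pad(fwd), pad(rev), panel), "AMP001")

    # two substitutions in the forward primer region still assign
    fwd2 <- fwd
    substr(fwd2, 3, 3) <- setdiff(c("A","C","G","T"), substr(fwd, 3, 3))[1]
    substr(fwd2, 9, 9) <- setdiff(c("A","C","G","T"), substr(fwd, 9, 9))[1]
    expect_equal(assignAmplicon(pad(fwd2), pad(rev), panel), "AMP001")

    # four mismatches exceed the default budget of 3
    fwd4 <- fwd2
    substr(fwd4, 12, 12) <- setdiff(c("A","C","G","T"), substr(fwd, 12, 12))[1]
    substr(fwd4, 15, 15) <- setdiff(c("A","C","G","T"), substr(fwd, 15, 15))[1]
    expect_true(is.na(assignAmplicon(pad(fwd4), pad(rev), panel)))

    # random primers match nothing
    expect_true(is.na(assignAmplicon(randomDnaStr(80), randomDnaStr(80),
                                     panel)))
})

test_that("ambiguous primer matches leave the pair unassigned", {
    set.seed(421)
    insert <- randomDnaStr(80)
    p <- miniPanel(insert)
    amps <- amplicons(p)
    # a second amplicon with identical primers elsewhere
    gr2 <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = 5001, width = GenomicRanges::width(amps)[1]))
    names(gr2) <- "MINI2"
    S4Vectors::mcols(gr2)$fwdPrimer <- S4Vectors::mcols(amps)$fwdPrimer
    S4Vectors::mcols(gr2)$revPrimer <- S4Vectors::mcols(amps)$revPrimer
    refs <- c(refSeqs(p),
              stats::setNames(Biostrings::DNAStringSet(
                  as.character(refSeqs(p))[1]), "MINI2"))
    twin <- AmpliconPanel(c(amps, gr2), refs)
    rp <- readPairFromHap(ampRefStr(twin), readLen = 80)
    expect_true(is.na(assignAmplicon(rp$seq1, rp$seq2, twin)))
})

test_that("read-vs-reference calling extracts substitutions and indels", {
    set.seed(422)
    insert <- paste0(randomDnaStr(40), "AAAAAA", randomDnaStr(40))
    p <- miniPanel(insert)  # amplicon at 501..626, insert at 521..606
    refseq <- ampRefStr(p)
    start <- GenomicRanges::start(amplicons(p))[1]

    # identical read: no variants, full coverage
    m <- list(seq = refseq)
    cr <- callRead(m, "MINI1", p)
    expect_equal(nrow(cr$variants), 0L)
    expect_equal(unname(cr$cov["start"]), start)

    # one substitution at insert offset 10 (local 30)
    hap <- refseq
    local <- 30L
    old <- substr(hap, local, local)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(hap, local, local) <- new
    cr <- callRead(list(seq = hap), "MINI1", p)
    expect_equal(cr$variants,
                 data.frame(chrom = "chrT", pos = start + local - 1L,
                            ref = old, alt = new,
                            stringsAsFactors = FALSE))

    # 3-base deletion inside the A-homopolymer (local 61..66): one
    # anchored deletion whose edit reproduces the read
    hap2 <- paste0(substr(refseq, 1, 62), substr(refseq, 66, nchar(refseq)))
    cr <- callRead(list(seq = hap2), "MINI1", p)
    expect_equal(nrow(cr$variants), 1L)
    v <- cr$variants
    expect_equal(nchar(v$ref) - nchar(v$alt), 3L)
    localPos <- v$pos - start + 1L
    expect_equal(applyLocalEdit(refseq, localPos, v$ref, v$alt), hap2)

    # 2-base insertion: one anchored insertion
    hap3 <- paste0(substr(refseq, 1, 50), "GT",
                   substr(refseq, 51, nchar(refseq)))
    cr <- callRead(list(seq = hap3), "MINI1", p)
    expect_equal(nrow(cr$variants), 1L)
    v <- cr$variants
    expect_equal(nchar(v$alt) - nchar(v$ref), 2L)
    expect_equal(applyLocalEdit(refseq, v$pos - start + 1L, v$ref, v$alt),
                 hap3)
})

test_that("variants in primer regions are dropped; garbage reads are unalignable", {
    set.seed(423)
    p <- miniPanel(randomDnaStr(80))
    refseq <- ampRefStr(p)
    # substitution inside the forward primer (local 5)
    hap <- refseq
    substr(hap, 5, 5) <- setdiff(c("A","C","G","T"), substr(hap, 5, 5))[1]
    cr <- callRead(list(seq = hap), "MINI1", p)
    expect_equal(nrow(cr$variants), 0L)
    # read mostly unrelated to the amplicon
    expect_null(callRead(list(seq = randomDnaStr(120)), "MINI1", p))
})

test_that("phasing groups variants by gap with a hard window boundary", {
    set.seed(424)
    p <- miniPanel(randomDnaStr(80))
    start <- GenomicRanges::start(amplicons(p))[1]
    mkvar <- function(pos, ref = "A", alt = "C")
        data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)

    # single variant: untouched
    ph <- phaseVariants(mkvar(start + 30), "MINI1", p)
    expect_equal(nrow(ph$singles), 1L)
    expect_length(ph$groups, 0)

    refseq <- ampRefStr(p)
    varAt <- function(local) {
        b <- substr(refseq, local, local)
        data.frame(chrom = "chrT", pos = start + local - 1L, ref = b,
                   alt = setdiff(c("A","C","G","T"), b)[1],
                   stringsAsFactors = FALSE)
    }
    # gap of 15 bases between spans: grouped; 16: independent
    v15 <- rbind(varAt(30), varAt(46))   # 15 bases strictly between
    phA <- phaseVariants(v15, "MINI1", p, window = 15)
    expect_length(phA$groups, 1)
    v16 <- rbind(varAt(30), varAt(47))
    phB <- phaseVariants(v16, "MINI1", p, window = 15)
    expect_length(phB$groups, 0)
    expect_equal(nrow(phB$singles), 2L)

    # phasing is order-invariant
    phR <- phaseVariants(v15[2:1, ], "MINI1", p, window = 15)
    expect_equal(phR$groups[[1]]$parent, phA$groups[[1]]$parent)
})

test_that("the phased parent delins reproduces the read segment", {
    set.seed(425)
    p <- miniPanel(randomDnaStr(80))
    refseq <- ampRefStr(p)
    start <- GenomicRanges::start(amplicons(p))[1]
    # two substitutions and an adjacent deletion, all within the window
    hap <- refseq
    b30 <- substr(refseq, 30, 30)
    a30 <- setdiff(c("A","C","G","T"), b30)[1]
    substr(hap, 30, 30) <- a30
    v1 <- data.frame(chrom = "chrT", pos = start + 29L, ref = b30,
                     alt = a30, stringsAsFactors = FALSE)
    # deletion of local 40..41, anchored at 39
    v2 <- data.frame(chrom = "chrT", pos = start + 38L,
                     ref = substr(refseq, 39, 41),
                     alt = substr(refseq, 39, 39),
                     stringsAsFactors = FALSE)
    ph <- phaseVariants(rbind(v1, v2), "MINI1", p, window = 15)
    expect_length(ph$groups, 1)
    parent <- ph$groups[[1]]$parent
    expect_equal(nrow(ph$groups[[1]]$constituents), 2L)
    # applying the parent to the reference equals applying both
    # constituents in turn
    viaParent <- applyLocalEdit(refseq, parent$pos - start + 1L,
                                parent$ref, parent$alt)
    viaBoth <- applyLocalEdit(refseq, 30L, b30, a30)
    viaBoth <- paste0(substr(viaBoth, 1, 39),
                      substr(viaBoth, 42, nchar(viaBoth)))
    expect_equal(viaParent, viaBoth)
})

test_that("sample processing aggregates counts, applies thresholds and caches", {
    mp <- toyPanel()
    panel <- mp$panel
    g <- mp$landmarks$codon600g
    pl <- data.frame(chrom = "chrS", pos = g[1], ref = "G", alt = "A",
                     fraction = 0.25)
    sim <- simulateSample(panel, pl, depth = 400, errorRate = 0,
                          seed = 31, mode = "exact")
    cs <- processSample(sim$fastq1, sim$fastq2, panel, sample = "s")
    df <- calls(cs)
    expect_equal(nrow(df), 1L)
    expect_equal(df$altPairs, 100L)
    expect_equal(df$depthPairs, 400L)
    expect_equal(df$vaf, 0.25)
    expect_equal(df$filter, "PASS")
    st <- runStats(cs)
    expect_equal(st$pairsRead, 1600L)
    expect_equal(st$pairsMerged, 1600L)
    expect_equal(st$pairsAssigned, 1600L)

    # below-threshold variant is excluded by default, kept with emitAll
    pl2 <- data.frame(chrom = "chrS", pos = g[1], ref = "G", alt = "A",
                      fraction = 0.05)
    sim2 <- simulateSample(panel, pl2, depth = 400, errorRate = 0,
                           seed = 32, mode = "exact")
    cs2 <- processSample(sim2$fastq1, sim2$fastq2, panel, sample = "s")
    expect_equal(nrow(calls(cs2)), 0L)
    cs2b <- processSample(sim2$fastq1, sim2$fastq2, panel, sample = "s",
                          emitAll = TRUE)
    expect_equal(calls(cs2b)$filter, "LowVAF")

    # cache equivalence on an error-laden sample
    sim3 <- simulateSample(panel, pl, depth = 150, errorRate = 0.005,
                           seed = 33)
    on <- processSample(sim3$fastq1, sim3$fastq2, panel, sample = "s",
                        cacheEnabled = TRUE, emitAll = TRUE)
    off <- processSample(sim3$fastq1, sim3$fastq2, panel, sample = "s",
                         cacheEnabled = FALSE, emitAll = TRUE)
    expect_identical(calls(on), calls(off))
    expect_equal(runStats(off)$cacheHits, 0L)
    expect_gt(runStats(on)$cacheHitRatio, 0)
})

test_that("an MNP parent is reported with its constituents sharing a link", {
    mp <- toyPanel()
    g <- mp$landmarks$codon600g
    # plant the dinucleotide GT>AG MNP as one haplotype
    pl <- data.frame(chrom = "chrS", pos = g[1], ref = "GT", alt = "AG",
                     fraction = 0.4)
    sim <- simulateSample(mp$panel, pl, depth = 200, errorRate = 0,
                          seed = 34, mode = "exact")
    cs <- processSample(sim$fastq1, sim$fastq2, mp$panel, sample = "s")
    df <- calls(cs)
    expect_equal(nrow(df), 3L)
    parent <- df[df$isMnpParent, ]
    kids <- df[!df$isMnpParent, ]
    expect_equal(nrow(parent), 1L)
    expect_equal(parent$ref, "GT")
    expect_equal(parent$alt, "AG")
    expect_equal(unique(kids$mnpLink), parent$mnpLink)
    expect_equal(kids$altPairs, c(80L, 80L))
    expect_equal(parent$altPairs, 80L)
})

test_that("per-locus support never exceeds depth", {
    mp <- toyPanel()
    g <- mp$landmarks$codon600g
    pl <- data.frame(chrom = "chrS",
                     pos = c(g[1], g[1]), ref = c("G", "G"),
                     alt = c("A", "C"), fraction = c(0.3, 0.3))
    sim <- simulateSample(mp$panel, pl, depth = 200, errorRate = 0.002,
                          seed = 35)
    cs <- processSample(sim$fastq1, sim$fastq2, mp$panel, sample = "s",
                        emitAll = TRUE)
    df <- calls(cs)
    for (loc in unique(df$pos[!df$isMnpParent])) {
        sub <- df[df$pos == loc & !df$isMnpParent &
                  nchar(df$ref) == 1 & nchar(df$alt) == 1, ]
        if (nrow(sub))
            expect_lte(sum(sub$altPairs), max(sub$depthPairs))
    }
})

test_that("empty input yields an empty call set with valid statistics", {
    f1 <- tempfile(fileext = ".fastq.gz")
    f2 <- tempfile(fileext = ".fastq.gz")
    ampliCall:::writeFastq(character(0), list(), character(0), f1)
    ampliCall:::writeFastq(character(0), list(), character(0), f2)
    cs <- processSample(f1, f2, toyPanel()$panel)
    expect_equal(nrow(calls(cs)), 0)
    st <- runStats(cs)
    expect_equal(st$pairsRead, 0L)
    expect_true(is.na(st$cacheHitRatio))
})

test_that("evaluation computes sensitivity and precision", {
    truth <- data.frame(chrom = "chrS", pos = 1:9, ref = "A", alt = "T",
                        stringsAsFactors = FALSE)
    called <- rbind(truth[1:8, ],
                    data.frame(chrom = "chrS", pos = c(100, 101),
                               ref = "G", alt = "C"))
    m <- evaluateCalls(called, truth)
    expect_equal(m$TP, 8)
    expect_equal(m$FP, 2)
    expect_equal(m$FN, 1)
    expect_equal(m$sensitivity, 8 / 9)
    expect_equal(m$precision, 0.8)

    perfect <- evaluateCalls(truth, truth)
    expect_equal(perfect$sensitivity, 1)
    expect_equal(perfect$precision, 1)

    none <- evaluateCalls(truth[0, ], truth)
    expect_equal(none$TP, 0)
    expect_equal(none$FN, 9)
    expect_equal(none$sensitivity, 0)

    emptyTruth <- evaluateCalls(truth, truth[0, ])
    expect_true(is.na(emptyTruth$sensitivity))
})
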