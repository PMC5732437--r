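test_that("parsimonious trimming reaches the minimal anchored form", {
    v <- trimParsimonious("chr1", 100, "CTT", "CT")
    expect_equal(v[c("pos", "ref", "alt")],
                 list(pos = 100L, ref = "CT", alt = "C"))
    v <- trimParsimonious("chr1", 50, "ACAC", "AC")
    expect_equal(v[c("pos", "ref", "alt")],
                 list(pos = 50L, ref = "ACA", alt = "A"))
    # already minimal SNV
    v <- trimParsimonious("chr1", 100, "G", "A")
    expect_equal(v[c("pos", "ref", "alt")],
                 list(pos = 100L, ref = "G", alt = "A"))
    # padded substitution trims to a plain SNV
    v <- trimParsimonious("chr1", 100, "GTAC", "GAAC")
    expect_equal(v[c("pos", "ref", "alt")],
                 list(pos = 101L, ref = "T", alt = "A"))
    # insertion keeps its single anchor base
    v <- trimParsimonious("chr1", 10, "AT", "AGGT")
    expect_equal(v[c("pos", "ref", "alt")],
                 list(pos = 10L, ref = "A", alt = "AGG"))
    expect_error(trimParsimonious("chr1", 10, "AC", "AC"), "not a variant")
    # idempotence on a sample of forms
    for (enc in list(c("CT", "C"), c("A", "AGG"), c("G", "A"),
                     c("GT", "AG"))) {
        v1 <- trimParsimonious("chr1", 20, enc[1], enc[2])
        v2 <- trimParsimonious(v1$chrom, v1$pos, v1$ref, v1$alt)
        expect_equal(v1, v2)
    }
})

test_that("3' shifting lands indels at the transcript-directed end of repeats", {
    mp <- toyPanel()
    panel <- mp$panel
    acc <- ampliconRefAccessor(panel)
    # find a homopolymer run inside the BRAF (plus-strand) amplicon 1
    amps <- amplicons(panel)
    s1 <- GenomicRanges::start(amps)[1]
    insert <- acc("chrS", s1 + 25L, GenomicRanges::end(amps)[1] - 25L)
    m <- regexpr("A{2,}|C{2,}|G{2,}|T{2,}", insert)
    runStart <- s1 + 25L + as.integer(m) - 1L
    runLen <- attr(m, "match.length")
    runBase <- acc("chrS", runStart, runStart)
    tx <- transcriptModels(panel)[["NM_TOY001.1"]]

    # deletion of the first run base, anchored upstream
    a0 <- acc("chrS", runStart - 1L, runStart - 1L)
    v <- trimParsimonious("chrS", runStart - 1L, paste0(a0, runBase), a0)
    sh <- shift3Prime(v, tx, acc)
    # plus strand: deletion reported at the run's last base
    expect_equal(sh$pos, runStart + runLen - 2L)
    expect_true(attr(sh, "shifted"))
    # an SNV is never shifted
    ref <- acc("chrS", runStart, runStart)
    vs <- trimParsimonious("chrS", runStart, ref,
                           setdiff(c("A","C","G","T"), ref)[1])
    expect_false(attr(shift3Prime(vs, tx, acc), "shifted"))

    # minus-strand transcript: the same kind of deletion moves to the
    # genomically first base of its run (amplicon 2 under NM_TOY002.1)
    s2 <- GenomicRanges::start(amps)[2]
    ins2 <- acc("chrS", s2 + 25L, GenomicRanges::end(amps)[2] - 25L)
    m2 <- regexpr("A{2,}|C{2,}|G{2,}|T{2,}", ins2)
    run2 <- s2 + 25L + as.integer(m2) - 1L
    len2 <- attr(m2, "match.length")
    txm <- transcriptModels(panel)[["NM_TOY002.1"]]
    # anchor the deletion at the LAST base of the run
    aL <- acc("chrS", run2 + len2 - 2L, run2 + len2 - 2L)
    vm <- trimParsimonious("chrS", run2 + len2 - 2L,
                           paste0(aL, acc("chrS", run2 + len2 - 1L,
                                          run2 + len2 - 1L)), aL)
    shm <- shift3Prime(vm, txm, acc)
    expect_equal(shm$pos, run2 - 1L)  # anchored just before the run
})

test_that("shift-equivalent encodings normalize to one representation", {
    mp <- toyPanel()
    panel <- mp$panel
    acc <- ampliconRefAccessor(panel)
    amps <- amplicons(panel)
    set.seed(430)
    refAcc <- ampliconRefAccessor(panel)
    for (ampIdx in 1:2) {
        st <- GenomicRanges::start(amps)[ampIdx]
        refseq <- ampRefStr(panel, ampIdx)
        for (k in 1:25) {
            # random small deletion or insertion inside the insert
            local <- sample(30:100, 1)
            isDel <- runif(1) < 0.5
            L <- sample(1:3, 1)
            if (isDel) {
                ref <- substr(refseq, local, local + L)
                alt <- substr(refseq, local, local)
            } else {
                ref <- substr(refseq, local, local)
                alt <- paste0(ref, randomDnaStr(L))
            }
            encs <- enumerateEncodings(refseq, local, ref, alt,
                                       window = 6L)
            norms <- unique(vapply(encs, function(e)
                paste(unlist(normalizeVariant("chrS",
                    st + e$pos - 1L, e$ref, e$alt, panel,
                    refAcc = refAcc)[c("pos", "ref", "alt", "hgvsG",
                                       "hgvsC")]),
                    collapse = "|"), character(1)))
            expect_length(norms, 1)
        }
    }
})

test_that("normalization is idempotent and round-trips the edit", {
    mp <- toyPanel()
    panel <- mp$panel
    acc <- ampliconRefAccessor(panel)
    amps <- amplicons(panel)
    st <- GenomicRanges::start(amps)[1]
    refseq <- ampRefStr(panel, 1)
    set.seed(431)
    for (k in 1:40) {
        local <- sample(30:110, 1)
        type <- sample(c("snv", "del", "ins"), 1)
        if (type == "snv") {
            ref <- substr(refseq, local, local)
            alt <- setdiff(c("A","C","G","T"), ref)[1]
        } else if (type == "del") {
            ref <- substr(refseq, local, local + sample(1:4, 1))
            alt <- substr(refseq, local, local)
        } else {
            ref <- substr(refseq, local, local)
            alt <- paste0(ref, randomDnaStr(sample(1:3, 1)))
        }
        n1 <- normalizeVariant("chrS", st + local - 1L, ref, alt, panel)
        n2 <- normalizeVariant(n1$chrom, n1$pos, n1$ref, n1$alt, panel)
        expect_equal(n1[c("pos", "ref", "alt", "kind", "hgvsG", "hgvsC")],
                     n2[c("pos", "ref", "alt", "kind", "hgvsG", "hgvsC")])
        # edit equivalence: canonical and original encodings mutate the
        # reference identically
        expect_equal(
            applyLocalEdit(refseq, n1$pos - st + 1L, n1$ref, n1$alt),
            applyLocalEdit(refseq, local, ref, alt))
    }
})

test_that("insertions equal to their upstream context become dup", {
    mp <- toyPanel()
    panel <- mp$panel
    acc <- ampliconRefAccessor(panel)
    d <- mp$landmarks$dupSiteG
    anchor <- acc("chrS", d[2], d[2])
    dupSeq <- acc("chrS", d[1], d[2])
    nv <- normalizeVariant("chrS", d[2], anchor,
                           paste0(anchor, dupSeq), panel)
    expect_equal(nv$kind, "dup")
    expect_equal(nv$hgvsC, "NM_TOY001.1:c.21_22dup")
    # single-base dup
    b21 <- acc("chrS", d[1], d[1])
    b20 <- acc("chrS", d[1] - 1L, d[1] - 1L)
    nv1 <- normalizeVariant("chrS", d[1] - 1L, b20, paste0(b20, b21),
                            panel)
    expect_equal(nv1$kind, "dup")
    # insertion of foreign sequence stays ins
    foreign <- if (substr(dupSeq, 1, 1) == "C") "GG" else "CC"
    nv2 <- normalizeVariant("chrS", d[2], anchor,
                            paste0(anchor, foreign), panel)
    expect_equal(nv2$kind, "ins")
})

test_that("transcript selection honours preference then exon distance", {
    # two overlapping transcripts; only one preferred
    mkTx <- function(acc, gene, exS, exE, strand = "+") {
        w <- sum(exE - exS + 1)
        TranscriptModel(acc, gene, "chr9", strand, exS, exE,
                        1, w - (w %% 3), paste(rep("A", w), collapse = ""))
    }
    txA <- mkTx("NM_0001.1", "G1", c(100, 300), c(199, 399))
    txB <- mkTx("NM_0002.1", "G1", c(100, 360), c(199, 459))
    txs <- list(NM_0001.1 = txA, NM_0002.1 = txB)

    sel <- selectTranscript("chr9", 150, "A", txs,
                            preferred = c(G1 = "NM_0002.1"))
    expect_equal(accession(sel), "NM_0002.1")

    # no preference: variant at 310 is exonic in A (0) but 50 away in B
    sel <- selectTranscript("chr9", 310, "A", txs)
    expect_equal(accession(sel), "NM_0001.1")

    # tie on distance: lexicographically smallest accession
    sel <- selectTranscript("chr9", 150, "A", txs)
    expect_equal(accession(sel), "NM_0001.1")

    # no overlap: intergenic
    expect_null(selectTranscript("chr9", 5000, "A", txs))
    expect_null(selectTranscript("chr1", 150, "A", txs))
})

test_that("coding and intronic c. coordinates render correctly", {
    # plus strand, 2 exons of 30, CDS 10..57 (48 nt)
    seqs <- paste(rep("ACGTAC", 10), collapse = "")
    tx <- TranscriptModel("NM_X.1", "GX", "chr5", "+",
                          exonStarts = c(1001, 2001),
                          exonEnds = c(1030, 2030),
                          cdsStart = 10, cdsEnd = 57, splicedSeq = seqs)
    expect_equal(ampliCall:::genomicToTx(tx, 1001), list(n = 1L, offset = 0L))
    expect_equal(ampliCall:::genomicToTx(tx, 2001), list(n = 31L, offset = 0L))
    # 3 bases past exon 1 end: c.N+3
    expect_equal(ampliCall:::genomicToTx(tx, 1033),
                 list(n = 30L, offset = 3L))
    # 3 bases before exon 2 start: c.(N+1)-3
    expect_equal(ampliCall:::genomicToTx(tx, 1998),
                 list(n = 31L, offset = -3L))
    expect_equal(ampliCall:::cNotation(tx, 30L, 3L), "21+3")
    expect_equal(ampliCall:::cNotation(tx, 31L, -3L), "22-3")
    expect_equal(ampliCall:::cNotation(tx, 5L, 0L), "-5")   # 5' UTR
    expect_equal(ampliCall:::cNotation(tx, 58L, 0L), "*1")  # 3' UTR

    # minus strand: transcript position 1 is the genomic end of the
    # last exon
    txm <- TranscriptModel("NM_Y.1", "GY", "chr5", "-",
                           exonStarts = c(1001, 2001),
                           exonEnds = c(1030, 2030),
                           cdsStart = 10, cdsEnd = 57, splicedSeq = seqs)
    expect_equal(ampliCall:::genomicToTx(txm, 2030), list(n = 1L, offset = 0L))
    expect_equal(ampliCall:::genomicToTx(txm, 1001), list(n = 60L, offset = 0L))
    # intron, 3 genomic bases before exon 2 start = transcript +3 after
    # transcript exon 1 (which ends at txm position 30)
    expect_equal(ampliCall:::genomicToTx(txm, 1998),
                 list(n = 30L, offset = 3L))
})

test_that("protein consequences cover sub, delins, synonymous, frameshift", {
    mp <- toyPanel()
    tx <- transcriptModels(mp$panel)[["NM_TOY001.1"]]
    # BRAF codon 600 worked example
    expect_equal(predictProtein(tx, 1798, 1798, "A"), "p.V600M")
    expect_equal(predictProtein(tx, 1799, 1799, "G"), "p.V600G")
    expect_equal(predictProtein(tx, 1798, 1799, "AG"), "p.V600R")
    # synonymous: GTG -> GTA is still valine
    expect_equal(predictProtein(tx, 1800, 1800, "A"), "p.V600=")
    # three-letter rendering
    expect_equal(predictProtein(tx, 1798, 1799, "AG", oneLetter = FALSE),
                 "p.Val600Arg")
    # frameshift: deleting one base of codon 600 shifts the frame; the
    # stop distance comes from translating the mutated CDS
    fs <- predictProtein(tx, 1798, 1798, "")
    expect_match(fs, "^p\\.V600.*fs\\*\\d+$|^p\\.V600\\*$")
    cds <- substr(tx@splicedSeq, tx@cdsStart, tx@cdsEnd)
    mut <- paste0(substr(cds, 1, 1797), substr(cds, 1799, nchar(cds)))
    aaMut <- ampliCall:::translateCds(mut)
    firstStop <- regexpr("*", substr(aaMut, 600, nchar(aaMut)),
                         fixed = TRUE)
    if (firstStop > 1)
        expect_equal(fs, sprintf("p.V600%sfs*%d",
                                 substr(aaMut, 600, 600),
                                 as.integer(firstStop)))
    # initiator codon disruption
    cdsFirst <- substr(tx@splicedSeq, tx@cdsStart, tx@cdsStart)
    other <- setdiff(c("A", "C", "G", "T"), cdsFirst)[1]
    expect_equal(predictProtein(tx, 1, 1, other), "p.?")
    # in-frame deletion of a whole codon
    del <- predictProtein(tx, 1798, 1800, "")
    expect_match(del, "^p\\..*del")
})
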