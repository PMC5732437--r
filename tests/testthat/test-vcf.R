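emptyCallSet <- function(sample = "s") {
    new("CallSet", sample = sample,
        calls = data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           amplicons = character(0),
                           altPairs = integer(0),
                           depthPairs = integer(0), vaf = numeric(0),
                           isMnpParent = logical(0),
                           mnpLink = character(0),
                           filter = character(0),
                           stringsAsFactors = FALSE),
        stats = list())
}

oneCallSet <- function(vaf = 0.25, depth = 2000L) {
    alt <- as.integer(round(vaf * depth))
    new("CallSet", sample = "s",
        calls = data.frame(chrom = "chrS", pos = 2858L, ref = "G",
                           alt = "A", amplicons = "AMP001",
                           altPairs = alt, depthPairs = depth,
                           vaf = alt / depth, isMnpParent = FALSE,
                           mnpLink = NA_character_, filter = "PASS",
                           stringsAsFactors = FALSE),
        stats = list())
}

test_that("an empty call set writes a parseable header-only VCF", {
    out <- tempfile(fileext = ".vcf")
    writeVcfFile(emptyCallSet(), out, panel = toyPanel()$panel)
    v <- readVcfFile(out)
    expect_equal(nrow(v$records), 0)
    expect_equal(v$samples, "s")
    expect_equal(length(VariantAnnotation::readVcf(out)), 0)
})

test_that("sample fields carry DP/VD/AF consistent with the counts", {
    out <- tempfile(fileext = ".vcf")
    writeVcfFile(oneCallSet(0.25, 2000L), out)
    v <- readVcfFile(out)
    expect_equal(v$records$s, "2000:500:0.25")
    expect_equal(v$records$format, "DP:VD:AF")
})

test_that("MNP groups write three records sharing MNP_LINK", {
    mp <- toyPanel()
    g <- mp$landmarks$codon600g
    pl <- data.frame(chrom = "chrS", pos = g[1], ref = "GT", alt = "AG",
                     fraction = 0.4)
    sim <- simulateSample(mp$panel, pl, depth = 100, errorRate = 0,
                          seed = 51, mode = "exact")
    cs <- normalizeCalls(processSample(sim$fastq1, sim$fastq2, mp$panel,
                                       sample = "s"), mp$panel)
    out <- tempfile(fileext = ".vcf")
    writeVcfFile(cs, out, panel = mp$panel)
    v <- readVcfFile(out)
    expect_equal(nrow(v$records), 3)
    infos <- lapply(v$records$info, ampliCall:::parseInfoString)
    links <- vapply(infos, function(x) unname(x["MNP_LINK"]), "")
    expect_equal(length(unique(links)), 1)
    expect_false(any(is.na(links)))
    isParent <- vapply(infos, function(x) "MNP_PARENT" %in% names(x),
                       NA)
    expect_equal(sum(isParent), 1)
})

test_that("write -> read -> write is byte-stable", {
    mp <- toyPanel()
    g <- mp$landmarks$codon600g
    pl <- data.frame(chrom = "chrS", pos = g[1], ref = "G", alt = "A",
                     fraction = 0.3)
    sim <- simulateSample(mp$panel, pl, depth = 100, errorRate = 0,
                          seed = 52, mode = "exact")
    cs <- normalizeCalls(processSample(sim$fastq1, sim$fastq2, mp$panel,
                                       sample = "s"), mp$panel)
    f1 <- tempfile(fileext = ".vcf")
    writeVcfFile(cs, f1, panel = mp$panel)
    f2 <- tempfile(fileext = ".vcf")
    writeSimpleVcf(readVcfFile(f1), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("duplicate records are fatal and named", {
    cs <- oneCallSet()
    bad <- calls(cs)[c(1, 1), ]
    csBad <- new("CallSet", sample = "s", calls = bad, stats = list())
    expect_error(writeVcfFile(csBad, tempfile()), "chrS:2858:G:A")
})

test_that("malformed and truncated VCFs report the offending line", {
    out <- tempfile(fileext = ".vcf")
    writeVcfFile(oneCallSet(), out)
    lines <- readLines(out)
    truncated <- c(lines, substr(lines[length(lines)], 1, 20))
    f <- tempfile(fileext = ".vcf")
    writeLines(truncated, f)
    expect_error(readVcfFile(f), "line")
    expect_error(readVcfFile(tempfile()), "not found")
})

test_that("the TSV export has stable columns and escaped values", {
    mp <- toyPanel()
    g <- mp$landmarks$codon600g
    amp2pos <- GenomicRanges::start(amplicons(mp$panel))[2] + 60L
    pl <- data.frame(chrom = "chrS",
                     pos = c(g[1], amp2pos, mp$landmarks$dupSiteG[1]),
                     ref = "X", alt = "Y", fraction = 0.3,
                     stringsAsFactors = FALSE)
    acc <- ampliconRefAccessor(mp$panel)
    pl$ref <- vapply(pl$pos, function(p) acc("chrS", p, p), "")
    pl$alt <- vapply(pl$ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
    sim <- simulateSample(mp$panel, pl, depth = 100, errorRate = 0,
                          seed = 53, mode = "exact")
    cs <- normalizeCalls(processSample(sim$fastq1, sim$fastq2, mp$panel,
                                       sample = "s"), mp$panel)
    hg <- calls(cs)$hgvsG
    ann <- stats::setNames(
        list(c(f1.a = "with\ttab", f2.b = "plain")), hg[1])
    out <- tempfile(fileext = ".tsv")
    writeVariantTsv(cs, out, annotations = ann,
                    fields = c("f1.a", "f2.b"))
    lines <- readLines(out)
    tab <- strsplit(lines, "\t")
    expect_equal(length(tab), 4)            # header + 3 records
    # 15 columns (13 fixed + 2 annotation): 14 separators per line
    nSep <- vapply(gregexpr("\t", lines, fixed = TRUE), length,
                   integer(1))
    expect_true(all(nSep == 14))
    expect_equal(tab[[1]][14:15], c("f1.a", "f2.b"))
    # the embedded tab is encoded, not splitting the row
    row1 <- tab[[which(vapply(tab, `[`, "", 8) == hg[1])]]
    expect_equal(row1[14], "with%09tab")

    # empty call set: header-only file
    out0 <- tempfile(fileext = ".tsv")
    writeVariantTsv(emptyCallSet(), out0)
    expect_equal(length(readLines(out0)), 1)
})

test_that("foreign INFO keys survive the annotate-only rewrite", {
    mp <- makePanel(dir = tempfile("pan"), nAmplicons = 3, seed = 54)
    g <- mp$landmarks$codon600g
    acc <- ampliconRefAccessor(mp$panel)
    refb <- acc("chrS", g[1], g[1])
    altb <- setdiff(c("A","C","G","T"), refb)[1]
    f <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chrS,length=30000>",
        '##INFO=<ID=FOREIGN,Number=1,Type=String,Description="kept">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", "s1"), collapse = "\t"),
        paste(c("chrS", g[1], ".", refb, altb, ".", "PASS",
                "FOREIGN=keepme", "DP:VD:AF", "100:30:0.3"),
              collapse = "\t")), f)
    res <- runPipeline(manifest = mp$paths$manifest,
                       fasta = mp$paths$fasta,
                       transcripts = mp$paths$transcripts,
                       preferred = mp$paths$preferred,
                       vcf = f, out = tempfile("anno"))
    v <- readVcfFile(res$vcf)
    info <- ampliCall:::parseInfoString(v$records$info[1])
    expect_equal(unname(info["FOREIGN"]), "keepme")
    expect_equal(unname(info["HGVSC"]),
                 sprintf("NM_TOY001.1:c.1798%s>%s", refb, altb))
    # HGVS INFO declarations were added to the header
    expect_true(any(grepl("ID=HGVSC", v$headerLines)))
})
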