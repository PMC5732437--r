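# Internal string/sequence helpers shared across modules.

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

substr1 <- function(x, start, end) {
    if (end < start) return("")
    substr(x, start, end)
}

hammingDistance <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    sum(av != bv)
}

# VCF-style application of a variant to a sequence given 1-based local pos
applyEdit <- function(seq, pos, ref, alt) {
    stopifnot(substr1(seq, pos, pos + nchar(ref) - 1L) == ref)
    paste0(substr1(seq, 1L, pos - 1L), alt,
           substr1(seq, pos + nchar(ref), nchar(seq)))
}

# percent-encode characters that break VCF INFO values; '%' first so the
# escape character itself survives a decode round trip
percentEncode <- function(x, chars = c(";", "=", ",", " ", "\t", "\n")) {
    x <- as.character(x)
    for (ch in c("%", chars)) {
        x <- gsub(ch, sprintf("%%%02X", utf8ToInt(ch)), x, fixed = TRUE)
    }
    x
}

#' @importFrom utils URLdecode
percentDecode <- function(x) {
    vapply(as.character(x), utils::URLdecode, character(1), USE.NAMES = FALSE)
}

isDna <- function(x, allowN = TRUE) {
    alpha <- if (allowN) "ACGTN" else "ACGT"
    grepl(sprintf("^[%s]*$", alpha), x)
}
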