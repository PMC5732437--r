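# Variant annotation: a pluggable backend contract that, given HGVSg
# identifiers and a list of hierarchical "dotted" field names (e.g.
# cadd.gene.prot.domain), returns per-variant attribute values to be
# injected into VCF INFO.

#' Annotation backends
#'
#' `AnnotationBackend` is the abstract contract: implementations resolve
#' a list of HGVSg identifiers against a set of dotted field names and
#' return one record per identifier (possibly empty - not every variant
#' has every attribute). Two implementations ship with the package:
#'
#' * `FixtureAnnotationBackend` reads a local JSON file mapping HGVSg
#'   strings to `{field: value}` objects; fully offline, used in tests.
#' * `HttpAnnotationBackend` queries a MyVariant-style batch HTTP API
#'   (batches of `batchSize` ids, one retry); requires network access
#'   and is never exercised by the test suite.
#'
#' @aliases AnnotationBackend-class FixtureAnnotationBackend-class
#'   HttpAnnotationBackend-class
#' @exportClass AnnotationBackend FixtureAnnotationBackend HttpAnnotationBackend
setClass("AnnotationBackend", representation("VIRTUAL"))

#' @rdname AnnotationBackend-class
setClass("FixtureAnnotationBackend",
    contains = "AnnotationBackend",
    representation(data = "list"))

#' @rdname AnnotationBackend-class
setClass("HttpAnnotationBackend",
    contains = "AnnotationBackend",
    representation(baseUrl = "character", batchSize = "integer"))

#' Create the offline fixture annotation backend
#'
#' @param path JSON file: an object keyed by HGVSg identifier, each
#'   value an object of dotted field name to scalar value.
#' @return A `FixtureAnnotationBackend`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"chrS:g.100A>T": {"cadd.gene.prot.domain": "kinase"}}', f)
#' be <- fixtureBackend(f)
#' fetchAnnotations(be, "chrS:g.100A>T", "cadd.gene.prot.domain")
#' @export
fixtureBackend <- function(path) {
    if (!file.exists(path))
        stop("annotation fixture not found: ", path)
    new("FixtureAnnotationBackend",
        data = jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' Create the HTTP batch annotation backend
#'
#' @param baseUrl endpoint accepting `POST`-style batched queries of ids
#'   and fields (MyVariant-compatible GET fallback is used here:
#'   `baseUrl?ids=...&fields=...`).
#' @param batchSize ids per request.
#' @return An `HttpAnnotationBackend`.
#' @export
httpBackend <- function(baseUrl, batchSize = 100L) {
    new("HttpAnnotationBackend", baseUrl = baseUrl,
        batchSize = as.integer(batchSize))
}

dottedFieldOk <- function(fields) {
    grepl("^[A-Za-z0-9_]+(\\.[A-Za-z0-9_]+)*$", fields)
}

#' Fetch annotations for a set of variants
#'
#' @param backend an [AnnotationBackend-class] implementation.
#' @param ids character vector of HGVSg identifiers.
#' @param fields character vector of dotted field names.
#' @return A named list (one element per id, in input order) of named
#'   character vectors; ids without data yield empty vectors, and only
#'   requested fields are returned.
#' @export
setGeneric("fetchAnnotations", function(backend, ids, fields)
    standardGeneric("fetchAnnotations"))

#' @rdname fetchAnnotations
#' @export
setMethod("fetchAnnotations", "FixtureAnnotationBackend",
    function(backend, ids, fields) {
        bad <- fields[!dottedFieldOk(fields)]
        if (length(bad))
            stop("malformed dotted field name(s): ",
                 paste(bad, collapse = ", "))
        out <- lapply(ids, function(id) {
            rec <- backend@data[[id]]
            if (is.null(rec)) return(stats::setNames(character(0),
                                                     character(0)))
            keep <- intersect(names(rec), fields)
            vapply(rec[keep], function(x) as.character(x)[1L],
                   character(1))
        })
        stats::setNames(out, ids)
    })

#' @rdname fetchAnnotations
#' @export
setMethod("fetchAnnotations", "HttpAnnotationBackend",
    function(backend, ids, fields) {
        bad <- fields[!dottedFieldOk(fields)]
        if (length(bad))
            stop("malformed dotted field name(s): ",
                 paste(bad, collapse = ", "))
        flatten <- function(x, prefix = "") {
            if (!is.list(x))
                return(stats::setNames(as.character(x)[1L], prefix))
            out <- character(0)
            for (nm in names(x))
                out <- c(out, flatten(x[[nm]], if (nzchar(prefix))
                    paste0(prefix, ".", nm) else nm))
            out
        }
        queryBatch <- function(batch) {
            u <- paste0(backend@baseUrl, "?ids=",
                        utils::URLencode(paste(batch, collapse = ","),
                                         reserved = TRUE),
                        "&fields=",
                        utils::URLencode(paste(fields, collapse = ","),
                                         reserved = TRUE))
            for (try in 1:2) {
                res <- tryCatch(jsonlite::fromJSON(u,
                                                   simplifyVector = FALSE),
                                error = function(e) NULL)
                if (!is.null(res)) return(res)
            }
            stop("annotation backend unreachable: ", backend@baseUrl,
                 call. = FALSE)
        }
        out <- stats::setNames(
            rep(list(stats::setNames(character(0), character(0))),
                length(ids)), ids)
        for (i in seq(1L, length(ids), by = backend@batchSize)) {
            batch <- ids[i:min(i + backend@batchSize - 1L, length(ids))]
            res <- queryBatch(batch)
            for (rec in res) {
                id <- rec[["_id"]]
                if (is.null(id) || !id %in% ids) next
                vals <- flatten(rec[setdiff(names(rec), "_id")])
                out[[id]] <- vals[names(vals) %in% fields]
            }
        }
        out
    })

sanitizeInfoKey <- function(k) gsub("[^A-Za-z0-9_.]", "_", k)

#' Inject HGVS names and annotations into a VCF INFO mapping
#'
#' Adds (or replaces) `HGVSG`/`HGVSC`/`HGVSP` and one key per dotted
#' annotation field. Existing keys keep their position; new keys are
#' appended. Keys are sanitized to `[A-Za-z0-9_.]` (dots preserved) and
#' values percent-encoded so the record remains parseable VCF.
#'
#' @param info named character vector of the record's current INFO
#'   entries (flags have value `NA`); may be empty.
#' @param triple named list/vector with `hgvsG`, `hgvsC`, `hgvsP`
#'   (elements may be `NA`).
#' @param ann named character vector of annotation values for this
#'   variant (dotted names).
#' @return The updated named character vector.
#' @export
injectInfo <- function(info = character(0), triple = NULL,
                       ann = character(0)) {
    setKey <- function(info, k, v) {
        if (is.na(v)) return(info)
        k <- sanitizeInfoKey(k)
        info[k] <- percentEncode(v)
        info
    }
    if (!is.null(triple)) {
        info <- setKey(info, "HGVSG", triple$hgvsG)
        info <- setKey(info, "HGVSC", triple$hgvsC)
        info <- setKey(info, "HGVSP", triple$hgvsP)
    }
    if (length(ann))
        for (k in names(ann)) info <- setKey(info, k, ann[[k]])
    info
}
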