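#' Accessors for motif model parameters and search results
#'
#' \code{motifLength} and \code{mutationBound} return the (l, d) parameters;
#' \code{distanceThreshold} returns the derived pairwise filter threshold 2d.
#' \code{cliqueStarts} returns the 0-based start matrix of a search result
#' (one row per clique, one column per sequence) and \code{cliqueStrings}
#' the corresponding character matrix of l-mers. \code{isComplete} reports
#' whether the search ran to exhaustion (FALSE after an early stop).
#'
#' @param x a [MotifModel-class], [MotifCliques-class] or
#'   [PlantedDataset-class] object, as appropriate.
#' @return See the method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("mutationBound", function(x) standardGeneric("mutationBound"))

#' @rdname accessors
#' @export
setGeneric("distanceThreshold",
           function(x) standardGeneric("distanceThreshold"))

#' @rdname accessors
#' @export
setGeneric("cliqueStarts", function(x) standardGeneric("cliqueStarts"))

#' @rdname accessors
#' @export
setGeneric("cliqueStrings", function(x) standardGeneric("cliqueStrings"))

#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname accessors
#' @export
setGeneric("trueMotif", function(x) standardGeneric("trueMotif"))

#' @rdname accessors
#' @export
setGeneric("plantedStarts", function(x) standardGeneric("plantedStarts"))

#' @rdname accessors
#' @export
setMethod("motifLength", "MotifModel", function(x) x@l)

#' @rdname accessors
#' @export
setMethod("mutationBound", "MotifModel", function(x) x@d)

#' @rdname accessors
#' @export
setMethod("distanceThreshold", "MotifModel", function(x) 2L * x@d)

#' @rdname accessors
#' @export
setMethod("cliqueStarts", "MotifCliques", function(x) x@starts)

#' @rdname accessors
#' @export
setMethod("cliqueStrings", "MotifCliques", function(x) {
    st <- x@starts
    l <- x@model@l
    out <- matrix(character(0), nrow(st), ncol(st))
    colnames(out) <- names(x@sequences)
    if (nrow(st) == 0L) return(out)
    seqs <- as.character(x@sequences)
    for (k in seq_len(ncol(st)))
        out[, k] <- substring(seqs[k], st[, k] + 1L, st[, k] + l)
    out
})

#' @rdname accessors
#' @export
setMethod("isComplete", "MotifCliques", function(x) x@complete)

#' @rdname accessors
#' @export
setMethod("trueMotif", "PlantedDataset", function(x) x@trueMotif)

#' @rdname accessors
#' @export
setMethod("plantedStarts", "PlantedDataset", function(x) x@plantedStarts)

#' @rdname accessors
#' @export
setMethod("length", "MotifCliques", function(x) nrow(x@starts))

setMethod("show", "MotifModel", function(object) {
    cat(sprintf("MotifModel (l = %d, d = %d): pairwise threshold 2d = %d\n",
                object@l, object@d, 2L * object@d))
})

setMethod("show", "MotifCliques", function(object) {
    cat(sprintf(
        "MotifCliques: %d clique(s) over %d sequences, (l, d) = (%d, %d)%s\n",
        nrow(object@starts), length(object@sequences),
        object@model@l, object@model@d,
        if (object@complete) "" else " [search stopped early: partial]"))
    n <- min(5L, nrow(object@starts))
    if (n > 0L) {
        cat("0-based starts (first", n, "of", nrow(object@starts), "):\n")
        print(object@starts[seq_len(n), , drop = FALSE])
    }
})

setMethod("show", "PlantedDataset", function(object) {
    cat(sprintf(
        "PlantedDataset: m = %d, n = %s, (l, d) = (%d, %d), mode = %s, seed = %d\n",
        length(object@sequences),
        paste(range(Biostrings::width(object@sequences)), collapse = "-"),
        object@model@l, object@model@d, object@mode, object@seed))
    cat("true motif:", object@trueMotif, "\n")
})

setMethod("show", "MotifConsensus", function(object) {
    cat("consensus:", object@consensus, "\n")
    cat("within-d valid:", object@validWithinD, "\n")
})
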