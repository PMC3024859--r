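#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' MotifModel: the (l, d) motif model
#'
#' A planted motif model is the pair (l, d): the motif length \code{l} and the
#' maximum number of mutations \code{d} between a motif instance and the
#' unknown true motif. Because every instance lies within Hamming distance
#' \code{d} of the true motif, any two instances lie within \code{2d} of each
#' other (triangle inequality); the search therefore filters candidate
#' substring pairs at the derived threshold \code{2d}.
#'
#' @slot l integer(1), motif length in bases (l >= 1).
#' @slot d integer(1), maximum mutations per instance (0 <= d < l).
#'
#' @seealso [MotifModel()], [distanceThreshold()], [findMotifCliques()]
#' @name MotifModel-class
#' @rdname MotifModel-class
#' @exportClass MotifModel
setClass("MotifModel", representation(l = "integer", d = "integer"))

setValidity("MotifModel", function(object) {
    msg <- character()
    if (length(object@l) != 1L || is.na(object@l) || object@l < 1L)
        msg <- c(msg, "'l' must be a single integer >= 1")
    if (length(object@d) != 1L || is.na(object@d) || object@d < 0L)
        msg <- c(msg, "'d' must be a single integer >= 0")
    if (length(msg) == 0L && object@d >= object@l)
        msg <- c(msg, "'d' must be strictly smaller than 'l'")
    if (length(msg)) msg else TRUE
})

#' Construct a MotifModel
#'
#' @param l motif length in bases.
#' @param d maximum number of mutations per motif instance; must satisfy
#'   \code{0 <= d < l}.
#' @return A [MotifModel-class] object.
#' @examples
#' mod <- MotifModel(15, 4)
#' distanceThreshold(mod)  # 8
#' @export
MotifModel <- function(l, d) {
    new("MotifModel", l = as.integer(l), d = as.integer(d))
}

#' MotifCliques: result of a clique search
#'
#' Holds every m-clique found in a sequence set: tuples of one length-l
#' substring per sequence with all pairwise Hamming distances <= 2d. Starts
#' are 0-based offsets (half-open windows \code{[j, j + l)}), one row per
#' clique, columns ordered as the input sequences.
#'
#' @slot starts integer matrix, cliques x m, 0-based window starts.
#' @slot sequences a [Biostrings::DNAStringSet] the search ran on.
#' @slot model the [MotifModel-class] used.
#' @slot complete logical(1); FALSE when the search stopped early on a
#'   clique quota or a soft time limit, so the set may be partial.
#'
#' @seealso [findMotifCliques()], [cliqueStarts()], [cliqueStrings()]
#' @name MotifCliques-class
#' @rdname MotifCliques-class
#' @exportClass MotifCliques
setClass("MotifCliques", representation(
    starts = "matrix", sequences = "ANY", model = "MotifModel",
    complete = "logical"))

setValidity("MotifCliques", function(object) {
    st <- object@starts
    if (!is.integer(st)) return("'starts' must be an integer matrix")
    if (ncol(st) != length(object@sequences))
        return("'starts' must have one column per sequence")
    if (nrow(st) && any(st < 0L)) return("starts are 0-based, must be >= 0")
    TRUE
})

#' PlantedDataset: a synthetic OOPS benchmark instance
#'
#' A simulated sequence set with one planted motif instance per sequence
#' (OOPS): i.i.d. uniform background over \{A,C,G,T\}, a uniform-random true
#' motif, and per-sequence instances obtained by mutating the true motif at
#' distinct random positions, each mutated base replaced by a different base.
#'
#' @slot sequences [Biostrings::DNAStringSet] of m sequences.
#' @slot trueMotif character(1), the unmutated length-l motif.
#' @slot plantedStarts integer(m), 0-based planted window starts.
#' @slot instances character(m), the embedded (mutated) instances.
#' @slot model the [MotifModel-class] used for planting.
#' @slot mode "up_to_d" (mutation count uniform on 0..d) or "exact_d".
#' @slot seed integer(1), the RNG seed the dataset is reproducible from.
#'
#' @seealso [generatePlantedDataset()], [writePlantedDataset()]
#' @name PlantedDataset-class
#' @rdname PlantedDataset-class
#' @exportClass PlantedDataset
setClass("PlantedDataset", representation(
    sequences = "ANY", trueMotif = "character", plantedStarts = "integer",
    instances = "character", model = "MotifModel", mode = "character",
    seed = "integer"))

setValidity("PlantedDataset", function(object) {
    m <- length(object@sequences)
    if (length(object@plantedStarts) != m || length(object@instances) != m)
        return("one planted start and instance per sequence required")
    if (nchar(object@trueMotif) != object@model@l)
        return("true motif length must equal the model's l")
    TRUE
})

#' MotifConsensus: column-wise consensus of a clique
#'
#' Per-column plurality consensus over the m members of a clique. Columns
#' whose plurality base does not exceed the dominance threshold are shown as
#' 'x' (no dominant base).
#'
#' @slot consensus character(1) over \{A,C,G,T,x\}, length l.
#' @slot columnCounts 4 x l integer matrix of per-column base counts
#'   (rows A, C, G, T).
#' @slot validWithinD logical(1): TRUE iff every member is within d of the
#'   ACGT-resolved consensus ('x' columns resolved to the plurality base).
#'
#' @seealso [cliqueConsensus()]
#' @name MotifConsensus-class
#' @rdname MotifConsensus-class
#' @exportClass MotifConsensus
setClass("MotifConsensus", representation(
    consensus = "character", columnCounts = "matrix",
    validWithinD = "logical"))
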