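#' Find all motif-instance cliques in a sequence set
#'
#' Exact, sample-driven planted (l, d)-motif search. A clique is one length-l
#' window per sequence such that all pairwise Hamming distances are at most
#' 2d. Under the OOPS assumption every planted instance lies within d of the
#' unknown true motif, so the m planted instances are pairwise within 2d and
#' the clique of planted positions is guaranteed to be among the results.
#'
#' The search anchors on sequence 0 (the first record, in input order) and
#' recursively promotes one reference vertex per sequence, filtering the
#' candidate sets of all remaining sequences against each newly chosen
#' reference. A path is extended only while every remaining sequence retains
#' at least one compatible candidate; otherwise the search backtracks and
#' substitutes the most recent reference vertex. Every m-clique is reported
#' exactly once, in lexicographic order of the start tuple
#' \code{(j_0, ..., j_{m-1})}.
#'
#' @param seqs a \code{DNAStringSet} or character vector of m >= 2 sequences
#'   over \{A,C,G,T\}, each at least l bases long.
#' @param model a [MotifModel-class]; the pairwise threshold is 2d.
#' @param firstK stop after this many cliques (default \code{Inf}: enumerate
#'   all). A truncated result is flagged incomplete.
#' @param maxSeconds soft wall-clock limit; the search aborts cleanly and the
#'   partial result is flagged incomplete. Default \code{Inf}.
#' @param skipAmbiguous drop windows containing non-ACGT bases instead of
#'   erroring (see [readMotifSequences()]).
#' @return A [MotifCliques-class] with the 0-based start matrix.
#' @examples
#' seqs <- c(s1 = "AAACGTAC", s2 = "TTACGTAA", s3 = "ACGTTTTT")
#' res <- findMotifCliques(seqs, MotifModel(4, 1))
#' cliqueStarts(res)
#' @seealso [exhaustiveCliques()] for the brute-force reference,
#'   [cliqueConsensus()] to derive the motif from a clique.
#' @export
findMotifCliques <- function(seqs, model, firstK = Inf, maxSeconds = Inf,
                             skipAmbiguous = FALSE) {
    stopifnot(is(model, "MotifModel"))
    chars <- .as_seq_chars(seqs, allowAmbiguous = skipAmbiguous)
    if (length(chars) < 2L)
        stop("need at least two sequences")
    l <- model@l
    short <- which(nchar(chars) < l)
    if (length(short))
        stop(sprintf("sequence %d (length %d) is shorter than l = %d",
                     short[1L], nchar(chars)[short[1L]], l))
    coded <- lapply(chars, .encode_seq)
    res <- .clique_search_cpp(coded, l, 2L * model@d, as.numeric(firstK),
                         if (is.finite(maxSeconds)) as.numeric(maxSeconds)
                         else -1)
    starts <- res$starts
    complete <- res$complete && nrow(starts) < firstK
    dss <- Biostrings::DNAStringSet(chars)
    if (is.null(names(dss)))
        names(dss) <- paste0("seq", seq_along(chars))
    new("MotifCliques", starts = starts, sequences = dss, model = model,
        complete = complete)
}

#' Clique search over an abstract compatibility graph
#'
#' The same recursive reference-vertex algorithm as [findMotifCliques()],
#' but driven by an arbitrary symmetric compatibility predicate on vertex
#' labels instead of the Hamming distance. One label list per part
#' (sequence); a clique is one label per part with all pairs compatible.
#' Useful for reasoning about the search on small hand-constructed graphs.
#'
#' @param parts list of m non-empty character vectors of vertex labels, in
#'   scan order.
#' @param compatible function \code{(a, b) -> logical(1)}; must be symmetric.
#'   Symmetry is verified over all label pairs before searching.
#' @param trace logical; record every dead end (a reference vertex whose
#'   filtered candidate set for some remaining part came up empty).
#' @return A character matrix with one row per clique (columns = parts), in
#'   lexicographic scan order. With \code{trace = TRUE} the matrix carries a
#'   \code{"trace"} attribute: a data.frame with columns \code{level} (the
#'   0-based depth of the failing reference vertex), \code{ref} (its label)
#'   and \code{emptyAt} (the 0-based part index whose candidate set emptied).
#' @examples
#' parts <- list(c("a1", "a2"), c("b1", "b2"))
#' cliqueSearchAbstract(parts, function(a, b) TRUE)  # all four tuples
#' @export
cliqueSearchAbstract <- function(parts, compatible, trace = FALSE) {
    if (!is.list(parts) || length(parts) < 2L)
        stop("'parts' must be a list of at least two label vectors")
    if (any(lengths(parts) == 0L))
        stop("every part must be non-empty")
    m <- length(parts)
    labels <- unique(unlist(parts))
    for (a in labels) for (b in labels)
        if (!identical(compatible(a, b), compatible(b, a)))
            stop(sprintf("compatibility predicate is not symmetric on (%s, %s)",
                         a, b))

    instance <- character(m)
    out <- list()
    deadEnds <- list()

    recurse <- function(level, pools) {
        if (level > m) {
            out[[length(out) + 1L]] <<- instance
            return(invisible(NULL))
        }
        for (v in pools[[level]]) {
            valid <- TRUE
            nxt <- pools
            for (k in seq(level + 1L, length.out = m - level)) {
                keep <- vapply(pools[[k]], function(w) compatible(v, w),
                               FALSE, USE.NAMES = FALSE)
                nxt[[k]] <- pools[[k]][keep]
                if (length(nxt[[k]]) == 0L) {
                    valid <- FALSE
                    if (trace)
                        deadEnds[[length(deadEnds) + 1L]] <<-
                            data.frame(level = level - 1L, ref = v,
                                       emptyAt = k - 1L)
                    break
                }
            }
            if (valid) {
                instance[level] <<- v
                recurse(level + 1L, nxt)
            }
        }
    }
    recurse(1L, parts)

    res <- if (length(out)) do.call(rbind, out)
           else matrix(character(0), 0L, m)
    if (trace) {
        tr <- if (length(deadEnds)) do.call(rbind, deadEnds)
              else data.frame(level = integer(0), ref = character(0),
                              emptyAt = integer(0))
        attr(res, "trace") <- tr
    }
    res
}
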