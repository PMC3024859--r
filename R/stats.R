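#' Motif difficulty probability
#'
#' The probability that two independent uniform-random l-mers over
#' \{A,C,G,T\} have Hamming distance at most 2d. Two random bases differ
#' with probability 3/4, so the number of mismatching positions is
#' Binomial(l, 3/4) and
#' \deqn{p = \sum_{i=0}^{\min(2d,\,l)} \binom{l}{i} (3/4)^i (1/4)^{l-i}.}
#' Larger p means weaker motifs: more random l-mer pairs pass the pairwise
#' 2d filter, so the search must eliminate more spurious partial cliques.
#' p equals 1 exactly when 2d >= l.
#'
#' @param l motif length (>= 1); vectorised.
#' @param d mutation bound (>= 0); vectorised.
#' @return Probability in \code{[0, 1]}.
#' @examples
#' neighborProbability(15, 4)   # ~0.0566, the classic challenge setting
#' neighborProbability(4, 2)    # exactly 1: 2d >= l
#' @export
neighborProbability <- function(l, d) {
    if (any(l < 1) || any(d < 0))
        stop("require l >= 1 and d >= 0")
    mapply(function(li, di) {
        if (2 * di >= li) return(1)  # every pair of l-mers is within 2d
        i <- 0:(2 * di)
        sum(choose(li, i) * (3 / 4)^i * (1 / 4)^(li - i))
    }, l, d)
}

## Round-half-up at `digits` decimals (round() is round-half-even).
roundHalfUp <- function(x, digits = 3L) {
    floor(x * 10^digits + 0.5) / 10^digits
}

#' Expand instance windows to base positions
#'
#' Converts per-sequence 0-based window starts into the set of base
#' positions the windows cover, the coordinate system of [recallRate()].
#'
#' @param starts integer vector of 0-based window starts, one per sequence
#'   (element t belongs to sequence t-1 in 0-based terms); \code{NA} marks a
#'   sequence with no window.
#' @param l window length.
#' @return data.frame with columns \code{seq} (0-based sequence index) and
#'   \code{pos} (0-based base coordinate).
#' @examples
#' basePositions(c(0L, 5L), l = 3)
#' @export
basePositions <- function(starts, l) {
    keep <- which(!is.na(starts))
    data.frame(
        seq = rep(keep - 1L, each = l),
        pos = as.integer(outer(0:(l - 1L), starts[keep], `+`))
    )
}

#' Recall rate over planted base positions
#'
#' Fraction of the known (planted) base positions that the predicted motif
#' windows recover: \code{|known n predicted| / |known|}. For OOPS data the
#' known set has exactly m*l elements (one length-l instance per sequence).
#' Partial window overlap earns partial credit because the metric works on
#' base positions, not window starts. Equals 1 iff the predictions cover
#' every planted position.
#'
#' @param known,predicted data.frames with columns \code{seq} and \code{pos}
#'   (see [basePositions()]). \code{known} must be non-empty.
#' @return Recall in \code{[0, 1]}.
#' @examples
#' known <- basePositions(c(0L, 4L), l = 4)
#' recallRate(known, known)  # 1
#' @export
recallRate <- function(known, predicted) {
    if (nrow(known) == 0L)
        stop("the known position set must be non-empty")
    key <- function(df) unique(paste(df$seq, df$pos, sep = ":"))
    k <- key(known)
    length(intersect(k, key(predicted))) / length(k)
}

#' Column-wise consensus of a clique
#'
#' Aligns the m members of a clique (they are unalignable only trivially:
#' all have length l) and emits, per column, the plurality base when its
#' frequency exceeds the dominance threshold, and \code{'x'} otherwise —
#' the display convention for columns without a dominant base. The result
#' also reports whether every member lies within d of the ACGT-resolved
#' consensus (each 'x' column resolved to its plurality base; ties broken
#' alphabetically), i.e. whether the clique is consistent with a planted
#' (l, d) motif centred on the consensus.
#'
#' @param members character vector of m equal-length l-mers (one clique),
#'   or a [MotifCliques-class] together with \code{which}.
#' @param model a [MotifModel-class] (supplies l and d).
#' @param dominanceThreshold minimum plurality frequency, exclusive, for a
#'   column to display its base (default 0.5: a strict majority).
#' @param which clique row index when \code{members} is a
#'   [MotifCliques-class].
#' @return A [MotifConsensus-class] object.
#' @examples
#' cliqueConsensus(c("AAA", "AAT", "AAC"), MotifModel(3, 1))  # "AAx"
#' @export
cliqueConsensus <- function(members, model, dominanceThreshold = 0.5,
                            which = 1L) {
    if (is(members, "MotifCliques")) {
        strings <- cliqueStrings(members)
        members <- strings[which, ]
    }
    stopifnot(is(model, "MotifModel"))
    l <- model@l
    if (any(nchar(members) != l))
        stop("all clique members must have length l")
    m <- length(members)
    mat <- do.call(rbind, strsplit(toupper(members), "", fixed = TRUE))
    counts <- vapply(seq_len(l),
                     function(j) tabulate(match(mat[, j], DNA_BASES), 4L),
                     integer(4L))
    rownames(counts) <- DNA_BASES
    top <- apply(counts, 2L, which.max)      # ties -> alphabetically first
    plurality <- DNA_BASES[top]
    dominant <- counts[cbind(top, seq_len(l))] / m > dominanceThreshold
    consensus <- ifelse(dominant, plurality, "x")
    resolved <- paste(plurality, collapse = "")
    valid <- all(hammingDist(resolved, members) <= model@d)
    new("MotifConsensus",
        consensus = paste(consensus, collapse = ""),
        columnCounts = counts, validWithinD = valid)
}
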