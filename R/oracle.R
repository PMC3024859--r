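## Brute-force reference solvers. Deliberately written in plain R with a
## naive per-character Hamming distance so they share no code with the
## compiled search core: they are the independent route used to validate it.

.hamming_naive <- function(u, v) {
    cu <- strsplit(u, "", fixed = TRUE)[[1L]]
    cv <- strsplit(v, "", fixed = TRUE)[[1L]]
    if (length(cu) != length(cv)) stop("unequal lengths")
    sum(cu != cv)
}

.all_lmers <- function(s, l) {
    n <- nchar(s)
    substring(s, 1:(n - l + 1L), l:n)
}

#' Exhaustive clique enumeration (reference solver)
#'
#' Enumerates the full product space of one-window-per-sequence position
#' tuples and keeps those whose l-mers are pairwise within 2d. Exponential
#' in m; intended only for validating [findMotifCliques()] on tiny
#' instances.
#'
#' @param seqs a \code{DNAStringSet} or character vector.
#' @param model a [MotifModel-class].
#' @param budget refuse when the product space exceeds this many tuples
#'   (default 1e6).
#' @return Integer matrix of 0-based starts, one row per clique, rows in
#'   lexicographic order.
#' @examples
#' exhaustiveCliques(c("AAAA", "AAAT"), MotifModel(4, 1))  # (0, 0)
#' @export
exhaustiveCliques <- function(seqs, model, budget = 1e6) {
    stopifnot(is(model, "MotifModel"))
    chars <- .as_seq_chars(seqs)
    m <- length(chars)
    l <- model@l
    thr <- 2L * model@d
    if (any(nchar(chars) < l)) stop("sequence shorter than l")
    lmers <- lapply(chars, .all_lmers, l = l)
    sizes <- lengths(lmers)
    if (prod(sizes) > budget)
        stop(sprintf("product space %.3g exceeds the budget %.3g",
                     prod(sizes), budget))
    ## pairwise compatibility lookup tables
    comp <- list()
    for (a in 1:(m - 1L)) for (b in (a + 1L):m) {
        mat <- outer(lmers[[a]], lmers[[b]],
                     Vectorize(function(x, y) .hamming_naive(x, y) <= thr))
        comp[[paste(a, b)]] <- mat
    }
    ## enumerate tuples in lexicographic order of (j_0, ..., j_{m-1})
    grid <- as.matrix(rev(expand.grid(rev(lapply(sizes, seq_len)))))
    ok <- rep(TRUE, nrow(grid))
    for (a in 1:(m - 1L)) for (b in (a + 1L):m)
        ok <- ok & comp[[paste(a, b)]][grid[, c(a, b), drop = FALSE]]
    res <- grid[ok, , drop = FALSE] - 1L
    dimnames(res) <- NULL
    res
}

## All strings within Hamming distance d of `w` (inclusive), as a character
## vector. Size sum_{i<=d} C(l,i) 3^i.
.neighborhood <- function(w, d) {
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    l <- length(chars)
    out <- list(w)
    if (d >= 1L) {
        for (k in seq_len(min(d, l))) {
            pos <- utils::combn(l, k)
            for (c0 in seq_len(ncol(pos))) {
                idx <- pos[, c0]
                subs <- lapply(idx, function(i) setdiff(DNA_BASES, chars[i]))
                reps <- as.matrix(expand.grid(subs, stringsAsFactors = FALSE))
                for (r in seq_len(nrow(reps))) {
                    v <- chars
                    v[idx] <- reps[r, ]
                    out[[length(out) + 1L]] <- paste(v, collapse = "")
                }
            }
        }
    }
    unlist(out)
}

#' Exhaustive pattern-driven motif search (reference solver)
#'
#' Enumerates the d-neighborhood of every l-mer of sequence 0 (sound for
#' OOPS data, where the true motif is within d of some window of every
#' sequence, in particular of sequence 0) and returns the candidate strings
#' that have at least one window within d in EVERY sequence: the set of
#' true (l, d) motifs. A validation oracle, not a performant solver.
#'
#' @param seqs a \code{DNAStringSet} or character vector.
#' @param model a [MotifModel-class].
#' @param budget refuse when the candidate neighborhood exceeds this many
#'   strings (default 1e6).
#' @return Character vector of motifs (sorted, unique); empty when no
#'   common (l, d) motif exists.
#' @examples
#' exhaustivePatternSearch(c("AACGTT", "TTACGT"), MotifModel(4, 0))  # "ACGT"
#' @export
exhaustivePatternSearch <- function(seqs, model, budget = 1e6) {
    stopifnot(is(model, "MotifModel"))
    chars <- .as_seq_chars(seqs)
    l <- model@l
    d <- model@d
    if (any(nchar(chars) < l)) stop("sequence shorter than l")
    anchors <- .all_lmers(chars[1L], l)
    nbhdSize <- sum(choose(l, 0:d) * 3^(0:d))
    if (length(anchors) * nbhdSize > budget)
        stop(sprintf("neighborhood space %.3g exceeds the budget %.3g",
                     length(anchors) * nbhdSize, budget))
    candidates <- unique(unlist(lapply(anchors, .neighborhood, d = d)))
    lmers <- lapply(chars, .all_lmers, l = l)
    hit <- vapply(candidates, function(w)
        all(vapply(lmers, function(ws)
            any(vapply(ws, .hamming_naive, 0L, u = w) <= d), FALSE)),
        FALSE)
    sort(candidates[hit])
}

#' Witness position tuples of a motif
#'
#' For a candidate motif, the per-sequence 0-based window starts whose
#' l-mers lie within d of it. Any one choice per sequence yields a tuple
#' that is pairwise within 2d, hence a clique the search must report.
#'
#' @param seqs a \code{DNAStringSet} or character vector.
#' @param motif candidate motif string of length l.
#' @param model a [MotifModel-class].
#' @return List (one element per sequence) of integer vectors of 0-based
#'   starts within d of the motif.
#' @export
motifWitnesses <- function(seqs, motif, model) {
    stopifnot(is(model, "MotifModel"))
    chars <- .as_seq_chars(seqs)
    lapply(chars, function(s) {
        ws <- .all_lmers(s, model@l)
        which(vapply(ws, .hamming_naive, 0L, u = motif) <= model@d) - 1L
    })
}
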