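#' Read and validate a DNA sequence set from FASTA
#'
#' Reads a multi-record FASTA file into a \code{DNAStringSet}, preserving
#' record order (the first record is the first reference sequence of the
#' search) and upcasing lowercase bases. The search alphabet is strictly
#' \{A, C, G, T\}: by default any other character (including IUPAC ambiguity
#' codes such as N) raises an error naming the record and the first offending
#' position. With \code{skipAmbiguous = TRUE} the sequences are kept and the
#' search instead drops every sliding window that touches a non-ACGT base,
#' with a warning here.
#'
#' @param file path to a FASTA file (wrapped or unwrapped lines).
#' @param skipAmbiguous logical; tolerate non-ACGT bases by excluding the
#'   windows that contain them rather than erroring.
#' @return A \code{DNAStringSet} with at least two records.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "ttttacgt"), fa)
#' seqs <- readMotifSequences(fa)
#' @export
readMotifSequences <- function(file, skipAmbiguous = FALSE) {
    if (!file.exists(file))
        stop("file not found: ", file)
    seqs <- tryCatch(Biostrings::readDNAStringSet(file),
                     error = function(e) stop("not a readable FASTA file: ",
                                              file, " (", conditionMessage(e),
                                              ")", call. = FALSE))
    if (length(seqs) == 0L)
        stop("FASTA file contains no records: ", file)
    chars <- toupper(as.character(seqs))
    if (any(nchar(chars) == 0L))
        stop("empty sequence record in ", file)
    bad <- gregexpr("[^ACGT]", chars)
    offending <- vapply(bad, function(x) x[1L], 0L)
    if (any(offending > 0L)) {
        i <- which(offending > 0L)[1L]
        if (!skipAmbiguous)
            stop(sprintf(
                "non-ACGT base in record '%s' at position %d; %s",
                names(seqs)[i], offending[i],
                "use skipAmbiguous = TRUE to drop affected windows"))
        warning(sprintf(
            "non-ACGT bases found (first in record '%s' at position %d); %s",
            names(seqs)[i], offending[i],
            "windows containing them will be skipped"))
    }
    Biostrings::DNAStringSet(chars)
}

## Normalise a user-supplied sequence set (DNAStringSet or character vector)
## to an upcased character vector, checking the alphabet.
.as_seq_chars <- function(seqs, allowAmbiguous = FALSE) {
    if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
    if (!is.character(seqs))
        stop("sequences must be a DNAStringSet or a character vector")
    chars <- toupper(seqs)
    if (!allowAmbiguous && any(grepl("[^ACGT]", chars))) {
        i <- which(grepl("[^ACGT]", chars))[1L]
        stop(sprintf("sequence %d contains a non-ACGT base", i))
    }
    chars
}

## Integer-code a sequence: A,C,G,T -> 0..3, anything else -> 4 (windows
## containing a 4 are excluded from the initial candidate sets).
.encode_seq <- function(s) {
    v <- match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
    v[is.na(v)] <- 4L
    v
}

#' Enumerate the l-mer vertices of one sequence
#'
#' Slides a window of length \code{l} over sequence \code{i} and returns all
#' window start offsets: the initial candidate set of that sequence. There
#' are exactly \code{n_i - l + 1} vertices, returned in ascending order.
#' Coordinates are 0-based, half-open windows \code{[j, j + l)}.
#'
#' @param seqs a \code{DNAStringSet} or character vector of sequences.
#' @param i sequence index, 0-based (sequence 0 is the first record).
#' @param l window (motif) length; must not exceed the sequence length.
#' @return Integer vector of 0-based start offsets \code{0, ..., n_i - l}.
#' @examples
#' enumerateVertices(c("ACGTACGT", "TTTTTTTT"), i = 0, l = 5)  # 0 1 2 3
#' @export
enumerateVertices <- function(seqs, i, l) {
    chars <- .as_seq_chars(seqs, allowAmbiguous = TRUE)
    if (i < 0 || i >= length(chars))
        stop("sequence index out of range (0-based)")
    n <- nchar(chars[i + 1L])
    if (l > n)
        stop(sprintf("sequence %d (length %d) is shorter than l = %d",
                     i, n, l))
    seq.int(0L, n - l)
}

#' Hamming distance between two equal-length strings
#'
#' The number of positions at which the two strings differ: the distance
#' underlying the entire clique search. Symmetric, zero on identical
#' strings, and bounded by the string length.
#'
#' @param u,v character strings of equal length, or \code{v} a character
#'   vector (each element compared against \code{u}).
#' @return Integer distance(s) in \code{0..nchar(u)}.
#' @examples
#' hammingDist("ACGT", "AGGA")  # 2
#' @export
hammingDist <- function(u, v) {
    if (length(u) != 1L) stop("'u' must be a single string")
    if (length(v) == 1L) return(.hamming_cpp(u, v))
    vapply(v, function(x) .hamming_cpp(u, x), 0L, USE.NAMES = FALSE)
}

#' Filter a candidate set against a reference vertex
#'
#' Keeps the candidates whose distance to the reference does not exceed the
#' threshold, preserving order. This is the single filtering step of the
#' recursive search: applied cumulatively along a search path, it yields the
#' candidate sets \code{P_{i+1,k}} of the remaining sequences.
#'
#' @param pool character vector (or any vector) of candidates.
#' @param ref the reference element.
#' @param threshold numeric distance cutoff (the search uses 2d).
#' @param dist distance function \code{dist(ref, pool)} returning one value
#'   per candidate; defaults to [hammingDist()].
#' @return The subset of \code{pool} within \code{threshold} of \code{ref}.
#' @examples
#' filterCandidates(c("AAAA", "AATA", "TTTT"), "AAAA", threshold = 2)
#' @export
filterCandidates <- function(pool, ref, threshold, dist = hammingDist) {
    pool[dist(ref, pool) <= threshold]
}
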