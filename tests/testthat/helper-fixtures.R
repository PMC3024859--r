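## Shared fixtures and independent oracles for the test suite.

## Character-loop Hamming distance, independent of the package's compiled
## implementation. Used as the reference in distance-axiom tests.
refHamming <- function(u, v) {
    cu <- strsplit(u, "", fixed = TRUE)[[1L]]
    cv <- strsplit(v, "", fixed = TRUE)[[1L]]
    stopifnot(length(cu) == length(cv))
    sum(cu != cv)
}

randomLmer <- function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
}

## The worked four-part compatibility graph: parts in scan order and the
## symmetric within-2d relation sets of the vertices that matter. Vertices
## not mentioned are beyond 2d of everything.
abstractFixture <- function() {
    rel <- list(
        A = c("Z", "E", "G", "H", "J", "M", "O", "R", "T"),
        Z = c("A", "H", "J", "M", "T"),
        E = "A",
        G = c("A", "T"),
        H = c("A", "Z"),
        J = c("A", "Z", "M", "T"),
        M = c("A", "Z", "J"),
        O = "A",
        R = c("A", "H"),
        T = c("A", "Z", "G", "J"))
    list(
        parts = list(c("A", "B", "C"),
                     c("Z", "E", "F", "G"),
                     c("H", "I", "J", "K", "L"),
                     c("M", "N", "O", "Q", "R", "T")),
        compatible = function(a, b)
            isTRUE(b %in% rel[[a]]) && isTRUE(a %in% rel[[b]]))
}

writeTempFasta <- function(records) {
    fa <- tempfile(fileext = ".fasta")
    writeLines(unlist(lapply(names(records), function(id)
        c(paste0(">", id), records[[id]]))), fa)
    fa
}

## Does the start matrix contain the given tuple as a row?
containsTuple <- function(starts, tuple) {
    nrow(starts) > 0L && any(apply(starts, 1L, function(r) all(r == tuple)))
}

## All pairwise Hamming distances of a clique's l-mers are within 2d
## (independent O(m^2) soundness check).
cliqueIsSound <- function(strings, threshold) {
    m <- length(strings)
    for (a in seq_len(m - 1L)) for (b in seq(a + 1L, m))
        if (refHamming(strings[a], strings[b]) > threshold) return(FALSE)
    TRUE
}
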