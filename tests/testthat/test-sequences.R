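test_that("FASTA reading preserves record order, upcases, and validates the alphabet", {
    fa <- writeTempFasta(list(s1 = "ACGT", s2 = "tttt"))
    seqs <- readMotifSequences(fa)
    expect_length(seqs, 2L)
    expect_identical(names(seqs), c("s1", "s2"))
    expect_identical(as.character(seqs), c(s1 = "ACGT", s2 = "TTTT"))

    fa2 <- writeTempFasta(list(ok = "ACGT", bad = "ACNGT"))
    expect_error(readMotifSequences(fa2), "bad.*position 3")
    expect_warning(readMotifSequences(fa2, skipAmbiguous = TRUE),
                   "non-ACGT")

    empty <- tempfile(fileext = ".fasta")
    file.create(empty)
    expect_error(readMotifSequences(empty), "no records|FASTA")

    expect_error(readMotifSequences(tempfile()), "not found")
})

test_that("wrapped and unwrapped FASTA lines parse identically", {
    fa1 <- writeTempFasta(list(s = paste(rep("ACGT", 5), collapse = "")))
    fa2 <- tempfile(fileext = ".fasta")
    writeLines(c(">s", "ACGTACGT", "ACGTACGT", "ACGT"), fa2)
    expect_error(readMotifSequences(fa1), NA)  # single record is read fine
    s1 <- Biostrings::readDNAStringSet(fa1)
    s2 <- Biostrings::readDNAStringSet(fa2)
    expect_identical(as.character(s1[[1]]), as.character(s2[[1]]))
})

test_that("vertex enumeration yields n - l + 1 ascending window starts", {
    long <- paste(rep("ACGT", 150), collapse = "")  # n = 600
    expect_identical(enumerateVertices(long, 0, 15), 0:585)
    expect_length(enumerateVertices(long, 0, 15), 586L)

    expect_identical(enumerateVertices("ACGTA", 0, 5), 0L)  # n = l boundary
    expect_length(enumerateVertices(strrep("A", 20), 0, 5), 16L)
    expect_error(enumerateVertices("ACG", 0, 5), "shorter than")

    # property: count formula over assorted (n, l)
    for (n in c(5L, 17L, 60L)) for (l in c(1L, 3L, n)) {
        v <- enumerateVertices(strrep("C", n), 0, l)
        expect_identical(v, seq.int(0L, n - l))
    }
})

test_that("Hamming distance matches the character-loop oracle and its axioms", {
    expect_identical(hammingDist("ACGT", "ACGT"), 0L)
    expect_identical(hammingDist("AAAA", "TTTT"), 4L)

    u <- "ACGTACGTACGTACG"
    v <- u
    substring(v, 1, 1) <- "C"; substring(v, 5, 5) <- "C"
    substring(v, 9, 9) <- "C"; substring(v, 13, 13) <- "C"
    expect_identical(refHamming(u, v), 4L)
    expect_identical(hammingDist(u, v), 4L)

    expect_error(hammingDist("ACGT", "ACG"), "equal-length")

    # exact agreement with the naive per-character oracle on 10,000 random
    # pairs, plus symmetry, identity and the triangle inequality
    set.seed(42)
    ok <- vapply(1:10000, function(rep) {
        l <- sample(c(5L, 15L, 31L), 1L)
        a <- randomLmer(l); b <- randomLmer(l); c0 <- randomLmer(l)
        dab <- hammingDist(a, b)
        dab == refHamming(a, b) &&
            dab == hammingDist(b, a) &&
            hammingDist(a, a) == 0L &&
            dab <= hammingDist(a, c0) + hammingDist(c0, b)
    }, FALSE)
    expect_true(all(ok))
})

test_that("candidate filtering keeps exactly the within-threshold members in order", {
    # the worked-example filter: reference A against the second part
    fx <- abstractFixture()
    dist01 <- function(ref, pool)
        ifelse(vapply(pool, fx$compatible, FALSE, a = ref), 0, 1)
    expect_identical(
        filterCandidates(c("Z", "E", "F", "G"), "A", 0, dist = dist01),
        c("Z", "E", "G"))
    expect_identical(
        filterCandidates(c("M", "T"), "H", 0, dist = dist01),
        character(0))

    # threshold = l keeps everything (all distances are <= l)
    pool <- replicate(8, randomLmer(6))
    expect_identical(filterCandidates(pool, randomLmer(6), 6), pool)
})

test_that("model parameters are validated and the threshold is 2d", {
    m <- MotifModel(15, 4)
    expect_identical(motifLength(m), 15L)
    expect_identical(mutationBound(m), 4L)
    expect_identical(distanceThreshold(m), 8L)
    expect_identical(distanceThreshold(MotifModel(7, 0)), 0L)
    expect_error(MotifModel(4, 4), "smaller than")
    expect_error(MotifModel(4, 5), "smaller than")
    expect_error(MotifModel(0, 0), "l")
    expect_error(MotifModel(5, -1), "d")
})
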