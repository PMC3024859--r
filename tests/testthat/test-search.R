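test_that("the worked four-part graph yields exactly its two cliques, in scan order", {
    fx <- abstractFixture()
    out <- cliqueSearchAbstract(fx$parts, fx$compatible, trace = TRUE)
    expect_identical(out[1, ], c("A", "Z", "J", "M"))
    expect_identical(out[2, ], c("A", "Z", "J", "T"))
    expect_identical(nrow(out), 2L)

    # the dead end: reference H at depth 2 empties the last part's candidates
    tr <- attr(out, "trace")
    expect_true(any(tr$level == 2L & tr$ref == "H" & tr$emptyAt == 3L))
})

test_that("abstract search handles complete, empty and asymmetric predicates", {
    allPairs <- cliqueSearchAbstract(list(c("a", "b"), c("c", "d")),
                                     function(x, y) TRUE)
    expect_identical(nrow(allPairs), 4L)
    expect_identical(allPairs[1, ], c("a", "c"))  # lexicographic scan order

    none <- cliqueSearchAbstract(list(c("a", "b"), c("c", "d")),
                                 function(x, y) FALSE)
    expect_identical(nrow(none), 0L)

    expect_error(
        cliqueSearchAbstract(list("a", "b"),
                             function(x, y) x == "a" && y == "b"),
        "not symmetric")
})

test_that("identical sequences yield every aligned start tuple", {
    seqs <- rep(strrep("ACGTAG", 3), 3)  # n = 18, three identical sequences
    res <- findMotifCliques(seqs, MotifModel(6, 0))
    st <- cliqueStarts(res)
    keys <- paste(st[, 1], st[, 2], st[, 3])
    expect_true(all(paste(0:12, 0:12, 0:12) %in% keys))
})

test_that("search output equals the exhaustive product-space oracle on small instances", {
    model <- MotifModel(5, 1)
    set.seed(11)
    for (rep in 1:3) {
        seqs <- vapply(1:4, function(i) randomLmer(20), "")
        mine <- cliqueStarts(findMotifCliques(seqs, model))
        oracle <- exhaustiveCliques(seqs, model)
        expect_identical(unname(mine), unname(oracle))
    }
})

test_that("every reported clique passes the independent pairwise soundness check", {
    model <- MotifModel(8, 2)
    ds <- generatePlantedDataset(5, 60, model, mode = "up_to_d", seed = 5)
    res <- findMotifCliques(ds@sequences, model)
    strs <- cliqueStrings(res)
    expect_gt(nrow(strs), 0L)
    sound <- vapply(seq_len(nrow(strs)), function(r)
        cliqueIsSound(strs[r, ], distanceThreshold(model)), FALSE)
    expect_true(all(sound))
})

test_that("the planted tuple is recovered across (l,d) settings and seeds", {
    settings <- list(c(7L, 1L), c(11L, 3L), c(15L, 4L))
    for (ld in settings) {
        model <- MotifModel(ld[1], ld[2])
        for (seed in 1:4) {
            ds <- generatePlantedDataset(8, 80, model, mode = "up_to_d",
                                         seed = seed)
            res <- findMotifCliques(ds@sequences, model)
            expect_true(containsTuple(cliqueStarts(res), plantedStarts(ds)),
                        label = sprintf("planted tuple found for (l=%d,d=%d) seed %d",
                                        ld[1], ld[2], seed))
        }
    }
})

test_that("search is deterministic and free of hidden state", {
    ds <- generatePlantedDataset(6, 60, MotifModel(8, 2), seed = 99)
    r1 <- findMotifCliques(ds@sequences, MotifModel(8, 2))
    r2 <- findMotifCliques(ds@sequences, MotifModel(8, 2))
    expect_identical(cliqueStarts(r1), cliqueStarts(r2))
})

test_that("no compatible vertex in some sequence means empty output", {
    # second sequence shares no 4-mer within threshold 0 of the first
    res <- findMotifCliques(c("AAAAAA", "CCCCCC"), MotifModel(4, 0))
    expect_identical(length(res), 0L)
    expect_true(isComplete(res))
})

test_that("clique quota and soft time limit stop the search early and flag it", {
    seqs <- rep(strrep("A", 30), 3)   # saturated: huge number of cliques
    res <- findMotifCliques(seqs, MotifModel(4, 1), firstK = 5)
    expect_identical(length(res), 5L)
    expect_false(isComplete(res))

    full <- findMotifCliques(seqs, MotifModel(4, 1))
    expect_identical(length(full), 19683L)  # 27^3 aligned tuples
    expect_true(isComplete(full))
})

test_that("contract violations are rejected", {
    expect_error(findMotifCliques("ACGT", MotifModel(4, 1)), "at least two")
    expect_error(findMotifCliques(c("ACGT", "ACG"), MotifModel(4, 1)),
                 "shorter than")
    expect_error(findMotifCliques(c("ACGT", "ANGT"), MotifModel(4, 1)),
                 "non-ACGT")
    # with skipAmbiguous the ambiguous window is dropped, not an error
    res <- findMotifCliques(c("ACGTN", "ACGTA"), MotifModel(4, 0),
                            skipAmbiguous = TRUE)
    expect_identical(unname(cliqueStarts(res)),
                     matrix(c(0L, 0L), 1L))
})
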