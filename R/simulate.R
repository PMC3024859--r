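#' Generate a synthetic planted-motif dataset
#'
#' Reproduces the standard OOPS benchmark protocol for the motif challenge
#' problem. Background sequences are i.i.d. uniform over \{A,C,G,T\}; a true
#' motif of length l is drawn uniformly; each sequence receives exactly one
#' instance, obtained by mutating the true motif at distinct uniform-random
#' positions (each mutated base replaced by a uniformly chosen *different*
#' base, so the realised Hamming distance equals the mutation count) and
#' planted at a uniform-random start in \code{0..n-l}, overwriting the
#' background. Fully reproducible from the seed.
#'
#' In \code{"up_to_d"} mode (the default, matching the problem statement
#' "up to d mutations") the per-instance mutation count is uniform on
#' \code{0..d}; in \code{"exact_d"} mode (the classical benchmark
#' convention) exactly d positions are mutated in every instance.
#'
#' @param m number of sequences (>= 2).
#' @param n sequence length; must exceed l.
#' @param model a [MotifModel-class].
#' @param mode \code{"up_to_d"} or \code{"exact_d"}.
#' @param seed integer RNG seed.
#' @return A [PlantedDataset-class].
#' @examples
#' ds <- generatePlantedDataset(20, 600, MotifModel(15, 4),
#'                              mode = "exact_d", seed = 1)
#' trueMotif(ds)
#' @export
generatePlantedDataset <- function(m, n, model,
                                   mode = c("up_to_d", "exact_d"), seed) {
    stopifnot(is(model, "MotifModel"))
    mode <- match.arg(mode)
    l <- model@l
    d <- model@d
    if (n <= l) stop("sequence length n must exceed the motif length l")
    if (m < 2) stop("need at least two sequences")
    set.seed(as.integer(seed))

    motif <- sample(DNA_BASES, l, replace = TRUE)
    seqs <- character(m)
    starts <- integer(m)
    instances <- character(m)
    for (i in seq_len(m)) {
        bg <- sample(DNA_BASES, n, replace = TRUE)
        k <- if (mode == "exact_d") d else sample(0:d, 1L)
        inst <- motif
        if (k > 0L) {
            at <- sample.int(l, k)        # distinct positions
            inst[at] <- vapply(inst[at], function(b)
                sample(setdiff(DNA_BASES, b), 1L), "")
        }
        j0 <- sample.int(n - l + 1L, 1L) - 1L   # uniform on 0..n-l
        bg[(j0 + 1L):(j0 + l)] <- inst
        seqs[i] <- paste(bg, collapse = "")
        starts[i] <- j0
        instances[i] <- paste(inst, collapse = "")
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- sprintf("seq%02d", seq_len(m))
    new("PlantedDataset", sequences = dss,
        trueMotif = paste(motif, collapse = ""),
        plantedStarts = starts, instances = instances, model = model,
        mode = mode, seed = as.integer(seed))
}

#' Write a planted dataset to disk
#'
#' Writes \code{<prefix>.fasta} (the sequences), a ground-truth sidecar
#' \code{<prefix>.truth.tsv} with columns \code{seq_id}, \code{start_0based},
#' \code{instance}, \code{distance_to_motif}, and \code{<prefix>.motif.txt}
#' holding the one-line true motif. Output is byte-identical across runs for
#' the same dataset.
#'
#' @param ds a [PlantedDataset-class].
#' @param prefix output path prefix.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
writePlantedDataset <- function(ds, prefix) {
    stopifnot(is(ds, "PlantedDataset"))
    paths <- c(fasta = paste0(prefix, ".fasta"),
               truth = paste0(prefix, ".truth.tsv"),
               motif = paste0(prefix, ".motif.txt"))
    Biostrings::writeXStringSet(ds@sequences, paths[["fasta"]])
    truth <- data.frame(
        seq_id = names(ds@sequences),
        start_0based = ds@plantedStarts,
        instance = ds@instances,
        distance_to_motif = hammingDist(ds@trueMotif, ds@instances))
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(ds@trueMotif, paths[["motif"]])
    invisible(paths)
}
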