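#' @importFrom stats rnorm runif dbinom dpois ppois quantile median sd var
#'   wilcox.test p.adjust
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
DNA_RAW <- charToRaw("ACGT")
# byte -> base index (1..4), 0 for non-ACGT
BASE_CODE <- local({
  code <- integer(256)
  code[as.integer(DNA_RAW) + 1L] <- 1:4
  code
})

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Draw from a normal truncated by clamping to [lo, hi]; returns draws plus
# the number of clamped values (the simulators report these).
clamped_normal <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  n_clamped <- sum(x < lo | x > hi)
  list(x = pmin(pmax(x, lo), hi), n_clamped = n_clamped)
}

# Random background DNA with a given GC fraction, as one string.
random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(DNA_BASES[sample.int(4L, n, replace = TRUE, prob = p)], collapse = "")
}

# Length of the longest TRUE run in a logical vector.
max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# Maximal runs of TRUE as a 0-based half-open interval data.frame.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Read set constructor
#'
#' A lightweight container for sequencing reads: parallel vectors of read
#' identifiers, sequences, per-base phred qualities and optional mate
#' identifiers.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences.
#' @param qual list of integer phred vectors, one per read.
#' @param mate character vector of mate identifiers (`NA` when unpaired).
#' @return an object of class `sat_reads`.
#' @export
sat_reads <- function(id, seq, qual, mate = rep(NA_character_, length(id))) {
  stopifnot(length(id) == length(seq), length(qual) == length(id),
            length(mate) == length(id), !anyDuplicated(id))
  structure(list(id = as.character(id), seq = toupper(seq), qual = qual,
                 mate = as.character(mate)),
            class = "sat_reads")
}

#' @export
length.sat_reads <- function(x) length(x$id)

#' @export
print.sat_reads <- function(x, ...) {
  cat(sprintf("<sat_reads> %d reads, mean length %.1f bp, %d with mates\n",
              length(x$id), mean(nchar(x$seq)), sum(!is.na(x$mate))))
  invisible(x)
}

#' Subset a read set by index or read id
#'
#' Works on both [sat_reads()] and the masked read sets produced by
#' [preprocess_reads()].
#'
#' @param reads a `sat_reads` or `masked_reads` object.
#' @param i integer indices or read ids.
#' @return the subsetted object (rejection table, if any, untouched).
#' @export
subset_reads <- function(reads, i) {
  if (is.character(i)) i <- match(i, reads$id)
  out <- reads
  for (f in intersect(names(reads), c("id", "seq", "mate")))
    out[[f]] <- reads[[f]][i]
  for (f in intersect(names(reads), c("qual", "mask")))
    out[[f]] <- reads[[f]][i]
  out
}

#' Write reads to FASTQ (phred+33)
#'
#' @param reads a [sat_reads()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$id
  qual <- Biostrings::PhredQuality(
    vapply(reads$qual, function(q) rawToChar(as.raw(pmin(q, 93L) + 33L)), ""))
  # Biostrings warns about dropping its internal metadata columns here
  withCallingHandlers(
    Biostrings::writeXStringSet(dss, path, format = "fastq",
                                qualities = qual),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path FASTQ file path.
#' @return a [sat_reads()] object.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual <- unname(lapply(as(Biostrings::quality(x), "IntegerList"), as.integer))
  sat_reads(id = sub("\\s.*$", "", names(x)),
            seq = unname(as.character(x)), qual = qual)
}

#' Write a read pair table
#'
#' @param pairs data.frame with columns `read_id`, `mate_id`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
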