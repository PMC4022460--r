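SAT_NAMES <- c("HSATII", "(CATTC)n", "(GAATG)n")

#' Parse a RepeatMasker `.out` file
#'
#' Reads the standard 15-column whitespace-delimited RepeatMasker `.out`
#' layout (real or the surrogate dialect written by
#' [write_repeatmasker_out()]). Query coordinates are converted from
#' RepeatMasker's 1-based inclusive convention to 0-based half-open; strand
#' `C` is mapped to `-`. Percent identity is reported as `100 - divergence`.
#'
#' @param path `.out` file path.
#' @return named list (by query/read id) of data.frames with columns
#'   `start`, `end`, `name`, `strand`, `pid`. Unannotated reads are absent.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  first_tok <- sub("^\\s*(\\S*).*$", "\\1", lines)
  body <- which(grepl("^[0-9]+$", first_tok))
  out <- list()
  if (length(body) == 0L) return(out)
  toks <- strsplit(trimws(lines[body]), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 14L)
  if (length(bad))
    stop("malformed RepeatMasker line ", body[bad[1]], ": ", lines[body[bad[1]]])
  qname <- vapply(toks, `[[`, "", 5L)
  qbeg <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 6L)))
  qend <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 7L)))
  if (anyNA(qbeg) || anyNA(qend)) {
    bad <- which(is.na(qbeg) | is.na(qend))[1]
    stop("malformed RepeatMasker line ", body[bad], ": ", lines[body[bad]])
  }
  strand <- ifelse(vapply(toks, `[[`, "", 9L) == "C", "-", "+")
  rname <- vapply(toks, `[[`, "", 10L)
  div <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 2L)))
  recs <- data.frame(start = qbeg - 1L, end = qend, name = rname,
                     strand = strand, pid = 100 - div,
                     stringsAsFactors = FALSE)
  split(recs, factor(qname, levels = unique(qname)))
}

#' Minimal Poisson screen threshold
#'
#' Smallest count `t` such that the expected number of reads with at least
#' `t` pentamer occurrences under a Poisson background with mean `lambda_bg`
#' does not exceed the false-positive budget across a dataset of `n_reads`
#' reads.
#'
#' @param lambda_bg Poisson mean of background pentamer count per read.
#' @param n_reads dataset size.
#' @param fp_budget expected number of false positives tolerated.
#' @return integer threshold.
#' @export
poisson_screen_threshold <- function(lambda_bg, n_reads, fp_budget = 1) {
  stopifnot(lambda_bg > 0, n_reads > 0, fp_budget > 0)
  t <- 0L
  # P(X >= t) = ppois(t - 1, lower.tail = FALSE)
  while (n_reads * ppois(t - 1, lambda_bg, lower.tail = FALSE) > fp_budget) {
    t <- t + 1L
  }
  t
}

# Occurrences of the pentamer on each strand of each read.
pentamer_counts <- function(seqs, pentamer = "CATTC") {
  dss <- Biostrings::DNAStringSet(seqs)
  cbind(fwd = Biostrings::vcountPattern(pentamer, dss),
        rev = Biostrings::vcountPattern(revcomp(pentamer), dss))
}

#' Pentamer-enrichment read screen
#'
#' Counts, per read, the occurrences of the satellite pentamer (or its
#' reverse complement, whichever is more frequent) and selects reads whose
#' count reaches the minimal threshold at which a Poisson background model
#' predicts at most `fp_budget` false positives across the dataset.
#'
#' @param reads a [sat_reads()] object.
#' @param pentamer screening pentamer (length 5).
#' @param lambda_bg background Poisson mean; estimated as the dataset mean
#'   count when `NULL`.
#' @param n_reads dataset size used for the false-positive budget; defaults
#'   to the number of reads supplied.
#' @param fp_budget expected false positives tolerated (default 1).
#' @return list with `selected` (read ids), `counts` (named per-read max
#'   count) and `model` (`lambda_bg`, `n_reads`, `fp_budget`, `threshold`).
#' @export
pentamer_screen <- function(reads, pentamer = "CATTC", lambda_bg = NULL,
                            n_reads = NULL, fp_budget = 1) {
  if (nchar(pentamer) != 5) stop("`pentamer` must have length 5")
  if (length(reads$id) == 0L) stop("`reads` must be non-empty")
  pc <- pentamer_counts(reads$seq, pentamer)
  counts <- stats::setNames(pmax(pc[, "fwd"], pc[, "rev"]), reads$id)
  if (is.null(lambda_bg)) lambda_bg <- mean(counts)
  if (is.null(n_reads)) n_reads <- length(counts)
  t <- poisson_screen_threshold(lambda_bg, n_reads, fp_budget)
  list(selected = names(counts)[counts >= t], counts = counts,
       model = list(lambda_bg = lambda_bg, n_reads = n_reads,
                    fp_budget = fp_budget, threshold = t))
}

#' Preprocessing parameters
#'
#' @param phred_min bases below this phred score are masked (default 20).
#' @param unmask_max_gap high-quality non-satellite islands shorter than
#'   this (bp) flanked by satellite are unmasked (default 100).
#' @param min_hq_run minimum continuous unmasked run for a read to be kept
#'   (default 75 bp).
#' @param min_match_run minimum continuous satellite-annotated bases for a
#'   read to be considered at all (default 20 bp).
#' @param sat_names annotation names counted as satellite.
#' @return a list of class `preprocess_params`.
#' @export
preprocess_params <- function(phred_min = 20L, unmask_max_gap = 100L,
                              min_hq_run = 75L, min_match_run = 20L,
                              sat_names = SAT_NAMES) {
  stopifnot(phred_min > 0, unmask_max_gap > 0, min_hq_run > 0, min_match_run > 0)
  structure(list(phred_min = as.integer(phred_min),
                 unmask_max_gap = as.integer(unmask_max_gap),
                 min_hq_run = as.integer(min_hq_run),
                 min_match_run = as.integer(min_match_run),
                 sat_names = sat_names),
            class = "preprocess_params")
}

# Coverage masks (plus, minus strand) for one read's satellite intervals.
interval_coverage <- function(iv, L) {
  plus <- logical(L); minus <- logical(L)
  for (r in seq_len(nrow(iv))) {
    span <- (iv$start[r] + 1L):iv$end[r]
    if (iv$strand[r] == "-") minus[span] <- TRUE else plus[span] <- TRUE
  }
  list(plus = plus, minus = minus)
}

#' Orient, mask and quality-filter satellite-containing reads
#'
#' Applies the satellite read preparation pipeline to each read, in order:
#' (1) reject reads with fewer than `min_match_run` continuous
#' satellite-annotated bases; (2) set aside reads with substantial satellite
#' annotation on both strands (possible inversion breakpoints); (3) reverse
#' complement reads to the canonical orientation (the strand with more
#' CATTC than GAATG); (4) mask all non-satellite and low-quality bases;
#' (5) unmask short (< `unmask_max_gap`) internal islands of high-quality
#' non-satellite sequence flanked by satellite; (6) reject reads without an
#' unmasked run of at least `min_hq_run` bases. Rejections carry reasons,
#' not errors.
#'
#' @param reads a [sat_reads()] object.
#' @param annotations per-read annotation list
#'   ([parse_repeatmasker_out()] / [surrogate_annotate()]).
#' @param params a [preprocess_params()].
#' @return an object of class `masked_reads`: list with `id`, `seq`
#'   (canonical orientation), `qual`, `mask` (list of logicals, `TRUE` =
#'   usable satellite base), `mate`, and `rejected` (data.frame `read_id`,
#'   `reason` covering unannotated and filtered reads).
#' @export
preprocess_reads <- function(reads, annotations, params = preprocess_params()) {
  n <- length(reads$id)
  keep <- logical(n)
  seq_out <- character(n); qual_out <- vector("list", n)
  mask_out <- vector("list", n)
  rej_id <- character(0); rej_reason <- character(0)
  n_ties <- 0L
  pc_all <- pentamer_counts(reads$seq)
  for (i in seq_len(n)) {
    rid <- reads$id[i]
    iv <- annotations[[rid]]
    if (!is.null(iv)) iv <- iv[iv$name %in% params$sat_names, , drop = FALSE]
    if (is.null(iv) || nrow(iv) == 0L) {
      rej_id <- c(rej_id, rid); rej_reason <- c(rej_reason, "no_annotation")
      next
    }
    L <- nchar(reads$seq[i])
    if (any(iv$start < 0) || any(iv$end > L) || any(iv$start >= iv$end))
      stop("invalid annotation intervals for read ", rid)
    cov <- interval_coverage(iv, L)
    covered <- cov$plus | cov$minus
    if (max_run(covered) < params$min_match_run) {
      rej_id <- c(rej_id, rid); rej_reason <- c(rej_reason, "short_match")
      next
    }
    if (sum(cov$plus) >= params$min_match_run &&
        sum(cov$minus) >= params$min_match_run) {
      rej_id <- c(rej_id, rid); rej_reason <- c(rej_reason, "both_strand")
      next
    }
    s <- reads$seq[i]
    q <- reads$qual[[i]]
    if (pc_all[i, "rev"] > pc_all[i, "fwd"]) {
      s <- revcomp(s)
      q <- rev(q)
      covered <- rev(covered)
    } else if (pc_all[i, "rev"] == pc_all[i, "fwd"]) {
      n_ties <- n_ties + 1L
    }
    hq <- q >= params$phred_min
    usable <- covered & hq
    island <- hq & !covered
    if (any(island)) {
      runs <- true_runs(island)
      for (r in seq_len(nrow(runs))) {
        a <- runs$start[r]; b <- runs$end[r]
        if ((b - a) < params$unmask_max_gap && a > 0L && b < L &&
            usable[a] && usable[b + 1L]) {
          usable[(a + 1L):b] <- TRUE
        }
      }
    }
    if (max_run(usable) < params$min_hq_run) {
      rej_id <- c(rej_id, rid); rej_reason <- c(rej_reason, "short_hq_run")
      next
    }
    keep[i] <- TRUE
    seq_out[i] <- s; qual_out[[i]] <- q; mask_out[[i]] <- usable
  }
  if (n_ties > 0L)
    warning(n_ties, " read(s) had equal CATTC and GAATG counts; ",
            "input orientation kept")
  structure(list(id = reads$id[keep], seq = seq_out[keep],
                 qual = qual_out[keep], mask = mask_out[keep],
                 mate = reads$mate[keep],
                 rejected = data.frame(read_id = rej_id, reason = rej_reason,
                                       stringsAsFactors = FALSE),
                 params = params),
            class = "masked_reads")
}

#' @export
print.masked_reads <- function(x, ...) {
  cat(sprintf(paste0("<masked_reads> %d accepted reads (mean %.0f unmasked bp),",
                     " %d rejected\n"),
              length(x$id),
              if (length(x$id)) mean(vapply(x$mask, sum, 0L)) else 0,
              nrow(x$rejected)))
  invisible(x)
}

#' @export
length.masked_reads <- function(x) length(x$id)

# Annotation list equivalent to a masked read's own mask (used e.g. to check
# idempotence of preprocessing).
annotation_from_mask <- function(masked) {
  out <- list()
  for (i in seq_along(masked$id)) {
    iv <- true_runs(masked$mask[[i]])
    iv$name <- "HSATII"; iv$strand <- "+"; iv$pid <- 100
    out[[masked$id[i]]] <- iv
  }
  out
}

#' Remove duplicate clone-end reads and enforce canonical orientation
#'
#' Duplicates (same read id, same clone-end key when supplied, or identical
#' sequence otherwise) are removed keeping the first occurrence. Any read
#' with more GAATG than CATTC occurrences is reverse complemented so all
#' retained reads lie on the CATTC-dominant strand, and the pair table is
#' restricted to retained reads.
#'
#' @param masked a `masked_reads` object (or [sat_reads()]).
#' @param pairs data.frame `read_id`, `mate_id`.
#' @param clone_key optional character vector (parallel to the reads) of
#'   clone-end identifiers used as the duplicate key.
#' @return list with `reads` and `pairs`.
#' @export
orient_and_dedupe <- function(masked, pairs = NULL, clone_key = NULL) {
  key <- if (!is.null(clone_key)) clone_key else masked$seq
  dup <- duplicated(masked$id) | duplicated(key)
  reads <- subset_reads(masked, which(!dup))
  pc <- pentamer_counts(reads$seq)
  flip <- pc[, "rev"] > pc[, "fwd"]
  if (any(flip)) {
    reads$seq[flip] <- revcomp(reads$seq[flip])
    reads$qual[flip] <- lapply(reads$qual[flip], rev)
    if (!is.null(reads$mask)) reads$mask[flip] <- lapply(reads$mask[flip], rev)
  }
  if (!is.null(pairs)) {
    pairs <- pairs[pairs$read_id %in% reads$id & pairs$mate_id %in% reads$id, ,
                   drop = FALSE]
  }
  list(reads = reads, pairs = pairs)
}
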