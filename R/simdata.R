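#' Simulation configuration
#'
#' Parameters of the synthetic shotgun-read generator. The defaults emulate
#' the whole-genome Sanger dataset the satellite classification method was
#' developed on: reads averaging 877 bp at 7.8-fold coverage, with clone
#' insert lengths around 5 kb and roughly 65% of reads having a sequenced
#' mate.
#'
#' @param seed integer RNG seed.
#' @param read_len_mean,read_len_sd read length distribution (bp); lengths are
#'   drawn from a normal clamped to `[50, 5 * read_len_mean]`.
#' @param insert_len_mean,insert_len_sd clone insert length distribution (bp),
#'   clamped to `[read length, 5 * insert_len_mean]`.
#' @param coverage fold sequence coverage of the genome.
#' @param phred_high,phred_low,low_q_rate per-base quality model: each base
#'   gets `phred_high` except a fraction `low_q_rate`, which get `phred_low`.
#'   Substitution errors are drawn at the rate implied by each base's phred
#'   value (no indels).
#' @param mate_frac fraction of output reads that have a sequenced mate.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, read_len_mean = 877, read_len_sd = 150,
                       insert_len_mean = 5000, insert_len_sd = 1000,
                       coverage = 7.8, phred_high = 40L, phred_low = 10L,
                       low_q_rate = 0.02, mate_frac = 0.65) {
  stopifnot(read_len_mean > 0, coverage > 0, insert_len_mean >= read_len_mean,
            mate_frac >= 0, mate_frac <= 1, low_q_rate >= 0, low_q_rate <= 1)
  structure(list(seed = as.integer(seed), read_len_mean = read_len_mean,
                 read_len_sd = read_len_sd, insert_len_mean = insert_len_mean,
                 insert_len_sd = insert_len_sd, coverage = coverage,
                 phred_high = as.integer(phred_high),
                 phred_low = as.integer(phred_low),
                 low_q_rate = low_q_rate, mate_frac = mate_frac),
            class = "sim_config")
}

#' Generate satellite subfamily repeat units
#'
#' Each unit starts as the ancestral pentamer CATTC concatenated to
#' `unit_length`, then diverges by i.i.d. per-base substitution (to a
#' uniformly chosen different base) with probability `divergence`. Units for
#' different subfamilies are independent draws, emulating subfamilies that
#' diverged separately from a common pentameric ancestor.
#'
#' @param n_subfamilies number of units to generate.
#' @param unit_length unit length in bp; must be a multiple of 5.
#' @param divergence per-base substitution probability in `[0, 0.75)`.
#' @param seed integer RNG seed.
#' @return character vector of unit sequences, named `SF1`, `SF2`, ...
#' @export
gen_subfamily_units <- function(n_subfamilies, unit_length, divergence, seed = 1L) {
  if (divergence < 0 || divergence >= 0.75)
    stop("`divergence` must be in [0, 0.75)")
  if (unit_length %% 5 != 0) stop("`unit_length` must be a multiple of 5")
  ancestral <- strsplit(strrep("CATTC", unit_length / 5), "")[[1]]
  anc_idx <- match(ancestral, DNA_BASES)
  units <- with_seed(seed, {
    vapply(seq_len(n_subfamilies), function(s) {
      idx <- anc_idx
      hit <- runif(unit_length) < divergence
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        idx[hit] <- ((idx[hit] - 1L + shift) %% 4L) + 1L
      }
      paste(DNA_BASES[idx], collapse = "")
    }, "")
  })
  names(units) <- paste0("SF", seq_len(n_subfamilies))
  units
}

#' Build a synthetic genome with planted satellite arrays
#'
#' Arrays are tandem repetitions of a subfamily unit (final copy truncated),
#' optionally with independent per-copy substitution noise, embedded in
#' i.i.d. background sequence of a given GC fraction. Ground truth (array
#' intervals and total bp per subfamily) is recorded. Coordinates are 0-based
#' half-open throughout.
#'
#' @param array_spec data.frame with columns `chrom`, `pos` (0-based array
#'   start), `subfamily` (name into `units`), `length` (bp).
#' @param units named character vector of unit sequences
#'   (see [gen_subfamily_units()]).
#' @param background_length chromosome length in bp; a single value or a
#'   vector named by chromosome.
#' @param gc background GC fraction.
#' @param copy_divergence per-base substitution probability applied
#'   independently to each tandem copy (0 = perfect tandem).
#' @param seed integer RNG seed.
#' @return a list of class `sat_genome` with elements `chromosomes` (named
#'   character vector) and `truth` (`arrays` data.frame with 0-based
#'   half-open intervals, and `true_array_bp` per subfamily).
#' @export
build_genome <- function(array_spec, units, background_length, gc = 0.4,
                         copy_divergence = 0, seed = 1L) {
  stopifnot(all(c("chrom", "pos", "subfamily", "length") %in% names(array_spec)))
  chroms <- unique(as.character(array_spec$chrom))
  if (length(background_length) == 1L && is.null(names(background_length))) {
    background_length <- stats::setNames(rep(background_length, length(chroms)), chroms)
  }
  chroms <- union(chroms, names(background_length))
  with_seed(seed, {
    seqs <- stats::setNames(vapply(chroms, function(cn)
      random_dna(background_length[[cn]], gc), ""), chroms)
    arrays <- array_spec
    arrays$chrom <- as.character(arrays$chrom)
    arrays$subfamily <- as.character(arrays$subfamily)
    arrays$start <- as.integer(arrays$pos)
    arrays$end <- as.integer(arrays$pos + arrays$length)
    arrays$unit_length <- nchar(units[arrays$subfamily])
    if (any(arrays$length < arrays$unit_length))
      stop("array_length must be >= unit_length")
    for (cn in chroms) {
      a <- arrays[arrays$chrom == cn, , drop = FALSE]
      if (nrow(a) == 0L) next
      a <- a[order(a$start), , drop = FALSE]
      if (any(a$start < 0) || any(a$end > nchar(seqs[[cn]])))
        stop("arrays must fit within their chromosome")
      if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)]))
        stop("overlapping arrays on chromosome ", cn)
      pieces <- character(0)
      cursor <- 0L
      bg <- seqs[[cn]]
      for (r in seq_len(nrow(a))) {
        unit <- units[[a$subfamily[r]]]
        n_copies <- ceiling(a$length[r] / nchar(unit))
        copies <- rep(unit, n_copies)
        if (copy_divergence > 0) {
          copies <- vapply(copies, function(u) {
            b <- strsplit(u, "")[[1]]
            hit <- runif(length(b)) < copy_divergence
            if (any(hit)) {
              idx <- match(b[hit], DNA_BASES)
              b[hit] <- DNA_BASES[((idx - 1L + sample.int(3L, sum(hit), TRUE)) %% 4L) + 1L]
            }
            paste(b, collapse = "")
          }, "", USE.NAMES = FALSE)
        }
        arr <- substr(paste(copies, collapse = ""), 1L, a$length[r])
        pieces <- c(pieces, substr(bg, cursor + 1L, a$start[r]), arr)
        cursor <- a$end[r]
      }
      pieces <- c(pieces, substr(bg, cursor + 1L, nchar(bg)))
      seqs[[cn]] <- paste(pieces, collapse = "")
    }
    arrays <- arrays[, c("chrom", "start", "end", "subfamily", "unit_length")]
    structure(list(
      chromosomes = seqs,
      truth = list(
        arrays = arrays,
        true_array_bp = tapply(arrays$end - arrays$start, arrays$subfamily, sum)
      )), class = "sat_genome")
  })
}

#' @export
print.sat_genome <- function(x, ...) {
  cat(sprintf("<sat_genome> %d chromosome(s), %.0f bp total, %d planted array(s)\n",
              length(x$chromosomes), sum(nchar(x$chromosomes)),
              nrow(x$truth$arrays)))
  invisible(x)
}

# Apply the phred quality model and quality-implied substitution errors to a
# set of extracted read sequences (vectorized over all bases at once).
# Returns list(seq, qual).
apply_quality_model <- function(seqs, config) {
  n <- length(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  if (total == 0L)
    return(list(seq = seqs, qual = rep(list(integer(0)), n)))
  q <- rep(config$phred_high, total)
  if (config$low_q_rate > 0)
    q[runif(total) < config$low_q_rate] <- config$phred_low
  grp <- rep.int(seq_len(n), lens)
  attr(grp, "levels") <- as.character(seq_len(n))
  class(grp) <- "factor"
  qual <- unname(split(as.integer(q), grp))
  err <- runif(total) < 10^(-q / 10)
  if (any(err)) {
    braw <- charToRaw(paste(seqs, collapse = ""))
    idx <- BASE_CODE[as.integer(braw[err]) + 1L]
    ok <- which(err)[idx > 0L]
    idx <- idx[idx > 0L]
    braw[ok] <- DNA_RAW[((idx - 1L + sample.int(3L, length(idx),
                                                replace = TRUE)) %% 4L) + 1L]
    ends <- cumsum(lens)
    seqs <- substring(rawToChar(braw), ends - lens + 1L, ends)
  }
  list(seq = seqs, qual = qual)
}

# Draw a chromosome index per read, proportional to chromosome length.
draw_chroms <- function(genome, n) {
  lens <- nchar(genome$chromosomes)
  sample.int(length(lens), n, replace = TRUE, prob = lens / sum(lens))
}

#' Simulate Sanger-like paired reads from a genome
#'
#' Clones are placed uniformly on the genome (chromosomes weighted by
#' length); each clone yields a forward read at one end of the insert and a
#' reverse-strand read at the other end. Read and insert lengths are drawn
#' from clamped normals, qualities follow the config's phred model, and
#' substitution errors occur at the rate implied by each base's quality. A
#' fraction of reads (config `mate_frac`) keeps its sequenced mate; for the
#' rest, one read of the clone is dropped, emulating single-ended clones.
#'
#' @param genome a [build_genome()] result.
#' @param config a [sim_config()].
#' @return list with elements `reads` ([sat_reads()], mate ids filled in),
#'   `pairs` (data.frame `read_id`, `mate_id`, complete pairs only),
#'   `origins` (data.frame `read_id`, `chrom`, `start`, `end`, `strand`,
#'   0-based half-open, coordinates of the error-free source interval) and
#'   `n_clamped` (number of clamped length draws).
#' @export
sim_sanger_pairs <- function(genome, config = sim_config()) {
  G <- sum(nchar(genome$chromosomes))
  n_clones <- round(config$coverage * G / (2 * config$read_len_mean))
  max_insert <- 5 * config$insert_len_mean
  if (any(nchar(genome$chromosomes) <= max_insert))
    stop("all chromosomes must be longer than the maximum insert (",
         max_insert, " bp)")
  with_seed(config$seed, {
    ci <- draw_chroms(genome, n_clones)
    clens <- nchar(genome$chromosomes)[ci]
    l1 <- clamped_normal(n_clones, config$read_len_mean, config$read_len_sd,
                         50, 5 * config$read_len_mean)
    l2 <- clamped_normal(n_clones, config$read_len_mean, config$read_len_sd,
                         50, 5 * config$read_len_mean)
    ins <- clamped_normal(n_clones, config$insert_len_mean, config$insert_len_sd,
                          50, max_insert)
    len1 <- as.integer(round(l1$x)); len2 <- as.integer(round(l2$x))
    insert <- pmax(as.integer(round(ins$x)), len1, len2)
    start <- as.integer(floor(runif(n_clones) * (clens - insert + 1)))
    cn <- names(genome$chromosomes)[ci]
    s1 <- start; e1 <- start + len1
    s2 <- start + insert - len2; e2 <- start + insert
    fwd <- substring(genome$chromosomes[ci], s1 + 1L, e1)
    rev <- revcomp(substring(genome$chromosomes[ci], s2 + 1L, e2))
    # which clones keep both reads: solve for fraction of reads with mates
    f <- config$mate_frac
    p_both <- if (f >= 1) 1 else f / (2 - f)
    keep_both <- runif(n_clones) < p_both
    drop_fwd <- !keep_both & (runif(n_clones) < 0.5)
    id1 <- sprintf("clone%07d/1", seq_len(n_clones))
    id2 <- sprintf("clone%07d/2", seq_len(n_clones))
    ids <- c(id1, id2)
    seqs <- c(fwd, rev)
    mates <- c(ifelse(keep_both, id2, NA_character_),
               ifelse(keep_both, id1, NA_character_))
    origins <- data.frame(read_id = ids, chrom = c(cn, cn),
                          start = c(s1, s2), end = c(e1, e2),
                          strand = rep(c("+", "-"), each = n_clones),
                          stringsAsFactors = FALSE)
    keep <- c(keep_both | !drop_fwd, keep_both | drop_fwd)
    qm <- apply_quality_model(seqs[keep], config)
    reads <- sat_reads(ids[keep], qm$seq, qm$qual, mates[keep])
    ord <- order(reads$id)
    reads <- subset_reads(reads, ord)
    list(reads = reads,
         pairs = data.frame(read_id = id1[keep_both], mate_id = id2[keep_both],
                            stringsAsFactors = FALSE),
         origins = origins[keep, ][order(origins$read_id[keep]), ],
         n_clamped = l1$n_clamped + l2$n_clamped + ins$n_clamped)
  })
}

#' Simulate a flow-sorted (whole-chromosome shotgun) read sample
#'
#' Each read's chromosome of origin is drawn from the supplied mixing
#' proportions, emulating an imperfectly pure flow-sorted chromosome
#' library; reads are single-ended with Sanger-like lengths and qualities.
#'
#' @param genome a [build_genome()] result.
#' @param mixing numeric vector of per-chromosome proportions summing to 1,
#'   named by chromosome (or in `names(genome$chromosomes)` order).
#' @param n_reads number of reads to draw.
#' @param config a [sim_config()].
#' @param target label for the chromosome(s) the sample nominally targets
#'   (defaults to the highest-proportion chromosome).
#' @return list with `reads`, `origins`, `mixing` (the truth) and `target`.
#' @export
sim_wcs_sample <- function(genome, mixing, n_reads, config = sim_config(),
                           target = NULL) {
  cn <- names(genome$chromosomes)
  if (is.null(names(mixing))) names(mixing) <- cn
  mixing <- mixing[cn]
  if (any(mixing < 0)) stop("mixing proportions must be non-negative")
  if (abs(sum(mixing) - 1) > 1e-9) stop("mixing proportions must sum to 1")
  if (is.null(target)) target <- cn[which.max(mixing)]
  with_seed(config$seed, {
    ci <- sample.int(length(cn), n_reads, replace = TRUE, prob = mixing)
    lens <- clamped_normal(n_reads, config$read_len_mean, config$read_len_sd,
                           50, 5 * config$read_len_mean)
    len <- as.integer(round(lens$x))
    clen <- nchar(genome$chromosomes)[ci]
    len <- pmin(len, clen)
    start <- as.integer(floor(runif(n_reads) * (clen - len + 1)))
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    seqs <- substring(genome$chromosomes[ci], start + 1L, start + len)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    qm <- apply_quality_model(seqs, config)
    ids <- sprintf("wcs%07d", seq_len(n_reads))
    list(reads = sat_reads(ids, qm$seq, qm$qual),
         origins = data.frame(read_id = ids, chrom = cn[ci], start = start,
                              end = start + len, strand = strand,
                              stringsAsFactors = FALSE),
         mixing = mixing, target = target)
  })
}

#' Simulate fixed-length short (Illumina-like) single-end reads
#'
#' @param genome a [build_genome()] result.
#' @param read_len read length in bp.
#' @param coverage fold coverage.
#' @param config a [sim_config()] (only the quality model and seed are used).
#' @return list with `reads` and `origins` as in [sim_sanger_pairs()].
#' @export
sim_illumina_reads <- function(genome, read_len = 100L, coverage = 4,
                               config = sim_config()) {
  G <- sum(nchar(genome$chromosomes))
  n <- round(coverage * G / read_len)
  with_seed(config$seed, {
    ci <- draw_chroms(genome, n)
    clen <- nchar(genome$chromosomes)[ci]
    if (any(clen < read_len)) stop("chromosomes shorter than read_len")
    start <- as.integer(floor(runif(n) * (clen - read_len + 1)))
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- substring(genome$chromosomes[ci], start + 1L, start + read_len)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    qm <- apply_quality_model(seqs, config)
    ids <- sprintf("sr%08d", seq_len(n))
    list(reads = sat_reads(ids, qm$seq, qm$qual),
         origins = data.frame(read_id = ids, chrom = names(genome$chromosomes)[ci],
                              start = start, end = start + read_len,
                              strand = strand, stringsAsFactors = FALSE))
  })
}

#' Surrogate satellite annotator
#'
#' Marks maximal read intervals in which the sliding-window density of a
#' pentamer (or its reverse complement) meets `density_min`. Stands in for a
#' RepeatMasker screen of pentamer-derived satellite: the default window and
#' density are chosen so pure `(CATTC)n` sequence scores 1, subfamilies up
#' to roughly 30% diverged from the pentameric ancestor are still marked
#' (emulating RepeatMasker's tolerance of diverged satellite), and random
#' background scores about 0. Emits per-read interval annotations that
#' [parse_repeatmasker_out()] consumers handle identically to real
#' RepeatMasker `.out` records (see [write_repeatmasker_out()]).
#'
#' @param reads a [sat_reads()] object (or list with `id`, `seq`).
#' @param pentamer satellite pentamer (default CATTC).
#' @param window sliding window size in bp (>= 5).
#' @param density_min minimum fraction of window bases covered by pentamer
#'   occurrences.
#' @return named list (by read id) of annotation data.frames with columns
#'   `start`, `end` (0-based half-open), `name`, `strand`, `pid`. Reads with
#'   no interval are absent.
#' @export
surrogate_annotate <- function(reads, pentamer = "CATTC", window = 100L,
                               density_min = 0.15) {
  if (window < 5) stop("`window` must be >= 5")
  if (nchar(pentamer) != 5) stop("`pentamer` must have length 5")
  rc <- revcomp(pentamer)
  dss <- Biostrings::DNAStringSet(reads$seq)
  hits_p <- Biostrings::vmatchPattern(pentamer, dss)
  hits_m <- Biostrings::vmatchPattern(rc, dss)
  name_p <- sprintf("(%s)n", pentamer)
  name_m <- sprintf("(%s)n", rc)
  out <- list()
  for (i in seq_along(reads$id)) {
    L <- nchar(reads$seq[i])
    if (L < window) next
    sp <- Biostrings::start(hits_p[[i]]); sm <- Biostrings::start(hits_m[[i]])
    if (length(sp) + length(sm) == 0L) next
    cov_p <- logical(L); cov_m <- logical(L)
    for (s in sp) cov_p[s:(s + 4L)] <- TRUE
    for (s in sm) cov_m[s:(s + 4L)] <- TRUE
    cov <- cov_p | cov_m
    cs <- c(0L, cumsum(cov))
    nwin <- L - window + 1L
    dens <- (cs[(window + 1L):(L + 1L)] - cs[1:nwin]) / window
    ok <- dens >= density_min
    if (!any(ok)) next
    marked <- logical(L)
    # a base is marked if any window containing it passes the density test
    starts <- which(ok)
    delta <- integer(L + 1L)
    delta[starts] <- delta[starts] + 1L
    delta[starts + window] <- delta[starts + window] - 1L
    marked <- cumsum(delta[seq_len(L)]) > 0L
    iv <- true_runs(marked)
    np <- nm <- integer(nrow(iv))
    for (r in seq_len(nrow(iv))) {
      np[r] <- sum(sp > iv$start[r] & sp <= iv$end[r] - 4L)
      nm[r] <- sum(sm > iv$start[r] & sm <= iv$end[r] - 4L)
    }
    iv$name <- ifelse(nm > np, name_m, name_p)
    iv$strand <- ifelse(nm > np, "-", "+")
    iv$pid <- round(100 * vapply(seq_len(nrow(iv)), function(r)
      mean(cov[(iv$start[r] + 1L):iv$end[r]]), 0), 1)
    out[[reads$id[i]]] <- iv
  }
  out
}

#' Write annotations in RepeatMasker `.out` layout
#'
#' Emits the 15-column whitespace-delimited RepeatMasker `.out` dialect
#' (3 header lines; 1-based inclusive query coordinates; strand `+` or `C`)
#' so downstream parsing treats surrogate and real annotation files
#' identically.
#'
#' @param annotations result of [surrogate_annotate()] or
#'   [parse_repeatmasker_out()].
#' @param reads the annotated [sat_reads()] (for read lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW  perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score  div. del. ins.  sequence  begin  end   (left)   repeat    class/family  begin  end (left)  ID",
    ""), con)
  id_counter <- 0L
  lens <- stats::setNames(nchar(reads$seq), reads$id)
  for (rid in names(annotations)) {
    iv <- annotations[[rid]]
    for (r in seq_len(nrow(iv))) {
      id_counter <- id_counter + 1L
      w <- iv$end[r] - iv$start[r]
      writeLines(sprintf(
        "%5d %5.1f  0.0  0.0  %s  %d  %d  (%d)  %s  %s  Satellite  1  %d  (0)  %d",
        10L * w, 100 - iv$pid[r], rid, iv$start[r] + 1L, iv$end[r],
        lens[[rid]] - iv$end[r],
        if (iv$strand[r] == "-") "C" else "+", iv$name[r], w, id_counter), con)
    }
  }
  invisible(path)
}
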