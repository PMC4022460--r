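#' 24-mer library parameters
#'
#' @param kmer_len diagnostic k-mer length (default 24).
#' @param phred_min all bases of a window must have phred above this
#'   (default 20).
#' @param min_read_support a k-mer must be seen on at least this many reads
#'   overall to be considered (default 2; screens out sequencing errors).
#' @param in_frac minimum fraction of a subfamily's reads carrying the
#'   k-mer (default 0.01, i.e. present on more than 1% of reads).
#' @param out_frac maximum fraction of any other subfamily's reads carrying
#'   it (default 0.001).
#' @return a list of class `library_params`.
#' @export
library_params <- function(kmer_len = 24L, phred_min = 20L,
                           min_read_support = 2L, in_frac = 0.01,
                           out_frac = 0.001) {
  stopifnot(out_frac < in_frac, in_frac <= 1, out_frac >= 0)
  structure(list(kmer_len = as.integer(kmer_len),
                 phred_min = as.integer(phred_min),
                 min_read_support = as.integer(min_read_support),
                 in_frac = in_frac, out_frac = out_frac),
            class = "library_params")
}

#' High-quality k-mer windows of a read
#'
#' Every window of `kmer_len` bases that are all unmasked and above the
#' phred threshold.
#'
#' @param seq read sequence (canonical orientation).
#' @param qual integer phred vector.
#' @param mask logical usable-base vector, or `NULL` for all usable.
#' @param params a [library_params()].
#' @return character vector of windows, in read order (with multiplicity).
#' @export
collect_hq_kmers <- function(seq, qual, mask = NULL,
                             params = library_params()) {
  k <- params$kmer_len
  L <- nchar(seq)
  ok <- qual > params$phred_min
  if (!is.null(mask)) ok <- ok & mask
  if (L < k || !any(ok)) return(character(0))
  runs <- true_runs(ok)
  runs <- runs[runs$end - runs$start >= k, , drop = FALSE]
  if (nrow(runs) == 0L) return(character(0))
  starts <- unlist(lapply(seq_len(nrow(runs)), function(r)
    (runs$start[r] + 1L):(runs$end[r] - k + 1L)))
  substring(seq, starts, starts + k - 1L)
}

# All HQ windows of a masked read set, as list(kmer = chr, read = int index).
hq_windows <- function(masked, params) {
  qual <- masked$qual
  mask <- masked$mask
  per_read <- lapply(seq_along(masked$id), function(i)
    collect_hq_kmers(masked$seq[i], qual[[i]],
                     if (is.null(mask)) NULL else mask[[i]], params))
  list(kmer = unlist(per_read, use.names = FALSE),
       read = rep.int(seq_along(per_read), lengths(per_read)),
       n_reads_with_window = sum(lengths(per_read) > 0L))
}

#' Build subfamily-specific k-mer libraries
#'
#' For each subfamily, retains the high-quality 24-mers that occur on more
#' than `in_frac` of that subfamily's reads, on at most `out_frac` of reads
#' in every other subfamily, on no read of the non-satellite sample, and on
#' at least `min_read_support` reads across all subfamilies. Read-fraction
#' denominators are reads with at least one HQ window; k-mers are stored in
#' the reads' canonical orientation.
#'
#' @param read_sets named list of `masked_reads`, one per subfamily (at
#'   least 2).
#' @param nonsat_reads a read set sampled from reads lacking satellite
#'   annotation (may be empty).
#' @param params a [library_params()].
#' @return named list of `kmer_library` objects: `subfamily`, `kmers`,
#'   `read_fraction`, `window_fraction`, `params`.
#' @export
build_specific_library <- function(read_sets, nonsat_reads = NULL,
                                   params = library_params()) {
  if (length(read_sets) < 2L) stop("need at least 2 subfamilies")
  if (any(vapply(read_sets, function(r) length(r$id) == 0L, TRUE)))
    stop("empty subfamily read set")
  wins <- lapply(read_sets, hq_windows, params = params)
  # per-subfamily: reads carrying each k-mer, and window totals
  read_counts <- lapply(wins, function(w) {
    if (length(w$kmer) == 0L) return(integer(0))
    key <- !duplicated(paste0(w$read, "\r", w$kmer))
    table(w$kmer[key])
  })
  win_counts <- lapply(wins, function(w) table(w$kmer))
  denoms <- vapply(wins, `[[`, 0L, "n_reads_with_window")
  nonsat_kmers <- if (is.null(nonsat_reads)) character(0) else
    unique(hq_windows(nonsat_reads, params)$kmer)
  all_kmers <- unique(unlist(lapply(read_counts, names), use.names = FALSE))
  support <- stats::setNames(numeric(length(all_kmers)), all_kmers)
  for (rc in read_counts) support[names(rc)] <- support[names(rc)] + rc
  out <- list()
  for (s in names(read_sets)) {
    rc <- read_counts[[s]]
    if (length(rc) == 0L) {
      out[[s]] <- structure(list(subfamily = s, kmers = character(0),
                                 read_fraction = numeric(0),
                                 window_fraction = numeric(0), params = params),
                            class = "kmer_library")
      next
    }
    frac_in <- as.numeric(rc) / denoms[[s]]
    keep <- frac_in > params$in_frac
    km <- names(rc)[keep]
    for (t in setdiff(names(read_sets), s)) {
      rc_t <- read_counts[[t]]
      f_out <- ifelse(km %in% names(rc_t),
                      as.numeric(rc_t[km]) / denoms[[t]], 0)
      km <- km[f_out <= params$out_frac]
    }
    km <- km[!(km %in% nonsat_kmers)]
    km <- km[support[km] >= params$min_read_support]
    wc <- win_counts[[s]]
    out[[s]] <- structure(list(
      subfamily = s, kmers = km,
      read_fraction = stats::setNames(as.numeric(rc[km]) / denoms[[s]], km),
      window_fraction = stats::setNames(
        as.numeric(wc[km]) / sum(wc), km),
      params = params), class = "kmer_library")
  }
  out
}

#' @export
print.kmer_library <- function(x, ...) {
  cat(sprintf("<kmer_library> %s: %d specific %d-mers\n",
              x$subfamily, length(x$kmers), x$params$kmer_len))
  invisible(x)
}

#' Fold compression and pairwise k-mer overlap of subfamily read sets
#'
#' Fold compression is the total number of high-quality k-mer windows
#' divided by the number of distinct k-mers — a self-similarity measure (1
#' iff all windows are distinct). Pairwise overlap is the multiset
#' containment of the smaller subfamily's window multiset in the larger's:
#' matched windows are not re-used, so the overlap equals
#' `sum_k min(mult_small(k), mult_large(k)) / total_small`. Windows are
#' restricted to k-mers seen on at least `min_read_support` reads across
#' all subfamilies.
#'
#' @param read_sets named list of `masked_reads`, one per subfamily.
#' @param params a [library_params()].
#' @return list with `fold_compression` (named vector), `overlap`
#'   (symmetric matrix), `total_windows`, `distinct_kmers`.
#' @export
library_stats <- function(read_sets, params = library_params()) {
  wins <- lapply(read_sets, hq_windows, params = params)
  read_counts <- lapply(wins, function(w) {
    if (length(w$kmer) == 0L) return(integer(0))
    key <- !duplicated(paste0(w$read, "\r", w$kmer))
    table(w$kmer[key])
  })
  all_kmers <- unique(unlist(lapply(read_counts, names), use.names = FALSE))
  support <- stats::setNames(numeric(length(all_kmers)), all_kmers)
  for (rc in read_counts) support[names(rc)] <- support[names(rc)] + rc
  supported <- names(support)[support >= params$min_read_support]
  multisets <- lapply(wins, function(w) {
    km <- w$kmer[w$kmer %in% supported]
    table(km)
  })
  totals <- vapply(multisets, sum, 0)
  distinct <- vapply(multisets, length, 0L)
  fold <- ifelse(distinct > 0, totals / distinct, NA_real_)
  ns <- names(read_sets)
  ov <- matrix(NA_real_, length(ns), length(ns), dimnames = list(ns, ns))
  for (a in seq_along(ns)) for (b in seq_along(ns)) {
    if (a == b) { ov[a, b] <- 1; next }
    small <- if (totals[a] <= totals[b]) a else b
    large <- if (small == a) b else a
    ms <- multisets[[small]]; ml <- multisets[[large]]
    common <- intersect(names(ms), names(ml))
    ov[a, b] <- if (totals[small] == 0) NA_real_ else
      sum(pmin(as.numeric(ms[common]), as.numeric(ml[common]))) / totals[small]
  }
  list(fold_compression = stats::setNames(as.numeric(fold), ns),
       overlap = ov,
       total_windows = stats::setNames(as.numeric(totals), ns),
       distinct_kmers = stats::setNames(as.integer(distinct), ns))
}

#' Classify a sequence by perfect matches to subfamily k-mer libraries
#'
#' Counts exact occurrences of each library's k-mers on both strands of the
#' sequence and assigns the subfamily with the most hits; ties and zero
#' hits yield `"unassigned"`.
#'
#' @param sequence a DNA sequence.
#' @param libraries named list of `kmer_library` objects (or character
#'   vectors of k-mers).
#' @return list with `assignment` and `hits` (named counts).
#' @export
classify_sequence <- function(sequence, libraries) {
  if (length(libraries) == 0L) stop("`libraries` must be non-empty")
  kml <- lapply(libraries, function(l) if (is.list(l)) l$kmers else l)
  k <- unique(nchar(unlist(kml, use.names = FALSE)))
  if (length(k) == 0L) stop("all libraries are empty")
  stopifnot(length(k) == 1L)
  L <- nchar(sequence)
  if (L < k) {
    return(list(assignment = "unassigned",
                hits = stats::setNames(rep(0L, length(kml)), names(kml))))
  }
  starts <- seq_len(L - k + 1L)
  wins <- c(substring(sequence, starts, starts + k - 1L),
            substring(revcomp(sequence), starts, starts + k - 1L))
  hits <- vapply(kml, function(km) sum(wins %in% km), 0L)
  top <- which(hits == max(hits))
  assignment <- if (max(hits) == 0L || length(top) > 1L) "unassigned" else
    names(kml)[top]
  list(assignment = assignment, hits = hits)
}

#' Write a k-mer library table
#'
#' TSV with columns `kmer`, `subfamily`, `read_fraction`, `window_fraction`.
#'
#' @param libraries result of [build_specific_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_library <- function(libraries, path) {
  rows <- do.call(rbind, lapply(libraries, function(l)
    if (length(l$kmers)) data.frame(kmer = l$kmers, subfamily = l$subfamily,
                                    read_fraction = l$read_fraction,
                                    window_fraction = l$window_fraction,
                                    stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_library
#' @export
read_kmer_library <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(split(tab, tab$subfamily), function(d)
    structure(list(subfamily = d$subfamily[1], kmers = d$kmer,
                   read_fraction = stats::setNames(d$read_fraction, d$kmer),
                   window_fraction = stats::setNames(d$window_fraction, d$kmer),
                   params = library_params()), class = "kmer_library"))
}
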