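#' Array-size estimation parameters
#'
#' @param rho proportion of all high-quality 24-mers on the subfamily's
#'   reference reads that match the subfamily-specific library. This is
#'   data-specific: 0.459 for the published DYZ1 (HSat3A6) library; for
#'   synthetic subfamilies use [compute_rho()].
#' @param G genome size in bp the hit proportion is scaled by (default the
#'   hg19 diploid male genome, 5,976,710,698 bp).
#' @param kmer_len,phred_min as in [library_params()].
#' @return a list of class `size_params`.
#' @export
size_params <- function(rho = 0.459, G = 5976710698, kmer_len = 24L,
                        phred_min = 20L) {
  stopifnot(rho > 0, rho <= 1, G > 0)
  structure(list(rho = rho, G = G, kmer_len = as.integer(kmer_len),
                 phred_min = as.integer(phred_min)),
            class = "size_params")
}

# Vectorized HQ-window accounting for a chunk of reads: replaces low-quality
# or non-ACGT bases with N and counts the remaining k-windows.
# Returns list(seqs = masked sequences, n_windows = HQ window count).
mask_and_count_windows <- function(seqs, quals, phred_min, k) {
  lens <- nchar(seqs)
  total <- sum(lens)
  braw <- charToRaw(paste(seqs, collapse = ""))
  bad <- (unlist(quals, use.names = FALSE) <= phred_min) |
    BASE_CODE[as.integer(braw) + 1L] == 0L
  # count HQ windows per maximal good run, with sentinels at read boundaries
  good2 <- logical(total + length(seqs))
  pos <- seq_len(total) + rep.int(seq_along(seqs) - 1L, lens)
  good2[pos] <- !bad
  r <- rle(good2)
  n_windows <- sum(pmax(r$lengths[r$values] - k + 1L, 0L))
  if (any(bad)) {
    braw[bad] <- charToRaw("N")
    ends <- cumsum(lens)
    seqs <- substring(rawToChar(braw), ends - lens + 1L, ends)
  }
  list(seqs = seqs, n_windows = n_windows)
}

#' Count library-matching high-quality 24-mers in short reads
#'
#' Streams over reads counting `T`, the number of 24-bp windows whose bases
#' all exceed the phred threshold, and `M`, those exactly matching the
#' k-mer library on either strand. Reads are processed in chunks so memory
#' stays constant in the dataset size.
#'
#' @param reads a [sat_reads()] object, or a FASTQ path.
#' @param library a `kmer_library` or character vector of k-mers.
#' @param params a [size_params()].
#' @param chunk_size reads per processing chunk.
#' @return named numeric vector `c(M = ..., T = ...)`.
#' @export
count_library_hits <- function(reads, library, params = size_params(),
                               chunk_size = 100000L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  kml <- if (is.list(library)) library$kmers else library
  if (length(kml) == 0L) stop("`library` must be non-empty")
  k <- params$kmer_len
  stopifnot(all(nchar(kml) == k))
  both <- unique(c(kml, revcomp(kml)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(both))
  M <- 0; Tn <- 0
  n <- length(reads$id)
  for (b0 in seq.int(1L, n, by = chunk_size)) {
    b1 <- min(b0 + chunk_size - 1L, n)
    sel <- b0:b1
    mc <- mask_and_count_windows(reads$seq[sel], reads$qual[sel],
                                 params$phred_min, k)
    Tn <- Tn + mc$n_windows
    dss <- Biostrings::DNAStringSet(mc$seqs)
    M <- M + sum(Biostrings::vcountPDict(pd, dss, collapse = 1L))
  }
  c(M = M, T = Tn)
}

#' Raw array size from k-mer hit proportions
#'
#' `raw_size = (M / T) / rho * G`: the genome-wide proportion of
#' high-quality 24-mers matching the subfamily library, calibrated by the
#' matching proportion `rho` observed on the subfamily's own reference
#' reads, scaled to genome size.
#'
#' @param M library-matching HQ 24-mer count.
#' @param T_total total HQ 24-mer count (> 0).
#' @param params a [size_params()].
#' @return raw array size in bp.
#' @export
estimate_size <- function(M, T_total, params = size_params()) {
  if (T_total <= 0) stop("total HQ 24-mer count must be positive")
  (M / T_total) / params$rho * params$G
}

#' Matching proportion of a library on its reference reads
#'
#' The fraction of all high-quality 24-mer windows on the subfamily's
#' reference reads that exactly match the subfamily-specific library
#' (either strand) — the `rho` calibration constant of [estimate_size()].
#'
#' @param masked subfamily reference reads (`masked_reads`).
#' @param library the subfamily's `kmer_library` (or k-mer vector).
#' @param params a [library_params()] controlling window extraction.
#' @return proportion in `[0, 1]`.
#' @export
compute_rho <- function(masked, library, params = library_params()) {
  w <- hq_windows(masked, params)
  if (length(w$kmer) == 0L) stop("no HQ windows on the reference reads")
  kml <- if (is.list(library)) library$kmers else library
  both <- unique(c(kml, revcomp(kml)))
  mean(w$kmer %in% both)
}

#' Build an AT-matched single-copy control k-mer set
#'
#' Samples control 24-mers that occur exactly once in the reference
#' sequence and outside excluded (repeat) intervals, stratified by AT count
#' (0-24) to match the target library's AT-count histogram (proportional
#' allocation with largest-remainder rounding; shortfalls in a stratum are
#' filled from the nearest stratum with a warning).
#'
#' @param reference reference sequence (single string) the controls are
#'   unique within.
#' @param target_library the subfamily `kmer_library` (or k-mer vector)
#'   whose AT distribution is matched.
#' @param n_controls number of controls requested.
#' @param exclusions optional data.frame `start`, `end` (0-based half-open)
#'   of intervals controls may not overlap.
#' @param params a [size_params()] (for k-mer length).
#' @param seed integer RNG seed.
#' @return an object of class `control_set`: `kmers`, `at_count`, `start`
#'   (0-based position in the reference).
#' @export
build_control_set <- function(reference, target_library, n_controls,
                              exclusions = NULL, params = size_params(),
                              seed = 1L) {
  k <- params$kmer_len
  kml <- if (is.list(target_library)) target_library$kmers else target_library
  L <- nchar(reference)
  starts <- seq_len(L - k + 1L)
  wins <- substring(reference, starts, starts + k - 1L)
  valid <- !grepl("[^ACGT]", wins)
  tab <- table(wins[valid])
  unique_k <- names(tab)[tab == 1L]
  cand <- which(valid & wins %in% unique_k)
  if (!is.null(exclusions) && nrow(exclusions)) {
    s0 <- starts[cand] - 1L
    bad <- rep(FALSE, length(cand))
    for (r in seq_len(nrow(exclusions)))
      bad <- bad | (s0 < exclusions$end[r] & s0 + k > exclusions$start[r])
    cand <- cand[!bad]
  }
  if (length(cand) < n_controls)
    stop("reference has only ", length(cand), " unique candidate 24-mers")
  at_of <- function(x) as.integer(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(x), "AT"))
  target_at <- at_of(kml)
  cand_at <- at_of(wins[cand])
  hist_t <- tabulate(target_at + 1L, nbins = k + 1L)
  want <- hist_t / sum(hist_t) * n_controls
  alloc <- floor(want)
  rem <- n_controls - sum(alloc)
  if (rem > 0) {
    ord <- order(want - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  with_seed(seed, {
    chosen <- integer(0)
    shortfall <- 0L
    for (a in 0:k) {
      pool <- cand[cand_at == a]
      take <- min(alloc[a + 1L], length(pool))
      shortfall <- shortfall + alloc[a + 1L] - take
      if (take > 0)
        chosen <- c(chosen, sample(pool, take))
    }
    if (shortfall > 0L) {
      warning("filling ", shortfall,
              " control(s) from nearest AT strata")
      remaining <- setdiff(cand, chosen)
      # prefer candidates whose AT count is closest to the target mean
      pref <- order(abs(at_of(wins[remaining]) - mean(target_at)))
      chosen <- c(chosen, remaining[pref][seq_len(shortfall)])
    }
    chosen <- sort(chosen)
    structure(list(kmers = wins[chosen], at_count = at_of(wins[chosen]),
                   start = starts[chosen] - 1L),
              class = "control_set")
  })
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("<control_set> %d single-copy control 24-mers (mean AT %.1f)\n",
              length(x$kmers), mean(x$at_count)))
  invisible(x)
}

#' Calibrate array-size estimates with control k-mer coverage
#'
#' Eliminates control k-mers in the bottom or top `trim_frac` of total
#' coverage across male samples, and (when female counts are supplied, for
#' Y-linked targets) controls with more than `female_max_reads` hits in any
#' female. Each male's control-region size is then estimated by the same
#' hit-rate calculation with `rho = 1` (single-copy) and compared with the
#' true control size (the number of retained controls, in bp of unique
#' anchor sequence); all raw estimates are corrected down by the mean
#' signed relative error, and samples with absolute control error above
#' `outlier_error` are flagged excluded.
#'
#' @param raw_sizes named per-sample raw array size estimates (bp).
#' @param control_counts controls x samples matrix of per-control read hit
#'   counts in the male samples.
#' @param T_total named per-sample total HQ 24-mer counts.
#' @param control_set a [build_control_set()] result (or k-mer vector).
#' @param params a [size_params()] (for `G`).
#' @param female_counts optional controls x samples matrix for female
#'   samples.
#' @param trim_frac coverage fraction trimmed from each tail (default
#'   0.005).
#' @param female_max_reads maximum female hits tolerated (default 10).
#' @param outlier_error absolute control error above which a sample is
#'   excluded (default 0.30).
#' @return an object of class `size_estimates`: data.frame with
#'   `sample_id`, `raw_size`, `control_error`, `corrected_size`,
#'   `excluded`; attributes `mean_error`, `n_controls_retained`, `C_true`.
#' @export
calibrate_and_correct <- function(raw_sizes, control_counts, T_total,
                                  control_set, params = size_params(),
                                  female_counts = NULL, trim_frac = 0.005,
                                  female_max_reads = 10L,
                                  outlier_error = 0.30) {
  control_counts <- as.matrix(control_counts)
  K <- nrow(control_counts)
  if (length(raw_sizes) < 2L) stop("need at least 2 male samples")
  stopifnot(ncol(control_counts) == length(raw_sizes),
            length(T_total) == length(raw_sizes))
  tot <- rowSums(control_counts)
  n_trim <- ceiling(trim_frac * K)
  ord <- order(tot, seq_len(K))
  drop <- rep(FALSE, K)
  if (n_trim > 0) {
    drop[ord[seq_len(n_trim)]] <- TRUE
    drop[ord[(K - n_trim + 1L):K]] <- TRUE
  }
  if (!is.null(female_counts))
    drop <- drop | apply(as.matrix(female_counts) > female_max_reads, 1L, any)
  if (all(drop)) stop("all control 24-mers were eliminated")
  kept <- which(!drop)
  C_true <- length(kept)
  Mc <- colSums(control_counts[kept, , drop = FALSE])
  est_c <- (Mc / as.numeric(T_total)) * params$G
  err <- (est_c - C_true) / C_true
  mean_err <- mean(err)
  corrected <- as.numeric(raw_sizes) / (1 + mean_err)
  out <- data.frame(sample_id = names(raw_sizes), raw_size = as.numeric(raw_sizes),
                    control_error = err, corrected_size = corrected,
                    excluded = abs(err) > outlier_error,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("size_estimates", "data.frame"),
            mean_error = mean_err, n_controls_retained = C_true,
            C_true = C_true)
}

#' Compare array sizes between groups (haplogroups)
#'
#' Per-group summaries plus all pairwise two-sided two-sample Wilcoxon
#' rank-sum tests with Holm correction. The exact distribution is used when
#' the smaller group has at most 10 members and there are no ties; the
#' normal approximation with continuity correction otherwise. Groups with
#' fewer than 2 members appear in the summary but are excluded from tests.
#'
#' @param sizes numeric array sizes.
#' @param groups group (haplogroup) label per size.
#' @param alpha significance level applied to Holm-adjusted p-values
#'   (default 0.001).
#' @return an object of class `haplogroup_tests`: `summary` (per group: n,
#'   mean, sd, min, max), `pairs` (data.frame with raw and Holm-adjusted
#'   p-values, difference of medians, Hodges-Lehmann shift, significance),
#'   `alpha`.
#' @export
haplogroup_compare <- function(sizes, groups, alpha = 0.001) {
  groups <- as.character(groups)
  sp <- split(as.numeric(sizes), groups)
  smry <- data.frame(group = names(sp),
                     n = vapply(sp, length, 0L),
                     mean = vapply(sp, mean, 0),
                     sd = vapply(sp, sd, 0),
                     min = vapply(sp, min, 0),
                     max = vapply(sp, max, 0),
                     row.names = NULL, stringsAsFactors = FALSE)
  eligible <- names(sp)[vapply(sp, length, 0L) >= 2L]
  if (length(eligible) < 2L) stop("need at least 2 groups with >= 2 members")
  combos <- utils::combn(eligible, 2L)
  pairs <- data.frame(group1 = combos[1L, ], group2 = combos[2L, ],
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    x <- sp[[pairs$group1[r]]]; y <- sp[[pairs$group2[r]]]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- min(length(x), length(y)) <= 10L && !ties
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                       conf.int = TRUE))
    c(p = wt$p.value, hl = unname(wt$estimate))
  })
  pairs$p <- vapply(res, `[[`, 0, "p")
  pairs$p_holm <- p.adjust(pairs$p, method = "holm")
  pairs$median_diff <- vapply(seq_len(nrow(pairs)), function(r)
    median(sp[[pairs$group1[r]]]) - median(sp[[pairs$group2[r]]]), 0)
  pairs$hl_shift <- vapply(res, `[[`, 0, "hl")
  pairs$significant <- pairs$p_holm < alpha
  structure(list(summary = smry, pairs = pairs, alpha = alpha),
            class = "haplogroup_tests")
}

#' @export
print.haplogroup_tests <- function(x, ...) {
  cat("<haplogroup_tests>\n")
  print(x$summary, row.names = FALSE)
  sig <- x$pairs[x$pairs$significant, , drop = FALSE]
  cat(sprintf("%d of %d pairs significant at Holm-adjusted p < %g\n",
              nrow(sig), nrow(x$pairs), x$alpha))
  invisible(x)
}

#' Read a per-sample array-size table
#'
#' Parses the published per-individual DYZ1 (HSat3A6) array-size layout:
#' five whitespace-delimited columns — sample id, population, Y haplogroup
#' (major), Y haplogroup (full), and array size estimate in bp. A header
#' line is detected and skipped automatically.
#'
#' @param path file path.
#' @param combine_QP collapse haplogroups `Q` and `P` into the combined
#'   `Q/P` group used in published summaries (default TRUE).
#' @return data.frame with `sample_id`, `population`, `haplogroup`,
#'   `haplogroup_full`, `size_bp`.
#' @export
read_array_size_table <- function(path, combine_QP = TRUE) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "\\s+")[[1L]]
  header <- length(toks) >= 5L && is.na(suppressWarnings(as.numeric(toks[5L])))
  tab <- read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L) stop("expected 5 columns (id, population, haplogroup, ",
                           "haplogroup_full, size_bp)")
  tab <- tab[, 1:5]
  names(tab) <- c("sample_id", "population", "haplogroup", "haplogroup_full",
                  "size_bp")
  tab$size_bp <- as.numeric(tab$size_bp)
  if (combine_QP) tab$haplogroup[tab$haplogroup %in% c("Q", "P")] <- "Q/P"
  tab
}

#' Population statistics of a per-sample array-size table
#'
#' Recomputes the headline population summaries from a table in the layout
#' of [read_array_size_table()]: overall mean size, per-haplogroup group
#' means, the raw Wilcoxon rank-sum p-value for a chosen pair of
#' haplogroups, and the number of haplogroup pairs significant at `alpha`
#' after Holm correction.
#'
#' @param tab data.frame from [read_array_size_table()].
#' @param focus_pair two haplogroup labels whose raw Wilcoxon p-value is
#'   reported (default O vs E).
#' @param alpha Holm-adjusted significance level (default 0.001).
#' @return list with `mean_size_bp`, `group_means_mb` (named), `focus_p`,
#'   `n_significant_pairs`, and the full `tests` object.
#' @export
array_size_population_stats <- function(tab, focus_pair = c("O", "E"),
                                        alpha = 0.001) {
  tests <- haplogroup_compare(tab$size_bp, tab$haplogroup, alpha = alpha)
  pr <- tests$pairs
  hit <- (pr$group1 == focus_pair[1] & pr$group2 == focus_pair[2]) |
    (pr$group1 == focus_pair[2] & pr$group2 == focus_pair[1])
  list(mean_size_bp = mean(tab$size_bp),
       group_means_mb = stats::setNames(tests$summary$mean / 1e6,
                                        tests$summary$group),
       focus_p = if (any(hit)) pr$p[hit] else NA_real_,
       n_significant_pairs = sum(pr$significant),
       tests = tests)
}
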