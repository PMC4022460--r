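# Replace masked bases with N so k-mer windows never span a masked base.
masked_to_n <- function(masked) {
  if (is.null(masked$mask)) return(masked$seq)
  vapply(seq_along(masked$seq), function(i) {
    m <- masked$mask[[i]]
    if (all(m)) return(masked$seq[i])
    b <- strsplit(masked$seq[i], "")[[1]]
    b[!m] <- "N"
    paste(b, collapse = "")
  }, "")
}

#' k-mer frequency matrix of masked reads
#'
#' Counts every k-mer window whose bases are all unmasked (windows touching
#' a masked base are skipped) and row-normalizes counts to sum to 1.
#' Columns are the `4^k` k-mers in lexicographic order (A < C < G < T).
#' Reads with no countable window are dropped with a warning.
#'
#' @param masked a `masked_reads` object (or [sat_reads()]; then all bases
#'   count).
#' @param k k-mer length, between 4 and 7 (default 5).
#' @return an object of class `kmer_matrix`: list with `values`
#'   (reads x 4^k matrix, rownames = read ids), `k`, `state`
#'   (`"row_normalized"`), and `dropped` (ids of zero-window reads).
#' @export
kmer_feature_matrix <- function(masked, k = 5L) {
  if (k < 4 || k > 7) stop("`k` must be in [4, 7]")
  seqs <- masked_to_n(masked)
  dss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(dss, width = k)
  rownames(m) <- masked$id
  rs <- rowSums(m)
  dropped <- masked$id[rs == 0]
  if (length(dropped))
    warning(length(dropped), " read(s) had no countable ", k,
            "-mer window and were dropped")
  m <- m[rs > 0, , drop = FALSE]
  m <- m / rowSums(m)
  structure(list(values = m, k = as.integer(k), state = "row_normalized",
                 dropped = dropped),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("<kmer_matrix> %d reads x %d %d-mers (%s)\n",
              nrow(x$values), ncol(x$values), x$k, x$state))
  invisible(x)
}

#' Standardize a k-mer frequency matrix
#'
#' Z-scores each column using the population standard deviation (columns
#' rescaled to mean 0, variance 1). Constant columns are set to zero and
#' recorded rather than dropped, keeping the `4^k` indexing stable. The
#' column means and SDs are retained so other matrices (e.g. flow-sorted
#' chromosome reads) can be projected into the same basis with
#' [standardize_with()].
#'
#' @param fm a row-normalized `kmer_matrix`.
#' @return the matrix with `state = "standardized"` and added
#'   `col_means`, `col_sds`, `constant_cols`.
#' @export
standardize_matrix <- function(fm) {
  if (fm$state != "row_normalized")
    stop("matrix must be row_normalized (state is '", fm$state, "')")
  x <- fm$values
  mu <- colMeans(x)
  v <- colMeans(x * x) - mu^2
  sds <- sqrt(pmax(v, 0))
  const <- sds < 1e-12
  sds_safe <- ifelse(const, 1, sds)
  x <- sweep(sweep(x, 2L, mu, "-"), 2L, sds_safe, "/")
  x[, const] <- 0
  fm$values <- x
  fm$state <- "standardized"
  fm$col_means <- mu
  fm$col_sds <- sds
  fm$constant_cols <- colnames(fm$values)[const]
  fm
}

#' Project a matrix into the standardization basis of a reference
#'
#' @param fm a row-normalized `kmer_matrix`.
#' @param ref a standardized `kmer_matrix` whose column means/SDs are used.
#' @return `fm` standardized in `ref`'s basis.
#' @export
standardize_with <- function(fm, ref) {
  if (ref$state != "standardized") stop("`ref` must be standardized")
  if (fm$state != "row_normalized") stop("`fm` must be row_normalized")
  if (fm$k != ref$k) stop("k mismatch between matrices")
  const <- ref$col_sds < 1e-12
  sds_safe <- ifelse(const, 1, ref$col_sds)
  x <- sweep(sweep(fm$values, 2L, ref$col_means, "-"), 2L, sds_safe, "/")
  x[, const] <- 0
  fm$values <- x
  fm$state <- "standardized"
  fm$col_means <- ref$col_means
  fm$col_sds <- ref$col_sds
  fm$constant_cols <- ref$constant_cols
  fm
}

#' Principal component projection of read feature vectors
#'
#' Exact singular value decomposition of the standardized matrix (no
#' randomized solver), deterministic up to component sign; signs are fixed
#' so the largest-magnitude loading of each component is positive.
#'
#' @param fm a standardized `kmer_matrix`.
#' @param n_components number of components to return.
#' @return list with `scores` (reads x `n_components`),
#'   `explained_var` (fractions, non-increasing), `loadings`, `d`
#'   (all singular values).
#' @export
pca_project <- function(fm, n_components = 2L) {
  if (fm$state != "standardized") stop("matrix must be standardized")
  x <- fm$values
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds matrix rank (", rank, ")")
  for (cmp in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, cmp]))
    if (sv$v[j, cmp] < 0) {
      sv$v[, cmp] <- -sv$v[, cmp]
      sv$u[, cmp] <- -sv$u[, cmp]
    }
  }
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(x)
  list(scores = scores,
       explained_var = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
       loadings = sv$v[, seq_len(n_components), drop = FALSE],
       d = sv$d)
}

#' Tile simulated reads along a (circular) clone sequence
#'
#' Samples reads of fixed length starting every `step` bases along a clone
#' sequence treated as circular (reads span the junction from the end of one
#' tandem copy to the start of the next), for overlaying onto a PCA
#' projection to reveal ring-like cluster topology.
#'
#' @param clone clone sequence (one tandem repeat unit).
#' @param read_len simulated read length in bp (at most twice the clone
#'   length).
#' @param step start-position spacing in bp.
#' @return a [sat_reads()]-compatible list with `id`, `seq`, `qual` and a
#'   `start` vector of 0-based start positions (mod clone length).
#' @export
tile_clone_reads <- function(clone, read_len, step = 10L) {
  L <- nchar(clone)
  if (L == 0L) stop("`clone` must be non-empty")
  if (step < 1) stop("`step` must be >= 1")
  if (read_len > 2 * L) stop("`read_len` must be at most twice the clone length")
  starts <- seq.int(0L, L - 1L, by = step)
  doubled <- paste0(clone, clone)
  seqs <- substring(doubled, starts + 1L, starts + read_len)
  ids <- sprintf("tile%05d", starts)
  res <- sat_reads(ids, seqs, lapply(nchar(seqs), function(n) rep(40L, n)))
  res$start <- starts
  res
}
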