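# Nearest reference row for each query row (exact, blockwise Euclidean).
nearest_reference <- function(query, ref, block = 1024L) {
  sqr <- rowSums(ref * ref)
  n <- nrow(query)
  idx <- integer(n)
  for (b0 in seq.int(1L, n, by = block)) {
    b1 <- min(b0 + block - 1L, n)
    rows <- b0:b1
    d2 <- outer(rowSums(query[rows, , drop = FALSE]^2), sqr, "+") -
      2 * tcrossprod(query[rows, , drop = FALSE], ref)
    idx[rows] <- max.col(-d2, ties.method = "first")
  }
  idx
}

#' Assign flow-sorted chromosome reads to subfamilies by nearest neighbor
#'
#' Each whole-chromosome shotgun (WCS) read inherits the subfamily label of
#' its single nearest reference read in the shared standardized feature
#' space (ties broken by smallest reference index). When `samples` is
#' given, per-sample subfamily counts are tabulated.
#'
#' @param wcs_fm `kmer_matrix` of WCS reads; row-normalized matrices are
#'   projected into the reference basis with [standardize_with()].
#' @param ref_fm standardized reference `kmer_matrix`.
#' @param ref_labels subfamily label per reference read.
#' @param samples optional sample id per WCS read.
#' @param n_screened optional named per-sample totals of satellite-screened
#'   reads (defaults to reads per sample in `wcs_fm`).
#' @return list with `labels` (per WCS read), `nn_index`, and when `samples`
#'   is given a `counts` object of class `count_table` (`y`: samples x
#'   subfamilies matrix; `n`: per-sample totals).
#' @export
assign_wcs_reads <- function(wcs_fm, ref_fm, ref_labels, samples = NULL,
                             n_screened = NULL) {
  if (wcs_fm$k != ref_fm$k) stop("k mismatch between matrices")
  if (ref_fm$state != "standardized") stop("`ref_fm` must be standardized")
  if (wcs_fm$state == "row_normalized")
    wcs_fm <- standardize_with(wcs_fm, ref_fm)
  stopifnot(length(ref_labels) == nrow(ref_fm$values))
  nn <- nearest_reference(wcs_fm$values, ref_fm$values)
  labels <- stats::setNames(as.character(ref_labels)[nn],
                            rownames(wcs_fm$values))
  out <- list(labels = labels, nn_index = nn)
  if (!is.null(samples)) {
    y <- table(sample = samples, subfamily = labels)
    y <- matrix(y, nrow = nrow(y), dimnames = dimnames(y))
    n <- if (is.null(n_screened))
      stats::setNames(as.integer(table(samples)[rownames(y)]), rownames(y))
    else n_screened[rownames(y)]
    if (any(rowSums(y) > n)) stop("per-sample counts exceed totals")
    out$counts <- structure(list(y = y, n = n), class = "count_table")
  }
  out
}

#' Estimate the WCS mixing matrix from unique-base coverage
#'
#' Each sample's per-chromosome coverage of uniquely mappable bases is
#' multiplied by the chromosome size (yielding the reads expected if the
#' whole chromosome were uniquely mappable) and row-normalized into
#' proportions of reads originating from each chromosome.
#'
#' @param coverage samples x chromosomes matrix of unique-base coverage.
#' @param chrom_sizes chromosome sizes in bp (named or in column order).
#' @return samples x chromosomes matrix with rows summing to 1.
#' @export
estimate_mixing_matrix <- function(coverage, chrom_sizes) {
  coverage <- as.matrix(coverage)
  if (any(coverage < 0)) stop("coverage must be non-negative")
  if (!is.null(names(chrom_sizes)) && !is.null(colnames(coverage)))
    chrom_sizes <- chrom_sizes[colnames(coverage)]
  x <- sweep(coverage, 2L, as.numeric(chrom_sizes), "*")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("uninformative sample(s) with all-zero coverage: ",
         paste(rownames(coverage)[rs == 0], collapse = ", "))
  x / rs
}

# Shortest interval containing `prob` of the sorted samples.
hpd_interval <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(prob * n)
  if (m >= n) return(c(xs[1], xs[n]))
  widths <- xs[m:n] - xs[1:(n - m + 1L)]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

# Split-half potential scale reduction factor across chains.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sample the chromosome-abundance posterior for one subfamily
#'
#' Bayesian binomial mixing model: for WCS sample `i`, the subfamily read
#' count is `y_i | beta ~ Binomial(n_i, X_i . beta)`, where `X_i` is the
#' sample's chromosome mixing vector and `beta_c` is the proportion of
#' chromosome `c` occupied by the subfamily. The prior is independent
#' truncated uniforms on `(1e-8, 0.5)` per chromosome (no subfamily may
#' occupy more than half a chromosome; the lower bound avoids degeneracy at
#' 0). Sampling is Metropolis-within-Gibbs with a per-chromosome random
#' walk on the logit scale, step sizes adapted during burn-in and frozen
#' afterwards. Draws are thinned so that exactly `retain` samples are kept,
#' spread evenly over the chains.
#'
#' @param y per-sample subfamily read counts.
#' @param n per-sample totals of screened reads.
#' @param X mixing matrix (samples x chromosomes, rows summing to 1).
#' @param chrom_sizes optional chromosome sizes (bp) for abundance
#'   estimates in bp.
#' @param prior lower and upper truncation bounds for each `beta_c`.
#' @param chains,iterations,burn_in,retain MCMC settings (defaults 4 chains
#'   of 16,000 iterations, 1,000 burn-in, 3,000 retained draws).
#' @param seed integer RNG seed.
#' @return an object of class `sat_posterior`: `samples` (retain x
#'   chromosomes), `median`, `hpd` (2 x chromosomes 95% bounds), `rhat`,
#'   `abundance_bp` (median and HPD times chromosome size, when sizes are
#'   given), `settings`, `accept_rate`.
#' @export
sample_beta_posterior <- function(y, n, X, chrom_sizes = NULL,
                                  prior = c(1e-8, 0.5), chains = 4L,
                                  iterations = 16000L, burn_in = 1000L,
                                  retain = 3000L, seed = 1L) {
  X <- as.matrix(X)
  S <- nrow(X); C <- ncol(X)
  stopifnot(length(y) == S, length(n) == S, all(y <= n))
  if (any(abs(rowSums(X) - 1) > 1e-6)) stop("rows of X must sum to 1")
  lo <- prior[1]; hi <- prior[2]
  per_chain <- diff(round(seq(0, retain, length.out = chains + 1L)))
  if (any(per_chain > iterations - burn_in))
    stop("not enough post-burn-in iterations to retain ", retain, " draws")
  loglik <- function(p) sum(dbinom(y, n, p, log = TRUE))
  all_draws <- vector("list", chains)
  acc_tot <- 0; acc_n <- 0
  with_seed(seed, {
    for (ch in seq_len(chains)) {
      m <- per_chain[ch]
      keep_at <- burn_in + round(seq(1, iterations - burn_in, length.out = m))
      beta <- runif(C, lo, hi)
      theta <- stats::qlogis((beta - lo) / (hi - lo))
      p <- as.numeric(X %*% beta)
      ll <- loglik(p)
      logJ <- log(beta - lo) + log(hi - beta)
      step <- rep(1, C)
      acc_win <- integer(C); win_n <- 0L
      draws <- matrix(NA_real_, m, C)
      ki <- 1L
      for (it in seq_len(iterations)) {
        for (cc in seq_len(C)) {
          th_new <- theta[cc] + rnorm(1L, 0, step[cc])
          b_new <- lo + (hi - lo) * stats::plogis(th_new)
          p_new <- p + X[, cc] * (b_new - beta[cc])
          ll_new <- loglik(p_new)
          lj_new <- log(b_new - lo) + log(hi - b_new)
          if (log(runif(1L)) < ll_new - ll + lj_new - logJ[cc]) {
            theta[cc] <- th_new; beta[cc] <- b_new
            p <- p_new; ll <- ll_new; logJ[cc] <- lj_new
            acc_win[cc] <- acc_win[cc] + 1L
            if (it > burn_in) acc_tot <- acc_tot + 1
          }
          if (it > burn_in) acc_n <- acc_n + 1
        }
        win_n <- win_n + 1L
        if (it <= burn_in && win_n == 50L) {
          rate <- acc_win / 50
          step <- pmin(pmax(step * exp(rate - 0.44), 1e-3), 50)
          acc_win[] <- 0L; win_n <- 0L
        }
        if (ki <= m && it == keep_at[ki]) {
          draws[ki, ] <- beta
          ki <- ki + 1L
        }
      }
      all_draws[[ch]] <- draws
    }
  })
  samples <- do.call(rbind, all_draws)
  colnames(samples) <- colnames(X)
  med <- apply(samples, 2L, median)
  hpd <- apply(samples, 2L, hpd_interval)
  rownames(hpd) <- c("lower", "upper")
  rhat <- vapply(seq_len(C), function(cc)
    split_rhat(lapply(all_draws, function(d) d[, cc])), 0)
  names(rhat) <- colnames(X)
  out <- list(samples = samples, median = med, hpd = hpd, rhat = rhat,
              converged = rhat <= 1.1,
              accept_rate = if (acc_n > 0) acc_tot / acc_n else NA_real_,
              settings = list(chains = chains, iterations = iterations,
                              burn_in = burn_in, retain = retain,
                              prior = prior, seed = seed))
  if (!is.null(chrom_sizes)) {
    cs <- as.numeric(chrom_sizes)
    out$abundance_bp <- rbind(median = med * cs, hpd * rep(cs, each = 2L))
  }
  structure(out, class = "sat_posterior")
}

#' @export
print.sat_posterior <- function(x, ...) {
  cat(sprintf("<sat_posterior> %d retained draws over %d chromosome(s)\n",
              nrow(x$samples), ncol(x$samples)))
  tab <- data.frame(median = signif(x$median, 4),
                    hpd_lower = signif(x$hpd["lower", ], 4),
                    hpd_upper = signif(x$hpd["upper", ], 4),
                    rhat = round(x$rhat, 3))
  print(tab)
  if (any(!x$converged))
    cat("warning: R-hat > 1.1 for ",
        paste(names(x$rhat)[!x$converged], collapse = ", "), "\n")
  invisible(x)
}

#' Localize an unmapped scaffold to chromosomes
#'
#' Poisson model for the WCS read counts hitting a scaffold's unique
#' 24-mers: under the hypothesis that the scaffold lies on chromosome `c`,
#' the count in sample `i` is Poisson with rate
#' `n_i * X_ic * U / L_c`, where `U` is the scaffold's count of uniquely
#' mappable non-repeat 24-mers and `L_c` the chromosome's mappable size.
#' With a uniform (or supplied) prior over chromosomes, the posterior is
#' normalized across chromosomes and all chromosomes reaching
#' `assign_prob` are called.
#'
#' @param counts per-sample scaffold read counts.
#' @param U number of unique scaffold 24-mers (>= 1).
#' @param X mixing matrix (samples x chromosomes).
#' @param n_total per-sample total read counts.
#' @param mappable_sizes per-chromosome mappable sizes in bp.
#' @param prior prior probability per chromosome (default uniform).
#' @param assign_prob posterior probability needed to assign (default 0.9).
#' @param scaffold_id optional identifier carried through.
#' @return an object of class `scaffold_call`: `posterior` (named,
#'   summing to 1), `assigned`, `U`, `scaffold_id`.
#' @export
localize_scaffold <- function(counts, U, X, n_total, mappable_sizes,
                              prior = NULL, assign_prob = 0.9,
                              scaffold_id = NA_character_) {
  if (U < 1) stop("`U` must be >= 1")
  X <- as.matrix(X)
  C <- ncol(X)
  stopifnot(length(counts) == nrow(X), length(n_total) == nrow(X),
            length(mappable_sizes) == C)
  if (is.null(prior)) prior <- rep(1 / C, C)
  ll <- vapply(seq_len(C), function(cc) {
    lam <- n_total * X[, cc] * U / mappable_sizes[cc]
    sum(dpois(counts, lam, log = TRUE))
  }, 0)
  lp <- ll + log(prior)
  if (all(!is.finite(lp))) {
    post <- rep(NA_real_, C)
  } else {
    lp <- lp - max(lp[is.finite(lp)])
    post <- exp(lp) / sum(exp(lp[is.finite(lp)]))
    post[!is.finite(post)] <- 0
  }
  names(post) <- colnames(X)
  assigned <- names(post)[!is.na(post) & post >= assign_prob]
  structure(list(scaffold_id = scaffold_id, posterior = post,
                 assigned = assigned, U = U, assign_prob = assign_prob),
            class = "scaffold_call")
}

#' @export
print.scaffold_call <- function(x, ...) {
  cat(sprintf("<scaffold_call> %s: assigned to [%s]\n",
              x$scaffold_id, paste(x$assigned, collapse = ", ")))
  print(round(x$posterior, 4))
  invisible(x)
}
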