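test_that("library hit counting enumerates HQ windows on both strands", {
  p <- size_params(rho = 0.5, G = 1e6)
  lib <- substr(strrep("ACGTT", 5), 1, 24)
  r100 <- reads_from_seqs(paste(rep("CA", 50), collapse = ""))
  expect_equal(count_library_hits(r100, lib, p), c(M = 0, T = 77))
  rhit <- reads_from_seqs(lib)
  expect_equal(count_library_hits(rhit, lib, p), c(M = 1, T = 1))
  rrc <- reads_from_seqs(revcomp(lib))
  expect_equal(count_library_hits(rrc, lib, p), c(M = 1, T = 1))
  # low-quality bases break windows
  q <- rep(40L, 100); q[50] <- 10L
  rq <- sat_reads("q", strrep("CA", 50), list(q))
  expect_equal(unname(count_library_hits(rq, lib, p)[["T"]]), 77 - 24)
})

test_that("the size estimator applies the printed formula", {
  p <- size_params(rho = 0.459, G = 5976710698)
  expect_equal(estimate_size(459, 1e5, p), 0.00459 / 0.459 * 5976710698)
  expect_equal(estimate_size(459, 1e5, p), 59767106.98, tolerance = 1e-9)
  expect_equal(estimate_size(0, 1e5, p), 0)
  expect_equal(estimate_size(918, 1e5, p), 2 * estimate_size(459, 1e5, p))
  expect_error(estimate_size(1, 0, p), "positive")
})

test_that("control sets are unique in the reference and AT-matched", {
  set.seed(31)
  reference <- paste(sample(c("A", "C", "G", "T"), 40000, TRUE),
                     collapse = "")
  # all-AT=16 target: every control has AT count 16
  target16 <- vapply(1:30, function(i)
    paste(sample(c(rep(c("A", "T"), 8), rep(c("G", "C"), 4))), collapse = ""),
    "")
  cs <- build_control_set(reference, target16, 40, seed = 32)
  expect_true(all(cs$at_count == 16))
  expect_length(cs$kmers, 40)
  for (km in cs$kmers[1:10])
    expect_equal(Biostrings::countPattern(km,
                                          Biostrings::DNAString(reference)), 1)
  # mixed-AT target: control histogram matches largest-remainder allocation
  target_mix <- c(rep(target16[1:10], 2),
                  vapply(1:10, function(i)
                    paste(sample(c(rep(c("A", "T"), 6),
                                   rep(c("G", "C"), 6))), collapse = ""), ""))
  cs2 <- build_control_set(reference, target_mix, 60, seed = 33)
  h <- tabulate(cs2$at_count + 1, 25)
  expect_equal(h[17], 40)  # 20/30 of target at AT 16
  expect_equal(h[13], 20)  # 10/30 at AT 12
  # duplicated k-mers are never eligible
  dup <- paste0(reference, substr(reference, 101, 200))
  csd <- build_control_set(dup, target16, 30, seed = 34)
  for (km in csd$kmers[1:10])
    expect_equal(Biostrings::countPattern(km, Biostrings::DNAString(dup)), 1)
  # exclusion intervals are honored
  excl <- data.frame(start = 0, end = 20000)
  cse <- build_control_set(reference, target16, 30,
                           exclusions = excl, seed = 35)
  expect_true(all(cse$start >= 20000 - 23))
  expect_true(all(cse$start + 24 > 20000))
})

test_that("control calibration corrects by the mean error and flags outliers", {
  K <- 100
  samples <- paste0("m", 1:4)
  raw <- stats::setNames(rep(2.1e7, 4), samples)
  p <- size_params(rho = 0.459, G = 1000)
  # every sample sees 5% more control hits than truth: est_c = 1.05 * K
  counts <- matrix(rep(c(rep(2, 5), rep(1, 95)), 4), K, 4,
                   dimnames = list(NULL, samples))  # colSums = 105
  T_total <- stats::setNames(rep(1000, 4), samples)
  est <- calibrate_and_correct(raw, counts, T_total,
                               control_set = NULL, params = p,
                               trim_frac = 0)
  expect_equal(attr(est, "mean_error"), 0.05)
  expect_equal(est$corrected_size, rep(2.1e7 / 1.05, 4))
  expect_false(any(est$excluded))
  # a sample with 40% control error is excluded
  counts2 <- counts
  counts2[, 2] <- c(rep(2, 40), rep(1, 60))  # colSum 140 -> est 140, err 0.4
  est2 <- calibrate_and_correct(raw, counts2, T_total, NULL, p,
                                trim_frac = 0)
  expect_true(est2$excluded[2])
  expect_false(any(est2$excluded[-2]))
  # trimming drops the extreme-coverage controls
  counts3 <- counts
  counts3[1, ] <- 50   # grossly over-covered control
  est3 <- calibrate_and_correct(raw, counts3, T_total, NULL, p,
                                trim_frac = 0.01)
  expect_equal(attr(est3, "n_controls_retained"), K - 2)
  # female filter
  fem <- matrix(0, K, 2); fem[7, 1] <- 11
  est4 <- calibrate_and_correct(raw, counts, T_total, NULL, p,
                                female_counts = fem, trim_frac = 0)
  expect_equal(attr(est4, "n_controls_retained"), K - 1)
})

test_that("coverage-bias correction moves estimates toward the truth", {
  truth <- 25e6
  set.seed(41)
  bias <- runif(6, 0.02, 0.12)           # per-sample AT-bias inflation
  raw <- stats::setNames(truth * (1 + bias), paste0("m", 1:6))
  K <- 200
  base <- rep(1, K)
  counts <- vapply(bias, function(b) {
    inflated <- base
    inflated[seq_len(round(K * b))] <- 2   # inflate ~b of control coverage
    inflated
  }, numeric(K))
  colnames(counts) <- names(raw)
  T_total <- stats::setNames(rep(K, 6), names(raw))
  est <- calibrate_and_correct(raw, counts, T_total, NULL,
                               size_params(rho = 1, G = K), trim_frac = 0)
  err_raw <- abs(raw - truth)
  err_cor <- abs(est$corrected_size - truth)
  # a single dataset-wide correction improves the estimates in aggregate
  expect_lt(mean(err_cor), mean(err_raw))
  expect_gt(mean(err_cor < err_raw), 0.5)
})

arraysize_bench <- function() bench_cached("arraysize", function() {
  b <- planted2_errorfree()
  fx <- list(b = b)
  truth <- b$truth[b$reads$id]
  sets <- list(SF1 = subset_reads(b$reads, which(truth == "SF1")),
               SF2 = subset_reads(b$reads, which(truth == "SF2")))
  fx$libs <- build_specific_library(sets, NULL)
  fx$rho <- compute_rho(sets$SF1, fx$libs$SF1)
  fx
})

test_that("the estimator is unbiased on error-free uniform coverage", {
  fx <- arraysize_bench()
  array_bp <- 100000; G <- 300000
  spec <- data.frame(chrom = "pop", pos = 100000, subfamily = "SF1",
                     length = array_bp)
  genome <- build_genome(spec, fx$b$units, background_length = G, seed = 950)
  p <- size_params(rho = fx$rho, G = G)
  ests <- vapply(1:10, function(s) {
    il <- sim_illumina_reads(genome, read_len = 100, coverage = 4,
                             config = sim_config(seed = 950 + s,
                                                 phred_high = 93L,
                                                 low_q_rate = 0))
    mt <- count_library_hits(il$reads, fx$libs$SF1, p)
    estimate_size(mt[["M"]], mt[["T"]], p)
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - array_bp), 3 * se + 0.005 * array_bp)
})

test_that("raw size estimates increase with planted array size", {
  fx <- arraysize_bench()
  G <- 400000
  p <- size_params(rho = fx$rho, G = G)
  ests <- vapply(c(50000, 100000, 150000), function(L) {
    spec <- data.frame(chrom = "pop", pos = 100000, subfamily = "SF1",
                       length = L)
    genome <- build_genome(spec, fx$b$units, background_length = G,
                           seed = 960)
    il <- sim_illumina_reads(genome, read_len = 100, coverage = 2,
                             config = sim_config(seed = 961, phred_high = 93L,
                                                 low_q_rate = 0))
    mt <- count_library_hits(il$reads, fx$libs$SF1, p)
    estimate_size(mt[["M"]], mt[["T"]], p)
  }, 0)
  expect_true(all(diff(ests) > 0))
})

test_that("group comparisons use the exact Wilcoxon test and Holm correction", {
  res <- haplogroup_compare(c(1, 2, 3, 4, 5, 6),
                            rep(c("g1", "g2"), each = 3), alpha = 0.05)
  expect_equal(res$pairs$p, 0.1)  # enumeration of C(6,3) rank assignments
  expect_equal(res$pairs$median_diff, -3)
  # identical groups are indistinguishable
  res2 <- haplogroup_compare(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))
  expect_gt(res2$pairs$p, 0.99)
  # Holm never lowers p-values; significance set shrinks
  set.seed(51)
  sizes <- c(rnorm(8, 10), rnorm(8, 14), rnorm(8, 10.5))
  groups <- rep(c("A", "B", "C"), each = 8)
  res3 <- haplogroup_compare(sizes, groups, alpha = 0.05)
  expect_true(all(res3$pairs$p_holm >= res3$pairs$p))
  expect_true(all(res3$pairs$p[res3$pairs$significant] < 0.05))
  # groups with < 2 members are summarized but not tested
  res4 <- haplogroup_compare(c(sizes, 12), c(groups, "D"), alpha = 0.05)
  expect_true("D" %in% res4$summary$group)
  expect_false("D" %in% c(res4$pairs$group1, res4$pairs$group2))
})

test_that("per-sample array-size tables parse and summarize", {
  set.seed(61)
  tab <- data.frame(id = sprintf("HG%05d", 1:40),
                    pop = rep(c("GBR", "CHB", "YRI", "FIN"), 10),
                    hap = rep(c("O", "E", "Q", "P"), each = 10),
                    hapfull = rep(c("O2b", "E1a", "Q1", "P1"), each = 10),
                    size = round(rlnorm(40, log(2.4e7), 0.4)))
  f <- tempfile(fileext = ".txt")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_array_size_table(f)
  expect_equal(nrow(parsed), 40)
  expect_true(all(parsed$haplogroup %in% c("O", "E", "Q/P")))
  stats <- array_size_population_stats(parsed, focus_pair = c("O", "E"),
                                       alpha = 0.05)
  expect_equal(stats$mean_size_bp, mean(tab$size))
  expect_equal(unname(stats$group_means_mb[["Q/P"]]),
               mean(tab$size[tab$hap %in% c("Q", "P")]) / 1e6)
  oe <- suppressWarnings(wilcox.test(tab$size[tab$hap == "O"],
                                     tab$size[tab$hap == "E"]))
  expect_equal(stats$focus_p, oe$p.value)
})
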