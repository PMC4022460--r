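test_that("subfamily units follow the pentamer-ancestor mutation model", {
  expect_equal(unname(gen_subfamily_units(1, 10, 0)), "CATTCCATTC")
  u <- gen_subfamily_units(1, 5000, 0.1, seed = 7)
  anc <- strsplit(strrep("CATTC", 1000), "")[[1]]
  frac <- mean(strsplit(u[[1]], "")[[1]] == anc)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 5000))
  u2 <- gen_subfamily_units(2, 1770, 0.2, seed = 11)
  expect_false(u2[[1]] == u2[[2]])
  expect_error(gen_subfamily_units(1, 10, 0.8), "divergence")
  expect_error(gen_subfamily_units(1, 7, 0.1), "multiple of 5")
})

test_that("planted arrays are recorded faithfully in the genome truth", {
  units <- gen_subfamily_units(1, 1770, 0.1, seed = 3)
  spec <- data.frame(chrom = "c1", pos = 40000, subfamily = "SF1",
                     length = 100000)
  g <- build_genome(spec, units, background_length = 200000, seed = 4)
  expect_equal(unname(g$truth$true_array_bp[["SF1"]]), 100000)
  expect_equal(sum(g$truth$true_array_bp),
               sum(g$truth$arrays$end - g$truth$arrays$start))
  # perfect tandem when array length is an exact multiple of the unit
  spec3 <- data.frame(chrom = "c1", pos = 1000, subfamily = "SF1",
                      length = 3 * 1770)
  g3 <- build_genome(spec3, units, background_length = 40000, seed = 5)
  expect_equal(substr(g3$chromosomes[["c1"]], 1001, 1000 + 3 * 1770),
               strrep(units[[1]], 3))
  # overlapping arrays are a specification error
  bad <- data.frame(chrom = "c1", pos = c(100, 1500), subfamily = "SF1",
                    length = c(2000, 2000))
  expect_error(build_genome(bad, units, background_length = 40000),
               "overlap")
})

test_that("diverged subfamilies separate in 5-mer space within the genome", {
  units <- gen_subfamily_units(2, 1770, 0.3, seed = 21)
  spec <- data.frame(chrom = c("c1", "c2"), pos = 1000,
                     subfamily = names(units), length = 35400)
  g <- build_genome(spec, units, background_length = 40000, seed = 22)
  chunk <- function(chrom, from, n, size = 2000)
    substring(g$chromosomes[[chrom]], from + size * (seq_len(n) - 1) + 1,
              from + size * seq_len(n))
  a <- chunk("c1", 1000, 10); b <- chunk("c2", 1000, 10)
  fm <- kmer_feature_matrix(reads_from_seqs(c(a, b)))$values
  d <- as.matrix(dist(fm))
  within <- mean(c(d[1:10, 1:10][upper.tri(diag(10))],
                   d[11:20, 11:20][upper.tri(diag(10))]))
  between <- mean(d[1:10, 11:20])
  expect_gt(between, within)
})

sanger_fixture <- function() bench_cached("sanger_1mb", function() {
  units <- gen_subfamily_units(1, 1000, 0.1, seed = 31)
  spec <- data.frame(chrom = "c1", pos = 200000, subfamily = "SF1",
                     length = 50000)
  g <- build_genome(spec, units, background_length = 1e6, seed = 32)
  list(genome = g, sim = sim_sanger_pairs(g, sim_config(seed = 33)))
})

test_that("paired-read counts follow the coverage identity", {
  fx <- sanger_fixture()
  sim <- fx$sim
  # each clone contributes either a complete pair or one unpaired read
  n_clones <- nrow(sim$pairs) + sum(is.na(sim$reads$mate))
  expect_lt(abs(n_clones - 7.8e6 / (2 * 877)) / (7.8e6 / (2 * 877)), 0.05)
  # roughly the configured fraction of reads has a mate
  expect_lt(abs(mean(!is.na(sim$reads$mate)) - 0.65), 0.05)
})

test_that("read origins are consistent with the genome", {
  fx <- sanger_fixture()
  org <- fx$sim$origins
  lens <- nchar(fx$genome$chromosomes)
  expect_true(all(org$start >= 0))
  expect_true(all(org$end <= lens[org$chrom]))
  # with an error-free quality model, reads reproduce their source interval
  units <- gen_subfamily_units(1, 1000, 0.1, seed = 41)
  spec <- data.frame(chrom = "c1", pos = 50000, subfamily = "SF1",
                     length = 20000)
  g <- build_genome(spec, units, background_length = 200000, seed = 42)
  sim <- sim_sanger_pairs(g, sim_config(seed = 43, coverage = 0.5,
                                        phred_high = 93L, low_q_rate = 0))
  org <- sim$origins[match(sim$reads$id, sim$origins$read_id), ]
  src <- substring(g$chromosomes[org$chrom], org$start + 1, org$end)
  src[org$strand == "-"] <- revcomp(src[org$strand == "-"])
  expect_identical(sim$reads$seq, src)
})

test_that("simulation is deterministic under a fixed seed", {
  units <- gen_subfamily_units(1, 1000, 0.1, seed = 51)
  spec <- data.frame(chrom = "c1", pos = 30000, subfamily = "SF1",
                     length = 20000)
  g <- build_genome(spec, units, background_length = 100000, seed = 52)
  cfg <- sim_config(seed = 53, coverage = 1)
  s1 <- sim_sanger_pairs(g, cfg)
  s2 <- sim_sanger_pairs(g, cfg)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  w1 <- sim_wcs_sample(g, c(1), 200, cfg)
  w2 <- sim_wcs_sample(g, c(1), 200, cfg)
  expect_identical(w1$reads$seq, w2$reads$seq)
})

test_that("FASTQ round-trips through Biostrings", {
  fx <- sanger_fixture()
  sub <- subset_reads(fx$sim$reads, 1:20)
  f <- tempfile(fileext = ".fastq")
  write_fastq(sub, f)
  back <- read_fastq(f)
  expect_identical(back$seq, sub$seq)
  expect_identical(back$qual, sub$qual)
})

test_that("flow-sorted samples draw chromosomes from the mixing vector", {
  units <- gen_subfamily_units(2, 1000, 0.2, seed = 61)
  spec <- data.frame(chrom = c("c1", "c2"), pos = 30000,
                     subfamily = names(units), length = 20000)
  g <- build_genome(spec, units, background_length = 100000, seed = 62)
  pure <- sim_wcs_sample(g, c(c1 = 1, c2 = 0), 500, sim_config(seed = 63))
  expect_true(all(pure$origins$chrom == "c1"))
  mix <- sim_wcs_sample(g, c(c1 = 0.8, c2 = 0.2), 10000, sim_config(seed = 64))
  frac <- mean(mix$origins$chrom == "c1")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_error(sim_wcs_sample(g, c(c1 = 1.2, c2 = -0.2), 10), "non-negative")
})

test_that("short-read simulation honors length, count and uniformity", {
  units <- gen_subfamily_units(1, 1000, 0.1, seed = 71)
  spec <- data.frame(chrom = "c1", pos = 40000, subfamily = "SF1",
                     length = 20000)
  g <- build_genome(spec, units, background_length = 100000, seed = 72)
  il <- sim_illumina_reads(g, read_len = 100, coverage = 4,
                           config = sim_config(seed = 73))
  expect_equal(length(il$reads$id), 4000)
  expect_true(all(nchar(il$reads$seq) == 100))
  il2 <- sim_illumina_reads(g, read_len = 100, coverage = 50,
                            config = sim_config(seed = 74))
  h <- table(cut(il2$origins$start, breaks = seq(0, 100000 - 100,
                                                 length.out = 21),
                 include.lowest = TRUE))
  expect_gt(chisq.test(h)$p.value, 0.001)
})

test_that("surrogate annotator marks satellite intervals and skips background", {
  pure <- reads_from_seqs(strrep("CATTC", 40), ids = "pure")
  ann <- surrogate_annotate(pure)
  expect_equal(nrow(ann[["pure"]]), 1)
  expect_equal(ann[["pure"]]$start, 0)
  expect_equal(ann[["pure"]]$end, 200)
  clean <- reads_from_seqs(strrep("AC", 100), ids = "clean")
  expect_length(surrogate_annotate(clean), 0)
  # satellite segment flanked by pentamer-free sequence
  mixed <- reads_from_seqs(paste0(strrep("CA", 50), strrep("CATTC", 40),
                                  strrep("GT", 50)), ids = "mix")
  annm <- surrogate_annotate(mixed, window = 100)
  expect_equal(nrow(annm[["mix"]]), 1)
  expect_lt(abs(annm[["mix"]]$start - 100), 100)
  expect_lt(abs(annm[["mix"]]$end - 300), 100)
  # reverse-complement arrays are annotated on the minus strand
  rcread <- reads_from_seqs(strrep("GAATG", 40), ids = "rc")
  annrc <- surrogate_annotate(rcread)
  expect_equal(annrc[["rc"]]$strand, "-")
  expect_error(surrogate_annotate(pure, window = 4), "window")
})

test_that("pentamer coverage density separates diverged satellite from background", {
  covfrac <- function(s) {
    L <- nchar(s)
    cov <- logical(L)
    for (p in c("CATTC", "GAATG")) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      if (m[1] != -1) for (st in m) cov[st:(st + 4)] <- TRUE
    }
    mean(cov)
  }
  d10 <- covfrac(gen_subfamily_units(1, 50000, 0.10, seed = 142)[[1]])
  d25 <- covfrac(gen_subfamily_units(1, 50000, 0.25, seed = 167)[[1]])
  d30 <- covfrac(gen_subfamily_units(1, 50000, 0.30, seed = 172)[[1]])
  set.seed(1)
  bg <- covfrac(paste(sample(c("A", "C", "G", "T"), 50000, TRUE),
                      collapse = ""))
  # the regimes the annotator's default density threshold (0.15) separates
  expect_equal(d10, 0.59, tolerance = 0.05)
  expect_equal(d25, 0.24, tolerance = 0.1)
  expect_equal(d30, 0.18, tolerance = 0.1)
  expect_lt(bg, 0.02)
  expect_gt(min(d10, d25, d30), 0.15)
  expect_lt(bg, 0.15)
})

test_that("surrogate annotations survive the RepeatMasker .out round trip", {
  fx <- sanger_fixture()
  sub <- subset_reads(fx$sim$reads, 1:300)
  ann <- surrogate_annotate(sub)
  f <- tempfile(fileext = ".out")
  write_repeatmasker_out(ann, sub, f)
  back <- parse_repeatmasker_out(f)
  expect_setequal(names(back), names(ann))
  for (id in names(ann)) {
    expect_equal(back[[id]]$start, ann[[id]]$start)
    expect_equal(back[[id]]$end, ann[[id]]$end)
    expect_equal(back[[id]]$strand, ann[[id]]$strand)
    expect_equal(back[[id]]$name, ann[[id]]$name)
  }
})
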