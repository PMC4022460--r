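# Shared planted-subfamily fixtures, built once per test run and cached.

.bench_env <- new.env(parent = emptyenv())

bench_cached <- function(name, builder) {
  if (is.null(.bench_env[[name]])) .bench_env[[name]] <- builder()
  .bench_env[[name]]
}

# Truth subfamily label per read id: a read belongs to an array if at least
# `min_overlap` of its source interval lies inside it.
truth_labels <- function(origins, arrays, min_overlap = 75L) {
  lab <- rep(NA_character_, nrow(origins))
  for (r in seq_len(nrow(arrays))) {
    ov <- origins$chrom == arrays$chrom[r] &
      pmin(origins$end, arrays$end[r]) -
        pmax(origins$start, arrays$start[r]) >= min_overlap
    lab[ov] <- arrays$subfamily[r]
  }
  stats::setNames(lab, origins$read_id)
}

# Planted multi-subfamily pipeline: genome -> paired reads -> surrogate
# annotation -> masked reads -> standardized features.
build_planted <- function(n_subfamilies = 2, divergence = 0.3,
                          unit_length = 1770, array_length = 120000,
                          flank = 30000, coverage = 3, seed = 400,
                          units = NULL, config = NULL) {
  if (is.null(units))
    units <- gen_subfamily_units(n_subfamilies, unit_length, divergence,
                                 seed = seed)
  spec <- data.frame(chrom = paste0("chr", seq_along(units)), pos = flank,
                     subfamily = names(units), length = array_length)
  genome <- build_genome(spec, units,
                         background_length = array_length + 2 * flank,
                         seed = seed + 1)
  if (is.null(config)) config <- sim_config(seed = seed + 2, coverage = coverage)
  sim <- sim_sanger_pairs(genome, config)
  ann <- surrogate_annotate(sim$reads)
  masked <- suppressWarnings(preprocess_reads(sim$reads, ann))
  od <- orient_and_dedupe(masked, sim$pairs)
  fm <- standardize_matrix(kmer_feature_matrix(od$reads, k = 5))
  list(units = units, genome = genome, sim = sim, ann = ann, masked = masked,
       reads = od$reads, pairs = od$pairs, fm = fm,
       truth = truth_labels(sim$origins, genome$truth$arrays))
}

# Two subfamilies at divergence 0.3 — the workhorse fixture.
planted2 <- function() bench_cached("planted2", function() build_planted())

# Same, with error-free sequencing (quality model at phred 93, no low-quality
# bases) for estimator-exactness checks.
planted2_errorfree <- function() bench_cached("planted2_ef", function()
  build_planted(seed = 500,
                config = sim_config(seed = 502, coverage = 3,
                                    phred_high = 93L, low_q_rate = 0)))

# Apply further i.i.d. substitution to a unit (for hierarchically diverged
# subfamily fixtures); independent of the package's generator internals.
mutate_unit <- function(unit, divergence, seed) {
  set.seed(seed)
  b <- strsplit(unit, "")[[1]]
  bases <- c("A", "C", "G", "T")
  hit <- runif(length(b)) < divergence
  idx <- match(b[hit], bases)
  b[hit] <- bases[((idx - 1L + sample.int(3L, sum(hit), TRUE)) %% 4L) + 1L]
  paste(b, collapse = "")
}

# Plain read-set constructors for crafted fixtures.
reads_from_seqs <- function(seqs, phred = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  sat_reads(ids, seqs, lapply(nchar(seqs), function(n) rep(phred, n)))
}

# Independent normalized-cut computation (naive loop over edges).
naive_ncut <- function(edges, deg, inA) {
  cut <- 0
  for (r in seq_len(nrow(edges))) {
    if (xor(inA[edges$i[r]], inA[edges$j[r]])) cut <- cut + edges$weight[r]
  }
  volA <- sum(deg[inA]); volB <- sum(deg[!inA])
  if (volA == 0 || volB == 0) return(Inf)
  cut / volA + cut / volB
}

# Hand-assembled read_graph for small exact cases.
make_graph <- function(n, edges) {
  structure(list(ids = paste0("v", seq_len(n)), n = n, k_nn = 1L,
                 d_max = NA_real_, edges = edges),
            class = "read_graph")
}

graph_degrees <- function(g) {
  deg <- numeric(g$n)
  for (r in seq_len(nrow(g$edges))) {
    deg[g$edges$i[r]] <- deg[g$edges$i[r]] + g$edges$weight[r]
    deg[g$edges$j[r]] <- deg[g$edges$j[r]] + g$edges$weight[r]
  }
  deg
}

# Subfamily read sets, a non-satellite sample and the specific 24-mer
# libraries for the planted2 fixture.
planted2_library_fixture <- function() bench_cached("planted2_libs", function() {
  b <- planted2()
  truth <- b$truth[b$reads$id]
  sets <- list(SF1 = subset_reads(b$reads, which(truth == "SF1")),
               SF2 = subset_reads(b$reads, which(truth == "SF2")))
  nonsat_ids <- b$masked$rejected$read_id[
    b$masked$rejected$reason == "no_annotation"]
  nonsat <- subset_reads(b$sim$reads, utils::head(nonsat_ids, 150))
  list(sets = sets, nonsat = nonsat,
       libs = build_specific_library(sets, nonsat))
})

# Best label agreement between a 2-cluster assignment and truth.
two_cluster_agreement <- function(pred, truth) {
  pred <- as.integer(factor(pred)); truth <- as.integer(factor(truth))
  max(mean(pred == truth), mean(3L - pred == truth))
}
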