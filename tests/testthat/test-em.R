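test_that("effective start positions sum over contigs with clamping", {
  expect_equal(effective_start_positions(1000, 10000), 9000)
  expect_equal(effective_start_positions(1000, c(5000, 3000)), 6000)
  expect_equal(effective_start_positions(1000, 800), 1)
  expect_equal(effective_start_positions(1000, c(5000, 800)), 4001)
})

test_that("read likelihood and posterior match manual arithmetic", {
  # 3-read, 2-genome toy table, worked by hand
  F_vec <- c(gA = 0.8, gB = 0.2)
  r1 <- data.frame(genome_id = c("gA", "gB"),
                   mapping_quality = c(0.7, 0.3),
                   eff_starts = c(9000, 4000))
  manual <- 0.7 / 9000 * 0.8 + 0.3 / 4000 * 0.2
  expect_equal(read_likelihood(r1, F_vec), manual, tolerance = 1e-15)
  post <- composition_posterior(r1, F_vec)
  expect_equal(post, c(0.7 / 9000 * 0.8, 0.3 / 4000 * 0.2) / manual)
  expect_equal(sum(post), 1)

  # single candidate and F_g = 1: likelihood reduces to 1/E
  r2 <- data.frame(genome_id = "gA", mapping_quality = 1,
                   eff_starts = 5000)
  expect_equal(read_likelihood(r2, c(gA = 1)), 1 / 5000)
  expect_equal(composition_posterior(r2, c(gA = 1)), 1)

  # equal quality and E: posteriors reproduce F
  r3 <- data.frame(genome_id = c("gA", "gB"),
                   mapping_quality = c(0.5, 0.5),
                   eff_starts = c(1000, 1000))
  expect_equal(composition_posterior(r3, F_vec), c(0.8, 0.2))

  # degenerate: all candidate genomes at zero mass -> uniform + warning
  expect_warning(p0 <- composition_posterior(r3, c(gA = 0, gB = 0)),
                 "degenerate")
  expect_equal(p0, c(0.5, 0.5))
})

test_that("EM update has the documented fixed points", {
  # all reads unique to one genome -> indicator, a fixed point
  cands <- data.table::data.table(
    read_id = c("r1", "r2", "r3"), genome_id = "gA",
    mapping_quality = 1, eff_starts = 1000)
  F0 <- c(gA = 0.5, gB = 0.5)
  F1 <- em_update(cands, F0)
  expect_equal(F1, c(gA = 1, gB = 0))
  expect_equal(em_update(cands, F1), F1)

  # reads split 50/50 across two genomes under uniform F stay uniform
  cands2 <- data.table::data.table(
    read_id = rep(c("r1", "r2"), each = 2),
    genome_id = rep(c("gA", "gB"), 2),
    mapping_quality = 0.5, eff_starts = 1000)
  expect_equal(em_update(cands2, F0), c(gA = 0.5, gB = 0.5))
})

test_that("EM is monotone, normalized and conservative on random instances", {
  for (seed in 1:50) {
    set.seed(seed)
    n_reads <- sample(5:25, 1)
    n_gen <- sample(2:6, 1)
    genomes <- paste0("g", seq_len(n_gen))
    cands <- data.table::rbindlist(lapply(seq_len(n_reads), function(r) {
      k <- sample(seq_len(min(3L, n_gen)), 1)
      g <- sample(genomes, k)
      q <- runif(k); q <- q / sum(q)
      data.table::data.table(read_id = paste0("r", r), genome_id = g,
                             mapping_quality = q,
                             eff_starts = sample(500:20000, k))
    }))
    fit <- run_em(cands, genome_contigs =
                    setNames(as.list(sample(5000:50000, n_gen)), genomes))
    # log-likelihood non-decreasing (1e-9 slack)
    expect_true(all(diff(fit$loglik) >= -1e-9))
    # per-read posterior normalization
    sums <- fit$candidates[, sum(posterior), by = read_id]$V1
    expect_true(all(abs(sums - 1) < 1e-9))
    # composition over genomes sums to 1
    expect_equal(sum(fit$F), 1, tolerance = 1e-9)
  }
})

test_that("EM recovers a two-genome mixture and splits identical twins", {
  db <- simulate_genomes(2, genome_length = 40000, divergence = 0.1,
                         n_species = 2, seed = 51)
  sim <- simulate_reads(db, abundances = c(g01 = 0.7, g02 = 0.3),
                        n_reads = 200, length_mean = 3000,
                        accuracy = 0.88, seed = 52)
  idx <- build_index(db$sequences)
  mp <- map_reads(sim$reads, idx)
  fit <- run_em(mp, index_contig_lengths(idx))
  truth <- prop.table(table(sim$truth$genome_id))
  expect_lt(abs(fit$F[["g01"]] - truth[["g01"]]), 0.02)

  # identical twin genomes: strain-level split unidentifiable (~50/50),
  # species-level sum correct
  twin <- simulate_genomes(2, genome_length = 40000, divergence = 0,
                           n_species = 1, seed = 53)
  sim2 <- simulate_reads(twin$sequences[1], n_reads = 80,
                         length_mean = 3000, accuracy = 0.9, seed = 54)
  idx2 <- build_index(twin$sequences)
  mp2 <- map_reads(sim2$reads, idx2)
  fit2 <- run_em(mp2, index_contig_lengths(idx2))
  expect_equal(unname(fit2$F[["g01"]] + fit2$F[["g02"]]), 1,
               tolerance = 1e-9)
  expect_lt(abs(fit2$F[["g01"]] - 0.5), 0.05)
})

test_that("finalization adds the unassigned bin and is deterministic", {
  comm <- small_community()
  fit <- run_em(comm$mp, index_contig_lengths(comm$idx))
  res <- finalize_composition(fit, comm$mp, comm$db$taxonomy)
  n_unassigned <- sum(comm$mp$reads$status != "mapped")
  expect_equal(res$unassigned_fraction, n_unassigned / nrow(comm$mp$reads))
  expect_equal(sum(res$composition$fraction) + res$unassigned_fraction, 1,
               tolerance = 1e-9)
  # every mapped read gets exactly one assignment with a strain taxon
  expect_equal(nrow(res$assignments), sum(comm$mp$reads$status == "mapped"))
  expect_true(all(res$assignments$taxon_id %in%
                    comm$db$taxonomy$nodes$taxon_id))
  # deterministic across repeated finalization
  res2 <- finalize_composition(fit, comm$mp, comm$db$taxonomy)
  expect_identical(res$assignments$genome_id, res2$assignments$genome_id)
  expect_identical(res$assignments$start, res2$assignments$start)

  # long-reads denominator excludes sub-length reads
  resL <- finalize_composition(fit, comm$mp, comm$db$taxonomy,
                               denominator = "long-reads")
  expect_equal(sum(resL$composition$fraction) + resL$unassigned_fraction, 1,
               tolerance = 1e-9)
  expect_equal(resL$n_total,
               sum(comm$mp$reads$status != "too_short"))
})

test_that("read order does not change EM results", {
  comm <- small_community()
  fit <- run_em(comm$mp, index_contig_lengths(comm$idx))
  mp_rev <- comm$mp
  mp_rev$candidates <- comm$mp$candidates[rev(seq_len(.N))]
  fit_rev <- run_em(mp_rev, index_contig_lengths(comm$idx))
  expect_equal(fit$F, fit_rev$F, tolerance = 1e-12)
  expect_equal(tail(fit$loglik, 1), tail(fit_rev$loglik, 1),
               tolerance = 1e-12)
})

test_that("composition projects to levels by taxon buckets", {
  comm <- small_community()
  fit <- run_em(comm$mp, index_contig_lengths(comm$idx))
  res <- finalize_composition(fit, comm$mp, comm$db$taxonomy)
  for (l in c("strain", "species", "genus", "family")) {
    pr <- project_composition(res, comm$db$taxonomy, l)
    expect_equal(sum(pr$fraction), 1, tolerance = 1e-9)
    # brute-force groupby of strain masses
    tax <- comm$db$taxonomy
    ref <- data.table::data.table(
      taxon_id = to_level(tax, taxon_of_genome(tax,
        res$composition$genome_id), l),
      fraction = res$composition$fraction)[, .(fraction = sum(fraction)),
                                           by = taxon_id]
    for (i in seq_len(nrow(ref))) {
      if (ref$taxon_id[i] == 0L) next
      expect_equal(pr[taxon_id == ref$taxon_id[i], fraction],
                   ref$fraction[i], tolerance = 1e-12)
    }
  }
  # two strains of one species sum their masses
  tax <- toy_taxonomy()
  comp <- structure(list(
    composition = data.table::data.table(
      genome_id = c("g_a", "g_b", "g_c"),
      fraction = c(0.5, 0.3, 0.2), read_count = c(5L, 3L, 2L)),
    unassigned_fraction = 0, n_total = 10L, n_mapped = 10L),
    class = "sample_composition")
  pr <- project_composition(comp, tax, "species")
  expect_equal(pr[taxon_id == 31L, fraction], 0.5)
  expect_equal(pr[taxon_id == 30L, fraction], 0.5)
})

test_that("median-identity filter moves mass to the unassigned bin", {
  tax <- toy_taxonomy()
  comp <- structure(list(
    composition = data.table::data.table(
      genome_id = c("g_a", "g_b"), fraction = c(0.6, 0.3),
      read_count = c(6L, 3L)),
    unassigned_fraction = 0.1,
    assignments = data.table::data.table(
      read_id = paste0("r", 1:9),
      genome_id = rep(c("g_a", "g_b"), c(6, 3)),
      identity_hat = c(rep(0.9, 6), rep(0.75, 3))),
    n_total = 10L, n_mapped = 9L),
    class = "sample_composition")
  filt <- filter_composition_by_identity(comp, threshold = 0.8)
  expect_equal(filt$composition[genome_id == "g_b", fraction], 0)
  expect_equal(filt$unassigned_fraction, 0.4)
  expect_equal(sum(filt$composition$fraction) + filt$unassigned_fraction, 1)
  # removed mass is gone at every projected level too
  pr <- project_composition(filt, tax, "species")
  expect_equal(pr[taxon_id == 31L, fraction], 0)
  expect_equal(pr[taxon_id == 0L, fraction], 0.4)
  # thresholds at/below all medians are no-ops
  expect_equal(filter_composition_by_identity(comp, threshold = 0)$composition,
               comp$composition)
})
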