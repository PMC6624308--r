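test_that("expected k-mer matches follow the closed form", {
  # 1000 bp read at 15% uniform error shares ~73 exact 16-mers with its
  # source locus
  expect_equal(round(expected_kmer_matches(1000, 16, 0.15)), 73)
  expect_equal(expected_kmer_matches(16, 16, 0), 1)
  expect_equal(expected_kmer_matches(100, 10, 0.05), 91 * 0.95^10,
               tolerance = 1e-12)
  expect_error(expected_kmer_matches(10, 16, 0.1))
})

test_that("sketch Jaccard matches hand enumeration on explicit sets", {
  a <- c(3, 8, 15, 21, 30, 42, 55, 61, 70, 88)
  b <- c(2, 8, 9, 21, 33, 42, 57, 61, 72, 90)
  s <- 6
  # brute-force oracle: s smallest of the union, count members in both
  u <- sort(unique(c(a, b)))[1:s]            # 2 3 8 9 15 21
  shared <- sum(u %in% a & u %in% b)         # 8, 21
  got <- jaccard_estimate(a, b, s)
  expect_equal(got$n_union, s)
  expect_equal(got$n_shared, shared)
  expect_equal(got$jaccard_hat, shared / s)

  expect_equal(jaccard_estimate(a, a)$jaccard_hat, 1)
  expect_equal(jaccard_estimate(a, b + 1000)$n_shared, 0)
  expect_error(jaccard_estimate(numeric(0), numeric(0)), "empty")
})

test_that("identity estimator inverts the Jaccard relation", {
  expect_equal(identity_from_jaccard(1, 16), 1)
  expect_equal(identity_from_jaccard(0, 16), 0)
  expect_equal(identity_from_jaccard(0.2, 16), (1 / 3)^(1 / 16),
               tolerance = 1e-12)
  # strictly increasing in J, decreasing in k
  j <- seq(0.01, 0.99, by = 0.01)
  v <- identity_from_jaccard(j, 16)
  expect_true(all(diff(v) > 0))
  expect_true(all(identity_from_jaccard(0.3, c(12, 16, 20)) ==
                    sort(identity_from_jaccard(0.3, c(12, 16, 20)),
                         decreasing = TRUE)))
})

test_that("mapping qualities equal normalized binomial probabilities", {
  cands <- data.table::data.table(
    n_union = c(50L, 50L, 50L), n_shared = c(40L, 35L, 30L))
  e <- 0.12; k <- 16
  got <- mapping_quality(data.table::copy(cands), e, k)
  p <- (1 - e)^k
  ref <- dbinom(cands$n_shared, cands$n_union, p)
  expect_equal(got$mapping_quality, ref / sum(ref), tolerance = 1e-12)
  expect_equal(sum(got$mapping_quality), 1, tolerance = 1e-9)

  # single candidate -> 1; symmetric candidates -> 0.5 each
  one <- mapping_quality(data.table::data.table(n_union = 80L,
                                                n_shared = 12L), 0.1, 16)
  expect_equal(one$mapping_quality, 1)
  two <- mapping_quality(data.table::data.table(n_union = c(60L, 60L),
                                                n_shared = c(9L, 9L)),
                         0.15, 16)
  expect_equal(two$mapping_quality, c(0.5, 0.5))

  # extreme counts underflow the PMF; log-space normalization still sums to 1
  big <- mapping_quality(data.table::data.table(
    n_union = c(5000L, 5000L), n_shared = c(4999L, 4500L)), 0.3, 16)
  expect_equal(sum(big$mapping_quality), 1, tolerance = 1e-9)
  expect_true(all(is.finite(big$mapping_quality)))
})

test_that("exact substrings map back to their source interval", {
  set.seed(21)
  g <- random_dna(30000)
  contigs <- Biostrings::DNAStringSet(g)
  names(contigs) <- "c1 genome=g1"
  idx <- build_index(contigs)
  w <- idx$params$window_size
  for (start in c(0L, 12000L, 28000L)) {
    len <- min(2000L, 30000L - start)
    if (len < 1000L) next
    read <- substr(g, start + 1, start + len)
    cand <- candidate_locations(read, idx)
    expect_gte(nrow(cand), 1L)
    best <- cand[which.max(n_shared)]
    expect_equal(best$strand, "+")
    expect_lte(abs(best$start - start), w)
    expect_equal(best$identity_hat, 1)
  }
  # reverse-strand read
  read <- revcomp(substr(g, 5001, 7000))
  cand <- candidate_locations(read, idx)
  best <- cand[which.max(n_shared)]
  expect_equal(best$strand, "-")
  expect_lte(abs(best$start - 5000), w)
  # random read absent from the reference -> no candidate
  alien <- random_dna(2000)
  expect_equal(nrow(candidate_locations(alien, idx)), 0L)
})

test_that("low-identity filtering keeps exactly the passing candidates", {
  cands <- data.table::data.table(identity_hat = c(0.95, 0.80, 0.79, 0.5))
  expect_equal(nrow(filter_low_identity(cands, 0.8)), 2L)
  expect_equal(filter_low_identity(cands, 0), cands)
  expect_equal(nrow(filter_low_identity(cands[0], 0.8)), 0L)
})

test_that("estimated identity is calibrated to the simulated accuracy", {
  set.seed(31)
  g <- Biostrings::DNAStringSet(random_dna(200000))
  names(g) <- "c1 genome=g1"
  idx <- build_index(g)
  for (e in c(0.05, 0.12, 0.15)) {
    sim <- simulate_reads(g, n_reads = 60, length_mean = 4000,
                          accuracy = 1 - e, seed = 100 + round(1000 * e))
    mp <- map_reads(sim$reads, idx)
    best <- mp$candidates[, max(identity_hat), by = read_id]$V1
    expect_lt(abs(median(best) - (1 - e)), 0.02)
  }
})

test_that("mapping qualities per read always sum to one", {
  comm <- small_community()
  sums <- comm$mp$candidates[, sum(mapping_quality), by = read_id]$V1
  expect_true(all(abs(sums - 1) < 1e-9))
  # error estimate equals 1 - best identity for every mapped read
  best <- comm$mp$candidates[, max(identity_hat), by = read_id]
  ei <- comm$mp$reads[match(best$read_id, read_id), e]
  expect_equal(ei, pmax(0, 1 - best$V1), tolerance = 1e-12)
})

test_that("candidate generation finds the true source for divergent genomes", {
  db <- simulate_genomes(10, genome_length = 30000, divergence = 0.1,
                         n_species = 10, seed = 17)
  sim <- simulate_reads(db, n_reads = 120, length_mean = 3000,
                        accuracy = 0.88, seed = 18)
  idx <- build_index(db$sequences)
  mp <- map_reads(sim$reads, idx)
  asn <- mp$candidates[, .SD[which.max(mapping_quality)], by = read_id]
  m <- merge(asn, sim$truth, by = "read_id", suffixes = c("", ".true"))
  long <- m[sim$truth[read_length >= 1000, read_id], on = "read_id",
            nomatch = NULL]
  hit <- mean(long$genome_id == long$genome_id.true)
  expect_gte(hit, 0.99)
  # and the recovered interval sits on the true one (within one window)
  w <- idx$params$window_size
  ok <- long[genome_id == genome_id.true]
  expect_gte(mean(abs(ok$start - ok$start.true) <= w), 0.99)
})
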