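make_truth <- function(tax) {
  syn_b <- tax$synthetic[genome_id == "g_b", taxon_id]
  syn_c <- tax$synthetic[genome_id == "g_c", taxon_id]
  data.frame(read_id = paste0("r", 1:4),
             taxon_id = c(30L, syn_b, syn_c, 30L),
             read_length = c(2000L, 1000L, 1000L, 1000L))
}

test_that("precision, recall and precision2 follow their definitions", {
  tax <- toy_taxonomy()
  truth <- make_truth(tax)
  syn_b <- tax$synthetic[genome_id == "g_b", taxon_id]
  # 4 truth reads, 3 assigned, 2 correct at species level
  asn <- data.frame(read_id = c("r1", "r2", "r3"),
                    taxon_id = c(30L, syn_b, 30L),
                    read_length = c(2000L, 1000L, 1000L))
  m <- read_metrics(asn, truth, tax, "species")
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 4)
  expect_equal(m$precision2, 2 / 3)

  # an assignment projecting to 0 at the level leaves V'' but stays in V'
  asn2 <- data.frame(read_id = c("r1", "r2", "r3"),
                     taxon_id = c(30L, syn_b, 20L),  # genus -> 0 at species
                     read_length = c(2000L, 1000L, 1000L))
  m2 <- read_metrics(asn2, truth, tax, "species")
  expect_equal(m2$precision2, 1)       # both non-0 calls correct
  expect_equal(m2$precision, 2 / 3)
  expect_error(read_metrics(
    data.frame(read_id = "nope", taxon_id = 30L, read_length = 100L),
    truth, tax, "species"), "absent from truth")
})

test_that("strain-level truth without genome counts an inferred 0 as correct", {
  tax <- toy_taxonomy()
  truth <- data.frame(read_id = "r1", taxon_id = 32L, read_length = 1500L)
  asn <- data.frame(read_id = "r1", taxon_id = 0L, read_length = 1500L)
  m <- read_metrics(asn, truth, tax, "strain")
  expect_equal(m$precision, 1)  # truth projects to 0 too
})

test_that("base metrics weight reads by length", {
  tax <- toy_taxonomy()
  truth <- make_truth(tax)
  syn_b <- tax$synthetic[genome_id == "g_b", taxon_id]
  asn <- data.frame(read_id = c("r1", "r2", "r3"),
                    taxon_id = c(30L, syn_b, 30L),
                    read_length = c(2000L, 1000L, 1000L))
  # equal lengths: base == read metrics
  tr_eq <- truth; tr_eq$read_length <- 1000L
  expect_equal(base_metrics(asn, tr_eq, tax, "species")$precision,
               read_metrics(asn, tr_eq, tax, "species")$precision)
  # one long correct read dominates many short wrong ones
  b <- base_metrics(asn, truth, tax, "species")
  r <- read_metrics(asn, truth, tax, "species")
  expect_equal(b$precision, (2000 + 1000) / 4000)
  expect_gt(b$precision, r$precision)
  tr_bad <- truth; tr_bad$read_length[1] <- 0L
  expect_error(base_metrics(asn, tr_bad, tax, "species"))
})

test_that("read metrics equal a brute-force recount on a random instance", {
  tax <- toy_taxonomy()
  set.seed(77)
  ids <- paste0("r", 1:60)
  taxa <- c(30L, 31L, 32L, 20L, 21L, 10L,
            tax$synthetic$taxon_id, 0L)
  truth <- data.frame(read_id = ids,
                      taxon_id = sample(setdiff(taxa, 0L), 60, TRUE),
                      read_length = sample(1000:5000, 60, TRUE))
  assigned <- sort(sample(ids, 45))
  asn <- data.frame(read_id = assigned,
                    taxon_id = sample(taxa, 45, TRUE),
                    read_length = truth$read_length[match(assigned, ids)])
  for (l in c("strain", "species", "genus", "family")) {
    m <- read_metrics(asn, truth, tax, l)
    pt <- setNames(to_level(tax, truth$taxon_id, l), truth$read_id)
    pa <- setNames(to_level(tax, asn$taxon_id, l), asn$read_id)
    correct <- sum(pa == pt[names(pa)])
    expect_equal(m$precision, correct / length(pa))
    expect_equal(m$recall, correct / nrow(truth))
    nz <- names(pa)[pa != 0L]
    expect_equal(m$precision2,
                 if (length(nz)) sum(pa[nz] == pt[nz]) / length(nz) else NA)
    expect_gte(m$precision, m$recall)  # V' subset of V
  }
})

test_that("compositional L1 and r2 follow the support-column definitions", {
  est <- c(`30` = 0.5, `31` = 0.3, `32` = 0.2)
  tru <- c(`30` = 0.4, `31` = 0.4, `32` = 0.2)
  cm <- composition_metrics(est, tru)
  expect_equal(cm$l1, 0.2, tolerance = 1e-12)
  expect_equal(cm$r2, cor(est, tru)^2, tolerance = 1e-12)
  # identical vectors
  cm2 <- composition_metrics(tru, tru)
  expect_equal(cm2$l1, 0)
  expect_equal(cm2$r2, 1)
  # disjoint support -> maximal distance 2
  expect_equal(composition_metrics(c(a = 1), c(b = 1))$l1, 2)
  # zero-in-both columns are excluded from the correlation
  est3 <- c(a = 0.7, b = 0.3, c = 0)
  tru3 <- c(a = 0.6, b = 0.4, c = 0)
  expect_equal(composition_metrics(est3, tru3)$r2,
               cor(c(0.7, 0.3), c(0.6, 0.4))^2)
})

test_that("binary metrics count presence/absence without the 0 bin", {
  est <- c(`0` = 0.1, `30` = 0.5, `31` = 0.4, `32` = 0)
  tru <- c(`30` = 0.5, `32` = 0.5)
  b <- binary_metrics(est, tru)
  expect_equal(b$binary_precision, 1 / 2)  # {30,31} predicted, {30} true
  expect_equal(b$binary_recall, 1 / 2)     # of {30,32}, only 30 found
  # predicted superset of truth
  b2 <- binary_metrics(c(`30` = 0.6, `31` = 0.4), c(`30` = 1))
  expect_equal(b2$binary_recall, 1)
  expect_lt(b2$binary_precision, 1)
  expect_equal(binary_metrics(c(`30` = 1), c(`30` = 1)),
               list(binary_precision = 1, binary_recall = 1))
})

test_that("metrics are invariant under read reordering", {
  tax <- toy_taxonomy()
  truth <- make_truth(tax)
  asn <- data.frame(read_id = c("r1", "r2", "r3"),
                    taxon_id = c(30L, 31L, 30L),
                    read_length = c(2000L, 1000L, 1000L))
  perm <- c(3, 1, 2)
  m1 <- read_metrics(asn, truth, tax, "species")
  m2 <- read_metrics(asn[perm, ], truth[c(4, 2, 3, 1), ], tax, "species")
  expect_equal(m1, m2)
})
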