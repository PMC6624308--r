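library(data.table)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# hand-built 7-node taxonomy:
#   1 root -> 10 family -> 20 genus -> 30 species (g_a direct)
#                               -> 31 species -> {strains for g_b, g_c}
#            -> 11 family -> 21 genus -> 32 species (no genome)
toy_taxonomy <- function() {
  nodes <- data.frame(
    taxon_id  = c(1L, 10L, 11L, 20L, 21L, 30L, 31L, 32L),
    parent_id = c(1L, 1L, 1L, 10L, 11L, 20L, 20L, 21L),
    rank = c("root", "family", "family", "genus", "genus",
             "species", "species", "species"))
  gm <- data.frame(genome_id = c("g_a", "g_b", "g_c"),
                   taxon_id = c(30L, 31L, 31L))
  load_taxonomy(nodes, NULL, gm)
}

# random tree generator for property tests: node i's parent is a random
# earlier node; ranks drawn from the ladder plus "no rank"
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  ranks <- c("species", "genus", "family", "order", "no rank", "no rank")
  ids <- seq_len(n_nodes)
  parent <- c(1L, vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1)))
  nodes <- data.frame(taxon_id = ids, parent_id = parent,
                      rank = c("root", sample(ranks, n_nodes - 1L,
                                              replace = TRUE)))
  load_taxonomy(nodes, NULL, NULL)
}

# brute-force winnowing oracle: per-window minima (leftmost tie-break) over
# the valid k-mer list; runs shorter than w contribute their minimum
brute_winnow <- function(seq, k, w) {
  km <- as.data.frame(strainmap:::cpp_kmer_hashes(seq, k, 76438003))
  if (nrow(km) == 0L) return(km)
  runs <- split(seq_len(nrow(km)), cumsum(c(1, diff(km$pos) != 1)))
  keep <- integer(0)
  for (r in runs) {
    if (length(r) < w) {
      keep <- c(keep, r[which.min(km$hash[r])])
    } else {
      for (s in 1:(length(r) - w + 1)) {
        win <- r[s:(s + w - 1)]
        keep <- c(keep, win[which.min(km$hash[win])])
      }
    }
  }
  km[sort(unique(keep)), ]
}

# small shared end-to-end fixture, built once per test run
fixture_env <- new.env()
small_community <- function() {
  if (!is.null(fixture_env$comm)) return(fixture_env$comm)
  db <- simulate_genomes(5, genome_length = 50000, divergence = 0.12,
                         seed = 7)
  sim <- simulate_reads(db, abundances = "log-normal", n_reads = 150,
                        length_mean = 4000, accuracy = 0.88, seed = 8)
  idx <- build_index(db$sequences)
  mp <- map_reads(sim$reads, idx)
  fixture_env$comm <- list(db = db, sim = sim, idx = idx, mp = mp)
  fixture_env$comm
}
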