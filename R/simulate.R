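#' Simulate a reference database of related genomes with a toy taxonomy
#'
#' Draws a random ancestor sequence, derives one ancestor per species by
#' substituting a fraction `divergence` of its bases, and one genome per
#' strain by substituting a further `within_species_divergence` fraction of
#' the species ancestor. Species are grouped round-robin into genera and
#' genera into families in the emitted toy taxonomy, so compositional
#' projection is exercised at every level. Deterministic given `seed`.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length of every genome (one contig per genome
#'   unless `contigs_per_genome > 1`, in which case the genome is split
#'   into equal contigs).
#' @param divergence Per-base substitution fraction of each species
#'   ancestor from the common ancestor (0 = identical genomes).
#' @param within_species_divergence Substitution fraction of each strain
#'   from its species ancestor (default `divergence / 10`).
#' @param n_species Number of species (default: one per genome).
#' @param n_genera,n_families Taxonomy grouping (defaults derived from
#'   `n_species`).
#' @param contigs_per_genome Contigs each genome is split into.
#' @param seed Mandatory integer seed.
#' @param out_dir If non-NULL, writes `genomes.fasta`, taxonomy dmp tables
#'   and `genome_map.tsv` into this directory.
#' @return List: `sequences` ([Biostrings::DNAStringSet], headers carry
#'   `genome=<id>` tokens), `genome_map` (data.table `genome_id`,
#'   `taxon_id`), `nodes`, `names` (toy taxonomy tables), `taxonomy` (the
#'   loaded, strain-extended [load_taxonomy()] object), `config`.
#' @export
simulate_genomes <- function(n_genomes, genome_length = 100000L,
                             divergence = 0.1,
                             within_species_divergence = divergence / 10,
                             n_species = n_genomes,
                             n_genera = max(1L, ceiling(n_species / 3)),
                             n_families = max(1L, ceiling(n_genera / 2)),
                             contigs_per_genome = 1L, seed,
                             out_dir = NULL) {
  stopifnot(!missing(seed), n_species <= n_genomes)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, genome_length, replace = TRUE)
  species_of_genome <- rep_len(seq_len(n_species), n_genomes)
  genus_of_species <- rep_len(seq_len(n_genera), n_species)
  family_of_genus <- rep_len(seq_len(n_families), n_genera)

  sp_anc <- lapply(seq_len(n_species), function(s)
    mutate_bases(anc, divergence, bases))
  gids <- sprintf("g%02d", seq_len(n_genomes))
  seqs <- vapply(seq_len(n_genomes), function(i)
    paste(mutate_bases(sp_anc[[species_of_genome[i]]],
                       within_species_divergence, bases), collapse = ""),
    character(1))

  contigs <- list(); headers <- character(0)
  for (i in seq_len(n_genomes)) {
    if (contigs_per_genome == 1L) {
      contigs <- c(contigs, seqs[i])
      headers <- c(headers, sprintf("%s_c1 genome=%s", gids[i], gids[i]))
    } else {
      cuts <- floor(seq(0, nchar(seqs[i]), length.out =
                          contigs_per_genome + 1L))
      for (j in seq_len(contigs_per_genome)) {
        contigs <- c(contigs, substr(seqs[i], cuts[j] + 1L, cuts[j + 1L]))
        headers <- c(headers, sprintf("%s_c%d genome=%s", gids[i], j,
                                      gids[i]))
      }
    }
  }
  dss <- Biostrings::DNAStringSet(unlist(contigs))
  names(dss) <- headers

  # toy taxonomy: root=1, families 10+, genera 100+, species 1000+
  fam_ids <- 10L + seq_len(n_families)
  gen_ids <- 100L + seq_len(n_genera)
  sp_ids <- 1000L + seq_len(n_species)
  nodes <- rbind(
    data.table(taxon_id = 1L, parent_id = 1L, rank = "root"),
    data.table(taxon_id = fam_ids, parent_id = 1L, rank = "family"),
    data.table(taxon_id = gen_ids,
               parent_id = fam_ids[family_of_genus], rank = "genus"),
    data.table(taxon_id = sp_ids,
               parent_id = gen_ids[genus_of_species], rank = "species"))
  nms <- data.table(taxon_id = nodes$taxon_id,
                    name = c("root", sprintf("family_%d", seq_len(n_families)),
                             sprintf("genus_%d", seq_len(n_genera)),
                             sprintf("species_%d", seq_len(n_species))))
  genome_map <- data.table(genome_id = gids,
                           taxon_id = sp_ids[species_of_genome])
  taxonomy <- load_taxonomy(nodes, nms, genome_map)
  out <- list(sequences = dss, genome_map = genome_map, nodes = nodes,
              names = nms, taxonomy = taxonomy,
              config = list(n_genomes = n_genomes,
                            genome_length = genome_length,
                            divergence = divergence,
                            within_species_divergence =
                              within_species_divergence,
                            n_species = n_species, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(dss, file.path(out_dir, "genomes.fasta"))
    write_taxonomy_tables(taxonomy, out_dir)
    fwrite(genome_map, file.path(out_dir, "source_genome_map.tsv"),
           sep = "\t", col.names = FALSE)
  }
  out
}

mutate_bases <- function(chars, rate, bases) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases, uniformly
    offs <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(chars[hit], bases)
    chars[hit] <- bases[((cur - 1L + offs) %% 4L) + 1L]
  }
  chars
}

#' Simulate error-bearing long reads with truth labels
#'
#' Emulates a pbsim-style CLR run: read lengths are log-normal around
#' `length_mean` (truncated below at `min_length`, by default half the
#' usual 1000-base minimum mapping length so that sub-length reads exist),
#' start positions are uniform within contigs, strands are random, and
#' errors are applied at per-base rate `1 - accuracy`, split between
#' substitutions and indels by `sub_frac`. Genomes are drawn per read
#' according to `abundances`. Deterministic given `seed`.
#'
#' @param genomes A [simulate_genomes()] result, a named
#'   [Biostrings::DNAStringSet] with `genome=` header tokens, or a FASTA
#'   path.
#' @param abundances Named numeric vector over genome ids (summing to 1)
#'   or unnamed in genome order; `"log-normal"` to draw log-normal
#'   abundances (meanlog 0, sdlog 1, normalized); `"uniform"` for equal
#'   abundances.
#' @param n_reads Number of reads (alternatively give `total_bases`).
#' @param total_bases Approximate total bases; `n_reads` is derived as
#'   `round(total_bases / length_mean)`.
#' @param length_mean Mean read length (default 5000).
#' @param length_sdlog Log-sd of the length distribution (default 0.5).
#' @param min_length Lower truncation of read lengths (default 500).
#' @param accuracy Per-base accuracy (default 0.88, i.e. 12% error).
#' @param sub_frac Fraction of errors that are substitutions (default 0.9;
#'   the remainder is split evenly between insertions and deletions).
#' @param seed Mandatory integer seed.
#' @param out_fastq,out_truth Optional output paths (FASTQ and truth TSV).
#' @return List: `reads` (DNAStringSet), `truth` (data.table `read_id`,
#'   `genome_id`, `taxon_id` (NA unless `genomes` carries a taxonomy),
#'   `contig_id`, `start`, `end`, `strand`, `read_length`), `abundances`
#'   (the realized named vector used).
#' @export
simulate_reads <- function(genomes, abundances = "uniform", n_reads = NULL,
                           total_bases = NULL, length_mean = 5000,
                           length_sdlog = 0.5, min_length = 500L,
                           accuracy = 0.88, sub_frac = 0.9, seed,
                           out_fastq = NULL, out_truth = NULL) {
  stopifnot(!missing(seed), accuracy > 0.5, accuracy <= 1)
  set.seed(seed)
  taxonomy <- NULL
  if (is.list(genomes) && !is.null(genomes$sequences)) {
    taxonomy <- genomes$taxonomy
    genomes <- genomes$sequences
  }
  seqs <- load_contigs(genomes)
  genome_of <- resolve_genomes(seqs, NULL)
  gids <- unique(genome_of)

  if (identical(abundances, "uniform"))
    abundances <- setNames(rep(1 / length(gids), length(gids)), gids)
  if (identical(abundances, "log-normal")) {
    x <- rlnorm(length(gids), 0, 1)
    abundances <- setNames(x / sum(x), gids)
  }
  if (is.null(names(abundances))) names(abundances) <- gids
  stopifnot(abs(sum(abundances) - 1) < 1e-8)

  if (is.null(n_reads)) {
    stopifnot(!is.null(total_bases))
    n_reads <- max(1L, round(total_bases / length_mean))
  }
  e <- 1 - accuracy
  meanlog <- log(length_mean) - length_sdlog^2 / 2
  gsel <- sample(names(abundances), n_reads, replace = TRUE,
                 prob = abundances)
  lens <- pmax(as.integer(round(rlnorm(n_reads, meanlog, length_sdlog))),
               as.integer(min_length))

  contig_of_genome <- split(seq_along(seqs$contig_id), genome_of)
  recs <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    cand <- contig_of_genome[[gsel[i]]]
    ci <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = seqs$lengths[cand])
    clen <- seqs$lengths[ci]
    len <- min(lens[i], clen)
    start <- sample.int(clen - len + 1L, 1L) - 1L  # 0-based
    tmpl <- as.character(Biostrings::subseq(seqs$sequences[[ci]],
                                            start + 1L, start + len))
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-")
      tmpl <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tmpl)))
    read <- apply_errors(tmpl, e, sub_frac)
    recs[[i]] <- list(seq = read, genome_id = gsel[i],
                      contig_id = seqs$contig_id[ci], start = start,
                      end = start + len, strand = strand)
  }
  reads <- Biostrings::DNAStringSet(vapply(recs, `[[`, character(1), "seq"))
  ids <- sprintf("sim_%05d", seq_len(n_reads))
  names(reads) <- ids
  truth <- data.table(
    read_id = ids,
    genome_id = vapply(recs, `[[`, character(1), "genome_id"),
    contig_id = vapply(recs, `[[`, character(1), "contig_id"),
    start = vapply(recs, `[[`, numeric(1), "start"),
    end = vapply(recs, `[[`, numeric(1), "end"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    read_length = Biostrings::width(reads))
  truth[, taxon_id := if (!is.null(taxonomy))
    taxon_of_genome(taxonomy, genome_id) else NA_integer_]
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq, accuracy)
  if (!is.null(out_truth)) fwrite(truth, out_truth, sep = "\t")
  list(reads = reads, truth = truth, abundances = abundances)
}

# apply substitution/indel errors to a template sequence (character scalar)
apply_errors <- function(tmpl, e, sub_frac) {
  if (e <= 0) return(tmpl)
  chars <- strsplit(tmpl, "")[[1]]
  bases <- c("A", "C", "G", "T")
  err <- which(runif(length(chars)) < e)
  if (!length(err)) return(tmpl)
  type <- sample(c("S", "I", "D"), length(err), replace = TRUE,
                 prob = c(sub_frac, (1 - sub_frac) / 2, (1 - sub_frac) / 2))
  sub_at <- err[type == "S"]
  if (length(sub_at)) {
    offs <- sample.int(3L, length(sub_at), replace = TRUE)
    cur <- match(chars[sub_at], bases)
    cur[is.na(cur)] <- 1L
    chars[sub_at] <- bases[((cur - 1L + offs) %% 4L) + 1L]
  }
  del_at <- err[type == "D"]
  ins_at <- err[type == "I"]
  if (length(ins_at))
    chars[ins_at] <- paste0(sample(bases, length(ins_at), replace = TRUE),
                            chars[ins_at])
  if (length(del_at)) chars[del_at] <- ""
  paste(chars, collapse = "")
}

write_fastq <- function(reads, path, accuracy) {
  q <- min(41L, max(2L, as.integer(round(-10 * log10(max(1e-4,
    1 - accuracy))))))
  qc <- rawToChar(as.raw(q + 33L))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    s <- as.character(reads[[i]])
    writeLines(c(paste0("@", names(reads)[i]), s, "+",
                 strrep(qc, nchar(s))), con)
  }
  invisible(path)
}

#' Simulate contaminant reads from an out-of-database genome
#'
#' Generates an independent random genome (unrelated to any database
#' ancestor) and simulates reads from it; the truth taxon is 0 at every
#' level. Used to test robustness against large out-of-database genomes
#' (e.g. host or environmental contamination).
#'
#' @param genome_length Length of the contaminant genome.
#' @param n_reads Number of reads.
#' @param seed Mandatory integer seed.
#' @param ... Passed to [simulate_reads()] (accuracy, length_mean, ...).
#' @return As [simulate_reads()]; `truth$taxon_id` is 0 and
#'   `truth$genome_id` is `"contaminant"`.
#' @export
simulate_contaminant <- function(genome_length = 200000L, n_reads = 100L,
                                 seed, ...) {
  stopifnot(!missing(seed))
  set.seed(seed + 104729L)
  g <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
             collapse = "")
  dss <- Biostrings::DNAStringSet(g)
  names(dss) <- "contaminant_c1 genome=contaminant"
  out <- simulate_reads(dss, abundances = c(contaminant = 1),
                        n_reads = n_reads, seed = seed, ...)
  out$truth[, taxon_id := 0L]
  out
}
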