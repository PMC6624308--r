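#' Indexing parameters
#'
#' Parameters controlling minimizer selection. The winnowing window `w` is
#' auto-tuned from the minimum read length so that a read of minimum length
#' is expected to contain at least `sketch_target` minimizers (winnowing
#' selects a fraction of about `2/(w+1)` of all k-mers); the minimum mapping
#' identity sets the candidate-acceptance cutoff used during mapping.
#'
#' @param k K-mer size (default 16).
#' @param min_read_length Minimum read length in bases (default 1000);
#'   shorter reads are not mapped.
#' @param min_identity Minimum alignment identity as a fraction in (0, 1)
#'   (default 0.80); candidate locations with lower estimated identity are
#'   discarded.
#' @param sketch_target Target number of minimizers per minimum-length read
#'   (default 200); also caps the minhash sketch size.
#' @param window_size Winnowing window `w`; derived with [tune_density()]
#'   when `NULL`.
#' @return A list of class `index_params`.
#' @export
index_params <- function(k = 16L, min_read_length = 1000L,
                         min_identity = 0.80, sketch_target = 200L,
                         window_size = NULL) {
  stopifnot(k >= 4L, min_identity > 0, min_identity < 1,
            min_read_length >= k)
  if (is.null(window_size))
    window_size <- tune_density(min_read_length, min_identity, sketch_target)
  stopifnot(window_size >= 1L)
  structure(list(k = as.integer(k),
                 min_read_length = as.integer(min_read_length),
                 min_identity = min_identity,
                 sketch_target = as.integer(sketch_target),
                 window_size = as.integer(window_size)),
            class = "index_params")
}

#' Auto-tune the winnowing window from read-length assumptions
#'
#' Returns the largest window `w` such that the expected number of winnowed
#' minimizers in a minimum-length read, approximately
#' `2 * min_read_length / (w + 1)`, is at least `sketch_target`. If even
#' `w = 1` cannot reach the target (target larger than twice the minimum
#' read length), `w = 1` is returned with a warning (every k-mer kept).
#'
#' @param min_read_length Minimum read length (bases).
#' @param min_identity Minimum mapping identity; retained in the signature
#'   because density tuning is conceptually tied to both assumptions, but
#'   the expected-count rule used here depends on length only (the identity
#'   enters through the candidate cutoff, see [min_sketch_overlap()]).
#' @param sketch_target Required expected minimizer count (>= 10).
#' @return Integer window size `w >= 1`.
#' @examples
#' tune_density(1000, 0.8, 200)  # 9
#' @export
tune_density <- function(min_read_length, min_identity, sketch_target = 200L) {
  stopifnot(sketch_target >= 10)
  w <- floor(2 * min_read_length / sketch_target - 1)
  if (w < 1) {
    warning("sketch_target ", sketch_target, " infeasible for minimum read ",
            "length ", min_read_length, "; using window_size = 1")
    w <- 1
  }
  as.integer(w)
}

#' Minimum sketch-intersection count for a candidate location
#'
#' Inverts the identity estimator at the minimum identity: a mapping at
#' identity `id` has expected Jaccard `J = id^k / (2 - id^k)`, so a
#' candidate must share at least `ceiling(J * sketch_target)` (and at least
#' 2) minimizers with the read to be considered.
#'
#' @param params An [index_params()] object.
#' @return Integer cutoff `m_min`.
#' @export
min_sketch_overlap <- function(params) {
  idk <- params$min_identity^params$k
  jmin <- idk / (2 - idk)
  max(2L, as.integer(ceiling(jmin * params$sketch_target)))
}

#' Winnowed minimizers of a DNA sequence
#'
#' Canonical-strand minimizer selection: every k-mer is hashed together with
#' its reverse complement under a fixed-seed 64-bit hash (masked to 53 bits
#' so values are exact doubles), the numerically smaller orientation defines
#' the canonical hash, and within every window of `w` consecutive k-mers the
#' minimum-hash k-mer is kept once (leftmost on ties). K-mers containing an
#' ambiguous base (N) are skipped; no reported minimizer spans an N.
#'
#' @param sequence A single DNA string (character or `DNAString`).
#' @param params An [index_params()] object.
#' @return data.table with columns `hash` (double), `pos` (0-based k-mer
#'   start) and `strand` (+1/-1, orientation achieving the canonical form;
#'   palindromes are +1). Sequences shorter than `k` give zero rows.
#' @export
winnow <- function(sequence, params = index_params()) {
  dt <- as.data.table(cpp_winnow(as.character(sequence), params$k,
                                 params$window_size, hash_seed()))
  dt
}

#' Canonical k-mer hash
#'
#' @param seq A k-length DNA string.
#' @param k K-mer size (defaults to `nchar(seq)`).
#' @return Named list `hash` (double; NA if the k-mer contains a non-ACGT
#'   base) and `strand` (+1 if the forward orientation is canonical).
#' @export
canonical_kmer_hash <- function(seq, k = nchar(seq)) {
  stopifnot(nchar(seq) == k)
  dt <- cpp_kmer_hashes(as.character(seq), as.integer(k), hash_seed())
  if (nrow(dt) == 0L) return(list(hash = NA_real_, strand = NA_integer_))
  list(hash = dt$hash[1], strand = dt$strand[1])
}

#' Build a minimizer index over reference contigs
#'
#' Winnows every contig of the reference database and stores the selected
#' minimizers in a hash-keyed posting table. Contigs are associated with
#' genomes either through an explicit `contig_map`, a `genome=<id>` token in
#' the FASTA description line, or (fallback) a contig name equal to the
#' genome id.
#'
#' @param genomes Path to a (multi-)FASTA file or a named
#'   [Biostrings::DNAStringSet].
#' @param params An [index_params()] object.
#' @param contig_map Optional data.frame with columns `contig_id`,
#'   `genome_id` overriding header-based genome resolution.
#' @return An object of class `minimizer_index`: posting table (`hash`,
#'   `genome_id`, `contig_id`, `pos`, `strand`), per-contig minimizer
#'   arrays, contig lengths, genome-of-contig map and the parameters.
#' @export
build_index <- function(genomes, params = index_params(), contig_map = NULL) {
  seqs <- load_contigs(genomes)
  if (length(seqs$sequences) == 0L) stop("empty reference input")
  if (anyDuplicated(seqs$contig_id))
    stop("duplicate contig ids in reference input")
  genome_of <- resolve_genomes(seqs, contig_map)
  tabs <- lapply(seq_along(seqs$sequences), function(i) {
    mm <- winnow(seqs$sequences[[i]], params)
    if (nrow(mm)) mm[, `:=`(genome_id = genome_of[i],
                            contig_id = seqs$contig_id[i])]
    mm
  })
  new_minimizer_index(rbindlist(tabs),
                      setNames(seqs$lengths, seqs$contig_id),
                      setNames(genome_of, seqs$contig_id), params)
}

new_minimizer_index <- function(postings, contig_lengths, genome_of_contig,
                                params) {
  setcolorder(postings, c("hash", "genome_id", "contig_id", "pos", "strand"))
  setkey(postings, hash)
  by_contig <- lapply(split(postings[, .(hash, pos, strand)],
                            postings$contig_id), function(d) {
    o <- order(d$pos)
    list(pos = d$pos[o], hash = d$hash[o], strand = d$strand[o])
  })
  structure(list(postings = postings, by_contig = by_contig,
                 contig_lengths = contig_lengths,
                 genome_of_contig = genome_of_contig, params = params),
            class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat("<minimizer_index> ", nrow(x$postings), " minimizers over ",
      length(x$contig_lengths), " contigs / ",
      length(unique(x$genome_of_contig)), " genomes (k=", x$params$k,
      ", w=", x$params$window_size, ")\n", sep = "")
  invisible(x)
}

#' All genome ids covered by an index (monolithic or chunked)
#' @param index A `minimizer_index` or `chunked_index`.
#' @return Character vector of genome ids.
#' @export
index_genomes <- function(index) {
  sort(unique(unlist(lapply(index_chunks(index),
                            function(ch) unname(ch$genome_of_contig)))))
}

#' Contig lengths per genome from an index
#' @param index A `minimizer_index` or `chunked_index`.
#' @return Named list: for each genome id, an integer vector of its contig
#'   lengths.
#' @export
index_contig_lengths <- function(index) {
  chunks <- index_chunks(index)
  cl <- unlist(lapply(chunks, `[[`, "contig_lengths"))
  go <- unlist(lapply(chunks, `[[`, "genome_of_contig"))
  cl <- cl[!duplicated(names(cl))]
  go <- go[!duplicated(names(go))]
  split(unname(cl), unname(go[names(cl)]))
}

index_chunks <- function(index) {
  if (inherits(index, "chunked_index")) index$chunks else list(index)
}

#' Build a memory-limited chunked index
#'
#' Contigs are randomly permuted (seeded) and packed sequentially into
#' sub-indexes whose posting count stays at or below `memory_target`
#' entries; reads are later mapped against every chunk and candidate sets
#' merged, so the union of chunk contents equals the monolithic index. A
#' single contig exceeding the budget gets its own chunk with a warning.
#'
#' @inheritParams build_index
#' @param memory_target Maximum posting entries per chunk.
#' @param seed Integer seed for the contig permutation.
#' @return An object of class `chunked_index` (list of `minimizer_index`
#'   chunks).
#' @export
build_index_chunked <- function(genomes, params = index_params(),
                                memory_target, contig_map = NULL, seed = 1L) {
  mono <- build_index(genomes, params, contig_map)
  contigs <- names(mono$contig_lengths)
  perm <- withr_seed(seed, sample(contigs))
  sizes <- vapply(perm, function(cid) {
    bc <- mono$by_contig[[cid]]
    if (is.null(bc)) 0L else length(bc$pos)
  }, integer(1))
  chunk_of <- integer(length(perm))
  cur <- 1L; used <- 0L
  for (i in seq_along(perm)) {
    if (sizes[i] > memory_target && used == 0L) {
      warning("contig ", perm[i], " alone exceeds memory_target (",
              sizes[i], " > ", memory_target, "); placing it in its own chunk")
      chunk_of[i] <- cur; cur <- cur + 1L; used <- 0L
      next
    }
    if (used > 0L && used + sizes[i] > memory_target) {
      cur <- cur + 1L; used <- 0L
    }
    chunk_of[i] <- cur
    used <- used + sizes[i]
  }
  chunks <- lapply(seq_len(max(chunk_of)), function(ci) {
    cids <- perm[chunk_of == ci]
    new_minimizer_index(mono$postings[contig_id %in% cids],
                        mono$contig_lengths[cids],
                        mono$genome_of_contig[cids], params)
  })
  structure(list(chunks = chunks, params = params, seed = seed),
            class = "chunked_index")
}

#' @export
print.chunked_index <- function(x, ...) {
  cat("<chunked_index> ", length(x$chunks), " chunks, ",
      sum(vapply(x$chunks, function(ch) nrow(ch$postings), numeric(1))),
      " minimizers total\n", sep = "")
  invisible(x)
}

# run expr under a temporary seed without disturbing the global RNG stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

load_contigs <- function(genomes) {
  if (is.character(genomes)) genomes <- Biostrings::readDNAStringSet(genomes)
  full <- names(genomes)
  if (is.null(full)) full <- paste0("contig_", seq_along(genomes))
  contig_id <- vapply(strsplit(full, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", full)
  list(sequences = genomes, contig_id = contig_id, desc = desc,
       lengths = Biostrings::width(genomes))
}

resolve_genomes <- function(seqs, contig_map) {
  if (!is.null(contig_map)) {
    cm <- as.data.table(contig_map)
    g <- setNames(as.character(cm$genome_id), cm$contig_id)[seqs$contig_id]
    if (anyNA(g)) stop("contig(s) missing from contig_map: ",
                       paste(seqs$contig_id[is.na(g)], collapse = ", "))
    return(unname(g))
  }
  has <- grepl("genome=", seqs$desc)
  g <- seqs$contig_id
  g[has] <- sub("^genome=", "", regmatches(seqs$desc,
    regexpr("genome=\\S+", seqs$desc)))
  g
}

#' Serialize an index to a TSV file with an embedded parameter header
#'
#' Plain-text format: `#params:` and `#contigs:` JSON header lines followed
#' by the posting table. [read_index()] restores an identical object.
#'
#' @param index A `minimizer_index`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "minimizer_index"))
  hdr <- c(
    paste0("#params:", jsonlite::toJSON(unclass(index$params),
                                        auto_unbox = TRUE)),
    paste0("#contigs:", jsonlite::toJSON(list(
      contig_id = names(index$contig_lengths),
      length = unname(index$contig_lengths),
      genome_id = unname(index$genome_of_contig)), auto_unbox = FALSE)))
  writeLines(hdr, path)
  p <- copy(index$postings)
  p[, hash := sprintf("%.0f", hash)]
  fwrite(p, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  hdr <- readLines(path, n = 2L)
  stopifnot(startsWith(hdr[1], "#params:"), startsWith(hdr[2], "#contigs:"))
  pj <- jsonlite::fromJSON(sub("^#params:", "", hdr[1]))
  params <- index_params(k = pj$k, min_read_length = pj$min_read_length,
                         min_identity = pj$min_identity,
                         sketch_target = pj$sketch_target,
                         window_size = pj$window_size)
  cj <- jsonlite::fromJSON(sub("^#contigs:", "", hdr[2]))
  postings <- fread(path, skip = 2L, sep = "\t",
                    colClasses = list(character = "contig_id"))
  postings[, hash := as.numeric(hash)]
  new_minimizer_index(postings,
                      setNames(as.integer(cj$length), cj$contig_id),
                      setNames(as.character(cj$genome_id), cj$contig_id),
                      params)
}
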