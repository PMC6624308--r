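#' Expected number of exact k-mer matches under a uniform error model
#'
#' Under independent per-base errors at rate `e`, a k-mer survives
#' sequencing without error with probability `(1 - e)^k`, so a read of
#' length `L` is expected to share `(L - k + 1) * (1 - e)^k` exact k-mers
#' with its error-free source locus. For a 1000 bp read at 15% error and
#' k = 16 this is about 73 matches, which is why sets of consistently
#' positioned short exact matches remain a usable mapping signal even at
#' long-read error rates.
#'
#' @param read_length Read length in bases (>= k).
#' @param k K-mer size.
#' @param error_rate Per-base error rate in [0, 1).
#' @return Expected match count (double).
#' @examples
#' expected_kmer_matches(1000, 16, 0.15)  # ~73
#' @export
expected_kmer_matches <- function(read_length, k, error_rate) {
  stopifnot(error_rate >= 0, error_rate < 1, read_length >= k)
  (read_length - k + 1) * (1 - error_rate)^k
}

#' Winnowed-minhash Jaccard estimate between two hash sets
#'
#' The union sketch is formed from the `sketch_size` smallest values of the
#' union of the two (already winnowed) hash sets; the Jaccard similarity is
#' estimated as the fraction of sketch members present in both sets.
#'
#' @param s_r,s_i Numeric vectors of minimizer hashes (read and reference
#'   window); duplicates are removed.
#' @param sketch_size Sketch size `s`; defaults to the smaller set size.
#' @return List with `n_union` (= realized sketch size), `n_shared` and
#'   `jaccard_hat = n_shared / n_union`.
#' @export
jaccard_estimate <- function(s_r, s_i, sketch_size = NULL) {
  a <- sort(unique(as.numeric(s_r)))
  b <- sort(unique(as.numeric(s_i)))
  if (length(a) == 0L && length(b) == 0L)
    stop("both sketches are empty; no Jaccard estimate")
  if (is.null(sketch_size)) sketch_size <- min(length(a), length(b))
  sketch_size <- max(1L, as.integer(sketch_size))
  st <- cpp_sketch_stats(a, b, sketch_size)
  list(n_union = st[1], n_shared = st[2],
       jaccard_hat = if (st[1] > 0) st[2] / st[1] else 0)
}

#' Alignment identity from a Jaccard estimate
#'
#' Inverts the expected relation between k-mer Jaccard similarity and
#' per-base identity: `identity = (2J / (1 + J))^(1/k)`.
#'
#' @param jaccard_hat Jaccard estimate in [0, 1].
#' @param k K-mer size.
#' @return Estimated identity in [0, 1] (0 when `jaccard_hat` is 0).
#' @export
identity_from_jaccard <- function(jaccard_hat, k) {
  stopifnot(all(jaccard_hat >= 0), all(jaccard_hat <= 1))
  ifelse(jaccard_hat == 0, 0, (2 * jaccard_hat / (1 + jaccard_hat))^(1 / k))
}

#' Remove candidate locations below a minimum identity
#'
#' @param candidates data.table of candidate mappings with an
#'   `identity_hat` column.
#' @param min_identity Identity cutoff (fraction).
#' @return The surviving rows.
#' @export
filter_low_identity <- function(candidates, min_identity) {
  candidates[identity_hat >= min_identity]
}

#' Composition-independent mapping qualities for one read
#'
#' The number of shared sketch members at a true mapping location is
#' modelled as binomial with size `n_union` and success probability equal
#' to the k-mer survival rate `(1 - e)^k`, where `e` is the read's error
#' estimate. Each candidate's binomial probability is normalized over the
#' read's candidates (in log space, so qualities are well defined even when
#' all probabilities underflow) to give the mapping quality `P_r(i)`.
#'
#' @param candidates data.table with columns `n_union`, `n_shared` (one
#'   read's candidates; >= 1 row).
#' @param e Per-read error estimate in [0, 1); by convention
#'   `1 - max(identity_hat)` over the read's candidates.
#' @param k K-mer size.
#' @return The input with a `mapping_quality` column added; qualities sum
#'   to 1.
#' @export
mapping_quality <- function(candidates, e, k) {
  stopifnot(nrow(candidates) >= 1L, e >= 0, e < 1)
  p <- (1 - e)^k
  lw <- dbinom(candidates$n_shared, candidates$n_union, p, log = TRUE)
  candidates[, mapping_quality := exp(lw - logsumexp(lw))]
  candidates
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Map long reads against a minimizer index
#'
#' For each read of at least the minimum length, read minimizers are looked
#' up in the index; reference windows of read-length extent sharing at
#' least [min_sketch_overlap()] distinct minimizers with the read become
#' candidate mapping locations (overlapping windows merged, maximal-count
#' offset kept). Per candidate, alignment identity is estimated from the
#' winnowed-minhash Jaccard statistic; candidates below the minimum
#' identity are discarded; surviving candidates are scored with the
#' binomial mapping-quality model using the read's error estimate
#' `e = 1 - max(identity_hat)`. With a `chunked_index`, candidates are
#' generated per chunk and pooled before filtering and quality
#' computation, so results are identical to the monolithic index.
#'
#' @param reads Path to a FASTA/FASTQ file or a named
#'   [Biostrings::DNAStringSet].
#' @param index A `minimizer_index` or `chunked_index`.
#' @return An object of class `read_mappings`: `candidates` (data.table:
#'   `read_id`, `genome_id`, `contig_id`, `start`, `end`, `strand`,
#'   `n_union`, `n_shared`, `jaccard_hat`, `identity_hat`,
#'   `mapping_quality`), `reads` (data.table: `read_id`, `read_length`,
#'   `n_minimizers`, `e`, `status` in mapped/unmapped/too_short) and the
#'   `params` used.
#' @export
map_reads <- function(reads, index) {
  params <- if (inherits(index, "chunked_index")) index$params else
    index$params
  seqs <- load_reads(reads)
  n <- length(seqs$sequences)
  read_info <- data.table(read_id = seqs$read_id,
                          read_length = seqs$lengths,
                          n_minimizers = 0L, e = NA_real_,
                          status = "unmapped")
  eligible <- which(seqs$lengths >= params$min_read_length)
  read_info[setdiff(seq_len(n), eligible), status := "too_short"]

  empty <- data.table(read_id = character(), genome_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_union = integer(), n_shared = integer(),
                      jaccard_hat = numeric(), identity_hat = numeric(),
                      mapping_quality = numeric())
  if (length(eligible) == 0L)
    return(new_read_mappings(empty, read_info, params))

  # read minimizers, one table per eligible read, distinct by hash
  rsk <- lapply(eligible, function(i) {
    mm <- winnow(seqs$sequences[[i]], params)
    mm <- mm[!duplicated(hash)]
    setorder(mm, hash)
    mm
  })
  names(rsk) <- as.character(eligible)
  read_info[eligible, n_minimizers := vapply(rsk, nrow, integer(1))]

  m_min <- min_sketch_overlap(params)
  cand_list <- lapply(index_chunks(index), function(chunk)
    candidates_one_chunk(rsk, eligible, seqs$lengths, chunk, params, m_min))
  cands <- rbindlist(cand_list)
  if (nrow(cands) == 0L)
    return(new_read_mappings(empty, read_info, params))

  # per-read error estimate from the best candidate, then identity filter
  best <- cands[, .(best_id = max(identity_hat)), by = ridx]
  read_info[best$ridx, e := pmax(0, 1 - best$best_id)]
  cands <- filter_low_identity(cands, params$min_identity)
  if (nrow(cands) > 0L) {
    cands[, mapping_quality := {
      p <- (1 - read_info$e[ridx[1]])^params$k
      lw <- dbinom(n_shared, n_union, p, log = TRUE)
      exp(lw - logsumexp(lw))
    }, by = ridx]
  }
  read_info[unique(cands$ridx), status := "mapped"]
  out <- cands[, .(read_id = read_info$read_id[ridx],
                   genome_id, contig_id, start, end, strand,
                   n_union, n_shared, jaccard_hat, identity_hat,
                   mapping_quality)]
  setorder(out, read_id, genome_id, contig_id, start)
  new_read_mappings(out, read_info, params)
}

# candidate generation + sketch statistics for one index chunk;
# returns a data.table keyed by global read index `ridx`
candidates_one_chunk <- function(rsk, eligible, read_lengths, chunk, params,
                                 m_min) {
  rm <- rbindlist(lapply(seq_along(rsk), function(ii)
    data.table(ridx = eligible[ii], hash = rsk[[ii]]$hash,
               rpos = rsk[[ii]]$pos, rstrand = rsk[[ii]]$strand)))
  hits <- chunk$postings[rm, on = "hash", nomatch = NULL,
                         allow.cartesian = TRUE]
  out_empty <- data.table(ridx = integer(), genome_id = character(),
                          contig_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_union = integer(), n_shared = integer(),
                          jaccard_hat = numeric(), identity_hat = numeric())
  if (nrow(hits) == 0L) return(out_empty)
  setorder(hits, ridx, contig_id, pos)
  hits[, grp := .GRP - 1L, by = .(ridx, contig_id)]
  grp_first <- hits[, .(row1 = .I[1]), by = grp]
  L_grp <- read_lengths[hits$ridx[grp_first$row1]]
  hits[, hid := as.integer(factor(hash))]
  sc <- as.data.table(cpp_scan_candidates(hits$grp, hits$pos, hits$hid,
                                          as.integer(L_grp), m_min))
  if (nrow(sc) == 0L) return(out_empty)

  # per-candidate strand (majority) and start estimate (median anchor diff)
  sc[, cid := .I]
  span <- sc[, .(row = seq.int(row_lo, row_hi - 1L)), by = cid]
  mem <- hits[span$row, .(ridx, contig_id, pos, strand, rpos, rstrand)]
  mem[, cid := span$cid]
  mem[, L := read_lengths[ridx]]
  est <- mem[, {
    agree <- strand * rstrand
    str <- if (sum(agree) >= 0) "+" else "-"
    d <- if (str == "+") pos - rpos else pos - (L - rpos - params$k)
    # indel drift accumulates along the read, so anchor the start estimate
    # on the hits closest to the read end that enters at `start` (read
    # start for +, read end for -), where the drift is smallest
    o <- order(if (str == "+") rpos else -rpos)
    .(strand = str,
      start_est = as.integer(round(median(d[head(o, 5L)]))))
  }, by = .(cid, ridx, contig_id)]
  est[, L := read_lengths[ridx]]
  clen <- chunk$contig_lengths[est$contig_id]
  est[, start := pmin(pmax(start_est, 0L), pmax(as.integer(clen) - 1L, 0L))]
  est[, end := pmin(start + L, as.integer(clen))]

  # sketch statistics against the reference minimizers of the interval
  stats <- vapply(seq_len(nrow(est)), function(i) {
    bc <- chunk$by_contig[[est$contig_id[i]]]
    lo <- findInterval(est$start[i] - 1L, bc$pos) + 1L
    hi <- findInterval(est$end[i] - params$k, bc$pos)
    if (hi < lo) return(c(0L, 0L))
    b <- sort(unique(bc$hash[lo:hi]))
    a <- rsk[[as.character(est$ridx[i])]]$hash
    s <- min(length(a), length(b), params$sketch_target)
    cpp_sketch_stats(a, b, s)
  }, integer(2))
  est[, `:=`(n_union = stats[1, ], n_shared = stats[2, ])]
  est <- est[n_union > 0L]
  est[, jaccard_hat := n_shared / n_union]
  est[, identity_hat := identity_from_jaccard(jaccard_hat, params$k)]
  est[, genome_id := unname(chunk$genome_of_contig[contig_id])]
  est[, .(ridx, genome_id, contig_id, start, end, strand, n_union,
          n_shared, jaccard_hat, identity_hat)]
}

new_read_mappings <- function(candidates, reads, params) {
  structure(list(candidates = candidates, reads = reads, params = params),
            class = "read_mappings")
}

#' @export
print.read_mappings <- function(x, ...) {
  st <- table(x$reads$status)
  cat("<read_mappings> ", nrow(x$reads), " reads (",
      paste(names(st), as.integer(st), sep = "=", collapse = ", "), "); ",
      nrow(x$candidates), " candidate locations\n", sep = "")
  invisible(x)
}

#' Raw candidate intervals for a single read
#'
#' Convenience wrapper around the candidate-generation stage (before
#' identity filtering and quality computation) for one read.
#'
#' @param read A DNA string (character or `DNAString`).
#' @param index A `minimizer_index` or `chunked_index`.
#' @param read_id Identifier used in the output.
#' @return data.table of candidate locations with sketch statistics and
#'   estimated identities (possibly zero rows).
#' @export
candidate_locations <- function(read, index, read_id = "read1") {
  params <- index$params
  seqs <- Biostrings::DNAStringSet(setNames(as.character(read), read_id))
  if (Biostrings::width(seqs)[1] < params$min_read_length)
    return(data.table())
  rsk <- winnow(seqs[[1]], params)
  rsk <- rsk[!duplicated(hash)]
  setorder(rsk, hash)
  m_min <- min_sketch_overlap(params)
  out <- rbindlist(lapply(index_chunks(index), function(chunk)
    candidates_one_chunk(setNames(list(rsk), "1"), 1L,
                         Biostrings::width(seqs), chunk, params, m_min)))
  out
}

load_reads <- function(reads) {
  if (is.character(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  full <- names(reads)
  if (is.null(full)) full <- paste0("read_", seq_along(reads))
  list(sequences = reads,
       read_id = vapply(strsplit(full, "\\s+"), `[`, character(1), 1L),
       lengths = Biostrings::width(reads))
}
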