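#' Per-genome identity and spatial coverage diagnostics
#'
#' For each genome with assigned reads: a histogram of estimated alignment
#' identities (bins of width 0.01 over \[0, 1\]), the median identity, and
#' mean sequencing depth per fixed-size contig window (placed bases
#' overlapping the window divided by window size, read intervals clipped at
#' contig boundaries). A stark identity shift away from `1 - error rate`
#' together with uneven coverage flags a database-sample mismatch.
#'
#' @param assignments data.frame of final read placements with columns
#'   `genome_id`, `contig_id`, `start`, `end`, `identity_hat` (e.g.
#'   `finalize_composition()$assignments`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param genome_of_contig Named character vector mapping contig to genome
#'   (needed to emit empty diagnostics for covered contigs; defaults to the
#'   genomes seen in `assignments`).
#' @param window Window size in bases (default 1000).
#' @return Named list per genome, each with `identity_hist` (data.table
#'   `bin_lo`, `bin_hi`, `count`; counts sum to the genome's assigned
#'   reads), `median_identity`, `n_reads` and `coverage` (data.table
#'   `contig_id`, `window_start`, `depth`).
#' @export
genome_diagnostics <- function(assignments, contig_lengths,
                               genome_of_contig = NULL, window = 1000L) {
  asn <- as.data.table(assignments)
  genomes <- sort(unique(asn$genome_id))
  brk <- seq(0, 1, by = 0.01)
  out <- lapply(genomes, function(g) {
    a <- asn[genome_id == g]
    h <- hist_counts(a$identity_hat, brk)
    cov <- rbindlist(lapply(unique(a$contig_id), function(cid) {
      clen <- contig_lengths[[cid]]
      if (is.null(clen) || is.na(clen))
        stop("contig ", cid, " missing from contig_lengths")
      nw <- ceiling(clen / window)
      depth <- numeric(nw)
      ai <- a[contig_id == cid]
      s <- pmax(ai$start, 0L); e <- pmin(ai$end, clen)
      for (j in seq_along(s)) {
        if (e[j] <= s[j]) next
        w1 <- s[j] %/% window + 1L
        w2 <- (e[j] - 1L) %/% window + 1L
        for (wi in w1:w2) {
          lo <- (wi - 1L) * window
          depth[wi] <- depth[wi] + min(e[j], lo + window) - max(s[j], lo)
        }
      }
      data.table(contig_id = cid,
                 window_start = (seq_len(nw) - 1L) * window,
                 depth = depth / window)
    }))
    list(identity_hist = h, median_identity = median(a$identity_hat),
         n_reads = nrow(a), coverage = cov)
  })
  names(out) <- genomes
  out
}

hist_counts <- function(x, brk) {
  bin <- pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE), 1L),
              length(brk) - 1L)
  data.table(bin_lo = brk[-length(brk)], bin_hi = brk[-1],
             count = tabulate(bin, nbins = length(brk) - 1L))
}

#' Count read placements overlapping annotated feature groups
#'
#' For every feature-group label (e.g. a COG category) attached to gene
#' annotations, counts how many read placements overlap (by at least
#' `min_overlap` bases, half-open intervals) a feature carrying that label.
#' A read counts toward every group it touches, but at most once per group
#' even when it spans several genes of the same group. Strand is ignored.
#'
#' @param assignments data.frame of read placements with columns `read_id`,
#'   `contig_id`, `start`, `end` (0-based half-open).
#' @param annotations Path to a GFF3 file or a `GRanges` with a group
#'   metadata column; multiple comma-separated labels per feature are
#'   split.
#' @param group_key Name of the GFF3 attribute holding the group label
#'   (default `"cog_category"`).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @param known_contigs Optional character vector of valid contig ids;
#'   features on unknown contigs are skipped with a warning.
#' @return data.table `group`, `read_count`, sorted by count.
#' @export
feature_overlap_counts <- function(assignments, annotations,
                                   group_key = "cog_category",
                                   min_overlap = 1L, known_contigs = NULL) {
  asn <- as.data.table(assignments)
  gr <- if (is.character(annotations))
    rtracklayer::import(annotations, format = "gff3") else annotations
  if (!group_key %in% names(S4Vectors::mcols(gr)))
    stop("annotation attribute '", group_key, "' not found")
  if (!is.null(known_contigs)) {
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% known_contigs)
    if (any(bad)) {
      warning(sum(bad), " feature(s) on contigs absent from the database; ",
              "skipped")
      gr <- gr[!bad]
    }
  }
  reads_gr <- GenomicRanges::GRanges(
    seqnames = asn$contig_id,
    ranges = IRanges::IRanges(start = asn$start + 1L, end = asn$end))
  hits <- GenomicRanges::findOverlaps(reads_gr, gr,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.table(group = character(), read_count = integer()))
  lab <- as.character(S4Vectors::mcols(gr)[[group_key]][
    S4Vectors::subjectHits(hits)])
  pairs <- data.table(read_id = asn$read_id[S4Vectors::queryHits(hits)],
                      group = lab)
  pairs <- pairs[!is.na(group) & nzchar(group)]
  pairs <- pairs[, .(group = unlist(strsplit(group, ","))), by = read_id]
  pairs[, group := trimws(group)]
  pairs <- unique(pairs)
  out <- pairs[, .(read_count = .N), by = group]
  setorder(out, -read_count, group)
  out[]
}
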