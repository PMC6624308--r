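#' Effective start positions of a read in a genome
#'
#' The number of distinct positions at which a read could start within a
#' genome: contig length minus read length, summed over all contigs
#' (contigs are treated as linear; circular and non-circular contigs are
#' not distinguished). Each contig's contribution is clamped to at least 1
#' so the likelihood stays defined when a read is longer than a contig.
#'
#' @param read_length Read length in bases.
#' @param contig_lengths Integer vector of the genome's contig lengths.
#' @return Positive integer count `E_{r;g}`.
#' @examples
#' effective_start_positions(1000, 10000)        # 9000
#' effective_start_positions(1000, c(5000, 3000)) # 6000
#' effective_start_positions(1000, 800)          # 1 (clamped)
#' @export
effective_start_positions <- function(read_length, contig_lengths) {
  stopifnot(length(contig_lengths) >= 1L)
  sum(pmax(contig_lengths - read_length, 1))
}

#' Likelihood of one read under a sample composition
#'
#' `L(r; F) = sum_g sum_{i in map(r,g)} P_r(i) * (1 / E_{r;g}) * F_g`: the
#' probability of the read under the composition-dependent prior, summing
#' its mapping qualities weighted by the abundance of each candidate's
#' genome and the genome-size regularizer `E_{r;g}`.
#'
#' @param candidates One read's candidates: data.frame with columns
#'   `genome_id`, `mapping_quality`, `eff_starts`.
#' @param F_vec Named numeric vector: composition over genomes.
#' @return The likelihood (double).
#' @export
read_likelihood <- function(candidates, F_vec) {
  stopifnot(nrow(candidates) >= 1L)
  sum(candidates$mapping_quality / candidates$eff_starts *
        F_vec[candidates$genome_id])
}

#' Composition-dependent posterior over one read's mapping locations
#'
#' `P_r(i; F)` is each candidate's term of [read_likelihood()] divided by
#' their sum. If all terms are zero (every candidate genome has zero
#' abundance) the posterior is uniform over the candidates, with a warning.
#'
#' @inheritParams read_likelihood
#' @return Numeric vector of posteriors (sums to 1).
#' @export
composition_posterior <- function(candidates, F_vec) {
  w <- candidates$mapping_quality / candidates$eff_starts *
    F_vec[candidates$genome_id]
  s <- sum(w)
  if (s <= 0) {
    warning("degenerate posterior denominator; using uniform posterior")
    return(rep(1 / length(w), length(w)))
  }
  unname(w / s)
}

#' One EM update of the composition vector
#'
#' `F'_g = sum_r sum_{i in map(r,g)} P_r(i; F) / |R|` over the mapped read
#' set `R`.
#'
#' @param candidates All candidates of all mapped reads: data.table with
#'   columns `read_id`, `genome_id`, `mapping_quality`, `eff_starts`.
#' @param F_vec Named numeric vector over genomes (must cover all candidate
#'   genomes).
#' @return Named numeric vector `F'` over the same genomes (sums to 1).
#' @export
em_update <- function(candidates, F_vec) {
  st <- em_step(as.data.table(candidates), F_vec)
  st$F_new
}

# shared E-step/M-step: returns posteriors, updated F and log-likelihood
em_step <- function(cands, F_vec) {
  cands <- copy(cands)
  cands[, num := mapping_quality / eff_starts * F_vec[genome_id]]
  cands[, den := sum(num), by = read_id]
  n_degenerate <- cands[den <= 0, uniqueN(read_id)]
  if (n_degenerate > 0L) {
    warning(n_degenerate, " read(s) with zero-probability candidates; ",
            "using uniform posteriors for them this iteration")
    cands[den <= 0, posterior := 1 / .N, by = read_id]
  }
  cands[den > 0, posterior := num / den]
  n_reads <- uniqueN(cands$read_id)
  upd <- cands[, .(mass = sum(posterior)), by = genome_id]
  F_new <- setNames(numeric(length(F_vec)), names(F_vec))
  F_new[upd$genome_id] <- upd$mass / n_reads
  per_read <- cands[, .(den = den[1]), by = read_id]
  ll <- sum(log(pmax(per_read$den, .Machine$double.xmin)))
  list(F_new = F_new, posteriors = cands$posterior, loglik = ll,
       cands = cands)
}

#' Estimate sample composition by EM
#'
#' Starting from the uniform composition `1/|G|` over all database genomes,
#' iterates [em_update()] until the relative improvement of the total
#' log-likelihood falls below `tolerance` or `max_iter` is reached. Mapping
#' qualities and effective start counts are computed once and held fixed;
#' only the composition changes across iterations.
#'
#' @param mappings A [map_reads()] result (or a data.table of candidates
#'   with columns `read_id`, `genome_id`, `mapping_quality` plus
#'   `read_length` if `eff_starts` is absent).
#' @param genome_contigs Named list of per-genome contig-length vectors
#'   defining the genome universe `G` (e.g. [index_contig_lengths()]);
#'   defaults to the candidate genomes only.
#' @param tolerance Relative log-likelihood convergence threshold
#'   (default 1e-5).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `em_fit`: `F` (named composition over `G`,
#'   sums to 1), `candidates` (with `posterior` column), `loglik` trace,
#'   `converged`, `n_reads`.
#' @export
run_em <- function(mappings, genome_contigs = NULL, tolerance = 1e-5,
                   max_iter = 500L) {
  cands <- em_candidates(mappings, genome_contigs)
  if (nrow(cands) == 0L) stop("no mapped reads; nothing to estimate")
  genomes <- if (!is.null(genome_contigs)) names(genome_contigs) else
    sort(unique(cands$genome_id))
  F_vec <- setNames(rep(1 / length(genomes), length(genomes)), genomes)
  ll_trace <- numeric(0)
  converged <- FALSE
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- em_step(cands, F_vec)
    ll_trace <- c(ll_trace, st$loglik)
    F_vec <- st$F_new
    if (it > 1L) {
      prev <- ll_trace[it - 1L]
      rel <- abs(st$loglik - prev) / max(1, abs(prev))
      if (rel < tolerance) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")
  out_cands <- st$cands[, !c("num", "den")]
  structure(list(F = F_vec, candidates = out_cands, loglik = ll_trace,
                 converged = converged, n_reads = uniqueN(cands$read_id)),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat("<em_fit> ", length(x$F), " genomes, ", x$n_reads, " mapped reads, ",
      length(x$loglik), " iterations (",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

em_candidates <- function(mappings, genome_contigs) {
  cands <- if (inherits(mappings, "read_mappings")) {
    ci <- copy(mappings$candidates)
    rl <- setNames(mappings$reads$read_length, mappings$reads$read_id)
    ci[, read_length := rl[read_id]]
    ci
  } else copy(as.data.table(mappings))
  if (!"eff_starts" %in% names(cands)) {
    if (is.null(genome_contigs))
      stop("genome_contigs required to compute effective start positions")
    pairs <- unique(cands[, .(read_id, genome_id, read_length)])
    pairs[, eff_starts := mapply(effective_start_positions, read_length,
                                 genome_contigs[genome_id])]
    cands[pairs, eff_starts := i.eff_starts, on = .(read_id, genome_id)]
  }
  cands
}

#' Finalize composition and per-read assignments
#'
#' Adds the "unassigned" bin (special taxon id 0): unmapped reads of
#' sufficient length and sub-length reads are counted to taxon 0, and the
#' composition is rescaled so that all bins sum to 1 over the complete set
#' of input reads. Each mapped read is assigned to its maximum-posterior
#' location (ties broken by higher mapping quality, then lexicographic
#' genome, contig and start, so assignment is deterministic).
#'
#' @param fit An [run_em()] `em_fit`.
#' @param mappings The [map_reads()] result the fit was computed from.
#' @param taxonomy Optional [load_taxonomy()] object; if supplied,
#'   assignments carry the strain-level `taxon_id` of their genome.
#' @param denominator `"all-reads"` (default: sub-length reads count toward
#'   the unassigned bin) or `"long-reads"` (sub-length reads excluded from
#'   the denominator).
#' @return An object of class `sample_composition`: `composition`
#'   (data.table `genome_id`, `fraction`, `read_count`),
#'   `unassigned_fraction`, `assignments` (one row per mapped read) and
#'   counts.
#' @export
finalize_composition <- function(fit, mappings, taxonomy = NULL,
                                 denominator = c("all-reads", "long-reads")) {
  denominator <- match.arg(denominator)
  reads <- mappings$reads
  n_mapped <- sum(reads$status == "mapped")
  n_unmapped <- sum(reads$status == "unmapped")
  n_short <- sum(reads$status == "too_short")
  n_total <- if (denominator == "all-reads") nrow(reads) else
    n_mapped + n_unmapped
  stopifnot(n_mapped == fit$n_reads)

  cands <- copy(fit$candidates)
  tie_cols <- intersect(c("genome_id", "contig_id", "start"), names(cands))
  setorderv(cands, c("read_id", "posterior", "mapping_quality", tie_cols),
            order = c(1L, -1L, -1L, rep(1L, length(tie_cols))))
  assignments <- cands[, .SD[1], by = read_id]
  assignments[, read_length := setNames(reads$read_length,
                                        reads$read_id)[read_id]]
  if (!is.null(taxonomy))
    assignments[, taxon_id := taxon_of_genome(taxonomy, genome_id)]

  counts <- assignments[, .(read_count = .N), by = genome_id]
  comp <- data.table(genome_id = names(fit$F),
                     fraction = unname(fit$F) * n_mapped / n_total)
  comp[counts, read_count := i.read_count, on = "genome_id"]
  comp[is.na(read_count), read_count := 0L]
  unassigned <- (n_total - n_mapped) / n_total
  structure(list(composition = comp, unassigned_fraction = unassigned,
                 assignments = assignments, n_total = n_total,
                 n_mapped = n_mapped, n_unmapped = n_unmapped,
                 n_too_short = n_short, denominator = denominator),
            class = "sample_composition")
}

#' @export
print.sample_composition <- function(x, ...) {
  cat("<sample_composition> ", nrow(x$composition), " genomes; unassigned ",
      sprintf("%.4f", x$unassigned_fraction), " of ", x$n_total,
      " reads\n", sep = "")
  invisible(x)
}

#' Project a composition to a taxonomic level
#'
#' Sums genome fractions into buckets defined by [to_level()] of each
#' genome's strain node; mass whose projection is 0 joins the unassigned
#' bin. The output sums to 1.
#'
#' @param composition A [finalize_composition()] object.
#' @param taxonomy A [load_taxonomy()] object covering all genomes.
#' @param level Target rank (see [to_level()]).
#' @return data.table with columns `taxon_id` (0 = unassigned), `name`,
#'   `level`, `fraction`, `read_count`.
#' @export
project_composition <- function(composition, taxonomy, level) {
  comp <- copy(composition$composition)
  comp[, taxon_id := to_level(taxonomy,
                              taxon_of_genome(taxonomy, genome_id), level)]
  out <- comp[, .(fraction = sum(fraction), read_count = sum(read_count)),
              by = taxon_id]
  ua <- data.table(taxon_id = 0L,
                   fraction = composition$unassigned_fraction,
                   read_count = composition$n_total - composition$n_mapped)
  out <- rbind(out[taxon_id != 0L], {
    z <- out[taxon_id == 0L]
    if (nrow(z)) data.table(taxon_id = 0L,
                            fraction = z$fraction + ua$fraction,
                            read_count = z$read_count + ua$read_count)
    else ua
  })
  nm <- setNames(taxonomy$nodes$name, taxonomy$nodes$taxon_id)
  out[, name := ifelse(taxon_id == 0L, "unassigned",
                       nm[as.character(taxon_id)])]
  out[, level := level]
  setorder(out, -fraction)
  out[, .(taxon_id, name, level, fraction, read_count)]
}

#' Median estimated identity per genome from final assignments
#'
#' @param composition A [finalize_composition()] object.
#' @return data.table `genome_id`, `median_identity`, `read_count`.
#' @export
genome_median_identities <- function(composition) {
  composition$assignments[, .(median_identity = median(identity_hat),
                              read_count = .N), by = genome_id]
}

#' Remove low-identity genomes from a composition
#'
#' Database-sample mismatches (reads from strains or species absent from
#' the database) show up as genomes whose assigned reads have low median
#' estimated alignment identity. This filter removes strain entries with a
#' median identity below `threshold` (and thereby their contributions at
#' every higher taxonomic level obtained via [project_composition()]),
#' moving the removed mass to the unassigned bin so bins still sum to 1.
#'
#' @param composition A [finalize_composition()] object.
#' @param medians Optional data.table as from [genome_median_identities()];
#'   computed from the assignments when `NULL`.
#' @param threshold Median-identity cutoff (default 0.80); 0 disables the
#'   filter.
#' @return A new `sample_composition` with filtered entries zeroed and
#'   their mass added to `unassigned_fraction`; filtered genomes' reads are
#'   dropped from `assignments`.
#' @export
filter_composition_by_identity <- function(composition, medians = NULL,
                                           threshold = 0.80) {
  if (is.null(medians)) medians <- genome_median_identities(composition)
  drop <- medians[median_identity < threshold, genome_id]
  out <- composition
  if (length(drop)) {
    comp <- copy(composition$composition)
    moved <- comp[genome_id %in% drop, sum(fraction)]
    comp[genome_id %in% drop, `:=`(fraction = 0, read_count = 0L)]
    out$composition <- comp
    out$unassigned_fraction <- composition$unassigned_fraction + moved
    out$assignments <- composition$assignments[!genome_id %in% drop]
    out$n_mapped <- nrow(out$assignments)
  }
  out
}

#' Classify a read set end to end
#'
#' Convenience pipeline: [map_reads()], [run_em()],
#' [finalize_composition()] and (optionally) the median-identity filter.
#'
#' @param reads Reads (path or `DNAStringSet`).
#' @param index A `minimizer_index` or `chunked_index`.
#' @param taxonomy Optional [load_taxonomy()] object.
#' @param min_identity_filter Median-identity threshold for
#'   [filter_composition_by_identity()]; `NULL` (default) disables it.
#' @param tolerance,max_iter Passed to [run_em()].
#' @return A `sample_composition` (with the `em_fit` attached as `$fit`
#'   and the `read_mappings` as `$mappings`).
#' @export
classify_sample <- function(reads, index, taxonomy = NULL,
                            min_identity_filter = NULL, tolerance = 1e-5,
                            max_iter = 500L) {
  mp <- map_reads(reads, index)
  fit <- run_em(mp, genome_contigs = index_contig_lengths(index),
                tolerance = tolerance, max_iter = max_iter)
  res <- finalize_composition(fit, mp, taxonomy)
  if (!is.null(min_identity_filter))
    res <- filter_composition_by_identity(res,
                                          threshold = min_identity_filter)
  res$fit <- fit
  res$mappings <- mp
  res
}
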