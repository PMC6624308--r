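#' Read-level precision, recall and precision2 at a taxonomic level
#'
#' An assignment is correct at level `l` iff the level-`l` projections
#' ([to_level()]) of the inferred and true taxa agree. Precision is the
#' fraction of correct assignments among reads that have an assignment
#' (`V'`); recall is the fraction among all truth reads (`V`); precision2
#' is the fraction among reads whose inferred assignment projects to a
#' non-0 taxon at level `l` (`V''(l)`), i.e. the accuracy of the calls that
#' actually name a taxon at that level. Reads absent from `assignments`
#' are in `V` but not `V'` (unassigned without an assignment record).
#'
#' @param assignments data.frame with columns `read_id`, `taxon_id`
#'   (0 allowed) and, for base-level metrics, `read_length`.
#' @param truth data.frame with columns `read_id`, `taxon_id`
#'   (0 allowed) and `read_length`; must cover all assigned reads.
#' @param taxonomy A [load_taxonomy()] object.
#' @param level Target rank.
#' @param weights `"reads"` (each read counts 1) or `"bases"` (each read
#'   counts its length).
#' @return Named list: `precision`, `recall`, `precision2` (NA when the
#'   corresponding denominator is empty), plus the denominator sizes.
#' @export
read_metrics <- function(assignments, truth, taxonomy, level,
                         weights = c("reads", "bases")) {
  weights <- match.arg(weights)
  asn <- as.data.table(assignments)
  tr <- as.data.table(truth)
  missing <- setdiff(asn$read_id, tr$read_id)
  if (length(missing))
    stop("assigned read(s) absent from truth: ",
         paste(head(missing, 5), collapse = ", "))
  tr[, true_l := to_level(taxonomy, taxon_id, level)]
  asn[, inf_l := to_level(taxonomy, taxon_id, level)]
  stopifnot(all(tr$read_length >= 1))
  wt <- if (weights == "bases")
    setNames(as.numeric(tr$read_length), tr$read_id)
  else setNames(rep(1, nrow(tr)), tr$read_id)

  m <- tr[asn, on = "read_id"]  # V' rows
  m[, correct := as.integer(true_l == inf_l)]
  W <- sum(wt)
  W1 <- sum(wt[m$read_id])
  W2 <- sum(wt[m$read_id[m$inf_l != 0L]])
  list(precision = if (W1 > 0) sum(wt[m$read_id] * m$correct) / W1 else NA,
       recall = if (W > 0) sum(wt[m$read_id] * m$correct) / W else NA,
       precision2 = if (W2 > 0) {
         m2 <- m[inf_l != 0L]
         sum(wt[m2$read_id] * m2$correct) / W2
       } else NA,
       n_truth = W, n_assigned = W1, n_nonzero = W2)
}

#' Base-weighted read metrics
#'
#' Read-length-reweighted precision, recall and precision2: identical to
#' [read_metrics()] with each read weighted by its length in bases.
#'
#' @inheritParams read_metrics
#' @return As [read_metrics()].
#' @export
base_metrics <- function(assignments, truth, taxonomy, level) {
  read_metrics(assignments, truth, taxonomy, level, weights = "bases")
}

#' Compositional accuracy: L1 distance and Pearson r-squared
#'
#' Both vectors must be compositions at the same taxonomic level (each
#' summing to 1, taxon 0 bin included). Metrics are computed over the
#' columns that are > 0 in either vector: `L1 = sum |est - true|` and `r2 =
#' cor(est, true)^2`.
#'
#' @param estimate,truth Named numeric vectors (names = taxon ids, "0"
#'   allowed) or data.frames with columns `taxon_id`, `fraction`.
#' @return List `l1`, `r2` (`r2` is NA when fewer than 2 support columns).
#' @export
composition_metrics <- function(estimate, truth) {
  est <- as_comp_vector(estimate)
  tru <- as_comp_vector(truth)
  keys <- union(names(est), names(tru))
  e <- setNames(numeric(length(keys)), keys); e[names(est)] <- est
  t2 <- setNames(numeric(length(keys)), keys); t2[names(tru)] <- tru
  sup <- keys[e > 0 | t2 > 0]
  l1 <- sum(abs(e[sup] - t2[sup]))
  r2 <- if (length(sup) >= 2 && stats::sd(e[sup]) > 0 &&
            stats::sd(t2[sup]) > 0) cor(e[sup], t2[sup])^2 else NA_real_
  list(l1 = l1, r2 = r2)
}

#' Presence/absence accuracy of a compositional estimate
#'
#' A taxon is called present when its abundance is strictly greater than
#' `min_abundance` (default 0). Binary precision is the fraction of
#' predicted taxa that are truly present; binary recall the fraction of
#' true taxa that are predicted. The unassigned bin (taxon 0) is excluded.
#'
#' @inheritParams composition_metrics
#' @param min_abundance Presence threshold (abundance must exceed it).
#' @return List `binary_precision` (NA if nothing is predicted),
#'   `binary_recall` (NA if the truth support is empty).
#' @export
binary_metrics <- function(estimate, truth, min_abundance = 0) {
  est <- as_comp_vector(estimate)
  tru <- as_comp_vector(truth)
  pred <- setdiff(names(est)[est > min_abundance], "0")
  real <- setdiff(names(tru)[tru > min_abundance], "0")
  hit <- length(intersect(pred, real))
  list(binary_precision = if (length(pred)) hit / length(pred) else NA,
       binary_recall = if (length(real)) hit / length(real) else NA)
}

as_comp_vector <- function(x) {
  if (is.data.frame(x)) {
    x <- as.data.table(x)
    v <- setNames(x$fraction, as.character(x$taxon_id))
  } else {
    v <- x
    if (is.null(names(v))) stop("composition vector must be named")
  }
  tapply(v, names(v), sum)[unique(names(v))]
}

#' Project a truth table of per-read taxa to a compositional truth vector
#'
#' @param truth data.frame `read_id`, `taxon_id`, `read_length`.
#' @param taxonomy A [load_taxonomy()] object.
#' @param level Target rank.
#' @return Named numeric composition (fractions of reads per level-`l`
#'   taxon; projection 0 becomes the "0" bin). Sums to 1.
#' @export
truth_composition <- function(truth, taxonomy, level) {
  tr <- as.data.table(truth)
  tr[, tl := to_level(taxonomy, taxon_id, level)]
  tab <- tr[, .N, by = tl]
  setNames(tab$N / sum(tab$N), as.character(tab$tl))
}

#' Full evaluation report across taxonomic levels
#'
#' @param assignments data.frame `read_id`, `taxon_id`, `read_length`.
#' @param truth data.frame `read_id`, `taxon_id`, `read_length` covering
#'   the validation set.
#' @param composition Optional estimated composition per level: a
#'   data.frame from [project_composition()] covering `levels`, or a
#'   `sample_composition` plus `taxonomy` to project internally.
#' @param taxonomy A [load_taxonomy()] object.
#' @param levels Character vector of ranks to evaluate.
#' @return data.table with one row per level: read- and base-weighted
#'   precision/recall/precision2 and (when a composition is supplied)
#'   `l1`, `r2`, `binary_precision`, `binary_recall`.
#' @export
evaluate_assignments <- function(assignments, truth, taxonomy,
                                 levels = c("strain", "species", "genus",
                                            "family"),
                                 composition = NULL) {
  rows <- lapply(levels, function(l) {
    rm_ <- read_metrics(assignments, truth, taxonomy, l)
    bm <- base_metrics(assignments, truth, taxonomy, l)
    row <- data.table(level = l, precision = rm_$precision,
                      recall = rm_$recall, precision2 = rm_$precision2,
                      precision_bases = bm$precision,
                      recall_bases = bm$recall,
                      precision2_bases = bm$precision2)
    if (!is.null(composition)) {
      est <- if (inherits(composition, "sample_composition"))
        project_composition(composition, taxonomy, l) else
          as.data.table(composition)[level == l]
      tru <- truth_composition(truth, taxonomy, l)
      cm <- composition_metrics(est, tru)
      bn <- binary_metrics(est, tru)
      row[, `:=`(l1 = cm$l1, r2 = cm$r2,
                 binary_precision = bn$binary_precision,
                 binary_recall = bn$binary_recall)]
    }
    row
  })
  rbindlist(rows, fill = TRUE)
}
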