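# Amplicon responder screen: relative abundances, phylotype merging,
# increase-over-control detection, time averaging and diversity summaries.

.check_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a taxa x samples matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  invisible(counts)
}

#' Per-sample relative abundances
#'
#' Taxa whose total count across all samples is 1 (global singletons) are
#' removed before normalization, mirroring standard amplicon practice of
#' excluding likely-spurious phylotypes.
#'
#' @param counts taxa x samples integer matrix with dimnames.
#' @param drop_singletons remove global singletons first (default TRUE).
#' @return matrix of proportions; each column sums to 1.
#' @export
relative_abundances <- function(counts, drop_singletons = TRUE) {
  .check_counts(counts)
  if (drop_singletons) {
    counts <- counts[rowSums(counts) != 1, , drop = FALSE]
  }
  tot <- colSums(counts)
  zero <- colnames(counts)[tot == 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  }
  sweep(counts, 2, tot, "/")
}

#' Merge near-identical phylotypes by a similarity matrix
#'
#' Phylotype pairs at or above the similarity threshold are linked, and
#' connected components of the resulting graph (single linkage) are
#' merged by summing their counts. The merged taxon takes the label of
#' its most abundant member (ties: first in row order).
#'
#' @param counts taxa x samples integer matrix.
#' @param sim symmetric phylotype x phylotype similarity matrix in
#'   `[0, 1]` with unit diagonal, covering all taxa in `counts`.
#' @param threshold merge threshold as a fraction (default 0.97).
#' @return merged count matrix; `attr(, "members")` maps each merged
#'   label to its component members.
#' @export
merge_phylotypes <- function(counts, sim, threshold = 0.97) {
  .check_counts(counts)
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    stop("sim must be a square matrix")
  }
  if (is.null(rownames(sim)) ||
      !all(rownames(counts) %in% rownames(sim))) {
    stop("similarity matrix does not cover all phylotypes")
  }
  sim <- sim[rownames(counts), rownames(counts), drop = FALSE]
  if (max(abs(sim - t(sim))) > 1e-9) stop("similarity matrix not symmetric")
  if (any(abs(diag(sim) - 1) > 1e-12)) stop("similarity diagonal must be 1")
  if (any(sim < 0 | sim > 1)) stop("similarities must lie in [0, 1]")

  n <- nrow(counts)
  adj <- sim >= threshold
  # connected components by breadth-first search on the small graph
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    nc <- nc + 1L
    queue <- v
    comp[v] <- nc
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[u, ] & is.na(comp))
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  labels <- character(nc)
  members <- vector("list", nc)
  for (k in seq_len(nc)) {
    idx <- which(comp == k)
    members[[k]] <- rownames(counts)[idx]
    best <- idx[which.max(rowSums(counts)[idx])]
    labels[k] <- rownames(counts)[best]
  }
  merged <- rowsum(counts, group = comp, reorder = TRUE)
  rownames(merged) <- labels
  names(members) <- labels
  structure(merged, members = members)
}

#' Aggregate a count or abundance matrix to a higher taxonomic rank
#'
#' @param x taxa x samples matrix (counts or proportions).
#' @param taxonomy data.frame with a `taxon` column and rank columns
#'   (e.g. `phylum`, `family`); unassigned ranks should carry an explicit
#'   `"unclassified"` sentinel.
#' @param rank name of the taxonomy column to aggregate by.
#' @return rank x samples matrix of summed values.
#' @export
aggregate_taxa <- function(x, taxonomy, rank = "family") {
  if (!all(c("taxon", rank) %in% names(taxonomy))) {
    stop("taxonomy needs columns 'taxon' and ", sQuote(rank))
  }
  missing <- setdiff(rownames(x), taxonomy$taxon)
  if (length(missing) > 0) {
    stop("taxa not resolvable in taxonomy: ", paste(missing, collapse = ", "))
  }
  grp <- taxonomy[[rank]][match(rownames(x), taxonomy$taxon)]
  rowsum(x, group = grp, reorder = TRUE)
}

#' Responsive taxa: increase over the paired control
#'
#' A taxon is responsive when its relative abundance in the treatment arm
#' exceeds the paired control by at least `threshold_pp` percentage
#' points in at least one sampling period. The conventional thresholds
#' are 5 pp at the family level and 2 pp at the phylotype level. The
#' increase is the absolute difference of abundances in percent, not a
#' fold change.
#'
#' @param treatment,control taxa x periods matrices of relative
#'   abundances in percent, sharing dimnames (periods as columns).
#' @param threshold_pp responsiveness threshold in percentage points.
#' @param average_periods periods (column names) over which the
#'   time-averaged treatment abundance is reported; defaults to all
#'   periods except `"0"`.
#' @return `responsiveness_report` data.frame: `taxon`,
#'   `max_increase_pp`, `period_at_max`, `responsive`, `threshold_pp`,
#'   `time_averaged_pct`.
#' @export
responsive_taxa <- function(treatment, control, threshold_pp = 5,
                            average_periods = NULL) {
  if (!identical(dim(treatment), dim(control)) ||
      !identical(dimnames(treatment), dimnames(control))) {
    stop("treatment and control must share taxa and sampling periods")
  }
  if (is.null(colnames(treatment))) stop("period column names required")
  diff <- treatment - control
  max_inc <- apply(diff, 1, max)
  at <- colnames(diff)[apply(diff, 1, which.max)]
  if (is.null(average_periods)) {
    average_periods <- setdiff(colnames(treatment), "0")
  }
  avg <- time_averaged_abundance(treatment, average_periods)
  out <- data.frame(taxon = rownames(treatment),
                    max_increase_pp = unname(max_inc),
                    period_at_max = at,
                    responsive = unname(max_inc >= threshold_pp),
                    threshold_pp = threshold_pp,
                    time_averaged_pct = unname(avg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("responsiveness_report", "data.frame")
  out
}

#' Time-averaged relative abundance
#'
#' Arithmetic mean of abundances over the listed sampling periods (the
#' 0-h baseline is conventionally excluded by the caller).
#'
#' @param x taxa x periods abundance matrix (periods as column names).
#' @param periods character or numeric vector of periods to average.
#' @return named numeric vector, one mean per taxon.
#' @export
time_averaged_abundance <- function(x, periods) {
  periods <- as.character(periods)
  missing <- setdiff(periods, colnames(x))
  if (length(missing) > 0) {
    stop("sampling period(s) absent from the series: ",
         paste(missing, collapse = ", "))
  }
  rowMeans(x[, periods, drop = FALSE])
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln(p_i))` over taxa with positive counts, in nats.
#'
#' @param counts integer count vector for one sample.
#' @return Shannon index (natural log).
#' @export
#' @examples
#' shannon_index(c(25, 25, 25, 25))  # ln(4)
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stop("sample total must be > 0")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Expected richness: analytic rarefaction or Chao1
#'
#' Rarefaction gives the expected number of taxa observed in a random
#' subsample of `depth` reads without replacement (hypergeometric
#' expectation). Chao1 estimates total richness from singleton and
#' doubleton counts: `S_obs + F1^2 / (2 * F2)`, with the bias-corrected
#' form `S_obs + F1 * (F1 - 1) / 2` when no doubletons exist.
#'
#' @param counts integer count vector for one sample.
#' @param depth rarefaction depth (reads); required for
#'   `mode = "rarefaction"` and must not exceed the sample total.
#' @param mode `"rarefaction"` or `"chao1"`.
#' @return expected taxa count (real-valued).
#' @export
#' @examples
#' expected_richness(c(5, 5, 5, 5), depth = 1)   # 1.0
#' expected_richness(c(4, 4, rep(1, 4), 2, 2, 9, 9), mode = "chao1")
expected_richness <- function(counts, depth = NULL,
                              mode = c("rarefaction", "chao1")) {
  mode <- match.arg(mode)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total <= 0) stop("sample total must be > 0")
  if (mode == "rarefaction") {
    if (is.null(depth)) stop("rarefaction requires a depth")
    if (depth > total) stop("depth (", depth, ") exceeds sample total (",
                            total, ")")
    # E[S] = sum_i 1 - C(N - n_i, d) / C(N, d), via lchoose for stability
    p_absent <- exp(lchoose(total - counts, depth) - lchoose(total, depth))
    p_absent[total - counts < depth] <- 0
    sum(1 - p_absent)
  } else {
    s_obs <- length(counts)
    f1 <- sum(counts == 1)
    f2 <- sum(counts == 2)
    if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  }
}

#' Per-arm relative-abundance series from a count table
#'
#' Convenience wrapper: computes relative abundances in percent across
#' the whole table, then splits samples into treatment and control arms
#' and orders periods. When an arm has several samples for one period
#' (replicates at the final time point), their abundances are averaged.
#'
#' @param counts taxa x samples matrix.
#' @param metadata data.frame with columns `sample`, `arm`
#'   (`"treatment"`/`"control"`), `time_h`.
#' @param drop_singletons passed to [relative_abundances()].
#' @return list of two taxa x periods matrices (`treatment`, `control`)
#'   in percent, with period column names.
#' @export
arm_abundance_series <- function(counts, metadata, drop_singletons = TRUE) {
  req <- c("sample", "arm", "time_h")
  if (!all(req %in% names(metadata))) {
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(colnames(counts) %in% metadata$sample)) {
    stop("every sample column must appear in the metadata")
  }
  rel <- relative_abundances(counts, drop_singletons = drop_singletons) * 100
  periods <- sort(unique(metadata$time_h))
  one_arm <- function(arm) {
    m <- sapply(periods, function(tp) {
      ids <- metadata$sample[metadata$arm == arm & metadata$time_h == tp]
      if (length(ids) == 0) {
        stop("arm ", sQuote(arm), " has no sample at ", tp, " h")
      }
      rowMeans(rel[, ids, drop = FALSE])
    })
    colnames(m) <- as.character(periods)
    m
  }
  list(treatment = one_arm("treatment"), control = one_arm("control"))
}
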