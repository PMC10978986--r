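# From alignment/coverage evidence to presence, abundance and activity
# matrices ready for network inference.

#' Nucleotide identity of an alignment
#'
#' Identity ignoring ambiguous reference bases but counting gaps:
#' `1 - (NM - XN) / L`, where NM is the edit distance, XN the number of
#' ambiguous (N) reference bases in the alignment and L the read length.
#' Edits at ambiguous positions are not held against the read.
#'
#' @param L Read length(s), > 0.
#' @param NM Edit distance(s).
#' @param XN Ambiguous reference base count(s).
#' @return Identity fraction(s) in \[0, 1\].
#' @export
alignment_identity <- function(L, NM, XN = 0) {
  stop_if_not(all(L > 0), "L must be > 0")
  stop_if_not(all(XN >= 0 & XN <= NM & NM <= L),
              "need 0 <= XN <= NM <= L")
  1 - (NM - XN) / L
}

#' Filter alignment records for mapping specificity
#'
#' Keeps records with `MAPQ >= 20` and nucleotide identity `>= 0.95`
#' (both boundaries inclusive), the standard filter against non-specific
#' mappings.
#'
#' @param records Data frame with columns `L`, `NM`, `XN`, `MAPQ` (and
#'   typically `genome_id`).
#' @param min_mapq,min_identity Filter thresholds.
#' @return The kept rows; per-genome kept/discarded counts are attached as
#'   attribute `counts` when `genome_id` is present.
#' @export
filter_alignments <- function(records, min_mapq = 20, min_identity = 0.95) {
  ident <- alignment_identity(records$L, records$NM, records$XN)
  keep <- records$MAPQ >= min_mapq & ident >= min_identity
  out <- records[keep, , drop = FALSE]
  if ("genome_id" %in% names(records)) {
    counts <- as.data.frame(table(genome_id = records$genome_id, kept = keep))
    attr(out, "counts") <- counts
  }
  out
}

#' Depth and breadth of coverage from alignment spans
#'
#' Depth (vertical coverage) is the total number of aligned bases divided
#' by genome length; breadth (horizontal coverage) is the fraction of
#' genome positions covered at least once. Spans are 0-based half-open
#' (`start`, `end`).
#'
#' @param records Filtered alignment records with `genome_id`, `sample_id`,
#'   `start`, `end`.
#' @param genome_lengths Named numeric vector, genome id -> length.
#' @return Data frame (genome_id, sample_id, depth, breadth).
#' @export
coverage_from_alignments <- function(records, genome_lengths) {
  stop_if_not(all(records$genome_id %in% names(genome_lengths)),
              "unknown genome in records")
  grp <- split(records, list(records$genome_id, records$sample_id),
               drop = TRUE)
  out <- lapply(grp, function(g) {
    len <- genome_lengths[[g$genome_id[1]]]
    depth <- sum(g$end - g$start) / len
    # union of half-open spans
    ord <- order(g$start, g$end)
    s <- g$start[ord]; e <- g$end[ord]
    covered <- 0; cur_s <- s[1]; cur_e <- e[1]
    if (length(s) > 1) for (i in 2:length(s)) {
      if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
      else { covered <- covered + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
    }
    covered <- covered + (cur_e - cur_s)
    data.frame(genome_id = g$genome_id[1], sample_id = g$sample_id[1],
               depth = depth, breadth = covered / len,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$genome_id, res$sample_id), ]
}

#' Breadth-based genome detection
#'
#' A genome is observed (present and/or active) in a sample when at least
#' 30% of its genome is horizontally covered.
#'
#' @param breadth Breadth fraction(s) in \[0, 1\].
#' @param min_breadth Detection threshold (inclusive).
#' @return Logical vector.
#' @export
detect_genome <- function(breadth, min_breadth = 0.30) {
  stop_if_not(all(breadth >= 0 & breadth <= 1), "breadth must lie in [0,1]")
  breadth >= min_breadth
}

#' Genome abundance from metagenomic depth
#'
#' Depth of coverage already normalizes by genome length; the additional
#' per-million-base-pairs factor normalizes across samples by sequencing
#' effort: `abundance = depth / (sample_total_bases / 1e6)`. Invariant to
#' uniform rescaling of all depths in a sample.
#'
#' @param depth_mg Metagenomic depth(s), >= 0.
#' @param sample_total_bases Total mapped bases in the sample (> 0 when any
#'   depth is non-zero).
#' @return Abundance value(s).
#' @export
abundance <- function(depth_mg, sample_total_bases) {
  stop_if_not(all(depth_mg >= 0), "depth must be >= 0")
  stop_if_not(all(sample_total_bases > 0 | depth_mg == 0),
              "zero sample total with nonzero depth")
  ifelse(depth_mg == 0, 0, depth_mg / (sample_total_bases / 1e6))
}

#' Genome activity ratio
#'
#' Ratio of metatranscriptomic over metagenomic vertical coverage for a
#' genome present in the metagenome. No activity threshold is applied, so
#' null activity (0) is a valid value.
#'
#' @param depth_mt Metatranscriptomic depth(s), >= 0.
#' @param depth_mg Metagenomic depth(s), > 0 for present genomes.
#' @return Activity ratio(s).
#' @export
activity <- function(depth_mt, depth_mg) {
  stop_if_not(all(depth_mt >= 0), "metaT depth must be >= 0")
  stop_if_not(all(depth_mg > 0),
              "depth_mg = 0 for a present genome (inconsistent input)")
  depth_mt / depth_mg
}

#' Build abundance and activity matrices from coverage tables
#'
#' Converts metagenomic and metatranscriptomic coverage tables into
#' genomes-by-samples matrices with explicit missingness: cells where the
#' genome is unobserved (metagenomic breadth < `min_breadth`) are NA, and
#' genomes observed in fewer than `n_obs_min` samples are dropped,
#' independently per layer. The activity layer is restricted to samples
#' present in both tables (the metagenomic depth is its denominator).
#'
#' @param metaG,metaT Coverage data frames (genome_id, sample_id, depth,
#'   breadth); `metaT` may be NULL to build only the abundance layer.
#' @param n_obs_min Minimum observed samples per retained genome.
#' @param min_breadth Detection threshold.
#' @param normalization `"sample_million_bases"` (divide depths by total
#'   mapped sample megabases; needs `genome_lengths`) or `"none"`.
#' @param genome_lengths Named vector for the normalization option.
#' @return List with `abundance` and (when `metaT` given) `activity`
#'   matrices (genomes x samples, NA = unobserved), class `omics_matrix`
#'   each.
#' @export
build_matrices <- function(metaG, metaT = NULL, n_obs_min = 10,
                           min_breadth = 0.30,
                           normalization = c("sample_million_bases", "none"),
                           genome_lengths = NULL) {
  normalization <- match.arg(normalization)
  to_matrix <- function(df, field) {
    g <- sort(unique(df$genome_id)); s <- sort(unique(df$sample_id))
    m <- matrix(NA_real_, length(g), length(s), dimnames = list(g, s))
    m[cbind(match(df$genome_id, g), match(df$sample_id, s))] <- df[[field]]
    m
  }
  depth_g <- to_matrix(metaG, "depth")
  breadth_g <- to_matrix(metaG, "breadth")
  observed <- !is.na(breadth_g) & breadth_g >= min_breadth

  ab <- depth_g
  if (normalization == "sample_million_bases") {
    stop_if_not(!is.null(genome_lengths),
                "genome_lengths needed for sample_million_bases normalization")
    total <- colSums(depth_g * genome_lengths[rownames(depth_g)],
                     na.rm = TRUE)
    ab <- sweep(ab, 2, total / 1e6, "/")
  }
  ab[!observed] <- NA_real_
  keep <- rowSums(!is.na(ab)) >= n_obs_min
  ab <- ab[keep, , drop = FALSE]
  out <- list(abundance = structure(ab, class = c("omics_matrix", "matrix"),
                                    layer = "abundance",
                                    n_obs_min = n_obs_min))
  if (!is.null(metaT)) {
    depth_t <- to_matrix(metaT, "depth")
    shared <- intersect(colnames(depth_g), colnames(depth_t))
    stop_if_not(length(shared) > 0, "no samples shared between layers")
    shared_g <- intersect(rownames(depth_g), rownames(depth_t))
    act <- depth_t[shared_g, shared, drop = FALSE] /
      depth_g[shared_g, shared, drop = FALSE]
    obs_a <- observed[shared_g, shared, drop = FALSE] &
      !is.na(depth_g[shared_g, shared, drop = FALSE]) &
      depth_g[shared_g, shared, drop = FALSE] > 0
    act[!obs_a] <- NA_real_
    keep_a <- rowSums(!is.na(act)) >= n_obs_min
    act <- act[keep_a, , drop = FALSE]
    out$activity <- structure(act, class = c("omics_matrix", "matrix"),
                              layer = "activity", n_obs_min = n_obs_min)
  }
  out
}

#' Centred log-ratio transform with adaptive pseudo-count
#'
#' Per sample (column): zeros among observed values are replaced by half
#' the smallest non-zero observed value in that sample (adaptive
#' pseudo-count), values are logged and centred to zero mean over the
#' observed genomes. Masked (NA) cells remain NA and never contribute.
#' Scale-invariant per sample: multiplying a sample by a constant leaves
#' the output unchanged.
#'
#' @param mat Genomes x samples matrix with NA for unobserved cells.
#' @return Transformed matrix, same shape and NA pattern; observed values
#'   in each column sum to 0.
#' @export
clr_transform <- function(mat) {
  out <- mat
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    obs <- !is.na(v)
    if (!any(obs)) next
    x <- v[obs]
    stop_if_not(any(x > 0), "sample with all-zero observed values")
    pseudo <- min(x[x > 0]) / 2
    x[x == 0] <- pseudo
    lx <- log(x)
    out[obs, j] <- lx - mean(lx)
  }
  out
}
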