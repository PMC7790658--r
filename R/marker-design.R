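#' Contig-to-gene-model exon mapping tables
#'
#' Input to marker design: for each transcriptome contig, the ordered exons
#' of a single reference gene model it matched, with BLAST-style hit
#' metrics. One row per matched exon; hit metrics are per contig.
#'
#' @param df data frame with columns `contig_id`, `gene_model_id`,
#'   `exon_index` (position of the exon within the gene model, strictly
#'   increasing per contig), `length` (bp, positive), `start`, `end`
#'   (coordinates on the contig), `percent_identity`, `e_value`,
#'   `gap_count`, `multi_hit` (logical), `duplicate_contig` (logical).
#' @return A validated `contig_exon_map` data frame.
#' @export
contig_exon_map <- function(df) {
  req <- c("contig_id", "gene_model_id", "exon_index", "length",
           "start", "end", "percent_identity", "e_value", "gap_count",
           "multi_hit", "duplicate_contig")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop("exon lengths must be positive")
  by_contig <- split(df$exon_index, df$contig_id)
  nondec <- vapply(by_contig, function(x) any(diff(x) <= 0), logical(1))
  if (any(nondec))
    stop("exon indices not strictly increasing for contig: ",
         names(by_contig)[which(nondec)[1]])
  class(df) <- c("contig_exon_map", "data.frame")
  df
}

#' Assign exon-selection priorities per contig
#'
#' Implements the UTR-avoidance exon choice: contigs whose gene model
#' contains the exon more than twice are "priority 1" (with exactly three
#' matches the central exon is taken; with more, a seeded uniform choice
#' among the interior exons, i.e. excluding the first and last), contigs
#' with two matches are "priority 2" (the longest exon is taken), and
#' single-match contigs are "priority 3" (deprioritised, since a lone exon
#' gives no positional information and risks containing UTR).
#'
#' @param m a [contig_exon_map()] (may hold many contigs).
#' @param seed RNG seed for the interior-exon choice.
#' @return An `exon_selection` data frame: one row per contig with
#'   `contig_id`, `gene_model_id`, `exon_index`, `length`, `priority`,
#'   and the contig's hit metrics.
#' @export
assign_exon_priority <- function(m, seed = 1L) {
  stopifnot(inherits(m, "contig_exon_map"))
  if (nrow(m) == 0) stop("empty exon map")
  with_seed(seed, {
    pieces <- lapply(split(seq_len(nrow(m)), m$contig_id), function(idx) {
      rows <- m[idx[order(m$exon_index[idx])], , drop = FALSE]
      k <- nrow(rows)
      if (k > 2) {
        priority <- 1L
        pick <- if (k == 3) 2L else sample(2:(k - 1), 1L)
      } else if (k == 2) {
        priority <- 2L
        pick <- which.max(rows$length)
      } else {
        priority <- 3L
        pick <- 1L
      }
      cbind(rows[pick, c("contig_id", "gene_model_id", "exon_index", "length",
                         "percent_identity", "e_value", "gap_count",
                         "multi_hit", "duplicate_contig")],
            priority = priority, n_matched = k)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$contig_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("exon_selection", "data.frame")
    out
  })
}

#' Filter exon selections by length
#'
#' Keeps exons between `min_len` and `max_len` base pairs inclusive — long
#' enough for primer attachment, short enough to stay within the expected
#' exon-length regime.
#'
#' @param selections an `exon_selection` data frame.
#' @param min_len,max_len inclusive bounds (bp).
#' @return The filtered selections.
#' @export
length_filter <- function(selections, min_len = 100, max_len = 400) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  out <- selections[selections$length >= min_len &
                    selections$length <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank exon candidates and keep the top panel
#'
#' Excludes candidates flagged for multiple similar hits or identical
#' sequence shared across contigs, then sorts the remainder by priority
#' (ascending), e-value (ascending), percent identity (descending), gap
#' count (ascending), with contig id as the deterministic final tie-break,
#' and returns the first `n_target`.
#'
#' @param selections an `exon_selection` data frame with hit metrics.
#' @param n_target panel size to keep.
#' @return The ranked head of the candidate list (`<= n_target` rows).
#' @export
rank_candidates <- function(selections, n_target = 192L) {
  keep <- !(selections$multi_hit | selections$duplicate_contig)
  cand <- selections[keep, , drop = FALSE]
  ord <- order(cand$priority, cand$e_value, -cand$percent_identity,
               cand$gap_count, cand$contig_id)
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) < n_target)
    ht_log("only %d clean candidates for a target panel of %d",
           nrow(cand), n_target)
  out <- utils::head(cand, n_target)
  rownames(out) <- NULL
  out
}

#' Find candidate diagnostic SNPs between two aligned exon sequences
#'
#' Scans a pairwise alignment of the two species' copies of an exon and
#' reports every column where both bases are unambiguous (A/C/G/T),
#' non-gap, and different. Positions are 1-based on the alignment; alleles
#' are reported as (M allele, P allele).
#'
#' @param aligned_seq_M,aligned_seq_P equal-length aligned sequences over
#'   `A,C,G,T,-,N` (case-insensitive), as single strings.
#' @return data frame with `position`, `allele_M`, `allele_P`.
#' @export
find_candidate_snps <- function(aligned_seq_M, aligned_seq_P) {
  a <- toupper(strsplit(aligned_seq_M, "")[[1]])
  b <- toupper(strsplit(aligned_seq_P, "")[[1]])
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") & a != b
  data.frame(position = which(ok), allele_M = a[ok], allele_P = b[ok],
             stringsAsFactors = FALSE)
}

#' Simulate a contig-exon catalogue with planted priority composition
#'
#' Builds a [contig_exon_map()] whose contigs fall into known counts of the
#' three priority classes, with randomised exon lengths and hit metrics —
#' the planted truth for testing priority assignment, length filtering and
#' ranking.
#'
#' @param n_priority1,n_priority2,n_priority3 contigs per class (matched
#'   >2, exactly 2, and 1 time respectively).
#' @param frac_flagged fraction of contigs carrying a multi-hit or
#'   duplicate-contig flag.
#' @param length_range range exon lengths are drawn from (uniform).
#' @param seed RNG seed.
#' @return A `contig_exon_map`; the planted class of each contig is
#'   recoverable from its id prefix (`p1_`, `p2_`, `p3_`).
#' @export
simulate_exon_catalog <- function(n_priority1 = 10L, n_priority2 = 20L,
                                  n_priority3 = 50L, frac_flagged = 0.1,
                                  length_range = c(60, 450), seed = 1L) {
  with_seed(seed, {
    mk <- function(prefix, n, n_exons_fun) {
      if (n == 0) return(NULL)
      do.call(rbind, lapply(seq_len(n), function(i) {
        k <- n_exons_fun()
        idx <- sort(sample(1:15, k))
        len <- round(stats::runif(k, length_range[1], length_range[2]))
        st <- cumsum(c(1, utils::head(len, -1) + 50))
        data.frame(contig_id = sprintf("%s_%04d", prefix, i),
                   gene_model_id = sprintf("gm_%s_%04d", prefix, i),
                   exon_index = idx, length = len,
                   start = st, end = st + len - 1,
                   percent_identity = round(stats::runif(1, 85, 100), 2),
                   e_value = 10^stats::runif(1, -60, -5),
                   gap_count = stats::rpois(1, 0.5),
                   multi_hit = FALSE, duplicate_contig = FALSE,
                   stringsAsFactors = FALSE)
      }))
    }
    df <- rbind(mk("p1", n_priority1, function() sample(3:6, 1)),
                mk("p2", n_priority2, function() 2L),
                mk("p3", n_priority3, function() 1L))
    contigs <- unique(df$contig_id)
    n_flag <- round(frac_flagged * length(contigs))
    if (n_flag > 0) {
      flagged <- sample(contigs, n_flag)
      half <- seq_along(flagged) %% 2 == 0
      df$multi_hit[df$contig_id %in% flagged[half]] <- TRUE
      df$duplicate_contig[df$contig_id %in% flagged[!half]] <- TRUE
    }
    contig_exon_map(df)
  })
}
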