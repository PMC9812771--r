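as_granges <- function(d, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(d)))
    stop(what, " need columns: ", paste(need, collapse = ", "))
  GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(start = as.integer(d$start) + 1L,
                              end = as.integer(d$end)))
}

#' Distance from each locus to its nearest feature
#'
#' Genomic distance (bp) from each query locus to the nearest feature on the
#' same chromosome. Overlapping or book-ended intervals have distance 0.
#' Loci on chromosomes with no features get \code{NA}.
#'
#' @param loci,features data.frames with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @return Integer vector of distances, one per locus row.
#' @export
nearest_distance <- function(loci, features) {
  if (nrow(features) == 0) stop("empty feature set")
  gl <- as_granges(loci, "loci")
  gf <- as_granges(features, "features")
  hits <- GenomicRanges::distanceToNearest(gl, gf)
  out <- rep(NA_integer_, nrow(loci))
  out[S4Vectors::queryHits(hits)] <-
    as.integer(S4Vectors::mcols(hits)$distance)
  out
}

#' Distance from each locus to its chromosome arm end
#'
#' Distance from the locus midpoint to the nearer telomeric end of its
#' chromosome arm: p-arm loci measure to position 0, q-arm loci to the
#' chromosome length. A midpoint exactly on the centromere boundary counts
#' as q-arm.
#'
#' @param loci data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param centromeres Named numeric vector: centromere midpoint per
#'   chromosome.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @return Numeric vector of distances (bp).
#' @export
arm_end_distance <- function(loci, centromeres, chrom_lengths) {
  miss <- setdiff(unique(loci$chrom),
                  intersect(names(centromeres), names(chrom_lengths)))
  if (length(miss))
    stop("no centromere/length for chromosome(s): ",
         paste(miss, collapse = ", "))
  mid <- (as.numeric(loci$start) + as.numeric(loci$end)) / 2
  cen <- unname(centromeres[loci$chrom])
  len <- unname(chrom_lengths[loci$chrom])
  ifelse(mid < cen, mid, len - mid)
}

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test of enrichment (\code{"greater"}) or depletion
#' (\code{"less"}) of the top-left cell. A table with a zero margin carries
#' no information and returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative \code{"greater"} (default) or \code{"less"}.
#' @return One-tailed p-value.
#' @export
fisher_exact <- function(tab, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("tab must contain non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin): p = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Motif enrichment and depletion among prioritized loci
#'
#' For every motif, compares its count among \code{selected} loci against a
#' \code{background} catalogue with one-tailed Fisher's exact tests in both
#' directions, adjusting each direction separately with Benjamini-Hochberg.
#'
#' @param selected,background Character vectors of canonical motifs (the
#'   background must contain the selected set's universe).
#' @param fdr_cutoff Significance cutoff on q-values (default 0.01, strict).
#' @return data.frame per motif: counts, \code{p_enriched},
#'   \code{p_depleted}, \code{q_enriched}, \code{q_depleted},
#'   \code{enriched}, \code{depleted}.
#' @export
motif_enrichment <- function(selected, background, fdr_cutoff = 0.01) {
  if (length(selected) == 0 || length(background) == 0)
    stop("selected and background motif sets must be non-empty")
  selected <- canonical_motif(selected)
  background <- canonical_motif(background)
  motifs <- sort(unique(background))
  ns <- length(selected); nb <- length(background)
  res <- do.call(rbind, lapply(motifs, function(m) {
    a <- sum(selected == m)
    b <- sum(background == m)
    tab <- matrix(c(a, ns - a, b - a, nb - b - (ns - a)), 2L, 2L)
    if (any(tab < 0)) stop("selected set is not a subset of the background")
    data.frame(motif = m, n_selected = a, n_background = b,
               p_enriched = fisher_exact(tab, "greater"),
               p_depleted = fisher_exact(tab, "less"),
               stringsAsFactors = FALSE)
  }))
  res$q_enriched <- bh_fdr(res$p_enriched)
  res$q_depleted <- bh_fdr(res$p_depleted)
  res$enriched <- res$q_enriched < fdr_cutoff
  res$depleted <- res$q_depleted < fdr_cutoff
  rownames(res) <- NULL
  res
}

#' Per-gene association of expansion calls between two cohorts
#'
#' For every gene, a two-sided Fisher's exact test on the 2x2 table of
#' donors with/without an expansion call by cohort, Benjamini-Hochberg
#' adjusted across genes.
#'
#' @param calls data.frame with \code{donor_id}, \code{cohort},
#'   \code{gene} (one row per expansion call).
#' @param donors data.frame with \code{donor_id}, \code{cohort} (the full
#'   donor universe).
#' @return data.frame per gene: per-cohort counts, \code{p}, \code{q}.
#' @export
cohort_gene_association <- function(calls, donors) {
  if (anyNA(donors$cohort)) stop("unlabelled donor(s): cohort is NA")
  cohorts <- sort(unique(donors$cohort))
  if (length(cohorts) != 2)
    stop("exactly two cohorts required, got ", length(cohorts))
  if (!all(calls$donor_id %in% donors$donor_id))
    stop("call donor(s) absent from the donor table")
  n_tot <- c(sum(donors$cohort == cohorts[1]),
             sum(donors$cohort == cohorts[2]))
  genes <- sort(unique(calls$gene))
  res <- do.call(rbind, lapply(genes, function(g) {
    dg <- unique(calls$donor_id[calls$gene == g])
    coh <- donors$cohort[match(dg, donors$donor_id)]
    a <- sum(coh == cohorts[1]); b <- sum(coh == cohorts[2])
    tab <- matrix(c(a, n_tot[1] - a, b, n_tot[2] - b), 2L, 2L)
    p <- if (any(rowSums(tab) == 0)) 1 else stats::fisher.test(tab)$p.value
    data.frame(gene = g, n_first = a, n_second = b, p = p,
               stringsAsFactors = FALSE)
  }))
  names(res)[names(res) == "n_first"] <- paste0("n_", cohorts[1])
  names(res)[names(res) == "n_second"] <- paste0("n_", cohorts[2])
  res$q <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test of a continuous covariate between two groups
#' (e.g. telomeric distance of expanded versus non-expanded loci).
#'
#' @param x,y Numeric vectors with at least 2 observations each.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return List: \code{statistic}, \code{df}, \code{p}.
#' @export
welch_t <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
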