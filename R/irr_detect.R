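AUTOSOME_EXCLUDE <- c("X", "Y", "M", "MT")

is_autosome <- function(chrom) {
  !(sub("^chr", "", chrom) %in% AUTOSOME_EXCLUDE)
}

#' Scan aligned read pairs for anchored in-repeat reads
#'
#' Emits one anchored IRR event per read pair in which exactly one mate has
#' mapping quality at most \code{max_irr_mapq} and is an in-repeat read
#' (tiling purity >= \code{min_purity}), while the other mate (the anchor)
#' has mapping quality at least \code{min_anchor_mapq}. Pairs whose two mates
#' are both in-repeat reads carry no anchor and contribute nothing.
#' Secondary and supplementary records are ignored; pairs with a flagged
#' duplicate are dropped.
#'
#' @param alignments An alignment table (see [oracle_align()] or
#'   [read_alignments()]): coordinate-sorted data.frame with columns
#'   \code{qname}, \code{mate}, \code{chrom}, \code{pos} (0-based),
#'   \code{mapq}, \code{seq}, \code{secondary}, \code{supplementary},
#'   \code{duplicate}, and a \code{chrom_lengths} attribute.
#' @param min_anchor_mapq Minimum anchor mapping quality (default 50).
#' @param max_irr_mapq Maximum in-repeat-read mapping quality (default 40).
#' @param min_purity IRR purity threshold (default 0.9).
#' @param sample_id,role,pair_id Sample metadata; \code{sample_id} defaults to
#'   the table's attribute.
#' @return A \code{sample_profile}: list with \code{sample_id}, \code{role},
#'   \code{pair_id}, \code{read_length}, \code{global_depth} (mean autosomal
#'   per-base coverage), \code{events} (data.frame \code{sample_id},
#'   \code{chrom}, \code{anchor_pos}, \code{anchor_mapq}, \code{motif}), and
#'   \code{chrom_lengths}.
#' @export
scan_alignments <- function(alignments, min_anchor_mapq = 50L,
                            max_irr_mapq = 40L, min_purity = 0.9,
                            sample_id = attr(alignments, "sample_id"),
                            role = NA_character_, pair_id = NA_character_) {
  aln <- alignments
  if (is.null(aln) || nrow(aln) == 0)
    stop("empty alignment stream: global depth undefined")
  lens <- attr(alignments, "chrom_lengths")
  if (is.null(lens)) stop("alignment table lacks a chrom_lengths attribute")
  if (nrow(aln) > 1) {
    same <- aln$chrom[-1] == utils::head(aln$chrom, -1)
    if (any(same & diff(aln$pos) < 0) ||
        anyDuplicated(rle(aln$chrom)$values))
      stop("alignments must be coordinate-sorted")
  }
  aln <- aln[!aln$secondary & !aln$supplementary, , drop = FALSE]
  tab <- table(aln$qname)
  if (any(tab != 2L))
    stop("unpaired alignment records: ",
         paste(utils::head(names(tab)[tab != 2L], 3), collapse = ", "))
  dup_q <- unique(aln$qname[aln$duplicate])
  if (length(dup_q)) aln <- aln[!(aln$qname %in% dup_q), , drop = FALSE]

  read_length <- as.integer(stats::median(nchar(aln$seq)))
  auto <- is_autosome(aln$chrom)
  auto_len <- sum(as.numeric(lens[is_autosome(names(lens))]))
  if (auto_len <= 0) stop("no autosomal sequence in chrom_lengths")
  global_depth <- sum(as.numeric(nchar(aln$seq[auto]))) / auto_len
  if (global_depth <= 0) stop("zero autosomal depth")

  # classify only plausible IRR mates
  cand <- which(aln$mapq <= max_irr_mapq)
  irr <- logical(nrow(aln))
  motif <- rep(NA_character_, nrow(aln))
  if (length(cand)) {
    cls <- cpp_detect_irr(aln$seq[cand], min_purity, 2L, 20L)
    irr[cand] <- cls$is_irr
    motif[cand] <- as.character(cls$motif)
  }
  irr <- irr & aln$mapq <= max_irr_mapq

  o <- order(aln$qname, aln$mate)
  i1 <- o[seq(1, length(o), by = 2)]
  i2 <- o[seq(2, length(o), by = 2)]
  # event when exactly one mate is an IRR and the other anchors
  e1 <- irr[i1] & !irr[i2] & aln$mapq[i2] >= min_anchor_mapq
  e2 <- irr[i2] & !irr[i1] & aln$mapq[i1] >= min_anchor_mapq
  anchor_idx <- c(i2[e1], i1[e2])
  irr_idx <- c(i1[e1], i2[e2])
  sid <- if (is.null(sample_id)) NA_character_ else sample_id
  events <- data.frame(
    sample_id = rep(sid, length(anchor_idx)),
    chrom = aln$chrom[anchor_idx],
    anchor_pos = aln$pos[anchor_idx],
    anchor_mapq = aln$mapq[anchor_idx],
    motif = motif[irr_idx],
    stringsAsFactors = FALSE)
  events <- events[order(events$chrom, events$anchor_pos), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(sample_id = sample_id, role = role, pair_id = pair_id,
                 read_length = read_length, global_depth = global_depth,
                 events = events, chrom_lengths = lens),
            class = "sample_profile")
}

#' Cluster anchored IRR events into candidate repeat loci
#'
#' Events sharing a canonical motif whose anchor positions on a chromosome
#' are within \code{merge_distance} of the next event are merged into one
#' locus spanning \code{[min anchor, max anchor + read_length)}. Samples
#' without events at a locus get a raw count of 0.
#'
#' @param profiles List of \code{sample_profile} objects.
#' @param merge_distance Maximum gap between neighbouring anchors in one
#'   cluster (default 500 bp, the scale of the local-depth window).
#' @return List with \code{loci} (data.frame \code{locus_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{motif}) and \code{counts} (complete long
#'   data.frame \code{locus_id}, \code{sample_id}, \code{raw}).
#' @export
cluster_events <- function(profiles, merge_distance = 500L) {
  stopifnot(length(profiles) > 0)
  sample_ids <- vapply(profiles, function(p) p$sample_id, character(1))
  read_length <- max(vapply(profiles, function(p) p$read_length, integer(1)))
  ev <- do.call(rbind, lapply(profiles, function(p) p$events))
  if (is.null(ev) || nrow(ev) == 0) {
    loci <- data.frame(locus_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       motif = character(0), stringsAsFactors = FALSE)
    return(list(loci = loci,
                counts = data.frame(locus_id = character(0),
                                    sample_id = character(0),
                                    raw = numeric(0))))
  }
  ev <- ev[order(ev$chrom, ev$motif, ev$anchor_pos), , drop = FALSE]
  grp <- paste(ev$chrom, ev$motif, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != utils::head(grp, -1))
  gap <- c(0L, diff(ev$anchor_pos))
  new_cluster <- new_grp | gap > merge_distance
  cl <- cumsum(new_cluster)
  loci <- data.frame(
    chrom = tapply(ev$chrom, cl, `[`, 1),
    start = as.integer(tapply(ev$anchor_pos, cl, min)),
    end = as.integer(tapply(ev$anchor_pos, cl, max)) + read_length,
    motif = tapply(ev$motif, cl, `[`, 1),
    stringsAsFactors = FALSE)
  o <- order(loci$chrom, loci$start, loci$motif)
  loci <- loci[o, , drop = FALSE]
  loci$locus_id <- sprintf("L%04d", seq_len(nrow(loci)))
  loci <- loci[, c("locus_id", "chrom", "start", "end", "motif")]
  rownames(loci) <- NULL
  cl_locus <- loci$locus_id[match(cl, o)]
  counts <- as.data.frame(table(
    locus_id = factor(cl_locus, levels = loci$locus_id),
    sample_id = factor(ev$sample_id, levels = sample_ids)),
    responseName = "raw", stringsAsFactors = FALSE)
  counts$raw <- as.numeric(counts$raw)
  list(loci = loci, counts = counts)
}

#' Globally depth-normalized anchored IRR value
#'
#' Rescales a raw anchored IRR count to a common target depth so samples of
#' different sequencing depth are comparable. The target depth cancels in all
#' case-control comparisons; only the relative scale matters.
#'
#' @param raw_count Raw anchored IRR count(s).
#' @param global_depth Mean autosomal per-base coverage of the sample.
#' @param target_depth Reference depth (default 40).
#' @return \code{raw_count * target_depth / global_depth}.
#' @export
global_normalize <- function(raw_count, global_depth, target_depth = 40) {
  if (any(global_depth <= 0)) stop("global_depth must be positive")
  raw_count * target_depth / global_depth
}

#' Assemble a cohort matrix of anchored IRR values
#'
#' Combines per-sample profiles and a clustered locus catalogue into the
#' loci-by-samples value table the prioritization cascade operates on:
#' raw counts and globally normalized values, with tumour/normal pairing.
#'
#' @param profiles List of \code{sample_profile} objects with \code{role} and
#'   \code{pair_id} set.
#' @param clusters Output of [cluster_events()].
#' @param target_depth Target depth for global normalization (default 40).
#' @return A \code{cohort_matrix}: list with \code{loci}, \code{samples},
#'   \code{raw} and \code{global} (loci x samples matrices), and
#'   \code{local} (NULL until [add_local_values()] fills it).
#' @export
build_cohort_matrix <- function(profiles, clusters, target_depth = 40) {
  samples <- data.frame(
    sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
    role = vapply(profiles, `[[`, character(1), "role"),
    pair_id = vapply(profiles, `[[`, character(1), "pair_id"),
    read_length = vapply(profiles, `[[`, integer(1), "read_length"),
    global_depth = vapply(profiles, `[[`, numeric(1), "global_depth"),
    stringsAsFactors = FALSE)
  if (anyNA(samples$role) || anyNA(samples$pair_id))
    stop("profiles must carry role and pair_id")
  tum <- samples$pair_id[samples$role == "tumour"]
  nor <- samples$pair_id[samples$role == "normal"]
  if (anyDuplicated(tum) || anyDuplicated(nor) ||
      !setequal(tum, nor))
    stop("every tumour needs exactly one paired normal (pair_id mismatch)")
  loci <- clusters$loci
  raw <- matrix(0, nrow(loci), nrow(samples),
                dimnames = list(loci$locus_id, samples$sample_id))
  if (nrow(clusters$counts)) {
    idx <- cbind(match(clusters$counts$locus_id, loci$locus_id),
                 match(clusters$counts$sample_id, samples$sample_id))
    ok <- stats::complete.cases(idx)
    raw[idx[ok, , drop = FALSE]] <- clusters$counts$raw[ok]
  }
  glob <- sweep(raw, 2, target_depth / samples$global_depth, `*`)
  structure(list(loci = loci, samples = samples, raw = raw, global = glob,
                 local = NULL, target_depth = target_depth),
            class = "cohort_matrix")
}
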