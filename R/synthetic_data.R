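#' Simulation configuration
#'
#' Parameterizes the synthetic tumour-normal read simulator. Reads are
#' paired-end with substitution errors only (no indels), so every read's true
#' origin is an exact interval and truth tables stay coordinate-exact.
#'
#' @param read_length Read length in bp (default 100, matching typical
#'   cancer-cohort short-read data; 150 is the other common value).
#' @param coverage Mean per-base coverage of a sample (both haplotypes).
#' @param error_rate Substitution error rate per base (default 0.02, the
#'   classic short-read simulator default).
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param carrier_frequency Fraction of tumour-normal pairs carrying an
#'   expansion at a designated locus.
#' @param n_pairs Number of tumour-normal pairs in a simulated cohort.
#' @param carrier_mode \code{"fixed"} places exactly
#'   \code{round(carrier_frequency * n_pairs)} carriers at random pair
#'   positions (the default, so a benchmark's realized carrier fraction equals
#'   its nominal design); \code{"bernoulli"} draws each pair independently.
#' @param seed Integer seed; mandatory, every stochastic call derives its
#'   randomness from it.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(read_length = 100L, coverage = 30, error_rate = 0.02,
                       fragment_mean = 500, fragment_sd = 50,
                       carrier_frequency = 0.3, n_pairs = 20L,
                       carrier_mode = c("fixed", "bernoulli"), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for any stochastic call")
  read_length <- as.integer(read_length)
  if (read_length < 50L) stop("read_length must be >= 50")
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must lie in [0, 0.25)")
  if (fragment_mean < read_length) stop("fragment_mean must be >= read_length")
  if (carrier_frequency < 0 || carrier_frequency > 1)
    stop("carrier_frequency must lie in [0, 1]")
  structure(list(read_length = read_length, coverage = coverage,
                 error_rate = error_rate, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd,
                 carrier_frequency = carrier_frequency,
                 n_pairs = as.integer(n_pairs),
                 carrier_mode = match.arg(carrier_mode),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Derive a deterministic child seed
#'
#' Maps a parent seed and an index to a reproducible derived seed, so that
#' independent stochastic stages of a workflow can each receive their own
#' seed while all randomness still descends from a single user-supplied
#' value. Results always lie in \code{[1, 2^31 - 51]}.
#'
#' @param seed Integer parent seed.
#' @param i Integer stage index.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629 + 1)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a reference genome carrying tandem repeat loci
#'
#' Generates a random background sequence and embeds tandem repeat tracts at
#' the given starts. Coordinates are 0-based half-open throughout.
#'
#' @param chrom_length Background chromosome length in bp.
#' @param repeats data.frame with columns \code{start} (0-based), \code{motif},
#'   \code{copies} (tandem copy number in the reference).
#' @param chrom Chromosome name (default "chr1").
#' @param seed Integer seed for the background sequence.
#' @return A \code{repeat_genome}: list with \code{sequences} (named character)
#'   and \code{truth} (data.frame with reference and sequence-local coordinates
#'   per locus; identical for an unexpanded genome).
#' @export
make_repeat_genome <- function(chrom_length, repeats, chrom = "chr1", seed) {
  stopifnot(is.data.frame(repeats),
            all(c("start", "motif", "copies") %in% names(repeats)))
  set.seed(seed)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  repeats$motif <- vapply(repeats$motif, canonical_motif, character(1))
  tracts <- strrep(repeats$motif, repeats$copies)
  ends <- repeats$start + nchar(tracts)
  if (any(repeats$start[-1] < utils::head(ends, -1)))
    stop("overlapping repeat loci")
  if (utils::tail(ends, 1) > chrom_length)
    stop("repeat locus extends past chromosome end")
  bg <- random_dna(chrom_length)
  pieces <- character(2L * nrow(repeats) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(repeats))) {
    pieces[2L * i - 1L] <- substring(bg, prev + 1L, repeats$start[i])
    pieces[2L * i] <- tracts[i]
    prev <- ends[i]
  }
  pieces[length(pieces)] <- substring(bg, prev + 1L, chrom_length)
  seqs <- stats::setNames(paste(pieces, collapse = ""), chrom)
  truth <- data.frame(chrom = chrom,
                      ref_start = repeats$start, ref_end = ends,
                      start = repeats$start, end = ends,
                      motif = repeats$motif, copies = repeats$copies,
                      copy_number = 2L, stringsAsFactors = FALSE)
  structure(list(sequences = seqs, truth = truth), class = "repeat_genome")
}

#' Expand repeat tracts in a genome
#'
#' Replaces each designated tract with the target number of perfect motif
#' copies, shifting downstream coordinates consistently. The reference
#' interval must itself be a tandem tract of the locus motif (tiling purity
#' >= 0.9), otherwise an error is raised.
#'
#' @param genome A \code{repeat_genome}.
#' @param targets data.frame with columns \code{chrom}, \code{ref_start}
#'   (locus key) and \code{target_copies}.
#' @return A new \code{repeat_genome} whose \code{truth} carries updated
#'   sequence-local \code{start}/\code{end} and \code{copies}; \code{ref_start}
#'   and \code{ref_end} keep the original reference key.
#' @export
expand_reference <- function(genome, targets) {
  stopifnot(inherits(genome, "repeat_genome"),
            all(c("chrom", "ref_start", "target_copies") %in% names(targets)))
  truth <- genome$truth
  seqs <- genome$sequences
  key <- paste(truth$chrom, truth$ref_start)
  tkey <- paste(targets$chrom, targets$ref_start)
  idx <- match(tkey, key)
  if (anyNA(idx)) stop("target locus not present in genome truth table")
  if (any(targets$target_copies < 1)) stop("target copy count must be >= 1")
  for (chrom in unique(targets$chrom)) {
    rows <- idx[targets$chrom == chrom]
    tc <- targets$target_copies[targets$chrom == chrom]
    ord <- order(truth$start[rows])
    rows <- rows[ord]; tc <- tc[ord]
    s <- seqs[[chrom]]
    shift <- 0L
    for (j in seq_along(rows)) {
      i <- rows[j]
      cur_start <- truth$start[i] + shift
      cur_end <- truth$end[i] + shift
      tract <- substring(s, cur_start + 1L, cur_end)
      if (repeat_purity(tract, truth$motif[i]) < 0.9)
        stop("reference content at ", chrom, ":", truth$ref_start[i],
             " is not a tandem tract of motif ", truth$motif[i])
      new_tract <- strrep(truth$motif[i], tc[j])
      s <- paste0(substring(s, 1L, cur_start), new_tract,
                  substring(s, cur_end + 1L, nchar(s)))
      delta <- nchar(new_tract) - (cur_end - cur_start)
      # update this locus, then shift all downstream loci on the chromosome
      truth$start[i] <- cur_start
      truth$end[i] <- cur_start + nchar(new_tract)
      truth$copies[i] <- tc[j]
      shift <- shift + delta
    }
    # recompute downstream coordinates from scratch for untouched loci
    seqs[[chrom]] <- s
  }
  # rebuild start/end for all loci per chromosome from cumulative deltas
  for (chrom in unique(truth$chrom)) {
    sel <- which(truth$chrom == chrom)
    sel <- sel[order(truth$ref_start[sel])]
    delta <- (truth$end[sel] - truth$start[sel]) -
      (truth$ref_end[sel] - truth$ref_start[sel])
    cum <- cumsum(c(0, utils::head(delta, -1)))
    truth$start[sel] <- truth$ref_start[sel] + cum
    truth$end[sel] <- truth$start[sel] +
      (truth$ref_end[sel] - truth$ref_start[sel]) + delta
  }
  structure(list(sequences = seqs, truth = truth), class = "repeat_genome")
}

# map positions in a genome's own (haplotype) coordinates to reference
# coordinates, collapsing inserted bases onto the reference tract
hap_to_ref <- function(genome, chrom, pos) {
  truth <- genome$truth[genome$truth$chrom == chrom, , drop = FALSE]
  if (nrow(truth) == 0) return(pos)
  truth <- truth[order(truth$start), , drop = FALSE]
  delta <- (truth$end - truth$start) - (truth$ref_end - truth$ref_start)
  cumdelta <- cumsum(delta)
  out <- pos
  # interval index: 0 = before first locus, i = inside/after locus i
  idx_in <- findInterval(pos, truth$start)
  for (g in unique(idx_in)) {
    sel <- idx_in == g
    if (g == 0L) { out[sel] <- pos[sel]; next }
    inside <- sel & pos < truth$end[g]
    after <- sel & !inside
    if (any(inside)) {
      reflen <- truth$ref_end[g] - truth$ref_start[g]
      out[inside] <- truth$ref_start[g] +
        pmin(pos[inside] - truth$start[g], reflen - 1L)
    }
    if (any(after)) out[after] <- pos[after] - cumdelta[g]
  }
  out
}

# inverse map: reference position to haplotype position (left boundary rule)
ref_to_hap <- function(genome, chrom, pos) {
  truth <- genome$truth[genome$truth$chrom == chrom, , drop = FALSE]
  if (nrow(truth) == 0) return(pos)
  truth <- truth[order(truth$ref_start), , drop = FALSE]
  delta <- (truth$end - truth$start) - (truth$ref_end - truth$ref_start)
  cumdelta <- cumsum(delta)
  idx <- findInterval(pos, truth$ref_end)
  shift <- c(0, cumdelta)[idx + 1L]
  pos + shift
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are sampled uniformly along each sequence (chromosomes weighted
#' by length), fragment lengths are normal with the configured mean/sd
#' (truncated to at least the read length), the two mates are read inward from
#' the fragment ends on opposite strands, and independent substitution errors
#' are applied at \code{error_rate}. Every read records its true origin.
#'
#' @param genome A \code{repeat_genome} (one haplotype).
#' @param config A \code{sim_config}.
#' @param n_pairs Number of read pairs; default
#'   \code{round(coverage * genome_length / (2 * read_length))}.
#' @param seed Seed for this call (default \code{config$seed}).
#' @param qname_prefix Prefix for read names.
#' @return data.frame with one row per read: \code{qname}, \code{mate} (1/2),
#'   \code{chrom}, \code{start} (0-based leftmost origin in the genome's own
#'   coordinates), \code{strand}, \code{seq}.
#' @export
simulate_reads <- function(genome, config, n_pairs = NULL,
                           seed = config$seed, qname_prefix = "frag") {
  stopifnot(inherits(genome, "repeat_genome"), inherits(config, "sim_config"))
  L <- config$read_length
  lens <- nchar(genome$sequences)
  G <- sum(as.numeric(lens))
  if (is.null(n_pairs))
    n_pairs <- round(config$coverage * G / (2 * L))
  n_pairs <- as.integer(n_pairs)
  set.seed(seed)
  if (n_pairs == 0L)
    return(data.frame(qname = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      strand = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  chroms <- names(lens)
  ci <- if (length(chroms) == 1L) rep(1L, n_pairs) else
    sample.int(length(chroms), n_pairs, replace = TRUE, prob = lens / G)
  flen <- pmax(L, pmin(round(stats::rnorm(n_pairs, config$fragment_mean,
                                          config$fragment_sd)),
                       lens[ci]))
  if (any(flen < L)) stop("fragment length below read length")
  fstart <- floor(stats::runif(n_pairs) * (lens[ci] - flen + 1))
  m1 <- substring(genome$sequences[ci], fstart + 1, fstart + L)
  m2_start <- fstart + flen - L
  m2 <- revcomp(substring(genome$sequences[ci], m2_start + 1, m2_start + L))
  m1 <- cpp_add_errors(m1, config$error_rate)
  m2 <- cpp_add_errors(m2, config$error_rate)
  qn <- paste0(qname_prefix, seq_len(n_pairs))
  data.frame(
    qname = rep(qn, 2L),
    mate = rep(c(1L, 2L), each = n_pairs),
    chrom = rep(chroms[ci], 2L),
    start = as.integer(c(fstart, m2_start)),
    strand = rep(c("+", "-"), each = n_pairs),
    seq = c(m1, m2),
    stringsAsFactors = FALSE
  )
}

#' Oracle alignment of simulated reads
#'
#' A deterministic stand-in for a short-read aligner that encodes exactly the
#' mapping property anchored-IRR detection relies on: reads that are in-repeat
#' reads (tiling purity >= \code{min_purity} for some motif) multi-map and
#' receive mapping quality 0; all other reads map uniquely at their true
#' origin with mapping quality 60. Positions are reported in reference
#' coordinates (insertions lifted back onto the reference tract), as a real
#' aligner maps every sample onto one reference.
#'
#' @param reads A read table from [simulate_reads()].
#' @param genome The \code{repeat_genome} the reads were simulated from.
#' @param sample_id Sample identifier attached to the alignment table.
#' @param min_purity IRR purity threshold (default 0.9).
#' @return An alignment table: data.frame with \code{qname}, \code{mate},
#'   \code{chrom}, \code{pos} (0-based leftmost, reference coordinates),
#'   \code{mapq}, \code{strand}, \code{seq}, \code{secondary},
#'   \code{supplementary}, \code{duplicate}; sorted by chromosome and
#'   position, with \code{chrom_lengths} and \code{sample_id} attributes.
#' @export
oracle_align <- function(reads, genome, sample_id = "sample",
                         min_purity = 0.9) {
  stopifnot(inherits(genome, "repeat_genome"))
  cls <- cpp_detect_irr(reads$seq, min_purity, 2L, 20L)
  mapq <- ifelse(cls$is_irr, 0L, 60L)
  pos <- reads$start
  for (chrom in unique(reads$chrom)) {
    sel <- reads$chrom == chrom
    pos[sel] <- hap_to_ref(genome, chrom, reads$start[sel])
  }
  aln <- data.frame(qname = reads$qname, mate = reads$mate,
                    chrom = reads$chrom, pos = as.integer(pos), mapq = mapq,
                    strand = reads$strand, seq = reads$seq,
                    secondary = FALSE, supplementary = FALSE,
                    duplicate = FALSE, stringsAsFactors = FALSE)
  aln <- aln[order(aln$chrom, aln$pos, aln$qname, aln$mate), , drop = FALSE]
  rownames(aln) <- NULL
  # reference lengths: haplotype length minus net inserted bases
  lens <- nchar(genome$sequences)
  for (chrom in names(lens)) {
    tr <- genome$truth[genome$truth$chrom == chrom, , drop = FALSE]
    lens[chrom] <- lens[chrom] - sum((tr$end - tr$start) -
                                       (tr$ref_end - tr$ref_start))
  }
  attr(aln, "chrom_lengths") <- lens
  attr(aln, "sample_id") <- sample_id
  aln
}

#' Simulate copy-number amplification of repeat regions
#'
#' Draws additional read pairs from the region-plus-flank subreference of the
#' genome at a rate that brings the expected regional coverage to
#' \code{base coverage * copy_number / 2} (copy number 2 is the diploid
#' baseline and adds nothing). Mirrors the benchmark construction in which
#' per-copy-number amplified reads are concatenated with one base read set.
#'
#' @param genome The \code{repeat_genome} the amplified copies derive from.
#' @param regions data.frame of reference-coordinate intervals (\code{chrom},
#'   \code{start}, \code{end}).
#' @param copy_number Integer >= 2.
#' @param config A \code{sim_config} (its \code{coverage} is the base
#'   coverage of the sample being amplified).
#' @param flank Flanking sequence length added around each region (default
#'   1000 bp).
#' @param seed Seed for this call.
#' @return A read table as from [simulate_reads()], with \code{start} in the
#'   genome's own coordinates, ready to be pooled with base reads before
#'   [oracle_align()]. Zero rows when \code{copy_number == 2}.
#' @export
simulate_amplification <- function(genome, regions, copy_number, config,
                                   flank = 1000L, seed = config$seed,
                                   qname_prefix = "amp") {
  if (length(copy_number) != 1L || copy_number != round(copy_number) ||
      copy_number < 2)
    stop("copy_number must be a single integer >= 2")
  empty <- data.frame(qname = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      strand = character(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (copy_number == 2) return(empty)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    hs <- ref_to_hap(genome, chrom, regions$start[i])
    he <- ref_to_hap(genome, chrom, regions$end[i])
    # widen to the full haplotype extent of any expanded locus in the region
    tr <- genome$truth[genome$truth$chrom == chrom &
                         genome$truth$ref_start < regions$end[i] &
                         genome$truth$ref_end > regions$start[i], ,
                       drop = FALSE]
    if (nrow(tr) > 0) he <- max(he, max(tr$end))
    lo <- max(0L, hs - as.integer(flank))
    hi <- min(nchar(genome$sequences[[chrom]]), he + as.integer(flank))
    sub <- substring(genome$sequences[[chrom]], lo + 1L, hi)
    subg <- structure(list(
      sequences = stats::setNames(sub, chrom),
      truth = genome$truth[0, , drop = FALSE]), class = "repeat_genome")
    n_extra <- round((copy_number / 2 - 1) * config$coverage *
                       nchar(sub) / (2 * config$read_length))
    rr <- simulate_reads(subg, config, n_pairs = n_extra,
                         seed = child_seed(seed, i),
                         qname_prefix = paste0(qname_prefix, copy_number,
                                               "r", i, "f"))
    rr$start <- rr$start + lo
    out[[i]] <- rr
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Simulate a tumour-normal cohort with truth table
#'
#' Every sample is diploid (two haplotypes). Normal genomes carry the
#' reference-length repeats on both haplotypes; tumour genomes of carrier
#' pairs carry each designated expansion heterozygously (one haplotype).
#' Optional amplification regions add copy-number-amplified reads to tumour
#' samples. Reads for each haplotype are simulated independently and pooled,
#' then oracle-aligned to reference coordinates.
#'
#' @param genome Reference \code{repeat_genome} from [make_repeat_genome()].
#' @param expansions data.frame of designated loci: \code{chrom},
#'   \code{ref_start}, \code{target_copies}.
#' @param config A \code{sim_config} (\code{n_pairs}, \code{carrier_frequency},
#'   \code{carrier_mode}, \code{seed} are honoured).
#' @param amplification Optional list with \code{regions} (data.frame
#'   \code{chrom}, \code{start}, \code{end}), and either \code{copy_number}
#'   (single integer applied to every tumour) or \code{copy_numbers} (one per
#'   pair); tumour-only.
#' @return List with \code{alignments} (named list of alignment tables, one
#'   per sample), \code{manifest} (sample_id, role, pair_id, read_length),
#'   and \code{truth} (one row per pair x locus: carrier status, copies,
#'   copy_number).
#' @export
simulate_cohort <- function(genome, expansions, config, amplification = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(expansions) == 0) stop("no designated expansion loci")
  if (config$n_pairs < 2) stop("a cohort needs at least 2 pairs")
  set.seed(config$seed)
  n <- config$n_pairs
  nloc <- nrow(expansions)
  carrier <- matrix(FALSE, n, nloc)
  for (j in seq_len(nloc)) {
    if (config$carrier_mode == "bernoulli") {
      carrier[, j] <- stats::runif(n) < config$carrier_frequency
    } else {
      k <- round(config$carrier_frequency * n)
      carrier[sample.int(n, k), j] <- TRUE
    }
  }
  cn <- rep(2L, n)
  if (!is.null(amplification)) {
    cn <- if (!is.null(amplification$copy_numbers))
      as.integer(amplification$copy_numbers)
    else rep(as.integer(amplification$copy_number), n)
    if (length(cn) != n) stop("one copy number per pair required")
  }

  alignments <- list()
  manifest <- data.frame(sample_id = character(0), role = character(0),
                         pair_id = character(0), read_length = integer(0),
                         stringsAsFactors = FALSE)
  truth <- list()
  half <- config
  half$coverage <- config$coverage / 2  # per-haplotype share

  for (p in seq_len(n)) {
    pair_id <- sprintf("pair%02d", p)
    for (role in c("tumour", "normal")) {
      sid <- paste0(pair_id, "_", substr(role, 1, 1))
      hap1 <- genome
      if (role == "tumour" && any(carrier[p, ])) {
        sel <- which(carrier[p, ])
        hap1 <- expand_reference(genome, expansions[sel, , drop = FALSE])
      }
      hap2 <- genome
      s0 <- child_seed(config$seed, p * 1000L + (role == "tumour") * 500L)
      r1 <- simulate_reads(hap1, half, seed = child_seed(s0, 1),
                           qname_prefix = paste0(sid, "h1f"))
      r2 <- simulate_reads(hap2, half, seed = child_seed(s0, 2),
                           qname_prefix = paste0(sid, "h2f"))
      a1 <- oracle_align(r1, hap1, sample_id = sid)
      a2 <- oracle_align(r2, hap2, sample_id = sid)
      if (role == "tumour" && cn[p] > 2 && !is.null(amplification)) {
        # the amplified copies sample both haplotypes' coverage share
        ramp1 <- simulate_amplification(hap1, amplification$regions, cn[p],
                                        half, seed = child_seed(s0, 3),
                                        qname_prefix = paste0(sid, "h1a"))
        ramp2 <- simulate_amplification(hap2, amplification$regions, cn[p],
                                        half, seed = child_seed(s0, 4),
                                        qname_prefix = paste0(sid, "h2a"))
        if (nrow(ramp1) > 0) a1 <- rbind(a1, oracle_align(ramp1, hap1,
                                                          sample_id = sid))
        if (nrow(ramp2) > 0) a2 <- rbind(a2, oracle_align(ramp2, hap2,
                                                          sample_id = sid))
      }
      aln <- rbind(a1, a2)
      aln <- aln[order(aln$chrom, aln$pos, aln$qname, aln$mate), ,
                 drop = FALSE]
      rownames(aln) <- NULL
      attr(aln, "chrom_lengths") <- attr(a2, "chrom_lengths")
      attr(aln, "sample_id") <- sid
      alignments[[sid]] <- aln
      manifest <- rbind(manifest, data.frame(
        sample_id = sid, role = role, pair_id = pair_id,
        read_length = config$read_length, stringsAsFactors = FALSE))
    }
    truth[[p]] <- data.frame(
      pair_id = pair_id, chrom = expansions$chrom,
      ref_start = expansions$ref_start,
      carrier = carrier[p, ],
      target_copies = expansions$target_copies,
      copy_number = cn[p], stringsAsFactors = FALSE)
  }
  list(alignments = alignments, manifest = manifest,
       truth = do.call(rbind, truth))
}

#' Downsample read pairs
#'
#' Retains each fragment (both mates together) independently with the given
#' probability; seed-deterministic.
#'
#' @param x A read table or alignment table with a \code{qname} column.
#' @param fraction Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return Subset of \code{x} with attributes preserved.
#' @export
downsample <- function(x, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(x)
  set.seed(seed)
  qn <- unique(x$qname)
  keep <- qn[stats::runif(length(qn)) < fraction]
  out <- x[x$qname %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(x, "chrom_lengths")
  attr(out, "sample_id") <- attr(x, "sample_id")
  out
}
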