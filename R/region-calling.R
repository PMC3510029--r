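#' Region-calling parameters
#'
#' Bundles every tunable of the bin/z-score and block callers. Defaults are
#' the published procedure: 200 bp bins advancing by 100 bp (50% overlap),
#' single-condition enrichment at Z > 2 with regions within 200 bp merged,
#' differential cutoffs Z > 0.75 for met1 and Z > 0.8 for ibm1 comparisons,
#' depletion at Z < -3, and a > 500 bp minimum length for H3K27me3
#' hypermethylated calls (set `min_region_len = 500` for those). Ties at
#' exactly the cutoff are excluded (strict inequality).
#'
#' @param bin_size,step bin width and advance in bases; `step` must divide
#'   `bin_size`.
#' @param z_cut_enriched z cutoff for single-condition enriched bins.
#' @param z_cut_diff z cutoff for differential (mutant minus wild-type) gains;
#'   0.75 for met1-style comparisons, 0.8 for ibm1-style.
#' @param z_cut_hypo z cutoff (negative) for differential losses.
#' @param merge_gap regions separated by at most this many bases are merged.
#' @param min_region_len regions of length `<= min_region_len` are dropped
#'   when positive (i.e. "> 500 bp" is `min_region_len = 500`).
#' @param block_z_cut probe z cutoff seeding blocks in [call_blocks()].
#' @param max_gap_probes,min_probes block extension across up to this many
#'   consecutive sub-cutoff probes; blocks spanning fewer than `min_probes`
#'   probes are dropped.
#' @param fdr_permutations,fdr_alpha circular-permutation count and
#'   significance level for [estimate_fdr()].
#' @param seed integer seed for permutation offsets.
#' @return A `call_params` list.
#' @export
call_params <- function(bin_size = 200L, step = 100L,
                        z_cut_enriched = 2, z_cut_diff = 0.75,
                        z_cut_hypo = -3, merge_gap = 200L,
                        min_region_len = 0L,
                        block_z_cut = 1, max_gap_probes = 2L, min_probes = 4L,
                        fdr_permutations = 100L, fdr_alpha = 0.01,
                        seed = 1L) {
  stopifnot(step > 0, bin_size >= step, merge_gap >= 0,
            min_region_len >= 0, fdr_permutations >= 1)
  if (bin_size %% step != 0)
    stop("call_params: step must divide bin_size")
  structure(list(bin_size = as.integer(bin_size), step = as.integer(step),
                 z_cut_enriched = z_cut_enriched, z_cut_diff = z_cut_diff,
                 z_cut_hypo = z_cut_hypo, merge_gap = as.integer(merge_gap),
                 min_region_len = as.integer(min_region_len),
                 block_z_cut = block_z_cut,
                 max_gap_probes = as.integer(max_gap_probes),
                 min_probes = as.integer(min_probes),
                 fdr_permutations = as.integer(fdr_permutations),
                 fdr_alpha = fdr_alpha, seed = as.integer(seed)),
            class = "call_params")
}

#' Aggregate a probe track into sliding bins with genome-wide z-scores
#'
#' The genome is tiled into `bin_size` bins every `step` bases from position
#' 0 of each chromosome (trailing bins may be partial). Each bin's score is
#' the mean value of probes whose midpoint falls in `[start, end)`; bins with
#' no probe midpoint carry `NA` and are excluded from the z statistics, which
#' are computed jointly over all non-empty bins of the genome.
#'
#' @param track a `probe_track` (typically a `normalized_track`).
#' @param bin_size,step bin width and advance; `step` must divide `bin_size`.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximal probe end per chromosome.
#' @return A `bin_track` data frame: `chrom`, `start`, `end`, `score`, `z`,
#'   `n_probes`, with `bin_size`/`step` attributes.
#' @export
bin_track <- function(track, bin_size = 200L, step = 100L,
                      chrom_lengths = NULL) {
  stopifnot(nrow(track) > 0)
  if (bin_size %% step != 0) stop("bin_track: step must divide bin_size")
  r <- bin_size %/% step
  chroms <- unique(track$chrom)
  pieces <- lapply(chroms, function(ch) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(sub$end)
    n_slots <- as.integer(ceiling(len / step))
    mid <- (sub$start + sub$end) / 2
    slot <- pmin(as.integer(floor(mid / step)), n_slots - 1L) + 1L
    sums <- counts <- numeric(n_slots)
    agg_s <- tapply(sub$value, slot, sum)
    agg_n <- tapply(sub$value, slot, length)
    idx <- as.integer(names(agg_s))
    sums[idx] <- agg_s
    counts[idx] <- agg_n
    starts <- seq(0L, by = step, length.out = n_slots)
    # bin k aggregates slots k .. k+r-1 (clipped at the chromosome end)
    cs <- c(0, cumsum(sums)); cn <- c(0, cumsum(counts))
    hi <- pmin(seq_len(n_slots) + r - 1L, n_slots)
    bin_n <- cn[hi + 1L] - cn[seq_len(n_slots)]
    bin_s <- cs[hi + 1L] - cs[seq_len(n_slots)]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, as.numeric(len)),
               score = ifelse(bin_n > 0, bin_s / pmax(bin_n, 1), NA_real_),
               n_probes = as.integer(bin_n), stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  # a constant (or empty) score vector leaves z undefined; callers treat
  # all-NA z as a degenerate track
  bins$z <- tryCatch(zscore_transform(bins$score),
                     error = function(e) rep(NA_real_, nrow(bins)))
  bins <- bins[, c("chrom", "start", "end", "score", "z", "n_probes")]
  structure(bins, bin_size = as.integer(bin_size), step = as.integer(step),
            class = c("bin_track", "data.frame"))
}

# Union overlapping/adjacent intervals, merge across gaps <= merge_gap,
# drop regions with length <= min_region_len (when > 0), and summarise
# the supporting units (mean z, count) per region.
.assemble_regions <- function(hits, merge_gap, min_region_len, direction) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_z = numeric(), n = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  if (!nrow(hits))
    return(structure(empty, class = c("region_set", "data.frame")))
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  mz <- tapply(hits$z[S4Vectors::queryHits(ov)],
               S4Vectors::subjectHits(ov), mean)
  nn <- tapply(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov), length)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = as.numeric(GenomicRanges::end(red)),
                    mean_z = as.numeric(mz), n = as.integer(nn),
                    direction = direction, stringsAsFactors = FALSE)
  if (min_region_len > 0)
    out <- out[(out$end - out$start) > min_region_len, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("region_set", "data.frame"))
}

#' Call single-condition enriched regions from a bin track
#'
#' Bins with `z > z_cut_enriched` are taken as intervals, unioned, merged
#' across gaps of at most `merge_gap` bases, and filtered by
#' `min_region_len`.
#'
#' @param bins a `bin_track`.
#' @param params a [call_params()] object.
#' @return A `region_set` data frame (possibly empty).
#' @export
call_enriched_regions <- function(bins, params = call_params()) {
  hits <- bins[!is.na(bins$z) & bins$z > params$z_cut_enriched, , drop = FALSE]
  .assemble_regions(hits, params$merge_gap, params$min_region_len, "enriched")
}

#' Probe-wise difference of two normalized tracks
#'
#' @param mut,wt `probe_track`s on an identical grid, both already log2-scale.
#' @return A `probe_track` of `mut - wt` values.
#' @export
diff_track <- function(mut, wt) {
  if (nrow(mut) != nrow(wt) ||
      any(mut$chrom != wt$chrom | mut$start != wt$start | mut$end != wt$end)) {
    i <- which(mut$chrom != wt$chrom | mut$start != wt$start |
                 mut$end != wt$end)[1L]
    stop(sprintf("diff_track: grid mismatch at probe %s",
                 if (is.na(i)) "(size)" else as.character(i)))
  }
  probe_track(mut$chrom, mut$start, mut$end, mut$value - wt$value,
              mark = attr(mut, "mark"), genotype = attr(mut, "genotype"),
              channel = "normalized")
}

#' Call differential (hyper/hypo) regions between mutant and wild type
#'
#' The probe-wise difference of the two log2-scale tracks is z-score
#' transformed genome-wide (at probe or bin resolution) and thresholded:
#' gains at `z > z_cut_diff` (`direction = "hyper"`), losses at
#' `z < z_cut_hypo` (`direction = "hypo"`). Passing units are unioned,
#' merged across gaps of at most `merge_gap`, and length-filtered
#' (`min_region_len = 500` reproduces the "> 500 bp" rule used for
#' H3K27me3 hypermethylated calls).
#'
#' @param mut,wt `normalized_track`s on an identical probe grid.
#' @param params a [call_params()] object.
#' @param direction `"hyper"` or `"hypo"`.
#' @param resolution `"bin"` (default; the published bin procedure) or
#'   `"probe"` (mirrors the probe-level input of broad-block callers).
#' @return A `region_set`; an identical pair yields an empty set with a
#'   warning rather than an error.
#' @export
call_differential_regions <- function(mut, wt, params = call_params(),
                                      direction = c("hyper", "hypo"),
                                      resolution = c("bin", "probe")) {
  direction <- match.arg(direction)
  resolution <- match.arg(resolution)
  d <- diff_track(mut, wt)
  empty <- .assemble_regions(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               z = numeric()), params$merge_gap, params$min_region_len,
    direction)
  if (resolution == "bin") {
    units <- bin_track(d, params$bin_size, params$step)
    if (all(is.na(units$z))) units <- NULL
  } else {
    z <- tryCatch(zscore_transform(d$value), error = function(e) NULL)
    units <- if (is.null(z)) NULL else
      data.frame(chrom = d$chrom, start = d$start, end = d$end, z = z,
                 stringsAsFactors = FALSE)
  }
  if (is.null(units)) {
    warning("call_differential_regions: zero-variance difference; ",
            "returning no regions")
    return(empty)
  }
  keep <- if (direction == "hyper") {
    !is.na(units$z) & units$z > params$z_cut_diff
  } else {
    !is.na(units$z) & units$z < params$z_cut_hypo
  }
  .assemble_regions(units[keep, c("chrom", "start", "end", "z")],
                    params$merge_gap, params$min_region_len, direction)
}

#' Broad-block caller over probe-level z-scores
#'
#' A transparent stand-in for broad-domain ("block") detection from
#' probe-level ChIP signal: probes whose genome-wide z exceeds
#' `block_z_cut` seed blocks; a block extends across runs of up to
#' `max_gap_probes` consecutive sub-cutoff probes; blocks spanning fewer
#' than `min_probes` probes are dropped. Output satisfies the same
#' `region_set` invariants as the bin caller.
#'
#' @param track a `probe_track` of (log2-scale) signal, e.g. a normalized or
#'   differential track.
#' @param params a [call_params()] object (`block_z_cut`, `max_gap_probes`,
#'   `min_probes`, `merge_gap`, `min_region_len`).
#' @return A `region_set`.
#' @export
call_blocks <- function(track, params = call_params()) {
  z <- zscore_transform(track$value)
  rows <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    pass <- which(z[idx] > params$block_z_cut)
    if (!length(pass)) next
    brk <- which(diff(pass) > params$max_gap_probes + 1L)
    starts <- pass[c(1L, brk + 1L)]
    ends <- pass[c(brk, length(pass))]
    for (k in seq_along(starts)) {
      span <- ends[k] - starts[k] + 1L
      if (span < params$min_probes) next
      sel <- idx[starts[k]:ends[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = track$start[sel[1L]],
        end = track$end[sel[length(sel)]],
        z = mean(z[sel]), stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               z = numeric())
  .assemble_regions(hits, params$merge_gap, params$min_region_len, "enriched")
}

#' Permutation FDR for a region caller
#'
#' Re-runs the caller on permuted versions of the probe values and compares
#' region counts: `fdr = expected_null_count / max(observed_count, 1)`.
#' Two null models are available per chromosome: `"rotate"` (default)
#' shifts the value vector circularly by a random offset, preserving the
#' autocorrelation structure; `"shuffle"` permutes the values freely,
#' destroying it. Rotation also preserves any contiguous signal run, so it
#' bounds how much of the call count is explained by the track's run
#' structure; the shuffle null is the one under which strong planted
#' signal yields a small FDR. When no regions are observed the FDR is
#' reported as 0 with `zero_observed = TRUE`. A region set is deemed
#' significant when `observed_count > 0` and `fdr < fdr_alpha`.
#'
#' @param call_fn function `(track, params) -> region_set`, e.g.
#'   [call_blocks()] or a wrapper around the bin caller applied to a
#'   [diff_track()].
#' @param track the `probe_track` handed to `call_fn`.
#' @param params a [call_params()] object; `seed` drives the permutations.
#' @param null `"rotate"` or `"shuffle"`.
#' @return list with `observed_count`, `expected_null_count`, `fdr`,
#'   `significant`, `zero_observed`, `null`.
#' @export
estimate_fdr <- function(call_fn, track, params = call_params(),
                         null = c("rotate", "shuffle")) {
  null <- match.arg(null)
  observed <- nrow(call_fn(track, params))
  chroms <- unique(track$chrom)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  null_counts <- vapply(seq_len(params$fdr_permutations), function(p) {
    rot <- track
    for (ch in chroms) {
      i <- which(rot$chrom == ch)
      if (null == "shuffle") {
        rot$value[i] <- rot$value[i][sample.int(length(i))]
      } else {
        off <- sample.int(length(i), 1L) - 1L
        if (off > 0L) {
          v <- rot$value[i]
          rot$value[i] <- c(v[(off + 1L):length(v)], v[seq_len(off)])
        }
      }
    }
    nrow(call_fn(rot, params))
  }, numeric(1L))
  expected <- mean(null_counts)
  zero <- observed == 0L
  fdr <- if (zero) 0 else expected / observed
  list(observed_count = observed, expected_null_count = expected,
       fdr = fdr, significant = !zero && fdr < params$fdr_alpha,
       zero_observed = zero, null = null)
}

#' Base-pair Jaccard overlap between two region sets
#'
#' @param a,b data frames with `chrom`, `start`, `end` (0-based half-open).
#' @return intersection bases / union bases (1 when both sets are empty).
#' @export
region_jaccard <- function(a, b) {
  to_gr <- function(x) {
    if (!nrow(x)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1L, x$end)))
  }
  ga <- to_gr(a); gb <- to_gr(b)
  if (!length(ga) && !length(gb)) return(1)
  inter <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
  uni <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::union(ga, gb, ignore.strand = TRUE))))
  inter / uni
}

#' Write a region set as BED6 and/or full-precision TSV
#'
#' BED scores are mean z linearly rescaled to 0-1000 over the set.
#'
#' @param regions a `region_set`.
#' @param bed,tsv output paths (either may be `NULL`).
#' @param name_prefix feature-name prefix in the BED.
#' @return invisible list of written paths.
#' @export
write_regions <- function(regions, bed = NULL, tsv = NULL,
                          name_prefix = "region") {
  if (!is.null(bed)) {
    if (nrow(regions)) {
      zr <- range(regions$mean_z)
      sc <- if (diff(zr) == 0) rep(500L, nrow(regions)) else
        as.integer(round(1000 * (regions$mean_z - zr[1L]) / diff(zr)))
      lines <- sprintf("%s\t%d\t%d\t%s_%d\t%d\t.", regions$chrom,
                       as.integer(regions$start), as.integer(regions$end),
                       name_prefix, seq_len(nrow(regions)), sc)
    } else lines <- character()
    writeLines(lines, bed)
  }
  if (!is.null(tsv))
    utils::write.table(as.data.frame(regions), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(list(bed = bed, tsv = tsv))
}
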