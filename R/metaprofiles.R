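# Genomic intervals (5'->3' profile order) of the metagene bins of one gene.
.gene_bin_layout <- function(start, end, strand, flank, bin_width,
                             n_body_bins) {
  nf <- as.integer(flank / bin_width)
  len <- end - start
  body_edges <- start + len * seq(0, n_body_bins) / n_body_bins
  if (strand == "-") {
    up_lo <- end + flank - bin_width * seq_len(nf)
    body_lo <- rev(body_edges[-length(body_edges)])
    body_hi <- rev(body_edges[-1L])
    down_hi <- start - bin_width * (seq_len(nf) - 1L)
    # each bin still spans [lo, hi) in genome coordinates
    lo <- c(up_lo, body_lo, down_hi - bin_width)
    hi <- c(up_lo + bin_width, body_hi, down_hi)
  } else {
    up_lo <- start - flank + bin_width * (seq_len(nf) - 1L)
    body_lo <- body_edges[-length(body_edges)]
    body_hi <- body_edges[-1L]
    down_lo <- end + bin_width * (seq_len(nf) - 1L)
    lo <- c(up_lo, body_lo, down_lo)
    hi <- c(up_lo + bin_width, body_hi, down_lo + bin_width)
  }
  list(lo = lo, hi = hi, nf = nf,
       segment = rep(c("upstream", "body", "downstream"),
                     c(nf, n_body_bins, nf)))
}

# Aggregate per-gene bin values from point positions (probe/read midpoints,
# cytosine positions). `agg` receives the subscripts falling in one bin.
.metagene_core <- function(positions, chroms, genes, flank, bin_width,
                           n_body_bins, cell_fn) {
  stopifnot(flank %% bin_width == 0)
  nf <- as.integer(flank / bin_width)
  total <- 2L * nf + n_body_bins
  keep <- genes$end - genes$start >= n_body_bins
  if (any(!keep))
    warning(sum(!keep), " gene(s) shorter than n_body_bins bases skipped")
  genes <- genes[keep, , drop = FALSE]
  if (!nrow(genes)) stop("no genes long enough to profile")
  mat <- matrix(NA_real_, nrow(genes), total,
                dimnames = list(genes$id, NULL))
  by_chrom <- split(seq_along(positions), chroms)
  for (g in seq_len(nrow(genes))) {
    lay <- .gene_bin_layout(genes$start[g], genes$end[g], genes$strand[g],
                            flank, bin_width, n_body_bins)
    idx <- by_chrom[[genes$chrom[g]]]
    if (is.null(idx)) idx <- integer()
    pos <- positions[idx]
    near <- idx[pos >= min(lay$lo) & pos < max(lay$hi)]
    posn <- positions[near]
    for (b in seq_len(total)) {
      inb <- near[posn >= lay$lo[b] & posn < lay$hi[b]]
      mat[g, b] <- cell_fn(inb, lay$hi[b] - lay$lo[b])
    }
  }
  attr(mat, "scheme") <- list(flank = flank, bin_width = bin_width,
                              n_body_bins = n_body_bins, n_flank_bins = nf,
                              segment = .gene_bin_layout(0, n_body_bins, "+",
                                                         flank, bin_width,
                                                         n_body_bins)$segment)
  mat
}

#' Per-gene metagene matrix of probe signal
#'
#' Lays out, for every gene, fixed-width flank bins anchored at the TSS and
#' TTS plus `n_body_bins` equal-fraction bins across the scaled gene body,
#' and fills each bin with the mean value of probes whose midpoint falls in
#' it (midpoint rule; no probe is counted twice). Minus-strand genes are
#' flipped so that bin 1 is always 5'-most. Genes shorter than `n_body_bins`
#' bases are skipped with a warning; empty bins are `NA`.
#'
#' @param track a `probe_track`/`normalized_track`.
#' @param genes data frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @param flank flank size in bases (default 3000), a multiple of
#'   `bin_width`.
#' @param bin_width flank bin width in bases (default 150).
#' @param n_body_bins number of scaled body bins (default 20).
#' @return numeric matrix (genes x bins) with a `scheme` attribute.
#' @export
metagene_matrix <- function(track, genes, flank = 3000L, bin_width = 150L,
                            n_body_bins = 20L) {
  mid <- (track$start + track$end) / 2
  val <- track$value
  .metagene_core(mid, track$chrom, genes, flank, bin_width, n_body_bins,
                 function(i, w) if (length(i)) mean(val[i]) else NA_real_)
}

#' Average a metagene matrix into a profile
#'
#' Per-bin mean over genes ignoring `NA`, followed by a centred moving
#' average of width `smooth_window` bins (edges use the truncated window;
#' `smooth_window = 1` disables smoothing). Bins with no contributing gene
#' stay `NA`.
#'
#' @param matrix a matrix from [metagene_matrix()] (or the methylation/read
#'   variants).
#' @param smooth_window odd window width in bins (default 5).
#' @return A `metagene_profile` data frame: `bin`, `segment`, `value`, `n`.
#' @export
average_profile <- function(matrix, smooth_window = 5L) {
  stopifnot(nrow(matrix) >= 1L, smooth_window >= 1L)
  if (is.null(attr(matrix, "scheme")))
    stop("average_profile: matrix lacks its bin-scheme attribute ",
         "(subsetting a metagene matrix drops it; reattach with attr())")
  raw <- colMeans(matrix, na.rm = TRUE)
  raw[!is.finite(raw)] <- NA_real_
  n <- colSums(!is.na(matrix))
  half <- (smooth_window - 1L) %/% 2L
  sm <- vapply(seq_along(raw), function(b) {
    win <- raw[max(1L, b - half):min(length(raw), b + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1L))
  scheme <- attr(matrix, "scheme")
  structure(data.frame(bin = seq_along(raw), segment = scheme$segment,
                       value = sm, n = as.integer(n),
                       stringsAsFactors = FALSE),
            scheme = scheme, smooth_window = as.integer(smooth_window),
            class = c("metagene_profile", "data.frame"))
}

#' Ratio of two metagene profiles
#'
#' Since normalized ChIP tracks are already log2-scale, the "log2 ratio" of
#' two averaged signals is computed as the per-bin difference of the two
#' profiles (default). The explicit linearize-then-ratio mode
#' (`log2(mean(2^a) / mean(2^b))` per bin) is available when the per-gene
#' matrices are supplied instead of profiles. The mode used is recorded in
#' the `mode` attribute.
#'
#' @param a,b `metagene_profile`s (difference mode) or per-gene matrices
#'   (linear_ratio mode) on identical bin schemes.
#' @param mode `"difference"` or `"linear_ratio"`.
#' @return A `metagene_profile` of per-bin ratios.
#' @export
ratio_profile <- function(a, b, mode = c("difference", "linear_ratio")) {
  mode <- match.arg(mode)
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!identical(sa[c("flank", "bin_width", "n_body_bins")],
                 sb[c("flank", "bin_width", "n_body_bins")]))
    stop("ratio_profile: bin schemes differ")
  if (mode == "difference") {
    stopifnot(inherits(a, "metagene_profile"), inherits(b, "metagene_profile"))
    out <- a
    out$value <- a$value - b$value
    out$n <- pmin(a$n, b$n)
  } else {
    stopifnot(is.matrix(a), is.matrix(b))
    va <- colMeans(2^a, na.rm = TRUE)
    vb <- colMeans(2^b, na.rm = TRUE)
    out <- structure(data.frame(bin = seq_along(va), segment = sa$segment,
                                value = log2(va / vb),
                                n = pmin(colSums(!is.na(a)),
                                         colSums(!is.na(b))),
                                stringsAsFactors = FALSE),
                     scheme = sa,
                     class = c("metagene_profile", "data.frame"))
  }
  attr(out, "mode") <- mode
  out
}

#' Metagene profile of cytosine methylation ratios
#'
#' Per bin, the ratio of methylated cytosines to all cytosines of the
#' requested context: counts are pooled (`sum(m) / sum(t)`) over the
#' cytosines in the bin, not averaged per site, so splitting a site's counts
#' across rows cannot change the result. Bins with no cytosine of the
#' context are `NA`.
#'
#' @param calls data frame of cytosine calls: `chrom`, `pos` (1-based),
#'   `strand`, `context` (`CG`/`CHG`/`CHH`), `m_count`, `t_count`.
#' @param genes gene data frame (`id`, `chrom`, `start`, `end`, `strand`).
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @inheritParams metagene_matrix
#' @param smooth_window passed to [average_profile()].
#' @return A `metagene_profile`.
#' @export
methylation_profile <- function(calls, genes, context, flank = 3000L,
                                bin_width = 150L, n_body_bins = 20L,
                                smooth_window = 5L) {
  if (!context %in% c("CG", "CHG", "CHH"))
    stop("methylation_profile: unknown context '", context, "'")
  sub <- calls[calls$context == context, , drop = FALSE]
  m <- sub$m_count; t <- sub$t_count
  mat <- .metagene_core(sub$pos - 0.5, sub$chrom, genes, flank, bin_width,
                        n_body_bins,
                        function(i, w) {
                          if (!length(i) || sum(t[i]) == 0) return(NA_real_)
                          sum(m[i]) / sum(t[i])
                        })
  average_profile(mat, smooth_window)
}

#' Metagene profile of read density
#'
#' Counts read midpoints per bin (strand-flipped like [metagene_matrix()]).
#' With `normalize = "none"` (default) the per-bin value averaged over genes
#' is a raw midpoint count; `"cpkm"` scales each gene's bin count to counts
#' per kilobase of bin per million total reads.
#'
#' @param reads data frame of read intervals: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @inheritParams methylation_profile
#' @param normalize `"none"` or `"cpkm"`.
#' @param total_reads library size for `"cpkm"`; defaults to `nrow(reads)`.
#' @return A `metagene_profile`.
#' @export
read_density_profile <- function(reads, genes, flank = 3000L,
                                 bin_width = 150L, n_body_bins = 20L,
                                 smooth_window = 5L,
                                 normalize = c("none", "cpkm"),
                                 total_reads = NULL) {
  normalize <- match.arg(normalize)
  if (is.null(total_reads)) total_reads <- max(nrow(reads), 1L)
  mid <- (reads$start + reads$end) / 2
  cell <- if (normalize == "none") {
    function(i, w) length(i)
  } else {
    function(i, w) length(i) / (w / 1000) / (total_reads / 1e6)
  }
  mat <- .metagene_core(mid, reads$chrom, genes, flank, bin_width,
                        n_body_bins, cell)
  average_profile(mat, smooth_window)
}

#' @export
print.metagene_profile <- function(x, ...) {
  sc <- attr(x, "scheme")
  cat(sprintf(
    "metagene profile: %d bins (%d flank + %d body + %d flank), %s\n",
    nrow(x), sc$n_flank_bins, sc$n_body_bins, sc$n_flank_bins,
    if (!is.null(attr(x, "mode"))) paste0("mode=", attr(x, "mode"))
    else paste0("smooth=", attr(x, "smooth_window"))))
  invisible(x)
}
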