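#' Sequence C+G composition metrics
#'
#' Both readouts of "C+G density" used when comparing transposons that do or
#' do not gain H3K27me3: base composition (fraction of C or G among non-N
#' bases) and CpG dinucleotide density (count of CG dinucleotides over
#' non-N dinucleotide windows). CpG dinucleotide density is the default
#' metric for group comparisons because the proposed mechanism concerns
#' unmethylated CpG sites recruiting Polycomb.
#'
#' @param sequence a character string, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet] over A/C/G/T/N.
#' @return For a single sequence, a named numeric vector with `gc_fraction`
#'   and `cpg_density`; for a `DNAStringSet` (or character vector), a data
#'   frame with one row per sequence.
#' @export
cg_density <- function(sequence) {
  if (methods::is(sequence, "DNAStringSet") ||
      (is.character(sequence) && length(sequence) > 1L)) {
    res <- t(vapply(as.character(sequence), cg_density, numeric(2L)))
    out <- data.frame(gc_fraction = res[, 1L], cpg_density = res[, 2L])
    rownames(out) <- names(sequence)
    return(out)
  }
  s <- toupper(as.character(sequence))
  if (!nzchar(s)) stop("cg_density: empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("cg_density: sequence must be over A,C,G,T,N")
  non_n <- chars != "N"
  if (!any(non_n)) stop("cg_density: sequence is all N")
  gc <- sum(chars %in% c("C", "G")) / sum(non_n)
  n <- length(chars)
  if (n < 2L) return(c(gc_fraction = gc, cpg_density = 0))
  first <- chars[-n]; second <- chars[-1L]
  ok <- first != "N" & second != "N"
  cpg <- if (any(ok)) sum(first == "C" & second == "G" & ok) / sum(ok) else 0
  c(gc_fraction = gc, cpg_density = cpg)
}

#' Wilcoxon rank-sum test with an exact small-sample path
#'
#' Rank-sum statistic with midranks for ties. When the pooled sample size is
#' at most 12 and there are no ties, the two-tailed p-value is computed by
#' exact enumeration of all labelings; otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_max pooled size up to which exact enumeration is used
#'   (default 12).
#' @return list with `statistic` (rank sum of `x`, midranks), `p` (two-tailed)
#'   and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  W <- sum(r[seq_len(n)])
  ties <- any(duplicated(pooled))
  if (n + m <= exact_max && !ties) {
    ex <- mean(r) * n                     # = n*(n+m+1)/2
    obs_dev <- abs(W - ex)
    combs <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[combs], nrow = n))
    p <- mean(abs(sums - ex) >= obs_dev - 1e-9)
    return(list(statistic = W, p = p, method = "exact"))
  }
  N <- n + m
  mu <- n * (N + 1) / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = W, p = 1, method = "normal"))
  dev <- abs(W - mu)
  z <- max(dev - 0.5, 0) / sqrt(sigma2)   # continuity correction
  p <- min(1, 2 * stats::pnorm(-z))
  list(statistic = W, p = p, method = "normal")
}

#' Five-number boxplot summary with 1.5 x IQR whiskers
#'
#' Median and quartiles by linear interpolation between order statistics
#' (quantile type 7); whiskers reach to the most extreme data points within
#' 1.5 interquartile ranges of the box edges; points beyond are outliers.
#'
#' @param values numeric vector, at least one finite value.
#' @return A `boxplot_summary` list: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("boxplot_summary: no finite values")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  structure(list(median = q[2L], q1 = q[1L], q3 = q[3L],
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = sort(v[v < lo_fence | v > hi_fence]),
                 n = length(v), quartile_type = 7L),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "boxplot: n=%d  whiskers [%.4g, %.4g]  box [%.4g | %.4g | %.4g]  outliers: %d\n",
    x$n, x$whisker_low, x$whisker_high, x$q1, x$median, x$q3,
    length(x$outliers)))
  invisible(x)
}

#' Extract element sequences from a genome by annotation coordinates
#'
#' Minus-strand elements are reverse-complemented so sequences read 5' to 3'.
#'
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param elements data frame with `id`, `chrom`, `start` (0-based), `end`,
#'   `strand`.
#' @return A `DNAStringSet` named by element id.
#' @export
element_sequences <- function(genome, elements) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(elements)), function(i) {
    ch <- elements$chrom[i]
    if (!ch %in% names(genome))
      stop("element_sequences: chromosome not in genome: ", ch)
    as.character(Biostrings::subseq(genome[[ch]],
                                    start = elements$start[i] + 1L,
                                    end = elements$end[i]))
  }, character(1L)))
  names(seqs) <- elements$id
  minus <- which(elements$strand == "-")
  if (length(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  seqs
}
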