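#' Probe-level signal tracks
#'
#' A `probe_track` is a data frame with columns `chrom` (character), `start`
#' (0-based), `end` (half-open) and `value`, sorted by chromosome then start,
#' with non-overlapping probes within a chromosome. Metadata (`mark`,
#' `genotype`, `channel`) travel as attributes. A `normalized_track` is a
#' `probe_track` whose values are genome-mean-centred log2 ratios.
#'
#' @param chrom,start,end,value vectors of equal length describing probes.
#' @param mark,genotype,channel optional metadata strings; `channel` is one of
#'   `"chip"`, `"control"` or `"normalized"`.
#' @return A `probe_track` data frame.
#' @export
probe_track <- function(chrom, start, end, value,
                        mark = NA_character_, genotype = NA_character_,
                        channel = "chip") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end <= df$start))
    stop("probe_track: probes must satisfy end > start")
  .check_no_overlap(df)
  structure(df,
            mark = mark, genotype = genotype, channel = channel,
            class = c("probe_track", "data.frame"))
}

.check_no_overlap <- function(df) {
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L) {
      bad <- which(sub$start[-1L] < sub$end[-nrow(sub)])
      if (length(bad)) {
        i <- bad[1L]
        stop(sprintf(
          "overlapping probes on %s: [%d,%d) and [%d,%d)",
          ch, sub$start[i], sub$end[i], sub$start[i + 1L], sub$end[i + 1L]))
      }
    }
  }
  invisible(df)
}

.track_meta <- function(track) {
  list(mark = attr(track, "mark"), genotype = attr(track, "genotype"),
       channel = attr(track, "channel"))
}

#' Read a probe track from bedGraph or WIG
#'
#' Wraps [rtracklayer::import()] for the two tiling-track encodings used
#' throughout the package. Probes are returned sorted; chromosome names are
#' preserved verbatim; coordinates are converted to 0-based half-open.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bedGraph"` or `"wig"`.
#' @inheritParams probe_track
#' @return A `probe_track`.
#' @export
read_track <- function(path, format = c("auto", "bedGraph", "wig"),
                       mark = NA_character_, genotype = NA_character_,
                       channel = "chip") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     bedgraph = , bg = "bedGraph",
                     wig = "wig",
                     stop("read_track: cannot infer format from extension '",
                          ext, "'; pass format="))
  }
  gr <- rtracklayer::import(path, format = format)
  probe_track(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1L,
              GenomicRanges::end(gr),
              gr$score,
              mark = mark, genotype = genotype, channel = channel)
}

#' Write a probe track as bedGraph or fixed-step WIG
#'
#' @param track a `probe_track`.
#' @param path output path.
#' @param format `"bedGraph"` or `"wig"`; WIG export requires a regular grid
#'   (constant probe length and spacing per chromosome).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "bedGraph") {
    lines <- sprintf("%s\t%d\t%d\t%s", track$chrom,
                     as.integer(track$start), as.integer(track$end),
                     format(track$value, digits = 15, trim = TRUE,
                            scientific = FALSE))
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in unique(track$chrom)) {
      sub <- track[track$chrom == ch, , drop = FALSE]
      span <- unique(sub$end - sub$start)
      step <- if (nrow(sub) > 1L) unique(diff(sub$start)) else span
      if (length(span) != 1L || length(step) != 1L)
        stop("write_track: WIG export needs a regular probe grid on ", ch)
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         ch, as.integer(sub$start[1L]) + 1L,
                         as.integer(step), as.integer(span)), con)
      writeLines(format(sub$value, digits = 15, trim = TRUE,
                        scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' Log2-ratio normalization of a ChIP channel against a control
#'
#' Computes `log2(chip/control)` probe-wise (or `chip - control` when the
#' inputs are already log-scale) and centres the result so the average log2
#' ratio across the genome is zero. Both tracks must share an identical probe
#' grid; missing probes are a hard error, not imputed.
#'
#' @param chip,control `probe_track`s on the same grid.
#' @param already_log if `TRUE`, inputs are log-scale and subtraction is used;
#'   otherwise raw intensities are required to be strictly positive.
#' @return A `normalized_track` (also a `probe_track`), with attribute
#'   `genomewide_mean` storing the subtracted mean (the post-centering mean is
#'   zero to numerical precision).
#' @export
log2_ratio_normalize <- function(chip, control, already_log = FALSE) {
  if (nrow(chip) != nrow(control))
    stop("log2_ratio_normalize: probe grids differ in size (",
         nrow(chip), " vs ", nrow(control), ")")
  mism <- which(chip$chrom != control$chrom | chip$start != control$start |
                  chip$end != control$end)
  if (length(mism)) {
    i <- mism[1L]
    stop(sprintf(
      "log2_ratio_normalize: grid mismatch at probe %d: %s:[%d,%d) vs %s:[%d,%d)",
      i, chip$chrom[i], chip$start[i], chip$end[i],
      control$chrom[i], control$start[i], control$end[i]))
  }
  if (already_log) {
    ratio <- chip$value - control$value
  } else {
    bad <- which(chip$value <= 0 | control$value <= 0)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(
        "log2_ratio_normalize: nonpositive intensity at %s:[%d,%d)",
        chip$chrom[i], chip$start[i], chip$end[i]))
    }
    ratio <- log2(chip$value / control$value)
  }
  m <- mean(ratio)
  out <- probe_track(chip$chrom, chip$start, chip$end, ratio - m,
                     mark = attr(chip, "mark"),
                     genotype = attr(chip, "genotype"),
                     channel = "normalized")
  attr(out, "genomewide_mean") <- m
  class(out) <- c("normalized_track", class(out))
  out
}

#' Z-score transform of a signal vector
#'
#' Centers and scales to population standard deviation (divisor `n`, not
#' `n - 1`), so the output has mean 0 and sd 1 exactly.
#'
#' @param values numeric vector, length at least 2, non-constant. `NA`s are
#'   ignored for the statistics and propagated in the output.
#' @return numeric vector of z-scores.
#' @export
zscore_transform <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L)
    stop("zscore_transform: need at least 2 non-missing values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  # relative guard: numerically-constant input (e.g. a constant track
  # aggregated through floating-point sums) is degenerate too
  if (s <= 1e-12 * max(1, abs(m)))
    stop("zscore_transform: zero variance (degenerate track)")
  (values - m) / s
}

#' @export
print.probe_track <- function(x, ...) {
  meta <- .track_meta(x)
  cat(sprintf("<%s> %d probes on %d chromosome(s)",
              class(x)[1L], nrow(x), length(unique(x$chrom))))
  tags <- Filter(function(v) !is.na(v) && nzchar(v),
                 meta[c("mark", "genotype", "channel")])
  if (length(tags)) cat("  [", paste(unlist(tags), collapse = " / "), "]")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
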