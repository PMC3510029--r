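#' Assign genes overlapped by called regions
#'
#' A gene belongs to the set when its overlap with the called regions reaches
#' `min_overlap` bases — 150 bp by default, roughly the DNA wrapped around
#' one nucleosome. In `"union"` mode (default) overlap is summed over the
#' union of all regions, so several small overlaps can jointly reach the
#' threshold; `"single"` mode requires one region alone to contribute
#' `min_overlap` bases.
#'
#' @param regions a `region_set` (or any data frame with `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param genes data frame with `id`, `chrom`, `start`, `end`.
#' @param min_overlap minimum overlap in bases (default 150).
#' @param mode `"union"` or `"single"`.
#' @return character vector of gene ids meeting the rule.
#' @export
overlap_genes <- function(regions, genes, min_overlap = 150L,
                          mode = c("union", "single")) {
  mode <- match.arg(mode)
  if (!nrow(regions) || !nrow(genes)) return(character())
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  rr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  if (mode == "union") rr <- GenomicRanges::reduce(rr)
  # disjoint chromosome sets are legitimate here; silence the seqlevel note
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gg, rr, ignore.strand = TRUE))
  if (!length(ov)) return(character())
  w <- GenomicRanges::width(IRanges::pintersect(
    gg[S4Vectors::queryHits(ov)], rr[S4Vectors::subjectHits(ov)]))
  if (mode == "union") {
    tot <- tapply(w, S4Vectors::queryHits(ov), sum)
    ids <- genes$id[as.integer(names(tot))[tot >= min_overlap]]
  } else {
    ids <- unique(genes$id[S4Vectors::queryHits(ov)[w >= min_overlap]])
  }
  sort(as.character(ids))
}

#' Classify hypermethylated genes into Class I and Class II
#'
#' Given the set of genes gaining H3K9me2 in the mutant and the wild-type
#' mark-state gene sets, Class I are the hypermethylated genes already
#' H3K9me2-marked in wild type, Class II those H3K27me3-marked (Polycomb
#' targets) in wild type. Genes carrying both wild-type marks appear in both
#' classes and are tallied separately under `dual`; hypermethylated genes in
#' neither wild-type set are `unclassified`.
#'
#' @param hyper,wt_k9,wt_k27 character vectors of gene ids.
#' @return A `gene_classification` list with `class1`, `class2`, `dual`,
#'   `unclassified`, the input sets, and a `summary` data frame of counts
#'   and percentages (of `|hyper|`, half-up to one decimal).
#' @export
classify_hyper_genes <- function(hyper, wt_k9, wt_k27) {
  hyper <- unique(as.character(hyper))
  wt_k9 <- unique(as.character(wt_k9))
  wt_k27 <- unique(as.character(wt_k27))
  class1 <- sort(intersect(hyper, wt_k9))
  class2 <- sort(intersect(hyper, wt_k27))
  dual <- sort(intersect(class1, class2))
  unclassified <- sort(setdiff(hyper, union(class1, class2)))
  n <- length(hyper)
  pct <- function(k) if (n > 0) percentage(k, n) else NA_real_
  summary <- data.frame(
    set = c("hyper", "class1", "class2", "dual", "unclassified"),
    count = c(n, length(class1), length(class2), length(dual),
              length(unclassified)),
    percent_of_hyper = c(if (n > 0) 100 else NA_real_, pct(length(class1)),
                         pct(length(class2)), pct(length(dual)),
                         pct(length(unclassified))),
    stringsAsFactors = FALSE)
  structure(list(class1 = class1, class2 = class2, dual = dual,
                 unclassified = unclassified, hyper = sort(hyper),
                 wt_k9 = sort(wt_k9), wt_k27 = sort(wt_k27),
                 summary = summary),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("Gene classification of", length(x$hyper), "hypermethylated genes\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sizes and intersection of two gene sets
#'
#' @param a,b character vectors (treated as sets).
#' @return named integer vector `c(n_a, n_b, n_both)`.
#' @export
set_overlap <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  c(n_a = length(a), n_b = length(b), n_both = length(intersect(a, b)))
}

#' Percentage with half-up rounding
#'
#' `100 * part / whole` rounded half-up (not half-even) to `decimals`
#' places, matching how printed percentages are conventionally reported —
#' e.g. 515 of 6592 is 7.8125%, printed 7.8; 515 of 1833 is 28.0961%,
#' printed 28.1.
#'
#' @param part,whole non-negative counts, `part <= whole`, `whole > 0`.
#' @param decimals digits after the point (default 1).
#' @return numeric percentage.
#' @export
percentage <- function(part, whole, decimals = 1L) {
  if (any(whole <= 0)) stop("percentage: whole must be > 0")
  if (any(part < 0 | part > whole))
    stop("percentage: need 0 <= part <= whole")
  x <- 100 * part / whole
  f <- 10^decimals
  floor(x * f + 0.5 + 1e-9) / f
}

#' Fraction of genes carrying an annotation feature
#'
#' A gene carries a feature (dispersed repeat, tandem repeat, transposable
#' element) when it overlaps an annotation record of that type by at least
#' one base. Optionally restricts to genes *not* overlapped by a supplied
#' region set (e.g. "contain a dispersed repeat but no wild-type H3K9me2
#' region").
#'
#' @param gene_ids character vector of gene ids (non-empty).
#' @param genes gene data frame (`id`, `chrom`, `start`, `end`).
#' @param annotation data frame of feature records (`chrom`, `start`, `end`,
#'   `type`).
#' @param feature annotation `type` to test for.
#' @param excluding_regions optional `region_set`; when given, the numerator
#'   counts genes carrying the feature but overlapping none of these regions.
#' @return fraction in `[0, 1]`.
#' @export
repeat_content_fraction <- function(gene_ids, genes, annotation,
                                    feature = "dispersed_repeat",
                                    excluding_regions = NULL) {
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) stop("repeat_content_fraction: empty gene set")
  sub <- genes[genes$id %in% gene_ids, , drop = FALSE]
  if (nrow(sub) != length(gene_ids))
    stop("repeat_content_fraction: unknown gene id(s): ",
         paste(utils::head(setdiff(gene_ids, genes$id), 3L), collapse = ", "))
  feats <- annotation[annotation$type == feature, , drop = FALSE]
  flagged <- if (nrow(feats))
    overlap_genes(feats, sub, min_overlap = 1L) else character()
  if (!is.null(excluding_regions)) {
    touched <- overlap_genes(excluding_regions, sub, min_overlap = 1L)
    flagged <- setdiff(flagged, touched)
  }
  length(flagged) / length(gene_ids)
}
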