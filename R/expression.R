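#' RPKM expression table
#'
#' `rpkm = count / (length/1000) / (library_size/1e6)` — reads per kilobase
#' of feature per million mapped reads. Zero counts give exactly zero RPKM.
#'
#' @param counts named numeric vector of read counts, or a data frame with
#'   `id`, `length`, `count`.
#' @param lengths feature lengths in bases (ignored when `counts` is a data
#'   frame).
#' @param library_size total mapped reads (> 0); defaults to `sum(counts)`.
#' @param genotype optional label stored as an attribute.
#' @return An `expression_table` data frame: `id`, `length`, `count`, `rpkm`.
#' @export
compute_rpkm <- function(counts, lengths = NULL, library_size = NULL,
                         genotype = NA_character_) {
  if (is.data.frame(counts)) {
    df <- data.frame(id = as.character(counts$id),
                     length = as.numeric(counts$length),
                     count = as.numeric(counts$count),
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(lengths)) stop("compute_rpkm: lengths required")
    df <- data.frame(id = if (is.null(names(counts)))
      as.character(seq_along(counts)) else names(counts),
      length = as.numeric(lengths), count = as.numeric(counts),
      stringsAsFactors = FALSE)
  }
  if (is.null(library_size)) library_size <- sum(df$count)
  if (any(df$length <= 0)) stop("compute_rpkm: lengths must be > 0")
  if (library_size <= 0) stop("compute_rpkm: library_size must be > 0")
  if (any(df$count < 0)) stop("compute_rpkm: negative count")
  df$rpkm <- df$count / (df$length / 1000) / (library_size / 1e6)
  structure(df, library_size = library_size, genotype = genotype,
            class = c("expression_table", "data.frame"))
}

#' Fraction of a gene set with zero reads
#'
#' @param table an `expression_table`.
#' @param ids gene/element ids (non-empty, all present in `table`).
#' @return fraction of `ids` with `count == 0`.
#' @export
silent_fraction <- function(table, ids) {
  ids <- unique(as.character(ids))
  if (!length(ids)) stop("silent_fraction: empty gene set")
  missing <- setdiff(ids, table$id)
  if (length(missing))
    stop("silent_fraction: ids not in table: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  counts <- table$count[match(ids, table$id)]
  mean(counts == 0)
}

#' Expression change of single elements between genotypes
#'
#' Percent change of RPKM from wild type to mutant with a two-sided p-value
#' from the conditional exact binomial test: given the combined count
#' `x_wt + x_mut`, the mutant count is Binomial with success probability
#' `lib_mut / (lib_wt + lib_mut)` under the null of equal expression (the
#' design has no replicates, so the test treats counts as Poisson).
#'
#' @param wt_table,mut_table `expression_table`s.
#' @param ids element id(s) present in both tables.
#' @return data frame with `id`, `rpkm_wt`, `rpkm_mut`, `percent_change`
#'   (`NA` when `rpkm_wt` is 0), `p`.
#' @export
percent_change <- function(wt_table, mut_table, ids) {
  ids <- as.character(ids)
  iw <- match(ids, wt_table$id); im <- match(ids, mut_table$id)
  if (anyNA(iw) || anyNA(im))
    stop("percent_change: id(s) missing from a table")
  lw <- attr(wt_table, "library_size")
  lm <- attr(mut_table, "library_size")
  out <- data.frame(id = ids,
                    rpkm_wt = wt_table$rpkm[iw],
                    rpkm_mut = mut_table$rpkm[im],
                    percent_change = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  nz <- out$rpkm_wt > 0
  out$percent_change[nz] <-
    100 * (out$rpkm_mut[nz] - out$rpkm_wt[nz]) / out$rpkm_wt[nz]
  for (k in seq_along(ids)) {
    xw <- wt_table$count[iw[k]]; xm <- mut_table$count[im[k]]
    tot <- xw + xm
    out$p[k] <- if (tot == 0) 1 else
      stats::binom.test(xm, tot, p = lm / (lw + lm))$p.value
  }
  out
}

#' Boxplot summaries and rank-sum comparison of two expression groups
#'
#' Compares `log2(rpkm)` of two element sets; elements with RPKM = 0 are
#' removed first when `drop_zero = TRUE` (the convention used for
#' transposon expression boxplots), so no pseudocount is needed. The
#' p-value is the two-tailed Wilcoxon rank-sum test of
#' [wilcoxon_ranksum()].
#'
#' @param table an `expression_table`.
#' @param set_a,set_b element id vectors (subsets of `table$id`).
#' @param drop_zero drop zero-RPKM elements before comparing (default TRUE).
#' @return list with `stats_a`, `stats_b` ([boxplot_summary()] of log2 RPKM),
#'   `p`, `statistic`, `n_a`, `n_b`, `n_dropped_a`, `n_dropped_b`.
#' @export
group_expression_compare <- function(table, set_a, set_b, drop_zero = TRUE) {
  get_rpkm <- function(ids, label) {
    ids <- unique(as.character(ids))
    missing <- setdiff(ids, table$id)
    if (length(missing))
      stop("group_expression_compare: ids not in table (", label, "): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    table$rpkm[match(ids, table$id)]
  }
  a <- get_rpkm(set_a, "set_a"); b <- get_rpkm(set_b, "set_b")
  da <- db <- 0L
  if (drop_zero) {
    da <- sum(a == 0); db <- sum(b == 0)
    a <- a[a > 0]; b <- b[b > 0]
  }
  if (!length(a)) stop("group_expression_compare: set_a empty after zero removal")
  if (!length(b)) stop("group_expression_compare: set_b empty after zero removal")
  la <- log2(a); lb <- log2(b)
  w <- wilcoxon_ranksum(la, lb)
  list(stats_a = boxplot_summary(la), stats_b = boxplot_summary(lb),
       p = w$p, statistic = w$statistic,
       n_a = length(a), n_b = length(b),
       n_dropped_a = da, n_dropped_b = db)
}
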