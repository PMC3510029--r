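# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) assign(name, fn(), .fixture_cache)
  get(name, .fixture_cache)
}

# Small, fast genome whose planted effects still clear the published
# cutoffs in the noiseless limit (margins worked out in the vignette).
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 1L, chromosome_length = 40000L,
                   n_genes = 8L, n_transposons = 3L,
                   gene_length_range = c(1500L, 2500L),
                   te_length_range = c(800L, 1200L), seed = 42L)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

default_sim <- function() cached_fixture("default_sim", function()
  simulate_epigenome(synthetic_spec(seed = 1L), methylome = FALSE))

noiseless_sim <- function() cached_fixture("noiseless_sim", function()
  simulate_epigenome(synthetic_spec(seed = 1L, noise_sd = 0),
                     methylome = FALSE, reads = FALSE))

truth_intervals <- function(sim, labels) {
  el <- sim$truth$elements
  el[el$label %in% labels, c("chrom", "start", "end")]
}

# Paper-default differential call sets on a simulated epigenome.
differential_calls <- function(sim) {
  tr <- sim$tracks
  list(
    k9_hyper = call_differential_regions(
      tr[["H3K9m2.met1"]], tr[["H3K9m2.WT"]],
      call_params(z_cut_diff = 0.75), "hyper", "bin"),
    k27_hyper = call_differential_regions(
      tr[["H3K27m3.met1"]], tr[["H3K27m3.WT"]],
      call_params(z_cut_diff = 2, min_region_len = 500L), "hyper", "bin"),
    k27_hypo = call_differential_regions(
      tr[["H3K27m3.met1"]], tr[["H3K27m3.WT"]],
      call_params(z_cut_hypo = -3), "hypo", "bin"))
}

default_calls <- function() cached_fixture("default_calls", function()
  differential_calls(default_sim()))

# Classification of the default fixture from its own calls.
default_classification <- function() cached_fixture("default_class", function() {
  sim <- default_sim()
  calls <- default_calls()
  genes <- sim$annotation[sim$annotation$type == "gene", ]
  wt_k9 <- call_blocks(sim$tracks[["H3K9m2.WT"]], call_params(block_z_cut = 1))
  wt_k27 <- call_enriched_regions(bin_track(sim$tracks[["H3K27m3.WT"]]),
                                  call_params())
  classify_hyper_genes(overlap_genes(calls$k9_hyper, genes),
                       overlap_genes(wt_k9, genes),
                       overlap_genes(wt_k27, genes))
})

## ---- independent oracles -------------------------------------------------

# O(n^2) interval union + gap merge + length filter by repeated pairwise
# merging (no sorting tricks, no IRanges).
oracle_merge <- function(iv, gap = 0, min_len = 0) {
  iv <- lapply(seq_len(nrow(iv)), function(i)
    list(chrom = iv$chrom[i], start = iv$start[i], end = iv$end[i]))
  repeat {
    merged_any <- FALSE
    for (i in seq_along(iv)) {
      if (is.null(iv[[i]])) next
      for (j in seq_along(iv)) {
        if (i == j || is.null(iv[[j]])) next
        a <- iv[[i]]; b <- iv[[j]]
        if (a$chrom == b$chrom &&
            b$start - a$end <= gap && a$start - b$end <= gap) {
          iv[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                          end = max(a$end, b$end))
          iv[[j]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    iv <- Filter(Negate(is.null), iv)
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(iv, as.data.frame))
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  out <- out[out$end - out$start > min_len, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$chrom <- as.character(out$chrom)
  out
}

# Per-base bitmap oracle for the >= min_overlap gene assignment rule.
oracle_gene_overlap <- function(regions, genes, min_overlap = 150) {
  hit <- character()
  for (g in seq_len(nrow(genes))) {
    span <- genes$end[g] - genes$start[g]
    bitmap <- logical(span)
    for (r in seq_len(nrow(regions))) {
      if (regions$chrom[r] != genes$chrom[g]) next
      lo <- max(regions$start[r], genes$start[g]) - genes$start[g]
      hi <- min(regions$end[r], genes$end[g]) - genes$start[g]
      if (hi > lo) bitmap[(lo + 1):hi] <- TRUE
    }
    if (sum(bitmap) >= min_overlap) hit <- c(hit, genes$id[g])
  }
  sort(hit)
}

# Full enumeration of the rank-sum null distribution (no ties assumed):
# every labeling of the pooled sample is generated by bitmask.
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  ex <- n * (N + 1) / 2
  sums <- c()
  for (mask in 0:(2^N - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    if (length(sel) == n) sums <- c(sums, sum(r[sel]))
  }
  mean(abs(sums - ex) >= abs(W - ex) - 1e-9)
}

# Dinucleotide recount straight off a character sequence.
oracle_cpg_count <- function(s) {
  chars <- strsplit(toupper(s), "")[[1L]]
  sum(chars[-length(chars)] == "C" & chars[-1L] == "G")
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(300, n, replace = TRUE))
}
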