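make_track <- function(values, probe_len = 100L, chrom = "chr1") {
  n <- length(values)
  probe_track(rep(chrom, n), (seq_len(n) - 1L) * probe_len,
              seq_len(n) * probe_len, values)
}

test_that("bin_track aggregates probe midpoints and lays out sliding bins", {
  tr <- make_track(c(1, 3))
  bins <- bin_track(tr, 200L, 100L)
  expect_equal(bins$score[bins$start == 0], 2)        # mean of 1 and 3

  # chrom length 1000: bin starts 0,100,...,900, trailing bins partial
  tr2 <- make_track(rep(1, 10))
  bins2 <- bin_track(tr2, 200L, 100L)
  expect_equal(bins2$start, seq(0, 900, 100))
  expect_equal(bins2$end, pmin(seq(0, 900, 100) + 200, 1000))
  expect_true(all(bins2$score[!is.na(bins2$score)] == 1))

  # constant track: every non-empty bin equals the constant (within
  # floating-point aggregation error) and z is undefined
  tr3 <- make_track(rep(4.2, 25))
  b3 <- bin_track(tr3)
  expect_true(all(abs(b3$score - 4.2) < 1e-9))
  expect_true(all(is.na(b3$z)))
})

test_that("region merging follows the gap rule on hand examples", {
  hits <- function(df) cbind(df, z = 3)
  one <- chromredist:::.assemble_regions(
    hits(data.frame(chrom = "chr1", start = c(0, 300), end = c(200, 500))),
    merge_gap = 200L, min_region_len = 0L, direction = "hyper")
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0, 500))

  two <- chromredist:::.assemble_regions(
    hits(data.frame(chrom = "chr1", start = c(0, 600), end = c(200, 800))),
    merge_gap = 200L, min_region_len = 0L, direction = "hyper")
  expect_equal(nrow(two), 2L)
})

test_that("merging equals the brute-force union oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample.int(50, 1)
    iv <- random_regions(n)
    gap <- sample(c(0, 100, 200), 1)
    min_len <- sample(c(0, 250), 1)
    got <- chromredist:::.assemble_regions(cbind(iv, z = 1), gap, min_len,
                                           "hyper")
    want <- oracle_merge(iv, gap, min_len)
    expect_equal(got[, c("chrom", "start", "end")],
                 want, ignore_attr = TRUE)
  }
})

test_that("called regions are sorted, non-overlapping and cutoff-monotone", {
  set.seed(3)
  tr <- make_track(rnorm(800) + rep(c(0, 4, 0), c(300, 60, 440)))
  bins <- bin_track(tr)
  called_bases <- function(cut) {
    r <- call_enriched_regions(bins, call_params(z_cut_enriched = cut))
    if (nrow(r) > 1) {
      expect_true(all(diff(r$start) > 0))
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
    sum(r$end - r$start)
  }
  bases <- vapply(c(0.5, 1, 2, 3), called_bases, numeric(1))
  expect_true(all(diff(bases) <= 0))
})

test_that("differential calling: identical tracks warn and return nothing", {
  tr <- make_track(rnorm(100))
  expect_warning(r <- call_differential_regions(tr, tr, call_params()),
                 "zero-variance")
  expect_equal(nrow(r), 0L)
})

test_that("a lifted run of probes is called as exactly one hyper region", {
  set.seed(21)
  vals <- rnorm(1000)
  vals[401:450] <- vals[401:450] + 5
  mut <- make_track(vals)
  wt <- make_track(rep(0, 1000))
  r <- call_differential_regions(mut, wt, call_params(z_cut_diff = 2),
                                 "hyper", "probe")
  # brute-force scan of the z vector with the same threshold
  z <- zscore_transform(vals)
  pass <- which(z > 2)
  want <- oracle_merge(data.frame(chrom = "chr1", start = (pass - 1) * 100,
                                  end = pass * 100), gap = 200)
  expect_equal(r[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
  expect_equal(nrow(r), 1L)
  expect_lte(abs(r$start - 40000), 200)
  expect_lte(abs(r$end - 45000), 200)
})

test_that("hypo on (mut,wt) equals hyper on (wt,mut) with mirrored cutoff", {
  set.seed(5)
  a <- make_track(rnorm(500) + rep(c(0, -2, 0), c(200, 50, 250)))
  b <- make_track(rnorm(500))
  hypo <- call_differential_regions(a, b, call_params(z_cut_hypo = -2.5),
                                    "hypo", "probe")
  hyper <- call_differential_regions(b, a, call_params(z_cut_diff = 2.5),
                                     "hyper", "probe")
  expect_equal(hypo[, c("chrom", "start", "end")],
               hyper[, c("chrom", "start", "end")])
})

test_that("call_blocks follows the seed/gap/min-probe rule traces", {
  # values chosen so z > 0 exactly at the 'pass' probes
  params0 <- call_params(block_z_cut = 0, max_gap_probes = 2L,
                         min_probes = 4L, merge_gap = 0L)
  tr1 <- make_track(c(1, 1, -1, 1, -1, -1, -1, -1))  # pass,pass,fail,pass
  r1 <- call_blocks(tr1, params0)
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start, r1$end), c(0, 400))       # spans all four probes

  # pass,fail,fail,fail,pass: gap of 3 > 2 splits; 1-probe blocks dropped
  tr2 <- make_track(c(3, -1, -1, -1, 3, -1, -1, -1))
  expect_equal(nrow(call_blocks(tr2, params0)), 0L)
  params1 <- call_params(block_z_cut = 0, max_gap_probes = 2L,
                         min_probes = 1L, merge_gap = 0L)
  expect_equal(nrow(call_blocks(tr2, params1)), 2L)

  # all probes below cutoff: empty
  paramsh <- call_params(block_z_cut = 10)
  expect_equal(nrow(call_blocks(make_track(rnorm(50)), paramsh)), 0L)
})

test_that("permutation FDR separates planted signal from noise", {
  caller <- function(track, params) call_blocks(track, params)
  # broad domains: blocks must span at least 30 probes
  params <- call_params(block_z_cut = 2, min_probes = 30L,
                        fdr_permutations = 20L, seed = 123L)
  set.seed(42)
  vals <- rnorm(4000)
  starts <- seq(200, 3800, by = 400)        # ten planted 30-probe domains
  for (s in starts) vals[s:(s + 29)] <- vals[s:(s + 29)] + 5
  signal <- make_track(vals)
  noise <- make_track(rnorm(4000))

  # shuffle null: planted domains 5 sd above noise are unambiguous
  fs <- estimate_fdr(caller, signal, params, null = "shuffle")
  expect_gt(fs$observed_count, 0)
  expect_lt(fs$fdr, 0.01)
  expect_true(fs$significant)

  # a pure-noise track is never significant under either null
  for (nl in c("shuffle", "rotate")) {
    fn <- estimate_fdr(caller, noise, params, null = nl)
    expect_false(fn$significant)
    if (fn$observed_count == 0) {
      expect_true(fn$zero_observed)
      expect_equal(fn$fdr, 0)
    }
  }

  # the rotation null preserves contiguous runs: the planted block itself
  # survives every rotation, so the rotation FDR cannot go below ~1
  fr <- estimate_fdr(caller, signal, params, null = "rotate")
  expect_gte(fr$fdr, 0.5)

  # seeded determinism, and doubling permutations moves the estimate little
  expect_equal(estimate_fdr(caller, signal, params, null = "shuffle")$fdr,
               fs$fdr)
  params2 <- params; params2$fdr_permutations <- 40L
  expect_lt(abs(estimate_fdr(caller, signal, params2,
                             null = "shuffle")$fdr - fs$fdr), 0.02)
})
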