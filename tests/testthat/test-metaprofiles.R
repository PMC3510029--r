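cover_track <- function(values, probe_len = 100L, chrom = "chr1") {
  n <- length(values)
  probe_track(rep(chrom, n), (seq_len(n) - 1L) * probe_len,
              seq_len(n) * probe_len, values)
}

one_gene <- function(start, end, strand = "+", chrom = "chr1")
  data.frame(id = "g", chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)

test_that("a constant track gives a constant profile through every op", {
  tr <- cover_track(rep(2.5, 120))                  # covers 12 kb
  genes <- one_gene(4000, 7000)
  m <- metagene_matrix(tr, genes)
  expect_true(all(m == 2.5))
  p <- average_profile(m)
  expect_true(all(p$value == 2.5))
  expect_equal(nrow(p), 20 + 20 + 20)
  # difference-mode ratio of identical profiles is identically zero
  r <- ratio_profile(p, p)
  expect_true(all(r$value == 0))
})

test_that("body and flank bins separate signal laid down only in the body", {
  # 3000 bp gene, probes 1 inside the gene and 0 outside
  vals <- rep(0, 120)
  vals[(4000 / 100 + 1):(7000 / 100)] <- 1
  tr <- cover_track(vals)
  p <- average_profile(metagene_matrix(tr, one_gene(4000, 7000)),
                       smooth_window = 1)
  expect_true(all(p$value[p$segment == "body"] == 1))
  # flank bins away from the boundary are exactly 0 (probe midpoints at
  # x+50 make boundary bins clean here)
  expect_true(all(p$value[p$segment == "upstream"] == 0))
  expect_true(all(p$value[p$segment == "downstream"] == 0))
})

test_that("minus-strand genes are the mirror of plus-strand genes", {
  ramp <- cover_track(seq(0.1, 12, by = 0.1))
  plus <- average_profile(metagene_matrix(ramp, one_gene(4000, 7000, "+")),
                          smooth_window = 1)
  minus <- average_profile(metagene_matrix(ramp, one_gene(4000, 7000, "-")),
                           smooth_window = 1)
  expect_equal(minus$value, rev(plus$value), tolerance = 1e-12)

  # mirroring the signal and flipping the strand reproduces the profile
  # (bin edges kept off probe midpoints: 100 bp bins, 200 bp body bins)
  plus2 <- average_profile(
    metagene_matrix(ramp, one_gene(4000, 8000, "+"), flank = 3000,
                    bin_width = 100), smooth_window = 1)
  mirrored <- cover_track(rev(seq(0.1, 12, by = 0.1)))
  minus_m <- average_profile(
    metagene_matrix(mirrored, one_gene(12000 - 8000, 12000 - 4000, "-"),
                    flank = 3000, bin_width = 100), smooth_window = 1)
  expect_equal(minus_m$value, plus2$value, tolerance = 1e-12)
})

test_that("averaging and smoothing follow the stated conventions", {
  m <- rbind(c(0, 0, 3, 0, 0), c(0, 0, 1, 0, 0))
  attr(m, "scheme") <- list(flank = 150, bin_width = 150, n_body_bins = 1,
                            n_flank_bins = 2,
                            segment = c("upstream", "upstream", "body",
                                        "downstream", "downstream"))
  p1 <- average_profile(m, smooth_window = 1)
  expect_equal(p1$value, c(0, 0, 2, 0, 0))
  expect_equal(p1$n, rep(2L, 5))
  # single gene: profile equals the row (subsetting drops the scheme
  # attribute, so reattach it)
  m1 <- m[1, , drop = FALSE]
  attr(m1, "scheme") <- attr(m, "scheme")
  ps <- average_profile(m1, smooth_window = 1)
  expect_equal(ps$value, c(0, 0, 3, 0, 0))
  # window 3, truncated at the edges
  p3 <- average_profile(m, smooth_window = 3)
  expect_equal(p3$value, c(0, 2 / 3, 2 / 3, 2 / 3, 0))
})

test_that("ratio profiles are antisymmetric and check their schemes", {
  tr <- cover_track(rnorm(120))
  tr2 <- cover_track(rnorm(120))
  g <- one_gene(4000, 7000)
  a <- average_profile(metagene_matrix(tr, g))
  b <- average_profile(metagene_matrix(tr2, g))
  expect_equal(ratio_profile(a, b)$value, -ratio_profile(b, a)$value)
  wide <- average_profile(metagene_matrix(tr, g, n_body_bins = 10))
  expect_error(ratio_profile(a, wide), "schemes differ")
})

test_that("methylation profiles pool counts rather than average sites", {
  genes <- one_gene(0, 1500)
  calls <- data.frame(chrom = "chr1", pos = c(10, 20), strand = "+",
                      context = "CHG", m_count = c(0, 2), t_count = c(1, 2))
  p <- methylation_profile(calls, genes, "CHG", flank = 0, bin_width = 150,
                           n_body_bins = 1, smooth_window = 1)
  expect_equal(p$value, 2 / 3)            # pooled; per-site mean would be 0.5

  # splitting a site's counts across rows changes nothing
  split_calls <- data.frame(chrom = "chr1", pos = c(10, 20, 20),
                            strand = "+", context = "CHG",
                            m_count = c(0, 1, 1), t_count = c(1, 1, 1))
  p2 <- methylation_profile(split_calls, genes, "CHG", flank = 0,
                            bin_width = 150, n_body_bins = 1,
                            smooth_window = 1)
  expect_equal(p2$value, p$value)

  full <- data.frame(chrom = "chr1", pos = c(100, 900), strand = "+",
                     context = "CG", m_count = 5, t_count = 5)
  pf <- methylation_profile(full, genes, "CG", flank = 0, bin_width = 150,
                            n_body_bins = 2, smooth_window = 1)
  expect_true(all(pf$value == 1))
  expect_error(methylation_profile(calls, genes, "CXG"), "unknown context")
})

test_that("read density counts midpoints per bin as enumerated by hand", {
  genes <- one_gene(3000, 4500)           # 1500 bp gene
  # zero reads: all-zero profile
  none <- data.frame(chrom = character(), start = numeric(),
                     end = numeric())
  p0 <- read_density_profile(none, genes, flank = 300, bin_width = 150,
                             n_body_bins = 10, smooth_window = 1)
  expect_true(all(p0$value == 0))

  # 100 reads evenly spaced inside the body: 10 per 150 bp body bin
  starts <- 3000 + seq(0, 1485, by = 15)
  reads <- data.frame(chrom = "chr1", start = starts, end = starts + 24)
  p <- read_density_profile(reads, genes, flank = 300, bin_width = 150,
                            n_body_bins = 10, smooth_window = 1)
  mids <- starts + 12
  expected <- vapply(0:9, function(b)
    sum(mids >= 3000 + b * 150 & mids < 3000 + (b + 1) * 150), numeric(1))
  expect_equal(p$value[p$segment == "body"], expected)
  expect_true(all(p$value[p$segment != "body"] == 0))
})

test_that("short genes are skipped with a warning", {
  tr <- cover_track(rep(1, 120))
  genes <- data.frame(id = c("ok", "tiny"), chrom = "chr1",
                      start = c(4000, 9000), end = c(7000, 9010),
                      strand = "+")
  expect_warning(m <- metagene_matrix(tr, genes, n_body_bins = 20),
                 "skipped")
  expect_equal(rownames(m), "ok")
})
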