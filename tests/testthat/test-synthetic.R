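test_that("generation is deterministic and honours element counts", {
  spec <- small_spec(n_genes = 10L, n_transposons = 4L, seed = 7L,
                     chromosome_length = 50000L)
  a <- generate_annotation(spec)
  b <- generate_annotation(spec)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth$elements, b$truth$elements)
  expect_identical(as.character(a$genome), as.character(b$genome))
  el <- a$truth$elements
  expect_equal(sum(el$type == "gene"), 10L)
  expect_equal(sum(el$type == "transposable_element"), 4L)
  # label conservation over genes
  expect_equal(sum(el$label %in% c("class1", "class2", "pcg_stable",
                                   "plain_gene")), 10L)
})

test_that("degenerate fractions remove the corresponding classes", {
  ann <- generate_annotation(small_spec(frac_pcg_genes = 0))
  expect_false(any(ann$truth$elements$label %in% c("class2", "pcg_stable")))
})

test_that("elements do not overlap and planted intervals stay inside them", {
  ann <- generate_annotation(small_spec(seed = 3L))
  el <- ann$truth$elements
  el <- el[order(el$chrom, el$start), ]
  by_chr <- split(el, el$chrom)
  for (sub in by_chr)
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  for (gt in names(ann$truth$planted))
    for (mark in names(ann$truth$planted[[gt]])) {
      pl <- ann$truth$planted[[gt]][[mark]]
      i <- match(pl$element_id, el$id)
      expect_true(all(pl$start >= el$start[i] & pl$end <= el$end[i]))
    }
})

test_that("infeasible packing fails with an explicit constraint", {
  expect_error(synthetic_spec(n_genes = 100L, chromosome_length = 10000L),
               "infeasible packing")
})

test_that("K27-gaining transposons are CpG-richer, verified by direct recount", {
  spec <- synthetic_spec(n_chromosomes = 2L, chromosome_length = 60000L,
                         n_genes = 0L, n_transposons = 60L,
                         te_length_range = c(500L, 700L),
                         frac_te_gain_k27 = 0.5,
                         high_cpg_density = 0.20, low_cpg_density = 0.02,
                         flank_min = 100L, seed = 5L)
  ann <- generate_annotation(spec)
  el <- ann$truth$elements
  seqs <- element_sequences(ann$genome, el)
  recount <- vapply(as.character(seqs), function(s)
    oracle_cpg_count(s) / (nchar(s) - 1), numeric(1))
  # package metric equals the independent dinucleotide recount
  expect_equal(unname(cg_density(seqs)$cpg_density), unname(recount),
               tolerance = 1e-12)
  expect_equal(unname(el$cpg_density), unname(recount), tolerance = 1e-12)
  gain <- el$label == "te_gain_k27"
  expect_gt(mean(recount[gain]), mean(recount[!gain]) + 0.05)
})

test_that("noiseless tracks carry exactly the planted lifts and the class-II swap", {
  sim <- simulate_epigenome(small_spec(noise_sd = 0), methylome = FALSE,
                            reads = FALSE)
  delta <- sim$spec$enrichment_delta
  w <- sim$spec$class1_wt_fraction
  for (tr in sim$tracks)
    expect_true(all(tr$value %in% c(0, w * delta, delta)))

  el <- sim$truth$elements
  c2 <- el[el$label == "class2", ][1, ]
  probe_vals <- function(nm) {
    tr <- sim$tracks[[nm]]
    mid <- (tr$start + tr$end) / 2
    tr$value[tr$chrom == c2$chrom & mid >= c2$start & mid < c2$end]
  }
  expect_true(all(probe_vals("H3K27m3.WT") == delta))
  expect_true(all(probe_vals("H3K27m3.met1") == 0))
  expect_true(all(probe_vals("H3K9m2.WT") == 0))
  expect_true(all(probe_vals("H3K9m2.met1") == delta))
  # class I: half lift in wild type, full lift in met1
  c1 <- el[el$label == "class1", ][1, ]
  pv <- function(nm) {
    tr <- sim$tracks[[nm]]
    mid <- (tr$start + tr$end) / 2
    tr$value[tr$chrom == c1$chrom & mid >= c1$start & mid < c1$end]
  }
  expect_true(all(pv("H3K9m2.WT") == w * delta))
  expect_true(all(pv("H3K9m2.met1") == delta))
})

test_that("noisy planted intervals concentrate around their means", {
  spec <- small_spec(noise_sd = 0.2, enrichment_delta = 1.5, seed = 11L)
  sim <- simulate_epigenome(spec, methylome = FALSE, reads = FALSE)
  el <- sim$truth$elements
  pl <- sim$truth$planted$met1$H3K9m2
  tr <- sim$tracks[["H3K9m2.met1"]]
  mid <- (tr$start + tr$end) / 2
  for (r in seq_len(nrow(pl))) {
    v <- tr$value[tr$chrom == pl$chrom[r] & mid >= pl$start[r] &
                    mid < pl$end[r]]
    expect_lt(abs(mean(v) - spec$enrichment_delta * pl$lift[r]),
              3 * spec$noise_sd / sqrt(length(v)))
  }
})

test_that("methylome contexts come from the sequence on both strands", {
  ctx <- chromredist:::.cytosine_contexts(c("A", "C", "G", "T"), "+")
  expect_equal(ctx$pos, 2L)
  expect_equal(ctx$context, "CG")
  ctxm <- chromredist:::.cytosine_contexts(c("A", "C", "G", "T"), "-")
  expect_equal(ctxm$pos, 3L)          # G opposite the CG on the minus strand
  expect_equal(ctxm$context, "CG")
  expect_equal(chromredist:::.cytosine_contexts(
    c("C", "A", "G", "A"), "+")$context, "CHG")
  expect_equal(chromredist:::.cytosine_contexts(
    c("C", "A", "A", "A"), "+")$context, "CHH")
})

test_that("methylation rates land where planted and pool near their targets", {
  spec <- small_spec(meth_rate_te_cg = 1, meth_rate_te_chg = 1,
                     meth_rate_te_chh = 1, meth_rate_gene_cg = 0,
                     seed = 9L)
  ann <- generate_annotation(spec)
  meth <- simulate_methylome(ann$annotation, ann$truth, spec, ann$genome)
  el <- ann$truth$elements
  tes <- el[el$type == "transposable_element", ]
  wt <- meth$WT
  in_te <- rep(FALSE, nrow(wt))
  for (i in seq_len(nrow(tes)))
    in_te <- in_te | (wt$chrom == tes$chrom[i] & wt$pos > tes$start[i] &
                        wt$pos <= tes$end[i])
  expect_true(all(wt$m_count[in_te] == wt$t_count[in_te]))
  genes <- el[el$type == "gene", ]
  in_gene <- rep(FALSE, nrow(wt))
  for (i in seq_len(nrow(genes)))
    in_gene <- in_gene | (wt$chrom == genes$chrom[i] &
                            wt$pos > genes$start[i] &
                            wt$pos <= genes$end[i])
  expect_true(all(wt$m_count[!in_te & !in_gene] == 0))

  # binomial pooling: default TE CG rate recovered within 0.05
  spec2 <- small_spec(seed = 9L)
  ann2 <- generate_annotation(spec2)
  meth2 <- simulate_methylome(ann2$annotation, ann2$truth, spec2,
                              ann2$genome)
  el2 <- ann2$truth$elements
  te2 <- el2[el2$type == "transposable_element", ]
  w2 <- meth2$WT
  sel <- rep(FALSE, nrow(w2))
  for (i in seq_len(nrow(te2)))
    sel <- sel | (w2$chrom == te2$chrom[i] & w2$pos > te2$start[i] &
                    w2$pos <= te2$end[i])
  sel <- sel & w2$context == "CG"
  expect_gt(sum(w2$t_count[sel]), 500)
  expect_lt(abs(sum(w2$m_count[sel]) / sum(w2$t_count[sel]) -
                  spec2$meth_rate_te_cg), 0.05)
  # met1 zeroes CG methylation genome-wide
  expect_true(all(meth2$met1$m_count[meth2$met1$context == "CG"] == 0))
})

test_that("read counts respect tiers, silence and determinism", {
  spec <- small_spec(seed = 21L)
  ann <- generate_annotation(spec)
  rc <- simulate_read_counts(ann$annotation, ann$truth, spec)
  rc2 <- simulate_read_counts(ann$annotation, ann$truth, spec)
  expect_identical(as.data.frame(rc$mrna$WT), as.data.frame(rc2$mrna$WT))
  el <- ann$truth$elements
  wt <- rc$mrna$WT
  silent_ids <- el$id[el$label %in% c("class2", "pcg_stable")]
  expect_true(all(wt$count[match(silent_ids, wt$id)] == 0))

  # tier means ordered and near targets on a larger draw
  spec2 <- synthetic_spec(n_chromosomes = 3L, n_genes = 90L,
                          n_transposons = 10L, seed = 2L)
  ann2 <- generate_annotation(spec2)
  rc2 <- simulate_read_counts(ann2$annotation, ann2$truth, spec2)
  el2 <- ann2$truth$elements
  w2 <- rc2$mrna$WT
  mean_of <- function(tier) {
    ids <- el2$id[el2$tier_wt == tier & el2$type == "gene"]
    mean(w2$count[match(ids, w2$id)])
  }
  mu <- c(silent = mean_of("silent"), low = mean_of("low"),
          moderate = mean_of("moderate"))
  expect_true(mu[["silent"]] < mu[["low"]] && mu[["low"]] < mu[["moderate"]])
  n_low <- sum(el2$tier_wt == "low" & el2$type == "gene")
  se_low <- sqrt(spec2$expression_mean_low *
                   (1 + spec2$nb_dispersion * spec2$expression_mean_low) /
                   n_low)
  expect_lt(abs(mu[["low"]] - spec2$expression_mean_low), 3 * se_low)
  # small RNA concentrates on class I genes, more in met1
  expect_gt(nrow(rc2$smallrna$met1), nrow(rc2$smallrna$WT))
})

test_that("fixture bundles round-trip and have reproducible checksums", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- small_spec(seed = 13L)
  sim <- simulate_epigenome(spec)
  man1 <- write_fixture_bundle(sim, dir1)
  man2 <- write_fixture_bundle(simulate_epigenome(spec), dir2)
  expect_identical(man1$md5, man2$md5)

  nm <- "H3K9m2.met1"
  norm <- read_track(file.path(dir1, paste0(nm, ".norm.bedGraph")))
  expect_equal(norm$value, sim$tracks[[nm]]$value, tolerance = 1e-12)
  expect_equal(nrow(norm), nrow(sim$tracks[[nm]]))   # one line per probe

  # chip/control channels normalize back to the centred signal
  chip <- read_track(file.path(dir1, paste0(nm, ".chip.bedGraph")))
  ctrl <- read_track(file.path(dir1, "control.bedGraph"))
  renorm <- log2_ratio_normalize(chip, ctrl)
  centred <- sim$tracks[[nm]]$value - mean(sim$tracks[[nm]]$value)
  expect_equal(renorm$value, centred, tolerance = 1e-9)

  # genome and tables round-trip
  genome <- Biostrings::readDNAStringSet(file.path(dir1, "genome.fa"))
  expect_equal(as.character(genome[[1]]), as.character(sim$genome[[1]]))
  mr <- read_fixture_tsv(file.path(dir1, "mrna_WT.tsv"))
  expect_equal(mr$count, sim$expression$WT$count)
  genes <- read_annotation(file.path(dir1, "annotation.gff3"))
  genes <- genes[genes$type == "gene", ]
  truth_genes <- sim$truth$elements[sim$truth$elements$type == "gene", ]
  expect_equal(sort(genes$id), sort(truth_genes$id))
  expect_equal(genes$start[order(genes$id)],
               truth_genes$start[order(truth_genes$id)])
})
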