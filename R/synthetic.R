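#' Specification of a synthetic epigenome
#'
#' Parameters of the seeded generator that emulates two repressive marks
#' (H3K9me2, H3K27me3) across three genotypes (WT, met1, ibm1) on a small
#' multi-chromosome genome, with planted mark-redistribution effects:
#' Class I genes carry weak H3K9me2 in wild type and full-strength H3K9me2
#' in met1; Class II genes are Polycomb targets (H3K27me3 in wild type)
#' that swap to H3K9me2 in met1; a fraction of transposons loses H3K9me2
#' and gains H3K27me3 in met1, and those transposons are given CpG-richer
#' sequence than stable ones.
#'
#' Defaults describe an element-dense miniature genome (3 x 200 kb,
#' end-to-end 25-mer probes) calibrated so that the published cutoffs
#' (differential Z > 0.75, enrichment Z > 2, depletion Z < -3) separate the
#' planted effects from probe noise; see the package vignette for the
#' margin calculations.
#'
#' @param n_chromosomes,chromosome_length genome shape.
#' @param probe_spacing,probe_length tiling-probe grid in bases.
#' @param n_genes,n_transposons element counts.
#' @param frac_pcg_genes fraction of genes that are Polycomb targets in WT.
#' @param frac_class1_genes fraction of genes pre-marked with weak H3K9me2.
#' @param frac_class2_converted fraction of Polycomb-target genes that swap
#'   H3K27me3 for H3K9me2 in met1 (the rest stay stably marked).
#' @param frac_te_gain_k27 fraction of transposons gaining H3K27me3 in met1.
#' @param frac_ibm1_targets fraction of plain genes gaining H3K9me2 in ibm1.
#' @param frac_paralog_class2 fraction of Class II genes carrying a planted
#'   paralogous core (annotated as dispersed repeat; rounded down to pairs).
#' @param enrichment_delta mean log2-ratio lift inside a planted mark.
#' @param noise_sd probe noise standard deviation (log2-ratio units).
#' @param class1_wt_fraction WT H3K9me2 lift of Class I genes as a fraction
#'   of `enrichment_delta` (default 0.5: "pre-marked with less extensive
#'   levels").
#' @param high_cpg_density,low_cpg_density target CpG dinucleotide rates for
#'   K27-gaining vs stable transposon sequence.
#' @param gene_length_range,te_length_range element lengths in bases.
#' @param flank_min minimum clearance between elements and to chromosome
#'   ends.
#' @param expression_mean_silent,expression_mean_low,expression_mean_moderate
#'   expected read counts of the three expression tiers.
#' @param nb_dispersion negative-binomial dispersion of read counts.
#' @param library_size total mapped reads per mRNA library.
#' @param meth_coverage reads per cytosine in the simulated methylome.
#' @param meth_rate_gene_cg WT CG methylation rate in gene bodies.
#' @param meth_rate_te_cg,meth_rate_te_chg,meth_rate_te_chh WT methylation
#'   rates inside transposons by context.
#' @param meth_rate_chg_gain met1 CHG rate inside Class I/II gene bodies.
#' @param smallrna_rate_wt,smallrna_rate_met1 expected small-RNA reads per
#'   100 bp of Class I gene body.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chromosomes = 3L, chromosome_length = 200000L,
                           probe_spacing = 25L, probe_length = 25L,
                           n_genes = 60L, n_transposons = 30L,
                           frac_pcg_genes = 0.30, frac_class1_genes = 0.35,
                           frac_class2_converted = 0.55,
                           frac_te_gain_k27 = 0.40,
                           frac_ibm1_targets = 0.6,
                           frac_paralog_class2 = 0.40,
                           enrichment_delta = 1.5, noise_sd = 0.3,
                           class1_wt_fraction = 0.5,
                           high_cpg_density = 0.12, low_cpg_density = 0.02,
                           gene_length_range = c(1500L, 4000L),
                           te_length_range = c(1000L, 2000L),
                           flank_min = 500L,
                           expression_mean_silent = 0,
                           expression_mean_low = 5,
                           expression_mean_moderate = 100,
                           nb_dispersion = 0.2, library_size = 1e6,
                           meth_coverage = 10L,
                           meth_rate_gene_cg = 0.4,
                           meth_rate_te_cg = 0.9, meth_rate_te_chg = 0.8,
                           meth_rate_te_chh = 0.1,
                           meth_rate_chg_gain = 0.6,
                           smallrna_rate_wt = 0.2, smallrna_rate_met1 = 0.6,
                           seed = 1L) {
  spec <- as.list(environment())
  fracs <- c("frac_pcg_genes", "frac_class1_genes", "frac_class2_converted",
             "frac_te_gain_k27", "frac_ibm1_targets", "frac_paralog_class2",
             "high_cpg_density", "low_cpg_density", "class1_wt_fraction",
             "meth_rate_gene_cg", "meth_rate_te_cg", "meth_rate_te_chg",
             "meth_rate_te_chh", "meth_rate_chg_gain")
  for (f in fracs)
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop("synthetic_spec: ", f, " must be in [0, 1]")
  stopifnot(spec$probe_spacing >= 1, spec$probe_length >= 1,
            spec$noise_sd >= 0, spec$n_chromosomes >= 1,
            spec$flank_min >= 0, spec$library_size > 0,
            spec$nb_dispersion >= 0)
  if (spec$frac_pcg_genes + spec$frac_class1_genes > 1)
    stop("synthetic_spec: frac_pcg_genes + frac_class1_genes exceeds 1")
  footprint <- spec$n_genes * max(spec$gene_length_range) +
    spec$n_transposons * max(spec$te_length_range) +
    (spec$n_genes + spec$n_transposons + spec$n_chromosomes) * spec$flank_min
  if (footprint > spec$n_chromosomes * spec$chromosome_length)
    stop("synthetic_spec: infeasible packing - worst-case element footprint (",
         footprint, " bp incl. flank_min clearance) exceeds genome size (",
         spec$n_chromosomes * spec$chromosome_length, " bp)")
  structure(spec, class = "synthetic_spec")
}

# Evaluate fn under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  fn()
}

# Random sequence whose CpG dinucleotide rate is steered to `cpg` by the
# G-after-C transition probability (first-order Markov chain; other
# transitions uniform). The achieved rate is recorded in the truth table.
.sample_cpg_sequence <- function(n, cpg) {
  q <- min(1, cpg / 0.25)
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  out[1L] <- sample(bases, 1L)
  after_c <- c((1 - q) / 3, (1 - q) / 3, q, (1 - q) / 3)
  u <- stats::runif(n)
  for (i in 2:n) {
    out[i] <- if (out[i - 1L] == "C") {
      bases[findInterval(u[i], cumsum(after_c)) + 1L]
    } else bases[ceiling(u[i] * 4)]
  }
  paste(out, collapse = "")
}

#' Generate annotation, genome sequence and ground truth
#'
#' Places non-overlapping genes and transposons with at least `flank_min`
#' clearance on each chromosome, assigns class labels
#' (class1/class2/pcg_stable/plain_gene, te_gain_k27/te_stable), draws the
#' genome sequence (K27-gaining transposons CpG-rich, stable ones CpG-poor),
#' plants a tandem-repeat core in every Class I gene and paralogous
#' dispersed-repeat cores (300 bp copied, 20% of positions mutated) in a
#' subset of Class II gene pairs, and derives the planted per-genotype mark
#' intervals.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `annotation` (data frame: `id`, `chrom`, `start`, `end`,
#'   `strand`, `type`), `genome` ([Biostrings::DNAStringSet]) and `truth`
#'   (a `synthetic_truth` list: `elements` with labels, tiers and measured
#'   CpG density; `planted[[genotype]][[mark]]` interval tables;
#'   `ibm1_targets`; `paralog_pairs`).
#' @export
generate_annotation <- function(spec) {
  .with_seed(spec$seed, function() .generate_annotation_impl(spec))
}

.generate_annotation_impl <- function(spec) {
  n_pcg <- round(spec$frac_pcg_genes * spec$n_genes)
  n_class2 <- round(spec$frac_class2_converted * n_pcg)
  n_pcg_stable <- n_pcg - n_class2
  n_class1 <- round(spec$frac_class1_genes * spec$n_genes)
  n_plain <- spec$n_genes - n_pcg - n_class1
  if (n_plain < 0)
    stop("generate_annotation: infeasible class fractions - ",
         "pcg + class1 genes exceed n_genes")
  n_te_gain <- round(spec$frac_te_gain_k27 * spec$n_transposons)

  gene_labels <- sample(rep(c("class1", "class2", "pcg_stable", "plain_gene"),
                            c(n_class1, n_class2, n_pcg_stable, n_plain)))
  te_labels <- sample(rep(c("te_gain_k27", "te_stable"),
                          c(n_te_gain, spec$n_transposons - n_te_gain)))

  glen <- if (spec$n_genes)
    as.integer(round(stats::runif(spec$n_genes, spec$gene_length_range[1L],
                                  spec$gene_length_range[2L]))) else integer()
  tlen <- if (spec$n_transposons)
    as.integer(round(stats::runif(spec$n_transposons,
                                  spec$te_length_range[1L],
                                  spec$te_length_range[2L]))) else integer()

  el <- data.frame(
    id = c(sprintf("gene_%03d", seq_len(spec$n_genes)),
           sprintf("te_%03d", seq_len(spec$n_transposons))),
    type = rep(c("gene", "transposable_element"),
               c(spec$n_genes, spec$n_transposons)),
    label = c(gene_labels, te_labels),
    length = c(glen, tlen), stringsAsFactors = FALSE)
  n_el <- nrow(el)

  # random round-robin assignment to chromosomes, then sequential packing
  # with the leftover space spread randomly across the gaps
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  if (n_el) {
    ord <- sample.int(n_el)
    el <- el[ord, , drop = FALSE]
    el$chrom <- rep_len(chroms, n_el)[sample.int(n_el)]
    el$start <- NA_real_
    for (ch in chroms) {
      i <- which(el$chrom == ch)
      if (!length(i)) next
      need <- sum(el$length[i]) + (length(i) + 1L) * spec$flank_min
      slack <- spec$chromosome_length - need
      if (slack < 0)
        stop("generate_annotation: infeasible packing on ", ch, ": need ",
             need, " bp (elements + flank_min) but chromosome_length is ",
             spec$chromosome_length)
      extra <- if (slack > 0) {
        d <- diff(sort(c(0, stats::runif(length(i)), 1)))
        round(d * slack)
      } else rep(0, length(i) + 1L)
      pos <- spec$flank_min + extra[1L]
      for (k in seq_along(i)) {
        el$start[i[k]] <- pos
        pos <- pos + el$length[i[k]] + spec$flank_min + extra[k + 1L]
      }
    }
    el$end <- el$start + el$length
    el$strand <- sample(c("+", "-"), n_el, replace = TRUE)
    el <- el[order(el$chrom, el$start), , drop = FALSE]
    rownames(el) <- NULL
  } else {
    el$chrom <- character(); el$start <- el$end <- numeric()
    el$strand <- character()
  }

  # genome sequence: uniform background, transposons redrawn with steered
  # CpG rates
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), spec$chromosome_length,
                 replace = TRUE), collapse = ""), character(1L)))
  names(genome) <- chroms
  te_rows <- which(el$type == "transposable_element")
  for (i in te_rows) {
    rate <- if (el$label[i] == "te_gain_k27") spec$high_cpg_density else
      spec$low_cpg_density
    seq_i <- .sample_cpg_sequence(el$length[i], rate)
    Biostrings::subseq(genome[[el$chrom[i]]], el$start[i] + 1L,
                       el$end[i]) <- Biostrings::DNAString(seq_i)
  }

  # tandem-repeat cores inside Class I genes (repeats within the coding
  # region are what pre-marks them)
  extra_feats <- list()
  for (i in which(el$label == "class1")) {
    unit <- paste(sample(c("A", "C", "G", "T"), 75L, replace = TRUE),
                  collapse = "")
    core_start <- el$start[i] +
      sample.int(el$length[i] - 150L, 1L)
    Biostrings::subseq(genome[[el$chrom[i]]], core_start + 1L,
                       core_start + 150L) <-
      Biostrings::DNAString(strrep(unit, 2L))
    extra_feats[[length(extra_feats) + 1L]] <- data.frame(
      id = paste0(el$id[i], "_tr"), chrom = el$chrom[i], start = core_start,
      end = core_start + 150L, strand = "+", type = "tandem_repeat",
      stringsAsFactors = FALSE)
  }

  # paralogous cores: copy 300 bp between pairs of Class II genes with 20%
  # of positions mutated; both cores annotated as dispersed repeats
  class2_rows <- which(el$label == "class2")
  n_para <- 2L * (round(spec$frac_paralog_class2 * length(class2_rows)) %/% 2L)
  pairs <- if (n_para >= 2L) matrix(sample(class2_rows, n_para), ncol = 2L)
  else matrix(integer(), ncol = 2L)
  paralog_pairs <- data.frame(a = character(), b = character(),
                              stringsAsFactors = FALSE)
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1L]; b <- pairs[p, 2L]
    sa <- el$start[a] + sample.int(el$length[a] - 300L, 1L)
    sb <- el$start[b] + sample.int(el$length[b] - 300L, 1L)
    core <- strsplit(as.character(Biostrings::subseq(
      genome[[el$chrom[a]]], sa + 1L, sa + 300L)), "")[[1L]]
    mut <- sample.int(300L, 60L)   # 20% of positions
    core[mut] <- vapply(core[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
    Biostrings::subseq(genome[[el$chrom[b]]], sb + 1L, sb + 300L) <-
      Biostrings::DNAString(paste(core, collapse = ""))
    for (xx in list(c(a, sa), c(b, sb)))
      extra_feats[[length(extra_feats) + 1L]] <- data.frame(
        id = paste0(el$id[xx[1L]], "_dr"), chrom = el$chrom[xx[1L]],
        start = xx[2L], end = xx[2L] + 300L, strand = "+",
        type = "dispersed_repeat", stringsAsFactors = FALSE)
    paralog_pairs <- rbind(paralog_pairs,
                           data.frame(a = el$id[a], b = el$id[b],
                                      stringsAsFactors = FALSE))
  }

  # ibm1 targets: mostly plain genes, plus a small overlap with the met1 set
  plain_ids <- el$id[el$label == "plain_gene"]
  met1_ids <- el$id[el$label %in% c("class1", "class2")]
  ibm1_targets <- sort(c(
    sample(plain_ids, round(spec$frac_ibm1_targets * length(plain_ids))),
    if (length(met1_ids))
      sample(met1_ids, max(1L, round(0.05 * length(met1_ids))))))

  # planted mark intervals per genotype (lift as multiple of enrichment_delta)
  plant <- function(rows, lift) if (length(rows)) data.frame(
    chrom = el$chrom[rows], start = el$start[rows], end = el$end[rows],
    element_id = el$id[rows], lift = lift, stringsAsFactors = FALSE)
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  element_id = character(), lift = numeric())
  rows_of <- function(lab) which(el$label %in% lab)
  ibm1_rows <- which(el$id %in% ibm1_targets)
  w <- spec$class1_wt_fraction
  planted <- list(
    WT = list(
      H3K9m2 = rbind(plant(rows_of("class1"), w),
                     plant(rows_of(c("te_stable", "te_gain_k27")), 1)),
      H3K27m3 = plant(rows_of(c("class2", "pcg_stable")), 1)),
    met1 = list(
      H3K9m2 = rbind(plant(rows_of("class1"), 1),
                     plant(rows_of("class2"), 1),
                     plant(rows_of("te_stable"), 1)),
      H3K27m3 = rbind(plant(rows_of("pcg_stable"), 1),
                      plant(rows_of("te_gain_k27"), 1))),
    ibm1 = list(
      H3K9m2 = rbind(plant(setdiff(rows_of("class1"), ibm1_rows), w),
                     plant(rows_of(c("te_stable", "te_gain_k27")), 1),
                     plant(ibm1_rows, 1)),
      H3K27m3 = plant(rows_of(c("class2", "pcg_stable")), 1)))

  # expression tiers
  tier_wt <- ifelse(el$label %in% c("class2", "pcg_stable"), "silent",
             ifelse(el$label == "class1", "low",
             ifelse(el$label == "plain_gene", "moderate",
             ifelse(el$label == "te_gain_k27", "low", "moderate"))))
  tier_met1 <- ifelse(el$label %in% c("class2", "pcg_stable"), "silent",
               ifelse(el$label == "class1", "low",
               ifelse(el$label == "plain_gene", "moderate", "moderate")))

  elements <- el[, c("id", "chrom", "start", "end", "strand", "type",
                     "label")]
  elements$tier_wt <- tier_wt
  elements$tier_met1 <- tier_met1
  seqs <- element_sequences(genome, elements)
  dens <- cg_density(seqs)
  elements$cpg_density <- dens$cpg_density
  elements$gc_fraction <- dens$gc_fraction

  annotation <- rbind(el[, c("id", "chrom", "start", "end", "strand",
                             "type")],
                      if (length(extra_feats)) do.call(rbind, extra_feats))
  annotation <- annotation[order(annotation$chrom, annotation$start), ,
                           drop = FALSE]
  rownames(annotation) <- NULL

  truth <- structure(list(elements = elements, planted = planted,
                          ibm1_targets = ibm1_targets,
                          paralog_pairs = paralog_pairs),
                     class = "synthetic_truth")
  list(annotation = annotation, genome = genome, truth = truth)
}

#' Simulate probe-level signal tracks for each mark and genotype
#'
#' Probes tile each chromosome end to end (`probe_length`-mers every
#' `probe_spacing` bases). Each track is baseline Gaussian noise
#' (`Normal(0, noise_sd)` per probe, on the centred log2-ratio scale) plus
#' `enrichment_delta * lift` for probes whose midpoint lies inside a planted
#' interval of that mark and genotype. With `noise_sd = 0` every probe value
#' is exactly 0 or the planted lift.
#'
#' @param annotation,truth,spec outputs of [generate_annotation()] and the
#'   spec.
#' @return named list `tracks[["<mark>.<genotype>"]]` of `probe_track`s
#'   (channel `"normalized"`).
#' @export
simulate_probe_tracks <- function(annotation, truth, spec) {
  .with_seed(spec$seed + 1L, function() {
    chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    grid <- do.call(rbind, lapply(chroms, function(ch) {
      starts <- seq(0L, spec$chromosome_length - spec$probe_length,
                    by = spec$probe_spacing)
      data.frame(chrom = ch, start = starts,
                 end = starts + spec$probe_length, stringsAsFactors = FALSE)
    }))
    mid <- (grid$start + grid$end) / 2
    tracks <- list()
    for (mark in c("H3K9m2", "H3K27m3")) {
      for (gt in c("WT", "met1", "ibm1")) {
        vals <- if (spec$noise_sd > 0)
          stats::rnorm(nrow(grid), 0, spec$noise_sd) else numeric(nrow(grid))
        pl <- truth$planted[[gt]][[mark]]
        if (nrow(pl)) for (r in seq_len(nrow(pl))) {
          hit <- grid$chrom == pl$chrom[r] & mid >= pl$start[r] &
            mid < pl$end[r]
          vals[hit] <- vals[hit] + spec$enrichment_delta * pl$lift[r]
        }
        tracks[[paste(mark, gt, sep = ".")]] <-
          probe_track(grid$chrom, grid$start, grid$end, vals,
                      mark = mark, genotype = gt, channel = "normalized")
      }
    }
    tracks
  })
}

# cytosine positions and contexts of one strand of one chromosome
.cytosine_contexts <- function(seq_chars, strand) {
  n <- length(seq_chars)
  if (strand == "+") {
    pos <- which(seq_chars == "C")
    nxt1 <- ifelse(pos + 1L <= n, seq_chars[pmin(pos + 1L, n)], "N")
    nxt2 <- ifelse(pos + 2L <= n, seq_chars[pmin(pos + 2L, n)], "N")
    ctx <- ifelse(nxt1 == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
  } else {
    pos <- which(seq_chars == "G")
    prv1 <- ifelse(pos - 1L >= 1L, seq_chars[pmax(pos - 1L, 1L)], "N")
    prv2 <- ifelse(pos - 2L >= 1L, seq_chars[pmax(pos - 2L, 1L)], "N")
    ctx <- ifelse(prv1 == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
  }
  list(pos = pos, context = ctx)
}

#' Simulate per-cytosine methylation call tables
#'
#' Contexts (CG/CHG/CHH) are assigned from the genome sequence on both
#' strands. Wild type: gene bodies CG-methylated at `meth_rate_gene_cg`,
#' transposons methylated in all three contexts. met1: CG methylation
#' zeroed genome-wide; CHG elevated to `meth_rate_chg_gain` (and a little
#' CHH) inside Class I/II gene bodies; transposons keep their non-CG
#' methylation. Methylated counts are Binomial(`meth_coverage`, rate) per
#' site.
#'
#' @inheritParams simulate_probe_tracks
#' @param genome the genome `DNAStringSet`.
#' @return named list of call tables per genotype (`WT`, `met1`), each a
#'   data frame `chrom`, `pos` (1-based), `strand`, `context`, `m_count`,
#'   `t_count`.
#' @export
simulate_methylome <- function(annotation, truth, spec, genome) {
  .with_seed(spec$seed + 2L, function() {
    el <- truth$elements
    per_chrom <- lapply(names(genome), function(ch) {
      chars <- strsplit(as.character(genome[[ch]]), "")[[1L]]
      plus <- .cytosine_contexts(chars, "+")
      minus <- .cytosine_contexts(chars, "-")
      df <- data.frame(
        chrom = ch,
        pos = c(plus$pos, minus$pos),
        strand = rep(c("+", "-"), c(length(plus$pos), length(minus$pos))),
        context = c(plus$context, minus$context), stringsAsFactors = FALSE)
      df[order(df$pos), , drop = FALSE]
    })
    sites <- do.call(rbind, per_chrom)
    rownames(sites) <- NULL

    in_set <- function(rows) {
      hit <- logical(nrow(sites))
      for (r in rows) {
        hit <- hit | (sites$chrom == el$chrom[r] &
                        sites$pos > el$start[r] & sites$pos <= el$end[r])
      }
      hit
    }
    in_te <- in_set(which(el$type == "transposable_element"))
    in_gene <- in_set(which(el$type == "gene"))
    in_gain <- in_set(which(el$label %in% c("class1", "class2")))

    rate_for <- function(genotype) {
      rate <- numeric(nrow(sites))
      cg <- sites$context == "CG"; chg <- sites$context == "CHG"
      chh <- sites$context == "CHH"
      if (genotype == "WT") {
        rate[in_gene & cg] <- spec$meth_rate_gene_cg
        rate[in_te & cg] <- spec$meth_rate_te_cg
        rate[in_te & chg] <- spec$meth_rate_te_chg
        rate[in_te & chh] <- spec$meth_rate_te_chh
      } else {
        rate[in_te & chg] <- spec$meth_rate_te_chg
        rate[in_te & chh] <- spec$meth_rate_te_chh
        rate[in_gain & chg] <- spec$meth_rate_chg_gain
        rate[in_gain & chh] <- pmax(rate[in_gain & chh], 0.05)
      }
      rate
    }
    lapply(stats::setNames(nm = c("WT", "met1")), function(gt) {
      r <- rate_for(gt)
      out <- sites
      out$m_count <- stats::rbinom(nrow(sites), spec$meth_coverage, r)
      out$t_count <- rep(as.integer(spec$meth_coverage), nrow(sites))
      out
    })
  })
}

#' Simulate mRNA count tables and small-RNA reads
#'
#' mRNA counts per element are negative binomial around the element's
#' planted expression tier (silent/low/moderate; dispersion
#' `nb_dispersion`); Class II and stable Polycomb-target genes are silent
#' in both genotypes, transposons are reactivated in met1. Small-RNA reads
#' (24-mers) concentrate on Class I gene bodies, at a higher rate in met1.
#'
#' @inheritParams simulate_probe_tracks
#' @return list with `mrna` (per-genotype `expression_table`s) and
#'   `smallrna` (per-genotype read-interval data frames `chrom`, `start`,
#'   `end`).
#' @export
simulate_read_counts <- function(annotation, truth, spec) {
  .with_seed(spec$seed + 3L, function() {
    el <- truth$elements
    tier_mean <- c(silent = spec$expression_mean_silent,
                   low = spec$expression_mean_low,
                   moderate = spec$expression_mean_moderate)
    draw <- function(mu) {
      n <- length(mu)
      out <- numeric(n)
      pos <- mu > 0
      out[pos] <- if (spec$nb_dispersion > 0)
        stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / spec$nb_dispersion)
      else stats::rpois(sum(pos), mu[pos])
      out
    }
    mrna <- lapply(stats::setNames(nm = c("WT", "met1")), function(gt) {
      mu <- tier_mean[if (gt == "WT") el$tier_wt else el$tier_met1]
      compute_rpkm(data.frame(id = el$id, length = el$end - el$start,
                              count = draw(mu), stringsAsFactors = FALSE),
                   library_size = spec$library_size, genotype = gt)
    })
    class1 <- el[el$label == "class1", , drop = FALSE]
    smallrna <- lapply(stats::setNames(nm = c("WT", "met1")), function(gt) {
      rate <- if (gt == "WT") spec$smallrna_rate_wt else
        spec$smallrna_rate_met1
      reads <- list()
      for (i in seq_len(nrow(class1))) {
        len <- class1$end[i] - class1$start[i]
        k <- stats::rpois(1L, rate * len / 100)
        if (k > 0) {
          s <- class1$start[i] +
            floor(stats::runif(k, 0, max(len - 24L, 1L)))
          reads[[length(reads) + 1L]] <- data.frame(
            chrom = class1$chrom[i], start = s, end = s + 24L,
            stringsAsFactors = FALSE)
        }
      }
      # sparse genome-wide background
      for (ch in sprintf("chr%d", seq_len(spec$n_chromosomes))) {
        k <- stats::rpois(1L, 0.01 * spec$chromosome_length / 100)
        if (k > 0) {
          s <- floor(stats::runif(k, 0, spec$chromosome_length - 24L))
          reads[[length(reads) + 1L]] <- data.frame(
            chrom = ch, start = s, end = s + 24L, stringsAsFactors = FALSE)
        }
      }
      out <- if (length(reads)) do.call(rbind, reads) else
        data.frame(chrom = character(), start = numeric(), end = numeric())
      out <- out[order(out$chrom, out$start), , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    list(mrna = mrna, smallrna = smallrna)
  })
}

#' Generate a complete synthetic epigenome
#'
#' Runs [generate_annotation()], [simulate_probe_tracks()],
#' [simulate_methylome()] and [simulate_read_counts()] under the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param methylome,reads set `FALSE` to skip the corresponding component.
#' @return A `synthetic_epigenome` list: `spec`, `annotation`, `genome`,
#'   `truth`, `tracks`, `methylomes`, `expression`, `smallrna`.
#' @export
simulate_epigenome <- function(spec = synthetic_spec(), methylome = TRUE,
                               reads = TRUE) {
  ann <- generate_annotation(spec)
  tracks <- simulate_probe_tracks(ann$annotation, ann$truth, spec)
  meth <- if (methylome)
    simulate_methylome(ann$annotation, ann$truth, spec, ann$genome) else NULL
  rc <- if (reads) simulate_read_counts(ann$annotation, ann$truth, spec)
  else list(mrna = NULL, smallrna = NULL)
  structure(list(spec = spec, annotation = ann$annotation,
                 genome = ann$genome, truth = ann$truth, tracks = tracks,
                 methylomes = meth, expression = rc$mrna,
                 smallrna = rc$smallrna),
            class = "synthetic_epigenome")
}

#' @export
print.synthetic_epigenome <- function(x, ...) {
  tab <- table(x$truth$elements$label)
  cat(sprintf("synthetic epigenome: %d x %d bp, %d elements (%s), seed %d\n",
              x$spec$n_chromosomes, x$spec$chromosome_length,
              nrow(x$truth$elements),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$spec$seed))
  invisible(x)
}
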