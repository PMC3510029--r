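#' Pipeline configuration
#'
#' Collects every input path and parameter of the full analysis. Call-set
#' parameters default to the published cutoffs: differential H3K9me2 gains
#' at Z > 0.75 (met1) and Z > 0.8 (ibm1); H3K27me3 enrichment at Z > 2 with
#' 200 bp merging; H3K27me3 gains additionally kept only when > 500 bp;
#' H3K27me3 losses at Z < -3; genes assigned by >= 150 bp overlap.
#'
#' @param track_paths named list `"<mark>.<genotype>"` of either
#'   `list(norm = path)` (pre-normalized bedGraph) or
#'   `list(chip = path, control = path)` (raw intensities).
#' @param annotation_path GFF3 of genes and transposons.
#' @param repeats_path optional BED of dispersed/tandem repeats.
#' @param genome_path optional FASTA (needed for sequence statistics).
#' @param mrna_paths,smallrna_paths,methylome_paths named lists (`WT`,
#'   `met1`) of TSV paths; optional stages are skipped when `NULL`.
#' @param library_size mapped reads per mRNA library.
#' @param params named list of [call_params()] for the call sets `wt_k9`,
#'   `wt_k27`, `met1_k9`, `ibm1_k9`, `k27_hyper`, `k27_hypo`; missing
#'   entries take the documented defaults.
#' @param k9_resolution `"bin"` or `"probe"` differential resolution for the
#'   H3K9me2 comparisons.
#' @param min_overlap gene-assignment overlap in bases (default 150).
#' @param profile list of metagene parameters (`flank`, `bin_width`,
#'   `n_body_bins`, `smooth_window`).
#' @param out_dir report output directory.
#' @param seed integer seed (permutation FDR etc.).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(track_paths, annotation_path,
                            repeats_path = NULL, genome_path = NULL,
                            mrna_paths = NULL, smallrna_paths = NULL,
                            methylome_paths = NULL, library_size = 1e6,
                            params = list(), k9_resolution = "bin",
                            min_overlap = 150L,
                            profile = list(flank = 3000L, bin_width = 150L,
                                           n_body_bins = 20L,
                                           smooth_window = 5L),
                            out_dir = NULL, seed = 1L) {
  defaults <- list(
    wt_k9 = call_params(block_z_cut = 1, seed = seed),
    wt_k27 = call_params(z_cut_enriched = 2, seed = seed),
    met1_k9 = call_params(z_cut_diff = 0.75, seed = seed),
    ibm1_k9 = call_params(z_cut_diff = 0.8, seed = seed),
    k27_hyper = call_params(z_cut_enriched = 2, z_cut_diff = 2,
                            min_region_len = 500L, seed = seed),
    k27_hypo = call_params(z_cut_hypo = -3, seed = seed))
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  structure(list(track_paths = track_paths,
                 annotation_path = annotation_path,
                 repeats_path = repeats_path, genome_path = genome_path,
                 mrna_paths = mrna_paths, smallrna_paths = smallrna_paths,
                 methylome_paths = methylome_paths,
                 library_size = library_size, params = defaults,
                 k9_resolution = match.arg(k9_resolution,
                                           c("bin", "probe")),
                 min_overlap = as.integer(min_overlap), profile = profile,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a fixture-bundle directory
#'
#' Maps the file layout written by [write_fixture_bundle()] onto
#' [pipeline_config()], using the pre-normalized tracks.
#'
#' @param dir fixture-bundle directory.
#' @param ... passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
bundle_pipeline_config <- function(dir, ...) {
  combos <- c(t(outer(c("H3K9m2", "H3K27m3"), c("WT", "met1", "ibm1"),
                      paste, sep = ".")))
  tp <- lapply(stats::setNames(nm = combos), function(nm)
    list(norm = file.path(dir, sprintf("%s.norm.bedGraph", nm))))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  pipeline_config(
    track_paths = tp,
    annotation_path = file.path(dir, "annotation.gff3"),
    repeats_path = file.path(dir, "repeats.bed"),
    genome_path = file.path(dir, "genome.fa"),
    mrna_paths = list(WT = file.path(dir, "mrna_WT.tsv"),
                      met1 = file.path(dir, "mrna_met1.tsv")),
    smallrna_paths = list(WT = file.path(dir, "smallrna_WT.tsv"),
                          met1 = file.path(dir, "smallrna_met1.tsv")),
    methylome_paths = list(WT = file.path(dir, "methylome_WT.tsv"),
                           met1 = file.path(dir, "methylome_met1.tsv")),
    library_size = manifest$spec$library_size, ...)
}

#' Validate a pipeline configuration
#'
#' Checks every referenced file, parameter ranges and grid-compatible
#' settings; non-standard parameter choices yield warnings (e.g. an ibm1
#' differential cutoff other than 0.8).
#'
#' @param config a [pipeline_config()].
#' @return list with `ok`, `errors` (character), `warnings` (character).
#' @export
validate_config <- function(config) {
  errors <- character(); warnings <- character()
  need <- function(p, what) if (!is.null(p) && !file.exists(p))
    errors <<- c(errors, sprintf("%s file not found: %s", what, p))
  for (nm in names(config$track_paths))
    for (p in unlist(config$track_paths[[nm]])) need(p, paste("track", nm))
  need(config$annotation_path, "annotation")
  need(config$repeats_path, "repeats")
  need(config$genome_path, "genome")
  for (l in c(config$mrna_paths, config$smallrna_paths,
              config$methylome_paths))
    need(l, "table")
  for (nm in names(config$params)) {
    p <- config$params[[nm]]
    if (p$bin_size < p$step)
      errors <- c(errors, sprintf("%s: bin_size (%d) < step (%d)", nm,
                                  p$bin_size, p$step))
  }
  p <- config$params$ibm1_k9
  if (!is.null(p) && p$z_cut_diff != 0.8)
    warnings <- c(warnings, sprintf(
      "ibm1_k9 differential cutoff is %g; the published value is 0.8",
      p$z_cut_diff))
  p <- config$params$met1_k9
  if (!is.null(p) && p$z_cut_diff != 0.75)
    warnings <- c(warnings, sprintf(
      "met1_k9 differential cutoff is %g; the published value is 0.75",
      p$z_cut_diff))
  if (config$min_overlap != 150L)
    warnings <- c(warnings, sprintf(
      "gene-assignment overlap is %d bp; the published rule is 150 bp",
      config$min_overlap))
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}

#' Read a gene/transposon annotation GFF3 into the package's gene frame
#'
#' @param path GFF3 with `ID` attributes.
#' @return data frame `id`, `chrom`, `start` (0-based), `end`, `strand`,
#'   `type`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(id = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = sub("\\*", "+",
                          as.character(GenomicRanges::strand(gr))),
             type = as.character(gr$type), stringsAsFactors = FALSE)
}

#' Run the full redistribution analysis
#'
#' Executes, in order: track loading/normalization; wild-type H3K9me2 block
#' and H3K27me3 enriched region calling; differential H3K9me2 gains in met1
#' and ibm1; met1 H3K27me3 gains (> 500 bp) and losses; gene assignment and
#' Class I/II classification with summary percentages; metagene profiles
#' (ChIP signal, mutant/wild-type ratios, per-context methylation, small-RNA
#' density); and expression summaries (silent fractions, transposon
#' gain-vs-stable comparison, CpG-density comparison of the same groups).
#' When `config$out_dir` is set, region BEDs/TSVs and a JSON report are
#' written there; two runs with identical config and seed produce identical
#' report JSON.
#'
#' @param config a validated [pipeline_config()].
#' @return A `redistribution_report` list (regions, gene sets,
#'   classification, profiles, expression and sequence statistics, summary,
#'   config echo).
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (!v$ok)
    stop("run_pipeline: invalid config:\n  ",
         paste(v$errors, collapse = "\n  "))
  for (w in v$warnings) warning(w, call. = FALSE)
  stage <- function(x) message("[chromredist] ", x)

  stage("loading tracks")
  tracks <- lapply(stats::setNames(nm = names(config$track_paths)),
                   function(nm) {
    tp <- config$track_paths[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (!is.null(tp$norm)) {
      tr <- read_track(tp$norm, mark = parts[1L], genotype = parts[2L],
                       channel = "normalized")
      class(tr) <- c("normalized_track", class(tr))
      tr
    } else {
      log2_ratio_normalize(
        read_track(tp$chip, mark = parts[1L], genotype = parts[2L]),
        read_track(tp$control, channel = "control"))
    }
  })
  annotation <- read_annotation(config$annotation_path)
  genes <- annotation[annotation$type == "gene", , drop = FALSE]
  tes <- annotation[annotation$type == "transposable_element", , drop = FALSE]
  pr <- config$profile

  stage("calling wild-type mark regions")
  regions <- list()
  regions$wt_k9 <- call_blocks(tracks[["H3K9m2.WT"]], config$params$wt_k9)
  bins_wt_k27 <- bin_track(tracks[["H3K27m3.WT"]],
                           config$params$wt_k27$bin_size,
                           config$params$wt_k27$step)
  regions$wt_k27 <- call_enriched_regions(bins_wt_k27, config$params$wt_k27)

  stage("calling differential regions")
  regions$met1_k9_hyper <- call_differential_regions(
    tracks[["H3K9m2.met1"]], tracks[["H3K9m2.WT"]], config$params$met1_k9,
    "hyper", config$k9_resolution)
  regions$ibm1_k9_hyper <- call_differential_regions(
    tracks[["H3K9m2.ibm1"]], tracks[["H3K9m2.WT"]], config$params$ibm1_k9,
    "hyper", config$k9_resolution)
  regions$met1_k27_hyper <- call_differential_regions(
    tracks[["H3K27m3.met1"]], tracks[["H3K27m3.WT"]],
    config$params$k27_hyper, "hyper", "bin")
  regions$met1_k27_hypo <- call_differential_regions(
    tracks[["H3K27m3.met1"]], tracks[["H3K27m3.WT"]],
    config$params$k27_hypo, "hypo", "bin")

  stage("assigning genes and classifying")
  ov <- function(r, g = genes) overlap_genes(r, g, config$min_overlap)
  gene_sets <- list(wt_k9 = ov(regions$wt_k9),
                    wt_k27 = ov(regions$wt_k27),
                    hyper_met1 = ov(regions$met1_k9_hyper),
                    hyper_ibm1 = ov(regions$ibm1_k9_hyper),
                    k27_hyper_te = ov(regions$met1_k27_hyper, tes),
                    k27_hypo = ov(regions$met1_k27_hypo))
  classification <- classify_hyper_genes(gene_sets$hyper_met1,
                                         gene_sets$wt_k9, gene_sets$wt_k27)
  overlap_mut <- set_overlap(gene_sets$hyper_met1, gene_sets$hyper_ibm1)
  pct <- list(
    hyper_met1_of_all = percentage(length(gene_sets$hyper_met1),
                                   nrow(genes)),
    hyper_ibm1_of_all = percentage(length(gene_sets$hyper_ibm1),
                                   nrow(genes)),
    class2_of_pcg = if (length(gene_sets$wt_k27))
      percentage(length(classification$class2), length(gene_sets$wt_k27))
    else NA_real_)

  stage("metagene profiles")
  meta <- function(track, gset) {
    g <- genes[genes$id %in% gset, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    average_profile(metagene_matrix(track, g, pr$flank, pr$bin_width,
                                    pr$n_body_bins), pr$smooth_window)
  }
  profiles <- list()
  for (cls in c("class1", "class2")) {
    gset <- classification[[cls]]
    if (!length(gset)) next
    wtp <- meta(tracks[["H3K9m2.WT"]], gset)
    mtp <- meta(tracks[["H3K9m2.met1"]], gset)
    profiles[[paste0("k9_wt_", cls)]] <- wtp
    profiles[[paste0("k9_met1_", cls)]] <- mtp
    profiles[[paste0("k9_ratio_", cls)]] <- ratio_profile(mtp, wtp)
  }
  if (length(classification$class2)) {
    wtp <- meta(tracks[["H3K27m3.WT"]], classification$class2)
    mtp <- meta(tracks[["H3K27m3.met1"]], classification$class2)
    profiles$k27_wt_class2 <- wtp
    profiles$k27_met1_class2 <- mtp
    profiles$k27_ratio_class2 <- ratio_profile(mtp, wtp)
  }
  if (length(gene_sets$wt_k27)) {
    wtp <- meta(tracks[["H3K27m3.WT"]], gene_sets$wt_k27)
    mtp <- meta(tracks[["H3K27m3.met1"]], gene_sets$wt_k27)
    profiles$k27_ratio_pcg <- ratio_profile(mtp, wtp)
  }
  if (nrow(regions$wt_k9)) {
    # H3K27me3 across wild-type H3K9me2 domains, as pseudo-elements
    doms <- data.frame(id = sprintf("k9dom_%d", seq_len(nrow(regions$wt_k9))),
                       chrom = regions$wt_k9$chrom,
                       start = regions$wt_k9$start, end = regions$wt_k9$end,
                       strand = "+", stringsAsFactors = FALSE)
    doms <- doms[doms$end - doms$start >= pr$n_body_bins, , drop = FALSE]
    if (nrow(doms)) {
      wtp <- average_profile(metagene_matrix(tracks[["H3K27m3.WT"]], doms,
                                             pr$flank, pr$bin_width,
                                             pr$n_body_bins),
                             pr$smooth_window)
      mtp <- average_profile(metagene_matrix(tracks[["H3K27m3.met1"]], doms,
                                             pr$flank, pr$bin_width,
                                             pr$n_body_bins),
                             pr$smooth_window)
      profiles$k27_ratio_k9_domains <- ratio_profile(mtp, wtp)
    }
  }
  if (!is.null(config$methylome_paths) && length(classification$hyper)) {
    hg <- genes[genes$id %in% classification$hyper, , drop = FALSE]
    for (gt in names(config$methylome_paths)) {
      calls <- read_fixture_tsv(config$methylome_paths[[gt]])
      for (ctx in c("CG", "CHG", "CHH"))
        profiles[[paste0("meth_", ctx, "_", gt)]] <-
          methylation_profile(calls, hg, ctx, pr$flank, pr$bin_width,
                              pr$n_body_bins, pr$smooth_window)
    }
  }
  if (!is.null(config$smallrna_paths) && length(classification$class1)) {
    cg1 <- genes[genes$id %in% classification$class1, , drop = FALSE]
    for (gt in names(config$smallrna_paths)) {
      reads <- read_fixture_tsv(config$smallrna_paths[[gt]])
      profiles[[paste0("smallrna_", gt)]] <-
        read_density_profile(reads, cg1, pr$flank, pr$bin_width,
                             pr$n_body_bins, pr$smooth_window)
    }
  }

  expressionr <- NULL
  if (!is.null(config$mrna_paths)) {
    stage("expression summaries")
    tabs <- lapply(stats::setNames(nm = names(config$mrna_paths)),
                   function(gt) compute_rpkm(
                     read_fixture_tsv(config$mrna_paths[[gt]]),
                     library_size = config$library_size, genotype = gt))
    te_gain <- intersect(gene_sets$k27_hyper_te, tes$id)
    te_stable <- setdiff(tes$id, te_gain)
    expressionr <- list(
      tables = tabs,
      silent_fraction_hyper_met1 = if (length(gene_sets$hyper_met1))
        silent_fraction(tabs$WT, gene_sets$hyper_met1) else NA_real_,
      silent_fraction_hyper_ibm1 = if (length(gene_sets$hyper_ibm1))
        silent_fraction(tabs$WT, gene_sets$hyper_ibm1) else NA_real_,
      silent_fraction_all = silent_fraction(tabs$WT, genes$id),
      te_gain_ids = te_gain,
      te_compare_wt = if (length(te_gain) && length(te_stable))
        group_expression_compare(tabs$WT, te_gain, te_stable) else NULL,
      te_reactivation = if (length(te_gain))
        list(rpkm_wt = mean(tabs$WT$rpkm[match(te_gain, tabs$WT$id)]),
             rpkm_met1 = mean(tabs$met1$rpkm[match(te_gain,
                                                   tabs$met1$id)]))
      else NULL)
  }

  seqstats <- NULL
  if (!is.null(config$genome_path)) {
    stage("sequence statistics")
    genome <- Biostrings::readDNAStringSet(config$genome_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    te_gain <- intersect(gene_sets$k27_hyper_te, tes$id)
    te_stable <- setdiff(tes$id, te_gain)
    if (length(te_gain) && length(te_stable)) {
      dens <- cg_density(element_sequences(genome, tes))
      a <- dens$cpg_density[match(te_gain, tes$id)]
      b <- dens$cpg_density[match(te_stable, tes$id)]
      w <- wilcoxon_ranksum(a, b)
      seqstats <- list(cpg_gain_mean = mean(a), cpg_stable_mean = mean(b),
                       gc_gain_mean = mean(dens$gc_fraction[
                         match(te_gain, tes$id)]),
                       gc_stable_mean = mean(dens$gc_fraction[
                         match(te_stable, tes$id)]),
                       wilcoxon_p = w$p)
    }
  }

  summary <- list(
    n_genes = nrow(genes), n_transposons = nrow(tes),
    region_counts = vapply(regions, nrow, integer(1L)),
    gene_set_sizes = vapply(gene_sets, length, integer(1L)),
    classification = classification$summary,
    met1_ibm1_overlap = as.list(overlap_mut),
    percentages = pct)
  report <- structure(
    list(regions = regions, gene_sets = gene_sets,
         classification = classification, profiles = profiles,
         expression = expressionr, seqstats = seqstats, summary = summary,
         config = config),
    class = "redistribution_report")

  if (!is.null(config$out_dir)) {
    stage(paste("writing report to", config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(regions))
      write_regions(regions[[nm]],
                    bed = file.path(config$out_dir, paste0(nm, ".bed")),
                    tsv = file.path(config$out_dir, paste0(nm, ".tsv")),
                    name_prefix = nm)
    for (nm in names(gene_sets))
      writeLines(gene_sets[[nm]],
                 file.path(config$out_dir, paste0("genes_", nm, ".txt")))
    cfg_echo <- unclass(config)
    cfg_echo$params <- lapply(cfg_echo$params, unclass)
    jsonlite::write_json(
      list(summary = list(
        n_genes = summary$n_genes, n_transposons = summary$n_transposons,
        region_counts = as.list(summary$region_counts),
        gene_set_sizes = as.list(summary$gene_set_sizes),
        classification = summary$classification,
        met1_ibm1_overlap = summary$met1_ibm1_overlap,
        percentages = summary$percentages),
        expression = if (!is.null(expressionr))
          expressionr[setdiff(names(expressionr),
                              c("tables", "te_compare_wt"))],
        seqstats = seqstats,
        config = cfg_echo),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.redistribution_report <- function(x, ...) {
  cat("chromatin redistribution report\n")
  cat("  regions:", paste(names(x$summary$region_counts),
                          x$summary$region_counts, sep = "=",
                          collapse = ", "), "\n")
  cat("  gene sets:", paste(names(x$summary$gene_set_sizes),
                            x$summary$gene_set_sizes, sep = "=",
                            collapse = ", "), "\n")
  print(x$classification$summary, row.names = FALSE)
  invisible(x)
}
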