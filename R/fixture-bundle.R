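#' Write a synthetic epigenome to disk as a fixture bundle
#'
#' Emits the standard plain-text formats consumed by the analysis stages:
#' genome FASTA; gene/transposon annotation GFF3 (1-based closed per the
#' format); repeat and planted-truth BED files (0-based half-open);
#' per-mark, per-genotype bedGraphs of the normalized signal plus raw
#' chip/control intensity pairs (control constant, chip
#' `control * 2^signal`, so [log2_ratio_normalize()] recovers the centred
#' signal); methylome and count TSVs; and a JSON manifest with the spec
#' echo, seed and an md5 checksum per file. Re-running with the same spec
#' reproduces identical checksums.
#'
#' @param sim a `synthetic_epigenome` from [simulate_epigenome()].
#' @param dir output directory (created if needed).
#' @param control_intensity constant raw control-channel intensity.
#' @return data frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json`.
#' @export
write_fixture_bundle <- function(sim, dir, control_intensity = 500) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L)
    stop("write_fixture_bundle: directory not writable: ", dir)
  paths <- character()
  add <- function(p) paths[[length(paths) + 1L]] <<- p

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  add(fa)

  ann <- sim$annotation
  main <- ann[ann$type %in% c("gene", "transposable_element"), , drop = FALSE]
  gff <- file.path(dir, "annotation.gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\tchromredist\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       main$chrom, main$type, as.integer(main$start) + 1L,
                       as.integer(main$end), main$strand, main$id)), gff)
  add(gff)

  reps <- ann[ann$type %in% c("dispersed_repeat", "tandem_repeat"), ,
              drop = FALSE]
  bed <- file.path(dir, "repeats.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", reps$chrom,
                     as.integer(reps$start), as.integer(reps$end),
                     paste(reps$id, reps$type, sep = "|"), reps$strand), bed)
  add(bed)

  for (gt in names(sim$truth$planted)) {
    for (mark in names(sim$truth$planted[[gt]])) {
      pl <- sim$truth$planted[[gt]][[mark]]
      p <- file.path(dir, sprintf("truth_%s_%s.bed", mark, gt))
      writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", pl$chrom,
                         as.integer(pl$start), as.integer(pl$end),
                         pl$element_id, as.integer(round(1000 * pl$lift))),
                 p)
      add(p)
    }
  }

  ctrl_written <- FALSE
  for (nm in names(sim$tracks)) {
    tr <- sim$tracks[[nm]]
    p <- file.path(dir, sprintf("%s.norm.bedGraph", nm))
    write_track(tr, p)
    add(p)
    chip <- tr
    chip$value <- control_intensity * 2^tr$value
    p2 <- file.path(dir, sprintf("%s.chip.bedGraph", nm))
    write_track(chip, p2)
    add(p2)
    if (!ctrl_written) {
      ctrl <- tr
      ctrl$value <- rep(control_intensity, nrow(tr))
      pc <- file.path(dir, "control.bedGraph")
      write_track(ctrl, pc)
      add(pc)
      ctrl_written <- TRUE
    }
  }

  if (!is.null(sim$methylomes)) for (gt in names(sim$methylomes)) {
    p <- file.path(dir, sprintf("methylome_%s.tsv", gt))
    utils::write.table(sim$methylomes[[gt]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(p)
  }
  if (!is.null(sim$expression)) for (gt in names(sim$expression)) {
    p <- file.path(dir, sprintf("mrna_%s.tsv", gt))
    utils::write.table(
      as.data.frame(sim$expression[[gt]])[, c("id", "length", "count")],
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    add(p)
  }
  if (!is.null(sim$smallrna)) for (gt in names(sim$smallrna)) {
    p <- file.path(dir, sprintf("smallrna_%s.tsv", gt))
    utils::write.table(sim$smallrna[[gt]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(p)
  }
  p <- file.path(dir, "truth_elements.tsv")
  utils::write.table(sim$truth$elements, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(p)

  paths <- unlist(paths)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(seed = sim$spec$seed,
         spec = unclass(sim$spec),
         files = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture-bundle methylome / count / small-RNA TSV
#'
#' @param path TSV written by [write_fixture_bundle()].
#' @return data frame.
#' @export
read_fixture_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
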