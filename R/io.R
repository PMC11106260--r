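# Plain-text I/O: FASTA/FASTQ via Biostrings, BED6/bedGraph/TSV via readr,
# blueprint configs via yaml.

#' Read a FASTA file
#' @param path file path.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences as 60-column-wrapped FASTA
#' @param x `DNAStringSet` (or named character vector).
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#' @param path file path.
#' @return named `DNAStringSet`.
#' @export
read_fastq <- function(path)
  Biostrings::readDNAStringSet(path, format = "fastq")

#' Write reads as FASTQ (phred+33, constant quality)
#' @param x named `DNAStringSet`.
#' @param path output path.
#' @param qual quality character applied to every base (default "I", Q40).
#' @export
write_fastq <- function(x, path, qual = "I") {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    strrep(qual, w), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a 4-column bedGraph track
#' @param path file path.
#' @return tibble: `chrom`, `start`, `end`, `count`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "count"),
                  col_types = "ciid", progress = FALSE, comment = "#")
}

#' Write a 4-column bedGraph track
#' @param track tibble with `chrom`, `start`, `end` and a score column.
#' @param path output path.
#' @param score name of the score column (default `count`).
#' @export
write_bedgraph <- function(track, path, score = "count") {
  readr::write_tsv(track[, c("chrom", "start", "end", score)], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param x tibble with `chrom`, `start`, `end` plus optional name/score/
#'   strand columns.
#' @param path output path.
#' @param name,score,strand column names to use for BED fields 4-6 (missing
#'   columns are filled with `.`/`0`/`+`).
#' @export
write_bed6 <- function(x, path, name = NULL, score = NULL, strand = NULL) {
  get <- function(col, default) if (!is.null(col) && col %in% names(x))
    x[[col]] else rep(default, nrow(x))
  bed <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                        name = get(name, "."), score = get(score, 0),
                        strand = get(strand, "+"))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a simulation truth set as BED6 plus attribute TSV
#'
#' @param truth truth tibble from [simulate_genome()].
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.attrs.tsv`.
#' @export
write_truth <- function(truth, prefix) {
  write_bed6(truth, paste0(prefix, ".bed"), name = "feature_class",
             strand = "strand")
  readr::write_tsv(truth, paste0(prefix, ".attrs.tsv"))
  invisible(prefix)
}

#' Read a genome blueprint from a YAML config
#'
#' The config mirrors the blueprint constructors: top-level `chrom_lengths`
#' and `seed`, with optional `telomere`, `nor`, `ltr` (a list of family
#' entries), `centromere` and `organelle` blocks whose keys are the
#' corresponding `*_spec()` arguments.
#'
#' @param path YAML file path.
#' @return a [genome_blueprint()].
#' @export
read_blueprint_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_df <- function(x) if (is.null(x)) NULL else
    dplyr::bind_rows(lapply(x, tibble::as_tibble))
  genome_blueprint(
    chrom_lengths = unlist(cfg$chrom_lengths),
    seed = cfg$seed %||% 1L,
    telomere = if (is.null(cfg$telomere)) telomere_spec()
               else do.call(telomere_spec, cfg$telomere),
    nor = if (is.null(cfg$nor)) NULL else {
      args <- cfg$nor
      if (!is.null(args$classes)) args$classes <- as.data.frame(as_df(args$classes))
      do.call(nor_spec, args)
    },
    ltr = if (is.null(cfg$ltr)) NULL else
      dplyr::bind_rows(lapply(cfg$ltr, function(e) {
        # YAML 1.1 reads a bare `n:` key as logical FALSE; undo that
        names(e)[names(e) %in% c("FALSE", "count")] <- "n"
        do.call(ltr_spec, e)
      })),
    centromere = if (is.null(cfg$centromere)) NULL else
      do.call(centromere_spec, cfg$centromere),
    organelle = if (is.null(cfg$organelle)) NULL else {
      args <- cfg$organelle
      if (!is.null(args$insertions))
        args$insertions <- as.data.frame(as_df(args$insertions))
      do.call(organelle_spec, args)
    })
}
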