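# Organelle-contig screening (the >= 50% covered-bases removal rule) and
# detection of genuine nuclear organelle insertions supported by spanning
# reads.

# canonical k-mer set of the organelle references
.organelle_kmer_set <- function(organelle_refs, k) {
  unique(unlist(lapply(as.character(organelle_refs), function(s)
    canonical_kmers(kmers_chr(s, k))), use.names = FALSE))
}

# IRanges of organelle-matching positions on one contig (1-based)
.organelle_hits <- function(contig_chr, kset, k, merge_gap = 0L) {
  km <- kmers_chr(contig_chr, k)
  if (!length(km)) return(IRanges::IRanges())
  hit <- which(canonical_kmers(km) %chin% kset)
  if (!length(hit)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = hit, end = hit + k - 1L),
                  min.gapwidth = merge_gap + 1L)
}

#' Fraction of a contig covered by organelle sequence
#'
#' Matching intervals are the union of exact canonical `k_anchor`-mer hits
#' against the organelle references (each hit covering its k bases); the
#' fraction is the union length divided by the contig length.
#'
#' @param contig `DNAString`/character contig (non-empty).
#' @param organelle_refs `DNAStringSet` of organelle reference genomes.
#' @param k_anchor anchor k-mer size (default 31).
#' @return one-row tibble: `contig_id`, `covered_bp`, `contig_len`,
#'   `fraction`.
#' @export
coverage_fraction <- function(contig, organelle_refs, k_anchor = 31L) {
  contig_chr <- as.character(contig)
  if (!nzchar(contig_chr)) stop("contig is empty")
  if (!length(organelle_refs)) stop("organelle references are empty")
  kset <- .organelle_kmer_set(organelle_refs, k_anchor)
  iv <- .organelle_hits(contig_chr, kset, k_anchor)
  covered <- sum(IRanges::width(iv))
  tibble::tibble(contig_id = "contig", covered_bp = covered,
                 contig_len = nchar(contig_chr),
                 fraction = covered / nchar(contig_chr))
}

#' Filter organelle-derived contigs
#'
#' Removes contigs with at least `threshold` of their bases covered by
#' organelle reference sequence (the threshold is inclusive: a fraction of
#' exactly 0.5 is removed at the default). Filtering is idempotent on the
#' kept set.
#'
#' @param contigs named `DNAStringSet`.
#' @param organelle_refs `DNAStringSet` of organelle references.
#' @param threshold removal threshold in `(0, 1]` (default 0.5).
#' @param k_anchor anchor k-mer size.
#' @return list with `kept` and `removed` (`DNAStringSet`s) and `reports`
#'   tibble (`contig_id`, `covered_bp`, `contig_len`, `fraction`, `verdict`).
#' @export
filter_contigs <- function(contigs, organelle_refs, threshold = 0.5,
                           k_anchor = 31L) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(contigs))
    return(list(kept = contigs, removed = contigs,
                reports = tibble::tibble(contig_id = character(0),
                                         covered_bp = numeric(0),
                                         contig_len = numeric(0),
                                         fraction = numeric(0),
                                         verdict = character(0))))
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  kset <- .organelle_kmer_set(organelle_refs, k_anchor)
  reports <- lapply(seq_along(contigs), function(i) {
    s <- as.character(contigs[[i]])
    iv <- .organelle_hits(s, kset, k_anchor)
    covered <- sum(IRanges::width(iv))
    frac <- covered / nchar(s)
    tibble::tibble(contig_id = names(contigs)[i], covered_bp = covered,
                   contig_len = nchar(s), fraction = frac,
                   verdict = if (frac >= threshold) "remove" else "keep")
  })
  reports <- dplyr::bind_rows(reports)
  keep <- reports$verdict == "keep"
  list(kept = contigs[keep], removed = contigs[!keep], reports = reports)
}

#' Detect nuclear organelle insertions supported by spanning reads
#'
#' Candidates are maximal organelle-matching intervals on kept contigs with at
#' least `flank_bp` of non-organelle sequence on both sides. A candidate is
#' `supported` iff at least one read anchors with a consistent seed diagonal
#' in both flanking windows, i.e. spans the entire integration site.
#'
#' @param genome named `DNAStringSet` of (kept) contigs.
#' @param organelle_refs named `DNAStringSet`; names give `organelle_source`.
#' @param reads named `DNAStringSet` of long reads.
#' @param flank_bp required non-organelle flank (default 5,000 bp).
#' @param k_anchor anchor k-mer size (default 31).
#' @param min_flank_seeds minimum consistent seeds per flank for a spanning
#'   read.
#' @param merge_gap hits separated by at most this many bp are merged into
#'   one candidate interval.
#' @return tibble of insertion calls: `chrom`, `start`, `stop` (0-based
#'   half-open), `organelle_source`, `spanning_read_count`, `supported`.
#' @export
detect_nuclear_insertions <- function(genome, organelle_refs, reads,
                                      flank_bp = 5000L, k_anchor = 31L,
                                      min_flank_seeds = 5L, merge_gap = 200L) {
  if (flank_bp <= 0) stop("flank_bp must be > 0")
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  src_sets <- lapply(as.character(organelle_refs), function(s)
    unique(canonical_kmers(kmers_chr(s, k_anchor))))
  names(src_sets) <- names(organelle_refs) %||%
    paste0("organelle", seq_along(organelle_refs))
  kset <- unique(unlist(src_sets, use.names = FALSE))
  reads_chr <- as.character(reads)
  calls <- list()
  for (ci in seq_along(genome)) {
    s <- as.character(genome[[ci]])
    L <- nchar(s)
    iv <- .organelle_hits(s, kset, k_anchor, merge_gap = merge_gap)
    if (!length(iv)) next
    km <- kmers_chr(s, k_anchor)
    ckm <- canonical_kmers(km)
    for (j in seq_along(iv)) {
      st <- IRanges::start(iv)[j]; en <- IRanges::end(iv)[j]   # 1-based closed
      if (st - 1L < flank_bp || L - en < flank_bp) next
      # attribute to the source contributing most k-mers in the interval
      seg <- ckm[st:(en - k_anchor + 1L)]
      src_hits <- vapply(src_sets, function(ks) sum(seg %chin% ks), numeric(1))
      source <- names(src_sets)[which.max(src_hits)]
      # spanning support: consistent-diagonal seeds in both flank windows
      span_lo <- st - flank_bp; span_hi <- en + flank_bp
      wtab <- data.table::data.table(
        kmer = km[span_lo:(span_hi - k_anchor + 1L)],
        pos = span_lo:(span_hi - k_anchor + 1L))
      wtab <- wtab[, list(n = .N, pos = pos[1L]), by = "kmer"][n == 1L]
      n_span <- 0L
      for (ri in seq_along(reads_chr)) {
        spans <- FALSE
        for (strand in c("+", "-")) {
          rs <- if (strand == "+") reads_chr[ri] else revcomp_chr(reads_chr[ri])
          rtab <- .kmer_positions(rs, k_anchor)
          hits <- merge(rtab, wtab[, c("kmer", "pos")], by = "kmer",
                        suffixes = c("_r", "_w"))
          if (!nrow(hits)) next
          diag <- hits$pos_w - hits$pos_r
          dd <- sort(diag)
          grp <- cumsum(c(1L, as.integer(diff(dd) > 100L)))
          for (g in unique(grp)) {
            dsel <- dd[grp == g]
            hs <- hits[diag %in% dsel, ]
            left_n <- sum(hs$pos_w < st)
            right_n <- sum(hs$pos_w > en - k_anchor + 1L)
            if (left_n >= min_flank_seeds && right_n >= min_flank_seeds) {
              spans <- TRUE; break
            }
          }
          if (spans) break
        }
        if (spans) n_span <- n_span + 1L
      }
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = names(genome)[ci], start = st - 1, stop = en,
        organelle_source = source, spanning_read_count = n_span,
        supported = n_span >= 1L)
    }
  }
  if (!length(calls))
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          stop = numeric(0), organelle_source = character(0),
                          spanning_read_count = integer(0),
                          supported = logical(0)))
  dplyr::bind_rows(calls)
}
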