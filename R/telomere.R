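# Terminal telomere detection and read-based patching.
#
# Strand convention: a "right" chromosome end carries the forward telomeric
# motif (TTTAGGG)n; a "left" end carries its reverse complement (CCCTAAA)n.
# The scanner searches all 7 rotations of each motif so that a tandem run is
# recognized regardless of the register at which the array was assembled.

.check_motifs <- function(motifs) {
  if (!all(grepl("^[ACGT]{7}$", motifs)))
    stop("telomeric motifs must be 7-mers over ACGT")
  motifs
}

.rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n), function(i)
    paste0(substr(motif, i, n), substr(motif, 1, i - 1L)), "")
}

# Locate tandem runs of any rotation of the given motifs in one sequence.
# Returns a tibble with 1-based [start, end] spans, greedy non-overlapping
# copy counts, purity, and the majority base motif.
.tandem_runs <- function(seq_chr, motifs, gap_tol = 14L) {
  rots <- unique(unlist(lapply(motifs, .rotations)))
  loc <- stringi::stri_locate_all_fixed(seq_chr, rots, overlap = TRUE)
  starts <- sort(unique(unlist(lapply(loc, function(m) m[, 1]))))
  starts <- starts[!is.na(starts)]
  if (!length(starts))
    return(tibble::tibble(start = integer(0), end = integer(0),
                          copy_count = integer(0), purity = numeric(0),
                          motif = character(0)))
  grp <- cumsum(c(1L, as.integer(diff(starts) > gap_tol)))
  runs <- lapply(split(starts, grp), function(s) {
    # greedy maximal non-overlapping motif placement
    cnt <- 0L; nxt <- -Inf
    for (p in s) if (p >= nxt) { cnt <- cnt + 1L; nxt <- p + 7L }
    span_start <- s[1]; span_end <- s[length(s)] + 6L
    sub <- substr(seq_chr, span_start, span_end)
    occ <- vapply(motifs, function(m)
      stringi::stri_count_fixed(sub, m, overlap = TRUE), numeric(1))
    tibble::tibble(start = span_start, end = span_end, copy_count = cnt,
                   purity = 7 * cnt / (span_end - span_start + 1L),
                   motif = motifs[which.max(occ)])
  })
  dplyr::bind_rows(runs)
}

#' Scan contig termini for telomeric arrays
#'
#' Searches the terminal `scan_window_bp` of each contig for tandem runs of
#' the 7-bp telomeric motifs: the forward motifs at the right end and their
#' reverse complements at the left end. At most one call is made per end (the
#' run with the most copies that reaches within `max_offset` of the
#' terminus). Copy counts are maximal non-overlapping motif placements over
#' all 7 rotations; left-end calls are orientation-normalized so `motif`
#' always reports the forward motif.
#'
#' @param genome `DNAStringSet` (or single `DNAString`/character) of contigs.
#' @param motifs forward 7-mer motifs (default TTTAGGG plus its TTCAGGG
#'   variant).
#' @param scan_window_bp terminal window scanned at each end.
#' @param min_copies minimum copy count for an assembly-level call.
#' @param min_purity minimum fraction of the called interval covered by motif
#'   copies.
#' @param max_offset maximum distance (bp) between the array and the terminus.
#' @return tibble of telomere calls: `chrom`, `end_side`, `start`, `stop`
#'   (0-based half-open), `motif`, `copy_count`, `purity`.
#' @export
scan_terminal_telomere <- function(genome, motifs = c("TTTAGGG", "TTCAGGG"),
                                   scan_window_bp = 20000L, min_copies = 100L,
                                   min_purity = 0.8, max_offset = 1000L) {
  .check_motifs(motifs)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  if (inherits(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(list(contig = genome))
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  rc_motifs <- revcomp_chr(motifs)
  calls <- list()
  for (ci in seq_along(genome)) {
    L <- Biostrings::width(genome)[ci]
    if (L < scan_window_bp) next
    seq_chr <- as.character(genome[[ci]])
    for (side in c("left", "right")) {
      if (side == "left") {
        win <- substr(seq_chr, 1L, scan_window_bp)
        off0 <- 0L
        runs <- .tandem_runs(win, rc_motifs)
        # normalize to forward motif names
        if (nrow(runs))
          runs$motif <- motifs[match(runs$motif, rc_motifs)]
      } else {
        off0 <- L - scan_window_bp
        win <- substr(seq_chr, off0 + 1L, L)
        runs <- .tandem_runs(win, motifs)
      }
      if (!nrow(runs)) next
      runs$g_start <- off0 + runs$start - 1L   # 0-based
      runs$g_stop <- off0 + runs$end
      near <- if (side == "left") runs$g_start <= max_offset
              else runs$g_stop >= L - max_offset
      runs <- runs[near & runs$copy_count >= min_copies &
                     runs$purity >= min_purity, , drop = FALSE]
      if (!nrow(runs)) next
      best <- runs[which.max(runs$copy_count), ]
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = names(genome)[ci], end_side = side,
        start = best$g_start, stop = best$g_stop, motif = best$motif,
        copy_count = best$copy_count, purity = best$purity)
    }
  }
  if (!length(calls))
    return(tibble::tibble(chrom = character(0), end_side = character(0),
                          start = numeric(0), stop = numeric(0),
                          motif = character(0), copy_count = integer(0),
                          purity = numeric(0)))
  dplyr::bind_rows(calls)
}

#' Select telomere-bearing ultralong reads
#'
#' A read is selected iff its length exceeds `min_read_len` and it contains at
#' least `min_motif_copies` copies of any motif (or its reverse complement)
#' within one tandem run.
#'
#' @param reads named `DNAStringSet`.
#' @param min_read_len length threshold, exclusive (default 200,000 bp).
#' @param min_motif_copies tandem copy threshold (default 10).
#' @param motifs forward 7-mer motifs.
#' @return the selected subset of `reads`.
#' @export
select_telomere_reads <- function(reads, min_read_len = 200000L,
                                  min_motif_copies = 10L,
                                  motifs = c("TTTAGGG", "TTCAGGG")) {
  .check_motifs(motifs)
  if (!length(reads)) return(reads)
  long_enough <- Biostrings::width(reads) > min_read_len
  keep <- logical(length(reads))
  both <- c(motifs, revcomp_chr(motifs))
  for (i in which(long_enough)) {
    runs <- .tandem_runs(as.character(reads[[i]]), both)
    keep[i] <- nrow(runs) > 0 && max(runs$copy_count) >= min_motif_copies
  }
  reads[keep]
}

#' Anchor a read to a contig end by unique k-mer seeds
#'
#' Seeds are k-mers that occur exactly once within the terminal `terminal_bp`
#' window of the contig. The read (on each strand) is placed at the seed
#' diagonal supported by the most seeds; the placement is accepted iff it has
#' at least `min_seeds` consistent seeds. Ties between strands are broken by
#' seed count.
#'
#' @param read a `DNAString`/character read.
#' @param contig a `DNAString`/character contig.
#' @param end_side `"left"` or `"right"`.
#' @param k seed size (>= 15).
#' @param terminal_bp width of the terminal anchoring window.
#' @param min_seeds minimum consistent seeds for an accepted anchor.
#' @param diag_tol seeds whose diagonals differ by at most this many bp are
#'   treated as one chain (absorbs small indels).
#' @param read_id,chrom identifiers carried into the result.
#' @return one-row tibble: `read_id`, `chrom`, `end_side`, `orientation`,
#'   `contig_start`, `contig_end`, `read_start`, `read_end` (0-based
#'   half-open anchor spans), `overhang_len`, `n_seed_matches`.
#' @export
anchor_read_to_end <- function(read, contig, end_side = c("left", "right"),
                               k = 21L, terminal_bp = 50000L, min_seeds = 20L,
                               diag_tol = 100L, read_id = "read",
                               chrom = "contig") {
  end_side <- match.arg(end_side)
  if (k < 15) stop("anchor seed size k must be >= 15")
  contig_chr <- as.character(contig)
  L <- nchar(contig_chr)
  if (terminal_bp > L) stop("terminal_bp exceeds contig length")
  off1 <- if (end_side == "left") 1L else L - terminal_bp + 1L
  win <- substr(contig_chr, off1, off1 + terminal_bp - 1L)
  wtab <- .kmer_positions(win, k)
  wtab <- wtab[, list(n = .N, pos = pos[1L]), by = "kmer"][n == 1L]
  read_chr <- as.character(read)
  best <- NULL
  for (strand in c("+", "-")) {
    rseq <- if (strand == "+") read_chr else revcomp_chr(read_chr)
    rtab <- .kmer_positions(rseq, k)
    hits <- merge(rtab, wtab[, c("kmer", "pos")], by = "kmer",
                  suffixes = c("_r", "_w"))
    if (!nrow(hits)) next
    diag <- sort(hits$pos_w - hits$pos_r)
    grp <- cumsum(c(1L, as.integer(diff(diag) > diag_tol)))
    sizes <- tabulate(grp)
    gi <- which.max(sizes)
    if (is.null(best) || sizes[gi] > best$n) {
      dsel <- diag[grp == gi]
      hsel <- hits[(hits$pos_w - hits$pos_r) %in% dsel, ]
      best <- list(n = sizes[gi], strand = strand,
                   D = round(stats::median(dsel)) + off1 - 1L,
                   pos_w = hsel$pos_w, pos_r = hsel$pos_r)
    }
  }
  if (is.null(best) || best$n < min_seeds)
    stop("no qualifying anchor chain for read '", read_id, "'")
  rlen <- nchar(read_chr)
  overhang <- if (end_side == "right") max(0L, (rlen + best$D) - L)
              else max(0L, -best$D)
  tibble::tibble(
    read_id = read_id, chrom = chrom, end_side = end_side,
    orientation = best$strand,
    contig_start = min(best$pos_w) + off1 - 2L,
    contig_end = max(best$pos_w) + off1 - 1L + k - 1L,
    read_start = min(best$pos_r) - 1L,
    read_end = max(best$pos_r) + k - 1L,
    overhang_len = as.numeric(overhang), n_seed_matches = best$n)
}

#' Anchor a set of reads to a contig end
#'
#' Convenience wrapper over [anchor_read_to_end()]: reads with no qualifying
#' seed chain are skipped rather than raising an error.
#'
#' @inheritParams anchor_read_to_end
#' @param reads named `DNAStringSet`.
#' @return tibble of anchors (possibly empty).
#' @export
anchor_telomere_reads <- function(reads, contig, end_side, k = 21L,
                                  terminal_bp = 50000L, min_seeds = 20L,
                                  chrom = "contig") {
  res <- lapply(seq_along(reads), function(i) {
    tryCatch(anchor_read_to_end(reads[[i]], contig, end_side, k = k,
                                terminal_bp = terminal_bp,
                                min_seeds = min_seeds,
                                read_id = names(reads)[i], chrom = chrom),
             error = function(e) NULL)
  })
  dplyr::bind_rows(res)
}

# identity between two overhang sequences compared from the contig terminus
.overhang_identity <- function(a, b, side) {
  m <- min(nchar(a), nchar(b))
  if (m == 0L) return(1)
  if (side == "right") { a <- substr(a, 1L, m); b <- substr(b, 1L, m) }
  else { a <- substr(a, nchar(a) - m + 1L, nchar(a))
         b <- substr(b, nchar(b) - m + 1L, nchar(b)) }
  mean(charToRaw(a) == charToRaw(b))
}

.overhang_seq <- function(anchor, reads) {
  s <- as.character(reads[[anchor$read_id]])
  if (anchor$orientation == "-") s <- revcomp_chr(s)
  ov <- anchor$overhang_len
  if (anchor$end_side == "right") substr(s, nchar(s) - ov + 1L, nchar(s))
  else substr(s, 1L, ov)
}

#' Patch missing telomeres from anchored read overhangs
#'
#' For each contig end with at least `min_support` anchored reads whose
#' overhangs extend past the terminus, appends the overhang of the
#' best-ranked anchor (most seeds, then longest overhang, then lexicographic
#' read id), orientation-corrected. No base of the input contig is modified.
#' Overhangs that disagree pairwise (< `min_overhang_identity` over their
#' shared terminal-aligned span) raise a conflict error and nothing is
#' patched.
#'
#' @param contig `DNAString`/character contig.
#' @param anchors anchor tibble from [anchor_telomere_reads()].
#' @param reads named `DNAStringSet` holding the anchored reads.
#' @param min_support minimum concordant anchors per end.
#' @param min_overhang_identity pairwise identity floor among overhangs.
#' @return list with `contig` (patched `DNAString`) and `report` tibble
#'   (`end_side`, `read_id`, `overhang_len`, `support`, `patched_len`).
#' @export
patch_telomere <- function(contig, anchors, reads, min_support = 1L,
                           min_overhang_identity = 0.9) {
  contig_chr <- as.character(contig)
  report <- list()
  if (!is.null(anchors) && nrow(anchors)) {
    for (side in c("right", "left")) {
      cand <- anchors[anchors$end_side == side & anchors$overhang_len > 0, ,
                      drop = FALSE]
      if (nrow(cand) < min_support || nrow(cand) == 0L) next
      ovs <- vapply(seq_len(nrow(cand)), function(i)
        .overhang_seq(cand[i, ], reads), "")
      if (nrow(cand) > 1L) {
        for (i in seq_len(nrow(cand) - 1L)) for (j in (i + 1L):nrow(cand)) {
          idt <- .overhang_identity(ovs[i], ovs[j], side)
          if (idt < min_overhang_identity)
            stop("conflicting telomere overhangs at ", side, " end (reads '",
                 cand$read_id[i], "' and '", cand$read_id[j],
                 "', identity ", signif(idt, 3), ")")
        }
      }
      o <- order(-cand$n_seed_matches, -cand$overhang_len, cand$read_id)
      best <- o[1]
      contig_chr <- if (side == "right") paste0(contig_chr, ovs[best])
                    else paste0(ovs[best], contig_chr)
      report[[length(report) + 1L]] <- tibble::tibble(
        end_side = side, read_id = cand$read_id[best],
        overhang_len = cand$overhang_len[best], support = nrow(cand),
        patched_len = nchar(contig_chr))
    }
  }
  report <- if (length(report)) dplyr::bind_rows(report)
    else tibble::tibble(end_side = character(0), read_id = character(0),
                        overhang_len = numeric(0), support = integer(0),
                        patched_len = numeric(0))
  list(contig = Biostrings::DNAString(contig_chr), report = report)
}
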