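# Cis-regulatory motif scanning (IUPAC-aware, both strands), exact
# presence/absence enrichment against a background, and intersection of
# enriched sets across analyses.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
            W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
            V = "ACG", N = "ACGT")

#' Default cis-element motif library
#'
#' Consensus strings for the five transcription-factor binding motif families
#' commonly scanned in plant promoters and open chromatin: MYB (MYB binding
#' site), G-box, Box-4, ABRE and MYC (E-box). The table is plain data and can
#' be edited or extended before scanning.
#'
#' @return tibble: `name`, `consensus` (IUPAC string).
#' @export
motif_library <- function() {
  tibble::tibble(
    name = c("MYB", "G-box", "Box-4", "ABRE", "MYC"),
    consensus = c("CAACTG", "CACGTG", "ATTAAT", "ACGTGGC", "CANNTG"))
}

.check_iupac <- function(consensus) {
  bad <- !grepl(paste0("^[", paste(names(.IUPAC), collapse = ""), "]+$"),
                consensus)
  if (any(bad))
    stop("invalid IUPAC character in motif consensus: ",
         paste(consensus[bad], collapse = ", "))
  if (any(nchar(consensus) < 4)) stop("motif consensus must be >= 4 bp")
  invisible(consensus)
}

#' Scan sequences for motif occurrences
#'
#' IUPAC-aware exact matching on both strands. Ambiguity codes in the motif
#' expand to their base sets; `N` in a *sequence* never matches. A motif whose
#' consensus is its own reverse complement (e.g. a palindromic G-box) is
#' counted once per site.
#'
#' @param seqs named `DNAStringSet` (or character vector) over `ACGTN`.
#' @param motifs motif tibble (`name`, `consensus`), default
#'   [motif_library()].
#' @return tibble: `seq_id`, `motif`, `count`, `present`.
#' @export
scan_motifs <- function(seqs, motifs = motif_library()) {
  .check_iupac(motifs$consensus)
  if (is.character(seqs)) {
    nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(stats::setNames(seqs, nm))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  # N in a sequence must never match, so scan the N-free segments of each
  # sequence and sum their counts
  seq_chr <- as.character(seqs)
  segs <- strsplit(seq_chr, "N+")
  seg_idx <- rep(seq_along(seqs), lengths(segs))
  seg_set <- Biostrings::DNAStringSet(unlist(segs, use.names = FALSE))
  res <- lapply(seq_len(nrow(motifs)), function(mi) {
    pat <- motifs$consensus[mi]
    fixed <- c(pattern = FALSE, subject = TRUE)
    seg_cnt <- Biostrings::vcountPattern(pat, seg_set, fixed = fixed)
    rc <- revcomp_chr(pat)
    if (rc != pat)
      seg_cnt <- seg_cnt + Biostrings::vcountPattern(rc, seg_set, fixed = fixed)
    cnt <- integer(length(seqs))
    agg <- tapply(seg_cnt, seg_idx, sum)
    cnt[as.integer(names(agg))] <- as.integer(agg)
    tibble::tibble(seq_id = names(seqs), motif = motifs$name[mi],
                   count = cnt, present = cnt > 0)
  })
  dplyr::bind_rows(res)
}

#' Motif enrichment of a foreground against a background
#'
#' One-sided exact test of over-representation on the 2x2 presence table
#' (hypergeometric upper tail), per motif, with Benjamini-Hochberg q-values
#' across the motif set. A motif is `enriched` iff its raw p-value is below
#' `alpha` (default 0.01). An occurrence-count binomial test is available as
#' an alternative statistic.
#'
#' @param fg_scan,bg_scan scan tables from [scan_motifs()] for the foreground
#'   and background sequence sets (both non-empty).
#' @param alpha enrichment threshold on the raw p-value.
#' @param method `"presence"` (default; 2x2 exact hypergeometric) or
#'   `"occurrence"` (binomial on pooled occurrence counts, proportional to
#'   set sizes).
#' @return tibble: `motif`, `fg_with`, `fg_total`, `bg_with`, `bg_total`,
#'   `p_value`, `q_value`, `enriched`.
#' @export
enrich_motifs <- function(fg_scan, bg_scan, alpha = 0.01,
                          method = c("presence", "occurrence")) {
  method <- match.arg(method)
  if (!nrow(fg_scan)) stop("empty foreground scan")
  if (!nrow(bg_scan)) stop("empty background scan")
  fg <- dplyr::summarise(dplyr::group_by(fg_scan, .data$motif),
                         fg_with = sum(.data$present),
                         fg_total = dplyr::n(),
                         fg_occ = sum(.data$count), .groups = "drop")
  bg <- dplyr::summarise(dplyr::group_by(bg_scan, .data$motif),
                         bg_with = sum(.data$present),
                         bg_total = dplyr::n(),
                         bg_occ = sum(.data$count), .groups = "drop")
  tab <- dplyr::inner_join(fg, bg, by = "motif")
  p <- if (method == "presence") {
    # P(X >= fg_with) drawing fg_total from an urn of all 'present' sequences
    stats::phyper(tab$fg_with - 1L, tab$fg_with + tab$bg_with,
                  tab$fg_total + tab$bg_total - tab$fg_with - tab$bg_with,
                  tab$fg_total, lower.tail = FALSE)
  } else {
    vapply(seq_len(nrow(tab)), function(i) {
      n <- tab$fg_occ[i] + tab$bg_occ[i]
      if (n == 0) return(1)
      pr <- tab$fg_total[i] / (tab$fg_total[i] + tab$bg_total[i])
      stats::binom.test(tab$fg_occ[i], n, pr,
                        alternative = "greater")$p.value
    }, numeric(1))
  }
  tibble::tibble(motif = tab$motif, fg_with = tab$fg_with,
                 fg_total = tab$fg_total, bg_with = tab$bg_with,
                 bg_total = tab$bg_total, p_value = p,
                 q_value = stats::p.adjust(p, "BH"),
                 enriched = p < alpha)
}

#' Intersect two enrichment analyses
#'
#' Returns the motifs enriched (raw p below `alpha`) in both analyses,
#' sorted by the larger of the two p-values, ascending.
#'
#' @param results_a,results_b [enrich_motifs()] result tibbles computed at
#'   the same `alpha`.
#' @param alpha enrichment threshold.
#' @return tibble: `motif`, `p_a`, `p_b`, `max_p`.
#' @export
intersect_enriched <- function(results_a, results_b, alpha = 0.01) {
  a <- results_a[results_a$p_value < alpha, c("motif", "p_value")]
  b <- results_b[results_b$p_value < alpha, c("motif", "p_value")]
  j <- dplyr::inner_join(a, b, by = "motif", suffix = c("_a", "_b"))
  out <- tibble::tibble(motif = j$motif, p_a = j$p_value_a, p_b = j$p_value_b,
                        max_p = pmax(j$p_value_a, j$p_value_b))
  dplyr::arrange(out, .data$max_p)
}

#' Dinucleotide-preserving background shuffle
#'
#' Generates one background sequence per input by resampling a first-order
#' Markov chain fitted to that sequence, preserving length and (in
#' expectation) dinucleotide composition. Seeded, hence reproducible.
#'
#' @param seqs named `DNAStringSet` or character vector.
#' @param seed integer seed.
#' @return named `DNAStringSet` of shuffled sequences (names suffixed
#'   `_shuf`).
#' @export
shuffle_background <- function(seqs, seed = 1L) {
  seqs_chr <- as.character(seqs)
  nm <- names(seqs_chr) %||% paste0("seq", seq_along(seqs_chr))
  withr::with_seed(seed, {
    out <- vapply(seqs_chr, function(s) {
      n <- nchar(s)
      if (n < 2) return(s)
      ch <- strsplit(s, "")[[1]]
      bases <- c("A", "C", "G", "T")
      trans <- matrix(1, 4, 4, dimnames = list(bases, bases))  # +1 smoothing
      pair_from <- factor(ch[-n], levels = bases)
      pair_to <- factor(ch[-1], levels = bases)
      tt <- table(pair_from, pair_to)
      trans <- trans + as.matrix(tt)
      trans <- trans / rowSums(trans)
      res <- character(n)
      res[1] <- sample(bases, 1, prob = tabulate(match(ch, bases), 4) + 1)
      for (i in 2:n)
        res[i] <- sample(bases, 1, prob = trans[res[i - 1], ])
      paste(res, collapse = "")
    }, "")
    Biostrings::DNAStringSet(stats::setNames(out, paste0(nm, "_shuf")))
  })
}
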