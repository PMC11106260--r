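# LTR retrotransposon chronology: pairwise LTR divergence, insertion-time
# dating via T = K / (2r), solo:intact ratios and distribution comparisons.

#' Divergence between the two LTRs of an intact element
#'
#' The LTR pair is globally aligned with affine gap penalties (match +1,
#' mismatch -2, gap open -4, gap extend -1); the observed p-distance is the
#' mismatch fraction over aligned non-gap columns, optionally Jukes-Cantor
#' corrected: `K = -(3/4) ln(1 - 4p/3)`.
#'
#' @param ltr5_seq,ltr3_seq the two LTR sequences (character/`DNAString`),
#'   each >= 50 bp.
#' @param correction `"jc69"` (default) or `"raw"`.
#' @return one-row tibble: `K`, `p`, `n_sites` (aligned non-gap columns),
#'   `correction`.
#' @export
ltr_divergence <- function(ltr5_seq, ltr3_seq, correction = c("jc69", "raw")) {
  correction <- match.arg(correction)
  a <- as.character(ltr5_seq); b <- as.character(ltr3_seq)
  if (nchar(a) < 50 || nchar(b) < 50) stop("LTR sequences must be >= 50 bp")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 4, gapExtension = 1)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  n_sites <- nm + nmm
  if (n_sites == 0) stop("empty alignment: no aligned non-gap columns")
  p <- nmm / n_sites
  K <- if (correction == "raw") p else .jc69(p)
  tibble::tibble(K = K, p = p, n_sites = n_sites, correction = correction)
}

#' LTR insertion time
#'
#' `T = K / (2r)`: the element's age in years, given the divergence `K`
#' between its two LTRs (identical at insertion) and the substitution rate.
#'
#' @param K divergence between the two LTRs (substitutions/site), >= 0.
#' @param r substitution rate per site per year (default `7e-9`).
#' @return insertion time in years (vectorized over `K`).
#' @export
insertion_time <- function(K, r = 7e-9) {
  if (any(K < 0)) stop("K must be >= 0")
  if (any(r <= 0)) stop("substitution rate r must be > 0")
  K / (2 * r)
}

# TRUE where the element midpoint falls inside the region set
.midpoint_in_region <- function(elements, region) {
  if (is.character(region) && identical(region, "genome"))
    return(rep(TRUE, nrow(elements)))
  mid <- (elements$start + elements$end) / 2
  inr <- rep(FALSE, nrow(elements))
  for (i in seq_len(nrow(region))) {
    inr <- inr | (elements$chrom == region$chrom[i] &
                    mid >= region$start[i] & mid < region$end[i])
  }
  inr
}

#' Solo:intact LTR ratio within a region
#'
#' Elements belong to the region iff their midpoint lies inside it. A region
#' with zero intact elements yields `NA` (with a warning), never infinity.
#'
#' @param elements tibble with columns `chrom`, `start`, `end`, `status`
#'   (values `intact`/`solo`).
#' @param region `"genome"` or a tibble of intervals (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @return one-row tibble: `n_solo`, `n_intact`, `ratio`.
#' @export
solo_intact_ratio <- function(elements, region = "genome") {
  inr <- .midpoint_in_region(elements, region)
  n_solo <- sum(inr & elements$status == "solo")
  n_intact <- sum(inr & elements$status == "intact")
  ratio <- if (n_intact == 0) {
    warning("no intact elements in region; ratio is NA")
    NA_real_
  } else n_solo / n_intact
  tibble::tibble(n_solo = n_solo, n_intact = n_intact, ratio = ratio)
}

#' Compare two insertion-time distributions
#'
#' Two-sided Wilcoxon rank-sum test: exact when both samples have at most 20
#' observations and no ties, otherwise the tie-corrected normal approximation
#' with continuity correction. Medians and quartiles of both samples are
#' reported alongside.
#'
#' @param times_a,times_b numeric samples (each of size >= 3).
#' @return one-row tibble: `statistic`, `p_value`, `n_a`, `n_b`, `median_a`,
#'   `q1_a`, `q3_a`, `median_b`, `q1_b`, `q3_b`.
#' @export
compare_time_distributions <- function(times_a, times_b) {
  if (length(times_a) < 3 || length(times_b) < 3)
    stop("both samples must have at least 3 observations")
  use_exact <- length(times_a) <= 20 && length(times_b) <= 20 &&
    !anyDuplicated(c(times_a, times_b))
  wt <- suppressWarnings(stats::wilcox.test(
    times_a, times_b, alternative = "two.sided", exact = use_exact,
    correct = TRUE))
  q_a <- stats::quantile(times_a, c(0.25, 0.5, 0.75), names = FALSE)
  q_b <- stats::quantile(times_b, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(times_a), n_b = length(times_b),
                 median_a = q_a[2], q1_a = q_a[1], q3_a = q_a[3],
                 median_b = q_b[2], q1_b = q_b[1], q3_b = q_b[3])
}

#' Extract LTR elements from a simulation truth table
#'
#' Converts planted `ltr_intact`/`ltr_solo` truth features into the tabular
#' element form used by the chronology functions, carrying clade, status and
#' (for intact elements) the LTR spans encoded in the truth attributes.
#'
#' @param truth truth tibble from [simulate_genome()].
#' @return tibble: `chrom`, `start`, `end`, `status`, `clade`, `superfamily`,
#'   `K_target`, `K_realized`, `ltr5_start`, `ltr5_end`, `ltr3_start`,
#'   `ltr3_end`.
#' @export
ltr_elements_from_truth <- function(truth) {
  el <- truth[truth$feature_class %in% c("ltr_intact", "ltr_solo"), ,
              drop = FALSE]
  rows <- lapply(seq_len(nrow(el)), function(i) {
    a <- parse_attrs(el$attrs[i])
    span <- function(key) {
      if (is.na(a[key] %||% NA)) return(c(NA_real_, NA_real_))
      as.numeric(strsplit(a[[key]], "-", fixed = TRUE)[[1]])
    }
    s5 <- if ("ltr5" %in% names(a)) span("ltr5") else c(NA_real_, NA_real_)
    s3 <- if ("ltr3" %in% names(a)) span("ltr3") else c(NA_real_, NA_real_)
    tibble::tibble(
      chrom = el$chrom[i], start = el$start[i], end = el$end[i],
      status = if (el$feature_class[i] == "ltr_intact") "intact" else "solo",
      clade = unname(a["clade"]), superfamily = unname(a["superfamily"]),
      K_target = as.numeric(a["K_target"]),
      K_realized = as.numeric(a["K_realized"] %||% NA),
      ltr5_start = s5[1], ltr5_end = s5[2],
      ltr3_start = s3[1], ltr3_end = s3[2])
  })
  dplyr::bind_rows(rows)
}

#' Date intact LTR elements from genome sequence
#'
#' Extracts the two LTRs of each intact element, measures their divergence
#' with [ltr_divergence()] and converts it to an insertion time with
#' [insertion_time()].
#'
#' @param elements element tibble (see [ltr_elements_from_truth()]); solo
#'   elements pass through with `K = NA`.
#' @param genome named `DNAStringSet` holding the element chromosomes.
#' @param correction divergence correction, `"jc69"` or `"raw"`.
#' @param r substitution rate per site per year.
#' @return `elements` with added columns `K`, `p`, `T_years`.
#' @export
date_ltr_elements <- function(elements, genome, correction = c("jc69", "raw"),
                              r = 7e-9) {
  correction <- match.arg(correction)
  chr_seq <- as.character(genome)
  K <- p <- rep(NA_real_, nrow(elements))
  for (i in seq_len(nrow(elements))) {
    if (elements$status[i] != "intact" || is.na(elements$ltr5_start[i])) next
    s <- chr_seq[[elements$chrom[i]]]
    l5 <- substr(s, elements$ltr5_start[i] + 1L, elements$ltr5_end[i])
    l3 <- substr(s, elements$ltr3_start[i] + 1L, elements$ltr3_end[i])
    d <- ltr_divergence(l5, l3, correction)
    K[i] <- d$K; p[i] <- d$p
  }
  elements$K <- K
  elements$p <- p
  elements$T_years <- ifelse(is.na(K), NA_real_, K / (2 * r))
  elements
}
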