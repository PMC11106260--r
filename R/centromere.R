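# Centromere delineation from windowed ChIP enrichment or CRM density, and
# windowed pairwise identity matrices.

# aggregate a bedGraph-shaped track into tiling windows (overlap-weighted)
.aggregate_track <- function(track, chrom_lengths, window_bp) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    ws <- seq.int(0L, L - 1L, by = window_bp)
    we <- pmin(ws + window_bp, L)
    tr <- track[track$chrom == chrom, , drop = FALSE]
    cnt <- numeric(length(ws))
    if (nrow(tr)) {
      q <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
      s <- IRanges::IRanges(start = ws + 1L, end = we)
      ov <- IRanges::findOverlaps(q, s)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      contrib <- tr$count[qh] * w / IRanges::width(q)[qh]
      agg <- tapply(contrib, sh, sum)
      cnt[as.integer(names(agg))] <- agg
    }
    out[[chrom]] <- tibble::tibble(chrom = chrom, start = ws, end = we,
                                   count = cnt)
  }
  dplyr::bind_rows(out)
}

#' Windowed IP/input enrichment
#'
#' Aggregates IP and input tracks into tiling windows, scales each library to
#' the mean total count, and forms the pseudocounted ratio
#' `(ip + c) / (input + c)` per window.
#'
#' @param ip_track,input_track bedGraph-shaped tibbles (`chrom`, `start`,
#'   `end`, `count`) tiling the same genome.
#' @param window_bp window size (default 30,000 bp).
#' @param pseudocount the constant `c` (default 1).
#' @return tibble: `chrom`, `start`, `end`, `ip_count`, `input_count`,
#'   `ratio`.
#' @export
windowed_enrichment <- function(ip_track, input_track, window_bp = 30000L,
                                pseudocount = 1) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  span <- function(tr) tapply(tr$end, tr$chrom, max)
  sp_ip <- span(ip_track); sp_in <- span(input_track)
  if (!identical(sort(names(sp_ip)), sort(names(sp_in))) ||
      any(sp_ip[sort(names(sp_ip))] != sp_in[sort(names(sp_ip))]))
    stop("IP and input tracks do not tile the same genome")
  lens <- as.list(sp_ip)
  ip <- .aggregate_track(ip_track, lens, window_bp)
  inp <- .aggregate_track(input_track, lens, window_bp)
  tot_ip <- sum(ip$count); tot_in <- sum(inp$count)
  target <- mean(c(tot_ip, tot_in))
  ip_s <- ip$count * target / tot_ip
  in_s <- inp$count * target / tot_in
  tibble::tibble(chrom = ip$chrom, start = ip$start, end = ip$end,
                 ip_count = ip$count, input_count = inp$count,
                 ratio = (ip_s + pseudocount) / (in_s + pseudocount))
}

# shared caller: seed windows at score >= min_score, merge runs separated by
# <= merge_gap sub-threshold windows, drop calls shorter than min_len
.call_windows <- function(windows, score, min_score, merge_gap_windows,
                          min_len, evidence) {
  calls <- list()
  for (chrom in unique(windows$chrom)) {
    sel <- windows$chrom == chrom
    w <- windows[sel, , drop = FALSE]
    sc <- score[sel]
    seed <- which(sc >= min_score)
    if (!length(seed)) next
    grp <- cumsum(c(1L, as.integer(diff(seed) > merge_gap_windows + 1L)))
    for (g in unique(grp)) {
      idx <- seed[grp == g]
      start <- w$start[min(idx)]; end <- w$end[max(idx)]
      if (end - start < min_len) next
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = chrom, start = start, end = end, evidence = evidence,
        score = mean(sc[min(idx):max(idx)]),
        n_windows = max(idx) - min(idx) + 1L)
    }
  }
  if (!length(calls))
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), evidence = character(0),
                          score = numeric(0), n_windows = integer(0),
                          flagged_extra = logical(0)))
  calls <- dplyr::bind_rows(calls)
  # one call per chromosome is expected; flag all but the strongest
  calls <- dplyr::group_by(calls, .data$chrom)
  calls <- dplyr::mutate(calls, flagged_extra = dplyr::row_number(
    dplyr::desc(.data$score * .data$n_windows)) > 1L)
  dplyr::ungroup(calls)
}

#' Call centromeres from windowed ChIP enrichment
#'
#' Windows with enrichment ratio at or above `min_ratio` seed candidate
#' intervals; seed runs separated by at most `merge_gap_windows`
#' below-threshold windows are merged, and calls shorter than `min_len` are
#' discarded. One call per chromosome is expected; extras are flagged.
#'
#' @param windows enrichment windows from [windowed_enrichment()] (sorted by
#'   position within chromosome).
#' @param min_ratio seed threshold on the IP/input ratio (default 2).
#' @param merge_gap_windows maximum below-threshold windows bridged when
#'   merging (default 3).
#' @param min_len minimum call length in bp (default 300,000).
#' @return tibble of calls: `chrom`, `start`, `end`, `evidence`, `score`
#'   (mean ratio), `n_windows`, `flagged_extra`.
#' @export
call_centromeres_chip <- function(windows, min_ratio = 2,
                                  merge_gap_windows = 3L, min_len = 300000L) {
  .call_windows(windows, windows$ratio, min_ratio, merge_gap_windows,
                min_len, "chip")
}

#' Call centromeres from CRM retrotransposon density
#'
#' Computes the per-window CRM base-pair density from a TE annotation and
#' applies the same seeding/merging rule as the ChIP caller with density in
#' place of the enrichment ratio. CRM density works as a centromere marker
#' when no ChIP data are available.
#'
#' @param te_annotation tibble with columns `chrom`, `start`, `end`, `clade`
#'   (0-based half-open element spans).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window_bp window size (default 30,000).
#' @param min_density seed threshold in bp/bp (default 0.2).
#' @param merge_gap_windows,min_len as in [call_centromeres_chip()].
#' @return tibble of calls (as the ChIP caller, `evidence = "crm"`). Empty
#'   with a warning if the annotation carries no CRM-clade element.
#' @export
call_centromeres_crm <- function(te_annotation, chrom_lengths,
                                 window_bp = 30000L, min_density = 0.2,
                                 merge_gap_windows = 3L, min_len = 300000L) {
  crm <- te_annotation[toupper(te_annotation$clade) == "CRM", , drop = FALSE]
  if (!nrow(crm)) {
    warning("annotation contains no CRM-clade elements; no calls")
    return(.call_windows(tibble::tibble(chrom = character(0),
                                        start = numeric(0), end = numeric(0)),
                         numeric(0), min_density, merge_gap_windows, min_len,
                         "crm"))
  }
  win <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    ws <- seq.int(0L, L - 1L, by = window_bp)
    we <- pmin(ws + window_bp, L)
    cc <- crm[crm$chrom == chrom, , drop = FALSE]
    dens <- numeric(length(ws))
    if (nrow(cc)) {
      q <- IRanges::IRanges(start = cc$start + 1L, end = cc$end)
      s <- IRanges::IRanges(start = ws + 1L, end = we)
      ov <- IRanges::findOverlaps(q, s)
      w <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(ov)], s[S4Vectors::subjectHits(ov)]))
      agg <- tapply(w, S4Vectors::subjectHits(ov), sum)
      dens[as.integer(names(agg))] <- agg
    }
    win[[chrom]] <- tibble::tibble(chrom = chrom, start = ws, end = we,
                                   density = dens / (we - ws))
  }
  win <- dplyr::bind_rows(win)
  .call_windows(win, win$density, min_density, merge_gap_windows, min_len,
                "crm")
}

#' Jaccard overlap between a call set and truth intervals
#'
#' @param calls,truth tibbles with `chrom`, `start`, `end` columns (0-based
#'   half-open).
#' @return intersection length / union length across all chromosomes.
#' @export
interval_jaccard <- function(calls, truth) {
  if (!nrow(calls) || !nrow(truth)) return(0)
  inter <- 0; uni <- 0
  for (chrom in union(calls$chrom, truth$chrom)) {
    a <- calls[calls$chrom == chrom, , drop = FALSE]
    b <- truth[truth$chrom == chrom, , drop = FALSE]
    ia <- IRanges::reduce(IRanges::IRanges(a$start + 1, a$end))
    ib <- IRanges::reduce(IRanges::IRanges(b$start + 1, b$end))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) 0 else inter / uni
}

#' Windowed pairwise identity matrix
#'
#' Cuts a region into non-overlapping windows (trailing partial window
#' dropped) and computes percent identity between every window pair from a
#' global alignment. The diagonal is exactly 100 and the matrix is symmetric
#' up to alignment asymmetry.
#'
#' @param region_seq the region (character/`DNAString`), length >= 2 windows.
#' @param window_bp window size (default 5,000 bp).
#' @return an `identity_matrix`: list with `identity` (numeric matrix, percent
#'   identity), `windows` (tibble: `start`, `end`), `window_bp`.
#' @export
identity_matrix <- function(region_seq, window_bp = 5000L) {
  s <- as.character(region_seq)
  n <- nchar(s) %/% window_bp
  if (n < 2) stop("region must span at least two windows")
  starts <- (seq_len(n) - 1L) * window_bp
  wins <- substring(s, starts + 1L, starts + window_bp)
  dna <- Biostrings::DNAStringSet(wins)
  m <- matrix(100, n, n)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- Biostrings::pairwiseAlignment(dna[[i]], dna[[j]], type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 4, gapExtension = 1)
    pid <- Biostrings::pid(aln, type = "PID1")
    m[i, j] <- pid; m[j, i] <- pid
  }
  lab <- paste0("w", seq_len(n))
  dimnames(m) <- list(lab, lab)
  structure(list(identity = m,
                 windows = tibble::tibble(start = starts,
                                          end = starts + window_bp),
                 window_bp = as.integer(window_bp)),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("identity_matrix: ", nrow(x$identity), " x ", nrow(x$identity),
      " windows of ", x$window_bp, " bp\n", sep = "")
  cat("off-diagonal identity: ",
      paste(signif(range(x$identity[upper.tri(x$identity)]), 4),
            collapse = " - "), " %\n", sep = "")
  invisible(x)
}

#' Long-format view of an identity matrix
#'
#' @param x an `identity_matrix`.
#' @param ... unused.
#' @return tibble: `window_i`, `window_j`, `start_i`, `start_j`,
#'   `identity`.
#' @export
tidy.identity_matrix <- function(x, ...) {
  n <- nrow(x$identity)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  tibble::tibble(window_i = grid$i, window_j = grid$j,
                 start_i = x$windows$start[grid$i],
                 start_j = x$windows$start[grid$j],
                 identity = x$identity[cbind(grid$i, grid$j)])
}

#' Heatmap of a windowed identity matrix
#'
#' @param object an `identity_matrix`.
#' @param ... unused.
#' @return a ggplot heatmap of percent identity.
#' @export
autoplot.identity_matrix <- function(object, ...) {
  d <- tidy.identity_matrix(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start_i / 1e3,
                                  y = .data$start_j / 1e3,
                                  fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% identity") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "window start (kb)", y = "window start (kb)")
}

#' Plot windowed enrichment with centromere calls
#'
#' @param windows enrichment windows ([windowed_enrichment()] output).
#' @param calls optional centromere call tibble; shaded if given.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(windows, calls = NULL) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "IP / input")
  if (!is.null(calls) && nrow(calls))
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf), alpha = 0.2, fill = "grey40")
  p
}
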