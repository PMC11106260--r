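# NOR-style tandem rDNA array reconstruction from rare-19-mer anchors,
# with k-mer-depth copy-number estimation, unit-length typing and
# prefix/internal/suffix read classification.

#' Estimate tandem-array copy number from k-mer mass and depth
#'
#' The estimate is the floor of the unit-associated k-mer mass divided by the
#' genome-wide sequencing depth (e.g. a mass of 60,000 at 42x depth gives
#' 1,428 copies).
#'
#' @param M k-mer mass: summed (or median, see [measure_kmer_mass()])
#'   multiplicity of unit-associated k-mers in the read set; must be >= 0.
#' @param d genome-wide sequencing depth (x); must be > 0.
#' @return integer copy-number estimate `floor(M / d)`.
#' @export
estimate_copy_number <- function(M, d) {
  if (any(d <= 0)) stop("depth d must be > 0")
  if (any(M < 0)) stop("k-mer mass M must be >= 0")
  as.integer(floor(M / d))
}

#' Extract unit-containing reads
#'
#' Retains reads for which at least `min_unit_kmer_frac` of their canonical
#' k-mers occur in the canonical k-mer set of the unit consensus.
#'
#' @param reads named `DNAStringSet`.
#' @param unit_consensus unit consensus sequence (character or `DNAString`),
#'   length >= `k`.
#' @param min_unit_kmer_frac retention threshold (default 0.2).
#' @param k k-mer size (default 19).
#' @return the retained subset of `reads`.
#' @export
extract_unit_reads <- function(reads, unit_consensus, min_unit_kmer_frac = 0.2,
                               k = 19L) {
  unit_consensus <- as.character(unit_consensus)
  if (nchar(unit_consensus) < k)
    stop("unit consensus is shorter than k")
  uset <- unique(canonical_kmers(kmers_chr(unit_consensus, k)))
  frac <- .kmer_fraction_in_set(as.character(reads), uset, k)
  reads[frac >= min_unit_kmer_frac]
}

#' Measure unit k-mer mass in a read set
#'
#' The mass is the median, over the unit-internal canonical k-mers of the
#' consensus, of their total multiplicity in the read set -- a robust
#' statistic insensitive to flanking sequence in boundary reads. K-mers of the
#' consensus never observed in the reads count as multiplicity 0.
#'
#' @param unit_reads `DNAStringSet` of unit-containing reads (non-empty).
#' @param unit_consensus unit consensus sequence.
#' @param k k-mer size (default 19).
#' @return list with `M` (the mass) and `n_kmers` (number of unit-internal
#'   canonical k-mers used). `M = 0` with a warning if no unit k-mer is
#'   observed.
#' @export
measure_kmer_mass <- function(unit_reads, unit_consensus, k = 19L) {
  if (!length(unit_reads)) stop("unit_reads must be non-empty")
  uset <- unique(canonical_kmers(kmers_chr(as.character(unit_consensus), k)))
  counts <- .kmer_counts(as.character(unit_reads), k, canonical = TRUE)
  obs <- counts[counts$kmer %chin% uset, ]
  mult <- stats::setNames(rep(0, length(uset)), uset)
  if (nrow(obs)) mult[obs$kmer] <- obs$n
  M <- stats::median(mult)
  if (M == 0 && sum(mult) == 0) warning("no unit k-mer observed in reads; M = 0")
  list(M = unname(M), n_kmers = length(uset))
}

#' Cluster unit lengths into length classes
#'
#' Single-linkage clustering on unit length: sorted lengths are split wherever
#' the gap between neighbours is at least `gap_bp`. Classes are reported with
#' their min-max length range and proportion, sorted by descending
#' proportion and labelled `A`, `B`, ... in that order.
#'
#' @param unit_lengths integer vector of unit instance lengths (>= 1).
#' @param gap_bp split threshold (default 50 bp; gaps strictly below are
#'   merged).
#' @return tibble: `label`, `n`, `min_len`, `max_len`, `proportion`.
#' @export
type_units <- function(unit_lengths, gap_bp = 50L) {
  if (!length(unit_lengths)) stop("at least one unit length is required")
  s <- sort(unit_lengths)
  grp <- cumsum(c(1L, as.integer(diff(s) >= gap_bp)))
  cl <- tibble::tibble(
    n = as.integer(tapply(s, grp, length)),
    min_len = as.integer(tapply(s, grp, min)),
    max_len = as.integer(tapply(s, grp, max)))
  cl$proportion <- cl$n / sum(cl$n)
  cl <- dplyr::arrange(cl, dplyr::desc(.data$proportion), .data$min_len)
  cl$label <- LETTERS[seq_len(nrow(cl))]
  cl[, c("label", "n", "min_len", "max_len", "proportion")]
}

#' Classify unit-containing reads as prefix, internal or suffix
#'
#' Mirrors the read taxonomy used when walking outward from a telomere-linked
#' tandem array: `prefix` reads carry a telomeric-motif run, `internal` reads
#' are unit sequence at both ends (both terminal windows >= 80% unit k-mers),
#' `suffix` reads run off the array into unique sequence (one terminal window
#' < 20% unit k-mers, no telomere motif). Everything else is `ambiguous`.
#'
#' @param reads named `DNAStringSet` of unit-selected reads.
#' @param unit_consensus unit consensus sequence.
#' @param telomere_motifs forward telomeric 7-mers.
#' @param k k-mer size (default 19).
#' @param end_window terminal window width (default 2,000 bp).
#' @param min_tel_copies tandem telomere copies that define a prefix read.
#' @return tibble: `read_id`, `role`, `tel_copies`, `frac_start`, `frac_end`.
#' @export
classify_reads <- function(reads, unit_consensus,
                           telomere_motifs = c("TTTAGGG", "TTCAGGG"),
                           k = 19L, end_window = 2000L, min_tel_copies = 5L) {
  uset <- unique(canonical_kmers(kmers_chr(as.character(unit_consensus), k)))
  both <- c(telomere_motifs, revcomp_chr(telomere_motifs))
  res <- lapply(seq_along(reads), function(i) {
    s <- as.character(reads[[i]])
    n <- nchar(s)
    runs <- .tandem_runs(s, both)
    tel <- if (nrow(runs)) max(runs$copy_count) else 0L
    w <- min(end_window, n)
    f1 <- .kmer_fraction_in_set(substr(s, 1L, w), uset, k)
    f2 <- .kmer_fraction_in_set(substr(s, n - w + 1L, n), uset, k)
    role <- if (tel >= min_tel_copies) "prefix"
      else if (f1 >= 0.8 && f2 >= 0.8) "internal"
      else if (min(f1, f2) < 0.2 && max(f1, f2) >= 0.8) "suffix"
      else "ambiguous"
    tibble::tibble(read_id = names(reads)[i] %||% paste0("read", i),
                   role = role, tel_copies = tel,
                   frac_start = f1, frac_end = f2)
  })
  dplyr::bind_rows(res)
}

#' Orient fragments to the unit consensus strand
#'
#' Reverse-complements any fragment that shares more stranded (non-canonical)
#' k-mers with the reverse complement of the unit consensus than with its
#' forward strand, so that all array fragments lie on one strand before graph
#' building.
#'
#' @param fragments named `DNAStringSet`.
#' @param unit_consensus unit consensus sequence.
#' @param k k-mer size.
#' @return `DNAStringSet` with flipped fragments; attribute `"flipped"` gives
#'   their names.
#' @export
orient_to_unit <- function(fragments, unit_consensus, k = 19L) {
  fw <- unique(kmers_chr(as.character(unit_consensus), k))
  rc <- unique(revcomp_chr(fw))
  out <- as.character(fragments)
  flipped <- character(0)
  for (i in seq_along(out)) {
    km <- kmers_chr(out[i], k)
    if (sum(km %chin% rc) > sum(km %chin% fw)) {
      out[i] <- revcomp_chr(out[i])
      flipped <- c(flipped, names(fragments)[i])
    }
  }
  res <- Biostrings::DNAStringSet(stats::setNames(out, names(fragments)))
  attr(res, "flipped") <- flipped
  res
}

#' Build the rare-k-mer fragment graph of a tandem array
#'
#' A k-mer is *rare* iff it occurs exactly once in every fragment that
#' contains it and (when a read k-mer table is supplied) its read-set
#' multiplicity is at most `rare_max_read_mult`. Nodes are fragments; an edge
#' joins two fragments sharing at least one rare k-mer, annotated with the
#' implied placement offset. Fragments must already be on one strand (see
#' [orient_to_unit()]).
#'
#' @param fragments named, oriented `DNAStringSet` (reads and/or draft
#'   contigs).
#' @param roles optional character vector (parallel to `fragments`) with
#'   values in `prefix`, `internal`, `suffix`, `contig`; defaults to
#'   `internal`.
#' @param k k-mer size (default 19).
#' @param rare_max_read_mult maximum read-set multiplicity for a rare k-mer;
#'   the conventional choice is `ceiling(1.5 * depth)`. `Inf` disables the
#'   filter.
#' @return an `array_graph`: list with `nodes` (tibble: `name`, `role`,
#'   `length`), `edges` (tibble: `from`, `to`, `n_shared`, `offset`,
#'   `consistent`), `sequences`, `k`.
#' @export
build_array_graph <- function(fragments, roles = NULL, k = 19L,
                              rare_max_read_mult = Inf) {
  stopifnot(length(fragments) >= 1)
  if (is.null(names(fragments)))
    names(fragments) <- paste0("frag", seq_along(fragments))
  if (is.null(roles)) roles <- rep("internal", length(fragments))
  seqs <- as.character(fragments)
  tabs <- lapply(seq_along(seqs), function(i) {
    t <- .kmer_positions(seqs[i], k)
    t$frag <- i
    t
  })
  all <- data.table::rbindlist(tabs)
  # k-mers occurring more than once in any single fragment are disqualified
  per <- all[, list(n = .N), by = c("kmer", "frag")]
  bad <- unique(per$kmer[per$n > 1L])
  rare <- all[!all$kmer %chin% bad]
  if (is.finite(rare_max_read_mult)) {
    tot <- rare[, list(m = .N), by = "kmer"]
    bad2 <- tot$kmer[tot$m > rare_max_read_mult]
    rare <- rare[!rare$kmer %chin% bad2]
  }
  shared <- merge(rare, rare, by = "kmer", allow.cartesian = TRUE)
  shared <- shared[shared$frag.x < shared$frag.y, ]
  edges <- if (nrow(shared)) {
    # per fragment pair: modal implied offset and its support; an edge is
    # consistent when >= 80% of its shared rare k-mers agree on one offset
    sh <- shared[, {
      d <- pos.x - pos.y
      tb <- sort(table(d), decreasing = TRUE)
      list(n_shared = .N,
           offset = as.integer(names(tb)[1L]),
           n_support = as.integer(tb[1L]))
    }, by = c("frag.x", "frag.y")]
    tibble::tibble(from = names(fragments)[sh$frag.x],
                   to = names(fragments)[sh$frag.y],
                   n_shared = sh$n_shared, offset = sh$offset,
                   n_support = sh$n_support,
                   consistent = sh$n_support >= 0.8 * sh$n_shared)
  } else {
    tibble::tibble(from = character(0), to = character(0),
                   n_shared = integer(0), offset = integer(0),
                   n_support = integer(0), consistent = logical(0))
  }
  structure(list(
    nodes = tibble::tibble(name = names(fragments), role = roles,
                           length = nchar(seqs)),
    edges = edges, sequences = seqs, k = as.integer(k)),
    class = "array_graph")
}

#' @export
print.array_graph <- function(x, ...) {
  cat("array_graph: ", nrow(x$nodes), " fragments, ", nrow(x$edges),
      " rare-", x$k, "-mer edges\n", sep = "")
  print(table(x$nodes$role))
  invisible(x)
}

#' @export
tidy.array_graph <- function(x, ...) x$edges

#' @export
glance.array_graph <- function(x, ...) {
  tibble::tibble(n_fragments = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_prefix = sum(x$nodes$role == "prefix"),
                 n_suffix = sum(x$nodes$role == "suffix"),
                 k = x$k)
}

#' Reconstruct a tandem array from its fragment graph
#'
#' Places the (unique) prefix fragment at coordinate zero and propagates the
#' shared-rare-k-mer offsets across consistent edges. Every edge between
#' placed fragments must agree with the propagated coordinates and every
#' overlapping base must match; any disagreement (e.g. a planted bifurcation)
#' raises an ambiguity error naming the fragments rather than silently
#' tie-breaking. The merged sequence is trimmed to the region covered by
#' exact unit-consensus k-mers, and the copy count is the number of
#' unit-start anchor matches within it.
#'
#' @param graph an `array_graph` with exactly one `prefix` and one `suffix`
#'   node.
#' @param unit_consensus the unit consensus used for trimming and copy
#'   counting.
#' @param min_edge_support minimum agreeing shared rare k-mers for an edge to
#'   participate in the layout (default 3; screens repeat-induced single-k-mer
#'   links).
#' @param ambiguity_min_support a layout-contradicting edge with at least this
#'   many agreeing k-mers is a genuine ambiguity (error); weaker contradicting
#'   edges are treated as repeat noise and dropped.
#' @return list with `sequence` (merged, trimmed array as character),
#'   `copy_count`, `layout` (tibble: `name`, `coord`), `full_sequence`
#'   (untrimmed merge).
#' @export
reconstruct_array <- function(graph, unit_consensus,
                              min_edge_support = 3L,
                              ambiguity_min_support = 60L) {
  stopifnot(inherits(graph, "array_graph"))
  pref <- which(graph$nodes$role == "prefix")
  suff <- which(graph$nodes$role == "suffix")
  if (length(pref) != 1L || length(suff) != 1L)
    stop("reconstruction failure: graph must contain exactly one prefix and ",
         "one suffix fragment (found ", length(pref), " prefix, ",
         length(suff), " suffix)")
  nm <- graph$nodes$name
  idx <- stats::setNames(seq_along(nm), nm)
  ed <- graph$edges[graph$edges$consistent &
                      graph$edges$n_support >= min_edge_support, , drop = FALSE]
  # maximum-weight spanning layout: process edges by descending k-mer
  # support with a union-find carrying coordinates relative to each
  # component root; heavier edges fix the layout, and any later edge that
  # contradicts it is either a genuine ambiguity (well-supported) or
  # repeat-induced noise (weak, dropped)
  ed <- ed[order(-ed$n_support), , drop = FALSE]
  parent <- seq_along(nm)
  pot <- numeric(length(nm))           # coord(x) - coord(parent(x))
  find <- function(x) {
    root <- x; acc <- 0
    while (parent[root] != root) { acc <- acc + pot[root]; root <- parent[root] }
    # path compression
    cur <- x; a <- acc
    while (parent[cur] != cur) {
      nxt <- parent[cur]; p <- pot[cur]
      parent[cur] <<- root; pot[cur] <<- a
      a <- a - p; cur <- nxt
    }
    c(root, acc)
  }
  n_noise <- 0L
  for (j in seq_len(nrow(ed))) {
    a <- idx[[ed$from[j]]]; b <- idx[[ed$to[j]]]
    fa <- find(a); fb <- find(b)
    # coord(b) = coord(a) + offset
    if (fa[1] == fb[1]) {
      if (fb[2] - fa[2] != ed$offset[j]) {
        if (ed$n_support[j] >= ambiguity_min_support)
          stop("ambiguous reconstruction: fragments '", ed$from[j],
               "' and '", ed$to[j], "' admit conflicting placements (",
               "relative offsets ", fb[2] - fa[2], " vs ", ed$offset[j],
               ", ", ed$n_support[j], " supporting k-mers)")
        n_noise <- n_noise + 1L
      }
    } else {
      # attach root(b) under root(a): coord(root_b) = coord(a)+off - pot_b
      parent[fb[1]] <- fa[1]
      pot[fb[1]] <- fa[2] + ed$offset[j] - fb[2]
    }
  }
  fp <- find(pref)
  coord <- rep(NA_real_, length(nm))
  for (i in seq_along(nm)) {
    fi <- find(i)
    if (fi[1] == fp[1]) coord[i] <- fi[2] - fp[2]
  }
  if (is.na(coord[suff]))
    stop("reconstruction failure: no rare-k-mer path connects the prefix ",
         "fragment to the suffix fragment")
  placed <- which(!is.na(coord))
  shift <- min(coord[placed])
  coord <- coord - shift
  total <- max(coord[placed] + graph$nodes$length[placed])
  merged <- raw(total)
  owner <- integer(total)
  for (i in placed[order(coord[placed])]) {
    r <- charToRaw(graph$sequences[i])
    at <- (coord[i] + 1):(coord[i] + length(r))
    w <- owner[at] != 0L
    if (any(w) && any(merged[at[w]] != r[w])) {
      clash <- owner[at[w]][which(merged[at[w]] != r[w])[1]]
      stop("ambiguous reconstruction: fragments '", nm[clash], "' and '",
           nm[i], "' disagree within their overlap")
    }
    merged[at] <- r
    owner[at] <- i
  }
  if (any(owner == 0L))
    stop("reconstruction failure: merged layout has uncovered positions")
  merged_chr <- rawToChar(merged)
  k <- graph$k
  ucons <- as.character(unit_consensus)
  ukmers <- unique(kmers_chr(ucons, k))
  mk <- kmers_chr(merged_chr, k)
  hit <- which(mk %chin% ukmers)
  if (!length(hit))
    stop("reconstruction failure: merged sequence contains no unit k-mers")
  a_start <- min(hit); a_end <- max(hit) + k - 1L
  trimmed <- substr(merged_chr, a_start, a_end)
  anchor <- substr(ucons, 1L, k)
  copy_count <- stringi::stri_count_fixed(trimmed, anchor, overlap = TRUE)
  list(sequence = trimmed, copy_count = as.integer(copy_count),
       layout = tibble::tibble(name = nm[placed],
                               coord = coord[placed] - (a_start - 1L)),
       full_sequence = merged_chr)
}

#' Close N-gaps in an array draft using spanning reads
#'
#' Each N-run whose flanking k-mers are unique in the draft is replaced by
#' the subsequence of a read that contains both flanks (on either strand) at
#' consistent positions. Gaps with no spanning read are left untouched and
#' reported.
#'
#' @param array_draft draft sequence (character or `DNAString`), possibly
#'   containing N-runs.
#' @param unit_reads `DNAStringSet` of candidate spanning reads.
#' @param k flank k-mer size (default 19).
#' @return list with `sequence` (gap-filled character) and `report` tibble
#'   (`gap_start`, `gap_end` 0-based half-open on the input draft, `filled`,
#'   `read_id`, `replacement_len`).
#' @export
fill_array_gaps <- function(array_draft, unit_reads, k = 19L) {
  draft <- as.character(array_draft)
  gaps <- stringi::stri_locate_all_regex(draft, "N+")[[1]]
  if (all(is.na(gaps[, 1])))
    return(list(sequence = draft,
                report = tibble::tibble(gap_start = numeric(0),
                                        gap_end = numeric(0),
                                        filled = logical(0),
                                        read_id = character(0),
                                        replacement_len = numeric(0))))
  reads_chr <- as.character(unit_reads)
  ids <- names(unit_reads) %||% paste0("read", seq_along(unit_reads))
  report <- list()
  # process right-to-left so earlier coordinates stay valid after splicing
  for (g in rev(seq_len(nrow(gaps)))) {
    gs <- gaps[g, 1]; ge <- gaps[g, 2]
    lf <- substr(draft, gs - k, gs - 1L)
    rf <- substr(draft, ge + 1L, ge + k)
    ok <- FALSE; donor <- NA_character_; rep_len <- NA_real_
    if (nchar(lf) == k && nchar(rf) == k && !grepl("N", paste0(lf, rf)) &&
        stringi::stri_count_fixed(draft, lf) == 1L &&
        stringi::stri_count_fixed(draft, rf) == 1L) {
      for (ri in seq_along(reads_chr)) {
        for (s in c("+", "-")) {
          rs <- if (s == "+") reads_chr[ri] else revcomp_chr(reads_chr[ri])
          pl <- stringi::stri_locate_first_fixed(rs, lf)[1, 1]
          pr <- stringi::stri_locate_first_fixed(rs, rf)[1, 1]
          if (!is.na(pl) && !is.na(pr) && pr > pl + k - 1L) {
            repl <- substr(rs, pl + k, pr - 1L)
            draft <- paste0(substr(draft, 1L, gs - 1L), repl,
                            substr(draft, ge + 1L, nchar(draft)))
            ok <- TRUE; donor <- ids[ri]; rep_len <- nchar(repl)
            break
          }
        }
        if (ok) break
      }
    }
    report[[length(report) + 1L]] <- tibble::tibble(
      gap_start = gs - 1, gap_end = ge, filled = ok, read_id = donor,
      replacement_len = rep_len)
  }
  list(sequence = draft, report = dplyr::arrange(dplyr::bind_rows(report),
                                                 .data$gap_start))
}

#' End-to-end NOR array assembly from reads
#'
#' Pipeline convenience: select unit-containing reads, orient them to the
#' unit strand, classify them, designate a single prefix (most telomere
#' copies) and a single suffix (least unit-like terminal window) fragment,
#' build the rare-k-mer graph and reconstruct the array.
#'
#' @param reads named `DNAStringSet`.
#' @param unit_consensus unit consensus sequence.
#' @param depth sequencing depth used for the rare-k-mer multiplicity cutoff
#'   (`ceiling(2.5 * depth)`: long reads make coverage locally correlated, so
#'   the cutoff must clear routine coverage excursions while still excluding
#'   k-mers present at two or more array positions, whose multiplicity
#'   doubles the depth; the layout stage drops the few repeat k-mers that
#'   slip through).
#' @param telomere_motifs forward telomeric motifs.
#' @param k k-mer size (default 19).
#' @param min_unit_kmer_frac read-selection threshold.
#' @return the [reconstruct_array()] result, plus `classification` and
#'   `graph` elements.
#' @export
assemble_rdna_array <- function(reads, unit_consensus, depth,
                                telomere_motifs = c("TTTAGGG", "TTCAGGG"),
                                k = 19L, min_unit_kmer_frac = 0.2) {
  sel <- extract_unit_reads(reads, unit_consensus, min_unit_kmer_frac, k)
  if (!length(sel)) stop("no unit-containing reads found")
  sel <- orient_to_unit(sel, unit_consensus, k)
  cls <- classify_reads(sel, unit_consensus, telomere_motifs, k)
  roles <- cls$role
  # a graph wants exactly one prefix and one suffix; keep the best of each and
  # demote the rest (they still participate as ordinary fragments)
  pi <- which(roles == "prefix")
  if (length(pi) > 1L) {
    keep <- pi[order(-cls$tel_copies[pi], cls$read_id[pi])][1]
    roles[setdiff(pi, keep)] <- "internal"
  }
  si <- which(roles == "suffix")
  if (length(si) > 1L) {
    outer_frac <- pmin(cls$frac_start[si], cls$frac_end[si])
    keep <- si[order(outer_frac, cls$read_id[si])][1]
    roles[setdiff(si, keep)] <- "internal"
  }
  g <- build_array_graph(sel, roles = roles, k = k,
                         rare_max_read_mult = ceiling(2.5 * depth))
  res <- reconstruct_array(g, unit_consensus)
  res$classification <- cls
  res$graph <- g
  res
}
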