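# Synthetic genomes with exact feature truth. The simulator plants the feature
# repertoire of a T2T plant chromosome arm -- terminal telomeric 7-mer arrays
# (with a one-substitution variant), an NOR-style tandem rDNA array of two unit
# length classes, intact and solo LTR retrotransposons with controlled LTR-LTR
# divergence, a CRM-dense centromeric block, and nuclear organelle insertions --
# on an i.i.d. uniform ACGT background, and records every planted feature with
# exact 0-based half-open coordinates.

#' Telomere specification for a genome blueprint
#'
#' @param motif canonical telomeric repeat (7-mer).
#' @param copies tandem copies planted per chromosome end.
#' @param variant one-substitution variant motif interspersed in the array.
#' @param variant_frac fraction of copies drawn as the variant, in `[0, 1]`.
#' @return a `telomere_spec` list.
#' @export
telomere_spec <- function(motif = "TTTAGGG", copies = 500L,
                          variant = "TTCAGGG", variant_frac = 0.05) {
  stopifnot(nchar(motif) == 7L, nchar(variant) == 7L,
            grepl("^[ACGT]+$", motif), grepl("^[ACGT]+$", variant),
            copies >= 1, variant_frac >= 0, variant_frac <= 1)
  structure(list(motif = motif, copies = as.integer(copies),
                 variant = variant, variant_frac = variant_frac),
            class = "telomere_spec")
}

#' NOR (tandem rDNA array) specification
#'
#' Unit length classes are realized as prefixes of a single maximum-length
#' unit consensus; each planted unit additionally carries private interior
#' substitutions (low intra-array divergence), which is what makes rare-k-mer
#' anchoring of the array possible.
#'
#' @param chrom index of the chromosome carrying the array (placed directly
#'   after the left telomere, as on an acrocentric NOR arm).
#' @param copies total planted unit copies.
#' @param unit_length length of the unit consensus (bp); must be >= the
#'   largest class maximum.
#' @param classes data frame with columns `label`, `min_len`, `max_len`,
#'   `proportion` (proportions sum to 1; ranges non-overlapping).
#' @param divergence per-site private substitution rate within each unit.
#' @param boundary_margin bp at each unit end kept substitution-free.
#' @return a `nor_spec` list.
#' @export
nor_spec <- function(chrom = 1L, copies = 50L, unit_length = 8506L,
                     classes = data.frame(
                       label = c("A", "B"),
                       min_len = c(8351L, 8498L),
                       max_len = c(8377L, 8506L),
                       proportion = c(0.7, 0.3)),
                     divergence = 0.002, boundary_margin = 100L) {
  stopifnot(copies >= 1, unit_length >= max(classes$max_len),
            abs(sum(classes$proportion) - 1) < 1e-8,
            all(classes$min_len <= classes$max_len),
            divergence >= 0, divergence < 0.05)
  o <- order(classes$min_len)
  if (any(utils::head(classes$max_len[o], -1) >= classes$min_len[o][-1]))
    stop("nor_spec: class length ranges overlap")
  structure(list(chrom = as.integer(chrom), copies = as.integer(copies),
                 unit_length = as.integer(unit_length), classes = classes,
                 divergence = divergence,
                 boundary_margin = as.integer(boundary_margin)),
            class = "nor_spec")
}

#' One LTR retrotransposon family specification
#'
#' @param clade clade label (e.g. "Athila", "Tekay", "CRM").
#' @param superfamily "Gypsy" or "Copia".
#' @param n number of elements to plant.
#' @param K target LTR-LTR divergence (substitutions/site, Jukes-Cantor scale)
#'   for intact elements; solo LTRs are mutated at branch length `K/2`.
#' @param solo_frac fraction of the `n` elements planted as solo LTRs.
#' @param region `"genome"` (outside the centromere) or `"centromere"`.
#' @param ltr_len,internal_len lengths of the LTR and internal consensus.
#' @return one-row data frame; rows can be bound into a blueprint `ltr` table.
#' @export
ltr_spec <- function(clade, superfamily = c("Gypsy", "Copia"), n = 10L,
                     K = 0.05, solo_frac = 0.5, region = c("genome", "centromere"),
                     ltr_len = 1000L, internal_len = 4000L) {
  superfamily <- match.arg(superfamily)
  region <- match.arg(region)
  stopifnot(n >= 1, K >= 0, K <= 0.75, solo_frac >= 0, solo_frac <= 1,
            ltr_len >= 100)
  data.frame(clade = clade, superfamily = superfamily, n = as.integer(n),
             K = K, solo_frac = solo_frac, region = region,
             ltr_len = as.integer(ltr_len), internal_len = as.integer(internal_len),
             stringsAsFactors = FALSE)
}

#' Centromere specification
#'
#' A centromeric interval that is CRM-invaded: intact (and some solo) CRM-clade
#' Gypsy elements are planted inside until the requested bp density is reached.
#' The same interval drives ChIP-track enrichment in [simulate_chip_track()].
#'
#' @param chrom chromosome index.
#' @param start,stop centromere interval, 0-based half-open.
#' @param crm_density target fraction of centromere bases covered by CRM
#'   elements (bp/bp).
#' @param crm_K target LTR divergence of the planted CRM elements (younger
#'   than genome-background families by default).
#' @param crm_solo_frac fraction of planted CRM elements that are solo.
#' @return a `centromere_spec` list.
#' @export
centromere_spec <- function(chrom = 1L, start, stop, crm_density = 0.3,
                            crm_K = 0.01, crm_solo_frac = 0.2) {
  stopifnot(stop > start, crm_density >= 0, crm_density <= 0.7, crm_K >= 0)
  structure(list(chrom = as.integer(chrom), start = as.integer(start),
                 stop = as.integer(stop), crm_density = crm_density,
                 crm_K = crm_K, crm_solo_frac = crm_solo_frac),
            class = "centromere_spec")
}

#' Organelle genome and nuclear-insertion specification
#'
#' @param genome_length length of the simulated organelle genome (bp).
#' @param source organelle label, `"chloroplast"` or `"mitochondrion"`.
#' @param insertions data frame with columns `chrom`, `length`: nuclear
#'   insertions copied from random organelle subsequences.
#' @return an `organelle_spec` list.
#' @export
organelle_spec <- function(genome_length = 150000L,
                           source = c("chloroplast", "mitochondrion"),
                           insertions = data.frame(chrom = 1L, length = 20000L)) {
  source <- match.arg(source)
  stopifnot(genome_length > 0, all(insertions$length > 0),
            all(insertions$length < genome_length))
  structure(list(genome_length = as.integer(genome_length), source = source,
                 insertions = insertions),
            class = "organelle_spec")
}

#' Assemble a genome blueprint
#'
#' The blueprint is the single declarative description of a synthetic genome;
#' [simulate_genome()] realizes it deterministically from its seed.
#'
#' @param chrom_lengths integer vector of chromosome lengths (bp).
#' @param seed integer RNG seed.
#' @param telomere a [telomere_spec()] or `NULL`.
#' @param nor a [nor_spec()] or `NULL`.
#' @param ltr a data frame of [ltr_spec()] rows or `NULL`.
#' @param centromere a [centromere_spec()] or `NULL`.
#' @param organelle an [organelle_spec()] or `NULL`.
#' @return a `genome_blueprint` list.
#' @export
genome_blueprint <- function(chrom_lengths, seed = 1L,
                             telomere = telomere_spec(), nor = NULL,
                             ltr = NULL, centromere = NULL, organelle = NULL) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0))
  if (!is.null(nor) && nor$chrom > length(chrom_lengths))
    stop("nor_spec references a chromosome beyond chrom_lengths")
  if (!is.null(centromere)) {
    if (centromere$chrom > length(chrom_lengths))
      stop("centromere_spec references a chromosome beyond chrom_lengths")
    if (centromere$stop > chrom_lengths[centromere$chrom])
      stop("centromere interval exceeds chromosome length")
  }
  structure(list(chrom_lengths = as.integer(chrom_lengths),
                 seed = as.integer(seed), telomere = telomere, nor = nor,
                 ltr = ltr, centromere = centromere, organelle = organelle),
            class = "genome_blueprint")
}

# Jukes-Cantor correction of an observed p-distance
.jc69 <- function(p) {
  if (any(p >= 0.75)) stop("p-distance at or beyond Jukes-Cantor saturation (p >= 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

.hamming_p <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  mean(ra != rb)
}

# largest-remainder allocation: integer counts summing to total, proportional
.alloc_counts <- function(total, props) {
  raw <- total * props
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    o <- order(raw - n, decreasing = TRUE)
    n[o[seq_len(rem)]] <- n[o[seq_len(rem)]] + 1L
  }
  as.integer(n)
}

#' Mutate an LTR pair to a target divergence
#'
#' Places substitutions independently on the two copies of an LTR consensus so
#' that their expected divergence (Jukes-Cantor scale) is `K_target`: each copy
#' evolves along a branch of length `K_target/2`, with per-site substitution
#' probability `3/4 * (1 - exp(-(4/3) * K_target/2))`.
#'
#' @param ltr_consensus character LTR consensus, length >= 100.
#' @param K_target target divergence in substitutions/site, in `[0, 0.75]`.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return list with `ltr5`, `ltr3`, realized `p_distance` and Jukes-Cantor
#'   `K_realized`.
#' @export
mutate_ltr_pair <- function(ltr_consensus, K_target, seed = NULL) {
  ltr_consensus <- as.character(ltr_consensus)
  if (nchar(ltr_consensus) < 100) stop("LTR consensus must be >= 100 bp")
  if (K_target < 0) stop("K_target must be >= 0")
  if (K_target > 0.75) stop("K_target beyond Jukes-Cantor saturation (> 0.75)")
  run <- function() {
    p1 <- 0.75 * (1 - exp(-(4 / 3) * (K_target / 2)))
    ltr5 <- .mutate_seq(ltr_consensus, p1)
    ltr3 <- .mutate_seq(ltr_consensus, p1)
    p <- .hamming_p(ltr5, ltr3)
    list(ltr5 = ltr5, ltr3 = ltr3, p_distance = p,
         K_realized = if (p < 0.75) .jc69(p) else NA_real_)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# build a telomeric array string; returns list(seq, n_variant)
.telomere_array <- function(spec) {
  isvar <- stats::runif(spec$copies) < spec$variant_frac
  units <- ifelse(isvar, spec$variant, spec$motif)
  list(seq = paste(units, collapse = ""), n_variant = sum(isvar))
}

# free-position rejection sampler; occupied is a 2-col matrix (start, end)
.place_free <- function(len, lo, hi, occupied, what, tries = 400L) {
  if (hi - lo < len)
    stop("placement error: no room for feature '", what, "'")
  for (i in seq_len(tries)) {
    s <- lo + floor(stats::runif(1) * (hi - lo - len + 1))
    e <- s + len
    if (nrow(occupied) == 0L ||
        all(e <= occupied[, 1] | s >= occupied[, 2])) return(c(s, e))
  }
  stop("placement error: feature '", what,
       "' collides with previously placed features after ", tries, " attempts")
}

#' Realize a genome blueprint
#'
#' Deterministically generates the nuclear chromosomes, the organelle
#' reference (if specified) and a complete truth table of every planted
#' feature. Coordinates are 0-based half-open throughout.
#'
#' @param blueprint a [genome_blueprint()].
#' @return list of class `t2t_sim` with elements `genome`
#'   (`DNAStringSet`), `truth` (tibble: `chrom`, `start`, `end`,
#'   `feature_class`, `strand`, `attrs`), `organelle` (`DNAStringSet` or
#'   `NULL`), `nor_consensus` (character or `NULL`) and `blueprint`.
#' @export
simulate_genome <- function(blueprint) {
  stopifnot(inherits(blueprint, "genome_blueprint"))
  withr::with_seed(blueprint$seed, .simulate_genome_impl(blueprint))
}

.simulate_genome_impl <- function(bp) {
  n_chr <- length(bp$chrom_lengths)
  chroms <- paste0("chr", seq_len(n_chr))
  truth <- list()
  nor_consensus <- NULL
  organelle <- NULL

  if (!is.null(bp$organelle)) {
    org_seq <- .random_dna(bp$organelle$genome_length)
    organelle <- Biostrings::DNAStringSet(stats::setNames(org_seq, bp$organelle$source))
  }

  # clade consensus sequences (one LTR + internal consensus per clade)
  ltr_tab <- bp$ltr
  if (!is.null(bp$centromere) && bp$centromere$crm_density > 0) {
    cen <- bp$centromere
    span <- 2L * 1000L + 4000L
    n_crm <- ceiling(cen$crm_density * (cen$stop - cen$start) / span)
    crm_row <- ltr_spec("CRM", "Gypsy", n = max(1L, n_crm), K = cen$crm_K,
                        solo_frac = cen$crm_solo_frac, region = "centromere")
    ltr_tab <- rbind(ltr_tab, crm_row)
  }
  clade_cons <- list()
  if (!is.null(ltr_tab)) {
    for (cl in unique(ltr_tab$clade)) {
      row <- ltr_tab[ltr_tab$clade == cl, ][1, ]
      clade_cons[[cl]] <- list(ltr = .random_dna(row$ltr_len),
                               internal = .random_dna(row$internal_len))
    }
  }

  seqs <- character(n_chr)
  for (ci in seq_len(n_chr)) {
    L <- bp$chrom_lengths[ci]
    chrom <- chroms[ci]
    feats <- list()  # each: list(start, end, seq, class, strand, attrs)

    tel_len <- 0L
    if (!is.null(bp$telomere)) {
      tel <- bp$telomere
      tel_len <- tel$copies * 7L
      if (2L * tel_len >= L) stop("placement error: telomeres exceed chromosome ", chrom)
      right <- .telomere_array(tel)
      leftf <- .telomere_array(tel)
      feats <- c(feats, list(
        list(start = 0L, end = tel_len, seq = revcomp_chr(leftf$seq),
             class = "telomere", strand = "-",
             attrs = .format_attrs(side = "left", motif = tel$motif,
                                   copies = tel$copies, n_variant = leftf$n_variant)),
        list(start = L - tel_len, end = L, seq = right$seq,
             class = "telomere", strand = "+",
             attrs = .format_attrs(side = "right", motif = tel$motif,
                                   copies = tel$copies, n_variant = right$n_variant))))
    }

    if (!is.null(bp$nor) && bp$nor$chrom == ci) {
      nor <- bp$nor
      nor_consensus <- .random_dna(nor$unit_length)
      counts <- .alloc_counts(nor$copies, nor$classes$proportion)
      labels <- sample(rep(nor$classes$label, counts))
      pos <- tel_len
      for (u in seq_along(labels)) {
        cls <- nor$classes[nor$classes$label == labels[u], ]
        ulen <- sample(seq.int(cls$min_len, cls$max_len), 1L)
        useq <- substr(nor_consensus, 1L, ulen)
        m <- nor$boundary_margin
        interior <- ulen - 2L * m
        nsub <- stats::rbinom(1L, interior, nor$divergence)
        if (nsub > 0) useq <- .substitute_at(useq, m + sample.int(interior, nsub))
        feats <- c(feats, list(list(
          start = pos, end = pos + ulen, seq = useq, class = "rdna_unit",
          strand = "+",
          attrs = .format_attrs(class = labels[u], length = ulen, n_private = nsub))))
        pos <- pos + ulen
      }
      if (pos >= L - tel_len) stop("placement error: NOR overruns chromosome ", chrom)
    }

    cen_iv <- NULL
    if (!is.null(bp$centromere) && bp$centromere$chrom == ci) {
      cen <- bp$centromere
      cen_iv <- c(cen$start, cen$stop)
      fixed <- do.call(rbind, lapply(feats, function(f) c(f$start, f$end)))
      if (!is.null(fixed) &&
          any(cen$stop > fixed[, 1] & cen$start < fixed[, 2]))
        stop("placement error: centromere overlaps telomere/NOR on ", chrom)
    }

    occupied <- do.call(rbind, lapply(feats, function(f) c(f$start, f$end)))
    if (is.null(occupied)) occupied <- matrix(numeric(0), ncol = 2)
    if (!is.null(cen_iv)) occupied <- rbind(occupied, cen_iv)

    # LTR elements
    if (!is.null(ltr_tab)) {
      for (ri in seq_len(nrow(ltr_tab))) {
        row <- ltr_tab[ri, ]
        in_cen <- row$region == "centromere"
        if (in_cen && (is.null(cen_iv))) next   # centromere lives on another chrom
        if (!in_cen && n_chr > 1 && ci != 1L) next  # genome-wide families on chr1
        cons <- clade_cons[[row$clade]]
        n_solo <- round(row$n * row$solo_frac)
        n_int <- row$n - n_solo
        status <- sample(c(rep("intact", n_int), rep("solo", n_solo)))
        make_elem <- function(st) {
          if (st == "intact") {
            pair <- mutate_ltr_pair(cons$ltr, row$K)
            list(status = st, pair = pair,
                 seq = paste0(pair$ltr5, cons$internal, pair$ltr3))
          } else {
            p1 <- 0.75 * (1 - exp(-(4 / 3) * (row$K / 2)))
            list(status = st, pair = NULL, seq = .mutate_seq(cons$ltr, p1))
          }
        }
        elems <- lapply(status, make_elem)
        if (in_cen) {
          # the row count is a floor; keep adding elements until the planted
          # bases reach the requested fraction of the centromere
          cen_len <- cen_iv[2] - cen_iv[1]
          target_bp <- if (!is.null(bp$centromere) && row$clade == "CRM" &&
                             row$region == "centromere")
            bp$centromere$crm_density * cen_len else 0
          repeat {
            tot <- sum(vapply(elems, function(e) nchar(e$seq), numeric(1)))
            if (tot >= target_bp) break
            st <- sample(c("intact", "solo"), 1L,
                         prob = c(1 - row$solo_frac, row$solo_frac))
            elems <- c(elems, list(make_elem(st)))
          }
          # distribute evenly: one element per equal-width slot
          slot_w <- floor(cen_len / length(elems))
          placements <- lapply(seq_along(elems), function(i) {
            elen <- nchar(elems[[i]]$seq)
            if (elen > slot_w)
              stop("placement error: centromere too small for its CRM load")
            off <- sample.int(slot_w - elen + 1L, 1L) - 1L
            s <- cen_iv[1] + (i - 1L) * slot_w + off
            c(s, s + elen)
          })
        } else {
          placements <- vector("list", length(elems))
        }
        for (ei in seq_along(elems)) {
          el <- elems[[ei]]
          elen <- nchar(el$seq)
          if (in_cen) {
            s <- placements[[ei]][1]; e <- placements[[ei]][2]
          } else {
            se <- .place_free(elen, tel_len, L - tel_len, occupied,
                              paste0(row$clade, "_", el$status))
            s <- se[1]; e <- se[2]
          }
          occupied <- rbind(occupied, c(s, e))
          attrs <- if (el$status == "intact") .format_attrs(
            clade = row$clade, superfamily = row$superfamily,
            K_target = row$K, p_distance = signif(el$pair$p_distance, 6),
            K_realized = signif(el$pair$K_realized, 6),
            ltr5 = paste0(s, "-", s + row$ltr_len),
            ltr3 = paste0(e - row$ltr_len, "-", e))
          else .format_attrs(clade = row$clade, superfamily = row$superfamily,
                             K_target = row$K)
          feats <- c(feats, list(list(
            start = s, end = e, seq = el$seq,
            class = if (el$status == "intact") "ltr_intact" else "ltr_solo",
            strand = "+", attrs = attrs)))
        }
      }
    }

    if (!is.null(cen_iv)) {
      crm_bp <- sum(vapply(feats, function(f)
        if (f$class %in% c("ltr_intact", "ltr_solo") &&
            grepl("clade=CRM", f$attrs) && f$start >= cen_iv[1] &&
            f$end <= cen_iv[2]) f$end - f$start else 0L, numeric(1)))
      feats <- c(feats, list(list(
        start = cen_iv[1], end = cen_iv[2], seq = NULL, class = "centromere",
        strand = "+",
        attrs = .format_attrs(
          crm_density_realized = signif(crm_bp / (cen_iv[2] - cen_iv[1]), 4)))))
    }

    # organelle insertions
    if (!is.null(bp$organelle)) {
      ins <- bp$organelle$insertions
      ins <- ins[ins$chrom == ci, , drop = FALSE]
      if (nrow(ins)) {
        org_chr <- as.character(organelle[[1]])
        for (ii in seq_len(nrow(ins))) {
          ilen <- ins$length[ii]
          os <- sample.int(bp$organelle$genome_length - ilen, 1L)
          iseq <- substr(org_chr, os, os + ilen - 1L)
          se <- .place_free(ilen, tel_len, L - tel_len, occupied,
                            "organelle_insertion")
          occupied <- rbind(occupied, se)
          feats <- c(feats, list(list(
            start = se[1], end = se[2], seq = iseq, class = "organelle_insertion",
            strand = "+",
            attrs = .format_attrs(source = bp$organelle$source,
                                  org_start = os - 1L, org_end = os - 1L + ilen))))
        }
      }
    }

    # assemble: overlay features (with sequence) on a random background
    placed <- feats[!vapply(feats, function(f) is.null(f$seq), logical(1))]
    if (length(placed)) {
      o <- order(vapply(placed, `[[`, numeric(1), "start"))
      placed <- placed[o]
      starts <- vapply(placed, `[[`, numeric(1), "start")
      ends <- vapply(placed, `[[`, numeric(1), "end")
      if (any(starts[-1] < utils::head(ends, -1))) {
        i <- which(starts[-1] < utils::head(ends, -1))[1]
        stop("placement error: features '", placed[[i]]$class, "' and '",
             placed[[i + 1]]$class, "' overlap on ", chrom)
      }
      pieces <- character(2L * length(placed) + 1L)
      cur <- 0L
      for (i in seq_along(placed)) {
        gap <- starts[i] - cur
        pieces[2L * i - 1L] <- if (gap > 0) .random_dna(gap) else ""
        pieces[2L * i] <- placed[[i]]$seq
        cur <- ends[i]
      }
      pieces[2L * length(placed) + 1L] <-
        if (L - cur > 0) .random_dna(L - cur) else ""
      seqs[ci] <- paste(pieces, collapse = "")
    } else {
      seqs[ci] <- .random_dna(L)
    }
    stopifnot(nchar(seqs[ci]) == L)

    truth[[ci]] <- tibble::tibble(
      chrom = chrom,
      start = vapply(feats, function(f) as.numeric(f$start), numeric(1)),
      end = vapply(feats, function(f) as.numeric(f$end), numeric(1)),
      feature_class = vapply(feats, `[[`, character(1), "class"),
      strand = vapply(feats, `[[`, character(1), "strand"),
      attrs = vapply(feats, `[[`, character(1), "attrs"))
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  truth <- dplyr::arrange(dplyr::bind_rows(truth), .data$chrom, .data$start)
  structure(list(genome = genome, truth = truth, organelle = organelle,
                 nor_consensus = nor_consensus, blueprint = bp),
            class = "t2t_sim")
}

#' Long-read profile
#'
#' Two regimes are provided: `hifi_like` (shorter, near-perfect reads;
#' normal length distribution) and `ont_like` (long-tailed lognormal lengths
#' with higher substitution and 1% indel rates).
#'
#' @param mode `"hifi_like"` or `"ont_like"`.
#' @param depth target sequencing depth (x); must be > 0.
#' @param mean_len mean read length (bp).
#' @param sd_len length spread: normal sd (hifi) or lognormal sdlog (ont).
#' @param sub_rate,ins_rate,del_rate per-base error rates, each in `[0, 0.2]`.
#' @return a `read_profile` list.
#' @export
read_profile <- function(mode = c("hifi_like", "ont_like"), depth = 20,
                         mean_len = NULL, sd_len = NULL, sub_rate = NULL,
                         ins_rate = NULL, del_rate = NULL) {
  mode <- match.arg(mode)
  def <- if (mode == "hifi_like")
    list(mean_len = 18000, sd_len = 4500, sub_rate = 0.001,
         ins_rate = 0, del_rate = 0)
  else
    list(mean_len = 30000, sd_len = 0.7, sub_rate = 0.03,
         ins_rate = 0.01, del_rate = 0.01)
  p <- list(mode = mode, depth = depth,
            mean_len = mean_len %||% def$mean_len,
            sd_len = sd_len %||% def$sd_len,
            sub_rate = sub_rate %||% def$sub_rate,
            ins_rate = ins_rate %||% def$ins_rate,
            del_rate = del_rate %||% def$del_rate)
  if (p$depth <= 0) stop("depth must be > 0")
  rates <- c(p$sub_rate, p$ins_rate, p$del_rate)
  if (any(rates < 0) || any(rates > 0.2))
    stop("error rates must lie in [0, 0.2]")
  structure(p, class = "read_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply substitution/indel errors to one read (raw-byte implementation)
.corrupt_read <- function(seq, sub, ins, del) {
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  if (del > 0) r <- r[stats::runif(length(r)) >= del]
  if (sub > 0) {
    pos <- which(stats::runif(length(r)) < sub)
    if (length(pos)) {
      cur <- r[pos]
      r[pos] <- vapply(cur, function(b) sample(bases[bases != b], 1L), raw(1))
    }
  }
  if (ins > 0) {
    ipos <- which(stats::runif(length(r)) < ins)
    if (length(ipos)) {
      news <- sample(bases, length(ipos), replace = TRUE)
      vals <- c(r, news)
      r <- vals[order(c(seq_along(r), ipos + 0.5))]
    }
  }
  rawToChar(r)
}

#' Simulate long reads from a genome
#'
#' Read names encode the true origin as `chrom:start-end:strand` (0-based
#' half-open), so downstream recall/precision can be computed without
#' alignment. With zero error rates every read is an exact substring of the
#' genome (or its reverse complement).
#'
#' @param genome a `DNAStringSet` or a `t2t_sim` object.
#' @param profile a [read_profile()].
#' @param seed integer seed.
#' @return named `DNAStringSet` of reads.
#' @export
simulate_reads <- function(genome, profile, seed = 1L) {
  if (inherits(genome, "t2t_sim")) genome <- genome$genome
  stopifnot(inherits(profile, "read_profile"), length(genome) >= 1)
  if (sum(Biostrings::width(genome)) == 0) stop("genome is empty")
  withr::with_seed(seed, {
    chr_seq <- as.character(genome)
    lens <- nchar(chr_seq)
    target <- profile$depth * sum(lens)
    out <- character(0); names_out <- character(0)
    total <- 0; i <- 0L
    while (total < target) {
      n_chunk <- max(50L, ceiling((target - total) / profile$mean_len))
      rl <- if (profile$mode == "hifi_like")
        pmax(1000, round(stats::rnorm(n_chunk, profile$mean_len, profile$sd_len)))
      else
        pmax(1000, round(stats::rlnorm(
          n_chunk, log(profile$mean_len) - profile$sd_len^2 / 2, profile$sd_len)))
      ci <- sample.int(length(lens), n_chunk, replace = TRUE, prob = lens)
      rl <- pmin(rl, lens[ci])
      st <- floor(stats::runif(n_chunk) * (lens[ci] - rl + 1))  # 0-based
      strand <- sample(c("+", "-"), n_chunk, replace = TRUE)
      for (j in seq_len(n_chunk)) {
        if (total >= target) break
        i <- i + 1L
        s <- substr(chr_seq[ci[j]], st[j] + 1L, st[j] + rl[j])
        if (strand[j] == "-") s <- revcomp_chr(s)
        if (profile$sub_rate > 0 || profile$ins_rate > 0 || profile$del_rate > 0)
          s <- .corrupt_read(s, profile$sub_rate, profile$ins_rate, profile$del_rate)
        out[i] <- s
        names_out[i] <- sprintf("r%05d_%s:%d-%d:%s", i, names(genome)[ci[j]],
                                st[j], st[j] + rl[j], strand[j])
        total <- total + rl[j]
      }
    }
    Biostrings::DNAStringSet(stats::setNames(out, names_out))
  })
}

#' Simulate a windowed ChIP IP/input track pair
#'
#' Window counts are Poisson with mean `base_rate * width` in the input track
#' and everywhere in the IP track except windows whose midpoint falls inside a
#' planted centromere, where the IP mean is multiplied by `enrichment_factor`.
#' Both tracks tile the genome identically.
#'
#' @param genome `DNAStringSet` or `t2t_sim`.
#' @param truth truth tibble containing `centromere` features (may be empty).
#' @param window_bp window size (default 30,000 bp).
#' @param base_rate expected background count per base.
#' @param enrichment_factor IP fold enrichment inside centromeres (>= 1).
#' @param seed integer seed.
#' @return list with `ip` and `input` tibbles (`chrom`, `start`, `end`,
#'   `count`), bedGraph-shaped.
#' @export
simulate_chip_track <- function(genome, truth, window_bp = 30000L,
                                base_rate = 0.01, enrichment_factor = 4,
                                seed = 1L) {
  if (inherits(genome, "t2t_sim")) {
    if (missing(truth)) truth <- genome$truth
    genome <- genome$genome
  }
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  withr::with_seed(seed, {
    cen <- truth[truth$feature_class == "centromere", , drop = FALSE]
    win <- lapply(seq_along(genome), function(ci) {
      L <- Biostrings::width(genome)[ci]
      chrom <- names(genome)[ci]
      start <- seq.int(0L, L - 1L, by = window_bp)
      end <- pmin(start + window_bp, L)
      mid <- (start + end) / 2
      in_cen <- rep(FALSE, length(start))
      cc <- cen[cen$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(cc)))
        in_cen <- in_cen | (mid >= cc$start[k] & mid < cc$end[k])
      tibble::tibble(chrom = chrom, start = start, end = end, in_cen = in_cen)
    })
    win <- dplyr::bind_rows(win)
    width <- win$end - win$start
    input <- stats::rpois(nrow(win), base_rate * width)
    ip <- stats::rpois(nrow(win), base_rate * width *
                         ifelse(win$in_cen, enrichment_factor, 1))
    list(ip = tibble::tibble(chrom = win$chrom, start = win$start,
                             end = win$end, count = ip),
         input = tibble::tibble(chrom = win$chrom, start = win$start,
                                end = win$end, count = input))
  })
}
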