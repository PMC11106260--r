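# Shared fixtures, built in code and cached for the duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# substitute a fixed number of bases at seeded positions
mutate_positions <- function(seq, n_sub, seed) {
  withr::with_seed(seed, {
    pos <- sample(nchar(seq), n_sub)
    r <- charToRaw(seq)
    bases <- charToRaw("ACGT")
    r[pos] <- vapply(r[pos], function(b) sample(bases[bases != b], 1), raw(1))
    rawToChar(r)
  })
}

# genome with planted telomeres on two chromosomes, no other features
telomere_sim <- function() fixture("telomere_sim", {
  bp <- genome_blueprint(c(300000, 250000), seed = 21,
                         telomere = telomere_spec(copies = 400,
                                                  variant_frac = 0.05))
  simulate_genome(bp)
})

# 50-copy NOR simulation with zero-error reads and its reconstruction
nor_sim50 <- function() fixture("nor_sim50", {
  bp <- genome_blueprint(600000, seed = 11,
                         telomere = telomere_spec(copies = 300,
                                                  variant_frac = 0),
                         nor = nor_spec(copies = 50))
  sim <- simulate_genome(bp)
  reads <- simulate_reads(
    sim$genome,
    read_profile("hifi_like", depth = 10, mean_len = 30000, sd_len = 5000,
                 sub_rate = 0, ins_rate = 0, del_rate = 0),
    seed = 3)
  units <- sim$truth[sim$truth$feature_class == "rdna_unit", ]
  planted_nor <- substr(as.character(sim$genome[[1]]),
                        min(units$start) + 1, max(units$end))
  result <- assemble_rdna_array(reads, sim$nor_consensus, depth = 10)
  list(sim = sim, reads = reads, units = units, planted_nor = planted_nor,
       result = result)
})

# centromere simulation: CRM-dense block plus matched ChIP tracks
centromere_sim <- function() fixture("centromere_sim", {
  bp <- genome_blueprint(3000000, seed = 31,
                         telomere = NULL,
                         centromere = centromere_spec(1, 1200000, 1700000,
                                                      crm_density = 0.3,
                                                      crm_K = 0.01,
                                                      crm_solo_frac = 0.2))
  sim <- simulate_genome(bp)
  tracks <- simulate_chip_track(sim$genome, sim$truth, window_bp = 30000,
                                base_rate = 0.01, enrichment_factor = 4,
                                seed = 5)
  list(sim = sim, tracks = tracks,
       truth_cen = sim$truth[sim$truth$feature_class == "centromere", ])
})

# genome with background LTR families plus a younger, solo-poor centromere
ltr_sim <- function() fixture("ltr_sim", {
  bp <- genome_blueprint(2000000, seed = 41,
                         telomere = telomere_spec(copies = 200,
                                                  variant_frac = 0),
                         ltr = rbind(
                           ltr_spec("Athila", "Gypsy", n = 40, K = 0.05,
                                    solo_frac = 0.6),
                           ltr_spec("Tekay", "Gypsy", n = 30, K = 0.06,
                                    solo_frac = 0.6)),
                         centromere = centromere_spec(1, 1200000, 1600000,
                                                      crm_density = 0.3,
                                                      crm_K = 0.01,
                                                      crm_solo_frac = 0.1))
  sim <- simulate_genome(bp)
  elements <- ltr_elements_from_truth(sim$truth)
  dated <- date_ltr_elements(elements, sim$genome)
  cen_region <- sim$truth[sim$truth$feature_class == "centromere",
                          c("chrom", "start", "end")]
  list(sim = sim, elements = elements, dated = dated, cen_region = cen_region)
})

# LTR divergence parameter recovery at three target K values
ltr_recovery <- function() fixture("ltr_recovery", {
  cons <- rand_dna(2000, seed = 99)
  res <- lapply(c(0.01, 0.05, 0.1), function(K) {
    khat <- vapply(seq_len(100), function(i) {
      pair <- mutate_ltr_pair(cons, K, seed = 10000 + round(1000 * K) + i)
      ltr_divergence(pair$ltr5, pair$ltr3, "jc69")$K
    }, numeric(1))
    tibble::tibble(K_target = K, K_hat = khat)
  })
  dplyr::bind_rows(res)
})

# null and power simulations for the motif enrichment test
motif_null_sim <- function(n_reps = 500, n_seq = 50, len = 300,
                           plant_rate = 0.3, seed = 7) {
  motifs <- motif_library()
  withr::with_seed(seed, {
    out <- vapply(seq_len(n_reps), function(rep) {
      mk_set <- function() {
        s <- stringi::stri_rand_strings(n_seq, len, "[ACGT]")
        plant <- stats::runif(n_seq) < plant_rate
        mi <- sample.int(nrow(motifs), n_seq, replace = TRUE)
        ins <- gsub("N", "A", motifs$consensus[mi])
        s[plant] <- paste0(substr(s[plant], 1, 50), ins[plant],
                           substr(s[plant], 51 + nchar(ins[plant]), len))
        stats::setNames(s, paste0("s", seq_len(n_seq)))
      }
      fg <- scan_motifs(mk_set(), motifs)
      bg <- scan_motifs(mk_set(), motifs)
      er <- enrich_motifs(fg, bg, alpha = 0.01)
      sum(er$enriched)
    }, numeric(1))
    list(n_tests = n_reps * nrow(motifs), n_enriched = sum(out),
         rate = sum(out) / (n_reps * nrow(motifs)), n_reps = n_reps)
  })
}

motif_power_sim <- function(n_reps = 200, n_seq = 50, len = 300, seed = 8) {
  motifs <- motif_library()
  target <- "G-box"
  cons <- motifs$consensus[motifs$name == target]
  withr::with_seed(seed, {
    hits <- vapply(seq_len(n_reps), function(rep) {
      mk_set <- function(rate) {
        s <- stringi::stri_rand_strings(n_seq, len, "[ACGT]")
        plant <- stats::runif(n_seq) < rate
        s[plant] <- paste0(substr(s[plant], 1, 50), cons,
                           substr(s[plant], 51 + nchar(cons), len))
        stats::setNames(s, paste0("s", seq_len(n_seq)))
      }
      fg <- scan_motifs(mk_set(0.9), motifs)
      bg <- scan_motifs(mk_set(0.1), motifs)
      er <- enrich_motifs(fg, bg, alpha = 0.01)
      er$enriched[er$motif == target]
    }, logical(1))
    mean(hits)
  })
}
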