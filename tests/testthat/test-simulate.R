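# Synthetic-genome generator: determinism, truth completeness, read and
# ChIP-track statistical behaviour, LTR pair mutation.

test_that("blueprint realization is deterministic with exact telomere truth", {
  bp <- genome_blueprint(100000, seed = 3,
                         telomere = telomere_spec(copies = 500,
                                                  variant_frac = 0))
  sim1 <- simulate_genome(bp)
  sim2 <- simulate_genome(bp)
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(unname(Biostrings::width(sim1$genome)), 100000)
  tel <- sim1$truth[sim1$truth$feature_class == "telomere", ]
  expect_equal(nrow(tel), 2L)
  expect_equal(tel$end - tel$start, c(3500, 3500))  # 500 x 7 bp per end
  expect_setequal(c(tel$start, tel$end), c(0, 3500, 96500, 100000))
})

test_that("planted NOR units follow the class proportions exactly", {
  fx <- nor_sim50()
  units <- fx$units
  expect_equal(nrow(units), 50L)
  cls <- vapply(units$attrs, function(a) parse_attrs(a)[["class"]], "",
                USE.NAMES = FALSE)
  expect_equal(as.integer(sort(table(cls), decreasing = TRUE)), c(35L, 15L))
  # units tile the array without gaps
  o <- order(units$start)
  expect_true(all(units$start[o][-1] == head(units$end[o], -1)))
})

test_that("overlapping mandatory features raise a placement error", {
  bp <- genome_blueprint(100000, seed = 1,
                         telomere = telomere_spec(copies = 500),
                         centromere = centromere_spec(1, 1000, 60000,
                                                      crm_density = 0))
  expect_error(simulate_genome(bp), "placement error")
})

test_that("simulated reads hit the depth target and are exact at zero error", {
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(1000000, seed = 5)))
  prof <- read_profile("hifi_like", depth = 20, sub_rate = 0, ins_rate = 0,
                       del_rate = 0)
  reads <- simulate_reads(genome, prof, seed = 2)
  total <- sum(Biostrings::width(reads))
  expect_gte(total, 18e6)
  expect_lte(total, 22e6)
  # read names encode the true origin; every zero-error read is an exact
  # substring of the genome or its reverse complement
  chr <- as.character(genome[[1]])
  idx <- sample(length(reads), 25)
  for (i in idx) {
    m <- regmatches(names(reads)[i],
                    regexec("_(.+):([0-9]+)-([0-9]+):([+-])$",
                            names(reads)[i]))[[1]]
    s <- as.integer(m[3]); e <- as.integer(m[4])
    expected <- substr(chr, s + 1, e)
    if (m[5] == "-") expected <- revcomp_chr(expected)
    expect_identical(as.character(reads[[i]]), expected)
  }
})

test_that("ont-like reads have a larger N50 than hifi-like reads", {
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(400000, seed = 6)))
  hifi <- simulate_reads(genome, read_profile("hifi_like", depth = 5), seed = 1)
  ont <- simulate_reads(genome, read_profile("ont_like", depth = 5), seed = 1)
  expect_gt(n50(Biostrings::width(ont)), n50(Biostrings::width(hifi)))
})

test_that("read simulation rejects invalid profiles", {
  expect_error(read_profile("hifi_like", depth = 0), "depth")
  expect_error(read_profile("ont_like", sub_rate = 0.5), "error rates")
})

test_that("chip track is flat under no enrichment and elevated in centromere", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 3000000)))
  truth <- tibble::tibble(chrom = "chr1", start = 1200000, end = 1500000,
                          feature_class = "centromere", strand = "+",
                          attrs = "")
  # null: enrichment factor 1
  tr0 <- simulate_chip_track(genome, truth, window_bp = 30000,
                             base_rate = 0.01, enrichment_factor = 1,
                             seed = 9)
  expect_equal(nrow(tr0$ip), 100L)  # 3 Mb / 30 kb
  ratio0 <- tr0$ip$count / pmax(tr0$input$count, 1)
  se0 <- stats::sd(ratio0) / sqrt(length(ratio0))
  expect_lt(abs(mean(ratio0) - 1), 3 * se0)
  # enriched: factor 4 over a small fraction of a larger genome, so that
  # library-size scaling barely perturbs the ratio
  genome_big <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 30000000)))
  tr4 <- simulate_chip_track(genome_big, truth, window_bp = 30000,
                             base_rate = 0.01, enrichment_factor = 4,
                             seed = 10)
  enr <- windowed_enrichment(tr4$ip, tr4$input, window_bp = 30000)
  mid <- (enr$start + enr$end) / 2
  in_cen <- mid >= 1200000 & mid < 1500000
  cen_ratio <- enr$ratio[in_cen]
  se <- stats::sd(cen_ratio) / sqrt(sum(in_cen))
  expect_lt(abs(mean(cen_ratio) - 4), 3 * se + 0.15)
})

test_that("mutate_ltr_pair realizes the target divergence", {
  cons <- rand_dna(2000, seed = 12)
  # K = 0: copies identical
  p0 <- mutate_ltr_pair(cons, 0, seed = 1)
  expect_identical(p0$ltr5, p0$ltr3)
  expect_identical(p0$ltr5, cons)
  # beyond saturation
  expect_error(mutate_ltr_pair(cons, 0.8), "saturation")
  # Monte-Carlo: mean realized p-distance matches the closed-form expectation
  # for two branches of length K/2 each
  K <- 0.05
  p_exp <- 0.75 * (1 - exp(-4 * K / 3))
  ps <- vapply(1:100, function(i)
    mutate_ltr_pair(cons, K, seed = 100 + i)$p_distance, numeric(1))
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - p_exp), 3 * se)
})

test_that("blueprint round-trips through the YAML config reader", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "chrom_lengths: [200000]",
    "seed: 4",
    "telomere: {copies: 300, variant_frac: 0.0}",
    "nor: {copies: 10}",
    "ltr:",
    "  - {clade: Athila, n: 4, K: 0.05, solo_frac: 0.5}"), cfg)
  bp <- read_blueprint_config(cfg)
  expect_s3_class(bp, "genome_blueprint")
  expect_equal(bp$chrom_lengths, 200000L)
  expect_equal(bp$telomere$copies, 300L)
  expect_equal(bp$nor$copies, 10L)
  expect_equal(bp$ltr$clade, "Athila")
  sim <- simulate_genome(bp)
  expect_equal(sum(sim$truth$feature_class == "rdna_unit"), 10L)
})
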