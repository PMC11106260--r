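# Motif scanning, exact enrichment, intersection, and the statistical
# calibration of the enrichment test.

test_that("IUPAC scanning is strand-aware and never matches sequence N", {
  seqs <- c(gbox = "AAAACACGTGAAAA",      # palindromic G-box, one site
            myc = "GGGGCATATGGGGG",       # CANNTG via N expansion
            polyA = strrep("A", 30),
            withN = "GGGGCACNTGGGGG")     # N in the sequence itself
  sc <- scan_motifs(seqs)
  get <- function(id, m) sc$count[sc$seq_id == id & sc$motif == m]
  expect_equal(get("gbox", "G-box"), 1L)   # palindrome counted once per site
  expect_equal(get("gbox", "MYC"), 1L)     # CACGTG is also CANNTG
  expect_equal(get("myc", "MYC"), 1L)
  expect_equal(get("myc", "G-box"), 0L)
  expect_true(all(sc$count[sc$seq_id == "polyA"] == 0L))
  expect_equal(get("withN", "MYC"), 0L)    # N in subject never matches
  expect_error(scan_motifs(seqs, tibble::tibble(name = "bad",
                                                consensus = "ACZGT")),
               "IUPAC")
})

test_that("presence tables are invariant under reverse complement", {
  withr::with_seed(121, {
    seqs <- stats::setNames(stringi::stri_rand_strings(30, 400, "[ACGT]"),
                            paste0("s", 1:30))
  })
  fwd <- scan_motifs(seqs)
  rev <- scan_motifs(stats::setNames(revcomp_chr(seqs), names(seqs)))
  j <- dplyr::inner_join(fwd, rev, by = c("seq_id", "motif"))
  expect_equal(j$count.x, j$count.y)
})

test_that("enrichment p-values equal the exact hypergeometric tail", {
  mk_scan <- function(with, total, motif = "MYB") tibble::tibble(
    seq_id = paste0("s", seq_len(total)), motif = motif,
    count = as.integer(seq_len(total) <= with),
    present = seq_len(total) <= with)
  # 45/50 vs 5/50: strongly enriched
  e1 <- enrich_motifs(mk_scan(45, 50), mk_scan(5, 50))
  expect_lt(e1$p_value, 1e-6)
  expect_true(e1$enriched)
  # independent oracle: one-sided Fisher test on the same 2x2 table
  f <- stats::fisher.test(matrix(c(45, 5, 5, 45), 2), alternative = "greater")
  expect_equal(e1$p_value, f$p.value, tolerance = 1e-9)
  # 25/50 vs 25/50: p ~ 0.54, not enriched
  e2 <- enrich_motifs(mk_scan(25, 50), mk_scan(25, 50))
  expect_equal(e2$p_value,
               stats::phyper(24, 50, 50, 50, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(e2$p_value, 0.5)
  expect_false(e2$enriched)
  # 0/50 vs 10/50: no over-representation possible
  e3 <- enrich_motifs(mk_scan(0, 50), mk_scan(10, 50))
  expect_equal(e3$p_value, 1)
  expect_false(e3$enriched)
  expect_error(enrich_motifs(mk_scan(1, 1)[0, ], mk_scan(5, 50)), "empty")
})

test_that("intersection returns motifs enriched in both analyses, sorted", {
  mk <- function(motifs, ps) tibble::tibble(
    motif = motifs, fg_with = 40L, fg_total = 50L, bg_with = 5L,
    bg_total = 50L, p_value = ps, q_value = ps, enriched = ps < 0.01)
  five <- c("MYB", "G-box", "Box-4", "ABRE", "MYC")
  a <- mk(c(five, "other1"), c(1e-6, 1e-5, 1e-4, 1e-3, 5e-3, 0.5))
  b <- mk(c(five, "other2"), c(5e-3, 1e-6, 1e-5, 1e-4, 1e-3, 0.2))
  got <- intersect_enriched(a, b)
  expect_setequal(got$motif, five)
  expect_equal(got$max_p, sort(got$max_p))
  # disjoint enriched sets -> empty
  expect_equal(nrow(intersect_enriched(mk("MYB", 1e-6), mk("MYC", 1e-6))), 0L)
  # one side empty -> empty
  expect_equal(nrow(intersect_enriched(mk("MYB", 0.9), b)), 0L)
})

test_that("scanner-to-intersection pipeline recovers the five planted motifs", {
  motifs <- motif_library()
  plant_all <- function(n, seed) {
    withr::with_seed(seed, {
      s <- stringi::stri_rand_strings(n, 120, "[ACGT]")
      ins <- paste(gsub("N", "T", motifs$consensus), collapse = "AA")
      s <- paste0(substr(s, 1, 20), ins,
                  substr(s, 21 + nchar(ins), 120))
      stats::setNames(s, paste0("s", seq_len(n)))
    })
  }
  plain <- function(n, seed) withr::with_seed(seed, stats::setNames(
    stringi::stri_rand_strings(n, 120, "[ACGT]"), paste0("b", seq_len(n))))
  fg_a <- scan_motifs(plant_all(40, 122)); bg_a <- scan_motifs(plain(40, 123))
  fg_b <- scan_motifs(plant_all(40, 124)); bg_b <- scan_motifs(plain(40, 125))
  res_a <- enrich_motifs(fg_a, bg_a)
  res_b <- enrich_motifs(fg_b, bg_b)
  got <- intersect_enriched(res_a, res_b)
  expect_setequal(got$motif, motifs$name)
})

test_that("the enrichment test is calibrated and powered", {
  null <- motif_null_sim(n_reps = 500)
  ci <- 0.01 + c(-1, 1) * 1.96 * sqrt(0.01 * 0.99 / null$n_reps)
  expect_gte(null$rate, ci[1])
  expect_lte(null$rate, ci[2])
  power <- motif_power_sim(n_reps = 200)
  expect_gte(power, 0.99)
})

test_that("the Markov background shuffle preserves length and composition", {
  seqs <- c(a = rand_dna(2000, seed = 126))
  sh <- shuffle_background(seqs, seed = 1)
  expect_equal(unname(Biostrings::width(sh)), 2000L)
  comp_in <- table(strsplit(seqs[["a"]], "")[[1]]) / 2000
  comp_out <- table(strsplit(as.character(sh[[1]]), "")[[1]]) / 2000
  expect_true(all(abs(comp_in - comp_out[names(comp_in)]) < 0.05))
  expect_identical(as.character(shuffle_background(seqs, seed = 1)),
                   as.character(sh))
})
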