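# rDNA array toolkit: copy-number arithmetic, k-mer mass, unit typing, read
# classification, graph building, reconstruction and gap filling.

test_that("copy-number estimate is exact floor division", {
  expect_identical(estimate_copy_number(60000, 42), 1428L)
  expect_identical(estimate_copy_number(0, 42), 0L)
  expect_error(estimate_copy_number(100, 0), "depth")
  expect_error(estimate_copy_number(-1, 10), "mass")
  # scaling M and d together leaves the estimate unchanged (up to floor)
  for (f in c(2, 5, 10))
    expect_identical(estimate_copy_number(60000 * f, 42 * f),
                     estimate_copy_number(60000, 42))
})

test_that("k-mer mass is the median unit-k-mer multiplicity and is linear", {
  unit <- rand_dna(500, seed = 71)
  reads <- Biostrings::DNAStringSet(
    stats::setNames(rep(unit, 10), paste0("r", 1:10)))
  m <- measure_kmer_mass(reads, unit)
  expect_equal(m$M, 10)
  expect_equal(m$n_kmers, length(unique(
    canonical_kmers(kmers_chr(unit, 19)))))
  # duplicating every read doubles M
  m2 <- measure_kmer_mass(c(reads, reads), unit)
  expect_equal(m2$M, 20)
  # invariant to read order
  m3 <- measure_kmer_mass(rev(reads), unit)
  expect_equal(m3$M, m$M)
  # no unit k-mer observed
  noise <- Biostrings::DNAStringSet(c(x = rand_dna(500, seed = 72)))
  expect_warning(m0 <- measure_kmer_mass(noise, unit), "no unit k-mer")
  expect_equal(m0$M, 0)
})

test_that("unit-read extraction applies the k-mer fraction threshold", {
  unit <- rand_dna(800, seed = 73)
  reads <- Biostrings::DNAStringSet(c(
    tandem = strrep(unit, 3),                                  # frac ~ 1
    noise = rand_dna(2000, seed = 74),                         # frac 0
    boundary = paste0(substr(unit, 1, 500), rand_dna(1500, seed = 75))))
  sel <- extract_unit_reads(reads, unit)
  expect_setequal(names(sel), c("tandem", "boundary"))  # 25% unit retained
  expect_error(extract_unit_reads(reads, "ACGT"), "shorter than k")
})

test_that("unit length typing splits classes at the 50-bp gap", {
  cl <- type_units(c(rep(8360, 7), rep(8500, 3)))
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$proportion, c(0.7, 0.3))
  expect_equal(cl$label, c("A", "B"))
  expect_equal(cl$min_len, c(8360L, 8500L))
  # all identical lengths: one class, proportion 1
  one <- type_units(rep(8400, 5))
  expect_equal(nrow(one), 1L)
  expect_equal(one$proportion, 1)
  # 40-bp gap merges, 50-bp gap splits
  expect_equal(nrow(type_units(c(8360, 8400))), 1L)
  expect_equal(nrow(type_units(c(8360, 8410))), 2L)
  expect_error(type_units(integer(0)), "at least one")
})

test_that("reads classify as prefix, internal or suffix", {
  unit <- rand_dna(3000, seed = 76)
  reads <- Biostrings::DNAStringSet(c(
    pre = paste0(strrep("TTTAGGG", 50), strrep(unit, 2)),
    int = strrep(unit, 4),
    suf = paste0(strrep(unit, 2), rand_dna(10000, seed = 77))))
  cls <- classify_reads(reads, unit)
  expect_equal(cls$role[match(c("pre", "int", "suf"), cls$read_id)],
               c("prefix", "internal", "suffix"))
})

test_that("array graph links fragments through rare k-mers only", {
  # planted sequence cut into 3 overlapping fragments -> path graph, 2 edges
  full <- rand_dna(60000, seed = 78)
  frags <- Biostrings::DNAStringSet(c(
    f1 = substr(full, 1, 25000),
    f2 = substr(full, 20001, 45000),
    f3 = substr(full, 40001, 60000)))
  g <- build_array_graph(frags)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("f1 f2", "f2 f3"))
  expect_true(all(g$edges$consistent))
  # offsets reflect the true 20-kb shifts
  expect_setequal(abs(g$edges$offset), 20000)
  # two pure-repeat fragments with no unique sequence share no rare k-mer
  u <- rand_dna(1000, seed = 79)
  rep_frags <- Biostrings::DNAStringSet(c(a = strrep(u, 5), b = strrep(u, 5)))
  g0 <- build_array_graph(rep_frags)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("reconstruction demands one prefix, one suffix and a connecting path", {
  full <- rand_dna(40000, seed = 80)
  frags <- Biostrings::DNAStringSet(c(
    f1 = substr(full, 1, 15000),
    f2 = substr(full, 10001, 30000),
    f3 = substr(full, 25001, 40000)))
  g_no_suffix <- build_array_graph(frags,
                                   roles = c("prefix", "internal", "internal"))
  expect_error(reconstruct_array(g_no_suffix, substr(full, 1, 500)),
               "exactly one prefix and one suffix")
  # disconnected suffix
  far <- Biostrings::DNAStringSet(c(
    f1 = substr(full, 1, 15000), lone = rand_dna(15000, seed = 81)))
  g_disc <- build_array_graph(far, roles = c("prefix", "suffix"))
  expect_error(reconstruct_array(g_disc, substr(full, 1, 500)),
               "no rare-k-mer path")
})

test_that("a planted bifurcation raises an ambiguity error, not a guess", {
  junction <- rand_dna(8000, seed = 82)
  armA <- rand_dna(8000, seed = 83)
  armB <- rand_dna(8000, seed = 84)
  frags <- Biostrings::DNAStringSet(c(
    base = junction,
    brA = paste0(substr(junction, 2001, 8000), armA),
    brB = paste0(substr(junction, 2001, 8000), armB)))
  g <- build_array_graph(frags, roles = c("prefix", "internal", "suffix"))
  expect_error(reconstruct_array(g, substr(junction, 1, 500)),
               "ambiguous reconstruction")
})

test_that("zero-error reads reconstruct the planted NOR bit-exactly", {
  fx <- nor_sim50()
  expect_identical(fx$result$sequence, fx$planted_nor)
  expect_identical(fx$result$copy_count, 50L)
  # k-mer-mass route recovers the planted copy number to within 10%
  unit_reads <- extract_unit_reads(fx$reads, fx$sim$nor_consensus)
  mass <- measure_kmer_mass(unit_reads, fx$sim$nor_consensus)
  est <- estimate_copy_number(mass$M, 10)
  expect_gte(est, 45L)
  expect_lte(est, 55L)
})

test_that("N-gaps are closed only by reads spanning both unique flanks", {
  draft_full <- rand_dna(20000, seed = 85)
  gapped <- paste0(substr(draft_full, 1, 9000), strrep("N", 500),
                   substr(draft_full, 9501, 20000))
  spanning <- Biostrings::DNAStringSet(
    c(sp = substr(draft_full, 7000, 12000)))
  res <- fill_array_gaps(gapped, spanning)
  expect_identical(res$sequence, draft_full)
  expect_true(all(res$report$filled))
  # no Ns: unchanged, empty report
  res0 <- fill_array_gaps(draft_full, spanning)
  expect_identical(res0$sequence, draft_full)
  expect_equal(nrow(res0$report), 0L)
  # no spanning read: gap left untouched and reported
  off_target <- Biostrings::DNAStringSet(c(x = substr(draft_full, 1, 5000)))
  res1 <- fill_array_gaps(gapped, off_target)
  expect_identical(res1$sequence, gapped)
  expect_false(any(res1$report$filled))
})
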