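# Telomere scanning, read selection, anchoring and patching.

test_that("terminal scanner recovers planted arrays with exact counts", {
  body <- rand_dna(300000, seed = 51)
  # right-end forward array
  g_right <- paste0(body, strrep("TTTAGGG", 1000))
  calls <- scan_terminal_telomere(g_right)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$end_side, "right")
  expect_equal(calls$copy_count, 1000L)
  expect_equal(calls$purity, 1.0)
  expect_equal(calls$motif, "TTTAGGG")
  # left-end array stored as CCCTAAA repeats, orientation-normalized
  g_left <- paste0(strrep("CCCTAAA", 800), body)
  calls_l <- scan_terminal_telomere(g_left)
  expect_equal(nrow(calls_l), 1L)
  expect_equal(calls_l$end_side, "left")
  expect_equal(calls_l$motif, "TTTAGGG")
  expect_equal(calls_l$copy_count, 800L)
  # random sequence: nothing
  expect_equal(nrow(scan_terminal_telomere(rand_dna(1000000, seed = 52))), 0L)
  # non-ACGT motif rejected
  expect_error(scan_terminal_telomere(g_right, motifs = "TTTAGGX"), "7-mers")
})

test_that("scan calls mirror under reverse complement (strand consistency)", {
  sim <- telomere_sim()
  for (ci in seq_along(sim$genome)) {
    contig <- sim$genome[[ci]]
    L <- length(contig)
    fwd <- scan_terminal_telomere(contig)
    rev <- scan_terminal_telomere(Biostrings::reverseComplement(contig))
    expect_equal(nrow(fwd), nrow(rev))
    fwd <- fwd[order(fwd$end_side), ]
    mirrored <- tibble::tibble(end_side = ifelse(rev$end_side == "left",
                                                 "right", "left"),
                               start = L - rev$stop, stop = L - rev$start,
                               copy_count = rev$copy_count)
    mirrored <- mirrored[order(mirrored$end_side), ]
    expect_equal(fwd$end_side, mirrored$end_side)
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$stop, mirrored$stop)
    expect_equal(fwd$copy_count, mirrored$copy_count)
  }
})

test_that("telomere read selection enforces length and copy thresholds", {
  filler <- rand_dna(250000, seed = 53)
  mk <- function(len, copies) {
    arr <- strrep("TTTAGGG", copies)
    paste0(substr(filler, 1, len - nchar(arr)), arr)
  }
  reads <- Biostrings::DNAStringSet(c(
    ok = mk(250000, 12),          # long enough, 12 copies -> selected
    short = mk(150000, 100),      # rejected on length
    few = mk(250000, 9),          # rejected on copies
    boundary_len = mk(200000, 50),  # length not strictly > 200 kb
    boundary_cp = mk(250000, 10),   # exactly 10 copies -> selected
    rc = paste0(strrep("CCCTAAA", 15), substr(filler, 1, 230000))))
  sel <- select_telomere_reads(reads)
  expect_setequal(names(sel), c("ok", "boundary_cp", "rc"))
  expect_length(select_telomere_reads(Biostrings::DNAStringSet()), 0L)
})

test_that("read anchoring reports overhangs and strand symmetrically", {
  contig <- rand_dna(200000, seed = 54)
  novel <- rand_dna(5000, seed = 55)
  read <- paste0(substr(contig, 170001, 200000), novel)
  a <- anchor_read_to_end(read, contig, "right", read_id = "r1")
  expect_equal(a$overhang_len, 5000)
  expect_equal(a$orientation, "+")
  expect_gte(a$n_seed_matches, 20)
  # reverse-complemented read: same overhang, orientation -
  arc <- anchor_read_to_end(revcomp_chr(read), contig, "right", read_id = "r2")
  expect_equal(arc$overhang_len, 5000)
  expect_equal(arc$orientation, "-")
  # left end
  readL <- paste0(novel, substr(contig, 1, 30000))
  al <- anchor_read_to_end(readL, contig, "left", read_id = "r3")
  expect_equal(al$overhang_len, 5000)
  # no shared k-mers: error naming the read
  expect_error(anchor_read_to_end(rand_dna(30000, seed = 56), contig, "right",
                                  read_id = "stranger"),
               "no qualifying anchor chain.*stranger")
})

test_that("patching appends the best overhang and never edits the contig", {
  contig <- rand_dna(150000, seed = 57)
  tail20 <- substr(contig, 130001, 150000)
  ext <- rand_dna(6000, seed = 58)
  reads <- Biostrings::DNAStringSet(c(
    rA = paste0(tail20, substr(ext, 1, 4200)),
    rB = paste0(substr(contig, 135001, 150000), substr(ext, 1, 3000)),
    rC = revcomp_chr(paste0(tail20, substr(ext, 1, 2500)))))
  anchors <- anchor_telomere_reads(reads, contig, "right")
  expect_equal(nrow(anchors), 3L)
  res <- patch_telomere(contig, anchors, reads, min_support = 3)
  expect_equal(length(res$contig), 150000 + 4200)
  expect_identical(substr(as.character(res$contig), 1, 150000), contig)
  expect_identical(substr(as.character(res$contig), 150001, 154200),
                   substr(ext, 1, 4200))
  expect_equal(res$report$read_id, "rA")
  expect_equal(res$report$support, 3L)
  # no anchors: unchanged contig, empty report
  res0 <- patch_telomere(contig, anchors[0, ], reads)
  expect_identical(as.character(res0$contig), contig)
  expect_equal(nrow(res0$report), 0L)
  # irreconcilable overhangs: conflict error, no patch
  bad <- Biostrings::DNAStringSet(c(
    rA = paste0(tail20, rand_dna(3000, seed = 59)),
    rB = paste0(tail20, rand_dna(3000, seed = 60))))
  bad_anchors <- anchor_telomere_reads(bad, contig, "right")
  expect_error(patch_telomere(contig, bad_anchors, bad), "conflict")
})

test_that("full pipeline restores planted telomeres byte-exactly", {
  sim <- telomere_sim()
  chrom <- as.character(sim$genome[[1]])
  L <- nchar(chrom)
  # truncate both ends (telomere 2,800 bp + 2,200 bp subtelomere each side)
  cut <- 5000
  assembly <- substr(chrom, cut + 1, L - cut)
  # ultralong zero-error reads spanning each end
  reads <- Biostrings::DNAStringSet(c(
    endR = substr(chrom, L - 220000 + 1, L),
    endL = revcomp_chr(substr(chrom, 1, 220000)),
    decoy = substr(chrom, 100000, 140000)))
  sel <- select_telomere_reads(reads, min_read_len = 200000,
                               min_motif_copies = 10)
  expect_setequal(names(sel), c("endR", "endL"))
  anchors <- rbind(anchor_telomere_reads(sel, assembly, "right"),
                   anchor_telomere_reads(sel, assembly, "left"))
  res <- patch_telomere(assembly, anchors, sel, min_support = 1)
  expect_identical(as.character(res$contig), chrom)
  # patched ends now carry telomere calls matching truth
  calls <- scan_terminal_telomere(res$contig)
  expect_equal(nrow(calls), 2L)
})
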