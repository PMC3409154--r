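test_that("scanner finds core motifs on both strands with correct coordinates", {
  s <- scan_reference_motifs("GGTAATCCAA")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 2L)
  expect_equal(s$end, 8L)
  expect_equal(s$strand, "+")
  expect_equal(s$hexamer, "TAATCC")

  s <- scan_reference_motifs("CAGGATTACT")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 2L)
  expect_equal(s$end, 8L)
  expect_equal(s$strand, "-")
  expect_equal(s$hexamer, "GGATTA")

  expect_equal(nrow(scan_reference_motifs("AAAAAAAAAA")), 0L)
  expect_equal(nrow(scan_reference_motifs(strrep("TAATCCTAATCC", 1),
                                          both_strands = FALSE)), 2L)
  expect_error(scan_reference_motifs("ACGT", motif = "TAATXZ"), "IUPAC")
})

test_that("scanner agrees with the brute-force hexamer oracle", {
  set.seed(42)
  for (i in 1:200) {
    seq <- random_dna(sample(50:800, 1))
    got <- scan_reference_motifs(seq)
    want <- brute_force_taatcy(seq)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("reverse-complementing a block mirrors site coordinates and strand", {
  set.seed(7)
  for (i in 1:20) {
    rows <- c(mouse = random_dna(300), rat = random_dna(300))
    blk <- alignment_block(rows)
    L <- nchar(ref_sequence(blk))
    fwd <- annotate_conservation(blk, scan_reference_motifs(blk))
    rc <- revcomp_block(blk)
    rev <- annotate_conservation(rc, scan_reference_motifs(rc))
    mapped <- data.frame(
      start = L - fwd$end, end = L - fwd$start,
      strand = as.character(ifelse(fwd$strand == "+", "-", "+")),
      n_species = fwd$n_species, stringsAsFactors = FALSE)
    mapped <- mapped[order(mapped$start, match(mapped$strand, c("+", "-"))), ]
    expect_equal(rev$start, mapped$start)
    expect_equal(rev$end, mapped$end)
    expect_equal(rev$strand, mapped$strand)
    expect_equal(rev$n_species, mapped$n_species)
  }
})

test_that("conservation is a columnar check that rejects gaps and N", {
  blk <- alignment_block(c(mouse = "GGTAATCCAA",
                           rat   = "GGTAATCCAA",
                           human = "GGTAATCCAA"))
  s <- annotate_conservation(blk, scan_reference_motifs(blk))
  expect_equal(s$n_species, 3L)
  expect_setequal(s$conserved_species[[1]], c("mouse", "rat", "human"))

  # a gap inside the hexamer excludes that species; columns shift for it
  blk2 <- alignment_block(c(mouse = "GGTAATCCAA",
                            rat   = "GGTAATCCAA",
                            human = "GGTA-TCCAA"))
  s2 <- annotate_conservation(blk2, scan_reference_motifs(blk2))
  expect_equal(s2$n_species, 2L)
  expect_false("human" %in% s2$conserved_species[[1]])

  # N inside the hexamer also excludes
  blk3 <- alignment_block(c(mouse = "GGTAATCCAA", rat = "GGTANTCCAA"))
  s3 <- annotate_conservation(blk3, scan_reference_motifs(blk3))
  expect_equal(s3$n_species, 1L)

  # single-species block: the reference conserves its own site
  blk4 <- alignment_block(c(mouse = "GGTAATCCAA"))
  s4 <- annotate_conservation(blk4, scan_reference_motifs(blk4))
  expect_equal(s4$n_species, 1L)

  # insertion columns in the reference do not break the coordinate mapping
  blk5 <- alignment_block(c(mouse = "GG--TAATCCAA", rat = "GGCGTAATCCAA"))
  s5 <- scan_reference_motifs(blk5)
  expect_equal(s5$start, 2L)
  expect_equal(annotate_conservation(blk5, s5)$n_species, 2L)
})

test_that("removing a species row never increases any site's conservation", {
  set.seed(11)
  for (i in 1:10) {
    sim <- simulate_alignment(aln_sim_config(seed = 100 + i,
                                             substitution_rate = 0.05))
    blk <- sim$block
    full <- annotate_conservation(blk, scan_reference_motifs(blk))
    drop <- sample(setdiff(names(blk$rows), blk$ref_species), 1)
    blk2 <- alignment_block(blk$rows[setdiff(names(blk$rows), drop)],
                            ref_species = blk$ref_species)
    red <- annotate_conservation(blk2, scan_reference_motifs(blk2))
    expect_equal(red$start, full$start)
    expect_true(all(red$n_species <= full$n_species))
  }
})

test_that("candidate selection thresholds by conservation count", {
  sim <- simulate_alignment(aln_sim_config(seed = 3))
  sites <- annotate_conservation(sim$block, scan_reference_motifs(sim$block))
  expect_setequal(sites$n_species, c(4L, 6L, 7L))
  expect_equal(nrow(select_candidate_sites(sites, 6)), 2L)
  expect_equal(nrow(select_candidate_sites(sites, 1)), 3L)
  expect_equal(nrow(select_candidate_sites(sites[0, ], 6)), 0L)
  expect_error(select_candidate_sites(sites, 0), "min_species")
})

test_that("amplicon windows are centered, clipped and length-bounded", {
  mk_site <- function(start) {
    s <- scan_reference_motifs(paste0(strrep("A", start), "TAATCC",
                                      strrep("A", 20)))
    s
  }
  w <- design_amplicon_window(mk_site(500), seq_length = 10000,
                              target_len = 110)
  expect_equal(c(w$start, w$end, w$length), c(448, 558, 110))

  w2 <- design_amplicon_window(mk_site(2), seq_length = 10000,
                               target_len = 110)
  expect_equal(c(w2$start, w2$end), c(0, 110))

  expect_error(design_amplicon_window(mk_site(2), seq_length = 50),
               "70 bp")
  expect_error(design_amplicon_window(mk_site(2), seq_length = 10000,
                                      target_len = 160), "target_len")

  set.seed(5)
  for (i in 1:50) {
    L <- sample(120:5000, 1)
    pos <- sample(0:(L - 6), 1)
    tl <- sample(70:150, 1)
    st <- mk_site(pos)
    ww <- design_amplicon_window(st, seq_length = L, target_len = tl)
    expect_gte(ww$length, 70)
    expect_lte(ww$length, 150)
    expect_lte(ww$start, pos)
    expect_gte(ww$end, pos + 6)
    expect_gte(ww$start, 0)
    expect_lte(ww$end, L)
  }
})

test_that("control regions keep the exclusion distance from every site", {
  one_site <- scan_reference_motifs(paste0(strrep("A", 5000), "TAATCC",
                                           strrep("A", 4994)))
  ctl <- select_control_regions(10000, one_site, n = 1)
  expect_equal(c(ctl$start, ctl$end), c(0, 110))

  # sites tiled every 500 bp leave no admissible gap
  tiled <- scan_reference_motifs(paste(rep(paste0("TAATCC",
                                                  strrep("A", 494)), 20),
                                       collapse = ""))
  expect_equal(nrow(select_control_regions(10000, tiled, n = 3)), 0L)

  # no sites: regions tile from position 0
  empty <- scan_reference_motifs(strrep("A", 10000))
  ctl3 <- select_control_regions(10000, empty, n = 3)
  expect_equal(ctl3$start, c(0, 110, 220))

  # distance property on the demo locus
  sim <- simulate_alignment(aln_sim_config(seed = 9))
  sites <- scan_reference_motifs(sim$block)
  ctl4 <- select_control_regions(nchar(ref_sequence(sim$block)), sites,
                                 exclusion = 1000, n = 5)
  for (i in seq_len(nrow(ctl4))) {
    d <- pmax(sites$start - ctl4$end[i], ctl4$start[i] - sites$end)
    expect_true(all(d >= 1000))
  }
})

test_that("MAF blocks are parsed, ordered and concatenated over gaps", {
  maf <- c("##maf version=1", "",
           "a score=1.0",
           "s mm9.chr1 10 8 + 1000 GGTAATCC",
           "s rn4.chr5 20 8 + 2000 GGTAATCC",
           "",
           "a score=2.0",
           "s mm9.chr1 30 6 + 1000 TAATCT",
           "s hg18.chr7 5 6 + 3000 TAATCT")
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(maf, f)
  blocks <- read_maf(f, "mm9")
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$ref_start, 10L)

  blk <- concat_blocks(blocks)
  expect_equal(blk$ref_start, 10L)
  expect_equal(nchar(ref_sequence(blk)), 26L)  # 8 + 12 N gap + 6
  sites <- annotate_conservation(blk, scan_reference_motifs(blk))
  # one site per original block; nothing called in the N-filled gap
  expect_equal(sites$start, c(12L, 30L))
  expect_equal(sites$n_species, c(2L, 2L))
  expect_setequal(sites$conserved_species[[2]], c("mm9", "hg18"))
})

test_that("BED export writes 0-based half-open sites with conservation score", {
  sim <- simulate_alignment(aln_sim_config(seed = 3))
  sites <- annotate_conservation(sim$block, scan_reference_motifs(sim$block))
  f <- withr::local_tempfile(fileext = ".bed")
  export_sites_bed(sites, f)
  bed <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(bed$V2, sites$start)
  expect_equal(bed$V3, sites$end)
  expect_equal(bed$V5, sites$n_species)
  expect_equal(bed$V6, sites$strand)
})
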