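test_that("translation follows the standard code with stop and fuzzy handling", {
  tr <- translate_cds("ATGTGGGATCCGTAA")
  expect_equal(tr$protein, "MWDP")
  expect_true(tr$stop_reached)
  expect_equal(tr$stop_codon, 5L)
  tr2 <- translate_cds("ATG")
  expect_equal(tr2$protein, "M")
  expect_false(tr2$stop_reached)
  expect_warning(tr3 <- translate_cds("ATGGCCA"), "trailing 1 nt ignored")
  expect_equal(tr3$protein, "MA")
  tr4 <- translate_cds("ATGGNCTAA")
  expect_equal(tr4$protein, "MX")
  # agreement with an independent translation on random ORFs
  set.seed(5)
  for (rep in 1:10) {
    orf <- toy_orf(paste0("M", random_protein(30)), seed = rep)
    expect_identical(translate_cds(orf$cds)$protein, translate_oracle(orf$cds)$protein)
  }
})

test_that("orf_record enforces the coding-sequence invariants", {
  expect_error(orf_record("x", "ATGGCC"), "stop codon")
  expect_error(orf_record("x", "GCGGCCTAA"), "begin with ATG")
  expect_error(orf_record("x", "ATGGCCTA"), "divisible by 3")
  expect_error(orf_record("x", "ATGTAAGCCTAA"), "internal stop at codon 2")
  orf <- orf_record("ok", "ATGTGGGATCCGTAA")
  expect_equal(orf$protein, "MWDP")
})

test_that("WDP split points carry BamHI status and the synonymous edit", {
  # D codon GAT: GGATCC already spans the triad
  orf_gat <- orf_record("gat", "ATGTGGGATCCATAA")
  sp <- find_wdp_splits(orf_gat)
  expect_length(sp, 1L)
  expect_true(sp[[1]]$bamhi_present)
  expect_equal(nrow(sp[[1]]$required_edits), 0L)
  expect_equal(sp[[1]]$w_codon, 2L)
  expect_equal(sp[[1]]$split_after_codon, 3L)
  # D codon GAC: single C->T edit at nt 3 * d_codon
  orf_gac <- orf_record("gac", "ATGTGGGACCCATAA")
  sp2 <- find_wdp_splits(orf_gac)[[1]]
  expect_false(sp2$bamhi_present)
  expect_equal(sp2$required_edits$position, 9L)
  expect_equal(sp2$required_edits$from, "C")
  expect_equal(sp2$required_edits$to, "T")
  # no WDP -> empty list, not an error
  expect_length(find_wdp_splits(orf_record("n", "ATGGCCTAA")), 0L)
})

test_that("synonymous edits preserve the translation and create GGATCC", {
  for (seed in 1:10) {
    k <- sample(5:40, 1)
    sim <- simulate_orf(orf_spec(length = 60, wdp_positions = k,
                                 d_codon_choice = "GAC", seed = seed))
    sp <- find_wdp_splits(sim$orf)
    expect_length(sp, 1L)
    expect_equal(sp[[1]]$required_edits$position, 3L * (k + 1L))
    edited <- apply_synonymous_edits(sim$orf, sp[[1]])
    expect_identical(edited$protein, sim$orf$protein)
    # GGATCC starts at the last base of the W codon (nt 3k)
    expect_true(any(restriction_scan(edited$cds, "BamHI")$position == 3L * k))
    # no-op when the site is already there
    sim2 <- simulate_orf(orf_spec(length = 60, wdp_positions = k,
                                  d_codon_choice = "GAT", seed = seed))
    sp2 <- find_wdp_splits(sim2$orf)[[1]]
    expect_identical(apply_synonymous_edits(sim2$orf, sp2)$cds, sim2$orf$cds)
  }
})

test_that("splitting at WDP yields ...WD / P... fragments that reassemble", {
  orf <- orf_record("toy", "ATGTGGGATCCGTAA")
  sp <- find_wdp_splits(orf)[[1]]
  frag <- split_orf(orf, sp)
  expect_equal(frag$nt$protein, "MWD")
  expect_equal(frag$ct$protein, "P")
  expect_equal(paste0(frag$nt$cds, frag$ct$cds), orf$cds)
  expect_equal(nchar(frag$nt$protein) + nchar(frag$ct$protein),
               nchar(orf$protein))
  # split from a different ORF is rejected
  other <- orf_record("o", "ATGGCCGCCTGGGATCCGTAA")
  expect_error(split_orf(orf, find_wdp_splits(other)[[1]]), "does not belong")
})

test_that("chimeras join donors in frame at the WDP/BamHI junction", {
  simA <- simulate_orf(orf_spec(length = 80, wdp_positions = 40,
                                d_codon_choice = "GAC", seed = 21), id = "A")
  simB <- simulate_orf(orf_spec(length = 100, wdp_positions = 55,
                                d_codon_choice = "GAT", seed = 22), id = "B")
  spA <- find_wdp_splits(simA$orf)[[1]]
  spB <- find_wdp_splits(simB$orf)[[1]]
  ch <- assemble_chimera(simA$orf, spA, simB$orf, spB, id = "AB")
  expect_equal(ch$protein,
               paste0(substr(simA$orf$protein, 1, 41),
                      substr(simB$orf$protein, 57, 100)))
  expect_equal(ch$junction_codon, 41L)
  # BamHI site spans the junction codons
  sites <- restriction_scan(ch$cds, "BamHI")$position
  expect_true((3L * 40L) %in% sites)
  # self-chimera reproduces the donor protein exactly
  self <- assemble_chimera(simA$orf, spA, simA$orf, spA, id = "AA")
  expect_identical(self$protein, simA$orf$protein)
})

test_that("Nt-only constructs terminate with TAA and tags are prepended in frame", {
  sim <- simulate_orf(orf_spec(length = 50, wdp_positions = 30,
                               d_codon_choice = "GAC", seed = 4), id = "D")
  sp <- find_wdp_splits(sim$orf)[[1]]
  nt_only <- assemble_chimera(sim$orf, sp, id = "NtOnly")
  expect_equal(nchar(nt_only$protein), 31L)
  expect_equal(substr(nt_only$cds, nchar(nt_only$cds) - 2, nchar(nt_only$cds)),
               "TAA")
  expect_true(is.na(nt_only$junction_codon))
  his6 <- "ATGCATCACCATCACCATCAC"
  tagged <- assemble_chimera(sim$orf, sp, sim$orf, sp, tag_cds = his6, id = "tag")
  expect_equal(substr(tagged$protein, 1, 8), "MHHHHHHM")
  expect_equal(nchar(tagged$protein), 7L + nchar(sim$orf$protein))
  expect_error(assemble_chimera(sim$orf, sp, tag_cds = "ATGTAA"), "stop codon")
  expect_error(assemble_chimera(sim$orf, sp, tag_cds = "ATGCA"), "divisible by 3")
})

test_that("restriction scanning finds all overlapping motif occurrences", {
  expect_equal(restriction_scan("GGATCC", "BamHI")$position, 1L)
  expect_equal(restriction_scan("GGATCCGGATCC", "BamHI")$position, c(1L, 7L))
  expect_equal(nrow(restriction_scan("AAAAAA", "BamHI")), 0L)
  expect_error(restriction_scan("GGATCC", "NotAnEnzyme"), "unknown enzyme")
  expect_error(restriction_scan("", "BamHI"), "empty")
  # exhaustive-scan oracle on random sequences, all three enzymes
  set.seed(17)
  for (rep in 1:10) {
    dna <- paste(sample(c("A", "C", "G", "T", "GGATCC", "AGATCT", "AAGCTT"),
                        40, replace = TRUE), collapse = "")
    got <- restriction_scan(dna, c("BamHI", "BglII", "HindIII"))
    for (enz in c(BamHI = "GGATCC", BglII = "AGATCT", HindIII = "AAGCTT")) {
      expected <- which(vapply(seq_len(nchar(dna) - 5L), function(i)
        substr(dna, i, i + 5L) == enz, logical(1)))
      expect_equal(got$position[got$motif == enz], expected)
    }
  }
})
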