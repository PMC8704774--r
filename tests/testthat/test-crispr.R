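test_that("guide construction validates spacer length and content", {
  g <- guide_rna("AACTGGCTTTCAGCAAGCGC")
  expect_s3_class(g, "guide_rna")
  expect_error(guide_rna("ACGT"), "exactly 20 nt")
  expect_error(guide_rna("AACTGGCTTTCAGCAAGCGN"), "ambiguity")
})

test_that("planted protospacers are located with strand, PAM and cut site", {
  guide <- guide_rna("AACTGGCTTTCAGCAAGCGC")
  for (seed in 1:5) {
    b <- sample(3:20, 1)
    simp <- simulate_orf(orf_spec(length = 60, protospacers = list(
      list(seq = guide$protospacer, boundary = b, strand = "+")), seed = seed))
    sites <- locate_protospacer(simp$orf$cds, guide)
    expect_equal(nrow(sites), 1L)
    expect_equal(sites$strand, "+")
    expect_equal(sites$protospacer_start, 3L * b + 1L)
    expect_equal(sites$cut_after, sites$protospacer_start + 16L)
    expect_equal(sites$cut_after, simp$truth$protospacers$cut_after)

    simm <- simulate_orf(orf_spec(length = 60, protospacers = list(
      list(seq = guide$protospacer, boundary = b, strand = "-")), seed = seed))
    sm <- locate_protospacer(simm$orf$cds, guide)
    expect_equal(nrow(sm), 1L)
    expect_equal(sm$strand, "-")
    expect_equal(sm$protospacer_start, 3L * b + 4L)
    expect_equal(sm$cut_after, sm$protospacer_start + 2L)
    expect_equal(sm$cut_after, simm$truth$protospacers$cut_after)
  }
})

test_that("a protospacer without NGG is not a target", {
  proto <- "AACTGGCTTTCAGCAAGCGC"
  cds <- paste0("ATG", proto, "ATTGCAGCATAA")  # followed by ATT: no PAM
  expect_equal(nrow(locate_protospacer(cds, guide_rna(proto))), 0L)
  with_pam <- paste0("ATG", proto, "TGGGCATAA") # TGG is a valid NGG
  expect_equal(locate_protospacer(with_pam, guide_rna(proto))$protospacer_start, 4L)
})

test_that("deletion outcomes carry frameshift, stop and novel-residue detail", {
  orf <- toy_orf(paste0("M", random_protein(80)), seed = 3)
  L <- nchar(orf$cds)
  expect_error(apply_deletion(orf, 0, 5), "out of range")
  expect_error(apply_deletion(orf, 10, L + 1), "out of range")
  expect_error(apply_deletion(orf, 2, 6), "ATG")
  # in-frame 3-bp deletion at a codon boundary: one residue gone, no shift
  out3 <- apply_deletion(orf, 31, 33)
  expect_false(out3$frameshift)
  expect_false(out3$premature_stop)
  expect_equal(out3$product_length_aa, nchar(orf$protein) - 1L)
  expect_equal(classify_edit(out3), "in_frame_indel")
  # deleting then re-inserting restores the wild type
  deleted <- substr(orf$cds, 31, 33)
  restored <- apply_insertion(orf_record(orf$id, out3$edited_cds), 30, deleted)
  expect_identical(restored$edited_cds, orf$cds)
  expect_identical(restored$product, orf$protein)
})

test_that("a 1-bp deletion in a toy ORF matches a hand-translated product", {
  #      M  K  W  D  P  A  C  D  E  *
  cds <- "ATGAAATGGGATCCGGCCTGCGACGAGTAA"
  orf <- orf_record("toy30", cds)
  out <- apply_deletion(orf, 10, 10)  # drop the G of codon 4 (GAT)
  # edited: ATG AAA TGG ATC CGG CCT GCG ACG AGT AA -> M K W I R P A T S
  expect_true(out$frameshift)
  expect_equal(out$product, "MKWIRPATS")
  expect_false(out$premature_stop)   # frameshift runs past the old stop
  expect_equal(out$novel_residues, "IRPATS")
  expect_equal(classify_edit(out), "in_frame_indel")
})

test_that("insertions shift frame iff length is not a multiple of three", {
  sim <- simulate_orf(orf_spec(length = 60, protospacers = list(
    list(seq = "AACTGGCTTTCAGCAAGCGC", boundary = 10, strand = "+")),
    seed = 12))
  orf <- sim$orf
  cut <- sim$truth$protospacers$cut_after
  ins1 <- apply_insertion(orf, cut, "T")
  expect_true(ins1$frameshift)
  # in-frame TAA at a codon boundary stops translation right there
  ins_stop <- apply_insertion(orf, 30, "TAA")
  expect_false(ins_stop$frameshift)
  expect_true(ins_stop$premature_stop)
  expect_equal(ins_stop$stop_codon_position, 11L)
  expect_equal(ins_stop$product_length_aa, 10L)
  expect_equal(classify_edit(ins_stop), "nonsense_in_frame")
  # 3 random non-stop bases at a codon boundary: +1 aa, no shift
  set.seed(8)
  for (rep in 1:10) {
    codon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) next
    ins3 <- apply_insertion(orf, 33, codon)
    expect_false(ins3$frameshift)
    expect_equal(ins3$product_length_aa, nchar(orf$protein) + 1L)
  }
  expect_error(apply_insertion(orf, -1, "A"), "out of range")
  expect_error(apply_insertion(orf, 3, ""), "non-empty")
})

test_that("an insertion 3' of the stop codon is silent", {
  orf <- toy_orf(paste0("M", random_protein(20)), seed = 6)
  out <- apply_insertion(orf, nchar(orf$cds), "GGG")
  expect_identical(out$product, orf$protein)
  expect_equal(classify_edit(out), "silent")
})

test_that("knockout classification agrees with a brute-force translate oracle", {
  set.seed(99)
  for (rep in 1:40) {
    orf <- toy_orf(paste0("M", random_protein(sample(40:90, 1))), seed = rep)
    L <- nchar(orf$cds)
    if (runif(1) < 0.5) {
      len <- sample(1:6, 1)
      start <- sample(4:(L - len), 1)
      out <- apply_deletion(orf, start, start + len - 1L)
      lesion_len <- len
    } else {
      bases <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                            replace = TRUE), collapse = "")
      out <- apply_insertion(orf, sample(3:L, 1), bases)
      lesion_len <- nchar(bases)
    }
    ref <- translate_oracle(out$edited_cds)
    expect_identical(out$product, ref$protein)
    expect_equal(out$frameshift, lesion_len %% 3L != 0L)
    # premature = stop before the final complete codon; an indel 3' of the
    # stop codon leaves the product intact and is silent, never a knockout
    brute_knockout <- (lesion_len %% 3L != 0L) && ref$stop_reached &&
      ref$stop_codon < nchar(out$edited_cds) %/% 3L &&
      !identical(ref$protein, out$wt_protein)
    expect_equal(classify_edit(out) == "knockout", brute_knockout)
    expect_equal(nchar(out$edited_cds),
                 L + if (out$lesion$type == "deletion") -lesion_len else lesion_len)
  }
})
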