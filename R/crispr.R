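# SpCas9 protospacer location, NHEJ indel application and coding-consequence
# classification.

#' Construct a guide RNA (crRNA spacer)
#'
#' @param protospacer 20-nt DNA string matching the genomic protospacer; no
#'   ambiguity characters.
#' @param pam_pattern PAM requirement; only `"NGG"` (SpCas9) is supported.
#' @return An object of class `guide_rna`.
#' @examples
#' guide_rna("AACTGGCTTTCAGCAAGCGC")
#' @export
guide_rna <- function(protospacer, pam_pattern = "NGG") {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L) {
    stop("protospacer must be exactly 20 nt, got ", nchar(protospacer))
  }
  if (grepl("[^ACGT]", protospacer)) {
    stop("protospacer may not contain ambiguity characters")
  }
  if (!identical(pam_pattern, "NGG")) stop("only the SpCas9 NGG PAM is supported")
  structure(list(protospacer = protospacer, pam_pattern = pam_pattern),
            class = "guide_rna")
}

#' Locate protospacer target sites in a CDS
#'
#' Finds all exact protospacer matches on both strands with a valid `NGG`
#' PAM immediately 3' of the protospacer on the target strand. The predicted
#' SpCas9 blunt cut falls 3 nt 5' of the PAM, i.e. between protospacer
#' positions 17 and 18; `cut_after = n` means the cut lies between
#' plus-strand positions `n` and `n + 1`.
#'
#' All coordinates are 1-based plus-strand ORF positions; for minus-strand
#' sites, `protospacer_start` is the plus-strand start of the 20-nt match
#' and the PAM lies immediately 5' of it on the plus strand (as `CCN`).
#'
#' @param cds DNA string (plus strand of the ORF).
#' @param guide A [guide_rna()].
#' @return A `data.frame` with columns `strand`, `protospacer_start`,
#'   `pam_start`, `cut_after`, sorted by coordinate; zero rows when the
#'   guide has no target.
#' @export
locate_protospacer <- function(cds, guide) {
  stopifnot(inherits(guide, "guide_rna"))
  cds <- toupper(cds)
  subject <- Biostrings::DNAString(cds)
  L <- nchar(cds)
  p <- guide$protospacer

  plus <- Biostrings::start(Biostrings::matchPattern(p, subject))
  plus <- plus[plus + 22L <= L]
  if (length(plus) > 0L) {
    plus <- plus[substring(cds, plus + 21L, plus + 22L) == "GG"]
  }
  minus_pat <- revcomp(p)
  minus <- Biostrings::start(Biostrings::matchPattern(minus_pat, subject))
  minus <- minus[minus - 3L >= 1L]
  if (length(minus) > 0L) {
    minus <- minus[substring(cds, minus - 3L, minus - 2L) == "CC"]
  }

  out <- rbind(
    if (length(plus) > 0L)
      data.frame(strand = "+", protospacer_start = plus,
                 pam_start = plus + 20L, cut_after = plus + 16L,
                 stringsAsFactors = FALSE),
    if (length(minus) > 0L)
      data.frame(strand = "-", protospacer_start = minus,
                 pam_start = minus - 3L, cut_after = minus + 2L,
                 stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(strand = character(0), protospacer_start = integer(0),
                      pam_start = integer(0), cut_after = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$protospacer_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build the edit outcome shared by deletions and insertions.
.edit_outcome <- function(orf, edited_cds, lesion) {
  suppressWarnings(tr <- translate_cds(edited_cds))
  product <- tr$protein
  wt <- orf$protein
  n_codons <- nchar(edited_cds) %/% 3L
  premature <- tr$stop_reached && tr$stop_codon < n_codons
  # longest common prefix with the wild-type product
  pmin_len <- min(nchar(product), nchar(wt))
  lcp <- 0L
  if (pmin_len > 0L) {
    pa <- split_chars(substr(product, 1L, pmin_len))
    pb <- split_chars(substr(wt, 1L, pmin_len))
    diff <- which(pa != pb)
    lcp <- if (length(diff) == 0L) pmin_len else diff[1L] - 1L
  }
  novel <- if (lcp < nchar(product)) substr(product, lcp + 1L, nchar(product)) else ""
  len_change <- if (lesion$type == "deletion") -lesion$length else lesion$length
  frameshift <- abs(len_change) %% 3L != 0L
  structure(list(
    edited_cds = edited_cds,
    product = product,
    product_length_aa = nchar(product),
    frameshift = frameshift,
    premature_stop = premature,
    stop_codon_position = tr$stop_codon,
    stop_reached = tr$stop_reached,
    novel_residues = novel,
    lesion = lesion,
    wt_protein = wt
  ), class = "edit_outcome")
}

#' Apply an NHEJ deletion to an ORF and annotate its consequence
#'
#' Removes bases `start..end` (1-based, inclusive, plus strand) and
#' translates the result from the ATG to the first stop codon. The outcome
#' records whether the lesion shifts the reading frame (length not divisible
#' by 3), whether a premature stop appears (the first stop precedes the
#' final complete codon of the edited CDS), the truncated product and the
#' novel residues introduced after the last position still identical to the
#' wild type.
#'
#' @param orf An [orf_record()].
#' @param start,end Deletion bounds; the ATG (positions 1-3) may not be
#'   touched.
#' @return An object of class `edit_outcome`.
#' @export
apply_deletion <- function(orf, start, end) {
  stopifnot(inherits(orf, "orf_record"))
  L <- nchar(orf$cds)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > L || start > end) {
    stop(sprintf("deletion %d-%d out of range 1-%d", start, end, L))
  }
  if (start <= 3L) stop("deletion may not span the ATG (positions 1-3)")
  edited <- paste0(substr(orf$cds, 1L, start - 1L), substr(orf$cds, end + 1L, L))
  .edit_outcome(orf, edited,
                list(type = "deletion", start = start, length = end - start + 1L))
}

#' Apply an NHEJ insertion to an ORF and annotate its consequence
#'
#' Inserts `bases` immediately after plus-strand position `after`
#' (`after = 0` inserts before the first base). Consequence annotation is
#' symmetric to [apply_deletion()]: the frame shifts iff the insertion
#' length is not divisible by 3.
#'
#' @param orf An [orf_record()].
#' @param after 0-based insertion point (bases go between `after` and
#'   `after + 1`).
#' @param bases Non-empty DNA string to insert.
#' @return An object of class `edit_outcome`.
#' @export
apply_insertion <- function(orf, after, bases) {
  stopifnot(inherits(orf, "orf_record"))
  bases <- toupper(bases)
  L <- nchar(orf$cds)
  after <- as.integer(after)
  if (after < 0L || after > L) stop(sprintf("insertion point %d out of range 0-%d", after, L))
  if (nchar(bases) == 0L || grepl("[^ACGTN]", bases)) {
    stop("insertion must be a non-empty DNA string")
  }
  edited <- paste0(substr(orf$cds, 1L, after), bases,
                   substr(orf$cds, after + 1L, L))
  .edit_outcome(orf, edited,
                list(type = "insertion", start = after + 1L,
                     length = nchar(bases), bases = bases))
}

#' Classify the coding consequence of an indel
#'
#' Deterministic labels: `"silent"` when the edited product equals the
#' wild-type protein; `"knockout"` when the lesion shifts the frame AND a
#' premature stop appears (the pseudogenizing outcome sought in NHEJ
#' knockouts); `"nonsense_in_frame"` for an in-frame lesion that still
#' creates a premature stop; `"in_frame_indel"` otherwise. A frameshift that
#' runs to the end of the CDS without meeting a stop (possible only in short
#' toy sequences) falls through to `"in_frame_indel"`.
#'
#' @param outcome An `edit_outcome` from [apply_deletion()] or
#'   [apply_insertion()].
#' @return One of `"knockout"`, `"in_frame_indel"`, `"silent"`,
#'   `"nonsense_in_frame"`.
#' @export
classify_edit <- function(outcome) {
  stopifnot(inherits(outcome, "edit_outcome"))
  if (identical(outcome$product, outcome$wt_protein)) return("silent")
  if (outcome$frameshift && outcome$premature_stop) return("knockout")
  if (!outcome$frameshift && outcome$premature_stop) return("nonsense_in_frame")
  "in_frame_indel"
}

#' @export
print.edit_outcome <- function(x, ...) {
  cat(sprintf("%s of %d nt at %d: %s%s, product %d aa\n",
              x$lesion$type, x$lesion$length, x$lesion$start,
              if (x$frameshift) "frameshift" else "in frame",
              if (x$premature_stop) sprintf(", premature stop at codon %d",
                                            x$stop_codon_position) else "",
              x$product_length_aa))
  invisible(x)
}
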