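# WDP triad location, synonymous BamHI engineering, domain splitting and
# in-frame chimeric ORF assembly.
#
# The conserved W-D-P triad at the Nt/Ct boundary of P74 is encoded
# TGG GAT CCN, so the last two bases of the W codon through the first two of
# the P codon spell GGATCC (BamHI) whenever the aspartate codon is GAT; when
# it is GAC, a single synonymous third-position edit (C->T) creates the site
# without touching the protein.

RESTRICTION_ENZYMES <- c(BamHI = "GGATCC", BglII = "AGATCT",
                         HindIII = "AAGCTT", EcoRI = "GAATTC")

#' Locate WDP triads and their BamHI split points in an ORF
#'
#' Scans the ORF's translation for `WDP` occurrences. For each one, the
#' aspartate codon decides whether `GGATCC` is already present across the
#' triad (`GAT`) or a single synonymous edit at the codon's third base
#' (`GAC -> GAT`, i.e. C->T at ORF nucleotide `3 * d_codon`) is required.
#' The proline codon may be any `CCN`; it never needs editing. The domain
#' split falls immediately after the D codon: the Nt fragment ends `...WD`
#' and the Ct fragment begins `P...`.
#'
#' @param orf An [orf_record()].
#' @return A list of `split_point` objects (possibly empty), each with
#'   fields `w_codon`, `d_codon`, `p_codon` (1-based codon indices),
#'   `bamhi_present`, `required_edits` (data.frame `position`, `from`, `to`;
#'   ORF nucleotide coordinates, A of ATG = 1) and `split_after_codon`.
#' @export
find_wdp_splits <- function(orf) {
  stopifnot(inherits(orf, "orf_record"))
  hits <- gregexpr("WDP", orf$protein, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(list())
  lapply(as.integer(hits), function(w) {
    d <- w + 1L
    d_codon_seq <- substr(orf$cds, 3L * d - 2L, 3L * d)
    stopifnot(d_codon_seq %in% c("GAT", "GAC"))
    bamhi <- d_codon_seq == "GAT"
    edits <- if (bamhi) {
      data.frame(position = integer(0), from = character(0), to = character(0),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(position = 3L * d, from = "C", to = "T",
                 stringsAsFactors = FALSE)
    }
    structure(list(w_codon = w, d_codon = d, p_codon = w + 2L,
                   bamhi_present = bamhi, required_edits = edits,
                   split_after_codon = d),
              class = "split_point")
  })
}

#' @export
print.split_point <- function(x, ...) {
  cat(sprintf("WDP split: codons %d-%d, split after codon %d, BamHI %s\n",
              x$w_codon, x$p_codon, x$split_after_codon,
              if (x$bamhi_present) "present" else
                sprintf("requires %d synonymous edit(s)", nrow(x$required_edits))))
  invisible(x)
}

#' Apply the synonymous edits of a split point
#'
#' Introduces the edits recorded in a split point (in silico equivalent of
#' the same-sense mutation introduced by overlap-extension PCR) and asserts
#' that the translation is unchanged and that `GGATCC` now spans the triad.
#' A split point with `bamhi_present` returns the ORF unchanged.
#'
#' @param orf An [orf_record()].
#' @param split A `split_point` from [find_wdp_splits()] on the same ORF.
#' @return An [orf_record()] whose `edits` attribute records the applied
#'   edits.
#' @export
apply_synonymous_edits <- function(orf, split) {
  stopifnot(inherits(orf, "orf_record"), inherits(split, "split_point"))
  .check_split(orf, split)
  cds <- orf$cds
  ed <- split$required_edits
  for (i in seq_len(nrow(ed))) {
    if (substr(cds, ed$position[i], ed$position[i]) != ed$from[i]) {
      stop(sprintf("edit %d: expected '%s' at nt %d", i, ed$from[i], ed$position[i]))
    }
    substr(cds, ed$position[i], ed$position[i]) <- ed$to[i]
  }
  out <- orf_record(orf$id, cds)
  # internal consistency: synonymous by construction
  stopifnot(identical(out$protein, orf$protein))
  triad <- substr(cds, 3L * split$w_codon - 2L, 3L * split$p_codon)
  stopifnot(grepl("GGATCC", triad, fixed = TRUE))
  attr(out, "edits") <- ed
  out
}

.check_split <- function(orf, split) {
  if (split$p_codon > nchar(orf$protein) ||
      substr(orf$protein, split$w_codon, split$p_codon) != "WDP") {
    stop("split point does not belong to ORF '", orf$id, "'")
  }
  invisible(TRUE)
}

#' Split an ORF into Nt and Ct domain fragments at a WDP triad
#'
#' The Nt fragment spans codons 1..`split_after_codon` (protein ends
#' `...WD`); the Ct fragment spans the remaining codons including the stop
#' (protein begins `P...`). Concatenating the two fragment CDSs reproduces
#' the input CDS exactly.
#'
#' @inheritParams apply_synonymous_edits
#' @return A list with `nt` and `ct`, each a list of `id`, `cds`, `protein`.
#' @export
split_orf <- function(orf, split) {
  stopifnot(inherits(orf, "orf_record"), inherits(split, "split_point"))
  .check_split(orf, split)
  cut_nt <- 3L * split$split_after_codon
  nt_cds <- substr(orf$cds, 1L, cut_nt)
  ct_cds <- substr(orf$cds, cut_nt + 1L, nchar(orf$cds))
  list(
    nt = list(id = paste0(orf$id, "_Nt"), cds = nt_cds,
              protein = substr(orf$protein, 1L, split$split_after_codon)),
    ct = list(id = paste0(orf$id, "_Ct"), cds = ct_cds,
              protein = substr(orf$protein, split$split_after_codon + 1L,
                               nchar(orf$protein)))
  )
}

#' Assemble an in-frame chimeric ORF from two donors split at WDP
#'
#' Joins the Nt fragment of one donor to the Ct fragment of another at their
#' WDP/BamHI junction, optionally preceded by a tag coding sequence
#' (prepended verbatim; supply the exact tag CDS including its own ATG). Any
#' synonymous edits required by the splits are applied first, so the
#' junction always carries a BamHI site. With no Ct donor (an Nt-only
#' construct), a `TAA` stop codon is appended after the Nt fragment.
#'
#' @param nt_donor,ct_donor [orf_record()] donors; `ct_donor` may be `NULL`.
#' @param nt_split,ct_split Matching `split_point`s from [find_wdp_splits()].
#' @param tag_cds Optional tag coding sequence (length divisible by 3,
#'   starting ATG, stop-free).
#' @param id Identifier for the chimera (default derived from donor ids).
#' @return An object of class `chimera_result`: fields `id`, `cds`,
#'   `protein`, `nt_donor`, `ct_donor` (each id + codon range), `tag`,
#'   `junction_codon` (codon index of the junction D in the chimera, `NA`
#'   for Nt-only constructs).
#' @export
assemble_chimera <- function(nt_donor, nt_split, ct_donor = NULL,
                             ct_split = NULL, tag_cds = NULL, id = NULL) {
  stopifnot(inherits(nt_donor, "orf_record"))
  if (!is.null(tag_cds)) {
    tag_cds <- toupper(tag_cds)
    if (nchar(tag_cds) %% 3L != 0L) stop("tag CDS length must be divisible by 3")
    if (substr(tag_cds, 1L, 3L) != "ATG") stop("tag CDS must begin with ATG")
    if (any(codons_of(tag_cds) %in% STOP_CODONS)) stop("tag CDS contains a stop codon")
  }
  nt_donor <- apply_synonymous_edits(nt_donor, nt_split)
  nt_frag <- split_orf(nt_donor, nt_split)$nt
  tag_aa <- if (is.null(tag_cds)) 0L else nchar(tag_cds) %/% 3L
  if (is.null(ct_donor)) {
    cds <- paste0(if (is.null(tag_cds)) "" else tag_cds, nt_frag$cds, "TAA")
    ct_info <- NULL
    junction <- NA_integer_
  } else {
    stopifnot(inherits(ct_donor, "orf_record"))
    ct_donor <- apply_synonymous_edits(ct_donor, ct_split)
    ct_frag <- split_orf(ct_donor, ct_split)$ct
    cds <- paste0(if (is.null(tag_cds)) "" else tag_cds, nt_frag$cds, ct_frag$cds)
    ct_info <- list(id = ct_donor$id,
                    codons = c(ct_split$split_after_codon + 1L,
                               nchar(ct_donor$protein)))
    junction <- tag_aa + nt_split$split_after_codon
  }
  out <- orf_record(if (is.null(id)) paste0(nt_donor$id, "__", if (is.null(ct_donor)) "NtOnly" else ct_donor$id) else id,
                    cds)
  # junction must read ...W D | P... and fragment proteins must be preserved
  if (!is.null(ct_donor)) {
    if (substr(out$protein, junction - 1L, junction + 1L) != "WDP") {
      stop("chimera junction does not read WDP")
    }
    stopifnot(identical(substr(out$protein, tag_aa + 1L, junction), nt_frag$protein),
              identical(substr(out$protein, junction + 1L, nchar(out$protein)),
                        ct_frag$protein))
  } else {
    stopifnot(identical(substr(out$protein, tag_aa + 1L, nchar(out$protein)),
                        nt_frag$protein))
  }
  structure(list(id = out$id, cds = out$cds, protein = out$protein,
                 nt_donor = list(id = nt_donor$id,
                                 codons = c(1L, nt_split$split_after_codon)),
                 ct_donor = ct_info,
                 tag = tag_cds, junction_codon = junction),
            class = "chimera_result")
}

#' @export
print.chimera_result <- function(x, ...) {
  cat(sprintf("Chimera '%s': %d nt, %d aa (Nt from %s%s)\n", x$id,
              nchar(x$cds), nchar(x$protein), x$nt_donor$id,
              if (is.null(x$ct_donor)) ", Nt-only"
              else paste0(", Ct from ", x$ct_donor$id)))
  invisible(x)
}

#' Scan a DNA sequence for restriction sites
#'
#' Exact plus-strand motif occurrences, 1-based, overlaps allowed. The
#' built-in enzymes (BamHI GGATCC, BglII AGATCT, HindIII AAGCTT, EcoRI
#' GAATTC) all have palindromic sites, so plus-strand scanning finds every
#' cut site.
#'
#' @param dna DNA string.
#' @param enzymes Enzyme names among `names(RESTRICTION_ENZYMES)`.
#' @return A `data.frame` with columns `enzyme`, `motif`, `position`,
#'   `strand`, sorted by position.
#' @export
restriction_scan <- function(dna, enzymes = c("BamHI", "BglII", "HindIII")) {
  dna <- toupper(dna)
  if (nchar(dna) == 0L) stop("empty sequence")
  unknown <- setdiff(enzymes, names(RESTRICTION_ENZYMES))
  if (length(unknown) > 0L) {
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  }
  subject <- Biostrings::DNAString(dna)
  hits <- lapply(enzymes, function(e) {
    m <- Biostrings::matchPattern(RESTRICTION_ENZYMES[[e]], subject)
    if (length(m) == 0L) return(NULL)
    data.frame(enzyme = e, motif = RESTRICTION_ENZYMES[[e]],
               position = Biostrings::start(m), strand = "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(enzyme = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$position, out$enzyme), , drop = FALSE]
}
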