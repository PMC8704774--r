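# Coding-sequence records and codon-by-codon translation.

#' Translate a coding sequence (standard genetic code)
#'
#' Codon-by-codon translation that stops at (and excludes) the first stop
#' codon. Codons containing non-ACGT characters (e.g. `N`) translate to `X`
#' rather than erroring. A trailing 1-2 nt remainder is ignored with a
#' warning.
#'
#' @param cds DNA string.
#' @return A list with `protein` (string), `stop_reached` (logical) and
#'   `stop_codon` (1-based codon index of the first stop, or `NA`).
#' @examples
#' translate_cds("ATGTGGGATCCGTAA")  # MWDP, stop at codon 5
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon")
  if (nchar(cds) %% 3L != 0L) {
    warning(sprintf("length %d not divisible by 3; trailing %d nt ignored",
                    nchar(cds), nchar(cds) %% 3L), call. = FALSE)
  }
  codons <- codons_of(cds)
  gc <- genetic_code()
  aa <- character(length(codons))
  stop_at <- NA_integer_
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (grepl("[^ACGT]", cod)) {
      aa[i] <- "X"
      next
    }
    r <- gc[[cod]]
    if (r == "*") {
      stop_at <- i
      break
    }
    aa[i] <- r
  }
  protein <- if (is.na(stop_at)) paste(aa, collapse = "")
             else paste(aa[seq_len(stop_at - 1L)], collapse = "")
  list(protein = protein, stop_reached = !is.na(stop_at), stop_codon = stop_at)
}

#' Construct a validated ORF record
#'
#' Enforces the invariants of a well-formed coding sequence: length divisible
#' by 3, starts with `ATG`, ends with a stop codon (TAA/TAG/TGA) and carries
#' no internal stop codon. The translation (stop excluded) is stored in the
#' record.
#'
#' @param id Record identifier.
#' @param cds DNA string.
#' @return An object of class `orf_record` with fields `id`, `cds`,
#'   `protein`.
#' @export
orf_record <- function(id, cds) {
  cds <- toupper(gsub("\\s", "", cds))
  .validate_residues(id, cds, "dna")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop(sprintf("ORF '%s': length %d not divisible by 3", id, n))
  if (substr(cds, 1L, 3L) != "ATG") stop(sprintf("ORF '%s' does not begin with ATG", id))
  last <- substr(cds, n - 2L, n)
  if (!last %in% STOP_CODONS) {
    stop(sprintf("ORF '%s' does not end with a stop codon (found %s)", id, last))
  }
  tr <- translate_cds(cds)
  if (!tr$stop_reached || tr$stop_codon != n %/% 3L) {
    stop(sprintf("ORF '%s' contains an internal stop at codon %d", id, tr$stop_codon))
  }
  structure(list(id = id, cds = cds, protein = tr$protein),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("ORF '%s': %d nt, %d aa\n", x$id, nchar(x$cds), nchar(x$protein)))
  invisible(x)
}

#' Read ORF records from a nucleotide FASTA file
#'
#' @param path FASTA path.
#' @return List of [orf_record()] objects.
#' @export
read_orfs <- function(path) {
  rec <- read_fasta(path, "dna")
  lapply(seq_len(nrow(rec)), function(i) orf_record(rec$id[i], rec$residues[i]))
}
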