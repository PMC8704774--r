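# Residue alphabets, ClustalW/X conservation groups, hydropathy scales and
# genetic-code helpers shared across the package.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA_STANDARD <- c("A", "C", "G", "T")

# ClustalW/X default conservation groups. A column whose residues all fall in
# one strong group prints ":", one weak group prints ".".
CLUSTAL_STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                           "MILV", "MILF", "HY", "FYW")
CLUSTAL_WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
                         "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")

.group_list <- function(groups) strsplit(groups, "", fixed = TRUE)

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values of Kyte & Doolittle (1982), the de facto
#' standard scale for sliding-window hydropathy plots. Positive values are
#' hydrophobic; transmembrane helices typically show windowed means above
#' ~1.6 at window 19-21.
#'
#' @format Named numeric vector of length 20 (one value per standard residue).
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Residues sharing at least one strong (or weak) group with `res`, excluding
# `res` itself. Used by the consensus scorer's group logic and by the family
# simulator so both sides agree on what a "conservative" substitution is.
group_partners <- function(res, groups) {
  members <- .group_list(groups)
  hits <- vapply(members, function(g) res %in% g, logical(1))
  setdiff(unique(unlist(members[hits])), res)
}

share_strong_group <- function(a, b) {
  any(vapply(.group_list(CLUSTAL_STRONG_GROUPS),
             function(g) all(c(a, b) %in% g), logical(1)))
}

# --- genetic code -----------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function() Biostrings::GENETIC_CODE

# codons encoding each amino acid (stops excluded), computed once
synonymous_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      gc <- chartr("U", "T", gc)
      names(gc) <- chartr("U", "T", names(gc))
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

codons_of <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
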