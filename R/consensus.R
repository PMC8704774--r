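# Clustal-style consensus line, windowed similarity profile, perfectly
# conserved residue detection and position-frequency matrices.

#' Derive a Clustal-style consensus line from a protein alignment
#'
#' Per column: `*` if all sequences share one residue (no gaps), `:` if all
#' residues fall within a single ClustalW/X strong conservation group, `.`
#' if within a single weak group, space otherwise. Any gap in a column forces
#' a space, and the ambiguity residue `X` never matches anything (including
#' another `X`).
#'
#' If the alignment already carries a consensus line (e.g. attached from a
#' Clustal file by [read_alignment()]), that line is returned verbatim unless
#' `recompute = TRUE`.
#'
#' @param aln An [aa_alignment()].
#' @param recompute Ignore an attached consensus line and recompute.
#' @return A single string over `* : .` and space, one symbol per column.
#' @examples
#' aln <- aa_alignment(c(a = "MCV", b = "MCI", c = "MCL"))
#' consensus_line(aln)  # "*:" for M and C...; V/I/L share strong group MILV
#' @export
consensus_line <- function(aln, recompute = FALSE) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!is.null(aln$consensus) && !recompute) return(aln$consensus)
  mat <- alignment_matrix(aln)
  strong <- .group_list(CLUSTAL_STRONG_GROUPS)
  weak <- .group_list(CLUSTAL_WEAK_GROUPS)
  symbols <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(col == "-") || any(col == "X")) return(" ")
    res <- unique(col)
    if (length(res) == 1L) return("*")
    if (any(vapply(strong, function(g) all(res %in% g), logical(1)))) return(":")
    if (any(vapply(weak, function(g) all(res %in% g), logical(1)))) return(".")
    " "
  }, character(1))
  paste(symbols, collapse = "")
}

#' Scoring scheme for consensus-symbol similarity profiles
#'
#' @param identity,strong,weak,other Scores assigned to `*`, `:`, `.` and
#'   space consensus symbols. Defaults +1, +0.5, +0.25 and -0.2.
#' @param window Odd window length in residues (default 35).
#' @return A named list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(identity = 1, strong = 0.5, weak = 0.25,
                           other = -0.2, window = 35L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer, got ", window)
  }
  if (!(identity >= strong && strong >= weak && weak > other)) {
    stop("scores must satisfy identity >= strong >= weak > other")
  }
  structure(list(identity = identity, strong = strong, weak = weak,
                 other = other, window = window),
            class = "scoring_scheme")
}

#' Windowed similarity profile from a consensus line
#'
#' Each consensus symbol receives a score (+1 for `*`, +0.5 for `:`, +0.25
#' for `.`, -0.2 for space, by default); a full sliding window of odd length
#' is summed, normalised by the window length and assigned to the window's
#' central column. Only full windows are evaluated, so the profile spans
#' columns `ceiling(w/2) .. L - floor(w/2)`.
#'
#' @param consensus A consensus string (see [consensus_line()]) or an
#'   [aa_alignment()] (its consensus is derived first).
#' @param scheme A [scoring_scheme()].
#' @return A `data.frame` with columns `column` (1-based window centre),
#'   `symbol` (the centre's consensus symbol) and `value`.
#' @export
similarity_profile <- function(consensus, scheme = scoring_scheme()) {
  if (inherits(consensus, "aa_alignment")) consensus <- consensus_line(consensus)
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (grepl("[^*:. ]", consensus)) {
    stop("consensus line may contain only '*', ':', '.', ' '")
  }
  L <- nchar(consensus)
  w <- scheme$window
  if (L < w) stop(sprintf("consensus (%d) shorter than window (%d)", L, w))
  chars <- split_chars(consensus)
  score_map <- c("*" = scheme$identity, ":" = scheme$strong,
                 "." = scheme$weak, " " = scheme$other)
  scores <- unname(score_map[chars])
  half <- (w - 1L) %/% 2L
  centres <- (half + 1L):(L - half)
  values <- vapply(centres, function(c) sum(scores[(c - half):(c + half)]) / w,
                   numeric(1))
  data.frame(column = centres, symbol = chars[centres], value = values,
             stringsAsFactors = FALSE)
}

#' Columns where one residue is perfectly conserved
#'
#' Returns the 1-based alignment columns at which every sequence carries
#' exactly the given residue (no gaps, no substitutions). Used, e.g., to
#' locate the six cysteines perfectly conserved across all P74 proteins.
#'
#' @param aln An [aa_alignment()].
#' @param residue A single standard amino-acid letter.
#' @return Integer vector of columns (possibly empty).
#' @export
conserved_residue_columns <- function(aln, residue) {
  stopifnot(inherits(aln, "aa_alignment"))
  residue <- toupper(residue)
  if (!residue %in% AA_STANDARD) stop("not a standard amino acid: ", residue)
  mat <- alignment_matrix(aln)
  which(colSums(mat == residue) == nrow(mat))
}

#' Position-frequency matrix with per-column information content
#'
#' Counts residues (including gaps) per alignment column; information content
#' is reported as `log2(20)` minus the Shannon entropy of the gap-excluded
#' residue frequencies, the quantity underlying sequence-logo letter heights.
#'
#' @param aln An [aa_alignment()].
#' @param columns 1-based columns to tabulate (default: all).
#' @return A list of class `freq_matrix` with `counts` (residues x columns
#'   matrix, gap row `-` included), `information` (bits, `NA` for all-gap
#'   columns), `columns` and `n_sequences`.
#' @export
frequency_matrix <- function(aln, columns = NULL) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (is.null(columns)) columns <- seq_len(aln$width)
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("empty column range")
  if (any(columns < 1L | columns > aln$width)) {
    stop("columns out of range 1..", aln$width)
  }
  mat <- alignment_matrix(aln)[, columns, drop = FALSE]
  levels <- c(AA_STANDARD, "X", "-")
  counts <- vapply(seq_len(ncol(mat)),
                   function(j) table(factor(mat[, j], levels = levels)),
                   integer(length(levels)))
  rownames(counts) <- levels
  colnames(counts) <- columns
  info <- vapply(seq_len(ncol(counts)), function(j) {
    cnt <- counts[setdiff(levels, "-"), j]
    n <- sum(cnt)
    if (n == 0L) return(NA_real_)
    p <- cnt[cnt > 0L] / n
    log2(20) - (-sum(p * log2(p)))
  }, numeric(1))
  structure(list(counts = counts, information = info,
                 columns = columns, n_sequences = aln$n),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("Position-frequency matrix: %d columns, %d sequences\n",
              length(x$columns), x$n_sequences))
  invisible(x)
}
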