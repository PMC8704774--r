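# Global pairwise alignment and percent identity/similarity for complete
# proteins and their WDP-split Nt/Ct domains.

.submatrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under a substitution matrix and affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`).
#' Defaults mirror the EMBOSS-needle convention: BLOSUM62, 10/0.5.
#'
#' @param a,b Protein sequences (strings, standard residues).
#' @param matrix Substitution matrix name available in Biostrings (e.g.
#'   `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a matrix.
#' @param gap_open,gap_extend Affine gap penalties (non-negative;
#'   `gap_open >= gap_extend`).
#' @return An object of class `pairwise_alignment`: gapped strings `a` and
#'   `b`, `score`, and the parameters used.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  if (!(gap_open >= gap_extend && gap_extend >= 0)) {
    stop("need gap_open >= gap_extend >= 0")
  }
  mat <- .submatrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    matrix = if (is.matrix(matrix)) "custom" else matrix,
    gap_open = gap_open, gap_extend = gap_extend
  ), class = "pairwise_alignment")
}

#' Percent identity and similarity of an aligned pair
#'
#' `identity_pct` is 100 times the number of identical aligned residue pairs
#' divided by the full alignment length (gapped columns included in the
#' denominator). `similarity_pct` additionally counts conservative pairs:
#' by default pairs with a positive substitution-matrix score
#' (`similarity = "positive"`); `similarity = "group"` instead counts pairs
#' sharing a ClustalW/X strong conservation group. Values are kept at full
#' precision; round only at report time.
#'
#' @param aln A `pairwise_alignment` from [global_align()], or a list/pair
#'   of equal-length gapped strings.
#' @param matrix Substitution matrix (name or matrix) used for the
#'   positive-score similarity definition.
#' @param similarity `"positive"` or `"group"`.
#' @return An object of class `pairwise_result`: `identity_pct`,
#'   `similarity_pct`, `alignment_length`, `aligned_pairs`.
#' @export
identity_similarity <- function(aln, matrix = "BLOSUM62",
                                similarity = c("positive", "group")) {
  similarity <- match.arg(similarity)
  if (inherits(aln, "pairwise_alignment")) {
    ga <- aln$a; gb <- aln$b
  } else {
    ga <- aln[[1L]]; gb <- aln[[2L]]
  }
  if (nchar(ga) != nchar(gb)) stop("aligned sequences differ in length")
  ca <- split_chars(ga); cb <- split_chars(gb)
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb & ca != "X"
  if (similarity == "positive") {
    mat <- .submatrix(matrix)
    pos <- both & !ident
    pos[pos] <- mat[cbind(ca[pos], cb[pos])] > 0
    sim <- ident | pos
  } else {
    pos <- both & !ident
    pos[pos] <- mapply(share_strong_group, ca[pos], cb[pos])
    sim <- ident | pos
  }
  structure(list(
    identity_pct = 100 * sum(ident) / len,
    similarity_pct = 100 * sum(sim) / len,
    alignment_length = len,
    aligned_pairs = sum(both)
  ), class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("identity %.1f%%, similarity %.1f%% over %d columns (%d aligned pairs)\n",
              x$identity_pct, x$similarity_pct, x$alignment_length,
              x$aligned_pairs))
  invisible(x)
}

#' Identity/similarity matrices for complete proteins and WDP domains
#'
#' For each ORF, the unique WDP triad defines its own Nt/Ct split (an ORF
#' with no triad, or more than one, is reported and excluded). All pairs of
#' the remaining sequences are globally aligned three times - complete
#' protein, Nt domain, Ct domain - and percent identity/similarity computed
#' with [identity_similarity()]. Diagonals are 100 by definition.
#'
#' @param orfs List of [orf_record()]s.
#' @inheritParams global_align
#' @param similarity Similarity definition, see [identity_similarity()].
#' @return A list of class `domain_matrices` with elements `complete`, `nt`,
#'   `ct` (each a list of `identity` and `similarity` matrices) and
#'   `excluded` (named character of skipped ids and reasons).
#' @export
domain_matrix <- function(orfs, matrix = "BLOSUM62", gap_open = 10,
                          gap_extend = 0.5, similarity = "positive") {
  stopifnot(length(orfs) >= 2L, all(vapply(orfs, inherits, logical(1), "orf_record")))
  excluded <- character(0)
  seqs <- list()
  for (orf in orfs) {
    sp <- find_wdp_splits(orf)
    if (length(sp) == 0L) {
      excluded[orf$id] <- "no WDP triad"
      next
    }
    if (length(sp) > 1L) {
      excluded[orf$id] <- sprintf("%d WDP triads", length(sp))
      next
    }
    frag <- split_orf(orf, sp[[1L]])
    seqs[[orf$id]] <- list(complete = orf$protein,
                           nt = frag$nt$protein, ct = frag$ct$protein)
  }
  if (length(seqs) < 2L) stop("fewer than 2 sequences with a unique WDP triad")
  ids <- names(seqs)
  regions <- c("complete", "nt", "ct")
  mats <- lapply(regions, function(r) {
    m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
    list(identity = m, similarity = m)
  })
  names(mats) <- regions
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    for (r in regions) {
      ga <- global_align(seqs[[i]][[r]], seqs[[j]][[r]], matrix = matrix,
                         gap_open = gap_open, gap_extend = gap_extend)
      res <- identity_similarity(ga, matrix = matrix, similarity = similarity)
      mats[[r]]$identity[i, j] <- mats[[r]]$identity[j, i] <- res$identity_pct
      mats[[r]]$similarity[i, j] <- mats[[r]]$similarity[j, i] <- res$similarity_pct
    }
  }
  structure(c(mats, list(excluded = excluded)), class = "domain_matrices")
}

#' @export
print.domain_matrices <- function(x, ...) {
  for (r in c("complete", "nt", "ct")) {
    cat("==", r, "identity (%) ==\n")
    print(round(x[[r]]$identity))
  }
  if (length(x$excluded) > 0L) {
    cat("excluded:", paste(names(x$excluded), x$excluded, sep = ": ",
                           collapse = "; "), "\n")
  }
  invisible(x)
}
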