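# Windowed hydropathy for single sequences and alignment-wide aggregation
# with a standard-deviation variability track.

# population sd (divide by n): descriptive variability track
.pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Windowed hydropathy of a single (ungapped) protein sequence
#'
#' The value at each position is the mean scale value over an odd window
#' centred there, sliding one residue at a time; only full windows are
#' evaluated.
#'
#' @param seq Ungapped protein sequence (string).
#' @param window Odd window length in residues; default 21.
#' @param scale Named numeric vector with one value per standard residue
#'   (default [kyte_doolittle]).
#' @return A `data.frame` with columns `position` (1-based centre, ungapped
#'   coordinates) and `value`; `length(seq) - window + 1` rows.
#' @examples
#' sequence_hydropathy(strrep("I", 25))  # flat at +4.5
#' @export
sequence_hydropathy <- function(seq, window = 21L, scale = kyte_doolittle) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer, got ", window)
  }
  if (!all(AA_STANDARD %in% names(scale))) {
    stop("hydropathy scale must cover all 20 standard residues")
  }
  seq <- toupper(seq)
  if (grepl("-", seq, fixed = TRUE)) stop("sequence must be ungapped")
  chars <- split_chars(seq)
  L <- length(chars)
  if (L < window) {
    stop(sprintf("sequence length %d shorter than window %d", L, window))
  }
  missing <- which(!chars %in% names(scale))
  if (length(missing) > 0L) {
    stop(sprintf("residue '%s' at position %d has no scale value",
                 chars[missing[1L]], missing[1L]))
  }
  vals <- unname(scale[chars])
  half <- (window - 1L) %/% 2L
  centres <- (half + 1L):(L - half)
  out <- vapply(centres, function(c) sum(vals[(c - half):(c + half)]) / window,
                numeric(1))
  data.frame(position = centres, value = out)
}

#' Alignment-wide hydropathy profile with variability track
#'
#' Each sequence's windowed hydropathy is computed on its ungapped residues
#' (windows never span gaps) and the values are projected back to the
#' alignment columns of their centre residues. Per column, the mean and the
#' population standard deviation (the variability track) are taken over the
#' sequences contributing a value there; columns with no contribution are
#' omitted.
#'
#' @inheritParams sequence_hydropathy
#' @param aln An [aa_alignment()].
#' @return A `data.frame` with columns `column` (1-based alignment column),
#'   `mean`, `sd`, `n`; attributes `scale` and `sd_form = "population"`.
#' @export
alignment_hydropathy <- function(aln, window = 21L, scale = kyte_doolittle) {
  stopifnot(inherits(aln, "aa_alignment"))
  acc <- vector("list", aln$width)
  contributed <- FALSE
  for (i in seq_len(aln$n)) {
    gapped <- split_chars(aln$seqs[[i]])
    cols <- which(gapped != "-")
    ungapped <- paste(gapped[cols], collapse = "")
    if (nchar(ungapped) < window) next
    prof <- sequence_hydropathy(ungapped, window = window, scale = scale)
    contributed <- TRUE
    for (k in seq_len(nrow(prof))) {
      col <- cols[prof$position[k]]
      acc[[col]] <- c(acc[[col]], prof$value[k])
    }
  }
  if (!contributed) {
    stop("no sequence has at least ", window, " ungapped residues")
  }
  keep <- which(lengths(acc) > 0L)
  out <- data.frame(
    column = keep,
    mean = vapply(acc[keep], mean, numeric(1)),
    sd = vapply(acc[keep], .pop_sd, numeric(1)),
    n = lengths(acc[keep])
  )
  attr(out, "scale") <- if (identical(scale, kyte_doolittle)) "kyte-doolittle" else "custom"
  attr(out, "sd_form") <- "population"
  out
}
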