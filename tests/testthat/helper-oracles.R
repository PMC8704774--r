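# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately re-derive quantities by direct enumeration or
# naive summation, sharing no code with the implementation paths they check.

# naive per-window summation of consensus symbol scores
window_profile_oracle <- function(consensus, window = 35L,
                                  scores = c("*" = 1, ":" = 0.5,
                                             "." = 0.25, " " = -0.2)) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  vals <- unname(scores[chars])
  L <- length(vals)
  half <- (window - 1L) %/% 2L
  centres <- (half + 1L):(L - half)
  data.frame(
    column = centres,
    value = vapply(centres, function(c) sum(vals[(c - half):(c + half)]) / window,
                   numeric(1))
  )
}

random_consensus <- function(L) {
  paste(sample(c("*", ":", ".", " "), L, replace = TRUE), collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(L, alphabet = AA20) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# column-wise mean / population-sd over per-sequence windowed hydropathy,
# valid for gap-free alignments only
hydropathy_alignment_oracle <- function(seqs, window, scale) {
  per_seq <- lapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    vals <- unname(scale[chars])
    half <- (window - 1L) %/% 2L
    centres <- (half + 1L):(length(vals) - half)
    vapply(centres, function(c) sum(vals[(c - half):(c + half)]) / window,
           numeric(1))
  })
  m <- do.call(rbind, per_seq)
  half <- (window - 1L) %/% 2L
  data.frame(
    column = (half + 1L):(nchar(seqs[[1L]]) - half),
    mean = colMeans(m),
    sd = apply(m, 2L, function(x) sqrt(mean((x - mean(x))^2))),
    n = nrow(m)
  )
}

# exhaustive global-alignment score by depth-first enumeration of all edit
# paths; affine gap run of length L costs open + L * ext
nw_score_oracle <- function(a, b, mat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na_ <- length(ca); nb_ <- length(cb)
  best <- -Inf
  rec <- function(i, j, acc, state) {
    if (i > na_ && j > nb_) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= na_ && j <= nb_) {
      rec(i + 1L, j + 1L, acc + mat[ca[i], cb[j]], "M")
    }
    if (i <= na_) {
      rec(i + 1L, j, acc - ext - if (state == "I") 0 else open, "I")
    }
    if (j <= nb_) {
      rec(i, j + 1L, acc - ext - if (state == "D") 0 else open, "D")
    }
  }
  rec(1L, 1L, 0, "M")
  best
}

# independent translation via Biostrings, trimming to whole codons; returns
# the residues up to (excluding) the first stop and the stop codon index
translate_oracle <- function(cds) {
  n <- nchar(cds) %/% 3L * 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)[[1L]]
  list(protein = if (stop_at > 0L) substr(aa, 1L, stop_at - 1L) else aa,
       stop_reached = stop_at > 0L,
       stop_codon = if (stop_at > 0L) stop_at else NA_integer_)
}

# a small valid ORF from a protein string (uniform codons, TAA stop)
toy_orf <- function(protein, id = "toy", seed = 1L) {
  spec <- orf_spec(protein = protein, seed = seed)
  simulate_orf(spec, id = id)$orf
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

write_lines_tmp <- function(lines, ext = ".txt") {
  tf <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
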