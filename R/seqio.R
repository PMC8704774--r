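# Sequence and alignment input/output with validation.

.validate_residues <- function(id, residues, alphabet, allow_gap = FALSE) {
  allowed <- switch(alphabet,
    protein = c(AA_STANDARD, "X"),
    dna     = c(DNA_STANDARD, "N"),
    stop("unknown alphabet: ", alphabet)
  )
  if (allow_gap) allowed <- c(allowed, "-")
  chars <- split_chars(residues)
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal %s residue '%s' at position %d",
                 id, alphabet, chars[bad[1L]], bad[1L]))
  }
  amb <- if (alphabet == "protein") "X" else "N"
  if (any(chars == amb)) {
    warning(sprintf("record '%s' contains ambiguous residue '%s'; it never counts as identity",
                    id, amb), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file into a validated record table
#'
#' Residues are uppercased and whitespace-stripped on read. Record ids (the
#' first whitespace-delimited token of each header) must be unique within a
#' file. Ambiguity characters (`X` for protein, `N` for DNA) are allowed but
#' flagged with a warning; they never count as identity in downstream scoring.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param allow_gap Permit `-` characters (used internally for gapped
#'   alignment FASTA; plain sequence sets must be ungapped).
#' @return A `data.frame` with columns `id`, `description`, `residues` and an
#'   `"alphabet"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a small protein", "MAV"), tf)
#' read_fasta(tf, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), allow_gap = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L ||
      !any(startsWith(readLines(path, warn = FALSE), ">"))) {
    stop("empty FASTA file: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA header with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicated record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  residues <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(ids)) {
    .validate_residues(ids[i], residues[i], alphabet, allow_gap = allow_gap)
  }
  out <- data.frame(id = ids, description = desc, residues = residues,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequence records to FASTA
#'
#' @param records A `data.frame` as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          residues = unname(records), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# --- alignments -------------------------------------------------------------

#' Construct a protein alignment object
#'
#' A light container for a gapped protein multiple alignment: at least two
#' records of identical gapped length, with an optional Clustal-style
#' consensus line. All-gap columns are dropped with a warning (the consensus
#' line, when present, is subset alongside). Alignment coordinates are 1-based
#' columns throughout the package's outputs.
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @param consensus Optional consensus string over `* : .` and space, with
#'   the same length as the alignment.
#' @return An object of class `aa_alignment` with fields `seqs`, `width`,
#'   `n`, `consensus`.
#' @export
aa_alignment <- function(seqs, consensus = NULL) {
  if (length(seqs) < 2L) stop("an alignment needs at least 2 records")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment records must be named")
  }
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    off <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged alignment: record '%s' has %d columns, expected %d",
                 names(seqs)[off], widths[off], widths[1L]))
  }
  for (i in seq_along(seqs)) {
    .validate_residues(names(seqs)[i], seqs[i], "protein", allow_gap = TRUE)
  }
  mat <- do.call(rbind, split_chars_all(seqs))
  all_gap <- which(colSums(mat != "-") == 0L)
  if (length(all_gap) > 0L) {
    warning(sprintf("dropping %d all-gap column(s): %s", length(all_gap),
                    paste(all_gap, collapse = ", ")), call. = FALSE)
    keep <- setdiff(seq_len(ncol(mat)), all_gap)
    seqs <- vapply(seq_along(seqs),
                   function(i) paste(mat[i, keep], collapse = ""),
                   character(1))
    names(seqs) <- rownames(mat)
    if (!is.null(consensus)) {
      consensus <- paste(split_chars(consensus)[keep], collapse = "")
    }
  }
  if (!is.null(consensus)) {
    if (nchar(consensus) != nchar(seqs[1L])) {
      stop("consensus length differs from alignment width")
    }
    if (grepl("[^*:. ]", consensus)) {
      stop("consensus line may contain only '*', ':', '.', ' '")
    }
  }
  structure(list(seqs = seqs, width = nchar(seqs[[1L]]), n = length(seqs),
                 consensus = consensus),
            class = "aa_alignment")
}

split_chars_all <- function(seqs) {
  m <- strsplit(seqs, "", fixed = TRUE)
  names(m) <- names(seqs)
  m
}

# character matrix view (rows = records, cols = alignment columns)
alignment_matrix <- function(aln) {
  do.call(rbind, split_chars_all(aln$seqs))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d records x %d columns%s\n", x$n, x$width,
              if (is.null(x$consensus)) "" else " (consensus line attached)"))
  invisible(x)
}

#' Read a protein multiple alignment
#'
#' Reads FASTA or Clustal (`.aln`) alignments. For Clustal input, a
#' conservation line of `* : .`/space symbols, when present under the
#' sequence blocks, is attached verbatim as the alignment's `consensus`
#' (downstream profiling uses it instead of recomputing).
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An [aa_alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    rec <- read_fasta(path, "protein", allow_gap = TRUE)
    if (nrow(rec) < 2L) stop("an alignment needs at least 2 records")
    seqs <- stats::setNames(rec$residues, rec$id)
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L) {
      off <- which(widths != widths[1L])[1L]
      stop(sprintf("ragged alignment: record '%s' has %d columns, expected %d",
                   names(seqs)[off], widths[off], widths[1L]))
    }
    return(aa_alignment(seqs))
  }
  parsed <- parse_clustal(path)
  aa_alignment(parsed$seqs, consensus = parsed$consensus)
}

# Clustal interleaved parser. Biostrings can read the sequence blocks but
# drops the conservation line, which this package must preserve, so blocks
# and the conservation chunks are scanned together here.
parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L])) {
    stop("not a Clustal file (missing CLUSTAL header line): ", path)
  }
  seq_re <- "^(\\S+)[ \t]+([A-Za-z-]+)([ \t]+\\d+)?[ \t]*$"
  chunks <- list()       # id -> concatenated residues
  cons_chunks <- character(0)
  block_width <- 0L
  last_start <- NA_integer_
  last_width <- NA_integer_
  in_block <- FALSE
  cons_seen <- FALSE
  flush_cons <- function(line) {
    # extract conservation symbols under the previous sequence chunk
    chunk <- substr(line, last_start, last_start + last_width - 1L)
    chunk <- paste0(chunk, strrep(" ", last_width - nchar(chunk)))
    chunk
  }
  pending_cons <- NA_character_
  n_blocks <- 0L
  for (ln in lines[-1L]) {
    m <- regexec(seq_re, ln)[[1L]]
    is_seq <- m[1L] != -1L && !grepl("^[*:. ]+$", ln)
    if (is_seq) {
      if (!in_block) {
        # starting a new block: commit conservation of the previous one
        if (n_blocks > 0L) {
          cons_chunks <- c(cons_chunks,
                           if (is.na(pending_cons)) strrep(" ", last_width)
                           else pending_cons)
        }
        pending_cons <- NA_character_
        in_block <- TRUE
        n_blocks <- n_blocks + 1L
      }
      parts <- regmatches(ln, regexec(seq_re, ln))[[1L]]
      id <- parts[2L]; res <- parts[3L]
      last_start <- m[3L]   # start of the residue group on this line
      last_width <- nchar(res)
      chunks[[id]] <- paste0(if (is.null(chunks[[id]])) "" else chunks[[id]], res)
    } else {
      if (in_block && grepl("^[*:. ]*$", ln) && is.na(pending_cons)) {
        chunk <- flush_cons(ln)
        if (grepl("[*:.]", chunk)) {
          pending_cons <- chunk
          cons_seen <- TRUE
        } else if (nzchar(trimws(ln))) {
          pending_cons <- NA_character_
        }
      }
      in_block <- FALSE
    }
  }
  if (n_blocks > 0L) {
    cons_chunks <- c(cons_chunks,
                     if (is.na(pending_cons)) strrep(" ", last_width)
                     else pending_cons)
  }
  if (length(chunks) == 0L) stop("no sequences found in Clustal file: ", path)
  seqs <- toupper(vapply(chunks, identity, character(1)))
  consensus <- if (cons_seen) paste(cons_chunks, collapse = "") else NULL
  if (!is.null(consensus)) {
    # chunks of the final block may be narrower than earlier ones; pad/trim
    w <- nchar(seqs[[1L]])
    if (nchar(consensus) < w) consensus <- paste0(consensus, strrep(" ", w - nchar(consensus)))
    consensus <- substr(consensus, 1L, w)
  }
  list(seqs = seqs, consensus = consensus)
}

#' Write a positional profile to a tab-separated table
#'
#' Writes one row per profile position with all numeric columns printed at
#' fixed 6-decimal precision, so written and re-read values agree to printed
#' precision. An empty profile yields a header-only file.
#'
#' @param profile A `data.frame` whose first column is a sorted 1-based
#'   alignment column/position index (e.g. the output of
#'   [similarity_profile()] or [alignment_hydropathy()]).
#' @param path Output TSV path.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(is.data.frame(profile))
  if (nrow(profile) > 0L && is.unsorted(profile[[1L]], strictly = TRUE)) {
    stop("profile positions must be strictly increasing")
  }
  out <- profile
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
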