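# Seeded generators for protein families and ORFs with planted, auditable
# ground truth: conserved columns, conservative-substitution structure,
# hydrophobic (TM-like) blocks, WDP triads and protospacer targets.

HYDROPHOBIC_SET <- c("I", "L", "V", "F", "A", "M")

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic protein family
#'
#' Describes a gap-free protein family derived from a random template:
#' planted perfectly conserved columns (e.g. cysteines), per-column
#' conservative-substitution structure reusing the ClustalW/X strong/weak
#' groups (so generator and consensus scorer agree on what "conservative"
#' means), and hydrophobic TM-like blocks drawn from `{I,L,V,F,A,M}`.
#'
#' @param n_sequences Number of derived sequences (>= 2).
#' @param length Alignment length in columns.
#' @param conserved_columns Named character vector: names are 1-based
#'   columns, values the planted residue (e.g. `c("12" = "C")`).
#' @param strong_sub_rate,weak_sub_rate,random_sub_rate Per-column
#'   probabilities (summing to <= 1) that a derived sequence replaces the
#'   template residue by a strong-group partner, a weak-group partner, or a
#'   uniformly random different residue.
#' @param hydrophobic_blocks List of `c(start, end)` column ranges whose
#'   template residues are drawn from the hydrophobic set.
#' @param seed Integer seed; one seed governs all draws.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_sequences = 10L, length = 300L,
                        conserved_columns = character(0),
                        strong_sub_rate = 0.10, weak_sub_rate = 0.05,
                        random_sub_rate = 0.05,
                        hydrophobic_blocks = list(), seed = 1L) {
  n_sequences <- as.integer(n_sequences); length <- as.integer(length)
  stopifnot(n_sequences >= 2L, length >= 1L)
  rates <- c(strong_sub_rate, weak_sub_rate, random_sub_rate)
  if (any(rates < 0) || sum(rates) > 1) {
    stop("substitution rates must be non-negative and sum to <= 1")
  }
  if (length(conserved_columns) > 0L) {
    cols <- as.integer(names(conserved_columns))
    if (anyNA(cols) || any(cols < 1L | cols > length)) {
      stop("conserved_columns names must be columns within 1..length")
    }
    if (anyDuplicated(cols)) stop("duplicated conserved column")
    if (!all(conserved_columns %in% AA_STANDARD)) {
      stop("conserved residues must be standard amino acids")
    }
  }
  for (b in hydrophobic_blocks) {
    if (length(b) != 2L || b[1L] > b[2L] || b[1L] < 1L || b[2L] > length) {
      stop("hydrophobic block ranges must be c(start, end) within 1..length")
    }
  }
  structure(list(n_sequences = n_sequences, length = length,
                 conserved_columns = conserved_columns,
                 strong_sub_rate = strong_sub_rate,
                 weak_sub_rate = weak_sub_rate,
                 random_sub_rate = random_sub_rate,
                 hydrophobic_blocks = hydrophobic_blocks,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Simulate a protein family with planted ground truth
#'
#' Draws a uniform random template (hydrophobic blocks drawn from the
#' hydrophobic set, planted conserved residues fixed), then derives each
#' family member by mutating every non-conserved column independently:
#' strong-group substitution with probability `strong_sub_rate` (uniform
#' over the template residue's strong-group partners), weak-group with
#' `weak_sub_rate`, uniform random different residue with
#' `random_sub_rate`. A planted residue lacking group partners when a rate
#' demands one falls back to a random substitution (recorded). The
#' alignment is generated gap-free and is deterministic for a given seed.
#'
#' @param spec A [family_spec()].
#' @return A list with `alignment` (an [aa_alignment()]) and `truth`:
#'   `template`, `conserved_columns`, `hydrophobic_blocks`,
#'   `mutated_columns` (logical per column: was any sequence mutated
#'   there?), `mutation_counts`, `fallbacks`.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    template <- sample(AA_STANDARD, L, replace = TRUE)
    for (b in spec$hydrophobic_blocks) {
      template[b[1L]:b[2L]] <- sample(HYDROPHOBIC_SET, b[2L] - b[1L] + 1L,
                                      replace = TRUE)
    }
    cons_cols <- integer(0)
    if (length(spec$conserved_columns) > 0L) {
      cons_cols <- as.integer(names(spec$conserved_columns))
      template[cons_cols] <- spec$conserved_columns
    }
    mutable <- setdiff(seq_len(L), cons_cols)
    p_strong <- spec$strong_sub_rate
    p_weak <- spec$weak_sub_rate
    p_rand <- spec$random_sub_rate
    strong_tab <- lapply(stats::setNames(AA_STANDARD, AA_STANDARD),
                         group_partners, CLUSTAL_STRONG_GROUPS)
    weak_tab <- lapply(stats::setNames(AA_STANDARD, AA_STANDARD),
                       group_partners, CLUSTAL_WEAK_GROUPS)
    mutation_counts <- integer(L)
    fallbacks <- 0L
    seqs <- character(spec$n_sequences)
    for (s in seq_len(spec$n_sequences)) {
      chars <- template
      u <- runif(L)
      for (j in mutable[u[mutable] < p_strong + p_weak + p_rand]) {
        kind <- if (u[j] < p_strong) "strong"
                else if (u[j] < p_strong + p_weak) "weak"
                else "random"
        res <- template[j]
        partners <- switch(kind,
          strong = strong_tab[[res]],
          weak = weak_tab[[res]],
          random = character(0))
        if (kind != "random" && length(partners) == 0L) {
          fallbacks <- fallbacks + 1L
          kind <- "random"
        }
        new <- if (kind == "random") sample(setdiff(AA_STANDARD, res), 1L)
               else if (length(partners) == 1L) partners
               else sample(partners, 1L)
        chars[j] <- new
        mutation_counts[j] <- mutation_counts[j] + 1L
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    names(seqs) <- sprintf("seq%03d", seq_len(spec$n_sequences))
    truth <- list(template = paste(template, collapse = ""),
                  conserved_columns = spec$conserved_columns,
                  hydrophobic_blocks = spec$hydrophobic_blocks,
                  mutated_columns = mutation_counts > 0L,
                  mutation_counts = mutation_counts,
                  fallbacks = fallbacks)
    list(alignment = aa_alignment(seqs), truth = truth)
  })
}

#' Specification for a synthetic ORF
#'
#' Describes a coding sequence built by uniform synonymous reverse
#' translation of a protein (given or random), with planted WDP triads
#' (tryptophan forced `TGG`, aspartate codon chosen `GAT`/`GAC`, proline
#' uniform over `CCN`) and planted 20-nt protospacer targets with an NGG
#' PAM.
#'
#' Each protospacer entry is a list with `seq` (20-nt DNA), `boundary`
#' (number of complete codons before the planted block; the block occupies
#' the next 8 codons), optional `strand` (`"+"` default, or `"-"`), and
#' optional `pam` (e.g. `"AGG"`, or `"NGG"` to let the generator pick the
#' N). The 20 nt + PAM are padded to a 24-nt in-frame block that overwrites
#' those 8 codons, with the free bases chosen so no in-frame stop appears.
#'
#' @param protein Protein sequence to encode (must start with M), or `NULL`
#'   to draw one at random.
#' @param length Protein length in aa (used when `protein` is `NULL`).
#' @param wdp_positions Codon indices of planted `W` of WDP triads.
#' @param d_codon_choice `"random"`, `"GAT"` or `"GAC"`.
#' @param protospacers List of protospacer entries (see Details).
#' @param seed Integer seed.
#' @return A list of class `orf_spec`.
#' @export
orf_spec <- function(protein = NULL, length = NULL,
                     wdp_positions = integer(0),
                     d_codon_choice = c("random", "GAT", "GAC"),
                     protospacers = list(), seed = 1L) {
  d_codon_choice <- match.arg(d_codon_choice)
  if (is.null(protein) && is.null(length)) stop("give either protein or length")
  if (!is.null(protein)) {
    protein <- toupper(protein)
    if (substr(protein, 1L, 1L) != "M") stop("protein must start with M")
    if (grepl("[^A-Z]", protein) || grepl("[BJOUZX]", protein)) {
      stop("protein must contain only standard residues")
    }
    length <- nchar(protein)
  }
  length <- as.integer(length)
  wdp_positions <- sort(as.integer(wdp_positions))
  if (any(wdp_positions < 2L | wdp_positions + 2L > length)) {
    stop("WDP positions must satisfy 2 <= k and k + 2 <= protein length")
  }
  wdp_codons <- unlist(lapply(wdp_positions, function(k) k:(k + 2L)))
  used <- wdp_codons
  for (ps in protospacers) {
    if (!is.list(ps) || is.null(ps$seq) || is.null(ps$boundary)) {
      stop("each protospacer needs fields 'seq' and 'boundary'")
    }
    if (nchar(ps$seq) != 20L || grepl("[^ACGT]", toupper(ps$seq))) {
      stop("protospacer seq must be 20 nt of ACGT")
    }
    b <- as.integer(ps$boundary)
    if (b < 1L || b + 8L > length) {
      stop("protospacer block (codons boundary+1..boundary+8) must fit inside the protein")
    }
    block <- (b + 1L):(b + 8L)
    if (length(intersect(block, used)) > 0L) stop("planted features overlap")
    used <- c(used, block)
  }
  structure(list(protein = protein, length = length,
                 wdp_positions = wdp_positions,
                 d_codon_choice = d_codon_choice,
                 protospacers = protospacers, seed = as.integer(seed)),
            class = "orf_spec")
}

# build the 8 in-frame codons of a protospacer block; free bases (PAM N on
# "+", complementary base on "-", plus one pad base) avoid in-frame stops
.protospacer_block <- function(seq, strand, pam) {
  seq <- toupper(seq)
  pick <- function(candidates, fixed_prefix) {
    ok <- candidates[!paste0(fixed_prefix, candidates) %in% STOP_CODONS]
    if (length(ok) == 0L) stop("no stop-free base choice for protospacer block")
    if (length(ok) == 1L) ok else sample(ok, 1L)
  }
  if (strand == "+") {
    fixed <- substring(seq, c(1L, 4L, 7L, 10L, 13L, 16L), c(3L, 6L, 9L, 12L, 15L, 18L))
    if (any(fixed %in% STOP_CODONS)) {
      stop("protospacer contains an in-frame stop codon at this boundary")
    }
    n_choices <- if (toupper(substr(pam, 1L, 1L)) == "N") c("A", "C", "G", "T")
                 else toupper(substr(pam, 1L, 1L))
    n <- pick(n_choices, substr(seq, 19L, 20L))
    if (paste0(substr(seq, 19L, 20L), n) %in% STOP_CODONS) {
      stop("PAM choice creates an in-frame stop codon")
    }
    pad <- pick(c("A", "C", "G", "T"), "GG")
    codons <- c(fixed, paste0(substr(seq, 19L, 20L), n), paste0("GG", pad))
  } else {
    rc <- revcomp(seq)
    fixed <- substring(rc, c(1L, 4L, 7L, 10L, 13L, 16L), c(3L, 6L, 9L, 12L, 15L, 18L))
    # codon 1 is CCx (proline, never stop); codons 2..7 carry rc[1..18]
    if (any(fixed %in% STOP_CODONS)) {
      stop("protospacer (reverse strand) contains an in-frame stop codon at this boundary")
    }
    n_choices <- if (toupper(substr(pam, 1L, 1L)) == "N") c("A", "C", "G", "T")
                 else revcomp(toupper(substr(pam, 1L, 1L)))
    n <- if (length(n_choices) == 1L) n_choices else sample(n_choices, 1L)
    pad <- pick(c("A", "C", "G", "T"), substr(rc, 19L, 20L))
    codons <- c(paste0("CC", n), fixed, paste0(substr(rc, 19L, 20L), pad))
  }
  codons
}

#' Simulate an ORF with planted WDP triads and protospacer targets
#'
#' Reverse-translates the (given or random) protein with uniform synonymous
#' codon choice, forces the planted triad codons (`TGG`, `GAT`/`GAC`,
#' `CCN`), appends a `TAA` stop, then overwrites 8-codon blocks with the
#' planted protospacer + PAM material (see [orf_spec()]). When the protein
#' is drawn at random, accidental `WDP` occurrences outside the planted
#' positions are scrubbed so planted truth stays exact. The result always
#' satisfies the [orf_record()] invariants.
#'
#' @param spec An [orf_spec()].
#' @param id Identifier for the generated record.
#' @return A list with `orf` (an [orf_record()]) and `truth`: the encoded
#'   `protein`, `wdp` (data.frame `w_codon`, `d_codon`, `d_codon_seq`,
#'   `edit_nt` - the nucleotide needing the synonymous C->T edit, `NA` when
#'   the BamHI site is already present) and `protospacers` (data.frame
#'   `strand`, `boundary`, `protospacer_start`, `pam_start`, `cut_after`,
#'   plus-strand 1-based coordinates).
#' @export
simulate_orf <- function(spec, id = "synthetic_orf") {
  stopifnot(inherits(spec, "orf_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    protein <- spec$protein
    if (is.null(protein)) {
      chars <- c("M", sample(AA_STANDARD, L - 1L, replace = TRUE))
      for (k in spec$wdp_positions) chars[k:(k + 2L)] <- c("W", "D", "P")
      # scrub accidental WDP triads so planted truth stays exact
      for (iter in seq_len(100L)) {
        prot <- paste(chars, collapse = "")
        hits <- as.integer(gregexpr("WDP", prot, fixed = TRUE)[[1L]])
        extra <- setdiff(hits[hits > 0L], spec$wdp_positions)
        if (length(extra) == 0L) break
        for (k in extra) chars[k + 1L] <- sample(setdiff(AA_STANDARD, "D"), 1L)
      }
      protein <- paste(chars, collapse = "")
    } else {
      chars <- split_chars(protein)
      for (k in spec$wdp_positions) {
        if (!identical(chars[k:(k + 2L)], c("W", "D", "P"))) {
          stop("given protein does not carry WDP at planted position ", k)
        }
      }
    }
    syn <- synonymous_codons()
    codons <- vapply(chars, function(r) {
      cc <- syn[[r]]
      if (length(cc) == 1L) cc else sample(cc, 1L)
    }, character(1), USE.NAMES = FALSE)
    wdp_truth <- NULL
    for (k in spec$wdp_positions) {
      d_seq <- switch(spec$d_codon_choice,
                      random = sample(c("GAT", "GAC"), 1L),
                      spec$d_codon_choice)
      codons[k] <- "TGG"
      codons[k + 1L] <- d_seq
      # proline stays CCN by the genetic code; no forcing needed
      wdp_truth <- rbind(wdp_truth, data.frame(
        w_codon = k, d_codon = k + 1L, d_codon_seq = d_seq,
        edit_nt = if (d_seq == "GAC") 3L * (k + 1L) else NA_integer_))
    }
    ps_truth <- NULL
    for (ps in spec$protospacers) {
      strand <- if (is.null(ps$strand)) "+" else ps$strand
      pam <- if (is.null(ps$pam)) "NGG" else ps$pam
      b <- as.integer(ps$boundary)
      codons[(b + 1L):(b + 8L)] <- .protospacer_block(ps$seq, strand, pam)
      if (strand == "+") {
        start <- 3L * b + 1L
        ps_truth <- rbind(ps_truth, data.frame(
          strand = "+", boundary = b, protospacer_start = start,
          pam_start = start + 20L, cut_after = start + 16L))
      } else {
        start <- 3L * b + 4L   # plus-strand start of the 20-nt match
        ps_truth <- rbind(ps_truth, data.frame(
          strand = "-", boundary = b, protospacer_start = start,
          pam_start = start - 3L, cut_after = start + 2L))
      }
    }
    cds <- paste(c(codons, "TAA"), collapse = "")
    orf <- orf_record(id, cds)
    truth <- list(protein = orf$protein,
                  wdp = if (is.null(wdp_truth))
                          data.frame(w_codon = integer(0), d_codon = integer(0),
                                     d_codon_seq = character(0), edit_nt = integer(0))
                        else wdp_truth,
                  protospacers = if (is.null(ps_truth))
                          data.frame(strand = character(0), boundary = integer(0),
                                     protospacer_start = integer(0),
                                     pam_start = integer(0), cut_after = integer(0))
                        else ps_truth)
    list(orf = orf, truth = truth)
  })
}
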