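---
title: "The p74tools in-silico pipeline: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The p74tools in-silico pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p74tools)
```

# Scope

`p74tools` implements the computational side of a P74 (PIF0) domain-swap
study: conservation profiling of a protein family alignment, hydropathy
profiling with a variability track, codon-aware engineering of a BamHI site
at the conserved WDP triad, splitting of *p74*-like ORFs into Nt/Ct domains
and assembly of in-frame chimeras, annotation of CRISPR/Cas9 NHEJ indel
outcomes, and domain-wise pairwise identity/similarity statistics. It does
*not* build multiple alignments (any standard protein MSA is accepted),
infer phylogenies, call transmembrane segments or disulfide connectivity
with probabilistic models, or predict CRISPR repair outcomes — those steps
belong to dedicated external tools.

# Conservation profiling

## The consensus line

The consensus is derived per alignment column with ClustalW/X conventions:
`*` when every sequence carries the same residue (no gaps), `:` when all
residues fall within one *strong* conservation group (`STA`, `NEQK`,
`NHQK`, `NDEQ`, `QHRK`, `MILV`, `MILF`, `HY`, `FYW`), `.` when all fall
within one *weak* group (`CSA`, `ATV`, `SAG`, `STNK`, `STPA`, `SGND`,
`SNDEQK`, `NDEQHK`, `NEQHRK`, `FVLIM`, `HFY`), and a space otherwise. Two
deliberate rules:

* **Gaps blank the column.** Any gap forces a space, matching how Clustal
  conservation lines treat gapped columns. When a Clustal file already
  carries a conservation line, `read_alignment()` attaches it and
  `consensus_line()` returns it verbatim — the printed line of the original
  program, when available, takes precedence over recomputation.
* **`X` never matches anything**, including another `X`: an ambiguous
  residue cannot attest identity.

## The windowed similarity score

Each symbol receives a score — +1 (`*`), +0.5 (`:`), +0.25 (`.`), −0.2
(space) — and a sliding window of odd length $w$ (default 35 residues) is
summed, divided by $w$, and assigned to the window's central column:

$$ S_c = \frac{1}{w}\sum_{j=c-\lfloor w/2\rfloor}^{c+\lfloor w/2\rfloor} s_j. $$

The stronger conservative class receives the larger of the two intermediate
scores; both are configurable through `scoring_scheme()`. Only full windows
are evaluated (the profile spans columns $\lceil w/2\rceil$ to
$L-\lfloor w/2\rfloor$), because a partial window would silently change the
normalising denominator at the plot edges. The window must be odd so the
centre is a column, not a boundary. Values are exact sums — no smoothing or
floating-point reorderings — so the profile is reproducible to the last bit
and is tested against a brute-force per-window oracle.

# Hydropathy with a variability track

Per-sequence hydropathy uses the Kyte–Doolittle scale (the de facto
standard; pluggable via the `scale` argument, and recorded in the output's
attributes) with an odd window, default 21 residues, displaced one residue
at a time. For an alignment, each sequence is profiled on its *ungapped*
residues — windows never span gaps — and each window value is projected to
the alignment column holding its centre residue. Per column the package
reports the mean, the **population** standard deviation (divide by $n$; it
is a descriptive variability track, not an inferential estimate — the form
is recorded in the output attributes), and the number of contributing
sequences; columns with no contribution are omitted rather than
interpolated. Aggregation is across sequences, the variant consistent with
a per-species standard-deviation track; a consensus-sequence variant is
deliberately not provided.

# WDP/BamHI engineering and chimeras

The conserved tryptophan–aspartate–proline triad is encoded
`TGG GAy CCn`. Because `GGATCC` (BamHI) spans the last base of the W codon
through the second base of the P codon, the site either exists already
(D = `GAT`) or is created by the single synonymous third-position edit
`GAC→GAT` at ORF nucleotide $3d$ (A of `ATG` = 1, $d$ = the D codon index).
The proline codon is `CCN` for every proline codon, so it never needs
editing. Conventions:

* **The split falls immediately after the D codon**: the Nt fragment ends
  `…WD`, the Ct fragment begins `P…`. This is forced by the domain
  arithmetic of the reference protein (a 458-aa Nt whose last residue is
  the mutated aspartate, and a 187-aa Ct).
* **Multiple triads** are all returned by `find_wdp_splits()`; the CLI
  requires an explicit `--triad-index` when there is more than one.
* **Nt-only constructs** are terminated with `TAA`; the codon choice is
  arbitrary and recorded here.
* **Tags are prepended verbatim** (supply the exact tag CDS, including its
  own ATG; the donor ATG is retained), mirroring a translational fusion
  without simulating any particular vector. `assemble_chimera()` asserts
  the junction reads `WDP` and that both donor fragment proteins are
  preserved residue-for-residue.
* Restriction scanning is plus-strand only; the enzymes involved (BamHI,
  BglII, HindIII, EcoRI) all have palindromic sites, so nothing is missed.

# CRISPR NHEJ annotation

`locate_protospacer()` reports every exact 20-nt protospacer match on
either strand with an `NGG` immediately 3′ on the target strand, and the
standard SpCas9 blunt-cut prediction 3 nt 5′ of the PAM (between
protospacer positions 17 and 18). `cut_after = n` always refers to the
plus strand: the cut falls between positions $n$ and $n+1$. Lesions are
user-specified (`apply_deletion()`, `apply_insertion()`, 1-based inclusive
plus-strand coordinates); microhomology or repair-outcome prediction is out
of scope. The outcome annotation is purely arithmetical:

* **frameshift** ⟺ lesion length ≢ 0 (mod 3);
* **premature stop** ⟺ the first stop codon of the edited CDS precedes its
  final complete codon (so an in-frame deletion whose product simply ends
  one codon earlier is *not* premature);
* **novel residues** = the edited product's suffix after its longest common
  prefix with the wild-type product, for display parity with
  mutant-sequencing figures.

`classify_edit()` gives `silent` (product identical — reachable for
insertions 3′ of the stop codon; a deletion always shortens the product,
so a deletion is never silent under strict product identity),
`knockout` (frameshift *and* premature stop), `nonsense_in_frame`
(premature stop without frameshift), else `in_frame_indel`. A frameshift
that runs to the end of a CDS without meeting any stop — possible only in
short toy sequences — has no dedicated label and reports `in_frame_indel`.

# Pairwise identity and similarity

Global alignment is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment`, defaulting to the EMBOSS-needle
convention (BLOSUM62, gap open 10, gap extend 0.5; a gap of length $L$
costs $10 + 0.5L$). Two conventions are stated explicitly because
published identity tables rarely state theirs:

* **Denominator = full alignment length**, gapped columns included. Any
  choice here is defensible; this one is reproducible and conservative.
* **Similarity = aligned pairs with a positive substitution score**
  (identities included). A looser definition counting Clustal strong-group
  pairs is available (`similarity = "group"`), since published
  "similarity" values are often computed that way.

Percentages are kept at full precision and rounded only at report time.
`domain_matrix()` computes the three matrices (complete, Nt, Ct) with each
sequence split at its *own* unique WDP triad; sequences with zero or
several triads are excluded and reported, not silently dropped.

# The synthetic-data generator

Every stage is testable without downloads because the generator plants
known truth:

* **Families** (`simulate_family()`): a uniform random template; planted
  perfectly conserved columns; hydrophobic blocks drawn from
  `{I,L,V,F,A,M}` (Kyte–Doolittle means near +3, far above the ~−0.5
  average of random sequence, so blocks behave like TM stretches); per
  non-conserved column, independent strong-group / weak-group / random
  substitutions at the spec'd rates, reusing the ClustalW/X groups so the
  generator and the consensus scorer agree about what "conservative"
  means. Families are generated gap-free so the planted truth stays exact;
  gap behaviour is exercised with hand-built fixtures instead. No
  tree-structured evolution is simulated: all sequences are independent
  draws around one template, so the generator emulates conservation
  *structure*, not phylogeny — a passing planted-truth test says nothing
  about rate heterogeneity or lineage effects in real families.
* **ORFs** (`simulate_orf()`): uniform synonymous reverse translation,
  planted WDP triads (W forced `TGG`, D per `d_codon_choice`, P uniform
  `CCN`), `TAA` appended. Protospacers are planted as in-frame 24-nt
  blocks (protospacer + PAM + one pad base on the plus strand; `CCN` +
  reverse-complement + pad on the minus strand) that overwrite eight
  codons at a chosen codon boundary; the free bases are chosen to avoid
  in-frame stops, and a protospacer whose fixed codons already contain a
  stop is rejected rather than silently moved. A literal 23-nt insertion
  would break the reading frame, which the ORF invariants forbid — the
  in-frame block keeps every planted coordinate exact
  (plus strand: start $3b+1$, cut after $3b+17$; minus strand: start
  $3b+4$, cut after $3b+6$, for boundary $b$).

One integer seed governs all draws, and the generator saves and restores
the caller's RNG state, so fixtures are reproducible and tests cannot
couple through the global stream.

# Numerical and validation choices

* Windows must be odd and fully contained; no partial-window values.
* All-gap alignment columns are dropped with a warning (the attached
  consensus is subset alongside) — they carry no information and would
  otherwise poison column statistics.
* `orf_record()` enforces ATG start, terminal stop, length divisible by 3
  and no internal stop; `apply_synonymous_edits()` *asserts* translation
  identity after editing (a failure would be an internal inconsistency,
  not a user error).
* Information content is $\log_2 20 - H$ of the gap-excluded column
  frequencies, the quantity behind sequence-logo letter heights; all-gap
  columns report `NA`.
* Profile tables print at fixed 6-decimal precision so that written and
  re-read values agree exactly at that precision.

# Problem sizes used in the checks

The package's own validation runs at desk scale, chosen to exercise every
code path while remaining quick on one CPU: 200 random consensus strings of
35–500 columns against the window-summation oracle; exhaustive
enumeration of all global alignment paths for sequence pairs up to length
8 over a reduced alphabet; 100 random indels for the frameshift/knockout
equivalence; and ≥10 generator seeds for planted-truth recovery of
conserved columns and hydrophobic blocks. The accompanying
`scripts/acceptance.R` rebuilds a full-size emulated study — a 76-member
family of 645-residue proteins with six invariant cysteines and three
TM-like blocks, and a 1938-nt *p74*-like ORF (Nt 458 aa + Ct 187 aa, GAC
aspartate at the triad, the knockout crRNA placed so the predicted cut
falls 207 nt downstream of the ATG) — and recomputes the pipeline's
headline numbers from scratch.

# Known limitations

* Consensus symbols require *all* sequences to agree (per Clustal); with
  many divergent sequences the profile is dominated by the floor score,
  which is faithful to the convention but means the profile's absolute
  level depends strongly on family size.
* Identity/similarity percentages depend on alignment parameters and on
  the two conventions above; comparisons with published tables whose
  conventions are unstated are calibration checks, not exact matches.
* The NHEJ annotator evaluates user-specified lesions only; it does not
  rank repair outcomes.
* Reverse translation is uniform over synonymous codons; no codon-usage
  tables.
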