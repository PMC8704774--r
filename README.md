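# p74tools

An R toolkit for in-silico analysis of baculovirus **P74 (PIF0)** and
similar protein families. P74 is an essential *per os* infectivity factor
anchored in the occlusion-derived virion envelope: its amino-terminal (Nt)
region carries the host-specific midgut-binding function while the
carboxyl-terminal (Ct) region holds the membrane-anchoring transmembrane
stretches. A conserved tryptophan–aspartate–proline (**WDP**) triad sits at
the Nt/Ct boundary, and because the triad is encoded `TGG GAy CCn`, the
BamHI site `GGATCC` either already spans it or can be created by one
synonymous point edit — which makes the triad a natural, protein-neutral
junction for swapping domains between species.

`p74tools` covers the complete computational workflow around such a study:

* **Conservation profiling** — derive a Clustal-style consensus line
  (`*`/`:`/`.`/space with the ClustalW/X strong and weak groups) and turn
  it into a windowed similarity profile: symbol scores +1, +0.5, +0.25 and
  −0.2 summed over an odd window (default 35 residues), normalised by the
  window length and assigned to the central column. Also: perfectly
  conserved residue detection (e.g. invariant cysteines) and
  position-frequency matrices with information content
  (log2 20 − Shannon entropy).
* **Hydropathy profiling** — Kyte–Doolittle windowed means (default 21
  residues) per sequence, projected onto alignment columns and aggregated
  into a mean profile with a standard-deviation variability track.
* **WDP/BamHI domain engineering** — locate WDP triads in a CDS, apply the
  minimal synonymous `GAC→GAT` edit, split ORFs into Nt (`…WD`) and Ct
  (`P…`) fragments and assemble in-frame chimeric ORFs (with optional tag
  fusion and Nt-only constructs), plus restriction-site scanning.
* **CRISPR NHEJ annotation** — locate 20-nt protospacers with NGG PAMs on
  both strands, predict the SpCas9 blunt cut 3 nt 5′ of the PAM, apply
  deletions/insertions and classify the coding consequence (frameshift,
  premature stop, knockout, silent).
* **Pairwise statistics** — Needleman–Wunsch global alignment (BLOSUM62,
  affine gaps 10/0.5) with percent identity/similarity matrices for
  complete proteins and their WDP-split Nt/Ct domains.
* **Synthetic data** — seeded generators for protein families with planted
  conserved columns, conservative-substitution structure and hydrophobic
  TM-like blocks, and for ORFs with planted WDP triads and protospacer
  targets — every pipeline stage is testable against known ground truth.

## Worked example

Build a *p74*-like ORF (645 aa = Nt 458 + Ct 187, aspartate of the WDP
triad encoded `GAC`, and a knockout crRNA placed so the predicted cut falls
207 nt downstream of the ATG), then run the engineering and knockout steps:

```r
library(p74tools)

sim <- simulate_orf(orf_spec(
  length = 645, wdp_positions = 457, d_codon_choice = "GAC",
  protospacers = list(list(seq = "AACTGGCTTTCAGCAAGCGC",
                           boundary = 67, strand = "-")),
  seed = 74), id = "p74_like")
orf <- sim$orf
orf
#> ORF 'p74_like': 1938 nt, 645 aa

sp <- find_wdp_splits(orf)[[1]]
sp
#> WDP split: codons 457-459, split after codon 458, BamHI requires 1 synonymous edit(s)
sp$required_edits
#>   position from to
#> 1     1374    C  T
```

The single synonymous edit sits at nucleotide 1374 — the third base of
codon 458, the aspartate — and creates `GGATCC` without touching the
protein. Splitting after that codon yields the two domains:

```r
edited <- apply_synonymous_edits(orf, sp)
frag <- split_orf(edited, sp)
c(nt_aa = nchar(frag$nt$protein), ct_aa = nchar(frag$ct$protein))
#> nt_aa ct_aa
#>   458   187
```

The guide targets the minus strand near the ORF start; the predicted
double-strand break falls between plus-strand positions 207 and 208, and
the 4-bp NHEJ deletion at nt 207–210 shifts the frame and truncates the
product:

```r
locate_protospacer(orf$cds, guide_rna("AACTGGCTTTCAGCAAGCGC"))
#>   strand protospacer_start pam_start cut_after
#> 1      -               205       202       207

outcome <- apply_deletion(orf, 207, 210)
outcome
#> deletion of 4 nt at 207: frameshift, premature stop at codon 74, product 73 aa
classify_edit(outcome)
#> [1] "knockout"
```

A chimera joining the Nt domain of one donor to the Ct domain of another at
the engineered junction is one call
(`assemble_chimera(orfA, spA, orfB, spB)`), and
`domain_matrix(list_of_orfs)` returns identity/similarity matrices for the
complete proteins and both domains. A thin command-line wrapper with the
subcommands `profile`, `hydropathy`, `split`, `chimera`, `knockout`,
`pairstats` and `simulate` is installed at
`system.file("cli", "p74tools", package = "p74tools")`.

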