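---
title: "Analysing synonymous codon usage bias in organellar protein-coding genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing synonymous codon usage bias in organellar protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
library(dplyr)
```

## The problem

Eighteen of the twenty standard amino acids are encoded by more than one
codon, and in real genes the synonymous alternatives are not used equally.
This synonymous codon usage bias (CUB) carries a signal about the forces
shaping a genome: directional mutation pressure (which pushes all codon
positions towards the same base composition) and natural selection (for
example on translational efficiency, which acts on the third, mostly
silent, position independently of the first two). Fungal mitochondrial
genomes are an extreme case: they are strongly AT-rich, their core
protein-coding genes (atp6, cob, cox1-3, nad1-6, nad4, nad5, nad6, rps3)
are short, and their synonymous third positions are almost devoid of G and
C. `cubtools` implements the complete analysis such a dataset calls for,
organised as strains x genes: composition statistics, the classical usage
indices, three mutation-versus-selection diagnostics, correspondence
analysis of RSCU, optimal-codon determination, and RSCU-based hierarchical
clustering of strains.

## Statistics implemented

**RSCU.** For codon $c$ in a synonymous family of size $k$ with counts
$n_1, \dots, n_k$, $\mathrm{RSCU}(c) = k\,n_c / \sum_i n_i$: the observed
usage relative to the uniform expectation. Within any observed family the
values sum to $k$; a family with zero usage is reported as missing, not as
zero bias.

**ENC.** Wright's effective number of codons. Per amino acid with total
count $n \ge 2$ the codon homozygosity is estimated as
$\hat F = (n \sum_i \hat p_i^2 - 1)/(n - 1)$; class averages
$\bar F_k$ are formed over amino acids of degeneracy $k$, and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$
under the standard code (the general form sums $N_k/\bar F_k$ plus one per
single-codon amino acid, so alternative code tables are handled
transparently). The result is capped to $[20, 61]$. When the 3-fold class
(Ile) is not computable it is imputed as the mean of the 2-fold and 4-fold
class averages; any other missing class drops its term and the partial sum
is rescaled by the represented amino-acid count. Six-fold families (Leu,
Ser, Arg) are kept as single 6-fold classes, matching Wright's original
9/1/5/3 class weights.

**CAI, CBI, FOP.** CAI is the geometric mean over a gene's codons
(single-codon amino acids and stops excluded) of relative adaptiveness
weights $w(c) = n_c / \max_{\text{family}} n$, derived from a reference
set of putatively highly expressed genes; unobserved reference codons get
a floor of $w = 0.01$ so the log-mean stays defined. CBI is the normalised
excess of optimal-codon usage over the uniform-within-family expectation,
$(N_{opt} - N_{ran})/(N_{tot} - N_{ran})$, and FOP the plain fraction
$N_{opt}/N_{tot}$. Because no external reference sets exist for these
mitochondrial genes, both the CAI reference and the optimal set default to
quantities derived from the dataset itself: the low-ENC tail of the
expression split provides the CAI reference, and the delta-RSCU
classification provides the optimal set. Both can be overridden with
user-supplied tables. Absolute CAI/CBI/FOP values therefore depend on
those conventions and are comparable within an analysis, not across
software.

**GRAVY and AROMO** are properties of the encoded protein: the mean
Kyte-Doolittle hydropathy (positive = hydrophobic) and the fraction of
Phe/Tyr/Trp residues.

**Composition.** GC1/GC2/GC3 are per-position G+C fractions over the whole
CDS; GC12 their mean. GC3s and the A3s/T3s/G3s/C3s third-position
frequencies are computed over synonymous codons only (families of size at
least 2, so Met, Trp and stops are excluded). The x3s statistics use
per-base denominators -- the number of synonymous codons whose family can
end in that base -- which is why the four values can sum to more than 1.
This is the convention under which published per-base synonymous
third-position values exceed 100% in total; a shared-simplex denominator
could not produce such numbers.

## Selection-versus-mutation diagnostics

**Neutrality plot.** OLS regression of per-gene GC12 on GC3, with the
two-sided Pearson test. Under pure directional mutation pressure all three
positions drift together (slope near 1, significant correlation); under
selective constraint on positions 1-2 the correlation disappears. The
significance threshold is fixed at 0.05, two-sided.

**ENC-GC3s plot.** The mutation-only expectation
$\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$ at GC3s $= s$, and the
relative shortfall
$\mathrm{ENC}_{ratio} = (\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs}) /
\mathrm{ENC}_{exp}$, reported as a percentage. Genes sitting well below
the curve (large positive ratio) are shaped by more than mutation.

**PR2 bias.** $A_3/(A_3+T_3)$ against $G_3/(G_3+C_3)$, tallied by default
over the fourfold-degenerate codon quartets (Sueoka's construction: the
XY-stems whose four codons encode one amino acid), with an
`all_synonymous` mode available since published analyses do not always
state their denominator. Quadrants follow the biological reading
(1 = A>T and G>C; 3 = T>A and C>G; 4 = A>T and C>G); boundary points are
excluded from quadrant counts.

## Multivariate analysis and clustering

Correspondence analysis is applied to the genes x 59 sense-codon RSCU
matrix (single-codon amino acids excluded; missing family values imputed
as 0 to keep the codon space fixed). This is the codon-usage convention --
CA of RSCU rather than of raw counts -- which removes amino-acid
composition before the decomposition. The implementation is the standard
one: divide by the grand total, form standardized residuals from the
independence model, SVD, principal coordinates; each axis's inertia share
is its squared singular value over the total, and the total inertia equals
the matrix's chi-square statistic divided by the grand total (a property
the test suite verifies against `chisq.test`, and the axis decomposition
against `vegan::cca`). The first four axes are reported by default.

Strain relationships are summarised by agglomerative clustering of
strain-aggregate RSCU vectors: Euclidean distance with average linkage
(UPGMA) by default -- the common default pairing of desktop statistics
packages -- both selectable. The dendrogram is exported as Newick with
merge heights as branch lengths, so it can be compared with
sequence-based phylogenies in standard tree tools. Because distance and
linkage conventions vary across software, topology comparisons with trees
from other programs should be read qualitatively (shared clades), not as
exact reproductions.

## Optimal codons

Genes are ranked by ENC as an expression proxy (lower ENC = stronger bias
= putatively higher expression) and a fraction (default 10%) is taken off
each end, with a minimum of one gene per end, so a 12-gene set yields one
gene per tail; ties break lexically by gene name for determinism. RSCU is
computed on the pooled codon counts of each tail (pooling is robust for
short genes; averaging per-gene RSCU vectors is available behind
`pool = FALSE`), and $\Delta\mathrm{RSCU} = \mathrm{RSCU}_{high} -
\mathrm{RSCU}_{low}$. A codon is *high-frequency* if its overall RSCU
exceeds 1, *highly expressed* if $\Delta\mathrm{RSCU} > 0.08$, and
*optimal* if both -- strict inequalities in all cases, so a codon exactly
at a threshold is not flagged.

## The synthetic data generator

Real mitochondrial panels are downloaded from public archives; to keep
every stage testable without network access, `sim_spec()` /
`simulate_cds()` generate a strains x genes panel with the statistical
structure the analysis assumes. Defaults emulate an 8-strain x 12-gene
AT-rich mitochondrial core-gene set: the canonical gene roster with
lengths 369-2262 nt, per-gene target GC3s spread over 0.06-0.21, a
hydrophobic membrane-protein amino-acid profile (with a basic-residue
profile for rps3, reproducing the sign structure of GRAVY), and a bias
concentration of 3, which lands mean ENC near 30 -- the strong-bias
regime (ENC < 35) typical of such genomes. Under these defaults the
realized composition is about 40% T and 33% A.

Each gene's codons are drawn i.i.d.: amino acids from the profile, then
codons from per-family distributions built in two steps -- a GC3 tilt
(mass `target_gc3` on the G/C-ending codons of the family, split evenly,
the rest on the A/T-ending ones) followed by a Dirichlet draw around the
tilt with concentration `bias_concentration`. An infinite concentration
uses the tilt exactly, which is the pure-mutation-pressure regime: such
genes sit on the expected ENC-GC3s curve up to the curve's own
approximation error. Small concentrations make one codon per family
dominate, driving ENC towards 20. A forced preferred-codon set is
implemented as a multiplicative tilt boost (default 8) applied before the
draw, so the preferred codon dominates its family deterministically in
expectation -- this is what makes forced sets recoverable by the
optimal-codon stage, which a boost that scaled with the concentration
parameter would not guarantee. One master seed yields per-(strain, gene)
substreams via a stable string hash, so adding a gene never perturbs the
others.

For neutrality-plot calibration, `simulate_neutrality_panel()` draws a
per-gene mutational parameter and either couples the amino-acid
frequencies to it (tilting towards amino acids with G/C-rich first and
second codon positions, so GC12 and GC3 co-vary, as shared mutational
pressure would) or leaves them fixed (GC12 independent of GC3). The
fitted p-value separates the two regimes reliably at 50 genes.

What the generator does **not** emulate: phylogenetic correlation between
strains (each strain is an independent draw, so strain trees from
synthetic data have no "true" topology), within-gene spatial structure,
indels/length variation between strains, gene-specific amino-acid
composition beyond the rps3 contrast, and any explicit substitution
process. Passing tests on synthetic data therefore validate the
statistical machinery and its calibration, not claims about any
particular organism.

## Numerical choices and problem sizes

- Tolerances: RSCU family sums, delta-RSCU conservation and CA inertia
  identities are asserted to 1e-9; estimator-versus-oracle agreement for
  ENC likewise.
- The mutation-only ENC-curve check uses 2000-codon genes with target GC3s
  in [0.3, 0.7], where the closed-form expected curve is an accurate
  approximation to the estimator's expectation; at extreme GC3s (below
  ~0.2) the published curve sits 2-3% below the exact class-wise
  expectation, a property of the approximation itself, not of the
  estimator.
- Recovery checks use 12 genes of 2000 codons with the preferred set
  forced in two genes; neutrality calibration uses 100 replicate panels of
  50 genes of 100 codons. The full synthetic study panel is 8 strains x 12
  genes at realistic lengths (~35k codons). These sizes keep the whole
  suite in the low minutes on one core while leaving sampling error well
  inside the asserted margins.
- Degenerate inputs: genes with no synonymous codons report missing (not
  zero) GC3s/x3s/CAI/FOP; constant GC3 makes the neutrality slope missing
  with a warning; identical RSCU rows give zero CA inertia and no axes;
  duplicate strain labels are refused by the clustering stage.

## A worked example

```{r example, eval = FALSE}
library(cubtools)
library(dplyr)

# synthetic 8-strain x 12-gene panel at the default study conditions
seqs <- simulate_cds(sim_spec(seed = 1))
res <- run_codon_pipeline(seqs)

res$strain_summary |> select(strain, enc, gc3s, gravy)
res$neutrality
glance(res$coa[["strain_01"]])
plot_enc_gc3s(res)
plot_pr2(res)
plot(res$tree)

# real data instead: one FASTA or GenBank file per strain
# seqs <- bind_rows(
#   read_cds("strainA.gb", "genbank", strain_id = "A"),
#   read_cds("strainB.fasta", "fasta", strain_id = "B")
# )

write_cub_results(res, "cub-report")
```

## Known limitations

- The genetic code defaults to NCBI table 1 (standard), which treats Met
  and Trp as single-codon and gives the 59-codon multivariate space; for
  fungal mitochondria table 4 (TGA = Trp) is biologically arguable and is
  fully supported (`genetic_code(4)`), but changes Trp's family and hence
  ENC's class census and the codon space. The default is a documented
  convention, not a biological claim.
- CAI/CBI/FOP absolute values depend on the self-contained reference
  conventions described above.
- The RSCU strain tree is a phenetic summary of codon usage, not a
  phylogeny; no sequence-based tree inference is included.
- GenBank parsing covers CDS features with plain, `join()` and
  `complement()` locations -- the forms organellar records use -- not the
  full location grammar (no external references or fuzzy positions beyond
  `<`/`>` trimming).
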