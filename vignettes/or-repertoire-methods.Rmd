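---
title: "Mining and molecular evolution of olfactory receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and molecular evolution of olfactory receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactoR)
```

## The problem

Olfactory receptor (OR) genes form the largest vertebrate multigene family:
single-exon, roughly 1 kb coding sequences encoding seven-transmembrane
(7-TM) class-A GPCRs. Repertoires evolve by birth and death — repeated
duplication, pseudogenization and loss — so any assembly of an OR-rich
region contains a mixture of intact genes, pseudogenes with premature stops
or frameshifts, incomplete gene fragments, and genes cut by contig edges.
In fragmented assemblies the integrity census itself (how many intact genes?
what ratio of disrupted to intact?) is a primary scientific result, and the
intact genes feed downstream questions: do they form lineage-specific
clades, and is there per-site positive selection at candidate
ligand-binding positions?

`olfactoR` implements that workflow end to end — six-frame ORF discovery,
profile-HMM identification, integrity classification, family assignment,
motif/conservation/TM profiling, neighbor-joining phylogenetics with
bootstrap monophyly tests, and recombination-aware per-site selection
analysis (SLAC and FEL) — together with a synthetic-data module that plants
genes of every class, with known families, disruptions, site-specific
dN/dS and recombination breakpoints, so each stage is validated against
ground truth rather than against an irreproducible real dataset.

## ORF discovery

`find_orfs()` scans the six frames of each contig for maximal stop-free
reading stretches (getorf-style). The reported CDS begins at the stretch's
first ATG when one exists and at the stretch start otherwise — start-less
fragments must remain discoverable, or the partial class would be invisible
by construction. Codons containing `N` translate to `X` and never terminate
a stretch (they are missing data, not stops). The default `min_aa = 75`
filter reflects the usual repertoire-mining discard of sub-75-aa
translations; it is applied to the reported CDS, so the cutoff counts the
initiator methionine when present. `edge5`/`edge3` flag stretches that run
into a contig boundary with no in-frame stop context — the operational
definition of a contig-edge-truncated locus, since no fixed distance
threshold is defensible when the reading frame itself is interrupted by the
assembly edge.

## Profile HMM identification

`build_profile_hmm()` estimates a match/insert/delete profile from a seed
alignment: match states are the columns with under 50% gaps; match
emissions are `(counts + w * background) / total` with `w` the pseudocount
weight (default 1, uniform background); insert states emit the background.
Transition probabilities are estimated from the seed paths with a
structured prior: match states strongly self-continue, and delete states
carry a long-extension prior (`D->D = 0.9` before counts). The delete prior
matters: truncated loci and the two pieces flanking a premature stop or
frameshift cover only part of the profile, and without a cheap way to
traverse the unmatched states a 100-aa fragment would pay hundreds of bits
in deletion penalties and fall below any usable threshold. This plays the
role that a second, partial-gene profile plays in classical OR screens.

Scoring is glocal Viterbi (full match path, free flanking sequence) in
log2-odds against an i.i.d. background, implemented in C++. Significance
uses a maximum-likelihood Gumbel fit to the scores of `n_null = 1000`
shuffles of the searched ORFs themselves — length- and composition-matched
nulls are essential here because OR-like amino-acid composition alone is
worth hundreds of bits against an OR profile; shuffled-input calibration
absorbs exactly that. The E-value is the fitted upper tail times the number
of ORFs searched, with the classical `1e-10` acceptance cutoff. Because the
null is built from the input set, E-values are calibrated per search, not
transferable across searches.

## Integrity classification

`classify_repertoire()` applies the precedence rules used for
fragmented-assembly censuses:

1. **truncated** — the reading stretch is cut by a contig edge;
2. **pseudogene** — a premature in-frame stop or an inferred frameshift
   interrupts an otherwise full-span locus. Disruption partners are two
   same-contig, same-strand profile hits whose pieces jointly reconstruct
   about one profile length; same-frame partners are premature-stop pairs,
   different-frame partners within 100 nt are frameshift pairs, and the
   pieces merge into one gene record;
3. **intact** — start and stop present and CDS length within 10% of the
   profile length;
4. **partial** — anything else (incomplete coding region internal to a
   contig).

Partner pairing prefers envelope complementarity (the second piece
continues the profile where the first stopped), but because the seven TM
helices share hydrophobic composition, the Viterbi envelope of a 3'
fragment can drift toward N-terminal match states; pairing therefore also
accepts length complementarity — the genomic span of the merged pieces
covering roughly one profile length (0.7–1.25x). Proximity
is measured between reading stretches, not reported CDSs, because a late
first ATG can push a reported CDS hundreds of nucleotides downstream of the
interrupting stop. The same-frame window (600 nt) is wider than the
frameshift window (100 nt) for that reason.

`summarize_repertoire()` reports counts by family and integrity, clade
totals, the non-edge breakdown with round-half-up percentages (so 20 of 56
prints as 36%), and the (pseudogene + partial) : intact ratio.
`loci_per_scaffold()` reports locus counts per scaffold and end-to-start
gaps for multi-locus scaffolds.

## Annotation

Family assignment is best-identity global alignment (BLOSUM62
Needleman–Wunsch via Biostrings) against a family-tagged panel, identity
computed over aligned residue pairs excluding gap positions; below the 0.4
identity floor a gene is `unknown`. The floor separates OR subfamilies
(typically 30–40% apart) while tolerating within-family divergence; it is a
config knob. `scan_motifs()` reports the canonical MAYDRYVAIC (up to 2
mismatches) and F-S-T-C-(L|P)-H (1 mismatch outside the bracket) motifs and
all cysteines. `conservation_profile()` computes per-column amino-acid
frequencies (gaps ignored) and information content `log2(20) - H`, the
sequence-logo scale; the small-sample correction is off by default because
the synthetic studies compare columns within one alignment, where the
correction cancels. `predict_tm_domains()` is Kyte–Doolittle sliding-window
hydropathy (window 19, threshold 1.6), with above-threshold runs extended
to at least 17 and split above 25 residues, numbered TM1–TMn; loops
alternate IC/EC assuming the extracellular N-terminus of class-A GPCRs, so
MAYDRYVAIC sits at the TM3–IC2 boundary and F-S-T-C-(L|P)-H at the end of
IC3 on the packaged template geometry.

## Phylogenetics

Distances are per-pair p-distances over shared non-gap columns with Poisson
correction `d = -ln(1 - p)`; pairs at `p >= 0.95` are flagged saturated and
capped at the largest finite corrected distance rather than propagating
infinities. `nj_tree()` is Saitou–Nei neighbor joining (C++) with two fixed
conventions: ties in the Q criterion break on the lexicographically
smallest pair of cluster representative labels, and negative branch-length
estimates are clamped to zero with the deficit moved to the sibling branch,
so trees are always valid and runs are reproducible. On additive matrices
NJ is exact, which the tests verify against independently constructed
trees. `bootstrap_support()` is the Felsenstein column bootstrap with
bipartition frequencies mapped onto the full-data tree — a 0–100 nodal
support convention. `is_monophyletic()` roots on a designated outgroup and
asks whether a taxon set is exactly some node's leaf set, returning that
node's support. Maximum-likelihood tree search and substitution-model
selection are out of scope.

## Codon models and per-site selection

Selection analyses run on codon alignments threaded from the protein MSA
and the CDSs (`thread_codon_alignment()`), over the 61 sense codons of the
standard code; gaps and ambiguous codons are missing data, and internal
stops are an error, so the codon model is never asked to explain a
pseudogene — which is why the pipeline restricts selection to intact genes.

The engine is MG94-with-HKY: single-nucleotide codon changes at rate
`kappa^[transition] * (alpha | beta)` for synonymous / nonsynonymous
changes, equal codon frequencies (matching the uniform-codon synthetic
generator; F1x4 would be a straightforward extension but is not needed for
the packaged studies). With uniform frequencies the rate matrix is
symmetric, so likelihoods come from one symmetric eigendecomposition per
rate pair, and `P(t)v` is applied in eigenspace without forming `P` — this,
plus the identity `Q(alpha, beta) = alpha * Q(1, beta/alpha)` that lets the
per-site FEL optimization profile over `omega = beta/alpha` with `alpha` as
a free eigenvalue scale, keeps a 20-replicate 18-taxon x 312-codon
calibration study in minutes on one CPU. Branch lengths are in expected
substitutions per codon site at the neutral (`omega = 1`) reference rate.

**SLAC** reconstructs ancestral codons by Fitch parsimony (multifurcations
resolved to binary with zero-length edges so counts are exact and
root-invariant; ties break toward the lexicographically smallest codon),
counts synonymous and nonsynonymous changes per site over branches with
multi-nucleotide changes averaged over all minimal mutational paths
(stop-free paths preferred, equal weights), and tests the synonymous count
against the site's expected synonymous fraction with the extended
(real-valued) binomial tail matching the observed deviation — too few
synonymous changes is the positive-selection tail. The expected fraction is
the kappa-weighted synonymous proportion of the site's observed codons;
kappa is taken from the single-omega model fit by default. Sites with no
inferred changes are neutral with p = 1.

**FEL** fits `kappa`, a branch-length scale and a shared omega globally,
then per site maximizes the likelihood over `(alpha, beta)` and over the
constrained `beta = alpha` model, with `2 * delta-logLik` against
chi-squared with 1 df. The chi-squared null is slightly conservative at the
`beta = 0` boundary; we accept that in exchange for simplicity. Positive
calls require `beta > alpha` and `p < 0.1`, the classical screening level.

**Breakpoints** (`detect_breakpoints()`): for every candidate split in
`[margin, S - margin]` the two partitions get their own NJ trees
(p-distances from prefix sums, so the scan is linear in candidates), scored
by the summed squared misfit between tree distances and the partition's own
distance matrix. The improvement of the two-tree fit over the single
full-data tree is weighted by partition size — p-distance noise scales as
1/sites, and unweighted misfits would let a small partition's tree overfit
noise and pin every scan to the margins. Significance is an empirical
upper-tail p from permutations of column order (which preserve composition
but destroy positional signal); a breakpoint is reported only at p < 0.05,
and downstream selection then runs per partition with its own tree.

`integrate_sites()` combines per-method positive-site lists into explicit
tiers (all methods / at least k / any); externally computed site lists
(e.g. REL or MEME run elsewhere) are accepted as plain site vectors, since
those methods' hierarchical-Bayes and mixture machinery is out of scope
here.

## The synthetic-data module

`make_or_template()` builds a 312-aa 7-TM protein on the canonical OR
layout — seven 23-residue strongly hydrophobic stretches separated by
hydrophilic loops, with MAYDRYVAIC straddling the TM3–IC2 boundary,
F-S-T-C-L-H ending IC3, one cysteine in each of EC1/EC2 and a proline in
TM7 at fixed, recorded positions. Families are derived by substituting 35%
of non-motif positions; genes diverge from their family template by i.i.d.
substitutions outside motif positions (motifs are conserved in real
repertoires, and keeping them fixed is what keeps them detectable);
back-translation uses uniform codon usage (no codon-bias model — SLAC and
FEL do not model bias either). `plant_genes()` assembles one contig per
element with at least 1 kb flanks, an in-frame stop immediately upstream of
every gene (and shortly downstream of stop-less partials) so planted
reading stretches have well-defined boundaries, and class-specific
disruptions: one premature stop or a 1–2 nt frameshifting indel at codons
90–215 (both resulting pieces stay reportable at the 75-aa filter, enforced
by resampling the disruption position against the known translation),
missing start and/or stop for partials (60–100 codons removed), edge cuts
for truncated genes (85–230 codons kept), and composition-matched
random-codon decoys guaranteed free of the MAYDRYVAIC motif. Everything is
byte-identical per seed.

`simulate_codon_alignment()` evolves sites independently under the same
MG94 process used for inference, with per-site omega and an optional
breakpoint switching to a second topology. The default study conditions are
18 taxa by 312 codons — the scale of a full-length OR gene set — on random
topologies with exponential branch lengths of mean 0.1, i.e. a total tree
length near 3.5 neutral substitutions per codon site. That is the moderate
depth typical of a recently expanded within-species paralog set and is deep
enough for counting methods to see several changes per site, which is what
"moderate" has to mean for a parsimony-based method to have power; it is
fixed once here and reused by all packaged studies.

What the generator does **not** emulate: repeats and segmental
duplications, sequencing error, assembly chimerism, codon-usage and GC
biases, introns, and alignment error (the in-pipeline MSA comes from the
profile, and an externally curated alignment can be supplied instead).
Passing the recovery suites therefore demonstrates the logic of each stage
under clean, known conditions — not robustness to every artifact of real
assemblies.

## Numerical and design choices

- Internal coordinates are 0-based half-open on the forward strand;
  conversion to 1-based inclusive happens only in the GFF3 writer.
- Site indices in selection reports are 1-based alignment coordinates.
- Gumbel fitting is by Nelder–Mead maximum likelihood from
  moment-estimator starts; upper tails below ~1e-13 switch to the
  asymptotic `exp(-z)` form to avoid underflow.
- Pruning partials are rescaled per node when they drop below 1e-150;
  per-site log-likelihoods accumulate the scale.
- FEL's outer (omega) golden-section search runs on `log omega` in
  [-13.8, 5.3] with tolerance 5e-3, the inner alpha search with 1e-4;
  non-finite optima are flagged non-converged with p = 1.
- The profile-likelihood CI for the global omega is the 1-df likelihood
  ratio at 95%, bracketed by doubling and solved by `uniroot`.
- The packaged census table carries the printed integrity breakdown of a
  220-gene repertoire; two unplaced genes lack a printed breakdown, so the
  integrity columns sum to 218 while the gene-count column sums to 220 —
  the table is stored as printed, not "repaired".

## Validation studies packaged as tests

The test suite regenerates every fixture in code and checks, among others:
ORF discovery against a brute-force six-frame enumerator (100 random 50-kb
contigs); Viterbi against exhaustive path enumeration on toy profiles;
pruning likelihoods against exhaustive ancestral-state summation on 3–4
taxon toys (1e-10 relative); NJ exactness on additive matrices; exact
class-count recovery on a planted 20/15/21/162 repertoire with 50 decoys at
divergence 0.1 and zero decoy hits at E <= 1e-10; SLAC/FEL false-positive
rates at most 0.15 under omega = 1 (18 x 312, 20 replicates) with SLAC
power at least 30% on omega = 5 sites; and breakpoint recovery within 10
codons in at least 80% of replicates with at most 10% false reports. The
problem sizes above are the packaged defaults of the study conditions;
`scripts/acceptance.R` re-runs the same studies at slightly reduced
replicate counts and reports the measured quantities as JSON.

## Known limitations

- E-values are calibrated against shuffled inputs, so they measure
  "better than composition-matched noise", not HMMER-comparable database
  E-values.
- The integrity rules assume one profile length; a mixed-length OR family
  (e.g. with indel-rich members) would blur the intact length band.
- SLAC inherits parsimony's undercounting at high divergence; FEL's
  chi-squared null is conservative at boundary hypotheses.
- The breakpoint scan models exactly one breakpoint; multiple breakpoints
  would be found (at best) one at a time.
- Equal codon frequencies are assumed throughout the codon machinery.
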