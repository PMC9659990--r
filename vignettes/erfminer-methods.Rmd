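---
title: "Methods: AP2/ERF family mining and ripening expression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AP2/ERF family mining and ripening expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erfminer)
```

# Scope

erfminer implements a desk-scale version of a genome-wide transcription
factor family study of the kind routinely carried out for plant AP2/ERF
superfamilies: identify and classify the family members of a genome,
characterise their gene structures, motifs and molecular evolution, and mine
several expression datasets to nominate the small set of genes most likely
to regulate a developmental transition — here, fruit ripening. Every stage
is a tested, reusable function; deterministic generators produce synthetic
inputs with planted ground truth so the whole pipeline is verifiable
without any external downloads.

# Family identification and classification

## Candidate merging

Family candidates typically come from two screens — homolog alignment
against a reference proteome and a profile-domain search. `merge_candidates()`
takes the union of the two id sets, removes redundancy, and keeps only ids
whose domain content passed an independent confirmation step.

## Subfamily calls from domain architecture

The AP2/ERF superfamily is defined by the ~60–70 aa AP2 DNA-binding domain.
`classify_subfamily()` applies the canonical architecture rules to a
protein's domain-hit table:

* at least one AP2 **and** at least one B3 domain → **RAV**;
* two or more AP2 domains (no B3) → **AP2**;
* exactly one AP2 domain → resolved by sequence (below), because
  single-domain proteins occur in the AP2 subfamily and the divergent
  *soloist* is indistinguishable from an ERF by architecture alone.

Domain hits are consumed from a tab-separated table (protein_id, domain,
start, end, score), the summary a `hmmsearch --domtblout` run reduces to.
We deliberately do not re-implement profile HMMs; a minimal consensus-block
scanner (`scan_consensus_domains()`) exists only so the synthetic fixtures
can be analysed end to end without an external search tool.

## Subgroup assignment by nearest labeled reference

Published family studies subdivide the ERF subfamily into 15 subclasses
(Ia–Xb) by placing proteins on a maximum-likelihood tree beside labeled
reference homologs. A bootstrapped ML phylogeny is neither deterministic nor
desk-scale, so erfminer replaces it with its operational core: the label of
the reference the protein would cluster with. `assign_subgroup()` aligns the
query globally (Needleman–Wunsch with affine gaps) against every entry of a
labeled reference panel and returns the best-scoring entry's label.
Defaults are the standard protein alignment parameters — BLOSUM62, gap open
10, gap extend 1 — all overridable. Exact score ties go to the
lexicographically smallest reference id, which makes the assignment
invariant to panel order. The panel format is a FASTA whose descriptions
read `id|subgroup`.

Two consequences of this design are worth stating. First, the *soloist*
call is purely nearest-reference: the original criterion ("significantly
different sequence and gene structure") is not operationalisable as a
closed rule, so a soloist exemplar in the panel stands for it. Second, a
RAV whose B3 hit was missed by the domain scanner still ends up called RAV
when its nearest reference is the RAV exemplar — sequence evidence degrades
the call gracefully rather than silently mislabeling it, and the synthetic
B3-dropout tests pin this behaviour down.

## Activation/repression motifs

`detect_cterm_motifs()` scans for three short functional motifs:

* **EAR** repression motif, `(L/F)DLN(L/F)(x)P`;
* **R/K-LFGV** repression motif, `(R/K)LFGV`;
* **EDLL** acidic activation motif, literal `EDLL`.

Whether such scans should be restricted to the C-terminal region is usually
implied rather than stated in the literature; erfminer scans the whole
sequence and annotates each hit with the sequence third containing it
(N-terminal, middle, C-terminal), so downstream filtering loses nothing.
Matches of one pattern are non-overlapping; the ambiguity letter X never
satisfies a motif class, including the wildcard position (a conservative
reading of ambiguous residues). The broader `LxLxL` EAR variant found in
the wider literature is available via `default_motif_patterns(ear_lxlxl =
TRUE)` but off by default; the stricter pattern is the one the family
literature uses.

## Protein properties

`protein_properties()` reports residue count, molecular weight (sum of
average residue masses plus one water, 18.0153 Da) and isoelectric point.
The pI is the root of the Henderson–Hasselbalch net-charge equation with
EMBOSS-style pKa values (N-terminus 8.6, C-terminus 3.6; K 10.8, R 12.5,
H 6.5; D 3.9, E 4.1, C 8.5, Y 10.1), found by bisection on pH 0–14 to a
tolerance of 0.01 pH units. X contributes length but neither mass nor
charge. Absolute pI values depend on the pKa table chosen — comparisons
between proteins computed with the same table are meaningful, comparisons
with other tools to more than ~0.5 pH are not.

# Gene structure

`read_gene_models()` parses GFF3 gene/mRNA/exon/CDS rows, keeping the
format's 1-based inclusive coordinates throughout to avoid off-by-one
errors against the interchange format. Genes without an mRNA child but with
direct exon children are accepted as a single implicit transcript, which
tolerates minimal annotations. Intron counts (`count_introns()`) are exon
count minus one on the *longest* transcript (greatest summed exon length;
ties to the lexicographically smallest transcript id) — annotation sources
rarely say which isoform a published count refers to, and the longest
transcript is the convention gene-structure figures follow. Counts use exon
rows rather than CDS rows so UTR-containing exons are respected.
`intron_class()` applies the standard eukaryotic classes: intron-less (0),
intron-poor (1–3), intron-rich (>3).

# Duplication and molecular evolution

## Duplication typing

`classify_duplication()` types a paralog pair with block evidence taking
precedence: any pair inside a within-species collinear block is
**segmental**; otherwise a pair on one chromosome with at most `max_gap`
(default 5) intervening gene models is **tandem**; everything else —
including genes not placed on any chromosome — is **dispersed**, with the
evidence string recording why. The 5-gene window mirrors common
collinearity-tool conventions and is configurable. Collinear blocks are
consumed as input (block_id, species, gene columns); detecting them is a
separate, solved problem that erfminer does not re-solve.
`find_paralog_pairs()` offers simple alignment-based pair discovery
(identity = matches / alignment length ≥ 0.70, mutual length coverage ≥
0.75 by default) for workflows without an external pair list.

## Ka/Ks by Nei–Gojobori (1986)

Study pipelines usually delegate Ka/Ks to a calculator binary without
recording the model. erfminer implements NG86 with Jukes–Cantor correction
as its single, fully specified method — it is the canonical counting
method, every intermediate quantity (S, N, Sd, Nd, pS, pN) is exposed, and
an exhaustive oracle can verify it exactly. Absolute values can differ from
model-averaged calculators (e.g. γ-MYN) especially at high divergence;
within-study comparisons are unaffected.

Definitions, per aligned codon pair:

* **Sites.** At each codon position the synonymous fraction is the number
  of the three possible single-base changes that preserve the amino acid,
  divided by 3. Changes *to stop codons count as nonsynonymous*, so
  S + N = 3 × codons exactly. S is averaged over the two sequences.
* **Differences.** For a codon differing at k positions, all k! orderings
  of single-step changes are enumerated; orderings passing through a stop
  codon are excluded; synonymous/nonsynonymous step counts are averaged
  over the remaining orderings. If every ordering is blocked by stops (a
  rare corner), the codon contributes its raw differences split in
  proportion to the mean synonymous fraction at the differing positions.
* **Correction.** pS = Sd/S, pN = Nd/N, and
  Ks = −(3/4)·ln(1 − (4/3)·pS), likewise Ka. A correction argument ≤ 0
  (saturation) yields NA — never a negative rate. Ka/Ks is NA when Ks is 0
  or NA.

## Divergence dating

`divergence_time()` applies the molecular clock T = Ks / (2λ) × 10⁻⁶ Mya
with the plant synonymous rate λ = 6.1 × 10⁻⁹ substitutions/site/year by
default. Times are conventionally reported to two decimals; the function
returns full precision and the CLI rounds. Saturated (NA) Ks propagates to
NA rather than an arbitrarily large age.

`conserved_across()` intersects per-species sets of focal genes found in
syntenic pairs, the standard "conserved in all n species" statistic.

# The three-dataset expression screen

## Normalisation and thresholds

`compute_fpkm()` and `compute_tpm()` implement the textbook definitions
(FPKM = count·10⁹ / (length · library size); TPM = length-normalised rate
scaled to 10⁶ per sample). Ratio rules all operate on whichever unit a
dataset declares; in the reference design the developmental dataset is
FPKM and the other two TPM.

Thresholds follow the printed rules exactly, with boundary behaviour pinned
by tests:

| rule | statistic | label |
|---|---|---|
| expressed | max over samples ≥ 20 (inclusive) | analysed |
| level group | max FPKM in [0,20) / [20,300) / [300,∞) | C / B / A |
| dominance | Σ flesh / Σ peel > 5 or < 0.2 (strict) | flesh / peel |
| ripening correlation | Σ stages 4–6 / Σ stages 1–3 > 2 or < 0.5 (strict), per tissue | positive / negative |
| DEG | \|log2 FC\| ≥ 1 (inclusive), optional BH-adjusted p < 0.05 | up / down |

Two boundary conventions had to be decided. The published level groups
overlap at 20 FPKM and cap A at the observed maximum; a partition requires
half-open bins, so erfminer uses [0,20), [20,300), [300,∞) and treats the
observed maximum as descriptive. Zero denominators with positive numerators
are treated as infinite ratios (flesh-dominant / positively correlated);
0/0 is "none". The expression filter is applied to the full matrix before
any tissue splitting.

## DEG calling

`call_degs()` computes log2((mean_case + 1)/(mean_control + 1)) — the
pseudocount (configurable) keeps fold changes bounded when a condition mean
is zero. The statistical test is optional: `test = "none"` reproduces the
fold-change-only rule that treatment/pollination comparisons typically use,
and `test = "welch"` adds a Welch t-test on log2(x + 1) with
Benjamini–Hochberg adjustment across genes — BH being the field's default
when a study says only "adjusted p". `bh_adjust()` is the standard step-up
procedure (monotone, capped at 1) and is verified against a brute-force
definition in the test suite.

## Intersection screen

`run_screen()` wires the stages together: per-dataset expression filter,
level groups, dominance and correlation on the developmental dataset, DEGs
for every ripening comparison, and the cross-dataset intersection
(`intersect_screen()`): a gene is a **key candidate** iff it is
differentially regulated, in either direction, in at least one comparison
of *every* comparison group. The default comparisons
(`default_screen_comparisons()`) contrast the riper against the less-ripe
member within each dataset: stage 6 vs 5 per tissue; ethephon-treated vs
control at days 4 and 6 per tissue; 100% vs 60% ripeness per pollination
treatment and tissue. In the source study's dataset the developmental
comparisons are printed as "F6/F5 and R6/R5" although that dataset has
flesh and peel, not receptacle; erfminer reads them as the two tissues the
dataset actually contains (flesh and peel), a tissue-consistency decision
the comparison builder makes explicit and overridable.

`delta_delta_ct()` (2^−ΔΔCT relative quantification against a reference
gene and calibrator sample) and `spearman_coexpression()` (rank correlation
with average ranks; a constant gene yields an NA row and column, the
diagonal-1 convention applying only to non-degenerate genes) support the
validation and co-expression steps.

# Synthetic data and what the tests do (and do not) show

The generators in `make_family_fixture()`, `make_annotation_fixture()`,
`make_codon_fixture()` and `make_expression_fixture()` are pure functions
of a `sim_config()` seed; their defaults *are* the study conditions:

* **Family**: 119 proteins planted as 95 ERF / 20 AP2 / 3 RAV / 1 soloist,
  six of the AP2s carrying a single domain; members are mutated copies
  (8% substitutions) of their subgroup exemplar with fixed consensus domain
  blocks at recorded coordinates; EAR/EDLL/R-K-LFGV motifs planted into
  designated members, one ERF carrying EAR in both the middle and the
  C-terminus. Optional boundary jitter and B3 dropout emulate scanner
  noise.
* **Annotation**: a 4-chromosome toy genome with planted exon counts
  (including one 12-exon gene), an adjacent tandem pair, a block-registered
  cross-chromosome segmental pair, mixed strands and a near-edge gene that
  forces promoter truncation.
* **Codon pairs**: substitutions are planted per position with probability
  pS*·f (synonymous) and pN*·(1−f) (nonsynonymous), where f is the
  position's synonymous site fraction and pS*, pN* the Jukes–Cantor
  expected difference proportions for the target rates — a per-site
  Bernoulli thinning of the Poisson substitution process that makes the
  estimator's expected value the target by construction. Stops are never
  introduced.
* **Expression**: negative-binomial counts (size 50, i.e. ~2% extra-Poisson
  noise) for the three designs (6 stages × 2 tissues; treated/control ×
  3 days × 2 tissues; 2 pollination modes × 2 ripeness levels × 2 tissues;
  3 replicates everywhere) over a 200-gene universe plus 300 filler genes
  that absorb the remaining library mass so realized FPKM/TPM values sit
  near their targets. Effects are multiplicative on the mean — 6× for
  dominance and DEGs, 3× for ripening correlation — so every ratio rule's
  expected value is known analytically and sits safely off its threshold.
  Seven key genes (five up, two down) are planted as differentially
  regulated in every comparison group, mirroring the six-ERFs-plus-one-RAV
  outcome such screens aim for.

Passing the planted-recovery tests shows the *rules* are implemented
exactly and are robust at these noise levels; it does not show that real
fig data would be classified correctly. The generators deliberately omit
isoform complexity, mapping bias, GC/length effects on counts, batch
structure, correlated genes and phylogenetic autocorrelation among family
members. Numbers tied to the real genome and SRA datasets (119 members, 83
expressed, the specific key genes, the 0.05–0.57 Ka/Ks range, 1.81–379.01
Mya) are properties of those data, not of this implementation, and are not
reproduced here.

# Numerical choices and problem sizes

* pI bisection tolerance 0.01 pH; TPM column-sum invariant holds to 1e-6
  relative; NG86 intermediates are exact rational arithmetic in doubles and
  verified to 1e-9 against an exhaustive oracle.
* Alignment ties, transcript-length ties and panel order are all resolved
  lexicographically, making every classification deterministic.
* The test and acceptance runs use desk-scale sizes chosen to keep the full
  suite under a couple of minutes while leaving no rule unexercised:
  10,000 oracle codon pairs, 200 estimator replicates at 300 codons, the
  119-protein family, a 500-gene three-dataset expression bundle, and 1,000
  random BH vectors.

# Known limitations

* Subgroup assignment is only as good as the reference panel; a query
  distant from every exemplar still receives the nearest label, with the
  alignment score as the only confidence signal.
* NG86 underestimates rates at high divergence and reports saturation as
  NA; for dating old duplications a maximum-likelihood model would be more
  appropriate.
* The promoter scanner is pattern counting, not PWM scoring, and the
  shipped cis-element catalog is illustrative, not a registry.
* DEG calling is mean/fold-change based (optionally Welch); it is not a
  dispersion-modelled negative-binomial GLM and is not intended to replace
  one for genome-wide inference.
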