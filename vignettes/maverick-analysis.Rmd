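---
title: "Models and methods behind mavkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mavkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mavkit analyses Maverick/Polinton elements — large (roughly 12–25 kb)
virus-like DNA transposons of eukaryotes that encode a protein-primed
family-B DNA polymerase (pPOLB), a retroviral-like integrase (INT) and
capsid-protein homologs, are bounded by terminal inverted repeats (TIRs),
and generate a perfect 6-bp target site duplication (TSD) on integration.
This vignette explains the models implemented, the choices that were
genuinely open, and what the synthetic-data tests do and do not show.

## Discovery model

Candidate loci are found by a translated homology scan: the INT and pPOLB
peptides are aligned (exact Smith–Waterman, affine gaps, BLOSUM62 with
gap open 11 / extend 1 — the BLAST protein defaults) against all six
reading frames of each contig. A candidate region is an (INT, pPOLB) hit
pair on one contig separated by 4–40 kb (separation measured between the
nearest ends of the two hits, consistent with the gene spacing inside an
element), extended by 20-kb flanks. The scan reports raw scores, not
E-values: E-value calibration depends on database size, whereas a raw
threshold (default 100) is reproducible; on random host sequence the
expected maximal local score for these seeds is ≈ 45–50, so the default
sits far above the noise floor while true gene hits score in the
thousands.

## Boundary mapping

Within a candidate region, TIRs are sought as reverse-complementary arm
pairs: every arm pair lies on an anti-diagonal of the self-comparison
matrix, and each anti-diagonal is scanned exhaustively for the window
maximising matches (= length × identity) subject to identity ≥ 0.8 and
arm length in [46, 1447] bp — the identity floor admits the imperfect
repeats real elements carry while random 1-kb sequence qualifies in
fewer than 5% of draws. For long sequences only anti-diagonals holding an
exact 12-mer seed are scanned; a window-of-minimal-length prefilter makes
this exact rather than heuristic for any window that could qualify.

The maximal-match window systematically overshoots an exact repeat by a
bounded amount (chance matches at ~25% density can be absorbed while
overall identity stays above 0.8), so the arm edges are only provisional.
The element boundary is settled by an arbiter: candidate start/end
positions near the arm edges where a family end-motif sits at both
termini (5'-(AGT)2…(ACT)2-3', 5'-(AG)3…(CT)3-3' or
5'-(AC)3A…T(GT)3-3'; overlapping motif occurrences are enumerated, since
repeat motifs overlap themselves) and the 6-mers immediately outside the
boundaries match exactly — the perfect TSD. A valid TSD wins; ties go to
the longer element. Without a motif only a ±10 bp TSD-consistent
adjustment is allowed, because an unconstrained TSD search over a ±160 bp
window would admit ≈ 25 chance 6-mer coincidences.

Termini are modelled with a position frequency matrix over the first 200
bp of aligned 5' TIRs (pseudocount 0.5), scanned as summed log2-odds
against a uniform background on both strands; this is a deliberate
simplification of profile HMMs — with a fixed 200-bp window, match-state
scoring is adequate and exactly testable, at the price of not modelling
indels within the terminus. Iterative refinement rebuilds profiles per
species/end-motif partition from resolved elements, rescans unresolved
candidates, and accepts new elements only with a perfect TSD; the
accepted set grows monotonically and the loop stops at a fixpoint or
after five rounds. Per-position conservation is summarised as
information content, IC = 2 + Σᵢ pᵢ log2 pᵢ bits with gaps excluded and
frequencies renormalised over A, C, G, T.

## Intact versus fossil

Gene content is assessed without splice modelling: intact vertebrate
Mavericks have intronless genes, so ORFs of ≥ 100 codons are extracted
from all six frames and assigned to the nine core-gene peptide references
(ppolb, atp, pm, pz / int, mcp, pw, Mcp, pro) by local alignment, one ORF
per gene, requiring ≥ 90% reference coverage for a "clean" call (the
coverage floor prevents a stop-split fragment from passing as a full
gene). Genes without a clean ORF are probed by frame-aware comparison to
report lesions: internal stops counted inside the matched span,
frameshifts when reference coverage splits across frames, and insertions
when ≥ 50 bp of extra DNA interrupts a match. An element is intact iff
the eight conserved genes (pm is detected but excluded from the
criterion, which predates its description; seven suffice under the
Xenopus-like flag) are clean, TIRs are discernible, and the TSD is
perfect. Module layout is classified from strand patterns as convergent
(the conserved state), divergent or same-strand.

## Alignment quality statistics

Candidate protein alignments are compared on summary statistics:
alignment length, ungapped sequence lengths, residue content, average
pairwise identity (computed over sites ungapped in both rows — gapped
sites say nothing about residue agreement), mean Shannon entropy in bits
(log base 2; gaps and X excluded, stated here because the base is a
convention), and mean pairwise distances under four corrections:
observed p; Jukes–Cantor generalised to alphabet size q
(−((q−1)/q)·ln(1 − qp/(q−1)), q = 20 for proteins so the same family of
corrections serves both alphabets); Poisson −ln(1−p); and Gamma
α((1−p)^(−1/α) − 1) with shape α defaulting to 1 (configurable; Gamma
converges to Poisson as α → ∞). Saturated comparisons (p at or past a
model's singularity) are flagged rather than silently dropped. Ranking
aggregates per-criterion ranks by mean rank — a deterministic stand-in
for what is otherwise a qualitative choice — with ties broken by higher
average identity, then input order.

## Orthology and ages

Orthologous insertions are detected from host context: 2-kb flanks
(excluding both TSD copies), reciprocal left–left and right–right local
alignments at identity ≥ 0.7 over ≥ 200 bp, then large-scale colinearity
by exact k-mer anchors chained monotonically (longest increasing
subsequence), scored as the fraction of flank positions covered, with
acceptance at ≥ 0.5 on both flanks and a 10-kb walk-out when no TIRs
delimit the element. The anchor size default is 12: a run-length
calculation shows exact 32-mers essentially vanish at the 5–10%
divergences orthologous flanks reach (expected covered fraction ≪ 0.5 at
5% mismatch density), while chance 12-mer collisions between unrelated
2-kb flanks contribute negligible coverage — so 12 separates the two
hypotheses where 32 cannot. Groups are connected components of the
accepted-pair graph. A group's age is a lower bound only: the tabulated
divergence of the carriers' most recent common ancestor. For dating
priors, the reported mean and 95% bounds become a lognormal with
real-space mean fixed and the smallest σ whose central 95% interval
contains the bounds; on (0, z₀.₉₇₅] both quantile constraints are
monotone in σ, so the minimal σ is found by bisection to |Δσ| < 1e-8.

## Cophylogenetics

Four event classes govern element/host coevolution: cospeciation,
duplication, host switch, loss. The simulator sends parasite lineages
down the host tree, drawing one event per lineage per host node; host
switches land on an edge alive at that time. Event probabilities are
inferred by multi-round rejection ABC (five rounds, tolerance 0.1):
round 1 draws from a flat Dirichlet, later rounds from a Dirichlet
kernel (concentration 100) around the previously accepted draws, with
normalised Euclidean distance on a summary vector of lineage survival
count, parasite tip and internal-node counts, the four event counts of a
unit-cost reconciliation, and host-tip coverage. Two design points
matter. First, each draw is simulated once and extinction rejects the
draw: the observed system did survive, and resimulating until survival
conditions the model on survival, which empirically collapses the loss
posterior onto the prior. Second, observed systems are treated as
several independent parasite lineages on one host tree (the realistic
situation — many element insertions per host clade); a single parasite
tree leaves a growth-versus-loss ridge in parameter space that multiple
lineages and the survival count break.

Reconciliation maps each parasite node to a host edge with event costs
cᵢ = −ln pᵢ (zero probability → infinite cost, i.e. the event is
disallowed), minimising total cost by dynamic programming over
(parasite node × host edge), with losses charged per host node passed
and switches restricted to time-overlapping, non-ancestral edges. Ties
break toward fewer switches (implemented as an infinitesimal switch
surcharge inside the DP; the reported total is replayed from the event
multiset at the true costs), then lowest host-edge id. Branches on which
a switch occurred feed the switch/no-switch codon model.

## Selection

Codon alignments are built by threading codons under a protein guide
alignment (every residue becomes its source codon, every gap a codon
triple). The substitution model is the standard 61-sense-codon process:
single-nucleotide changes at rate πⱼ, × κ for transitions, × ω for
nonsynonymous changes, scaled to one expected substitution per codon per
unit branch length, F1x4 or F61 frequencies optional (uniform default).
Likelihoods use Felsenstein pruning with per-pattern rescaling (the
kernel is C++ for speed; the test suite checks it against direct
summation over all internal states). Branch models: ω = 1 (neutral),
one-ratio, internal/terminal (terminal = pendant edges of the unrooted
tree), and switch/no-switch from the reconciliation labels, which are
carried through unrooting by matching tip bipartitions. Fitting is
bounded quasi-Newton on log-parameters with three starts (one start is
the neutral point, which guarantees the one-ratio optimum dominates the
neutral model as nesting requires); nested models are compared by the
χ² LRT, non-nested ones by AIC.

## Test conditions and their limits

The synthetic generator reproduces the features the analysis relies on:
the two-module gene layout, exact-reverse-complement TIRs opening with a
family motif, perfect 6-bp TSDs from the insertion-site 6-mer, fossils
with stop codons, 1-bp frameshifts, insertions and eroded TIRs, i.i.d.
host background, clade-restricted orthologous insertions with
substitution-diverged flanks, event-based cophylogenies, and codon data
from the exact model that is later fitted. It deliberately omits host
repeats, nested secondary insertions, within-family TIR divergence
beyond point substitutions, and real codon-usage bias. Passing tests
therefore demonstrate internal correctness and recoverability under the
stated model, not performance on repeat-rich genomes, which would
additionally need masking (out of scope here).

Problem sizes used by the test suite and the acceptance script were
chosen to exercise the methods at desk scale: 100 discovery round-trip
genomes of ~8 kb host sequence plus one 12.7–14.3 kb element (sizes and
TIR lengths cycled across the observed ranges); ABC at 2,000 simulations
per round for five rounds with five observed lineages on a six-tip host;
codon-model recovery at 2,000 codons on six-tip trees with branch
lengths 0.25 (long enough that even ω = 0.001 leaves ~10 expected
nonsynonymous events, so a factor-two recovery criterion is statistically
meaningful); and 500 two-taxon replicates for the LRT null calibration.
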