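---
title: "Methods: structure-based target prediction and transcriptome concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based target prediction and transcriptome concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetwise)
```

# The model

`targetwise` operationalizes a simple but powerful idea from systems
pharmacology: a drug's biological effects can be predicted from chemistry
alone, by transferring target annotations from structurally similar
compounds, and such predictions gain credibility when an independent
omics readout points at the same biology.

The prediction is a composition of five steps per drug:

1. **Metabolite generation.** Empirical phase-I biotransformation rules
   (ester hydrolysis, amide hydrolysis, aromatic hydroxylation,
   O-demethylation by default) are applied to the parent structure. Rules
   are substructure queries paired with graph transformations; every
   matching site yields one product, duplicates are collapsed by canonical
   SMILES. Metabolites matter because the circulating active species often
   is not the parent — fenofibrate's hydrolysis to fenofibric acid is the
   canonical example, and it is this package's anchor test.
2. **Fingerprinting.** Every structure is encoded as a hashed
   linear-fragment fingerprint: all heavy-atom paths of at most `maxLength`
   bonds (default 7) are serialized (element, aromaticity, bond order,
   direction-canonical) and hashed into `nbits` bits (default 1024).
3. **Similarity search.** Parent and metabolites are compared against every
   database compound with the Tanimoto coefficient
   $T = |A \cap B| / |A \cup B|$; database compounds with
   $T \ge$ `threshold` (default 0.7) against *any* query are retained, each
   reported once at its maximum similarity.
4. **Target collection and expansion.** The union of the hit compounds'
   annotated protein targets forms the drug's *possible targets*; a single
   hop over a protein–protein interaction graph adds first-step physical
   interaction partners. Expansion trades precision for recall: it
   generalizes a compound-level neighborhood to a pathway-level one.
5. **Partition and enrichment.** Across $k \ge 2$ drugs, every protein in
   the union of expanded sets is classified by its membership pattern:
   *common* (all $k$), *similar* (exactly one pair), *unique* (one drug);
   for $k \ge 4$ a *multi* class holds three-to-$(k-1)$-way memberships.
   Each set of interest is scored against ontology categories with the
   upper-tail hypergeometric probability, BH-adjusted, and ranked by raw p
   (ties: larger overlap, then name).

The expression arm is deliberately plain, mirroring the classical
microarray cascade: intensities are floored at 10, probe sets absent in all
arrays are removed, values are log2-transformed; each gene is tested by a
pooled-variance two-sample comparison (treatment vs. control, $n \ge 2$
each); genes pass if the class-comparison p < `alpha` (0.01), the BH FDR
< `fdr` (0.05), and a within-survivor Student *t*-test p < `tAlpha` (0.01);
finally an absolute log2-ratio threshold of `log2Cut` (1.1, i.e. 2.1-fold,
inclusive) splits up- from down-regulated genes.

Concordance between arms is reported per drug as the top-`k` (default 10)
category overlap with its Jaccard index, the Spearman correlation of ranks
over categories present in both lists (with the shared count, without which
the correlation is uninterpretable), and the set of categories significant
in both arms after adjustment. No significance test is attached to
concordance itself; the report is evidence to be read, matching how such
two-arm agreement is argued qualitatively in practice.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `threshold` | 0.7 | Tanimoto | conventional cut for fragment-fingerprint similarity; one shared value for parents and metabolites |
| `maxLength` | 7 | bonds | linear-fragment length typical of path fingerprints |
| `nbits` | 1024 | bits | collision rate vs. density trade-off at small-molecule scale |
| `hops` | 1 | graph steps | "first-step" physical partners only; more hops dilute specificity quickly |
| `alpha`, `tAlpha` | 0.01 | p | per-gene significance of the cascade |
| `fdr` | 0.05 | FDR | multiplicity control across genes |
| `log2Cut` | 1.1 | log2 ratio | 2.1-fold; applied inclusively, after the significance filters |
| `topK` | 10 | categories | length of the short lists compared across arms |

Two deliberate redundancies are kept for fidelity to the cascade structure
rather than statistical necessity: the class comparison *is* a Student
*t*-test here, so the within-survivor *t*-test stage reproduces the same
per-gene p (both are reported); and ranking uses raw p while the adjusted p
is reported alongside.

# Design choices where the design was open

- **Fingerprint scheme.** Commercial fragment cartridges are proprietary;
  any fixed, documented scheme supports the Tanimoto framework equally.
  Similarities computed here are reproducible against this package's
  descriptor (recorded in every `Fingerprint`) but are not numerically
  comparable to other software's values. The hash is a plain Horner
  polynomial mod $2^{31}-1$ — platform-independent and dependency-free.
- **Transformation vocabulary.** Reactant patterns are genuine substructure
  queries (a SMARTS subset: element/aromaticity, `#n`, `Hn`, `Xn`, charges,
  bond orders, `~`). Product templates, however, are named graph
  transformations from an extensible registry
  (`registerTransformation()`), not general reaction SMARTS: a full
  reaction interpreter would dwarf the rest of the package while the rule
  sets actually used in metabolite prediction are small and structured.
  Hydrolysis products keep the largest fragment — metabolite bookkeeping
  follows the drug-derived moiety, so fenofibrate yields fenofibric acid,
  not isopropanol.
- **Metabolite thresholding.** Metabolite-derived hits are thresholded at
  the same 0.7 as the parent (one coefficient governs the search); the
  threshold is a single CLI-overridable parameter.
- **Universe for enrichment.** Defaults to the union of ontology members,
  overridable per call; query and categories are intersected with the
  universe before counting.
- **Tail convention.** One-sided over-representation $P(X \ge k)$ — the
  universal reading of "hypergeometric" in enrichment; both-empty
  fingerprints get $T = 0$ (avoiding 0/0); zero-variance genes get
  $p = 1$ rather than an exception.
- **Identifier space.** One canonical symbol space for proteins and genes;
  an optional two-column map translates foreign ids at load, dropping
  unmapped rows with a logged count.

# Numerical choices

The hypergeometric upper tail is computed in log space (`lchoose` combined
by log-sum-exp), stable for universes of at least $10^5$; tests verify
equality with term-by-term enumeration (exact at $N \le 40$), with full
draw enumeration at small $N$, and with `phyper` across a random grid. BH
adjustment delegates to `p.adjust` behind input validation. The per-gene
test is a vectorized pooled-variance Student *t*, verified gene-by-gene
against `t.test`. All loaders sort canonically, every ranking defines its
tie-breaks, and the pipeline writes outputs deterministically — the same
config and inputs give byte-identical run directories, which the test
suite asserts.

# What the synthetic fixtures emulate — and what they do not

The generators produce every input the pipeline consumes, with planted
ground truth wired through the whole chain: compound clusters (decorated
shared scaffolds, ~20 heavy atoms) stand in for drug classes, each cluster
owning a disjoint block of target proteins; an ontology category is drawn
from the first cluster's block; and the first drug's planted expression
effects contain that category's members. The end-to-end pipeline — not just
the enrichment stage — can therefore be scored against known truth: the
planted category must rank first in the structure arm and be
shared-significant with the expression arm, and the two same-cluster drugs
must dominate the pairwise-similar partition class.

Generation is verified, not assumed: within-cluster pairwise Tanimoto must
reach `cluster_tightness` (default 0.7) and between-cluster similarity must
stay below 0.5, or generation fails with an actionable error. Scaffold
cores are sized (~20 heavy atoms against 0–2-atom decorations) so the
default fingerprint satisfies this contract.

Real data differ in ways the fixtures do not attempt to model: chemical
space is not cleanly clustered; target annotation is biased toward
well-studied proteins; expression noise is heteroskedastic and correlated
across genes; ontology categories overlap heavily and vary by orders of
magnitude in size. Passing fixture-based tests demonstrates correctness of
the machinery and recoverability of planted signal at the stated effect
sizes — not calibrated performance on experimental compendia.

Default study conditions follow the scale of the motivating design: 5
samples per group; 200 genes with 20 planted differentially expressed at
4-fold (2 log2) under gaussian log-scale noise $\sigma = 0.25$; a
60-compound, 3-cluster library over 300 proteins with expected PPI degree
4; 25 ontology categories. At these settings the cascade's planted-truth
sensitivity is essentially complete with no false calls, and the null
class-comparison level sits at its nominal 1%.

# Known limitations

- The SMILES reader covers the organic subset, brackets, charges, rings
  and aromatic notation, but ignores stereochemistry and isotopes —
  adequate for fingerprints and the shipped rules, not for
  stereo-selective metabolism.
- Effect signs (`activation`/`inhibition`) are carried through the
  knowledge base but not propagated through the network; expansion treats
  the PPI graph as unsigned and unweighted.
- Similarity magnitude is used only as a filter; hits are not weighted by
  it downstream.
- The expression arm assumes a pre-normalized matrix; normalization from
  raw intensity files is out of scope.
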