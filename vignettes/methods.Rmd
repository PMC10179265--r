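---
title: "Methods: variant prioritization in dominantly inherited cancer kindreds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization in dominantly inherited cancer kindreds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`varkin` packages, as tested code, the analysis chain used in family
studies of dominantly inherited cancer susceptibility with incomplete
penetrance: a germline filter cascade, pedigree segregation
classification, a parametric two-point LOD score, tumor–germline
somatic subtraction with panel restriction, and an interaction-network
path search. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and what the bundled
simulator does and does not establish.

## The setting and its assumptions

The intended data are a consanguineous multi-generation kindred in
which several relatives share a differentiated thyroid carcinoma (or a
comparable dominant tumor phenotype), a subset of patients have exome
calls, one patient has a tumor exome, and per-variant annotations
(population allele frequencies, in-silico scores, tissue expression in
TPM) come precomputed from standard sources. Three phenotype states are
carried throughout: `affected`, `unaffected`, and `unknown`. `unknown`
is load-bearing: members with benign thyroid disease (multinodular
goiter) or too young to have expressed a late-onset phenotype are coded
`unknown` and contribute *no* evidence anywhere — they cannot confirm
or negate a variant in segregation analysis and have penetrance-neutral
weight in the likelihood. Genotype calls are treated as error-free
(they are Sanger-verified in the motivating design); there is no
genotyping-error parameter.

## Germline cascade

Four pure subset-selection stages, each logged in a `filter_trace`
whose counts must chain exactly (`count_in` of stage *k+1* equals
`count_out` of stage *k*); the trace is the machine-readable audit of
the published-style filtration tables.

1. **Shared among carriers.** Keep variants where *every* named
   sequenced patient carries ≥ 1 alternate allele. A missing genotype
   fails the test (a variant unseen in a sequenced carrier is not
   "shared").
2. **Population databases, AF < 1%.** "Present at < 1%" is read as
   *keep iff the allele frequency is below threshold in every listed
   database*; a variant common in any single database is removed. This
   is the most conservative reading consistent with negating common
   variants. Frequencies are allele frequencies, not carrier
   frequencies; where a source reports het/hom carrier proportions they
   are converted as `het/2 + hom`. A database entry that is absent is
   stored as missing (`NA`) and counts as 0 *only at filter time* —
   "never observed" must remain distinguishable from "observed at 0".
3. **Internal cohort, AF < 1%.** Same rule against an in-house exome
   collection matched to the family's population of origin.
4. **Familial segregation** (next section).

Stages 2 and 3 are independent predicates, so their order is
immaterial; a property test asserts commutativity, and an oracle test
asserts that the cascade equals the naive per-record conjunction of all
predicates.

**Tiering.** Survivors are then tiered rather than filtered. A
splice-region variant predicted benign by *both* splice models —
spliceAI score `< 0.2` and dbscSNV-Ada `< 0.6`, the conventional
published benign cutoffs, both configurable — is `excluded`. Remaining
variants are `primary` when the gene's expression in the target tissue
is ≥ 10 TPM (boundary inclusive), else `secondary`. The 10 TPM default
separates a gene highly expressed in normal thyroid (≈ 19 TPM) from
ones at 1–7 TPM, matching how the motivating study prioritized; it is a
display-tier threshold, not a biological claim. A missing annotation
never excludes: a missing splice score leaves the rule unfired (noted
in the reason string) and a missing TPM demotes to `secondary` with a
reason rather than excluding.

## Segregation classification

For the dominant model, a variant is compatible iff every genotyped
affected individual carries at least one alternate allele. Affected
*homozygotes* count as carriers — in inbred kindreds the segregating
allele can appear in homozygous state, and that must not violate a
"heterozygous in patients" expectation. Genotyped unaffected carriers
are recorded as `non_penetrant_carriers` when incomplete penetrance is
allowed, and as `violators` under strict penetrance. For the recessive
model, all genotyped affecteds must be homozygous-alt, no unaffected
may be homozygous-alt, and an affected homozygote with a genotyped
homozygous-reference parent is an outright Mendelian violation. The
`allow_pseudo_dominant` flag records that affecteds in successive
generations are acceptable (an affected homozygote mating a
heterozygote under consanguinity); it deliberately grants no genotype
exemptions. No age-of-onset or liability-class adjustment is applied to
young unaffecteds — the `unknown` phenotype is the mechanism for that.
Both classifiers are verified against exhaustive truth-table oracles
over all `4^5` genotype vectors of a five-member family, and
`check_mendelian` against gamete enumeration over all 27 trio
combinations.

## Two-point LOD score

The LOD engine evaluates
`LOD = log10 L(θ) − log10 L(1/2)`
for a candidate variant treated as a fully observed marker linked at
recombination fraction θ to an unobserved biallelic disease locus.

Model structure:

* **Penetrance vector** `f = (f0, f1, f2)`, the probability of being
  affected given 0/1/2 disease alleles. Dominant with penetrance *p*
  and phenocopy rate *z* gives `f = (z, p, p)`; recessive gives
  `f = (z, z, p)`. Defaults: penetrance 0.9 (the motivating model),
  phenocopy 0.
* **Disease allele frequency** `q`, default 0.001 (rare-disease
  convention; the motivating study states none).
* **Marker allele frequency**, default 0.01, or the internal-cohort
  allele frequency when available; needed only for founders with
  unobserved genotypes, and its marginal contribution is θ-independent,
  so it largely cancels in the LOD.
* Founder haplotypes are drawn at Hardy–Weinberg and linkage
  equilibrium; each parent transmits a haplotype with recombination θ.

**Computation.** Each individual's latent state is an ordered pair of
(disease, marker) haplotypes — 16 states, restricted to those
consistent with the observed marker genotype. The likelihood is the sum
over all state assignments of founder priors × transmissions ×
evidence, computed by exact variable elimination with a greedy
smallest-factor order (leaf-first on tree pedigrees). Each elimination
rescales the factor by its maximum and accumulates the log, so
underflow cannot occur. Consanguinity loops need no special handling:
variable elimination is exact on loopy pedigrees, which is why the
engine uses it *instead of* the classical loop-breaker duplication (the
design originally envisioned loop breakers with a documented limit;
elimination gives the same likelihood with no breaker limit, and the
first-cousin-mating test asserts exact agreement with full
enumeration). A likelihood of zero at the tested θ with a positive
null likelihood is reported as `lod = -Inf` with
`incompatible_at_theta = TRUE` (an obligate recombinant at θ = 0); a
zero likelihood even at θ = ½ raises an "inconsistent data" error
(e.g. a Mendelian-impossible marker configuration). The engine is
checked against chunked full enumeration on 100 random small pedigrees
(≤ 8 members) to 1e-10 in log10, against the closed form
`m·log10(2)` on phase-known fully penetrant families, and for
invariance under relabeling and row order.

**The published 2.8 and what we report instead.** The motivating study
reports that recruiting the family "provided" a LOD of 2.8 under
dominant inheritance with 90% penetrance — a recruitment-stage figure,
i.e. the family's linkage *potential*, for which neither the allele
frequency nor the genotyped subset is stated. We therefore treat it as
a plausibility band, not a reproduction target. The package's
plausibility run computes the attainable LOD for a fully informative
co-segregating marker typed in the 17 sampled members of the
reconstructed two-branch pedigree (affecteds het, sampled unaffecteds
and unknown-status members non-carriers), dominant model, penetrance
0.90, q = 0.001: the acceptance test prints this value (3.165) and
asserts only that it falls in [2.0, 3.5]. For the observed genotype
rows of the candidate matrix the same engine gives 1.57–2.16 (printed,
not asserted): real data carry a homozygous affected, an untyped
obligate carrier and a non-penetrant carrier, each of which costs LOD
relative to the idealized recruitment calculation — the non-penetrant
carrier alone costs ≈ 0.7, since an unaffected marker carrier
contributes `1 − 0.9 = 0.1` at θ = 0 versus ≈ 0.55 under free
recombination.

## Somatic cascade

`subtract_germline` keeps tumor records carrying ≥ 1 alternate allele
whose matched (chrom, pos, ref, alt) germline genotype is
homozygous-reference. Two deliberate conventions: a site entirely
absent from the germline call set counts as reference (variant-only
call sets do not emit reference sites), while a germline genotype
explicitly missing ("./.") *excludes* the site — a conservative choice
that refuses to call somatic status inside germline coverage gaps, at
the price of missing true somatic variants there (configurable in
principle; the exclusion is the default and the tested behavior). The
frequency filter reuses the germline rule at the somatic threshold of
5%, and panel restriction is pure set membership against the 13-gene
somatic panel and a 19-gene germline susceptibility panel; a gene in
both is labelled `somatic_panel`. The susceptibility panel is
assembled from genes named in the motivating study's main text because
its appendix panel is unpublished; it is flagged as such in the
documentation. The second-hit scan lists tumor-only variants per
candidate gene by zygosity and enumerates all `C(k, 2)` pairs of
distinct heterozygous sites as potential compound heterozygotes.
There is no allele-fraction, purity or clonality modeling: calls are
genotype-level by design.

## Interaction paths

`find_paths` enumerates all simple paths of at most `max_edges` edges
from each candidate gene to a target set over an undirected, unweighted
edge list (evidence labels are annotations only: no interaction weights
are published, so none are modeled). When searching from one source the
other sources are removed from the graph interior unless they are
themselves targets, so a candidate is linked through shared biology
rather than through another candidate. The default `max_edges = 2`
captures one intermediate (candidate → partner → disease gene); the
known 3-edge chain through a lncRNA to a transcription factor requires
`max_edges = 3`, which is exercised in the tests. Path search is
delegated to igraph and independently verified against a recursive DFS
enumeration oracle on random graphs.

## The simulator: what a green test establishes

`simulate_pedigree` builds a three-generation, two-branch kindred
(optionally a first-cousin mating, giving exactly one consanguineous
loop); `gene_drop` plants one causal site at the model's allele
frequency — with the first founder forced to carry it — among rare
background sites whose frequencies default to a Beta(0.5, 5) spectrum
truncated to (1e-4, 0.5], draws founder genotypes at Hardy–Weinberg,
transmits alleles by fair Mendelian sampling, assigns phenotypes by the
penetrance vector, and masks genotypes at a configurable missing rate.
Because real kindreds enter a study through affected members — and the
phenotype is *defined* by ≥ 2 affected first-degree relatives — the
drop is rejection-sampled until at least `min_affected = 2` members are
affected (set 0 to disable). `spike_tumor` copies one member's
germline calls and adds heterozygous somatic variants in chosen genes
at fresh positions.

The simulator emulates: dominant transmission with 90% penetrance,
rare-skewed background frequencies, ascertainment, genotype
missingness, and tumor-only variants. It does **not** emulate:
genotyping error, linkage disequilibrium between background sites,
age-dependent penetrance, variant-calling artifacts, allele fractions,
or population substructure. A green recovery test therefore
establishes that the cascade's logic is sound under its own model —
that the planted allele always survives when every decoy is common
enough to fail a frequency filter, and that common decoys never
survive — not that the pipeline is robust to calling noise or to rare
decoys that genuinely mimic the causal configuration (a rare decoy
shared by all carriers by chance would legitimately survive, which is
why the recovery criterion fixes decoy frequencies above the filter
thresholds).

## Numerical and representational choices

* Coordinates are 1-based GRCh37 throughout; no liftover.
* Multi-allelic sites are split into biallelic records; on a split
  record, other alternate alleles count as reference. Indels are
  reduced to minimal representation by suffix-then-prefix trimming (no
  reference genome is consulted, so this is normalization, not true
  left-alignment against a fasta).
* Genotypes are integer alternate-allele dosages 0/1/2/NA, with
  bijective mappings to VCF GT strings and to the +/+, −/+, −/−
  symbols of family genotyping tables (both checked exhaustively).
* The likelihood engine works in linear space with per-step max
  rescaling and a log10 accumulator — equivalent to log-space
  arithmetic but allowing exact zeros to propagate.
* Oracle-versus-engine comparisons in the test suite are sized for a
  1-CPU runtime budget: the enumeration oracle's random pedigrees use
  marker frequency 0.2 and 5% genotype missingness so the exhaustive
  grids stay around 10^6 states; the comparison tolerance (1e-10 in
  log10) is unaffected by this sizing.

## Known limitations

* Autosomal models only; no X-linked or mitochondrial inheritance.
* Single-site germline models; compound-heterozygote logic exists only
  in the somatic second-hit scan.
* No probabilistic co-segregation scoring (Bayes-factor style); the
  segregation module is the published compatibility logic, and the LOD
  module is the quantitative complement.
* Two-point linkage only; no multipoint, no heterogeneity LOD.
* The kindred fixture's connectivity beyond the 11 genotyped members is
  a synthetic reconstruction from a simplified published drawing;
  functions and files that embed it say so.
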