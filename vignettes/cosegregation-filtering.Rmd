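---
title: "Cosegregation filtering of family variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosegregation filtering of family variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegr)
```

## The analysis in one paragraph

A family segregates an unexplained recessive-looking phenotype. Every
member is genotyped genome-wide, giving a multi-sample VCF; affection
status is recorded in a PED pedigree. For each candidate inheritance model
— a mapping from affection status to a required genotype class — the filter
keeps exactly those variants whose per-member genotype classes all lie in
the model's required sets. Survivors are triaged by functional consequence;
protein-coding survivors become candidates; a candidate is verified
internally (HGVS codon arithmetic) and externally (concordance in an
independent cohort). `cosegr` implements each stage as a plain function on
tabular data, and a gene-dropping simulator generates inputs with known
truth so that every stage is testable without access to any sequencing
archive.

## Inheritance models and matching semantics

The two built-in models describe a colony in which a second mutation
circulates among carriers:

* `het_carrier_hom_affected` — affected individuals are homozygous for the
  alternate allele, unaffected individuals are heterozygous. This is the
  natural first hypothesis when affected animals keep appearing from
  phenotypically normal parents: both founders must carry one copy.
* `wt_carrier_het_affected` — affected individuals are heterozygous,
  unaffected individuals are homozygous reference: the dominant-acting
  alternative.

Matching is **exact**: one discordant member rejects the variant. That is
the strictest reading of "fits the pattern", and it is what makes the
filter powerful — with six members required `hom_alt` and four required
`het`, an independent neutral variant survives with probability
$(q^2)^6 (2q(1-q))^4 = 16\,q^{16}(1-q)^4$, at most about
$7\times10^{-4}$ (at $q = 0.8$). A
`max_discordant` relaxation exists for noisy data but defaults to 0.
Requirement sets of the two built-in models are pointwise disjoint
(`hom_alt` vs `het` for affected, `het` vs `hom_ref` for unaffected), so no
fully-called variant can fit both models; the package asserts this
property over simulated datasets rather than assuming it.

Missing genotype calls need a policy. The default, `strict`, rejects a
variant with any missing or unclassifiable (`other`) call among required
members: conservative in the sense that a survivor is guaranteed to have a
fully concordant, fully observed pattern. `ignore_sample` instead drops
the missing member from the requirement for that variant (a variant with
*all* members missing is still rejected). Strict survivors are always a
subset of `ignore_sample` survivors, a monotonicity the tests check.

Both models are always evaluated side by side by `run_filter()`; the
package deliberately does not rank models against each other. What
discriminates them in practice is the consequence triage — a model whose
survivors contain no protein-coding variant is a weak explanation for a
severe phenotype.

### Genotype classes

Per-sample GT values reduce to `hom_ref`, `het`, `hom_alt`, `missing` or
`other`. Phasing is ignored (the filter is class-based), haploid calls
classify by their single allele, and any `.` allele means `missing`.
Multi-allelic VCF lines are split into one record per alternate allele;
alleles that are neither reference nor the focal alternate make the call
`other`, which preserves exact-match semantics without discarding sites.
Sex chromosomes are not treated specially: the filter uses autosomal
semantics throughout, and hemizygous modelling is an explicit
non-feature.

## Consequence triage

Annotations are read from the pipe-delimited `ANN` INFO field
(allele | effect | impact | gene | … | HGVS.c | HGVS.p). Classes are
assigned with precedence `protein_coding > intronic > intergenic > other`,
so when several transcripts annotate one site the most severe class wins
and entry order is irrelevant. The protein-coding effect-term set includes
the splice donor/acceptor terms alongside missense, nonsense, frameshift
and friends: splice-disrupting lesions destroy the protein product just as
coding changes can, and retinal-degeneration strains include canonical
examples of splice-donor deletions acting as null alleles. The set is a
configurable argument (`coding_terms`) rather than a constant, because the
boundary is a judgement call. Unannotated variants default to
`intergenic`.

## HGVS codon arithmetic

For a coding substitution `c.<pos><ref>><alt>`:

* codon index $= \lfloor(\mathrm{pos}-1)/3\rfloor + 1$,
* within-codon offset $= ((\mathrm{pos}-1) \bmod 3) + 1$.

`predict_aa_change()` applies the change to a stated reference codon,
translates both codons under the standard genetic code, and categorizes
the change (missense / synonymous / nonsense / stop-lost). A mismatch
between the codon and the stated reference base is reported as an
inconsistency — that is the point of the function: checking that a
reported `c.` description and protein-level description agree. Only the
substitution grammar is supported; intronic offsets, UTR positions and
indels raise explicit unsupported-notation errors rather than silently
parsing. Only the standard nuclear genetic code is implemented.

## Cohort concordance

The confirmation cohort is summarized under the recessive reading:
affected ⇔ homozygous alternate. Discordance counts affected
non-homozygotes plus unaffected homozygotes; unaffected carriers and
unaffected homozygous-reference animals are both concordant (carrier
status is reported separately, since an all-carrier unaffected group is
itself informative about the colony). On top of the descriptive counts the
package adds a one-sided exact test: conditioning on both margins of the
2×2 table, the p-value is the hypergeometric tail probability of at least
the observed number of affected homozygotes,
$$p = \sum_{k \ge x} \binom{K}{k}\binom{N-K}{n-k} \Big/ \binom{N}{n}.$$
For a perfectly concordant cohort of 8 affected homozygotes and 10
unaffected carriers this is $1/\binom{18}{8} = 1/43758 \approx
2.29\times10^{-5}$. The test is an addition to the descriptive readout
(labelled as such in output) so that synthetic, imperfect cohorts have a
quantitative measure; a cohort with a single phenotype class has no
defined test and is reported with $p = 1$ and a degenerate-margin warning.
The implementation's closed form is verified in the tests against
exhaustive enumeration over the table support and against `phyper()`.

## The simulator: what it emulates, and what it does not

`simulate_cosegregation()` performs classical gene dropping:

1. each background variant receives a founder alternate-allele frequency
   $q_i$ from the configured law;
2. founders draw two alleles Bernoulli($q_i$) (Hardy–Weinberg);
3. each offspring receives one uniformly random allele from each parent,
   generation by generation;
4. an optional causal variant is planted with genotypes assigned
   *deterministically* from affection status under the named model, after
   a trio-wise Mendelian feasibility check (an affection pattern the model
   cannot produce — e.g. an affected child of two homozygous-reference
   parents under the dominant-style model — is an explicit error naming
   the violating trio);
5. genotyping error (a call re-drawn to one of the two wrong informative
   classes, uniformly) and missingness are applied per call *after* the
   clean truth is recorded.

Defaults and why:

* `pedigree` — the ten-member nuclear family the analysis was designed
  around (2 founders; affected father, unaffected mother; 5 affected and
  3 unaffected offspring), shipped as `rd6_family()` and as a PED fixture.
  All ten members are flagged sequenced by default; the `unsequenced`
  argument reproduces designs in which some members were not sequenced,
  since published family descriptions do not always identify which.
* `n_background = 10000` — large enough that survivor counts are
  statistically meaningful and the needle-in-haystack recovery is
  non-trivial, small enough that hundreds of replicates run in minutes.
  Real genome-wide inputs are an order of magnitude larger (a mouse family
  yields on the order of $10^5$ called variants); nothing in the filter is
  sensitive to that difference because variants are processed
  independently.
* `founder_af = af_beta(0.5, 0.5)` — a U-shaped frequency spectrum
  putting mass on both rare and common variants, the qualitative shape of
  real site-frequency spectra; `af_fixed(q)` exists so closed-form
  expectations are exact in calibration tests. Beta draws are clamped to
  $[10^{-6}, 1-10^{-6}]$ so Hardy–Weinberg class probabilities stay
  defined.
* `genotyping_error_rate = 0`, `missing_rate = 0` — the clean baseline;
  error injection is opt-in per configuration. The causal record is
  exempt from corruption unless `corrupt_causal = TRUE`, so recovery
  tests separate "can the filter find a clean needle" (sensitivity 1 by
  construction, asserted over hundreds of seeds) from "how does recovery
  degrade with noise" (expected $(1-\varepsilon)^m$ for $m$ required
  members under the strict policy, checked against simulation).
* positions run every 100 bp along one synthetic contig `chrSim`;
  coordinates carry no meaning in the filter.
* background annotations are drawn from proportions
  (protein-coding 0.01, intronic 0.33, intergenic 0.66) — roughly the
  make-up expected when a hard genotype filter has already removed most
  sites and what remains is dominated by noncoding variation.

The `unrelated_panel` mode drops the pedigree transmission entirely and
draws every individual independently under Hardy–Weinberg. This exists
because within a family, transmission correlates genotypes across
relatives, so the closed-form null survival probability
$(q^2)^a(2q(1-q))^h((1-q)^2)^r$ — which assumes independence — is only
exact on an unrelated panel. Calibration checks therefore run in that
mode.

Known simplifications: background variants are unlinked (the filter treats
variants independently, so marginal correctness is all the survivor-count
checks need); there is no recombination map, no read-level or
coverage-dependent error structure, no population structure among
founders, and simulated sites are biallelic SNVs. Passing tests
demonstrate the pipeline's correctness on data satisfying the stated
generative assumptions — they do not certify behaviour under artefacts
those assumptions exclude (linkage blocks, batch-correlated missingness,
allele-balance-dependent miscalls).

## Numerical and interface choices

* Coordinates are 1-based inclusive (VCF convention) throughout; no
  liftover.
* No QUAL/DP/GQ thresholding is applied by default; `min_qual` and
  `require_pass` are opt-in pass-throughs, since upstream callers apply
  their own site filters and a reanalysis should not silently double
  filter.
* When a variant fails a model, the recorded exclusion reason is that of
  the first failing member in pedigree order (missing-genotype,
  other-class or pattern-mismatch) — a deterministic tie-break that makes
  `exclusions + survivors = inputs` an exact accounting identity.
* The hypergeometric tail is computed in log space (`lchoose`) for
  numerical robustness at larger cohorts.
* All file outputs (PED, VCF, truth JSON, run reports) contain no
  timestamps, and report JSON records input files by basename and MD5, so
  identical inputs and seeds give byte-identical outputs wherever they
  live — reproducibility is asserted, not assumed, in the tests.
* Simulation problem sizes used by the test-suite properties: brute-force
  oracle equivalence on 300-variant inputs over 100 seeds; planted-causal
  recovery at 10,000 background variants over 200 seeds; null calibration
  on 50,000-variant unrelated panels at $q \in \{0.1, 0.3, 0.5\}$;
  translation checked exhaustively over all $64 \times 3 \times 3$
  single-base codon substitutions. These sizes make the binomial
  3-standard-deviation acceptance bands tight enough to detect logic
  errors while keeping the full suite around three minutes.

## Open design points, resolved

* **Which family members were sequenced.** Published family descriptions
  sometimes report fewer sequenced genomes than pedigree members without
  identifying the omitted individuals. The package does not guess: the
  PED dialect carries an optional seventh `sequenced` column defaulting to
  1, `rd6_family(unsequenced = ...)` constructs any configuration, and
  requirements are derived only over sequenced members — so either reading
  (8 or 10 genomes) is runnable and explicit.
* **Members of unknown affection** cannot constrain any model; they are
  excluded from the requirement mapping and reported, not silently
  dropped.
* **Second protein-coding survivors.** When several protein-coding
  variants survive, the candidate table reports all of them with their
  consistency checks and ranks none; prioritization beyond consequence
  class (conservation, expression, prior gene knowledge) is outside the
  package's scope.

## Limitations

The filter is a single-family, single-model-at-a-time exact matcher: it
does not perform linkage analysis (no LOD scores), IBD inference,
imputation, de novo modelling or penetrance modelling, and multi-family
PED files are out of scope. The annotation module parses existing
annotations; it does not compute them from a reference genome. These are
boundaries, not roadmap items: each has mature dedicated tooling.
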