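---
title: "Methods: testing feed-on-family against feed-on-compound host selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing feed-on-family against feed-on-compound host selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the data model

Herbivorous insects - butterflies in the motivating system - are choosy
about their host plants. Two mechanisms can produce the same observed
choosiness: insects may track plant *taxonomy* (a clade feeds on one plant
family, wherever its members sit chemically), or they may track plant
*chemistry* (a clade feeds on plants sharing particular compounds, wherever
those plants sit taxonomically). Because secondary metabolites are
phylogenetically conserved, the two signals are entangled in nature;
`phytophagnet` provides the statistics that separate them.

The data are three tables: a bipartite interaction table (insect species x
plant species, unweighted - observation multiplicity is discarded because
the statistics count relationships, not sighting frequency), taxonomies for
both sides (species to genus/subfamily/family/order; family mandatory), and
a plant-compound table (plant species to opaque compound identifiers, e.g.
KNApSAcK-style accessions). All chemistry-aware statistics operate on the
network restricted to edges whose plant has at least one recorded compound
(`restrictToCompoundAnnotated()`); species isolated by that filter are
dropped, and the before/after counts are logged, since the attrition itself
is part of the record.

# Null models and Z-scores

Every significance statement has the form
$Z_X = (X_{\mathrm{real}} - \bar X_{\mathrm{rand}}) / \mathrm{SD}_{\mathrm{rand}}$
with the mean and sample standard deviation (denominator $n-1$; with 1,000
replicates the choice is numerically immaterial but must be fixed) taken
over randomized networks.

Two null models are implemented because two are defensible:

* `fixed_fixed` (default): checkerboard/curveball exchanges of the
  incidence matrix, preserving **both** degree sequences exactly. The
  sampler is the C implementation in \pkg{vegan}; between successive
  samples the chain advances by `swapsPerEdge * |edges|` attempted
  exchanges (default 10 per edge), which is far past the mixing times
  reported for curveball-type samplers on matrices of this shape. Exact
  degree preservation is what makes the evenness and food-pairing tests
  interpretable: a species keeps its diet breadth, only *which* plants it
  eats is randomized.
* `probabilistic`: each cell filled independently with probability
  $\min(1, d_i d_j / m)$, so degrees are preserved in expectation and the
  expected edge count equals the observed $m$. Offered because
  product-of-degrees phrasing is also common; results are always labelled
  with the model used.

Replicates form one seed-fixed stream: a run is exactly reproducible given
the master seed, and all statistics reported together (global and
per-category) are evaluated on the same replicates so their errors are
coherent. We deliberately do not restart the chain with a fresh burn-in per
replicate - that would multiply the cost by the replicate count for no
statistical gain. Degenerate nulls (zero spread) yield an explicit flag and
`NA`, never an infinite Z.

# The two focal statistics

**Family-based evenness** (feed-on-family). For insect category $i$ with
$S_i$ host plants spread over plant families with counts $N_{ij}$:

$$E(i) = -\frac{1}{\ln |m_f|} \sum_{j:\,N_{ij}>0} \frac{N_{ij}}{S_i}
\ln \frac{N_{ij}}{S_i}$$

where $m_f$ is the set of plant families in the *whole* network, not the
category's own families - the normalization must be shared for values to be
comparable across categories in one scatterplot. Conventions: natural
logarithms; $0 \ln 0 = 0$; $|m_f| = 1$ gives $E = 0$ (entropy and its
maximum vanish together). The global test statistic is the unweighted mean
of species-level $E$; taxonomy-driven selection shows up as
$Z^{E} \ll 0$.

**Food-pairing $N_s$** (feed-on-compound). For a butterfly $k$ with $n \ge
2$ hosts, $N_s(k)$ is the mean of $|C_a \cap C_b|$ over unordered host
pairs. Butterflies with fewer than two hosts have no pair average and are
excluded (the count is reported), never imputed as zero. Chemistry-driven
selection shows up as $Z^{N_s} \gg 0$ for the across-species mean.

**Compound contribution $\chi_i$.** Per plant, $\chi_i = T_1 - T_2$: $T_1$
averages, over the plant's herbivores, the mean compound overlap between
plant $i$ and the herbivore's *other* hosts; $T_2$ is the same average over
all other plants, i.e. the expectation if insects fed without selectivity.
Herbivores with a single host have no "other hosts" and are excluded from
both the numerator and the denominator of $T_1$; this is the only reading
under which $E[T_1] = T_2$ under random feeding, so that mean $\chi$ is
centred on zero in the absence of selectivity - the property the no-selectivity
interpretation of $T_2$ requires, and the one our calibration tests assert.
The mean host count $S(i)$ of the plant's herbivores is carried in the
output for transparency although the statistic does not use it.

**Enrichment screen.** Per compound and insect clade, a 2x2 table of
(clade vs non-clade) x (host plant carries the compound vs not), scored
with a two-sided Fisher's exact test and Cramer's
$V = \sqrt{\chi^2 / n}$ from the Pearson statistic *without* continuity
correction - correction would break the correspondence between $p$, $V$
and $n$ that motivates the fixed threshold. The default observation unit
is the plant-herbivore relationship; because relationship rows are not
independent, the plant-species unit is offered and the caveat is logged on
every relationship-unit run. The default decision rule is the fixed,
effect-size-calibrated threshold $p < 10^{-6}$; Benjamini-Hochberg
adjustment is an explicit opt-in rather than the default because the screen
is conventionally reported against a fixed cut chosen for a target $V$.

Compounds are also partitioned set-theoretically
(`commonVsCommonSpecific()`): *common* compounds occur in every plant of
host and background sets alike and are uninformative; *common specific*
compounds occur in every host plant and no background plant and are the
candidate attractants.

# The synthetic study design

`simulateStudy()` generates the standard test community: 4 plant families
x 25 plants, 5 insect families x 2 subfamilies x 5 species, 5 hosts per
species drawn without replacement - about 100 plants, 50 insects and 250
edges, sized so a full pipeline run with 1,000 null replicates takes a few
seconds and grid-style calibration experiments stay inside minutes on one
CPU. Host draws use probability proportional to
$\exp(\lambda \cdot [\text{preferred family}] + \beta \cdot
[\text{carries the clade's planted compounds}])$, so $\lambda = \beta = 0$
recovers uniform feeding exactly; per-edge generative log-weights are
emitted as ground truth.

Chemistry has four layers: one globally common compound (every plant); 3
core compounds per plant family (within-family "common" chemistry); 3
planted clade-specific compounds per insect family; 30 background
compounds, each present in any plant with probability 0.1. By default the
planted compounds go to every plant of the clade's preferred family
("family" placement): chemistry tracks taxonomy, as it does for real
secondary metabolites. This coupling is faithful but it means $\lambda$
alone also raises $N_s$ (hosts concentrated in one family share its core
compounds) and $\beta$ alone also lowers evenness. For parameter-recovery
experiments that need the two channels orthogonal, the generator offers
"scattered" placement - each clade's planted compounds go to a random
quarter of all plants irrespective of family - and the core-compound count
can be set to zero; with that design the evenness Z responds only to
$\lambda$ and the food-pairing Z only to $\beta$, which is what the
package's monotone recovery tests use. The default family placement is used
everywhere the coupling is the phenomenon of interest (the negative
correlation between $Z^E$ and $Z^{N_s}$ across clades, and recovery of
planted compounds by the enrichment screen).

What the generator does *not* emulate: real phylogenies with branch
lengths, abundance-weighted interactions, spatial structure, unequal clade
sizes, or synonymy and incompleteness of real interaction records. Passing
tests therefore demonstrate correctness and calibration of the statistics
under a clean generative model, not robustness to the sampling biases of
literature-compiled networks.

# Numerical and design choices

* Species matching is exact after whitespace normalization; synonym
  resolution is out of scope and would be nondeterministic.
* Delimiters are auto-detected between tab and comma, with an explicit
  override; a header row is mandatory.
* Edges whose endpoints lack taxonomy at a requested level are excluded
  and counted in the log, not imputed.
* Evenness category hosts are counted as *distinct plants* (the category's
  node degree), matching the index definition.
* The probabilistic null caps cell probabilities at 1; with all degrees
  equal the cells reduce to the uniform value $m/(n_i n_p)$.
* Spearman correlation of $\chi$ against degree is suppressed (with a
  message) below 3 plants or under zero variance rather than returning a
  misleading coefficient.
* Calibration bounds in the test-suite use exceedance counts with binomial
  slack (e.g. at most 5 of 50 replicates beyond $|Z| = 1.96$ under the
  nominal 5 percent rate).
* Test problem sizes: degree-exactness on a 50 x 80 network x 1,000
  replicates; oracle sweeps of 200 random instances; the exact-test oracle
  enumerates all 46,376 tables with total at most 30; calibration uses 50
  pipeline replicates x 1,000 nulls; recovery uses a 3 x 3 grid x 10
  replicates x 500 nulls.

# Known limitations

* The fixed-fixed sampler is a Markov chain; independence of replicates is
  approximate (mitigated by aggressive thinning), and isolated replicate
  reproducibility is traded away for speed.
* Relationship-unit enrichment inherits pseudo-replication from shared
  plants and insects; treat its p-values as screening scores, which is how
  the fixed effect-size-calibrated threshold is intended.
* $\chi_i$ is undefined (NA) for plants whose herbivores are all
  single-host; such plants are rare under the default design but common in
  very sparse empirical networks.
* The ecozone similarity is a descriptive correlation of composition
  proportions; it supports no biogeographic inference by itself.
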