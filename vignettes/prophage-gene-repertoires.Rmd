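---
title: "Models and methods: prophage gene repertoires along the parasitism-mutualism continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: prophage gene repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophageContinuum)
```

# The scientific question

Integrated prophages degrade. Bacterial mutation is deletion-biased, so a
prophage that provides no benefit is eroded gene by gene; a prophage that
retains functional induction genes is worse than useless to its host,
since induction kills the cell. Yet sequenced genomes are full of prophage
remnants of every length, and the *composition* of those remnants is
biased: lytic-machinery genes (terminase, portal, lysis, lysin) are
under-represented in incomplete prophages, while transposases and
integrases are over-represented. This package provides three tools to
study that pattern — a count-table analysis of annotated prophage gene
classes, an analytical frequency model, and an individual-based
simulation — each exposed as ordinary R functions and driven end to end
by the scripts under `analysis/`.

# Annotation repertoire analysis

## Keyword tabulation

`tabulate_gene_classes()` counts, for 13 phage gene classes and the three
completeness labels produced by prophage detectors ("intact",
"questionable", "incomplete"), the number of prophages containing at
least one coding sequence whose annotation matches the class keyword.
Matching is deliberately plain case-insensitive substring search
(`classify_annotation()`): it is the minimal reading of keyword search,
and its one visible consequence — "baseplate" matches the `plate`
keyword — is documented rather than patched, because the bundled count
tables were built under the same convention. A CDS matching several
keywords counts toward every matched class; a prophage counts at most
once per class.

## The percent-change statistic and its null

For a class with frequency $f_{int}$ among intact-prophage genes and
$f_{inc}$ among incomplete-prophage genes,
$$\%\text{change} = 100\,\frac{f_{inc} - f_{int}}{f_{int}},$$
computed per stratum against that stratum's total class count
(`class_frequencies()`, `percent_change()`). Questionable prophages are
tabulated and reported but excluded from the intact-vs-incomplete
comparison.

Significance is assessed by a proportional bootstrap
(`bootstrap_enrichment()`): under the null, a class's genes carry no
information about completeness, so its row total is re-assigned to the
three strata by a multinomial draw with probabilities equal to the column
totals over the grand total (82% intact / 11% incomplete in the first
bundled survey). We read "randomly assign ... preserving the proportion"
as independent multinomial draws rather than an exact permutation; the
two differ only in higher-order fluctuations. Each of the (default)
10,000 replicates recomputes the percent change; the observed value is
compared against the 2.5th/97.5th empirical percentiles (linear
interpolation, ties broken toward non-significance). Replicates whose
intact draw is zero leave the statistic undefined and are discarded with
a logged count; at the row totals of the bundled tables this affects no
retained class.

Classes carrying less than 1% of all class hits are flagged by
`apply_prevalence_filter()` and excluded from enrichment displays. The
type-I calibration test runs on the retained classes only: for the two
excluded classes (16 and 22 genes), the percent-change statistic is so
discrete that no empirical two-sided 5% test can attain its nominal
level — the very reason sparse classes are filtered.

## Transposase classification

`classify_transposase()` operationalizes "annotated as an IS transposase"
as: the annotation contains `IS` (case-sensitive) immediately followed by
digits, optionally with a family suffix ("IS3 transposase B", "IS630
family transposase"). This token rule is a deliberate choice from a
single exemplar string; it is conservative in that a bare "transposase"
annotation is never counted as IS. `transposase_summary()` reports
frequencies against all phage proteins per stratum and the
intact-to-incomplete relative change $(f_{inc}-f_{int})/f_{int}$, which
is what the conventional "$x$-fold enrichment" wording quotes.
`transposase_density_by_length()` profiles transposase CDS per kbp in
prophage-length bins (empty bins are `NA`, not zero).

# The analytical model

The state is the frequency vector of eight genotypes $P_{ber}$, indexed
by presence/absence of the Beneficial, Excision and Re-infection gene
functions. Degradation moves density down the gene-loss lattice at $r_D$
per gene; genomes with a functional excision gene are lost to induction
at $r_I$; genotypes with both E and R feed back into themselves at the
re-infection rate $r_L$; B-carriers grow at $r_S$; and a mean-fitness
term $\phi$ (`mean_fitness()`) keeps the frequencies on the simplex. One
term of the published form of the system is corrected here: frequency
conservation requires the inflow to the empty state $P_{000}$ to come
from the three single-gene states ($r_D(P_{100}+P_{010}+P_{001})$); the
implementation uses that form, and a property test asserts that the
derivative components sum to zero to machine precision.

Only four long-term outcomes exist, characterized by two conditions:
beneficial genes persist iff $r_S > r_D$, and the E/R pair persists iff
$r_L > 2r_D + r_I$ (`classify_regime()`). Boundary equalities are
classified as non-persistence — the equilibria are only marginally stable
there and the conditions are stated as strict inequalities — with a
warning. Note the domestication equilibrium is the mix
$P_{100} = 1 - r_D/r_S$, $P_{000} = r_D/r_S$: the beneficial-gene mean
approaches $1 - r_D/r_S \approx 0.98$ at the captioned rates, not exactly 1.

## Numerical choices

Integration uses `deSolve::lsoda` (stiff-safe, adaptive) at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$; states are stored
as computed, with no hard renormalization that could mask drift, and the
final frequency sum must stay within $10^{-6}$ of one. `infer_outcome()`
maps the final mean gene counts to a regime at tolerance $10^{-3}$, which
separates the four regimes by orders of magnitude at the captioned
parameters; if the last two stored mean-count vectors still differ by
more than that, it returns `"undetermined"` rather than guessing, and
`ode_outcome()` doubles the horizon until determined. The default initial
condition is $P_{111} = 1$ (a population founded by full prophages); the
published trajectories do not state their initial condition, and this is the
natural founding state, but regime classifications away from the
condition boundaries do not depend on it. The comparison grid
(`rate_grid()`, 63 combinations) excludes a margin of 0.05 around both
boundaries, where convergence times diverge.

# The individual-based simulator

Each of up to $K$ bacterial genomes carries one prophage locus laid out
as $[B|E|R|N]$ gene blocks; per gene we track presence and a TE-disruption
count. A gene is *functional* iff present and undisrupted. Per bacterial
generation (one timestep, $\Delta t$ prophage generations):

1. **deletion** — each present gene is removed with probability
   $r_D \Delta t$ (its TE record is erased: deletion removes the
   sequence, embedded IS copies included);
2. **TE disruption** — each present gene gains a disruption with
   probability $r_T \Delta t$; disrupted genes remain present (a
   sequence detector still sees them) but are non-functional, and hits
   accumulate;
3. **induction** — each genome whose $n_E$ excision genes are all
   functional is killed with probability $r_I \Delta t$;
4. **reproduction** — every survivor contributes one pool copy, plus a
   selection copy with probability $r_S \Delta t\, n_b/n_B$ ($n_b$ =
   functional beneficial genes), plus a re-infection copy with
   probability $r_L \Delta t$ if all E and R genes are functional;
5. **regulation** — if the pool exceeds $K$, each genome is kept with
   probability $K/N$.

TE placement within the generation (after deletion, before induction) is
a design choice left open by the published description; placing it before
induction makes
a disruption immediately consequential, matching the rule that a
disrupted excision gene blocks induction. $\Delta t$ defaults to 0.01
(a bacterial generation is 1/100 of a prophage generation); only
$r\Delta t$ is meaningful and the constructor enforces
$\max(r)\Delta t \le 0.1$ so the per-step probability approximation
holds. Defaults $n_B{:}n_E{:}n_R = 1{:}1{:}8$ follow the approximate
partition of the lambda genome into host-beneficial (~8%), lytic-switch
(~13%) and particle-production/lysogeny (~79%) genes. Literature anchors
for the per-gene rates are computed by `per_gene_rate_estimates()`:
$2\times10^{-10}$ substitutions/nt/generation over a 1.2 kbp gene gives
$2.4\times10^{-7}$ per gene per generation, and $10^{-5}$ transpositions
per IS element over 33 elements gives $3.3\times10^{-4}$ genome-wide,
i.e. $8.6\times10^{-8}$ per 1.2 kbp gene in a 4.6 Mbp genome — mutational
loss and TE disruption are comparable forces.

The per-generation loop is compiled (Rcpp) and uses R's RNG, so runs are
bit-reproducible from the seed; the exported `step_*()` functions are a
plain-R reference implementation of the same semantics, unit-tested
directly and cross-checked against the compiled engine through
closed-form envelopes (e.g. pure-decay survival $(1-r_D\Delta t)^t$
within binomial error).

## Outcome classification at finite horizons

`predicted_outcome()` generalizes the analytical conditions: B persists
iff $r_S > r_D + r_T$; the E/R function, destroyable by any of its
$n_E + n_R$ genes, persists iff
$r_L > (n_E + n_R)(r_D + r_T) + r_I$. To compare a *finished run*
against this prediction, `realized_outcome()` must decide persistence
from a finite series. ER intactness is fast on the simulated timescale,
so a level threshold works: ER persists iff the final ER-intact fraction
exceeds 0.01 (equilibrium fractions at the captioned parameter sets are
2–10%, transient residues orders of magnitude lower). The beneficial
function can decline much more slowly than the horizon (at one captioned
parasitism set, ~0.001 per prophage generation), so a level test alone
would misread it; B is therefore called persistent iff its final
frequency exceeds 0.05 *and* a log-linear trend over the second half of
the series is not both statistically significant (3 SE) and material
(shedding >10% of the frequency over the window — between the ~2–4%
drift wobble of an equilibrium series and the ~21% true decline of the
slow parasitism case). These thresholds were fixed from the dynamics
before the replicate comparisons were run.

## Scales used, and what the simulations do not show

Replicate outcome comparisons run 20 replicates per parameter set at
$K = 1{,}000$ over 5,000 generations — a scale at which every captioned
outcome is recovered as the majority call. Structural analyses
(length spectra, intact-vs-incomplete repertoires) need the persistence
regime to actually persist: the ER-intact class sits at a few percent of
the population under a selective excess of only 0.03–0.05 per prophage
generation, and in populations of 1,000–2,000 it reliably drifts to
extinction within 20,000 generations. Those analyses therefore run at
$K = 10{,}000$ (and $K = 20{,}000$ for the TE-disruption variant, whose
intact class is half as fit) — the scale at which the regime exists for
the full horizon. Even at these sizes the relative heights of the two
length-distribution modes fluctuate between runs; the *bimodality* (both
end classes outnumbering every intermediate re-infection class) is the
stable feature, not the mode heights. The strict-definition transposase
enrichment is reported as the pair of stratum frequencies rather than a
fold factor, because the intact stratum's TE frequency is often exactly
zero at feasible population sizes (only the single beneficial gene can
carry a TE in a strictly intact prophage), making the ratio infinite —
the qualitative claim (incomplete ≫ intact) is what the data support.

# The synthetic annotation generator

`generate_annotation_dataset()` emulates the statistical structure of a
PHASTER-style survey: completeness labels from a mixture, per-class CDS
counts Poisson with stratum-specific means, log-normal lengths per
stratum, Poisson distractor annotations built from keyword-free text, and
IS tokens planted in a configurable fraction of transposase annotations.
Poisson counts and log-normal lengths are simple defaults (nothing in the
emulated pipeline implies a particular generative model) and every
distribution parameter is overridable. The generator returns its ground
truth alongside the records, so recovery tests can assert against the
construction: a null-proportional spec yields non-significant bootstrap
flags, and a planted 3× incomplete excess is flagged enriched.

What the generator does *not* emulate: real BLAST hit text (annotations
are templated phrases around the keywords), correlated gene content
within prophages, detector-specific completeness calling, or nucleotide
sequence. Tests passing on synthetic data therefore validate the
counting, testing and I/O machinery — not the biological fidelity of any
particular annotation pipeline.

# Known limitations

* The simulator omits free-phage dynamics, superinfection of occupied
  hosts, burst size, spatial structure and horizontal transfer of partial
  prophages; the enrichment of integrases observed in real surveys is
  *not* reproduced by it, and plausibly requires exactly those omitted
  processes.
* One in-text figure of the emulated survey ("IS transposases account for
  41.4%...") differs in the last printed digit from what its own count
  table yields (41.3%); the package reports the table arithmetic.
* The strict-intact TE enrichment is inflated by construction (an intact
  prophage can host a TE only in its beneficial gene), which is why the
  threshold (80%-of-genes-present) intactness mode exists and is the
  better analogue of sequence-based detectors.
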