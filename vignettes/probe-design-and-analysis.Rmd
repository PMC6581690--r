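---
title: "Functional gene array probe design and hybridization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gene array probe design and hybridization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgarray)
```

# The problem

Functional gene arrays interrogate thousands of functional genes across a
whole microbial community in one hybridization. Because environmental DNA
contains a dense cloud of homologs around every target, the array is only
as good as its probes' specificity: a probe that binds a nontarget homolog
reports a gene that is not there. `fgarray` implements the two halves of
the workflow that can be done at a desk — designing 50-mer probes under
joint cross-hybridization criteria, and turning scanned intensities into
calls, normalized abundances, quantitation fits and community statistics —
plus a hybridization simulator that makes the analysis layer testable
end-to-end.

# Specificity model

Three statistics summarize how dangerously a probe resembles a nontarget
sequence, each computed over both strands:

* **Identity** — the best ungapped register of the probe along the
  subject, scored as matches divided by probe length. The alignment is
  ungapped by design: the stretch and free-energy statistics below assume
  a fixed register, and an ungapped scan is exactly reproducible. Registers
  may overhang the subject; overhanging positions count as mismatches.
* **Continuous stretch** — the longest exact common substring. Long
  perfect stretches nucleate stable duplexes even when global identity is
  low, which is why this is screened separately from identity.
* **Duplex free energy** — a nearest-neighbor ΔG°37 for the heteroduplex
  at the best-identity register. Only stacks flanked by two Watson–Crick
  matches contribute; a mismatch contributes nothing and breaks the
  stacking run; one pair of duplex-initiation terms is added when at least
  one matched run of length ≥ 2 exists (taken from the 5′ end of the first
  such run and the 3′ end of the last, so a fully matched window reduces
  to the ordinary matched-duplex sum). If no such run exists no duplex
  forms and ΔG = 0. Mismatch-specific nearest-neighbor parameters are
  deliberately not used: the screen is a coarse worst-case filter and its
  thresholds were calibrated against a comparably coarse model.

The packaged parameter set is the unified oligonucleotide ΔG°37 table
(`inst/extdata/nn_unified_dg37.tsv`); any table with the same schema can be
swapped in via `load_nn_params()`. No salt or temperature correction is
applied — thresholds are compared on the ΔG°37 scale.

A sequence-specific probe passes when, against its *closest* nontarget,
identity < 90%, stretch < 20 bp and ΔG > −35 kcal/mol. The identity
default sits at the conservative end of the established 90–92% range;
stricter screening can only improve specificity. A group-specific probe
must additionally bind its *weakest* family member at identity > 94%,
stretch > 35 bp and ΔG < −60 kcal/mol. All six inequalities are strict:
a statistic exactly on a threshold fails. One consequence worth knowing:
the −60 kcal/mol group criterion is hard to satisfy for AT-rich probes
(a perfectly matched all-AT 50-mer sits near −45 kcal/mol), so low-GC gene
families legitimately yield fewer group-specific probes.

ΔG is evaluated at the best-identity register only, not at every register.
This is an approximation — a lower-identity register could in principle
form a more stable duplex — accepted for bounded cost, because the
best-identity register dominates binding in an ungapped model.

# Probe selection

Candidates are all 50-nt windows of a target (step configurable), filtered
by GC content 30–70%, homopolymer runs ≤ 6 and a self reverse-complement
match < 12 bp. These filters are standard long-oligo synthesis hygiene,
not specificity criteria, and are all configurable. Passing candidates are
ranked by a *specificity margin*: the minimum over criteria of the
normalized distance from the threshold, e.g. `(90 − identity)/90`.
Maximizing this margin selects probes far from every rejection boundary,
so small changes in the sequence universe do not flip their status. Ties
break to the leftmost window. Two probes per target are kept by default —
a trade-off between redundancy and array real estate; per-target
multiplicity is a design convention, not a derived quantity.

Group-specific probes are enumerated from the longest family member
(maximizing the candidate space) and screened against all members; the
nontarget pool automatically excludes sequences sharing the target's
family id.

Legacy probes are revalidated with the same machinery: a probe survives
only if some current target contains it verbatim (stretch = probe length)
and it still passes the nontarget screen. A probe's coverage is its
exact-containment targets plus declared targets present in the current
set; targets covered only by retired probes are returned for re-design.

# Mismatch controls and layout

MM controls divide the PM 50-mer into five 10-nt segments and substitute
one uniformly chosen position per segment with a uniformly chosen
alternative base — 5 mismatches, 10% divergence. No attempt is made to
avoid creating new stretches: that is the plainest reading of a random
segment-wise rule, and the controls are interpreted through their signal
ratio, not their sequence. Generation is deterministic given the seed;
batch generation derives one substream per probe id so the set is
insensitive to processing order.

Layouts deal probes round-robin across subarrays per class, keeping PM/MM
partners in one subarray (their ratio is only meaningful against the same
local background), and require at least one negative control and one CORS
spot per subarray — the minimum for background estimation and
normalization to be defined at all. Calling additionally needs ≥ 2
negative controls per subarray for a background standard deviation; small
negative-control counts make the SNR denominator noisy, so realistic
layouts should carry several per subarray (physical arrays carry
thousands).

# The hybridization simulator

The generator emulates the evaluation experiments an FGA undergoes —
spike-in dilution series against a community background, PM/MM specificity
panels, dose-response curves — not a physical scanner. Expected specific
signal for probe *p* is

```
E[p] = gain × Σ_components mass × Σ_members yield(identity(p, member)) × (GC_p / 0.5)^gc_exponent
```

with `yield(id) = crosshyb_decay^(100 − id)` above an identity floor and 0
below it. A component's mass is a *genomic dose*: every member gene of a
pool scales with the component's full mass, the way every gene of a genome
does. Observed intensity multiplies the expectation by lognormal spot
noise (mean 1, CV `noise_cv`), adds Gaussian background, clips at zero and
saturates at the 16-bit ceiling. Negative controls receive background
only; CORS spots receive a fixed spike independent of the mixture, which
is precisely what makes cross-array rescaling legitimate.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `gain` | 100 units/ng | puts a 0.5 ng dose at SNR ≈ 2.5 over the default background, mirroring sub-ng detection limits |
| `gc_exponent` | 4 | a 37% vs 63% GC probe pair differs ~8× in sensitivity, the order of magnitude separating low- and high-GC organisms |
| `crosshyb_decay` | 0.1^(1/10) | yield(90%) = 0.1 exactly: probes at the 90% identity boundary pick up ~10% signal, making PM/MM ratios cluster near 10 |
| `crosshyb_identity_floor` | 85% | below this, cross-signal is negligible on real arrays |
| `background_mean`, `background_sd` | 100, 20 | weak additive background typical of a clean scan |
| `noise_cv` | 0.1 | replicate spot CV of a well-behaved single-channel hybridization |
| `saturation` | 65535 | 16-bit scanner |

The synthetic sequence generator grows each gene family from a random
ancestor of exact target GC composition; members carry substitutions at
half the requested family divergence so pairwise member identity lands at
the requested value (asserted within 2 points), and nontargets are the
same ancestors mutated at the requested divergence, emulating distant
homologs. What the generator does *not* model: spatial artifacts,
gridding errors, dye chemistry, partial-length targets, indels (all
alignment is ungapped), and any sequence-specific binding kinetics beyond
the GC factor. Passing tests therefore demonstrate the correctness of the
analysis machinery under the stated model, not the wet-lab performance of
any physical array.

# Signal analysis conventions

* **Background and SNR.** Per subarray within each array: background mean
  and sample standard deviation (n − 1) from negative controls;
  SNR = (raw − mean)/sd; positive iff SNR > 2, strictly. Net intensity
  floors at 0. If the negative controls have zero spread the SNR is
  undefined; such spots are flagged and fall back to `raw > mean`.
* **PM/MM ratio.** net(PM)/net(MM) with both nets floored at 1 intensity
  unit to avoid division by zero. A pair is called positive when the ratio
  exceeds 1.3 *and* the PM spot is itself SNR-positive: a large ratio
  between two background-level spots is noise, not hybridization, and
  without the PM-positivity condition the background false-positive rate
  at the default noise is far above what the ratio threshold suggests.
* **Normalization.** Each array is scaled by the global-to-local ratio of
  mean CORS intensity. This equalizes CORS means across arrays, preserves
  within-array ratios exactly, and is idempotent.
* **Quantitation.** Per probe, `log10(mean net)` regressed on
  `log10(mass)` over samples where the probe is detected; probes with
  fewer than 3 detected points are excluded and counted. Detection uses a
  replicate-majority rule: positive in ≥ 2 of 3 replicates by default
  (the per-spot rule is the only one fixed by convention; the replicate
  rule is configurable). Saturated series flatten the slope below 1 and
  can be flagged by passing the ceiling.
* **Community statistics.** Richness is the number of detected genes;
  Shannon–Weaver H′ uses natural log over relative normalized intensities
  (intensity as abundance proxy is the standing FGA convention); evenness
  is H′/ln S. Group contrasts report the relative difference
  (m₁ − m₂)/max(m₁, m₂) — bounded in [−1, 1], sign-flipping under group
  exchange — with a two-sided Mann–Whitney U p-value, significant at
  two-tailed p < 0.1 (i.e. one-tailed 0.05). No multiple-testing
  correction is applied by default, matching field practice for these
  screens; a Benjamini–Hochberg column is available. Note that with 3
  samples per group the smallest attainable exact two-sided p is 0.10,
  which strict `p < 0.1` excludes — significance at n = 3 per group is
  only reachable through the normal approximation under ties; 4 or more
  samples per group are needed for exact significance.

# Problem sizes and determinism

The test suite and examples run on deliberately small instances: families
of 3 members, 150-nt genes, pools of ~20 sequences, arrays of a few dozen
probes, 8-point dilution series in triplicate. These sizes exercise every
code path while keeping the full suite around a minute; the kernels
(ungapped register scan and longest common substring, implemented in C++)
scan desk-scale pools exactly, with no heuristic seeding. All stochastic
stages draw from per-stage substreams derived from a single run seed, so
identical inputs and seed reproduce outputs bit for bit, and adding a
stage never perturbs the draws of earlier ones. The dose-response
demonstration uses a reduced gain (10 units/ng) so the positive-fraction
curve spans the 1–1000 ng mass series instead of saturating at its first
point.

# Known limitations

* Ungapped identity only; a gapped homolog could evade the identity screen
  (though rarely the stretch and ΔG screens).
* Heteroduplex ΔG ignores mismatch-specific stacking; values near the
  thresholds should be read as screen scores, not physical energies.
* ΔG is evaluated at the best-identity register only.
* Group-probe intensities are reported per probe; mapping a group probe's
  signal back to individual member genes is not attempted.
* The simulator's cross-hybridization curve is a declared stand-in;
  conclusions drawn from it are property-level (ordering, monotonicity,
  ratio separation), never quantitative predictions for a physical array.
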