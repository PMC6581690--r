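# fgarray

Design and analysis toolkit for **functional gene arrays** (FGAs) —
oligonucleotide microarrays whose 50-mer probes target functional genes
(C/N/S/P cycling, contaminant degradation, metal homeostasis, ...) across
whole microbial communities rather than a single organism. The central
difficulty of FGA design is cross-hybridization: environmental samples
contain thousands of homologs of every gene, so each probe must be screened
against a nontarget sequence universe before it earns a spot on the array.

`fgarray` implements the complete desk-side workflow:

1. **Probe design.** Every 50-nt window of a target is a candidate, filtered
   by synthesis hygiene (GC 30–70%, homopolymer ≤ 6, self-complementarity
   < 12 bp) and screened against the nontarget pool under three joint
   criteria, evaluated over both strands:
   - ungapped sequence identity `< 90%`,
   - longest continuous sequence stretch `< 20 bp`,
   - nearest-neighbor duplex free energy `ΔG°37 > −35 kcal/mol`.

   *Group-specific* probes (one probe covering a whole gene family) must in
   addition bind every family member tightly: identity `> 94%`, stretch
   `> 35 bp`, `ΔG°37 < −60 kcal/mol` to the weakest member. All inequalities
   are strict; boundary values fail.
2. **Controls.** Mismatch (MM) partners for perfect-match (PM) probes are
   built by splitting the PM 50-mer into 5 equal segments and substituting
   one random base per segment (5 mismatches = 10% divergence). Layouts
   place negative controls and common oligonucleotide reference standards
   (CORS) in every subarray.
3. **Legacy revalidation.** Probes inherited from a previous array version
   stay only if they are still exactly contained in a current target *and*
   still pass the nontarget screen; targets covered only by retired probes
   are recycled into the design queue.
4. **Hybridization simulation.** A generative model of community
   hybridizations — linear dose response, GC-dependent efficiency,
   identity-dependent cross-hybridization (≈10% yield at 90% identity, zero
   below 85%), lognormal spot noise plus Gaussian background, 16-bit
   saturation — so every downstream routine is testable without a scanner.
5. **Signal analysis.** Positive calls at SNR > 2 against per-subarray
   negative controls, PM/MM ratio calls at ratio > 1.3, CORS-based
   cross-array normalization, per-probe log₁₀–log₁₀ quantitation fits over
   dilution series, and community statistics: richness, Shannon–Weaver
   diversity H′ = −Σ pᵢ ln pᵢ, evenness H′/ln S, and between-group
   contrasts using the relative difference (m₁ − m₂)/max(m₁, m₂) with
   two-sided Mann–Whitney U tests (significant at two-tailed p < 0.1).

## Worked example

```r
library(fgarray)

# three synthetic gene families (GC 40/50/60%, 97% within-family identity)
# and a divergent nontarget pool
pools <- make_synthetic_pools(n_families = 3, members_per_family = 3,
                              within_family_identity = 97,
                              gc_targets = c(0.4, 0.5, 0.6),
                              seq_length = 150, seed = 1)
universe <- rbind(pools$targets, pools$nontargets)

probes <- select_sequence_specific(pools$targets[1, ], universe,
                                   k = 2, step = 2)
as.data.frame(probes)[, c("probe_id", "start", "nt_max_identity_pct",
                          "nt_max_stretch_bp", "nt_min_dg_kcal", "passed")]
#>       probe_id start nt_max_identity_pct nt_max_stretch_bp nt_min_dg_kcal passed
#> 1 fam01_m1_p18    18                  52                 8         -20.24   TRUE
#> 2 fam01_m1_p64    64                  54                 7         -18.28   TRUE

pair <- generate_mm_probe(probes$sequence[1], seed = 42)
pair$mismatch_positions
#> [1]  0 14 20 38 49
```

The two selected probes sit far from every rejection threshold: their worst
nontarget identity (52–54%) is well under 90%, the longest shared stretch
(7–8 bp) is well under 20 bp, and the strongest predicted nontarget duplex
(−18 to −20 kcal/mol) is far above the −35 kcal/mol cutoff. The MM control
differs from its PM parent at exactly one position inside each 10-nt
segment.

The same stages are scriptable from a YAML configuration through
`fga_run()` (subcommands `design`, `design-group`, `validate-legacy`, `mm`,
`layout`, `simulate`, `call`, `normalize`, `quantify`, `stats`) or from a
shell via the thin wrapper in `inst/cli/fga.R`.

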