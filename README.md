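# exoorg

Positional organization of transcription-factor complexes from ChIP-exo
peak pairs.

## The problem

ChIP-exo trims immunoprecipitated chromatin with a 5'→3' lambda
exonuclease that stalls ~6 bp 5' of each protein–DNA cross-link. Tag 5'
ends therefore accumulate at two sharp strand-separated positions
flanking every cross-link — a plus-strand peak ~6 bp below it and a
minus-strand peak ~6 bp above it, ~12 bp apart. Pairing those peaks and
taking the midpoint localizes individual cross-link points to within a
few base pairs, which is precise enough to ask *where inside a
multi-protein complex each factor touches DNA*.

`exoorg` implements this inference end to end for the GATA1/TAL1
erythroid system: strand-separated Gaussian-smoothed peak calling with
an exclusion zone (σ = 5, exclusion = 10), plus/minus peak pairing
(separation window −5..+25 bp), binomial enrichment testing against an
input control (>2-fold, Benjamini–Hochberg q < 0.05), consolidation of
locations across conditions (40 bp) and intersection with an external
event list (100 bp), exact IUPAC/PWM motif scanning (p < 10⁻³) with
motif centering (40 bp), motif-anchored composite profiles (5-bp moving
average) with cross-link point estimation, composite-motif
(TG[N7–8]WGATAA) spacing analysis and ZZNNTG E-box classification,
factor-specific occupancy windows (GATA1 −25..+25, TAL1 −40..+30),
homotypic clustering (<500 bp, median coordinate) with nearest-TSS
expression comparison (Mann–Whitney), ChIP-exo/ChIP-seq concordance
(40-bp midpoint overlap; Spearman on log₁₀ counts in 400-bp windows),
and k-means kinetic classification (k = 6) of total-count-normalized
log₂ occupancy changes.

It ships a tested synthetic-data generator that encodes the structural
model — exonuclease stop offset 6 bp, GATA1 cross-links at the WGATAA
edges (−8/+8 from the motif reference point, major upstream), TAL1
cross-links upstream at −21/−13 flanking the TG half E-box, lognormal
occupancy, uniform background, and a sonication-breakpoint ChIP-seq
model — together with ground-truth tables, so the whole calling chain
can be validated against known geometry.

## Worked example

Simulate 250 WGATAA sites, generate GATA1 ChIP-exo tags under the
two-cross-link model, and recover the cross-link geometry from the
motif-anchored composite profile:

```r
library(exoorg)

genome <- generate_genome(250000, gc_fraction = 0.42, seed = 11)
sim <- embed_sites(genome, site_spec(n_gata_only = 250,
                                     min_site_separation = 1000),
                   seed = 12)
sl <- c(chr1 = nchar(sim$genome[[1]]))
track <- simulate_exo_tags(sim$truth, gata1_model(), sl,
                           mean_tags_per_site = 50, seed = 13)

anchors <- data.frame(chrom = sim$truth$chrom,
                      reference_point = sim$truth$reference_point,
                      strand = sim$truth$motif_strand)
profile <- composite_profile(track, anchors, flank = 60, smooth = 5)
estimate_crosslinks(profile)
```

```
  crosslink_offset separation intensity plus_offset minus_offset
1               -8         12  27.41571         -14           -2
2                8         12   9.29175           2           14
```

Read: the composite profile contains two plus/minus peak pairs, each
with the canonical 12-bp separation; their midpoints sit at −8 and +8
from the motif reference point (16 bp apart, i.e. at the two edges of
WGATAA), and the upstream pair carries ~3× the intensity — exactly the
double-pair geometry and major/minor asymmetry the generator encoded.

The full calling chain is exercised the same way:

```r
input <- simulate_input_track(sl, total_tags(track) / (2 * sl[[1]]),
                              seed = 14)
locs <- call_locations(track, input)   # pairs -> enrichment -> locations
```

`analysis/01_simulate.R` … `analysis/05_seq_vs_exo_kinetics.R` run the
complete study on a 350-kb synthetic genome (cobound, GATA-only and
E-box-only sites; three GATA1 activation time points; TAL1; input;
ChIP-seq; TSS/expression tables), writing all tables under `results/`.
Run them in order from the repository root.

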