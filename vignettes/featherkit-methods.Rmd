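---
title: "featherkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{featherkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featherkit)
```

featherkit bundles three computations used when mapping a feather-form
mutation — quantitative rachis-shape analysis from photographs, prediction of
the splicing consequence of a donor-site deletion, and two-point linkage
analysis of small pedigrees — together with seedable synthetic-data
generators that provide ground truth for all of them. This vignette explains
the models, the numerical choices, and what the synthetic validation does and
does not establish.

## Rachis morphometry: the tangent-angle profile θ(s)

A feather is treated as a two-dimensional object photographed from the dorsal
side. The *backbone* of the rachis is the curve equidistant from its two
edges (the rachis has a width, so its midline must be defined through both
fringes). Arc length from the proximal end is `s`, the total length is `L`,
and the bending of the rachis is summarised by the tangent angle `θ(s)` —
the orientation of the best local straight-line approximation to the
backbone, measured against an arbitrary fixed reference direction. Profiles
from different feathers are compared on the length-normalised coordinate
`u = s/L`. Because the reference direction is arbitrary, *every* comparison
in the package operates modulo an additive constant.

The measurement pipeline is:

1. **Segmentation** (`segment_feather`): Otsu threshold, largest connected
   component, hole filling.
2. **Fringe extraction** (`extract_fringes`): the silhouette boundary is
   traced and split at the two geodesically most distant points of the
   silhouette (the tips) into two edge polylines. The proximal end is the
   end with the larger mean width over its terminal 5% (the calamus); a tie
   falls back deterministically to the end nearer the image origin, and
   `flip_orientation` overrides the choice.
3. **Backbone** (`compute_backbone`): points of one fringe are paired with
   their nearest points on the other; midpoints are refined to equidistance
   from both polylines. The rounded tip caps of the silhouette are excluded
   from pairing — a cap-rim point lies within `sqrt(2) * r` of the tip while
   the true fringe does not, with `r` the local half width — so that the
   backbone starts and ends at the axial positions of the true midline ends.
   The result is resampled to at most 0.25 mm spacing.
4. **Smoothing** (`smooth_backbone`): the coordinates, as functions of arc
   length, are convolved with a Gaussian of σ = 3 mm (the default length
   scale for suppressing image noise). The curve is extended linearly by 5σ
   at both ends before convolution; a plainly renormalised truncated kernel
   drags the endpoints inward and shortens the curve by several
   millimetres. Whether one should smooth the coordinates or θ itself is a
   genuinely open choice; featherkit smooths coordinates, which keeps the
   backbone a curve in the plane at every stage.
5. **Tangent angles** (`tangent_angle_profile`): at each position, θ is the
   orientation of the total-least-squares line fitted over a centred 3-mm
   arc-length window (windowed moments via cumulative sums). Orientation is
   defined modulo 180°; it is disambiguated by the local direction of
   travel, unwrapped to a continuous function (nearest multiple of 360°),
   and resampled onto a uniform grid of 512 `u` values. Finite differences
   were rejected for tangent estimation as needlessly noise-amplifying.

**Kinks** (`detect_kinks`) are maximal runs where `|dθ/ds|` exceeds
5°/mm for at least 0.5 mm; runs closer than 2 mm merge, and each run is
called at its rate-weighted centroid. The thresholds are configurable: kinks
are identified visually in practice, so the defaults are validated only
against planted synthetic kinks.

**Group statistics.** Feathers from opposite wings should be mirror images:
mirroring flips the sign of θ up to a constant, so
`mirror_symmetry_residual` reports the RMS over `u` of
`mean θ_left + mean θ_right` after removing its best-fitting constant.
`profile_dispersion` centres each profile by its own mean and reports the
mean across-profile standard deviation — small when profiles converge on the
normalised coordinate, large when they are diverse.

### Validation at the measurement scale

The synthetic generator renders a ribbon of known width swept along the
integral curve of a known `θ_true(u)`, with correlated sub-pixel edge
jitter. Pipeline accuracy is scored against the **kernel-matched
reference** (`reference_profile`): the exact ground-truth curve passed
through the same 3-mm smoothing and tangent-window fit. This is deliberate.
An estimator operating at a 3-mm smoothing scale cannot, and should not,
reproduce sub-kernel detail: a 60° kink ramped over 1 mm is necessarily
spread over ±σ by the smoothing, and comparing against the unsmoothed truth
would conflate that resolution limit with measurement error. The same
reasoning applies to length: smoothing cuts the corners of kinks, so for
kinked feathers the recovered `L` is compared at the measurement scale,
while for kink-free feathers it is within 2% of the true length.

On 20 seeded feathers per phenotype preset, the profile RMS error against
the reference (excluding 5% end margins) stays below 2°, planted kinks are
recovered with sensitivity ≥ 0.9, and false calls stay below 0.1 per
feather; rotation changes θ by a constant only, and horizontal flips negate
it, to within 0.5° RMS (allowing up to two grid cells of arc-length origin
shift, which raster resampling can introduce).

### The phenotype presets

The four presets of `preset_feather` are illustrative parameter tables, not
fits — the underlying study reports θ(s) curves, not numerical curvature
parameters, so preset values cannot be validated against printed numbers:

* `wildtype` — gentle smooth bend (25° total), no kinks;
* `heterozygous` — whole-rachis curvature (60° total) plus three ±55–60°
  kinks, matching the qualitative description of kinks along the length;
* `homozygous` — dramatically increased smooth curvature (210° total) and
  *less* kinking (none planted);
* `krt75_mt` — moderate base curvature, two large kinks, a severe bend over
  the distal third, and much larger seeded feather-to-feather variability,
  which is what makes its group dispersion exceed the wildtype's.

Kink steps of ≈55–60° over a 1-mm ramp were chosen so that planted kinks
remain above the default 5°/mm threshold after 3-mm smoothing (a step Δθ
smoothed by σ has peak rate ≈ Δθ/(σ√2π)); markedly smaller kinks are
invisible at that smoothing scale by construction. Feathers are 130 mm long,
2.8 mm wide at the calamus tapering to 1.4 mm, rendered at 0.15 mm/px with
0.5 px edge jitter — a realistic contour-feather geometry. The generator's
rasters are idealised: uniform background, no barb occlusion of the rachis
(optional barb texture is rendered outside the returned rachis mask, off by
default, because the analysis concerns the rachis only), no illumination
gradients or shadows. Passing tests therefore demonstrate correctness of the
geometry pipeline, not robustness to photographic artefacts.

## Splice consequence of a donor-site deletion

`gene_model` holds a plus-strand genomic sequence with ordered exon
intervals (1-based inclusive coordinates throughout, for genome, CDS and
protein alike) and a CDS in spliced-mRNA coordinates.
`classify_junction_damage` marks a donor as lost when a deletion overlaps
its junction motif (last exonic nucleotide through the annotated donor motif
at the intron start), and analogously for acceptors. When a donor is lost,
`find_cryptic_donor` scans the surviving exonic sequence for hexamers
beginning `GT` and scores each by Hamming identity to the authentic donor
hexamer — the deliberately simple reading of "resembles the authentic
site"; no position-weight-matrix or maximum-entropy model is used, keeping
the scan dependency-free and easily replaced. Ties break toward the
candidate nearer the lost junction. `splice_mutant` then truncates the
damaged exon immediately before the chosen cryptic `GT` and splices; with no
candidate at all the intron is retained and a premature-stop scan is
reported. Acceptor rescue is intentionally unimplemented (`NotSupported`):
the motivating variant destroys a donor.

Two coordinate conventions coexist deliberately, mirroring how such variants
are reported in practice. The **CDS deletion interval** is mechanical: the
wild-type mRNA nucleotides physically absent from the mutant transcript
(genomic deletion plus cryptic truncation), which is how the 69-nt deletion
at CDS 934–1002 is printed. The **protein deletion interval** comes from
aligning the wild-type and mutant proteins and is left-aligned when a
flanking residue repeat makes the deletion ambiguous — which is how the
23-residue loss is printed as 311–333 rather than the codon-arithmetic
312–334. The KRT75-like preset (`krt75_like_gene`) plants an identical
codon at residues 311 and 334 to reproduce that repeat; its sequence is
otherwise random — only the printed structural coordinates (802 coding nt
upstream of a 200-nt fifth exon, GTGAAG at −69, an 84-bp deletion from −25
exonic to +59 intronic) are reproduced, not the real KRT75 sequence. The
printed exon/intron span of the real deletion ("−24 to +59", 83 nt) is one
short of its genomic coordinates (84 bp); featherkit trusts the genomic
coordinates.

The generator guarantees the planted cryptic site is the unique best-scoring
candidate in its exon by scrubbing every other `GT` dinucleotide there
(`T → C`, which can create neither a new `GT` nor a stop codon). A cryptic
hexamer needs six exonic nucleotides, so offsets below 6 are rejected as
colliding with the junction; the frame-law sweep therefore runs offsets
6–120 and separately asserts the rejection of 1–5.

## Two-point linkage

`two_point_lod` computes `log10 L(θ)/L(0.5)` exactly. Each individual's
state is an ordered, phased two-locus genotype — paternal and maternal
(trait, marker) haplotypes, 16 states — so the likelihood is the sum over
founder states (disease allele frequency 0.001 by default, complete
dominant penetrance `f(DD)=f(Dd)=1, f(dd)=0`), phases, and transmissions,
with sex-averaged recombination. Childless individuals collapse into exact
16×16 couple messages via the gamete-emission matrix; the remaining
variables are eliminated by greedy variable elimination. No Lander–Green
algorithm and no MCMC: pedigrees here are small (tens of individuals), and
exact elimination is fast because offspring dominate. Consanguineous
pedigrees are refused (`NotSupported`); unknown affection is summed over
both phenotype states; marker allele frequencies default to 0.5/0.5 and are
configurable, though they matter little when founder genotypes are observed
(they cancel between numerator and denominator). The θ grid defaults to
0–0.5 in steps of 0.01, with θ = 0 evaluated at 10⁻⁶ to avoid log-of-zero
when an obligate recombinant is present, and ties in the argmax resolve to
the smaller θ.

The engine is verified three ways: `LOD(0.5) = 0` analytically; agreement to
10⁻⁹ with an independent brute-force oracle that enumerates every ordered
phased genotype configuration on 200 random pedigrees of up to 8 members;
and the closed-form limit — n phase-known informative non-recombinant
meioses give max LOD `n·log10 2` (the test pedigree fixes the sire's phase
through genotyped grandparents; without them one meiosis is spent inferring
phase and the maximum drops by `log10 2`).

`check_mendelian` reports trios whose child genotype is impossible given the
parents, never flagging missing data. `haplotype_share` performs rule-based
transmission inference for the half-sib design: the paternally transmitted
allele is the child allele whose partner the mother could have supplied,
kept only when unique — ambiguous transmissions stay missing, never imputed.
Markers where the sire is homozygous or no affected offspring has an
inferred allele are bridged (they neither support nor break a sharing run).
The consensus carrier haplotype is the modal inferred allele among affected
offspring; offspring with mismatches are reported as recombinants with the
breakpoint bracketed by flanking informative markers.

### The simulated cross

`cross_spec` defaults are the mapping-study conditions: one heterozygous
carrier sire bred to 5 wild-type dams, 39 offspring (8+8+8+8+7, i.e. 45
genotyped birds), 2678 biallelic markers, 99.37% call rate, disease allele
frequency 0.001 — so `genotyping_summary` on a default simulation averages
≈ 2661 genotypes per bird. Missingness is independent per genotype call,
matching only the average call rate (no bird- or marker-level clustering).
Maternal marker alleles are drawn independently per marker (no maternal
linkage map), which is immaterial for two-point statistics on paternal
meioses. The reported LOD scores of the original scan (7.34 and 6.5) depend
on genotypes available only graphically, so they serve as context, not as
simulation targets; the θ-recovery condition (200 crosses of 100 informative
meioses at θ = 0.05, mean θ̂ within 0.02) plays that role instead.

## Problem sizes and reproducibility

Every stochastic component flows from one root seed through labelled child
streams (`child_seed`), so identical configuration plus seed reproduces
rasters, genotypes and reports byte for byte. The validation suite uses 20
feathers per preset for morphometry recovery, 200 random pedigrees for
oracle equivalence, and 200 simulated crosses for θ recovery — sizes at
which the checked means are stable to well inside their tolerances while a
full run stays comfortably interactive. `scripts/acceptance.R` recomputes
the headline quantities from scratch at the same sizes.

## Known limitations

* Morphometry is strictly planar: twist (torsion) of real frizzle feathers
  is not measured, only in-plane bending; no barb/barbule quantification.
* Absolute θ values carry an arbitrary reference and are not comparable
  across laboratories; only shapes modulo a constant are.
* The cryptic-donor score is a 6-nt identity count — adequate to rank a
  planted site and the motivating variant, but not a general splice-strength
  model.
* Minus-strand gene models and acceptor-loss rescue are not supported.
* The linkage engine targets loop-free pedigrees of at most a few dozen
  individuals; multipoint analysis, X-linkage, imputation and association
  testing are out of scope.
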