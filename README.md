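# featherkit

Tools for mapping a feather-form mutation end to end, in R:

* **Rachis morphometry** — extract the backbone (midline) of a feather
  rachis from a dorsal-view photograph and quantify its bending as the
  tangent-angle profile θ(s) on the length-normalised coordinate u = s/L;
  detect kinks, score bilateral mirror symmetry, and measure across-feather
  profile dispersion.
* **Splice-consequence prediction** — given a gene model and a genomic
  deletion that destroys a splice donor, find the activated cryptic donor,
  build the mutant transcript, and report the CDS and protein consequence.
  The motivating case is the frizzle (*F*) allele of chicken *KRT75*: an
  84-bp deletion across the exon 5 donor activates a cryptic GTGAAG donor
  69 nt upstream, producing a 69-bp in-frame CDS deletion (positions
  934–1002) and a 23-residue protein deletion (positions 311–333).
* **Two-point linkage** — exact LOD scores
  `LOD(θ) = log10 L(θ)/L(0.5)` for small loop-free pedigrees under a
  dominant complete-penetrance disease model, plus Mendelian-consistency
  checking, haplotype-sharing analysis of half-sib crosses, and
  genotyping call-rate bookkeeping.
* **Synthetic data with ground truth** — seedable generators for feather
  images (known backbone and θ_true), gene models (planted cryptic donors),
  and simulated mapping crosses (known transmissions), so every stage is
  testable without external data.

The audience is researchers quantifying appendage shape phenotypes and
mapping the underlying Mendelian variants — and anyone wanting a compact,
fully tested reference implementation of tangent-angle morphometry, cryptic
splice-site reasoning, or exact small-pedigree likelihoods.

## The statistics in brief

The rachis backbone is the curve equidistant from the two rachis edges,
parameterised by arc length s with total length L. Its bending is θ(s), the
orientation of the local total-least-squares line fit (3-mm window) to the
backbone after 3-mm Gaussian arc-length smoothing; θ carries an arbitrary
additive reference, so all comparisons are modulo a constant. A kink is a
run of |dθ/ds| > 5°/mm. The two-point LOD is computed by exact variable
elimination over phased two-locus genotypes (16 states per individual),
summing over founder genotypes at stated allele frequencies, phases and
transmissions, with sex-averaged recombination.

## Worked example

```r
library(featherkit)

## splice consequence of the KRT75-like deletion
g <- krt75_like_gene(seed = 1)          # synthetic gene, printed coordinates
deletion_length(g$variant)              # 84
cand <- find_cryptic_donor(g$model, g$variant)
cand
#>    pos hexamer score offset_nt
#> 1 1294  GTGAAG     3        69
splice_mutant(g$model, g$variant, cand)
#> <splice_outcome>
#>   CDS deletion 934-1002 (69 nt), in frame
#>   protein deletion 311-333 (23 aa)
amplicon_lengths(851, g$variant)$mut_len   # 767

## measure a synthetic mutant feather
fe <- generate_feather_image(preset_feather("krt75_mt", seed = 1))
pr <- measure_feather(fe)               # segment -> fringes -> backbone -> theta(u)
pr
#> <theta_profile> 512 samples, L = 127.4 mm, theta range [-7.2, 88.8] deg
detect_kinks(pr)
#>    u_center angular_rate_deg_per_mm extent_mm
#> 1 0.3483401                9.578708  5.983832
#> 2 0.5967130                7.718289  4.487874
```

The two kink calls sit at u = 0.348 and 0.597 — the preset plants kinks at
0.35 and 0.60 — with peak angular rates well above the 5°/mm threshold. A
ten-offspring fully linked phase-known backcross reproduces the textbook
maximum LOD of 10·log10 2:

```r
sc <- lod_scan(ped, 1)                  # ped: 10 informative meioses, theta = 0
sc
#> <two_point_result> M1: max LOD 3.010 at theta = 0.000
```

A complete demo (images, profiles, gene model, PED/MAP, LOD table, reports)
runs from one config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "featherkit"))
```

or from the shell via the thin CLI,
`Rscript inst/scripts/featherkit-cli.R pipeline --config demo_config.yaml`
(subcommands: `simulate-feather`, `simulate-gene`, `simulate-cross`,
`measure`, `compare`, `splice-consequence`, `pedcheck`, `lod`,
`haploshare`).

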