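# dnaBII

Analysis of the BI/BII phosphate-backbone equilibrium in B-DNA duplexes.

The phosphodiester linkage of B-DNA interconverts between two substates
defined by the ε/ζ torsion pair — **BI** (ε/ζ: *trans*/*g−*, (ε−ζ) ≈ −90°)
and **BII** (ε/ζ: *g−*/*trans*, (ε−ζ) ≈ +100°). The balance of the two
states is sequence dependent, is reported in solution by the ³¹P chemical
shift δP through the empirical conversion

    BII(%) = 143 δP + 621        (δP in ppm, TMP reference)

and is mechanically coupled to the inter base-pair parameters slide, roll
and twist. Within a complementary dinucleotide NpN•NpN the two *facing*
phosphates (one per strand) jointly occupy one of the combinations BI•BI,
BI•BII, BII•BI or BII•BII; when their states are statistically independent
the pooled combination populations follow from the individual BII
probabilities alone:

    P(BII•BII)       = p_i p_j
    P(BI•BII|BII•BI) = p_i + p_j − 2 p_i p_j
    P(BI•BI)         = 1 − the other two

together with the counting identity
`P(hybrid) + 2 P(BII•BII) = p_i + p_j`, which holds on any labelled
trajectory whatsoever.

The package is aimed at people analysing MD trajectories of DNA (or NMR
shift sets) who want to go from per-frame torsion/pucker series to:

* per-frame BI/BII states and per-phosphate BII percentages, with
  convergence diagnostics and histogram-based cutoff suggestion;
* facing-phosphate combination populations, a census of the four
  transition types, and an independence diagnostic of the two strands;
* NMR-derived BII percentages, tolerance bands, and combination
  populations inferred from shifts under independence;
* combination-conditional means/SDs of the six inter base-pair parameters.

A two-state Markov generator of synthetic duplex trajectories (torsions,
puckers, helical parameters, chemical shifts) with controllable stationary
BII probabilities, dwell times and cross-strand coupling makes every stage
testable without running MD.

## Worked example

A synthetic shift table for a dodecamer is shipped as a small CSV; we use
its converted BII percentages as generator targets, run the full analysis,
and compare back against the shifts:

```r
library(dnaBII)
topo <- duplex_topology("CGCACGTACGCG", "Oligo 4")
shifts <- read_shift_table(system.file("extdata", "synthetic_shifts_oligo4.csv",
                                       package = "dnaBII"))
fit <- analyze_duplex(topo, n_frames = 50000,
                      target_bii = shifts$bii_pct / 100,
                      persistence = 0.99, shifts = shifts, seed = 42)
fit
#> BI/BII backbone analysis: Oligo 4
#>   50000 frames x 18 phosphates, cutoff (eps-zeta) > 0 deg
#>   overall BII 27.1%
#>   combinations: BI.BI 55.2% | hybrid 35.4% | BII.BII 9.4%
#>   independence r: hybrid 0.995, BII.BII 0.998
#>   simultaneous two-phosphate transitions: 0.22%
#>   BII.BII - BI.BI: slide +0.80 A, roll -11.0 deg, twist +9.8 deg
#>   vs NMR: CC 0.89, delta_av 5.0
```

Reading the output: the 18 central phosphates average 27.1% BII; the
frame-counted facing-pair populations agree with the factorised
predictions (Pearson r ≥ 0.99 for both pooled categories), and only 0.22%
of combination transitions move both phosphates at once — the signature of
independent facing dynamics. Conditioning the helical parameters on the
combinations recovers the coupling put into the generator: going from
BI•BI to BII•BII shifts slide by +0.8 Å, roll by −11° and twist by +9.8°.
The simulated BII percentages track the shift-derived ones (CC 0.89, mean
absolute difference 5 points, inside the ±10-point conversion tolerance).

`summary(fit)` returns the per-phosphate and per-step tables,
`plot(fit)` draws the (ε−ζ) histogram and the independence scatter, and
`write_bii_analysis(fit, "out/")` writes the CSV/JSON report bundle.

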