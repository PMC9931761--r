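# scnet

Separating **emotional stress (ES)** from **physical stress (PS)** in
multi-band facial video. Both stress types perturb facial tissue blood
oxygen saturation (StO₂), but the perturbations are weak, noisy and
subject-dependent, so no single region's raw time series classifies
them. `scnet` implements the full pipeline that makes the problem
tractable, plus a forward-model simulator so every stage can be
verified against planted ground truth. It is aimed at researchers in
imaging photoplethysmography / affective computing who want a
reproducible, testable reference implementation at desk scale.

## The method

1. **StO₂ inversion.** Per pixel and frame, absorbance at four bands
   (540/556/560/576 nm) follows the Beer–Lambert model
   `A(λ) = ε_HbO₂(λ)c₁ + ε_Hb(λ)c₂ + ε_mel(λ)c₃ + G′`; the 4×4 system
   is solved exactly and `StO₂ = c₁/(c₁+c₂)`.
2. **Composite ROI selection.** Seven facial regions are ranked by
   `ε = m·λ_MSC + n·δ`: `λ_MSC = λ_max/λ₊` compares the top eigenvalue
   of the across-subject equal-time correlation matrix with the
   Marchenko–Pastur edge `λ± = 1 + 1/U ± 2/√U` (`U = T/N`) —
   universality of the response; `δ` is a coarse-wavelet correlation
   of windowed mean/variance features against a strong-response
   reference — strength of the response.
3. **Eulerian magnification.** StO₂ stacks are decomposed into
   Mexican-hat spatial sub-bands; the 1.2–2 Hz temporal band is
   amplified by `a = 20` (displacement gain `1 + a = 21`), with an
   optional noise-aware gain attenuation.
4. **MN-VLAD encoding.** Magnified windows become dense 128-D
   gradient-histogram features, quantized on a k-means codebook with a
   five-layer neighbor graph; integer-ambiguity least squares decides
   which neighbor words share each residual.
5. **LSTM classification.** Descriptor sequences are classified by a
   gate-equation LSTM trained with exact BPTT, subject-level 50/50
   split.

## Worked example

```r
library(scnet)

report <- runAll(scnetConfig(), seed = 1)
report
#> scnet run (seed 1 )
#>   selected ROI: mouth (planted: mouth)
#>   held-out accuracy: 0.900
#>     predicted
#> true ES PS
#>   ES  8  2
#>   PS  0 10
head(report$roi_ranking, 3)
#>          roi lambda_msc lambda_msc_scaled     delta   epsilon
#> 1      mouth   13.59266                 1 0.6935280 0.8467640
#> 2  left_face   11.14636                 1 0.5722597 0.7861298
#> 3 right_face   11.11542                 1 0.5717511 0.7858756
```

The run simulates a 40-subject, 60 s cohort, recovers StO₂, ranks the
seven candidate ROIs (the planted responsive region — the mouth — wins:
its multisubject correlation statistic `lambda_msc` is far above the
random-matrix bound *and* its strength correlation `delta` is highest),
magnifies the 1.2–2 Hz band, encodes MN-VLAD sequences and reports the
held-out confusion matrix over the 20 test subjects. Rerunning with the
same seed reproduces every number bit-for-bit.

Individual stages are exported (`extractStO2`, `selectRoi`,
`magnifyStack`, `encodeMNVlad`, `trainLstm`, ...), and
`inst/cli/scnet.R` provides a thin command-line wrapper
(`Rscript inst/cli/scnet.R run-all --seed 1 --out results/`).

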