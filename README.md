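# s1s2seg

Fully automated segmentation of rate-varying **S1S2 intracardiac
stimulation protocols** for amplitude and conduction-speed restitution
analysis.

During an electrophysiological restitution study, a catheter paces the
atrium with trains of fixed-interval stimuli (S1, basic cycle length
*BCL*) followed by one premature stimulus (S2) whose coupling interval
shrinks train by train until the effective refractory period (ERP) is
reached. Evaluating such recordings by hand — finding every stimulus,
uncovering the atrial response hidden next to (or under) the much larger
pacing artifact, and reading off amplitudes and activation times — is slow
and subjective. `s1s2seg` automates the whole chain for researchers
working with multichannel bipolar electrograms:

1. **Protocol inference from the signal alone.** The stimulating channel
   is identified by amplitude ranking with a spatial-adjacency check; a
   bior1.5 stationary-wavelet detector with an iteratively grown
   std-relative threshold *k* segments stimulation activity; the S1 BCL is
   the dominant value of the inter-peak interval histogram (accepted when
   its runners-up are integer multiples); pacing trains are split by
   deterministic 2-means clustering of the intervals; candidate stimuli
   must pass five trust conditions (synchrony across channels, energy
   operator agreement, principal-component amplitude and derivative
   thresholds, interval consistency) before S1/S2 tagging.
2. **Stimulus-artifact removal.** Per channel, a clean artifact template is
   taken from the shortest-S2 train (no atrial answer once the ERP is
   reached), amplitude-matched by least squares, aligned by normalized
   cross-correlation and subtracted; the leading artifact segment is
   linearly interpolated.
3. **Atrial activity detection.** The Teager–Kaiser non-linear energy
   operator `E[n] = x[n]² − x[n+1]·x[n−1]` on the cleaned trace yields
   activity windows; the local activation time (LAT) is the half-peak
   centroid of the energy pulse. Responses whose energy peak is clipped by
   the artifact window are reported undetected rather than guessed.
4. **Restitution curves.** Per channel, amplitude (peak-to-peak voltage)
   and propagation speed `p = ‖r_s − r_m‖ / LAT` (Euclidean within a
   catheter, mesh-geodesic across catheters) as functions of the S2
   coupling interval; ERP from the 20 %-of-mean-S1-amplitude rule.

A fully annotated **synthetic S1S2 generator** (biphasic stimulus pulses,
restitution-decaying atrial activities over an elliptic anisotropic
wavefront on a circular 10-electrode catheter plus CS bipoles,
clinical-spectrum noise, baseline wander, SNR scaling, random extra
beats) provides ground truth for validation, and an SNR-sweep harness
quantifies robustness.

## Worked example

```r
library(s1s2seg)

sim <- buildProtocol()                  # default synthetic S1S2 protocol
sim
#> SyntheticProtocol: 21 trains, 105 stimuli, 13 channels, 68.8 s @ 1000 Hz

run <- runPipeline(sim$recording)       # no protocol knowledge used
run$protocol
#> ProtocolEstimate: S1 BCL 600.0 ms (k = 0.04), 21 trains x 4 S1 + S2,
#>   gap 1200 ms, stim channel 1
#>   S2 intervals (ms): 500 450 400 350 340 330 320 310 300 290 280 270
#>   260 250 240 230 220 210 200 190 180

run$erp$erp_ms                          # longest non-capturing S2 interval
#> [1] 190

rep <- scoreRun(run$detections, sim$truth,
                exclude = overlapChannels(sim$truth))
rep
#> ErrorReport (SNR NA dB): 133/133 matched, 0 missed (0.0%)
#>   |LAT| error ms  Q1/med/Q3: 0.000 / 0.000 / 0.000
#>   |amp| error mV  Q1/med/Q3: 0.0055 / 0.0070 / 0.0081
#>   excluded channel(s): 2 with 13 non-detections
```

The inferred protocol matches the generator exactly (BCL 600 ms, 21
trains, all 21 coupling intervals); every evaluable atrial response is
found with zero activation-time error and amplitude deviations well below
0.05 mV. Channel 2, whose activity overlaps the pacing artifact by more
than 50 %, is deliberately reported undetected. Restitution curves are in
`run$curves` (tidy: channel, quantity, `s2_ms`, value). Noise robustness:

```r
sw <- snrSweep(snr_grid_db = c(40, 10, 0), seeds = 1)
sw$summary[, c("snr_db", "missed", "median_abs_lat_ms")]
#>             snr_db missed median_abs_lat_ms
#> snr40_seed1     40      0                 1
#> snr10_seed1     10      0                 1
#> snr0_seed1       0      0                 1
```

Even at 0 dB — noise power equal to the whole-record signal power — no
response is missed and the median activation-time error stays within one
sample (1 ms).

A thin command-line wrapper is installed under
`system.file("scripts/s1s2seg", package = "s1s2seg")` with `simulate`,
`segment`, `restitution` and `evaluate` subcommands.

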