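# erpmicro

Trial-by-trial topographic microstate analysis of event-related potentials
(ERPs), built around the overt picture-naming paradigm: the question is
*when*, between seeing a picture and starting to say its name, each
psycholinguistic property of the word does its work. The package treats the
scalp potential field as a sequence of quasi-stable topographies
(microstates), measures per single trial how long each topography lasts,
and regresses those durations on item-level predictors with crossed
random effects for participants and items.

## What it computes

**Topographic primitives.** For an average-referenced scalp map
$u \in \mathbb{R}^C$ over $C$ electrodes, the global field power is
$\mathrm{GFP}(u) = \sqrt{\tfrac{1}{C}\sum_c u_c^2}$; maps are compared by
the signed spatial correlation $r(u, v)$ and the dissimilarity
$\mathrm{DISS} = \sqrt{2(1 - r)}$. All quantities are independent of the
recording reference.

**Segmentation.** The merged grand-average ERP (picture onset to 100 ms
before articulation) is clustered over time frames with the topographic
atomize-and-agglomerate hierarchical clustering (TAAHC): every frame starts
as its own cluster and, at each step, the cluster contributing least global
explained variance (GEV) is dissolved and its frames reassigned by spatial
correlation. The number of template maps K is chosen by combining the
Krzanowski–Lai criterion
$KL(q) = |\mathrm{DIFF}(q)| / |\mathrm{DIFF}(q+1)|$ with
$\mathrm{DIFF}(q) = (q-1)^{2/C} W(q-1) - q^{2/C} W(q)$
on the within-cluster dispersion curve $W$, and a cross-validation
criterion $CV(q) = \hat\sigma^2_q \left(\frac{C-1}{C-1-q}\right)^2$.
Maps shorter than 20 ms are not retained.

**Backfitting.** Each frame of each single-trial ERP is labeled, inside
predefined fitting windows (50–180 ms, 180–460 ms, 460 ms to
articulation−100 ms), with the allowed template it correlates best with.
Per trial and map this yields presence, duration (ms) and GEV:
$\mathrm{GEV}_k = \sum_{t: L(t)=k} (\mathrm{GFP}_t\, r_t)^2 / \sum_t \mathrm{GFP}_t^2$.

**Topographic consistency test (TCT).** A randomization test of whether
trials share a topography at a frame: the GFP of the across-trial mean map
against a null built by shuffling channel values within each trial.

**Regression.** One latency model (α = 0.05) and one duration model per
map (α = 0.01, Bonferroni over five maps), each a linear mixed model with
crossed random intercepts for participants and items, by-participant
random slopes reduced on non-convergence, a second fit without residuals
beyond 2.5 SD, Satterthwaite t tests, marginal/conditional R², and
predictor tolerances. Predictors include phonological neighborhood density
(mean Levenshtein distance to the 20 closest lexicon neighbors),
positional segment/diphone frequency, log lexical frequency, concept
familiarity, visual complexity, image agreement, name agreement (% modal
name and the entropy H), and age of acquisition.

**Synthetic data.** Because no recordings ship with the package, a
generator produces ground-truthed studies: smooth orthogonal template
maps on a spherical montage, item norms with the reported predictor
correlation structure, per-trial state durations that depend linearly on
the predictors, and raw stimulus-/response-aligned epochs with sensor
noise — so every stage, and the whole pipeline, is testable end to end.

## Worked example

```r
library(erpmicro)

cfg <- synthetic_config(n_participants = 8, n_items = 30, n_channels = 32,
                        sampling_rate = 256, noise_sd_uv = 5, seed = 42)
run <- run_pipeline(cfg)
run$segmentation
#> Microstate segmentation: 5 template maps (GEV 96.62%)
#> Per-map GEV (%): A=28.10 B=13.64 C=30.27 D=13.70 E=10.91
```

Five stable topographies explain 96.6% of the grand-average variance; the
KL and CV criteria agreed on K = 5 (`run$segmentation$criteria` holds the
curves). Backfitting the templates into the 229 retained single trials
gives per-trial map durations, and the duration model for map D shows the
injected name-agreement effect (about −1 ms of map-D duration per percent
of name agreement) while unrelated predictors stay null:

```r
run$suite$map_models$D
#> Crossed random-effects model: duration_ms ~ LD20 + PSF + PDF + LexF_book +
#>   CFam + VCom + IAgr + NAgr_pct + AoA
#>   n = 228, R2m = 0.122, R2c = 0.160, alpha = 0.01
#>         term     beta     se   df     t       p significant
#>  (Intercept) 331.5000 77.000 19.3  4.31 0.00037        TRUE
#>         ...
#>     NAgr_pct  -0.9871  0.303 20.9 -3.26 0.00379        TRUE
#>          AoA   2.7560  2.900 20.1  0.95 0.35300       FALSE
```

`report(run, "out/")` writes every stage's tables (templates, labels,
criterion curves, rejection reports, fit tables, presence summaries, model
coefficients) as TSV files with a hashed run manifest.

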