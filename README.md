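# persotx — optimization of personalized combinatorial cancer therapies

`persotx` answers a design question in precision oncology: given a catalog
of drugs, a catalog of binary companion biomarkers (mutations, copy-number
states, tissue types), and a cohort of patients with known marker
profiles, **which markers should inform the use of which drugs, and under
what decision rule, so that the cohort-wide response rate is as high as
possible while each patient receives at most `c` drugs?** It is aimed at
computational biologists working with cell-line drug-sensitivity screens
or marker-stratified response data.

## The model

Each sample *i* carries a binary marker profile *X<sub>i</sub>* ∈
{0,1}<sup>m</sup>. Each drug *j* is assigned an ordered list of markers
and a non-degenerate Boolean function *f<sub>j</sub>* (one whose output
depends on every input); the drug is *suggested* for a sample when
*f<sub>j</sub>* evaluates to 1 on the sample's status for those markers.
Each sample is then treated with the *c* suggested drugs with the highest
estimated response rates (ties to the lower drug index). Under
independent drug action the probability that sample *i* responds to its
combination is

> P<sub>i</sub> = 1 − ∏<sub>j</sub> (1 − p<sub>ij</sub>)<sup>e<sub>ij</sub></sup>,

with an optional pairwise log-linear interaction correction
J<sub>jk</sub> (negative = synergy, positive = antagonism), and the
objective is the overall response rate **O = mean(P<sub>i</sub>)**.

Because per-patient response probabilities are unobservable in practice,
the optimizer only sees the **response-by-marker approximation**: samples
are grouped by their status on a drug's assigned markers and
p<sub>ij</sub> is replaced by the group mean q(j, s), with groups smaller
than `min_group_size` (default 10) shrunk to q = 0.

When responses come from a drug screen, the per-sample probabilities are
derived from logIC50 values through a pharmacokinetic model: drug *j* is
dosed at y<sub>j</sub> = mean(logIC50)<sub>j</sub> + log *h* (default
*h* = 2), the log-dose reaching the tumor is Normal(y<sub>j</sub>, σ²),
and

> p<sub>ij</sub> = ½ erfc((logIC50<sub>ij</sub> − y<sub>j</sub>) / (√2 σ)).

Missing screen entries are filled by a doubly-weighted nearest-neighbour
average: donors are other samples' values for the same drug, weighted by
exp(−α<sub>sample</sub>·d<sub>ikj</sub>), where the sample distance
d<sub>ikj</sub> itself down-weights drugs dissimilar from the target drug
by exp(−α<sub>drug</sub>·d<sub>jl</sub>); (α<sub>sample</sub>,
α<sub>drug</sub>) are chosen by a Pearson-correlation grid search.

The assignment search minimizes E = −sO by multi-restart simulated
annealing: each step mutates one drug's protocol (add a marker, remove a
marker, or swap the Boolean function, with truth-table compatibility sets
governing add/remove), accepts worsening moves with probability
exp(−βΔE), and raises β on a linear schedule; drugs that carry markers
but treat nobody are forced to shed them.

## Worked example

Simulate a screen of 80 samples, 6 markers and 4 drugs in which pairs of
drugs share a strong sensitizing marker (logIC50 shift −12 for carriers),
mask 20% of entries, then impute, model responses and optimize pairs
(`c = 2`):

```r
library(persotx)

coh <- generate_cohort(80, 6, prevalence = 0.5, seed = 1)
effects <- planted_effects(drug = 1:4, marker = c(1, 1, 2, 2), shift = -12)
sim <- generate_ic50(coh, 4, effects, background_mean = 6, noise_sd = 0.5,
                     missing_frac = 0.2, seed = 2)

gs <- grid_search(sim$ic50, alpha_sample_grid = c(1, 5, 20),
                  alpha_drug_grid = c(1, 3))
gs
#> Imputation grid search over 6 points
#>   best PCC = 0.8659 at alpha_sample = 1, alpha_drug = 3

completed <- impute_ic50(sim$ic50, gs$best["alpha_sample"], gs$best["alpha_drug"])
responses <- build_response_matrix(completed, h = 2, sigma = 1)

cfg <- anneal_config(c = 2, k_max = 2, steps_per_drug = 300, restarts = 10,
                     base_seed = 1, min_group_size = 10)
res <- multi_start(coh, responses, cfg)
res
#> Simulated annealing over 10 restart(s): best O* = 0.9380 (E = -75.041) at restart 4
#>   4/4 drugs carry markers; 4 used for treatment

report_catalog(list(res$eval), colnames(responses), coh$marker_names)
#>  drug pct_c2 K    f   markers
#>   D01   62.5 2 1011 M002,M006
#>   D02   48.8 2 0111 M001,M002
#>   D04   48.8 1   01      M002
#>   D03   40.0 2 1011 M001,M006
```

Reading the output: the masked entries were reconstructed with a Pearson
correlation of 0.87 against the held-back truth; the optimized catalog
achieves an estimated overall response rate O\* = 0.938, i.e. 93.8% of
samples are expected to respond to at least one drug of their
personalized pair. The catalog lists, per drug, the percentage of samples
treated with it, the number of assigned markers K, the Boolean rule as a
truth-table string (e.g. `01` = "suggest when the marker is present"),
and the marker names; drugs D02 and D04 are steered by marker M002, one
of the two planted sensitizers.

A thin command-line front end over the same functions is provided in
`inst/cli/persotx.R` (subcommands `simulate`, `impute`, `optimize`,
`pipeline`), and `run_pipeline()` executes the whole flow from
tab-separated matrix files plus a YAML configuration.

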