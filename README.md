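# PPiMSM

Markov state models (MSMs) for the kinetics of pyrophosphate (PPi) release
from bacterial RNA polymerase — and for any rare-event process observed as
time-ordered trajectory data on a few reaction coordinates.

After each nucleotide addition, RNA polymerase must expel the PPi
by-product from its active site through the secondary channel. The release
takes hundreds of nanoseconds while affordable unbiased simulations are an
order of magnitude shorter, so the kinetics must be stitched together
statistically: frames from many short trajectories are split into geometric
microstates, transitions are counted at a lag time Δt, and the
row-stochastic transition matrix `T` of the master equation

    P(nΔt) = P(0) Tⁿ,      T_ij = N_ij / Σ_j N_ij

propagates the slow dynamics. Lag adequacy is checked with implied
timescales `τ_k = −τ / ln μ_k(τ)` (flat in τ for Markovian models), the
microstates are lumped into metastable macrostates with PCCA+, and the
headline outputs are the macrostate equilibrium populations, the mean first
passage times from the exact linear solve

    MFPT_if = Σ_j T_ij (t_lag + MFPT_jf),   MFPT_ff = 0,

trajectory-bootstrap uncertainties, residence-probability validation
curves, and potential-of-mean-force projections in k_BT.

The package is aimed at computational biophysicists who have trajectory
data (plain CSV feature series or multi-frame XYZ) and want a tested,
deterministic, fully scriptable MSM pipeline — plus synthetic generators
with exact ground truth (a calibrated two-state jump process and overdamped
Langevin dynamics on explicit potentials with a Boltzmann quadrature
oracle) to validate every stage.

## A worked example

The calibrated preset encodes a two-state exchange whose exact stationary
probabilities are (0.126, 0.874) — bound and released — and whose exact
bound→released MFPT is 500 ns; the observed coordinate mimics the PPi–Mg²⁺A
distance (Gaussian emissions at 4.0 ± 0.8 Å and 15.0 ± 2.5 Å).

```r
library(PPiMSM)

sim <- simulateJump(ppiReleasePreset(), nFrames = 10000, frameInterval = 1,
                    nTrajectories = 100, seed = 2013)
cfg <- pipelineConfig("twostate-demo", seed = 2013)   # k = 50, lag 5 ns, PCCA+ m = 2
res <- runPipeline(sim$trajectories, cfg)
#> cluster: 1000000 frames from 100 trajectories, k = 50
#> its: lags {1, 2, 5, 10, 20} frames
#> build: lag 5 frames, ergodic subset 50 / 50 microstates (100.0% of counts)
#> build: macrostate populations 0.1353, 0.8647
#> bootstrap: 100 replicates used, 0 degenerate
#> validate: max |predicted - observed| residence = 0.0232, 0.00352

b <- boundMacrostate(res)
populations(res$macro)[b] * 100   # 13.53 (% bound; generating truth 12.6)
res$mfpt[b, 3 - b]                # 394.4 (ns, bound -> released)
bootstrapSummary(res$macro)$popSd # 0.0117 0.0117
```

The recovered populations sit within about one bootstrap standard deviation
of the generating truth. The MFPT at a 5 ns lag is biased low by ~20%: with
overlapping emissions a small fraction of released-state frames falls on
the bound side of any crisp state boundary and each such frame fakes one
escape event — the classic short-lag discretization error that
implied-timescale plateaus exist to catch (at a 20 ns lag the same pipeline
recovers ~475 ns). See the methods vignette
(`vignettes/msm-pipeline.Rmd`) for the full discussion.

`writePipelineOutputs(res, "msm_out")` serializes the clustering, count and
transition matrices, implied timescales, populations/MFPT tables with
bootstrap uncertainties, residence curves, the PMF and a run log; reruns
with the same configuration and seed are byte-identical. A thin
command-line wrapper with `simulate/cluster/build/validate/mfpt/pmf/all`
subcommands lives at `inst/scripts/msm_pipeline.R`.

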