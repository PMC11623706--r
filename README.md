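# swarmstall

Swarming *Bacillus subtilis* cells move collectively in dense rafts, yet a
cell that finds itself without close neighbours stops moving entirely until
liquid (and company) returns. `swarmstall` packages the complete analysis
chain used to study these temporarily immobile swarmer cells, together with
a synthetic swarm generator and microscopy renderer, so every stage of the
analysis can be exercised and validated without experimental data.

The package covers five linked analyses:

1. **Long-exposure immobility detection.** At 50 frames/s (0.02 s exposure)
   every cell is sharp; averaging 10 consecutive frames emulates 5 frames/s
   (0.2 s exposure), where moving cells smear into faint streaks and only
   immobile cells remain above an intensity threshold.
2. **Bin-occupancy statistics.** The field of view is divided into a 10×10
   grid; a bin counts as occupied when at least a third of a cell body of
   immobile-cell area lies inside it. Per-window occupation fractions are
   computed for durations 5–360 s: their mean is duration-invariant, their
   across-bin spread decays as *T*<sup>−1/2</sup> (central limit theorem),
   their distribution is Gaussian, and their temporal autocorrelation decays
   within seconds — the signatures of a homogeneous surface with no fixed
   traps.
3. **Kinematics.** Nearest-neighbour track linking, central-difference
   speeds, the fast-subset mean above 7 μm/s, Rayleigh (Gaussian-tail)
   checks of the speed distribution, and mean speed conditioned on the
   number of neighbours within a cutoff radius.
4. **DIC hue analysis.** Hue thresholds (≤20 black, 21–24 blue, 25–27
   green, 43–45 background) classify pixels into dry and wet classes;
   hysteresis on a per-cell dry fraction extracts stopping/wetting events
   and stall durations.
5. **Flagellar-state inference.** The three flagellar states — closed
   bundle ("run"), partially open ("tumble"), fully open ("stall") — form a
   continuous-time Markov chain. The package fits exponential dwell times by
   maximum likelihood (mean dwells 0.25, 0.21, 0.95 s give exit rates
   4, 4.76, 1.05 s⁻¹), compares single-exponential and two-component mixture
   fits by AIC, estimates the embedded jump matrix

   ```
            CLOSED PARTIAL OPEN
   CLOSED      0      1      0
   PARTIAL    1/2     0     1/2
   OPEN        0      1      0
   ```

   (no direct closed↔open jumps), and tests memorylessness by comparing the
   empirical two-step transition matrix with the square of the one-step
   matrix.

The synthetic generator simulates rod-shaped 1×7 μm cells at surface
fraction ρ = 0.3 whose speeds are coupled to their flagellar state (stalled
cells are pinned at zero) and to their local neighbour count (isolated cells
do not move; speed saturates near 20 μm/s by 5 neighbours), with a per-cell
wetness that dries out when the cell is isolated.

## Worked example

```r
library(swarmstall)

model <- swarm_transition_model()
track <- simulate_ctmc(model, n_jumps = 1e5, seed = 1)
ex    <- extract_dwells(track)
em    <- embedded_matrix(ex)
cat("exit rates (1/s):", signif(em$exit_rates, 3), "\n")
#> exit rates (1/s): 4.02 4.78 1.05

err <- memorylessness_error(em$embedded, two_step_matrix(ex))
cat(sprintf("memorylessness max relative error: %.3f%%\n", 100 * err))
#> memorylessness max relative error: 0.064%

open <- subset(ex$dwells, state == "OPEN" & !censored)$duration_s
fs <- mle_exponential(open)
fm <- fit_exponential_mixture(open, seed = 1)
cat(sprintf("open-state mean dwell: %.3f s; AIC(single) - AIC(mixture) = %.2f\n",
            fs$means, aic_compare(fs, fm)))
#> open-state mean dwell: 0.952 s; AIC(single) - AIC(mixture) = -4.00
```

The recovered exit rates match the generating model within sampling error,
the two-step transition matrix agrees with the square of the one-step matrix
to a fraction of a percent (the Markov-chain signature), and the AIC
difference is negative: the extra mixture parameters are not justified for
exponential dwell times.

For the full image pipeline (simulate → render → detect → occupancy →
kinematics → hue → inference):

```r
cfg <- pipeline_config(arena_width_um = 20, arena_height_um = 20,
                       n_cells = 8, duration_s = 6,
                       durations_s = c(1, 2, 3), seed = 2)
res <- run_pipeline(cfg, out_dir = "out")
res$summary$state_mean_speed_ums$OPEN   # 0: stalled cells never move
```

A command-line front end wrapping the same functions is installed at
`inst/scripts/swarmstall.R` with subcommands `simulate`, `render`, `detect`,
`occupancy`, `kinematics`, `hue`, `ctmc`, `all`.

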