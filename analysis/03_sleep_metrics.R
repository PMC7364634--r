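#!/usr/bin/env Rscript

# Sleep architecture and continuity over a simulated week: time in state per
# photoperiod, sleep and REM bouts, the REM episode-length distribution
# under progressive fragmentation, and the circadian NREM amplitude.

library(tausleep)
dir.create("results", showWarnings = FALSE)

mats <- default_transition_matrices()
hy <- simulate_hypnogram(photoperiod_schedule(), mats,
                         duration_hours = 168, seed = 201)

tis <- time_in_state(hy)
print(tis[, c("photoperiod", "pct_wake", "pct_nrem", "pct_rem")],
      digits = 3)
amp <- circadian_amplitude(tis[tis$photoperiod == "LIGHT", ],
                           tis[tis$photoperiod == "DARK", ])
cat(sprintf("\nCircadian NREM amplitude (light - dark): %.1f points\n", amp))

bouts <- detect_bouts(hy)
write.csv(bouts, "results/bouts.csv", row.names = FALSE)
for (k in c("SLEEP", "REM")) {
  b <- bouts[bouts$kind == k, ]
  cat(sprintf("%s bouts: %d, mean length %.0f s\n", k, nrow(b),
              mean(b$duration_s)))
}

# REM fragmentation: shrink the REM continuation probability as the
# transgenic trajectory does by week 44 (0.85^6 ~ 0.38 of baseline)
frag <- mats
frag$light <- fragment_rem(mats$light, 0.85^6)
frag$dark <- fragment_rem(mats$dark, 0.85^6)
hyF <- simulate_hypnogram(photoperiod_schedule(), frag, 168, seed = 201)
d0 <- rem_episode_distribution(hy)
dF <- rem_episode_distribution(hyF)
cat(sprintf("\nREM episodes 1 epoch long: baseline %.0f%%, fragmented %.0f%%\n",
            100 * d0[["1"]] / sum(d0), 100 * dF[["1"]] / sum(dF)))
cat(sprintf("REM bouts (>= 20 s): baseline %d, fragmented %d\n",
            sum(detect_bouts(hy)$kind == "REM"),
            sum(detect_bouts(hyF)$kind == "REM")))
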