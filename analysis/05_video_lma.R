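#!/usr/bin/env Rscript

# Home-cage locomotor activity from synthetic greyscale video: frame
# differencing with the 10-grey-level per-pixel threshold, split into
# light- and dark-period relative distance.

library(tausleep)
dir.create("results", showWarnings = FALSE)

# one simulated minute per phase at 1 Hz (distance is relative, so the
# frame rate only sets resolution); dark phase carries 4x the activity
set.seed(301)
intensity <- c(rpois(60, 50), rpois(60, 200))
frames <- synthesize_video(intensity, frame_shape = c(480, 720), seed = 302)
tr <- motion_trace(frames, frame_rate = 1 / 60, start_clock_time = 17)

write.csv(data.frame(frame = seq_along(tr$counts), count = tr$counts,
                     photoperiod = tr$photoperiod),
          "results/motion_trace.csv", row.names = FALSE)
cat(sprintf("Relative distance, light period: %d\n",
            tr$period_distance[["LIGHT"]]))
cat(sprintf("Relative distance, dark period:  %d\n",
            tr$period_distance[["DARK"]]))
cat(sprintf("Dark/light activity ratio: %.1f\n",
            tr$period_distance[["DARK"]] / tr$period_distance[["LIGHT"]]))
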