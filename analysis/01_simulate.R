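#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study fixtures with known ground truth:
# (a) a rendered high-speed video of the two arytenoid-disc markers during a
#     short stimulus train (multi-page TIFF + ground-truth trajectory CSV),
# (b) a full 40-stimulus ex vivo experiment: bead trajectories at 40 kfps
#     and the microphone trace at 30 kHz (WAV + per-stimulus truth CSV),
# (c) a synthetic advertisement call (biphasic trill, WAV).
# Everything downstream (02-04) runs from these files alone.

library(xenocall)

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = 1)
write_config(cfg, file.path(out, "config.yml"))

## (a) rendered stack: gentle motion resolvable at 10 kfps, pixel SNR 10
message("rendering bead video (3 stimuli, 10 kfps, SNR 10) ...")
train3 <- stimulus_train(rate_hz = 40, count = 3, t_first = 0.02)
gentle <- disc_motion_params(gap_max_um = 100, steepness = 2000,
                             rest_jitter_um = 0, scale_jitter_sd = 0,
                             facil_tau = 0.01)
vid <- gen_disc_trajectory(gentle, train3, frame_rate = 10000, seed = 1)
stack <- render_bead_frames(vid, bead_diam_um = 80, px_size_um = 5,
                            noise_sd = 0.06, seed = 2)
write_frame_stack(stack, file.path(out, "discs_10kfps.tif"))
utils::write.csv(cbind(bead = "left", vid$left), file.path(out, "video_truth_left.csv"),
                 row.names = FALSE)
utils::write.csv(cbind(bead = "right", vid$right), file.path(out, "video_truth_right.csv"),
                 row.names = FALSE)
utils::write.csv(vid$truth$stim, file.path(out, "video_truth_stim.csv"),
                 row.names = FALSE)
message(sprintf("  %d frames of %d x %d px -> discs_10kfps.tif",
                dim(stack$frames)[3], dim(stack$frames)[1],
                dim(stack$frames)[2]))

## (b) full mechanism experiment at the default (reported) kinematic regime
message("simulating 40-stimulus ex vivo experiment (40 kfps, 30 kHz) ...")
train40 <- stimulus_train(rate_hz = 40, count = 40, t_first = 0.1)
mech <- gen_disc_trajectory(disc_motion_params(), train40,
                            frame_rate = 40000, seed = 3)
snd <- synth_pulse_sound(mech$truth, pulse_sound_params(),
                         sample_rate = 30000, seed = 4,
                         duration_s = max(mech$truth$t_s) + 0.02)
write_wav(snd, file.path(out, "exvivo_mic.wav"), "float32")
utils::write.csv(mech$left, file.path(out, "exvivo_left.csv"), row.names = FALSE)
utils::write.csv(mech$right, file.path(out, "exvivo_right.csv"), row.names = FALSE)
utils::write.csv(mech$truth$stim, file.path(out, "exvivo_truth_stim.csv"),
                 row.names = FALSE)
utils::write.csv(attr(snd, "sound_truth"),
                 file.path(out, "exvivo_truth_sound.csv"), row.names = FALSE)
message(sprintf("  %.1f s audio, %d/%d stimuli produce sound",
                length(snd$samples) / snd$sample_rate,
                sum(attr(snd, "sound_truth")$sounded), train40$count))

## (c) advertisement call (X. borealis octave dyad, fast + slow trill);
## the 1251 Hz component separation is resolvable within single 8 ms pulses
message("synthesizing advertisement call (60 + 30 pulses) ...")
cs <- call_spec(df1_hz = 1253, df2_hz = 2504, n_fast = 60, n_slow = 30)
call <- synth_advertisement_call(cs, seed = 5)
write_wav(call, file.path(out, "call_borealis.wav"), "float32")
utils::write.csv(attr(call, "call_truth"),
                 file.path(out, "call_truth_onsets.csv"), row.names = FALSE)
message(sprintf("  %.2f s call -> call_borealis.wav",
                length(call$samples) / call$sample_rate))
message("done: fixtures under ", out)
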