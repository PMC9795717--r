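#!/usr/bin/env Rscript
# Generate the study's synthetic datasets: a 10-day 2D co-culture time
# series, a co-culture-like 3D stack (smooth sprouts, attached MSCs) and
# a monoculture-like 3D stack (rough sprouts, no MSCs), each with full
# ground truth. Volumes are written as multi-page TIFF + JSON sidecars
# under results/phantoms/.
suppressPackageStartupMessages(library(angiocross))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out_dir <- "results/phantoms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("2D co-culture series (10 days, 0.89 um/px) ...")
series <- make_coculture_series_2d(phantom_spec_2d(seed = seed))
saveRDS(series, file.path(out_dir, "series2d.rds"))
write.csv(series$truth, file.path(out_dir, "series2d_truth.csv"),
          row.names = FALSE)

spec_co <- function(amp, seed, with_mscs) phantom_spec_3d(
  domain_size = c(400, 560, 300), voxel_size = c(2.5, 2.5, 2.5),
  sprouts = list(
    sprout_spec(base_x = 150, base_angle = 90, length = 150,
                roughness_amplitude = amp, roughness_wavelength = 30),
    sprout_spec(base_x = 280, base_angle = 270, length = 150,
                roughness_amplitude = amp, roughness_wavelength = 30)),
  mscs = if (with_mscs) list(
    msc_spec(attached_to = "sprout_1", attach_s = 0.35, attach_angle = 0,
             semi_axes = c(35, 16, 16)),
    msc_spec(attached_to = "sprout_1", attach_s = 0.7, attach_angle = 180,
             semi_axes = c(35, 16, 16)),
    msc_spec(attached_to = "sprout_2", attach_s = 0.65, attach_angle = 90,
             semi_axes = c(35, 16, 16)),
    msc_spec(attached_to = "sprout_2", attach_s = 0.3, attach_angle = 270,
             semi_axes = c(35, 16, 16)),
    msc_spec(attached_to = "parent", attach_s = 0.15, attach_angle = 45,
             semi_axes = c(35, 16, 16))) else list(),
  seed = seed)

message("3D co-culture-like phantom (smooth sprouts + MSCs) ...")
co <- make_vessel_phantom_3d(spec_co(0, seed + 10L, TRUE))
write_volume_tiff(co$volume, file.path(out_dir, "stack_coculture.tif"))
saveRDS(co, file.path(out_dir, "stack_coculture.rds"))

message("3D monoculture-like phantom (rough sprouts) ...")
mono <- make_vessel_phantom_3d(spec_co(8, seed + 11L, FALSE))
write_volume_tiff(mono$volume, file.path(out_dir, "stack_monoculture.tif"))
saveRDS(mono, file.path(out_dir, "stack_monoculture.rds"))

write_run_manifest(out_dir, stage = "simulate", seed = seed,
                   frames_2d = length(series$series$frames),
                   true_sprout_coverage = mean(co$truth$sprout_coverage))
message("done; ground-truth sprout coverage (co-culture): ",
        round(mean(co$truth$sprout_coverage), 4))
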