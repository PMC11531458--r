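#!/usr/bin/env Rscript
# Validates the voxel-density quantification against synthetic phantoms with
# analytic ground truth: exact tissue-mass recovery on noise-free phantoms,
# unbiasedness under HU noise, and the effect of contrast-agent blobs on the
# uncorrected vs window-corrected calculated weight.

suppressPackageStartupMessages(library(edemaquant))
dir.create("results", showWarnings = FALSE)
set.seed(1)

## noise-free phantoms: calculated weight must equal the analytic truth
specs <- lapply(1:20, function(i)
  phantom_spec(shape = sample(16:48, 3, replace = TRUE),
               spacing = runif(3, 0.5, 2),
               base_tissue_fraction = runif(1, 0.1, 0.9),
               gradient_axis = sample(1:3, 1),
               gradient_amplitude = runif(1, 0, 0.4),
               noise_sd = 0, seed = i))
rep0 <- run_pipeline(run_config(phantom_specs = specs, seed = 1))
sr <- rep0$scan_results
sr$rel_error <- abs(sr$calculated_weight_g - sr$true_tissue_mass_g) /
  sr$true_tissue_mass_g
cat(sprintf("Noise-free phantoms (n = %d): max |relative error| of calculated weight vs truth = %.2e\n",
            nrow(sr), max(sr$rel_error)))

## noisy phantoms: error shrinks with mask size, mean error ~ 0
noisy <- do.call(rbind, lapply(1:30, function(i) {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32),
                                      base_tissue_fraction = 0.3,
                                      noise_sd = 40, seed = 100 + i))
  q <- quantify_lung(ph$volume, ph$truth$mask)
  data.frame(seed = 100 + i,
             error_g = q$calculated_lung_weight - ph$truth$true_tissue_mass)
}))
cat(sprintf("Noisy phantoms (sd 40 HU): mean error %.4f g, SD %.4f g over %d seeds\n",
            mean(noisy$error_g), sd(noisy$error_g), nrow(noisy)))

## contrast blobs: uncorrected weight inflates, windowed weight of the rest
## is untouched
contrast <- do.call(rbind, lapply(1:10, function(i) {
  base <- phantom_spec(shape = c(32, 32, 32), base_tissue_fraction = 0.35,
                       noise_sd = 15, seed = 200 + i)
  blob <- phantom_spec(shape = c(32, 32, 32), base_tissue_fraction = 0.35,
                       contrast_blobs = list(list(center = c(10, 16, 16),
                                                  radius_mm = 2.5,
                                                  hu = 250 + 35 * i)),
                       noise_sd = 15, seed = 200 + i)
  p0 <- generate_phantom(base); p1 <- generate_phantom(blob)
  q0 <- quantify_lung(p0$volume, p0$truth$mask)
  q1 <- quantify_lung(p1$volume, p1$truth$mask)
  q1w <- quantify_lung(p1$volume, p1$truth$mask, edema_window())
  data.frame(blob_hu = 250 + 35 * i, n_blob_voxels = sum(p1$truth$contrast_mask),
             weight_g = q1$calculated_lung_weight,
             weight_without_blob_g = q0$calculated_lung_weight,
             weight_windowed_g = q1w$calculated_lung_weight)
}))
cat(sprintf("Contrast blobs: uncorrected weight inflated by %.2f-%.2f g; windowed weight always below uncorrected: %s\n",
            min(contrast$weight_g - contrast$weight_without_blob_g),
            max(contrast$weight_g - contrast$weight_without_blob_g),
            all(contrast$weight_windowed_g < contrast$weight_g)))

write.csv(sr, "results/phantom_noise_free.csv", row.names = FALSE)
write.csv(noisy, "results/phantom_noisy.csv", row.names = FALSE)
write.csv(contrast, "results/phantom_contrast.csv", row.names = FALSE)
cat("wrote results/phantom_{noise_free,noisy,contrast}.csv\n")
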