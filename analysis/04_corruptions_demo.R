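#!/usr/bin/env Rscript
# Exercise the stimulus corruption operators on synthetic images and
# record their spectral summaries: additive uniform noise, Gaussian
# lowpass with gray padding, grayscale conversion, and the pink-noise
# backward mask.

suppressPackageStartupMessages(library(errcon))

dir.create("results/images", showWarnings = FALSE, recursive = TRUE)
img <- synth_image(224, 224, "edges", seed = 3L)
write_image(img, "results/images/original.png")
write_image(add_uniform_noise(img, half_width = 0.5, seed = 4L),
            "results/images/noise.png")
write_image(lowpass_filter(img, sigma = 5), "results/images/lowpass.png")
write_image(to_grayscale(img), "results/images/grayscale.png")
mask <- pink_noise_mask(224, 224, seed = 5L)
write_image(mask, "results/images/pink_mask.png")

lap <- function(ch) {
  h <- nrow(ch); w <- ncol(ch)
  l <- 4 * ch[2:(h - 1), 2:(w - 1)] - ch[1:(h - 2), 2:(w - 1)] -
    ch[3:h, 2:(w - 1)] - ch[2:(h - 1), 1:(w - 2)] - ch[2:(h - 1), 3:w]
  mean(l^2)
}
cat(sprintf("high-frequency (Laplacian) energy: original %.5f -> lowpass %.5f\n",
            lap(img[, , 1]), lap(lowpass_filter(img, sigma = 5)[, , 1])))

sp <- radial_spectrum(pink_noise_mask(512, 512, seed = 6L)[, , 1])
sp <- sp[sp$freq >= 2 & sp$freq <= 128, ]
slope <- coef(lm(log(amplitude) ~ log(freq), data = sp))[[2]]
cat(sprintf("pink-noise mask amplitude spectrum slope: %.3f (target -1)\n", slope))
write.table(sp, "results/mask_radial_spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("corrupted examples written under results/images/\n")
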