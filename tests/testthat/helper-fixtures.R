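# Shared fixtures, built in code at test time.

# A quick training configuration for tests that only need a plausible fit.
quick_train <- function(max_epochs = 150, ...) {
  bpnn_control(max_epochs = max_epochs, ...)
}

# Response model with only the two strongly informative components; used by
# the selection-recovery checks.
two_component_model <- function() {
  co <- numeric(36)
  co[9] <- -90   # FTPPFeCl:B
  co[24] <- 81   # MTPPTE:B
  response_model(co, saturation_half_od = 4, noise_sd = 2)
}

# Brute-force circular-ROI mean oracle: explicit loop over every pixel.
roi_mean_oracle <- function(image, cx, cy, r) {
  acc <- c(0, 0, 0); n <- 0
  for (yy in seq_len(dim(image)[1])) {
    for (xx in seq_len(dim(image)[2])) {
      if ((xx - cx)^2 + (yy - cy)^2 <= r^2) {
        acc <- acc + image[yy, xx, ]
        n <- n + 1
      }
    }
  }
  stats::setNames(acc / n, c("R", "G", "B"))
}

# Random admissible ROI for an image of the given size.
random_roi <- function(w, h, r) {
  list(x = sample(seq(r + 1, w - r), 1), y = sample(seq(r + 1, h - r), 1))
}
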