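# Brute-force reference implementations used as independent oracles.

# per-pixel loop thresholding
oracle_threshold_mask <- function(slice, threshold) {
  out <- matrix(FALSE, nrow(slice), ncol(slice))
  for (i in seq_len(nrow(slice))) {
    for (j in seq_len(ncol(slice))) {
      out[i, j] <- slice[i, j] >= threshold
    }
  }
  out
}

# AUC as the proportion of concordant (positive, negative) pairs, ties 1/2
oracle_auc_pairs <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# ICC(A,1) from an aov() variance decomposition (McGraw & Wong)
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    y = as.vector(t(m)),
    subj = factor(rep(seq_len(n), each = k)),
    rater = factor(rep(seq_len(k), times = n))
  )
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# deterministic tiny ultrasound slice used across tests
example_slice <- function() {
  rbind(c(0, 129, 130), c(250, 10, 140), c(0, 0, 0))
}

us_stack_of <- function(slices, pixel_spacing = c(1, 1), slice_spacing = 1,
                        axis = "none") {
  arr <- array(0, dim = c(length(slices), nrow(slices[[1]]), ncol(slices[[1]])))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  image_stack(arr, pixel_spacing, slice_spacing, modality = "US",
              axis_label = axis)
}

full_roi_set <- function(n_slices, nr, nc) {
  regions <- lapply(seq_len(n_slices), function(i) roi_rect(1, 1, nr, nc))
  roi_set(stats::setNames(regions, seq_len(n_slices)))
}
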