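# Shared fixtures: geometric masks and hand-built cell images.

# Boolean disk mask (Euclidean rasterisation) centred in a square frame.
disk_mask <- function(radius_px, frame = 2 * ceiling(radius_px) + 21) {
  ctr <- (frame + 1) / 2
  d <- sqrt(outer((seq_len(frame) - ctr)^2, (seq_len(frame) - ctr)^2, "+"))
  d <= radius_px
}

# Minimal cell_image wrapper around raw channel matrices.
as_cell_image <- function(channels, pixel_scale = 0.5, event_id = "fx") {
  structure(list(channels = channels, pixel_scale = pixel_scale,
                 event_id = event_id), class = "cell_image")
}

# Random connected blob: threshold smoothed noise, keep the largest
# component. Used for morphology property tests.
random_blob <- function(seed, frame = 48) {
  set.seed(seed)
  img <- matrix(stats::rnorm(frame^2), frame, frame)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 4))
  fg <- sm > stats::quantile(sm, 0.8)
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), frame, frame))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (independent oracle; no ties assumed).
enumerate_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n1 + n2, n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}
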