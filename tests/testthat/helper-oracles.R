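# Independent oracles used across the suite. These deliberately use naive
# per-pixel loops, not the package's vectorized/graph implementations.

random_mask <- function(nr, nc, p = 0.3) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# stack-based flood fill, scanning in column-major order
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  lab <- 0L
  sr <- integer(nr * nc); sc <- integer(nr * nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && labels[i, j] == 0L) {
      lab <- lab + 1L
      top <- 1L; sr[1] <- i; sc[1] <- j
      labels[i, j] <- lab
      while (top > 0L) {
        r0 <- sr[top]; c0 <- sc[top]; top <- top - 1L
        for (k in 1:length(dr)) {
          r <- r0 + dr[k]; cc <- c0 + dc[k]
          if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
              mask[r, cc] && labels[r, cc] == 0L) {
            labels[r, cc] <- lab
            top <- top + 1L; sr[top] <- r; sc[top] <- cc
          }
        }
      }
    }
  }
  labels
}

# per-pixel conjunction count by explicit double loop
brute_overlap_count <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] && b[i, j]) n <- n + 1L
  n
}

# textbook Pearson correlation from covariance and standard deviations
pearson_oracle <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# textbook Welch t statistic
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  (mean(b) - mean(a)) / sqrt(va + vb)
}

# shared overlap-index recovery experiment (also exercised in acceptance)
run_overlap_recovery <- function(base_seed, n_per_group = 10,
                                 control_target = 300, ratio = 2) {
  imgs <- list(); truths <- list(); k <- 0
  for (grp in c("control", "stress")) {
    target <- if (grp == "control") control_target else
      control_target * ratio
    for (i in seq_len(n_per_group)) {
      k <- k + 1
      r <- sim_cell_image(target_contact_px = target, n_capsules = 6,
                          noise_sd = 0.06,
                          sample_id = sprintf("%s_%02d", grp, i),
                          group = grp, seed = base_seed + 17L * k)
      imgs[[k]] <- r$image; truths[[k]] <- r$truth
    }
  }
  er <- preprocess_batch(imgs, "er")
  mito <- preprocess_batch(imgs, "mito")
  is_ctrl <- vapply(imgs, function(i) i$group == "control", logical(1))
  thr_er <- batch_otsu(er[is_ctrl])
  thr_mito <- batch_otsu(mito[is_ctrl])
  meas <- do.call(rbind, lapply(seq_along(imgs), function(i)
    overlap_pixels(binarize_and_filter(er[[i]], thr_er),
                   binarize_and_filter(mito[[i]], thr_mito),
                   sample_id = imgs[[i]]$sample_id,
                   group = imgs[[i]]$group)))
  oi <- overlap_index(meas, control_group = "control")
  true_contact <- vapply(truths, function(t) sum(t$contact_mask),
                         numeric(1))
  list(index = oi,
       stress_mean = oi$summary$mean_index[oi$summary$group == "stress"],
       control_mean = oi$summary$mean_index[oi$summary$group == "control"],
       true_ratio = mean(true_contact[!is_ctrl]) /
         mean(true_contact[is_ctrl]))
}
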