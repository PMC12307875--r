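# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed): randomness is scoped with withr::with_seed so global RNG
# state is never touched. Ground truth is returned alongside the rendered
# data so each analysis stage has a recovery oracle.

# pixels within `radius` of the segment p1-p2 (continuous coords, row/col)
seg_capsule_mask <- function(nr, nc, p1, p2, radius) {
  mask <- matrix(FALSE, nr, nc)
  r0 <- max(1L, floor(min(p1[1], p2[1]) - radius))
  r1 <- min(nr, ceiling(max(p1[1], p2[1]) + radius))
  c0 <- max(1L, floor(min(p1[2], p2[2]) - radius))
  c1 <- min(nc, ceiling(max(p1[2], p2[2]) + radius))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  v <- p2 - p1
  l2 <- sum(v^2)
  if (l2 == 0) {
    d2 <- (pr - p1[1])^2 + (pc - p1[2])^2
  } else {
    tt <- ((pr - p1[1]) * v[1] + (pc - p1[2]) * v[2]) / l2
    tt <- pmin(pmax(tt, 0), 1)
    d2 <- (pr - (p1[1] + tt * v[1]))^2 + (pc - (p1[2] + tt * v[2]))^2
  }
  mask[rr, cc] <- d2 <= radius^2
  mask
}

disc_mask <- function(nr, nc, center, radius) {
  seg_capsule_mask(nr, nc, center, center, radius)
}

# persistent 8-direction random walk, dilated to a tubule
walk_tubule_mask <- function(nr, nc, n_steps, radius, turn_prob = 0.3) {
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  pos <- c(round(runif(1, nr * 0.1, nr * 0.9)),
           round(runif(1, nc * 0.1, nc * 0.9)))
  dir <- sample(8, 1)
  path <- matrix(FALSE, nr, nc)
  path[pos[1], pos[2]] <- TRUE
  for (i in seq_len(n_steps)) {
    if (runif(1) < turn_prob)
      dir <- ((dir - 1 + sample(c(-1, 1), 1)) %% 8) + 1
    pos <- pos + offs[dir, ]
    pos <- pmin(pmax(pos, 2), c(nr - 1, nc - 1))
    path[pos[1], pos[2]] <- TRUE
  }
  dilate_mask(path, radius)
}

apply_noise <- function(x, noise_sd, poisson, photon_scale = 1e4) {
  if (poisson) x <- rpois(length(x), pmax(x, 0) * photon_scale) / photon_scale
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  matrix(pmin(pmax(x, 0), 1), nrow(x), ncol(x))
}

check_noise <- function(noise_sd) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop_param("noise_sd must be a single non-negative number")
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed))
    stop_param("an explicit integer seed is required")
}

#' Simulate a two-organelle cell image with known contact ground truth
#'
#' Renders an ER channel (dilated random-walk tubules), a mitochondrial
#' channel (capsule-shaped objects) and a punctate protein channel. A chosen
#' number of mitochondria are forced to cross the ER so the true contact
#' area is controlled; the remaining mitochondria are placed away from the
#' (dilated) ER, so chance overlap does not contaminate the contact ground
#' truth. True contact is defined as
#' `dilate(er, d) & dilate(mito, d)` with `d = contact_dilate`, reflecting
#' the convention that overlap of diffraction-limited signals marks a
#' contact. Protein puncta are placed at contacts with probability given by
#' `puncta_at_contact_fraction` (deterministic count via half-away rounding).
#'
#' @param width,height Image size in pixels (>= 64).
#' @param n_tubules,tubule_steps,tubule_radius ER tubule count, random-walk
#'   length and half-width (px).
#' @param n_capsules Number of mitochondria placed away from the ER.
#' @param n_contact_capsules Number of mitochondria forced to cross the ER
#'   (ignored when `target_contact_px` is given).
#' @param target_contact_px Optional target true-contact area in pixels:
#'   ER-crossing capsules are added until the contact mask reaches at least
#'   this many pixels (at most 100 capsules), giving direct control over the
#'   true contact fraction.
#' @param capsule_length_um Range (min, max) of true mitochondrial lengths in
#'   micrometres.
#' @param capsule_width Mitochondrion width in pixels (>= 3).
#' @param n_puncta Number of protein puncta.
#' @param puncta_at_contact_fraction Fraction of puncta whose centroid lies
#'   inside the contact mask.
#' @param puncta_radius Punctum radius in pixels.
#' @param contact_dilate Dilation half-width d (px) in the contact rule.
#' @param pixel_size Micrometres per pixel.
#' @param fg,bg Foreground and background intensities on the \[0, 1\] scale.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param poisson If `TRUE`, apply Poisson (shot) noise before Gaussian noise.
#' @param sample_id,group Sample annotation carried into the image.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#'
#' @return A list with `image` (a [multichannel_image] with channels `er`,
#'   `mito`, `protein`) and `truth` (list: `er_mask`, `mito_mask`,
#'   `contact_mask`, `puncta` data frame with `at_contact` flag,
#'   `pixel_size`, `seed`).
#' @export
sim_cell_image <- function(width = 192, height = 192,
                           n_tubules = 6, tubule_steps = 150,
                           tubule_radius = 2,
                           n_capsules = 8, n_contact_capsules = 4,
                           target_contact_px = NULL,
                           capsule_length_um = c(1, 4), capsule_width = 5,
                           n_puncta = 12, puncta_at_contact_fraction = 0.7,
                           puncta_radius = 2, contact_dilate = 1,
                           pixel_size = 0.07, fg = 0.6, bg = 0.02,
                           noise_sd = 0, poisson = FALSE,
                           sample_id = "sample", group = "control", seed) {
  check_seed(seed)
  check_noise(noise_sd)
  if (width < 64 || height < 64)
    stop_param("image dimensions must be at least 64x64")
  if (n_tubules < 0 || n_capsules < 0 || n_contact_capsules < 0 ||
      n_puncta < 0)
    stop_param("object counts must be >= 0")
  if (capsule_width < 3) stop_param("capsule_width must be >= 3 px")
  nr <- height; nc <- width
  withr::with_seed(seed, {
    er <- matrix(FALSE, nr, nc)
    for (i in seq_len(n_tubules))
      er <- er | walk_tubule_mask(nr, nc, tubule_steps, tubule_radius)
    er_avoid <- dilate_mask(er, contact_dilate + 1)
    mito <- matrix(FALSE, nr, nc)
    rad <- capsule_width / 2
    place_capsule <- function(center, len_px) {
      ang <- runif(1, 0, pi)
      half <- len_px / 2 * c(sin(ang), cos(ang))
      seg_capsule_mask(nr, nc, center - half, center + half, rad)
    }
    er_px <- which(er)
    er_dil <- dilate_mask(er, contact_dilate)
    propose_contact_capsule <- function() {
      p <- er_px[sample(length(er_px), 1)]
      center <- c(((p - 1) %% nr) + 1, ((p - 1) %/% nr) + 1)
      len_px <- runif(1, capsule_length_um[1], capsule_length_um[2]) /
        pixel_size
      place_capsule(center, len_px)
    }
    if (!is.null(target_contact_px) && length(er_px) > 0) {
      # add ER-crossing capsules until the true contact area reaches the
      # target; reject proposals overshooting it by > 5% so grazing
      # contacts can fill the remainder
      contact_cur <- matrix(FALSE, nr, nc)
      for (i in seq_len(500)) {
        if (sum(contact_cur) >= target_contact_px) break
        cand <- propose_contact_capsule()
        new_contact <- contact_cur | (er_dil & dilate_mask(cand,
                                                           contact_dilate))
        if (sum(new_contact) <= 1.05 * target_contact_px) {
          mito <- mito | cand
          contact_cur <- new_contact
        }
      }
    } else {
      for (i in seq_len(n_contact_capsules)) {
        if (length(er_px) == 0) break
        mito <- mito | propose_contact_capsule()
      }
    }
    for (i in seq_len(n_capsules)) {
      len_px <- runif(1, capsule_length_um[1], capsule_length_um[2]) /
        pixel_size
      for (try in 1:100) {
        center <- c(runif(1, rad + 1, nr - rad), runif(1, rad + 1, nc - rad))
        cand <- place_capsule(center, len_px)
        if (!any(cand & er_avoid)) break
      }
      mito <- mito | cand
    }
    contact <- dilate_mask(er, contact_dilate) & dilate_mask(mito,
                                                            contact_dilate)
    n_at <- round_half_away(n_puncta * puncta_at_contact_fraction)
    contact_px <- which(contact)
    n_at <- min(n_at, if (length(contact_px)) n_puncta else 0)
    puncta <- NULL
    protein <- matrix(FALSE, nr, nc)
    if (n_puncta > 0) {
      at_contact <- c(rep(TRUE, n_at), rep(FALSE, n_puncta - n_at))
      rows <- cols <- numeric(n_puncta)
      for (i in seq_len(n_puncta)) {
        if (at_contact[i]) {
          p <- contact_px[sample(length(contact_px), 1)]
          rows[i] <- ((p - 1) %% nr) + 1
          cols[i] <- ((p - 1) %/% nr) + 1
        } else {
          rows[i] <- round(runif(1, puncta_radius + 1, nr - puncta_radius))
          cols[i] <- round(runif(1, puncta_radius + 1, nc - puncta_radius))
        }
        protein <- protein | disc_mask(nr, nc, c(rows[i], cols[i]),
                                       puncta_radius)
      }
      puncta <- data.frame(row = rows, col = cols, radius = puncta_radius,
                           at_contact = at_contact)
    }
    channels <- lapply(list(er = er, mito = mito, protein = protein),
                       function(m) apply_noise(bg + (fg - bg) * m, noise_sd,
                                               poisson))
    list(image = multichannel_image(channels, pixel_size, sample_id, group),
         truth = list(er_mask = er, mito_mask = mito, contact_mask = contact,
                      puncta = puncta, contact_dilate = contact_dilate,
                      pixel_size = pixel_size, seed = seed))
  })
}

#' Simulate a mitochondrial channel of non-overlapping capsules
#'
#' Capsules (stadium shapes: a straight centreline dilated by half the width)
#' are placed with random position and orientation, rejecting placements that
#' touch an existing capsule. True length is the Euclidean centreline length
#' times the pixel size.
#'
#' @inheritParams sim_cell_image
#' @param n_capsules Number of capsules.
#' @param length_um Optional vector of true lengths in micrometres (recycled);
#'   if `NULL`, lengths are drawn uniformly from `length_range_um`.
#' @param length_range_um Range used when `length_um` is `NULL`.
#' @param width_px Capsule width in pixels (>= 3).
#' @param max_attempts Placement attempts per capsule before failing with an
#'   error naming how many capsules were placed.
#'
#' @return A list with `image` (single-channel [multichannel_image], channel
#'   `mito`) and `truth` (data frame: capsule endpoints, `width_px`,
#'   `length_um`; plus `pixel_size` and `seed` attributes).
#' @export
sim_capsule_image <- function(width = 256, height = 256, n_capsules = 12,
                              length_um = NULL, length_range_um = c(1, 8),
                              width_px = 5, pixel_size = 0.07,
                              fg = 0.6, bg = 0.02, noise_sd = 0,
                              poisson = FALSE, max_attempts = 200,
                              sample_id = "sample", group = "control", seed) {
  check_seed(seed)
  check_noise(noise_sd)
  if (width_px < 3) stop_param("width_px must be >= 3 px")
  if (!is.null(length_um) && any(length_um <= 0))
    stop_param("capsule lengths must be > 0")
  nr <- height; nc <- width
  rad <- width_px / 2
  withr::with_seed(seed, {
    lengths <- if (is.null(length_um)) {
      runif(n_capsules, length_range_um[1], length_range_um[2])
    } else rep_len(length_um, n_capsules)
    mito <- matrix(FALSE, nr, nc)
    occupied <- matrix(FALSE, nr, nc)
    truth <- data.frame(capsule = integer(0), r1 = numeric(0),
                        c1 = numeric(0), r2 = numeric(0), c2 = numeric(0),
                        width_px = numeric(0), length_um = numeric(0))
    for (i in seq_len(n_capsules)) {
      len_px <- lengths[i] / pixel_size
      placed <- FALSE
      for (try in seq_len(max_attempts)) {
        ang <- runif(1, 0, pi)
        half <- len_px / 2 * c(sin(ang), cos(ang))
        center <- c(runif(1, rad + 2, nr - rad - 1),
                    runif(1, rad + 2, nc - rad - 1))
        p1 <- center - half; p2 <- center + half
        if (any(c(p1, p2) < rad + 2) || p1[1] > nr - rad - 1 ||
            p2[1] > nr - rad - 1 || p1[2] > nc - rad - 1 ||
            p2[2] > nc - rad - 1) next
        cand <- seg_capsule_mask(nr, nc, p1, p2, rad)
        if (any(cand & occupied)) next
        mito <- mito | cand
        occupied <- occupied | dilate_mask(cand, 2)
        truth <- rbind(truth, data.frame(
          capsule = i, r1 = p1[1], c1 = p1[2], r2 = p2[1], c2 = p2[2],
          width_px = width_px,
          length_um = sqrt(sum((p2 - p1)^2)) * pixel_size))
        placed <- TRUE
        break
      }
      if (!placed)
        stop_param("could only place ", i - 1L, " of ", n_capsules,
                   " capsules without overlap after ", max_attempts,
                   " attempts each")
    }
    channel <- apply_noise(bg + (fg - bg) * mito, noise_sd, poisson)
    attr(truth, "pixel_size") <- pixel_size
    attr(truth, "seed") <- seed
    list(image = multichannel_image(list(mito = channel), pixel_size,
                                    sample_id, group),
         truth = truth)
  })
}

#' Simulate a tandem-fluorophore reporter image
#'
#' Two-channel (red, green) image of well-separated circular puncta. A
#' deterministic count `round(n_puncta * red_only_fraction)` (half away from
#' zero) of puncta are "red-only" (green at background, emulating EGFP
#' quenching in acidic vesicles); the rest are dual-positive.
#'
#' @inheritParams sim_cell_image
#' @param n_puncta Number of puncta (>= 0).
#' @param red_only_fraction True acidic fraction in \[0, 1\].
#' @param radius Punctum radius in pixels.
#' @param min_sep Minimum centre-to-centre separation in pixels (default keeps
#'   puncta as distinct connected components).
#'
#' @return A list with `image` ([multichannel_image] with channels `red`,
#'   `green`) and `truth` (data frame: `row`, `col`, `radius`, `class` in
#'   `{red_only, dual}`).
#' @export
sim_reporter_image <- function(n_puncta, red_only_fraction,
                               width = 192, height = 192, radius = 3,
                               fg = 0.6, bg = 0.05, noise_sd = 0,
                               poisson = FALSE, min_sep = NULL,
                               sample_id = "sample", group = "control",
                               seed) {
  check_seed(seed)
  check_noise(noise_sd)
  if (n_puncta < 0) stop_param("n_puncta must be >= 0")
  if (red_only_fraction < 0 || red_only_fraction > 1)
    stop_param("red_only_fraction must be in [0, 1]")
  if (is.null(min_sep)) min_sep <- 2 * radius + 4
  nr <- height; nc <- width
  withr::with_seed(seed, {
    n_red <- round_half_away(n_puncta * red_only_fraction)
    cls <- rep("dual", n_puncta)
    if (n_puncta > 0 && n_red > 0)
      cls[sample(n_puncta, n_red)] <- "red_only"
    rows <- cols <- numeric(n_puncta)
    for (i in seq_len(n_puncta)) {
      for (try in 1:500) {
        r <- round(runif(1, radius + 2, nr - radius - 1))
        cc <- round(runif(1, radius + 2, nc - radius - 1))
        if (i == 1 || all(sqrt((rows[seq_len(i - 1)] - r)^2 +
                               (cols[seq_len(i - 1)] - cc)^2) >= min_sep))
          break
      }
      rows[i] <- r; cols[i] <- cc
    }
    red <- green <- matrix(0, nr, nc)
    for (i in seq_len(n_puncta)) {
      d <- disc_mask(nr, nc, c(rows[i], cols[i]), radius)
      red[d] <- 1
      if (cls[i] == "dual") green[d] <- 1
    }
    channels <- list(red = apply_noise(bg + (fg - bg) * red, noise_sd,
                                       poisson),
                     green = apply_noise(bg + (fg - bg) * green, noise_sd,
                                         poisson))
    truth <- data.frame(row = rows, col = cols,
                        radius = rep(radius, n_puncta),
                        class = cls, stringsAsFactors = FALSE)
    list(image = multichannel_image(channels, 0.07, sample_id, group),
         truth = truth)
  })
}

#' Simulate an indicator/reference calcium trace pair
#'
#' The noiseless indicator follows `A * exp(-k t)` (efflux, e.g. ER store
#' depletion after histamine) or `f0 + A * (1 - exp(-k t))` (influx, e.g.
#' mitochondrial matrix uptake). The reference channel is constant. When
#' `bleach_rate > 0` both channels are multiplied by the shared factor
#' `exp(-bleach_rate * t)`, which the ratioed dF/F0 normalization cancels.
#'
#' @param direction `"efflux"` or `"influx"`.
#' @param rate First-order rate constant k in 1/s (>= 0).
#' @param amplitude Kinetic amplitude A (intensity units).
#' @param f0 Influx starting level (ignored for efflux).
#' @param reference_level Constant reference-channel intensity.
#' @param bleach_rate Shared photobleaching rate in 1/s.
#' @param n_timepoints Number of samples (>= 2).
#' @param dt Sampling interval in seconds (> 0).
#' @param noise_sd Additive Gaussian noise applied to both channels.
#' @param seed Integer seed.
#'
#' @return Data frame with columns `time`, `indicator`, `reference`.
#' @export
sim_calcium_traces <- function(direction = c("efflux", "influx"),
                               rate = 0.01, amplitude = 100,
                               f0 = amplitude, reference_level = 100,
                               bleach_rate = 0, n_timepoints = 121, dt = 5,
                               noise_sd = 0, seed) {
  check_seed(seed)
  check_noise(noise_sd)
  direction <- match.arg(direction)
  if (rate < 0) stop_param("rate constant must be >= 0")
  if (n_timepoints < 2) stop_param("n_timepoints must be >= 2")
  if (dt <= 0) stop_param("dt must be > 0")
  time <- (seq_len(n_timepoints) - 1) * dt
  ind <- if (direction == "efflux") {
    amplitude * exp(-rate * time)
  } else {
    f0 + amplitude * (1 - exp(-rate * time))
  }
  ref <- rep(reference_level, n_timepoints)
  if (bleach_rate > 0) {
    fade <- exp(-bleach_rate * time)
    ind <- ind * fade
    ref <- ref * fade
  }
  withr::with_seed(seed, {
    if (noise_sd > 0) {
      ind <- ind + rnorm(n_timepoints, 0, noise_sd)
      ref <- ref + rnorm(n_timepoints, 0, noise_sd)
    }
    data.frame(time = time, indicator = ind, reference = ref)
  })
}

#' Simulate an ATP luminescence plate from true pathway fractions
#'
#' Condition means follow the inhibitor logic of fractional ATP profiling:
#' control = B, 2-DG = B(1 - g), oligomycin A = B(1 - m) and the combined
#' condition defaults to B(1 - g)(1 - m) clipped at zero (the combination
#' rule is a modelling choice; no standard formula exists for the combined
#' inhibition). Replicates carry mean-preserving multiplicative lognormal
#' noise at the stated coefficient of variation.
#'
#' @param glucose_dependence True glucose dependence g in \[0, 1\].
#' @param mitochondrial_dependence True mitochondrial dependence m in
#'   \[0, 1\].
#' @param baseline Control-condition mean luminescence B (RLu).
#' @param cv Coefficient of variation of replicate noise (>= 0).
#' @param n_replicates Replicates per condition (>= 1).
#' @param sample_id,group Plate annotation.
#' @param seed Integer seed.
#'
#' @return A list with `plate` (data frame: `sample_id`, `group`,
#'   `condition` in `{control, DG, OA, DGOA}`, `replicate`, `rlu`) and
#'   `truth` (the generating parameters).
#' @export
sim_atp_plate <- function(glucose_dependence, mitochondrial_dependence,
                          baseline = 1000, cv = 0.05, n_replicates = 3,
                          sample_id = "sample", group = "control", seed) {
  check_seed(seed)
  glucose_dependence <- unname(glucose_dependence)
  mitochondrial_dependence <- unname(mitochondrial_dependence)
  if (glucose_dependence < 0 || glucose_dependence > 1 ||
      mitochondrial_dependence < 0 || mitochondrial_dependence > 1)
    stop_param("dependence fractions must be in [0, 1]")
  if (cv < 0) stop_param("cv must be >= 0")
  if (n_replicates < 1) stop_param("n_replicates must be >= 1")
  means <- c(control = baseline,
             DG = baseline * (1 - glucose_dependence),
             OA = baseline * (1 - mitochondrial_dependence),
             DGOA = max(0, baseline * (1 - glucose_dependence) *
                          (1 - mitochondrial_dependence)))
  withr::with_seed(seed, {
    rlu <- unlist(lapply(means, function(mu) {
      if (cv == 0 || mu == 0) return(rep(mu, n_replicates))
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n_replicates, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    }), use.names = FALSE)
    plate <- data.frame(
      sample_id = sample_id, group = group,
      condition = rep(names(means), each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = 4),
      rlu = rlu, stringsAsFactors = FALSE)
    list(plate = plate,
         truth = list(glucose_dependence = glucose_dependence,
                      mitochondrial_dependence = mitochondrial_dependence,
                      baseline = baseline, cv = cv,
                      n_replicates = n_replicates, seed = seed))
  })
}

#' Simulate a per-gene statistics table with spiked regulation
#'
#' Null genes have log2 fold changes near zero (sd 0.25) and uniform
#' p-values; spiked genes have |log2FC| at least `effect_log2fc` and
#' p-values below `p_spike`. A mitochondrial gene list is sampled from the
#' gene universe; the number of spiked genes it contains can be fixed with
#' `n_mito_deg`.
#'
#' @param n_null,n_up,n_down Gene counts (>= 0).
#' @param effect_log2fc Minimum |log2FC| of spiked genes.
#' @param n_mito_genes Size of the mitochondrial gene list (<= total genes).
#' @param n_mito_deg Optional number of spiked genes forced into the
#'   mitochondrial list (otherwise the list is a simple random sample).
#' @param p_spike Upper bound of spiked-gene p-values.
#' @param seed Integer seed.
#'
#' @return A list with `table` (data frame: `gene`, `log2fc`, `pvalue`,
#'   `truth` in `{null, up, down}`) and `mito_genes` (character vector).
#' @export
sim_gene_table <- function(n_null = 1000, n_up = 25, n_down = 15,
                           effect_log2fc = 2, n_mito_genes = 100,
                           n_mito_deg = NULL, p_spike = 0.009, seed) {
  check_seed(seed)
  if (n_null < 0 || n_up < 0 || n_down < 0)
    stop_param("gene counts must be >= 0")
  n_total <- n_null + n_up + n_down
  if (n_mito_genes > n_total)
    stop_param("n_mito_genes exceeds the number of genes")
  withr::with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_total))
    truth <- sample(c(rep("null", n_null), rep("up", n_up),
                      rep("down", n_down)))
    lfc <- numeric(n_total); pval <- numeric(n_total)
    is_null <- truth == "null"
    lfc[is_null] <- rnorm(sum(is_null), 0, 0.25)
    pval[is_null] <- runif(sum(is_null))
    up <- truth == "up"; down <- truth == "down"
    lfc[up] <- effect_log2fc + stats::rexp(sum(up), rate = 2)
    lfc[down] <- -(effect_log2fc + stats::rexp(sum(down), rate = 2))
    pval[up | down] <- runif(sum(up | down), 1e-8, p_spike)
    spiked <- genes[!is_null]
    if (is.null(n_mito_deg)) {
      mito <- sample(genes, n_mito_genes)
    } else {
      if (n_mito_deg > min(n_mito_genes, length(spiked)))
        stop_param("n_mito_deg exceeds the spiked genes or list size")
      mito <- c(sample(spiked, n_mito_deg),
                sample(genes[is_null], n_mito_genes - n_mito_deg))
      mito <- sample(mito)
    }
    list(table = data.frame(gene = genes, log2fc = lfc, pvalue = pval,
                            truth = truth, stringsAsFactors = FALSE),
         mito_genes = mito)
  })
}

#' Simulate flow-cytometry event intensities
#'
#' Per-channel independent lognormal event intensities, the conventional
#' model for fluorescence distributions of dye-stained populations.
#'
#' @param n_events Number of events (>= 1).
#' @param log_mean Named numeric vector of per-channel log-means (channel
#'   names become columns).
#' @param log_sd Per-channel log-sd (recycled; >= 0).
#' @param sample_id,group Sample annotation columns.
#' @param seed Integer seed.
#'
#' @return Data frame: `sample_id`, `group`, one column per channel.
#' @export
sim_flow_events <- function(n_events, log_mean = c(TMRM = 7, MTG = 6.5),
                            log_sd = 0.4, sample_id = "sample",
                            group = "control", seed) {
  check_seed(seed)
  if (n_events < 1) stop_param("n_events must be >= 1")
  if (any(log_sd < 0)) stop_param("log_sd must be >= 0")
  if (is.null(names(log_mean)))
    stop_param("log_mean must be a named vector of channels")
  log_sd <- rep_len(log_sd, length(log_mean))
  withr::with_seed(seed, {
    out <- data.frame(sample_id = rep(sample_id, n_events),
                      group = rep(group, n_events),
                      stringsAsFactors = FALSE)
    for (i in seq_along(log_mean))
      out[[names(log_mean)[i]]] <- rlnorm(n_events, log_mean[i], log_sd[i])
    out
  })
}
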