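`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an end-to-end simulate/quantify/summarize pipeline
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' data, writing every per-stage table as CSV plus a machine-readable JSON
#' run log (parameters, seeds, package version). Identical configuration
#' and seed give byte-identical outputs; the run log deliberately carries
#' no timestamps.
#'
#' Stages:
#' \describe{
#'   \item{simulate}{Generate a control/stress image batch (stress doubles
#'     the contact-capsule count), a capsule image, and ATP plates; images
#'     are written as multi-page TIFF.}
#'   \item{coloc}{Uniform preprocessing, pooled control-batch Otsu
#'     threshold, small-object filtering, pixel overlap and overlap index.}
#'   \item{morpho}{Mitochondrial length measurement and morphology
#'     classification on the capsule image.}
#'   \item{atp}{Metabolic profiles from the simulated plates.}
#' }
#'
#' @param config Named list or path to a YAML file. Recognized fields:
#'   `seed` (required), `outdir` (required), `stages` (default all),
#'   `n_images` per group (default 3), `control_contacts` (default 4),
#'   `stress_contact_ratio` (default 2), `image_size` (default 128),
#'   `noise_sd` (default 0.06), `atp` (list: `glucose_dependence`,
#'   `mitochondrial_dependence` per group).
#' @return Invisibly, a list with the per-stage results and the run-log
#'   path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_param("config$seed is required")
  if (is.null(config$outdir)) stop_param("config$outdir is required")
  seed <- as.integer(config$seed)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "coloc", "morpho", "atp")
  if (any(c("coloc", "morpho", "atp") %in% stages) &&
      !"simulate" %in% stages)
    stages <- c("simulate", stages)
  n_images <- config$n_images %||% 3
  control_contacts <- config$control_contacts %||% 4
  stress_ratio <- config$stress_contact_ratio %||% 2
  image_size <- config$image_size %||% 128
  noise_sd <- config$noise_sd %||% 0.06
  atp_cfg <- config$atp %||% list(
    control = list(glucose_dependence = 0.4, mitochondrial_dependence = 0.6),
    stress = list(glucose_dependence = 0.6, mitochondrial_dependence = 0.35))
  results <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_param("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  if ("simulate" %in% stages) {
    results$simulate <- run_stage("simulate", {
      cells <- list()
      k <- 0
      for (grp in c("control", "stress")) {
        ncontact <- if (grp == "control") control_contacts else
          round(control_contacts * stress_ratio)
        for (i in seq_len(n_images)) {
          k <- k + 1
          cells[[k]] <- sim_cell_image(
            width = image_size, height = image_size,
            n_contact_capsules = ncontact, noise_sd = noise_sd,
            sample_id = sprintf("%s_%02d", grp, i), group = grp,
            seed = seed + 100L * k)
          write_image_tiff(cells[[k]]$image,
                           file.path(outdir, sprintf("cell_%s_%02d.tif",
                                                     grp, i)))
        }
      }
      caps <- sim_capsule_image(sample_id = "capsules", seed = seed + 7L)
      write_image_tiff(caps$image, file.path(outdir, "capsules.tif"),
                       truth = list(capsules = caps$truth))
      plates <- lapply(names(atp_cfg), function(grp) {
        sim_atp_plate(atp_cfg[[grp]]$glucose_dependence,
                      atp_cfg[[grp]]$mitochondrial_dependence,
                      sample_id = grp, group = grp,
                      seed = seed + 11L + match(grp, names(atp_cfg)))
      })
      plate_df <- do.call(rbind, lapply(plates, `[[`, "plate"))
      write.csv(plate_df, file.path(outdir, "atp_plates.csv"),
                row.names = FALSE)
      list(cells = cells, capsules = caps, plates = plate_df)
    })
  }

  if ("coloc" %in% stages) {
    results$coloc <- run_stage("coloc", {
      cells <- results$simulate$cells
      imgs <- lapply(cells, `[[`, "image")
      er <- preprocess_batch(imgs, "er")
      mito <- preprocess_batch(imgs, "mito")
      is_ctrl <- vapply(imgs, function(i) i$group == "control", logical(1))
      thr_er <- batch_otsu(er[is_ctrl])
      thr_mito <- batch_otsu(mito[is_ctrl])
      meas <- do.call(rbind, lapply(seq_along(imgs), function(i) {
        overlap_pixels(binarize_and_filter(er[[i]], thr_er),
                       binarize_and_filter(mito[[i]], thr_mito),
                       sample_id = imgs[[i]]$sample_id,
                       group = imgs[[i]]$group)
      }))
      oi <- overlap_index(meas, control_group = "control")
      write.csv(oi$per_sample, file.path(outdir, "coloc_per_sample.csv"),
                row.names = FALSE)
      write.csv(oi$summary, file.path(outdir, "coloc_summary.csv"),
                row.names = FALSE)
      oi
    })
  }

  if ("morpho" %in% stages) {
    results$morpho <- run_stage("morpho", {
      caps <- results$simulate$capsules
      ch <- caps$image$channels$mito
      thr <- batch_otsu(list(ch))
      objs <- measure_lengths(binarize_and_filter(ch, thr),
                              pixel_size = caps$image$pixel_size)
      objs$sample_id <- caps$image$sample_id
      objs$group <- caps$image$group
      morph <- summarize_morphology(objs)
      write.csv(morph$per_object, file.path(outdir, "morpho_objects.csv"),
                row.names = FALSE)
      write.csv(morph$summary, file.path(outdir, "morpho_summary.csv"),
                row.names = FALSE)
      morph
    })
  }

  if ("atp" %in% stages) {
    results$atp <- run_stage("atp", {
      plate_df <- results$simulate$plates
      profs <- do.call(rbind, lapply(unique(plate_df$sample_id),
                                     function(sid) {
        p <- metabolic_profile(plate_df[plate_df$sample_id == sid, ])
        data.frame(sample_id = sid,
                   glucose_dependence = p$glucose_dependence,
                   fao_aao_capacity = p$fao_aao_capacity,
                   mitochondrial_dependence = p$mitochondrial_dependence,
                   glycolytic_capacity = p$glycolytic_capacity,
                   glucose_dependence_pct = p$percent[["glucose_dependence"]],
                   mitochondrial_dependence_pct =
                     p$percent[["mitochondrial_dependence"]],
                   stringsAsFactors = FALSE)
      }))
      write.csv(profs, file.path(outdir, "atp_profiles.csv"),
                row.names = FALSE)
      profs
    })
  }

  log <- list(package = "mamquant",
              version = as.character(utils::packageVersion("mamquant")),
              seed = seed, stages = stages,
              parameters = list(n_images = n_images,
                                control_contacts = control_contacts,
                                stress_contact_ratio = stress_ratio,
                                image_size = image_size,
                                noise_sd = noise_sd, atp = atp_cfg))
  log_path <- file.path(outdir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(run_log = log_path)))
}

#' Welch two-sample comparison with group summaries
#'
#' Unequal-variance (Welch) two-tailed t-test plus the descriptive
#' statistics reported alongside every figure-style comparison: group means
#' +/- SEM and fold change of group b versus group a. When both groups have
#' zero variance the t statistic is undefined; the degenerate case is
#' reported explicitly rather than erroring (t = 0, p = 1 when the means
#' are also equal, otherwise NA).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return A list: `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`,
#'   `fold_change` (mean_b / mean_a), `statistic`, `p_value`, `df`,
#'   `degenerate` flag.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_param("each group needs at least 2 values")
  out <- list(mean_a = mean(values_a), mean_b = mean(values_b),
              sem_a = sem(values_a), sem_b = sem(values_b),
              n_a = length(values_a), n_b = length(values_b),
              fold_change = mean(values_b) / mean(values_a),
              degenerate = FALSE)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    out$degenerate <- TRUE
    equal <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    out$statistic <- if (equal) 0 else NA_real_
    out$p_value <- if (equal) 1 else NA_real_
    out$df <- NA_real_
    return(out)
  }
  tt <- t.test(values_b, values_a, var.equal = FALSE)
  out$statistic <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}
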