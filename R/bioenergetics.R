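#' Fractional ATP metabolic profile from an inhibitor panel
#'
#' Partitions ATP production into pathway dependencies from luminescence
#' measured under four conditions: vehicle control, 2-deoxy-D-glucose (DG,
#' blocks glucose metabolism), oligomycin A (OA, blocks mitochondrial ATP
#' synthase) and the combination (DGOA). With condition means `A`:
#' \itemize{
#'   \item glucose dependence = (A_control - A_DG) / A_control
#'   \item FAO/AAO capacity = 1 - glucose dependence (fatty-acid and
#'     amino-acid oxidation)
#'   \item mitochondrial dependence = (A_control - A_OA) / A_control
#'   \item glycolytic capacity = 1 - mitochondrial dependence
#' }
#' The pair sums are 1 exactly and the profile is invariant to rescaling
#' all luminescence values. The combined DGOA condition is carried through
#' but does not enter the default formulas (each fraction is defined by a
#' single-inhibitor relative decrease); `baseline = "dgoa"` subtracts the
#' DGOA mean from every condition mean first, treating it as a
#' non-glycolytic, non-mitochondrial background. Fractions outside \[0, 1\]
#' are reported unclipped with an `out_of_range` flag.
#'
#' @param plate Data frame with columns `condition` (`control`, `DG`, `OA`,
#'   optionally `DGOA`) and `rlu` (replicate luminescence), e.g.
#'   `sim_atp_plate()$plate`.
#' @param baseline `"none"` (default) or `"dgoa"`.
#' @param per_replicate If `TRUE`, fractions are computed per matched
#'   replicate (paired by the `replicate` column) and averaged, instead of
#'   on condition means.
#' @return A list of class `metabolic_profile`: fractions
#'   (`glucose_dependence`, `fao_aao_capacity`, `mitochondrial_dependence`,
#'   `glycolytic_capacity`), the same values as percentages in `percent`,
#'   condition means in `condition_means`, and `out_of_range` flags.
#' @export
metabolic_profile <- function(plate, baseline = c("none", "dgoa"),
                              per_replicate = FALSE) {
  baseline <- match.arg(baseline)
  need <- c("condition", "rlu")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop_param("plate lacks column(s): ", paste(miss, collapse = ", "))
  if (any(plate$rlu < 0)) stop_param("luminescence values must be >= 0")
  conds <- c("control", "DG", "OA")
  miss <- setdiff(conds, unique(plate$condition))
  if (length(miss))
    stop_param("plate lacks condition(s): ", paste(miss, collapse = ", "))
  cond_mean <- vapply(c(conds, "DGOA"), function(cn) {
    v <- plate$rlu[plate$condition == cn]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  frac_from <- function(ctrl, dg, oa) {
    if (is.na(ctrl) || ctrl <= 0)
      stop_param("control mean luminescence must be > 0")
    g <- (ctrl - dg) / ctrl
    m <- (ctrl - oa) / ctrl
    c(glucose_dependence = g, fao_aao_capacity = 1 - g,
      mitochondrial_dependence = m, glycolytic_capacity = 1 - m)
  }
  if (per_replicate) {
    if (!"replicate" %in% names(plate))
      stop_param("per-replicate mode needs a replicate column")
    reps <- sort(unique(plate$replicate))
    per <- vapply(reps, function(r) {
      sub <- plate[plate$replicate == r, ]
      at <- function(cn) {
        v <- sub$rlu[sub$condition == cn]
        if (length(v) != 1) stop_param("replicate ", r,
                                       " lacks a single '", cn, "' value")
        v
      }
      off <- if (baseline == "dgoa") at("DGOA") else 0
      frac_from(at("control") - off, at("DG") - off, at("OA") - off)
    }, numeric(4))
    fracs <- rowMeans(per)
  } else {
    off <- if (baseline == "dgoa") {
      if (is.na(cond_mean["DGOA"]))
        stop_param("baseline = 'dgoa' needs DGOA measurements")
      cond_mean[["DGOA"]]
    } else 0
    fracs <- frac_from(cond_mean[["control"]] - off,
                       cond_mean[["DG"]] - off, cond_mean[["OA"]] - off)
  }
  structure(list(glucose_dependence = fracs[["glucose_dependence"]],
                 fao_aao_capacity = fracs[["fao_aao_capacity"]],
                 mitochondrial_dependence =
                   fracs[["mitochondrial_dependence"]],
                 glycolytic_capacity = fracs[["glycolytic_capacity"]],
                 percent = fracs * 100,
                 condition_means = cond_mean,
                 baseline = baseline,
                 out_of_range = fracs < 0 | fracs > 1),
            class = "metabolic_profile")
}

#' @export
print.metabolic_profile <- function(x, ...) {
  cat("<metabolic_profile>\n")
  for (nm in c("glucose_dependence", "fao_aao_capacity",
               "mitochondrial_dependence", "glycolytic_capacity")) {
    flag <- if (x$out_of_range[[nm]]) "  [out of range]" else ""
    cat(sprintf("  %-25s %6.1f %%%s\n", nm, 100 * x[[nm]], flag))
  }
  invisible(x)
}

#' Compare total ATP luminescence across groups
#'
#' Group means +/- SEM of a luminescence value and fold change against a
#' reference group (the reference group's fold change is 1).
#'
#' @param plates Data frame with columns `group` and `rlu` (one value per
#'   sample, e.g. per-plate control-condition means).
#' @param reference_group Group used as the fold-change denominator.
#' @return Data frame per group: `n`, `mean_rlu`, `sem_rlu`, `fold_change`.
#' @export
total_atp_comparison <- function(plates, reference_group = "control") {
  need <- c("group", "rlu")
  miss <- setdiff(need, names(plates))
  if (length(miss))
    stop_param("plates lacks column(s): ", paste(miss, collapse = ", "))
  groups <- unique(plates$group)
  if (!reference_group %in% groups)
    stop_param("reference group '", reference_group, "' not present")
  ref_mean <- mean(plates$rlu[plates$group == reference_group])
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- plates$rlu[plates$group == g]
    data.frame(group = g, n = length(v), mean_rlu = mean(v),
               sem_rlu = sem(v), fold_change = mean(v) / ref_mean,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
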