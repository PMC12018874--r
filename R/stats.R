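# Per-point, per-patient and population statistics.
#
# Population uncertainty follows the standard Van Herk decomposition:
#   GM    = mean over patients of the per-patient mean displacement,
#   Sigma = sample SD (n-1) over patients of the per-patient means
#           (systematic / preparation error),
#   sigma = root-mean-square over patients of the per-patient SDs
#           (random / execution error).
# Sample (n-1) SDs are used throughout, at patient and population level.

DIRECTIONS <- c("rl", "ap", "cc")

#' Percentile with linear interpolation between order statistics
#'
#' Uses the convention h = 1 + (n - 1) q / 100 (R's default quantile type 7).
#' The median is `percentile(x, 50)` and the IQR is
#' `percentile(x, 75) - percentile(x, 25)`.
#'
#' @param values numeric vector, at least one value.
#' @param q percentile in 0..100.
#' @return a single number.
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L || !is.numeric(values))
    pv_stop("percentile() needs at least one numeric value")
  stopifnot(length(q) == 1L, q >= 0, q <= 100)
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' Per-point mean and SD of signed displacements across a patient's scans
#'
#' @param fields list of >= 2 signed `displacement_field`s sharing one
#'   baseline cloud (one field per test scan).
#' @return class `per_point_stats`: list with `mean_mm` and `sd_mm`
#'   (N x 3 matrices, columns `rl_mm`, `ap_mm`, `cc_mm`) and `n_test`.
#' @export
per_point_stats <- function(fields) {
  if (!is.list(fields) || length(fields) < 2L)
    pv_stop("per_point_stats needs >= 2 displacement fields")
  if (!all(vapply(fields, inherits, logical(1), "displacement_field")))
    pv_stop("all elements must be displacement_field objects")
  if (any(vapply(fields, function(f) is.null(f$signed_mm), logical(1))))
    pv_stop("fields must be signed (run sign_components first)")
  n <- vapply(fields, function(f) nrow(f$baseline_points), integer(1))
  if (length(unique(n)) != 1L)
    pv_stop("mismatched point counts across fields: ",
            paste(unique(n), collapse = ", "))
  k <- length(fields)
  # n_points x n_scans per direction
  mean_mm <- sd_mm <- matrix(NA_real_, n[1L], 3L,
                             dimnames = list(NULL, c("rl_mm", "ap_mm", "cc_mm")))
  for (d in 1:3) {
    vals <- vapply(fields, function(f) f$signed_mm[, d], numeric(n[1L]))
    mean_mm[, d] <- rowMeans(vals)
    sd_mm[, d] <- sqrt(rowSums((vals - mean_mm[, d])^2) / (k - 1))
  }
  structure(list(mean_mm = mean_mm, sd_mm = sd_mm, n_test = k),
            class = "per_point_stats")
}

new_patient_summary <- function(patient_id, method, mean_mm, sd_mm,
                                median_mm = NULL, iqr_mm = NULL, p95_mm = NULL,
                                n_test) {
  structure(list(patient_id = patient_id, method = method,
                 mean_mm = mean_mm, sd_mm = sd_mm,
                 median_mm = median_mm, iqr_mm = iqr_mm, p95_mm = p95_mm,
                 n_test = n_test),
            class = "patient_summary")
}

#' @export
print.patient_summary <- function(x, ...) {
  cat(sprintf("<patient_summary '%s', method %s>\n", x$patient_id, x$method))
  m <- rbind(mean_mm = x$mean_mm, sd_mm = x$sd_mm)
  colnames(m) <- c("RL", "AP", "CC")
  print(round(m, 3))
  invisible(x)
}

#' Surface-based patient summary (95th-percentile aggregation)
#'
#' Per direction, the patient's representative mean is the 95th percentile
#' over baseline points of the per-point means, and likewise for SDs
#' (`mode = "p95_of_stats"`, the default). The alternative
#' `mode = "stats_of_p95"` takes the 95th percentile per scan first, then
#' the mean/SD across scans — kept as a sensitivity switch. Global
#' median/IQR/p95 per direction are computed from the pooled signed values
#' of all points and scans.
#'
#' @param stats a [per_point_stats()] result.
#' @param fields the signed fields the stats came from (for pooled values and
#'   the `stats_of_p95` mode).
#' @param patient_id identifier carried into the summary.
#' @param q percentile used for aggregation (default 95).
#' @param mode `"p95_of_stats"` or `"stats_of_p95"`.
#' @return class `patient_summary` with per-direction `mean_mm`, `sd_mm`,
#'   `median_mm`, `iqr_mm`, `p95_mm`.
#' @export
patient_summary_surface <- function(stats, fields, patient_id = NA_character_,
                                    q = 95,
                                    mode = c("p95_of_stats", "stats_of_p95")) {
  stopifnot(inherits(stats, "per_point_stats"))
  mode <- match.arg(mode)
  if (mode == "p95_of_stats") {
    mean_mm <- apply(stats$mean_mm, 2L, percentile, q = q)
    sd_mm <- apply(stats$sd_mm, 2L, percentile, q = q)
  } else {
    per_scan <- vapply(fields, function(f)
      apply(f$signed_mm, 2L, percentile, q = q), numeric(3L))  # 3 x k
    mean_mm <- rowMeans(per_scan)
    sd_mm <- apply(per_scan, 1L, stats::sd)
  }
  pooled <- lapply(1:3, function(d)
    unlist(lapply(fields, function(f) f$signed_mm[, d]), use.names = FALSE))
  names(mean_mm) <- names(sd_mm) <- c("rl_mm", "ap_mm", "cc_mm")
  new_patient_summary(patient_id, "surface_p95", mean_mm, sd_mm,
                      median_mm = vapply(pooled, percentile, numeric(1), q = 50),
                      iqr_mm = vapply(pooled, function(v)
                        percentile(v, 75) - percentile(v, 25), numeric(1)),
                      p95_mm = vapply(pooled, percentile, numeric(1), q = q),
                      n_test = stats$n_test)
}

#' COM-based patient summary
#'
#' Per direction: mean and sample SD of the signed COM shifts across the
#' patient's test scans.
#'
#' @param shifts list of >= 2 [com_displacement()]s.
#' @param patient_id identifier carried into the summary.
#' @return class `patient_summary`.
#' @export
patient_summary_com <- function(shifts, patient_id = NA_character_) {
  if (!is.list(shifts) || length(shifts) < 2L)
    pv_stop("patient_summary_com needs >= 2 COM displacements")
  m <- t(vapply(shifts, unclass, numeric(3)))
  mean_mm <- colMeans(m)
  sd_mm <- apply(m, 2L, stats::sd)
  new_patient_summary(patient_id, "com", mean_mm, sd_mm,
                      median_mm = apply(m, 2L, percentile, q = 50),
                      iqr_mm = apply(m, 2L, function(v)
                        percentile(v, 75) - percentile(v, 25)),
                      p95_mm = apply(m, 2L, percentile, q = 95),
                      n_test = length(shifts))
}

#' Population systematic, random and group-mean errors
#'
#' Van Herk decomposition over patients: GM = mean of per-patient means,
#' Sigma = sample SD of per-patient means, sigma = RMS of per-patient SDs.
#'
#' @param summaries list of >= 2 `patient_summary` objects sharing a method.
#' @return class `population_errors`: list with per-direction `Sigma_mm`,
#'   `sigma_mm`, `gm_mm`, plus `method` and `n_patients`.
#' @export
population_errors <- function(summaries) {
  if (!is.list(summaries) || length(summaries) < 2L)
    pv_stop("population_errors needs >= 2 patient summaries")
  methods <- unique(vapply(summaries, `[[`, character(1), "method"))
  if (length(methods) != 1L)
    pv_stop("all summaries must share one method; got: ",
            paste(methods, collapse = ", "))
  means <- t(vapply(summaries, `[[`, numeric(3), "mean_mm"))
  sds <- t(vapply(summaries, `[[`, numeric(3), "sd_mm"))
  structure(list(method = methods,
                 gm_mm = colMeans(means),
                 Sigma_mm = apply(means, 2L, stats::sd),
                 sigma_mm = sqrt(colMeans(sds^2)),
                 n_patients = length(summaries)),
            class = "population_errors")
}

#' @export
print.population_errors <- function(x, ...) {
  cat(sprintf("Population errors (%s method, %d patients):\n",
              x$method, x$n_patients))
  m <- rbind(`Systematic Sigma (mm)` = x$Sigma_mm,
             `Random sigma (mm)` = x$sigma_mm,
             `Group mean (mm)` = x$gm_mm)
  colnames(m) <- c("RL", "AP", "CC")
  print(round(m, 2))
  invisible(x)
}

#' @export
as.data.frame.population_errors <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(method = x$method,
             direction = c("RL", "AP", "CC"),
             Sigma_mm = unname(x$Sigma_mm),
             sigma_mm = unname(x$sigma_mm),
             gm_mm = unname(x$gm_mm),
             n_patients = x$n_patients)
}
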