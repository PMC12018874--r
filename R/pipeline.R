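# Orchestration: per-patient analysis, cohort-level fit, and the
# simulate / analyze / aggregate pipeline stages with manifests.
# All randomness lives in the simulator; analysis is fully deterministic.

#' Analyse one patient: COM and BLD surface paths
#'
#' Applies each test scan's rigid transform (point clouds and COMs are
#' transformed, contours are never re-sliced), computes COM displacements
#' and signed BLD displacement fields against the baseline, per-point
#' statistics across the test scans, and both patient summaries.
#'
#' @param patient a [patient_record()].
#' @param spacing_mm surface sampling distance (mm).
#' @param q aggregation percentile (default 95).
#' @param mode surface-summary mode, see [patient_summary_surface()].
#' @param surfaces compute the surface path (set `FALSE` for a COM-only,
#'   much faster analysis).
#' @param keep_fields retain the per-scan displacement fields (memory-heavy).
#' @return class `patient_analysis`: list with `patient`, `summary_com`,
#'   and, when `surfaces`, `cloud`, `stats`, `summary_surface` (and
#'   optionally `fields`).
#' @export
analyze_patient <- function(patient, spacing_mm = 1, q = 95,
                            mode = c("p95_of_stats", "stats_of_p95"),
                            surfaces = TRUE, keep_fields = FALSE) {
  stopifnot(inherits(patient, "patient_record"))
  mode <- match.arg(mode)
  bl <- baseline_scan(patient)
  tests <- test_scans(patient)
  if (length(tests) < 2L)
    pv_stop("patient '", patient$patient_id, "' has fewer than 2 test scans")
  com_b <- center_of_mass(bl$gtvp)
  shifts <- lapply(tests, function(s) {
    com_t <- transform_points(center_of_mass(s$gtvp), s$transform_to_baseline)
    com_displacement(com_b, com_t, test_scan_id = s$scan_id)
  })
  out <- list(patient_id = patient$patient_id, patient = patient,
              summary_com = patient_summary_com(shifts, patient$patient_id),
              com_shifts = shifts)
  if (surfaces) {
    cloud <- sample_surface(bl$gtvp, spacing_mm, scan_id = bl$scan_id)
    fields <- lapply(tests, function(s) {
      tc <- transform_points(sample_surface(s$gtvp, spacing_mm, s$scan_id),
                             s$transform_to_baseline)
      sign_components(bld_map(cloud, tc), bl$gtvp, com_b)
    })
    stats <- per_point_stats(fields)
    out$cloud <- cloud
    out$stats <- stats
    out$summary_surface <- patient_summary_surface(stats, fields,
                                                  patient$patient_id,
                                                  q = q, mode = mode)
    if (keep_fields) out$fields <- fields
  }
  structure(out, class = "patient_analysis")
}

#' @export
print.patient_analysis <- function(x, ...) {
  cat(sprintf("<patient_analysis '%s'%s>\n", x$patient_id,
              if (is.null(x$summary_surface)) " (COM only)" else ""))
  invisible(x)
}

as_patient_records <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) return(cohort$records)
  if (is.character(cohort) && length(cohort) == 1L && dir.exists(cohort)) {
    files <- sort(list.files(cohort, pattern = "\\.json$", full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    return(lapply(files, read_patient))
  }
  if (inherits(cohort, "patient_record")) return(list(cohort))
  if (is.list(cohort) &&
      all(vapply(cohort, inherits, logical(1), "patient_record")))
    return(cohort)
  pv_stop("cohort must be a synthetic_cohort, a directory path, or a list of patient_record objects")
}

#' Fit the interfraction positional-variation model to a cohort
#'
#' The package's front door: runs the COM and BLD surface paths on every
#' patient, decomposes population uncertainty into systematic (Sigma),
#' random (sigma) and group-mean errors for both methods, and (for the
#' surface path) maps per-patient statistics onto a common reference rectum
#' with directional/height segmentation plus the cranial/caudal end-slice
#' analysis.
#'
#' @param cohort a [generate_cohort()] result, a directory of patient JSON
#'   files, or a list of [patient_record()]s.
#' @param spacing_mm surface sampling distance (mm; default 1, which puts
#'   study-sized tumors in the 7000-28000 point range).
#' @param q aggregation percentile (default 95).
#' @param mode surface-summary mode, see [patient_summary_surface()].
#' @param min_patients reference-map validity threshold (default 5).
#' @param ref reference rectum geometry.
#' @param scheme directional/height [section_scheme()].
#' @param method `"both"`, `"com"` (skips surfaces entirely) or `"surface"`.
#' @param on_error `"stop"` or `"skip"` (skip-and-report partial-failure
#'   semantics; skipped patients are listed in the result).
#' @return an object of class `positional_variation` with components
#'   `analyses`, `population` (per method), `reference_map`, `segments`
#'   (4 directions x 3 bands plus cranial/caudal), `cc`, `skipped`, and the
#'   echoed parameters. Methods: `print`, `summary`, `coef`, `plot`.
#' @export
positional_variation <- function(cohort, spacing_mm = 1, q = 95,
                                 mode = c("p95_of_stats", "stats_of_p95"),
                                 min_patients = 5L,
                                 ref = build_reference_rectum(),
                                 scheme = section_scheme(),
                                 method = c("both", "com", "surface"),
                                 on_error = c("stop", "skip")) {
  records <- as_patient_records(cohort)
  mode <- match.arg(mode)
  method <- match.arg(method)
  on_error <- match.arg(on_error)
  surfaces <- method != "com"
  analyses <- list()
  skipped <- data.frame(patient_id = character(0), reason = character(0))
  for (rec in records) {
    a <- tryCatch(analyze_patient(rec, spacing_mm, q, mode, surfaces),
                  error = function(e) e)
    if (inherits(a, "error")) {
      if (on_error == "stop") stop(a)
      skipped <- rbind(skipped, data.frame(patient_id = rec$patient_id,
                                           reason = conditionMessage(a)))
      message("skipping patient '", rec$patient_id, "': ",
              conditionMessage(a))
    } else analyses[[rec$patient_id]] <- a
  }
  if (length(analyses) < 2L)
    pv_stop("need >= 2 successfully analysed patients")

  population <- list()
  if (method != "surface")
    population$com <- population_errors(lapply(analyses, `[[`, "summary_com"))
  reference_map <- segments <- cc <- NULL
  if (surfaces) {
    population$surface <- population_errors(lapply(analyses, `[[`,
                                                   "summary_surface"))
    contribs <- lapply(analyses, function(a)
      map_patient_to_reference(a$cloud, a$stats, a$patient, ref))
    reference_map <- aggregate_reference(contribs, ref, min_patients)
    segs_inplane <- segment_summary(reference_map, scheme)
    cc <- cc_extremes(analyses, ref, min_patients)
    segments <- rbind(segs_inplane, cc$segments)
    class(segments) <- c("segment_summaries", "data.frame")
  }
  structure(list(analyses = analyses, population = population,
                 reference_map = reference_map, segments = segments,
                 cc = cc, skipped = skipped,
                 spacing_mm = spacing_mm, q = q, mode = mode,
                 min_patients = as.integer(min_patients),
                 ref = ref, scheme = scheme, method = method),
            class = "positional_variation")
}

#' @export
print.positional_variation <- function(x, ...) {
  cat(sprintf("Interfraction positional variation: %d patients (%s)\n\n",
              length(x$analyses), x$method))
  for (p in x$population) { print(p); cat("\n") }
  if (nrow(x$skipped)) cat(sprintf("skipped %d patient(s)\n", nrow(x$skipped)))
  invisible(x)
}

#' @export
summary.positional_variation <- function(object, ...) {
  cat(sprintf("Cohort of %d patients; surface sampling %g mm; percentile q = %g\n",
              length(object$analyses), object$spacing_mm, object$q))
  print(object)
  if (!is.null(object$segments)) {
    cat("Segment summaries (median over valid reference points, mm):\n")
    print(round_df(object$segments[, c("direction", "band", "n_points",
                                       "median_Sigma_mm", "median_sigma_mm",
                                       "median_gm_mm")], 2))
  }
  invisible(object)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Population error coefficients
#'
#' @param object a [positional_variation()] fit.
#' @param ... unused.
#' @return numeric matrix: one row per method x error type (`Sigma`,
#'   `sigma`, `gm`), columns RL/AP/CC (mm).
#' @export
coef.positional_variation <- function(object, ...) {
  rows <- list()
  for (m in names(object$population)) {
    p <- object$population[[m]]
    rows[[paste0(m, ".Sigma")]] <- p$Sigma_mm
    rows[[paste0(m, ".sigma")]] <- p$sigma_mm
    rows[[paste0(m, ".gm")]] <- p$gm_mm
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("RL", "AP", "CC")
  out
}

#' Plot a reference-map overview of a fit
#'
#' Azimuth x CAX maps of the inter-patient systematic error, colored per
#' valid reference point; invalid (under-occupied) points are drawn black.
#'
#' @param x a [positional_variation()] fit (surface method required).
#' @param what one of `"Sigma"`, `"sigma"`, `"gm"`.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.positional_variation <- function(x, what = c("Sigma", "sigma", "gm"),
                                      ...) {
  if (is.null(x$reference_map))
    pv_stop("fit has no reference map (method = 'com')")
  what <- match.arg(what)
  m <- x$reference_map
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (d in c("rl", "ap")) {
    v <- m[[paste0(what, "_", d)]]
    col <- rep("black", nrow(m))
    okv <- m$valid & is.finite(v)
    if (any(okv)) {
      pal <- grDevices::hcl.colors(64, "viridis")
      col[okv] <- pal[cut(v[okv], breaks = 64, labels = FALSE,
                          include.lowest = TRUE)]
    }
    graphics::plot(m$theta_deg, m$cax_mm, col = col, pch = 15, cex = 0.5,
                   xlab = "azimuth (deg from anterior)",
                   ylab = "CAX from anal verge (mm)",
                   main = sprintf("%s, %s", what, toupper(d)), ...)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pipeline stages (simulate -> analyze -> aggregate) with run manifests.
# ---------------------------------------------------------------------------

write_manifest <- function(path, stage, params, seed = NULL) {
  jsonlite::write_json(
    list(stage = stage, package = "rectvar",
         package_version = as.character(utils::packageVersion("rectvar")),
         seed = seed, params = params),
    path, auto_unbox = TRUE, digits = 8L, null = "null")
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Wraps [generate_cohort()]: writes patient files, the ground-truth
#' manifest, and a run manifest echoing the configuration.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
pv_simulate <- function(config, out_dir, overwrite = FALSE) {
  generate_cohort(config, dir = out_dir, overwrite = overwrite)
  write_manifest(file.path(out_dir, "run_manifest.json"), "simulate",
                 unclass(config), seed = config$seed)
  invisible(out_dir)
}

#' Analyse a cohort directory
#'
#' Reads every patient file, runs [analyze_patient()] on each (patients
#' failing validation are skipped with a logged reason), writes a
#' per-patient summary CSV, optional per-point CSVs, and a serialized
#' analysis set consumed by [pv_aggregate()].
#'
#' @param cohort_dir directory of patient JSON files.
#' @param out_dir output directory.
#' @param spacing_mm,q,mode forwarded to [analyze_patient()].
#' @param per_point also write one per-point displacement CSV per patient.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a list with `analyses` and `skipped`.
#' @export
pv_analyze <- function(cohort_dir, out_dir, spacing_mm = 1, q = 95,
                       mode = c("p95_of_stats", "stats_of_p95"),
                       per_point = FALSE, overwrite = FALSE) {
  mode <- match.arg(mode)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    pv_stop("output directory '", out_dir, "' is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(cohort_dir, pattern = "^patient_.*\\.json$",
                           full.names = TRUE))
  if (!length(files))
    files <- sort(setdiff(list.files(cohort_dir, pattern = "\\.json$",
                                     full.names = TRUE),
                          file.path(cohort_dir, c("manifest.json",
                                                  "run_manifest.json"))))
  analyses <- list()
  skipped <- data.frame(file = character(0), reason = character(0))
  for (f in files) {
    res <- tryCatch({
      rec <- read_patient(f)
      analyze_patient(rec, spacing_mm, q, mode, surfaces = TRUE,
                      keep_fields = per_point)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped, data.frame(file = basename(f),
                                           reason = conditionMessage(res)))
      message("skipping '", basename(f), "': ", conditionMessage(res))
      next
    }
    if (per_point) {
      pp <- do.call(rbind, lapply(res$fields, as.data.frame))
      utils::write.csv(pp, file.path(out_dir, paste0("per_point_",
                                                     res$patient_id, ".csv")),
                       row.names = FALSE)
      res$fields <- NULL
    }
    analyses[[res$patient_id]] <- res
  }
  summaries <- do.call(rbind, lapply(analyses, function(a) {
    row <- function(s) data.frame(
      patient_id = a$patient_id, method = s$method,
      mean_rl_mm = s$mean_mm[1L], mean_ap_mm = s$mean_mm[2L],
      mean_cc_mm = s$mean_mm[3L],
      sd_rl_mm = s$sd_mm[1L], sd_ap_mm = s$sd_mm[2L], sd_cc_mm = s$sd_mm[3L],
      n_test = s$n_test)
    rbind(row(a$summary_com), row(a$summary_surface))
  }))
  rownames(summaries) <- NULL
  utils::write.csv(summaries, file.path(out_dir, "patient_summaries.csv"),
                   row.names = FALSE)
  saveRDS(analyses, file.path(out_dir, "analyses.rds"))
  if (nrow(skipped))
    utils::write.csv(skipped, file.path(out_dir, "skipped.csv"),
                     row.names = FALSE)
  write_manifest(file.path(out_dir, "run_manifest.json"), "analyze",
                 list(cohort_dir = cohort_dir, spacing_mm = spacing_mm,
                      q = q, mode = mode, n_analyzed = length(analyses),
                      n_skipped = nrow(skipped)))
  invisible(list(analyses = analyses, skipped = skipped))
}

#' Aggregate analysed patients into population outputs
#'
#' Writes the population-errors CSV (two methods x three directions), the
#' reference-map CSV (per reference point Sigma/sigma/GM with validity
#' mask), and the segment CSV (four directions x three height bands plus
#' cranial/caudal), with a run manifest.
#'
#' @param analyze_dir output directory of [pv_analyze()].
#' @param out_dir output directory.
#' @param min_patients reference-map validity threshold.
#' @param ref reference rectum geometry.
#' @param scheme [section_scheme()].
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a list with `population`, `reference_map`, `segments`.
#' @export
pv_aggregate <- function(analyze_dir, out_dir, min_patients = 5L,
                         ref = build_reference_rectum(),
                         scheme = section_scheme(), overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    pv_stop("output directory '", out_dir, "' is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analyses <- readRDS(file.path(analyze_dir, "analyses.rds"))
  if (length(analyses) < 2L) pv_stop("need >= 2 analysed patients")
  population <- rbind(
    as.data.frame(population_errors(lapply(analyses, `[[`, "summary_com"))),
    as.data.frame(population_errors(lapply(analyses, `[[`, "summary_surface"))))
  contribs <- lapply(analyses, function(a)
    map_patient_to_reference(a$cloud, a$stats, a$patient, ref))
  reference_map <- aggregate_reference(contribs, ref, min_patients)
  cc <- cc_extremes(analyses, ref, min_patients)
  segments <- rbind(segment_summary(reference_map, scheme), cc$segments)
  utils::write.csv(population, file.path(out_dir, "population_errors.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(reference_map),
                   file.path(out_dir, "reference_map.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(segments),
                   file.path(out_dir, "segments.csv"), row.names = FALSE)
  write_manifest(file.path(out_dir, "run_manifest.json"), "aggregate",
                 list(analyze_dir = analyze_dir, min_patients = min_patients,
                      ref = list(length_mm = max(ref$slice_cax),
                                 slice_spacing_mm = ref$slice_spacing_mm,
                                 radius_mm = ref$radius_mm,
                                 n_points = ref$n_points),
                      bands = scheme$bands))
  invisible(list(population = population, reference_map = reference_map,
                 segments = segments))
}
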