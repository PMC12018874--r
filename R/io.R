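# Canonical JSON patient dialect.
#
# {"patient_id": str, "anal_verge_z_mm": num, "centerline_mm": [[x,y,z],...],
#  "scans": [{"scan_id": str, "timepoint": 1-6, "role": "baseline"|"test",
#             "transform_to_baseline": {"rotation_deg": [rx,ry,rz],
#                                       "translation_mm": [tx,ty,tz],
#                                       "center_mm": [cx,cy,cz]},
#             "structures": {"GTVp": {"slices": [{"z_mm": num,
#                                                 "points_mm": [[x,y],...]}]}}}]}
#
# Serialization is canonical: fixed key order, numbers rounded to 6 decimals,
# so write -> read -> write is byte-stable.

pv_parse_error <- function(field, why) {
  pv_stop(sprintf("cannot parse patient file: field '%s' %s", field, why),
          class = c("rectvar_parse_error", "rectvar_error"))
}

need_field <- function(obj, field, where) {
  if (is.null(obj[[field]])) pv_parse_error(paste0(where, field), "is missing")
  obj[[field]]
}

#' Read a patient record from the canonical JSON dialect
#'
#' Parses and fully validates a patient file: exactly one baseline scan,
#' unique timepoints, simple contours with strictly increasing slice
#' positions at constant spacing, and a centerline covering the tumor
#' z range. All invariant violations found are reported together.
#'
#' @param path path to a patient JSON file.
#' @return a validated [patient_record()].
#' @seealso [write_patient()]
#' @export
read_patient <- function(path) {
  if (!file.exists(path))
    pv_parse_error(path, "does not exist")
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = TRUE),
                  error = function(e) pv_parse_error(path, paste0(
                    "is not valid JSON (", conditionMessage(e), ")")))
  pid <- need_field(obj, "patient_id", "")
  verge <- need_field(obj, "anal_verge_z_mm", "")
  cl <- need_field(obj, "centerline_mm", "")
  scans_raw <- need_field(obj, "scans", "")
  if (!is.list(scans_raw) || length(scans_raw) == 0L)
    pv_parse_error("scans", "must be a non-empty array")
  scans <- lapply(seq_along(scans_raw), function(i) {
    s <- scans_raw[[i]]
    where <- sprintf("scans[%d].", i)
    tr <- need_field(s, "transform_to_baseline", where)
    structures <- need_field(s, "structures", where)
    gt <- structures[["GTVp"]]
    if (is.null(gt)) pv_parse_error(paste0(where, "structures.GTVp"), "is missing")
    slices_raw <- need_field(gt, "slices", paste0(where, "structures.GTVp."))
    slices <- lapply(seq_along(slices_raw), function(k) {
      sl <- slices_raw[[k]]
      swhere <- sprintf("%sstructures.GTVp.slices[%d].", where, k)
      contour_slice(need_field(sl, "z_mm", swhere),
                    need_field(sl, "points_mm", swhere))
    })
    scan_record(scan_id = need_field(s, "scan_id", where),
                timepoint = need_field(s, "timepoint", where),
                role = need_field(s, "role", where),
                transform_to_baseline = rigid_transform(
                  rotation_deg = need_field(tr, "rotation_deg", paste0(where, "transform_to_baseline.")),
                  translation_mm = need_field(tr, "translation_mm", paste0(where, "transform_to_baseline.")),
                  center_mm = need_field(tr, "center_mm", paste0(where, "transform_to_baseline."))),
                gtvp = structure_set("GTVp", slices))
  })
  patient_record(patient_id = pid, anal_verge_z_mm = verge,
                 centerline = cl, scans = scans)
}

#' Write a patient record in canonical JSON form
#'
#' Keys are emitted in a fixed order and numbers rounded to 6 decimals, so
#' `write_patient(read_patient(f))` reproduces `f` byte for byte when `f`
#' itself is canonical. Non-finite coordinates are rejected.
#'
#' @param record a [patient_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patient <- function(record, path) {
  if (!inherits(record, "patient_record"))
    pv_validation_error("record must be a patient_record")
  # re-validate: records may have been modified after construction
  for (s in record$scans) {
    if (!is.list(s$gtvp$slices) || length(s$gtvp$slices) == 0L)
      pv_validation_error(sprintf("scan '%s': slices must be a non-empty list",
                                  s$scan_id))
    for (sl in s$gtvp$slices)
      if (!is.finite(sl$z_mm) || !all(is.finite(sl$vertices)))
        pv_validation_error(sprintf(
          "scan '%s': coordinates must be finite for serialization", s$scan_id))
  }
  record <- suppressWarnings(
    patient_record(record$patient_id, record$anal_verge_z_mm,
                   record$centerline, record$scans))
  obj <- list(
    patient_id = record$patient_id,
    anal_verge_z_mm = record$anal_verge_z_mm,
    centerline_mm = unname(record$centerline),
    scans = lapply(record$scans, function(s) {
      list(scan_id = s$scan_id,
           timepoint = s$timepoint,
           role = s$role,
           transform_to_baseline = list(
             rotation_deg = s$transform_to_baseline$rotation_deg,
             translation_mm = s$transform_to_baseline$translation_mm,
             center_mm = s$transform_to_baseline$center_mm),
           structures = list(GTVp = list(
             slices = lapply(s$gtvp$slices, function(sl)
               list(z_mm = sl$z_mm, points_mm = unname(sl$vertices))))))
    }))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 6L, pretty = FALSE)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) pv_stop("cannot open '", path,
                                              "' for writing",
                                              class = "rectvar_io_error"))
  on.exit(close(con))
  writeBin(charToRaw(as.character(txt)), con)
  invisible(path)
}
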