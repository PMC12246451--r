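#' Default feasibility checks
#'
#' The built-in limitation/check table for each reconstruction method.
#' Iterative (ITR) checks: detector coverage within 1–6 alpha (below the
#' low-count region), probe overlap at least 70%, maximum detected angle
#' within the 10 degree small-angle limit, resolution gain >= 1, combined
#' sampling >= 1, chosen pattern-recovery level below the combined sampling,
#' and the probe fitting half the probe window. SSB checks: scan step within
#' the Nyquist bound, detector coverage at least 1 alpha (fixed) and a
#' bright-field disk of at least 4 pixels (fixed). Fixed rows fail hard;
#' editable rows warn when within 10% of their threshold.
#'
#' @param method `"ITR"` or `"SSB"`.
#' @return A data.frame of check specifications (id, description, bound
#'   type, thresholds, fixed flag).
#' @export
default_checks <- function(method = c("ITR", "SSB")) {
  method <- match.arg(method)
  if (method == "ITR") {
    data.frame(
      id = c("detector_coverage", "probe_overlap", "small_angle",
             "resolution_gain", "combined_sampling", "pattern_recovery",
             "probe_window"),
      description = c(
        "Detector cover is at least the BF disk and less than the low count area",
        "Proper reconstruction requires significant real-space probe overlap",
        "Maximum detected angle within the small-angle approximation limit",
        "Reconstructed image has more pixels than scanning beam positions",
        "Combined real- and reciprocal-space sampling is above the set level",
        "Chosen pattern recovery level is lower than the combined sampling",
        "Electron probe fulfils the Nyquist (probe window) condition"),
      bound = c("range", "ge", "le", "ge", "ge", "ge", "le"),
      lo = c(1, 70, NA, 1, 1, NA, NA),
      hi = c(6, NA, 174.532925199433, NA, NA, NA, NA),  # 10 deg in mrad
      fixed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      id = c("ssb_step", "detector_coverage", "min_bf_disk"),
      description = c(
        "Scanning step size is below the semi-angle related Nyquist bound",
        "Detector cover is at least 1 alpha",
        "BF disk diameter is at least the minimal 4 pixel limit"),
      bound = c("le", "ge", "ge"),
      lo = c(NA, 1, 4),
      hi = c(NA, NA, NA),
      fixed = c(FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  }
}

# one verdict: value against [lo, hi] bounds; warn when editable and within
# warn_frac of the binding threshold (on the passing side)
.verdict <- function(value, lo, hi, fixed, warn_frac = 0.1) {
  pass <- (is.na(lo) || value >= lo) && (is.na(hi) || value <= hi)
  if (!pass) return("fail")
  if (fixed) return("pass")
  near <- FALSE
  if (!is.na(lo) && lo != 0) near <- near || (value - lo) / abs(lo) <= warn_frac
  if (!is.na(hi) && hi != 0) near <- near || (hi - value) / abs(hi) <= warn_frac
  if (near) "warn" else "pass"
}

#' Run the feasibility checks on a plan
#'
#' Evaluates every check of [default_checks()] (or a user-edited copy)
#' against the plan's sampling report. Verdicts are pure functions of the
#' plan and thresholds.
#'
#' @param plan An [acquisition_plan()].
#' @param report Its [build_report()]; recomputed when missing.
#' @param specs Check specification data.frame; defaults to
#'   `default_checks(plan$method)`.
#' @param pattern_recovery Requested synthetic pattern-upsampling level for
#'   the pattern-recovery check (default 1).
#' @return An object of class `check_report`: data.frame with columns `id`,
#'   `measured`, `lo`, `hi`, `verdict`, `message`; attribute `overall` is
#'   `"fail"` if any check fails, else `"warn"` if any warns, else `"pass"`.
#' @export
run_checks <- function(plan, report = build_report(plan),
                       specs = default_checks(plan$method),
                       pattern_recovery = 1) {
  geom <- attr(report, "geometry")
  if (is.null(geom)) stop_domain("report carries no derived geometry")
  measured <- vapply(seq_len(nrow(specs)), function(i) {
    switch(specs$id[i],
      detector_coverage = geom$coverage_alpha,
      probe_overlap = report$SR_overlap,
      small_angle = geom$theta_mrad,
      resolution_gain = report$resolution_gain,
      combined_sampling = report$S_hat,
      pattern_recovery = report$S_hat,
      probe_window = report$d_probe_A,
      ssb_step = report$step_used_A,
      min_bf_disk = geom$bf_disk_diameter_px,
      stop_domain(sprintf("unknown check id `%s`", specs$id[i])))
  }, numeric(1))
  lo <- specs$lo; hi <- specs$hi
  # data-dependent thresholds
  i <- match("pattern_recovery", specs$id); if (!is.na(i)) lo[i] <- pattern_recovery
  i <- match("probe_window", specs$id); if (!is.na(i)) hi[i] <- report$d_probe_max_A
  i <- match("ssb_step", specs$id); if (!is.na(i)) hi[i] <- report$ssb_step_A
  verdict <- vapply(seq_len(nrow(specs)), function(i)
    .verdict(measured[i], lo[i], hi[i], specs$fixed[i]), character(1))
  msg <- sprintf("%s: measured %.4g (bounds %s..%s) -> %s", specs$id,
                 measured, ifelse(is.na(lo), "-inf", format(lo, digits = 6)),
                 ifelse(is.na(hi), "inf", format(hi, digits = 6)), verdict)
  out <- data.frame(id = specs$id, measured = measured, lo = lo, hi = hi,
                    verdict = verdict, message = msg, stringsAsFactors = FALSE)
  overall <- if (any(verdict == "fail")) "fail" else if (any(verdict == "warn")) "warn" else "pass"
  structure(out, overall = overall, class = c("check_report", "data.frame"))
}

#' Serialise a check report as stable JSON
#'
#' The same plan and thresholds always produce byte-identical JSON.
#' @param report A `check_report`.
#' @return A JSON string.
#' @export
check_report_json <- function(report) {
  payload <- list(
    overall = attr(report, "overall"),
    checks = lapply(seq_len(nrow(report)), function(i) list(
      id = report$id[i],
      measured = signif(report$measured[i], 12),
      lo = if (is.na(report$lo[i])) NULL else signif(report$lo[i], 12),
      hi = if (is.na(report$hi[i])) NULL else signif(report$hi[i], 12),
      verdict = report$verdict[i]))
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

#' Camera-length selection guide
#'
#' Recomputes the design metrics and check verdicts of a plan across a list
#' of candidate effective camera lengths. When the plan's detector carries a
#' measured angular pitch, it is rescaled inversely with camera length
#' relative to the detector's own camera length.
#'
#' @param plan An [acquisition_plan()].
#' @param camera_lengths_cm Ordered vector of effective camera lengths, cm.
#' @param nominal_cm Optional matching nominal camera lengths (for labelling).
#' @return A data.frame with one row per camera length: `nominal_cm`,
#'   `effective_cm`, `dtheta_mrad`, `theta_mrad`, `coverage_alpha`,
#'   `itr_pixel_A`, `r_z_A`, `D_psi_A`, `d_probe_max_A`, `S_hat`, `verdict`.
#' @export
camera_length_guide <- function(plan, camera_lengths_cm, nominal_cm = NULL) {
  if (length(camera_lengths_cm) < 1) stop_domain("need at least one camera length")
  if (is.null(nominal_cm)) nominal_cm <- rep(NA_real_, length(camera_lengths_cm))
  rows <- lapply(seq_along(camera_lengths_cm), function(i) {
    L <- camera_lengths_cm[i]
    det <- plan$detector
    if (!is.null(det$dtheta_mrad) && !is.na(det$camera_length_cm)) {
      det$dtheta_mrad <- det$dtheta_mrad * det$camera_length_cm / L
    } else {
      det$dtheta_mrad <- NULL
    }
    det$camera_length_cm <- L
    p <- plan; p$detector <- det
    rep <- build_report(p)
    g <- attr(rep, "geometry")
    chk <- run_checks(p, rep)
    data.frame(nominal_cm = nominal_cm[i], effective_cm = L,
               dtheta_mrad = g$dtheta_mrad, theta_mrad = g$theta_mrad,
               coverage_alpha = g$coverage_alpha, itr_pixel_A = rep$itr_pixel_A,
               r_z_A = rep$r_z_A, D_psi_A = rep$D_psi_A,
               d_probe_max_A = rep$d_probe_max_A, S_hat = rep$S_hat,
               verdict = attr(chk, "overall"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum camera length keeping 1 alpha on the detector (SSB)
#'
#' The largest candidate camera length whose detected-angle range still
#' covers the full bright-field disk (`theta >= alpha`).
#'
#' @inheritParams camera_length_guide
#' @return The camera length in cm, or `NA` if none qualifies.
#' @export
ssb_max_camera_length <- function(plan, camera_lengths_cm) {
  guide <- camera_length_guide(plan, camera_lengths_cm)
  ok <- guide$coverage_alpha >= 1
  if (!any(ok)) return(NA_real_)
  max(guide$effective_cm[ok])
}
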