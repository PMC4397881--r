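STANDARD_MOTIONS <- c("max_flexion", "max_abduction", "max_ir_0",
                      "max_ir_30", "max_ir_60", "max_ir_90")

#' ROM record
#'
#' One subject/source/condition set of endpoint angles for the six standard
#' motions, in the long format the ROM CSV uses.
#'
#' @param subject subject identifier.
#' @param source `"simulation"` or `"reference"` (e.g. a tracking system).
#' @param condition `"native"` or `"cam"`.
#' @param angles named numeric vector over the six standard motion labels,
#'   or a `rom_table` from [simulate_standard_set()].
#' @return A tibble: `subject`, `source`, `condition`, `motion`, `angle_deg`.
#' @export
rom_record <- function(subject, source, condition, angles) {
  source <- match.arg(source, c("simulation", "reference"))
  condition <- match.arg(condition, c("native", "cam"))
  if (inherits(angles, "rom_table"))
    angles <- stats::setNames(angles$angle, angles$motion)
  if (!setequal(names(angles), STANDARD_MOTIONS))
    stop("angles must cover exactly the six standard motions: ",
         paste(STANDARD_MOTIONS, collapse = ", "), call. = FALSE)
  if (!all(is.finite(angles))) stop("angles must be finite", call. = FALSE)
  tibble::tibble(subject = as.character(subject), source = source,
                 condition = condition,
                 motion = STANDARD_MOTIONS,
                 angle_deg = as.numeric(angles[STANDARD_MOTIONS]))
}

#' Compare native and cam conditions
#'
#' Per-motion limitation: `difference = native - cam` degrees; a motion is
#' flagged `limited` when the difference strictly exceeds the threshold
#' (restricted by *more than* `threshold` degrees).
#'
#' @param native,cam [rom_record()] tibbles for the same subject and source.
#' @param threshold limitation threshold, degrees (default 5).
#' @return A tibble of class `rom_comparison`: `motion`, `native`, `cam`,
#'   `difference`, `limited`; subject/source/threshold as attributes.
#' @export
compare_conditions <- function(native, cam, threshold = 5) {
  stopifnot(all(native$condition == "native"), all(cam$condition == "cam"))
  if (!identical(unique(native$subject), unique(cam$subject)) ||
      !identical(unique(native$source), unique(cam$source)))
    stop("native and cam records must share subject and source", call. = FALSE)
  if (!setequal(native$motion, cam$motion))
    stop("motion sets differ between conditions", call. = FALSE)
  out <- dplyr::inner_join(
    dplyr::select(native, "motion", native = "angle_deg"),
    dplyr::select(cam, "motion", cam = "angle_deg"),
    by = "motion")
  out <- dplyr::mutate(out,
                       difference = .data$native - .data$cam,
                       limited = .data$difference > threshold)
  attr(out, "subject") <- unique(native$subject)
  attr(out, "source") <- unique(native$source)
  attr(out, "threshold") <- threshold
  class(out) <- c("rom_comparison", class(out))
  out
}

#' Per-motion error of simulated limitations against a reference
#'
#' `error = simulated difference - reference difference`, per motion.
#'
#' @param sim,ref [compare_conditions()] results over the same motions.
#' @return A tibble: `motion`, `sim_difference`, `ref_difference`, `error`.
#' @export
error_vs_reference <- function(sim, ref) {
  if (!setequal(sim$motion, ref$motion))
    stop("motion sets differ between simulation and reference", call. = FALSE)
  dplyr::inner_join(
    dplyr::select(sim, "motion", sim_difference = "difference"),
    dplyr::select(ref, "motion", ref_difference = "difference"),
    by = "motion") |>
    dplyr::mutate(error = .data$sim_difference - .data$ref_difference)
}

#' Descriptive error statistics
#'
#' Median (average of the middle two for even n), interquartile range
#' (25th/75th percentiles, linear interpolation between order statistics),
#' and maximum absolute error.
#'
#' @param errors numeric vector of per-motion errors (degrees).
#' @return Object of class `rom_error_stats`.
#' @export
error_stats <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0) stop("empty error list", call. = FALSE)
  if (!all(is.finite(errors))) stop("errors must be finite", call. = FALSE)
  q <- stats::quantile(errors, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(median = stats::median(errors), q25 = q[1], q75 = q[2],
                 max_abs = max(abs(errors)), n = length(errors),
                 errors = errors),
            class = "rom_error_stats")
}

#' @export
print.rom_error_stats <- function(x, ...) {
  cat(sprintf(
    "<rom_error_stats: n=%d, median %.1f deg (IQR %.1f - %.1f), max |error| %.1f deg>\n",
    x$n, x$median, x$q25, x$q75, x$max_abs))
  invisible(x)
}

#' @export
glance.rom_error_stats <- function(x, ...) {
  tibble::tibble(n = x$n, median = x$median, q25 = x$q25, q75 = x$q75,
                 max_abs = x$max_abs)
}

#' Limitation-detection confusion counts
#'
#' Reference flags define the ground truth; simulated flags are scored
#' against them at a common (strict) threshold, recomputed from the
#' differences.
#'
#' @param sim,ref lists of [compare_conditions()] results, aligned by
#'   subject (same order) and motion.
#' @param threshold limitation threshold, degrees.
#' @return A tibble: `tp`, `fp`, `fn`, `tn`, `n` (= subjects x motions).
#' @export
detection_confusion <- function(sim, ref, threshold = 5) {
  stopifnot(length(sim) == length(ref))
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(sim)) {
    s <- sim[[i]]; r <- ref[[i]]
    if (!setequal(s$motion, r$motion))
      stop("motion sets differ at subject ", i, call. = FALSE)
    m <- dplyr::inner_join(
      dplyr::select(s, "motion", sd = "difference"),
      dplyr::select(r, "motion", rd = "difference"), by = "motion")
    sflag <- m$sd > threshold
    rflag <- m$rd > threshold
    tp <- tp + sum(sflag & rflag)
    fp <- fp + sum(sflag & !rflag)
    fn <- fn + sum(!sflag & rflag)
    tn <- tn + sum(!sflag & !rflag)
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn)
}

#' Read/write the ROM CSV
#'
#' Long schema: `subject,source,condition,motion,angle_deg`.  Angles are
#' written to 0.1 degree.
#'
#' @param path file path.
#' @return A tibble in the [rom_record()] layout.
#' @export
read_rom_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("ROM CSV has no data rows", call. = FALSE)
  hdr <- strsplit(lines[1], ",")[[1]]
  need <- c("subject", "source", "condition", "motion", "angle_deg")
  if (!identical(trimws(hdr), need))
    stop("ROM CSV header must be: ", paste(need, collapse = ","), call. = FALSE)
  rows <- lapply(seq.int(2, length(lines)), function(i) {
    p <- strsplit(lines[i], ",")[[1]]
    if (length(p) != 5)
      stop(sprintf("parse error at line %d: expected 5 fields, got %d",
                   i, length(p)), call. = FALSE)
    ang <- suppressWarnings(as.numeric(p[5]))
    if (is.na(ang))
      stop(sprintf("parse error at line %d: angle_deg '%s' is not numeric",
                   i, p[5]), call. = FALSE)
    if (!p[4] %in% STANDARD_MOTIONS)
      stop(sprintf("parse error at line %d: unknown motion '%s'", i, p[4]),
           call. = FALSE)
    tibble::tibble(subject = p[1], source = p[2], condition = p[3],
                   motion = p[4], angle_deg = ang)
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_rom_csv
#' @param records tibble in the [rom_record()] layout (rows from one or
#'   several records).
#' @export
write_rom_csv <- function(records, path) {
  df <- dplyr::mutate(records, angle_deg = round(.data$angle_deg, 1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a comparison report
#'
#' Per-motion comparison table as CSV (one row per subject and motion, with
#' native/cam angles, difference and limitation flag) plus a JSON summary
#' with the error statistics and detection counts.
#'
#' @param comparisons list of [compare_conditions()] results (simulation).
#' @param stats a [error_stats()] result, or `NULL`.
#' @param confusion a [detection_confusion()] tibble, or `NULL`.
#' @param prefix output path prefix (writes `<prefix>.csv`, `<prefix>.json`).
#' @export
write_report <- function(comparisons, stats = NULL, confusion = NULL, prefix) {
  tab <- dplyr::bind_rows(lapply(comparisons, function(cmp)
    dplyr::mutate(tibble::as_tibble(cmp), subject = attr(cmp, "subject"),
                  .before = 1)))
  tab <- dplyr::mutate(tab, dplyr::across(
    c("native", "cam", "difference"), ~ round(.x, 1)))
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  summ <- list(n_comparisons = length(comparisons))
  if (!is.null(stats))
    summ$error_stats <- list(median = stats$median, q25 = stats$q25,
                             q75 = stats$q75, max_abs = stats$max_abs,
                             n = stats$n)
  if (!is.null(confusion)) summ$detection <- as.list(confusion)
  jsonlite::write_json(summ, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
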