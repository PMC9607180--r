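# Pipeline orchestration: simulate -> filter -> register -> deviate ->
# summarize -> stats, reproducible from a single seed, with per-stage logs
# and a run manifest.

#' Pipeline run configuration
#'
#' All defaults match the reference study's analysis choices: 19 men and
#' 41 women, 10% ICP trim, 1e-4 mm convergence tolerance, 3 mm display cap
#' and relevance threshold, 95th-percentile region statistic, alpha 0.05.
#'
#' @param seed integer master seed; per-subject substreams are derived.
#' @param n_men,n_women cohort composition.
#' @param resolution face-grid resolution per axis.
#' @param trim,tol,max_iter trimmed-ICP options.
#' @param cap,max_valid deviation display cap and validity bound (mm).
#' @param flag_prob quantile used as the region statistic (default 0.95).
#' @param alpha significance level for the contingency calls.
#' @param min_region_vertices assessability threshold per region.
#' @param write_heatmaps write a PLY heatmap per subject (default TRUE).
#' @param out_dir output directory.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_men = 19, n_women = 41, resolution = 140,
                       trim = 0.10, tol = 1e-4, max_iter = 100,
                       cap = 3, max_valid = 10, flag_prob = 0.95,
                       alpha = 0.05, min_region_vertices = 20,
                       write_heatmaps = TRUE, out_dir = "facedev_run") {
  structure(list(seed = as.integer(seed), n_men = n_men, n_women = n_women,
                 resolution = resolution, trim = trim, tol = tol,
                 max_iter = max_iter, cap = cap, max_valid = max_valid,
                 flag_prob = flag_prob, alpha = alpha,
                 min_region_vertices = min_region_vertices,
                 write_heatmaps = write_heatmaps, out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as key: value text
#'
#' A flat, YAML-style `key: value` file that round-trips losslessly
#' through [read_config()].
#' @param config a [run_config()]; `path` a file path.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.logical(v)) ifelse(v, "true", "false")
    else if (is.numeric(v)) sprintf("%.17g", v)
    else as.character(v)
  }, "")
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  conf <- run_config()
  for (m in kv) {
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    if (!key %in% names(conf)) stop("unknown config key: ", key)
    conf[[key]] <- if (val %in% c("true", "false")) val == "true"
      else if (grepl("^-?[0-9.eE+-]+$", val)) as.numeric(val)
      else val
    if (key == "seed") conf$seed <- as.integer(conf$seed)
  }
  conf
}

stage_log <- function(stage, subject, ...) {
  message(sprintf("[%s] subject=%s %s", stage, subject,
                  paste(sprintf("%s=%s", names(list(...)),
                                unlist(lapply(list(...), format))),
                        collapse = " ")))
}

#' Analyze a single shell/scan pair
#'
#' Registration (landmark Kabsch seed + trimmed ICP), deviation field,
#' and regional summary for one subject. The common core of [run_all()]
#' and [compare_external()].
#'
#' @param pair a `face_pair` (or compatible list with `shell`, `scan`,
#'   `shell_atlas`, `scan_atlas`, `shell_landmarks`, `scan_landmarks`).
#' @param config a [run_config()].
#' @return list with `report` (registration), `field` (deviation),
#'   `summary` (regional table), `scan_aligned`.
#' @export
analyze_pair <- function(pair, config = run_config()) {
  rep <- register_pair(pair, trim = config$trim, tol = config$tol,
                       max_iter = config$max_iter)
  scan_aligned <- rt_apply(rep$transform, pair$scan)
  field <- absolute_deviation(scan_aligned, pair$shell,
                              cap = config$cap, max_valid = config$max_valid)
  summ <- summarize_regions(field, pair$scan_atlas, prob = config$flag_prob,
                            min_vertices = config$min_region_vertices)
  list(report = rep, field = field, summary = summ, scan_aligned = scan_aligned)
}

#' Run the full pipeline
#'
#' Deterministic given the seed: simulates the cohort, applies the
#' selection criteria, registers and measures every included subject, and
#' writes per-subject bundles (STL meshes, transform, deviation CSV,
#' optional PLY heatmap, region summary) plus cohort tables
#' (`table_contingency.csv`, `table_friedman.csv`), the exclusion log and
#' a JSON run manifest to `config$out_dir`. Subjects whose summary already
#' exists on disk are skipped, so an interrupted run can be resumed.
#'
#' @param config a [run_config()].
#' @param profile a [deviation_profile()] (default: the reference cohort's
#'   observed rates).
#' @return invisibly, a list with the cohort `flags`, `values`, `tables`,
#'   `filter` result and the output directory.
#' @export
run_all <- function(config = run_config(), profile = default_deviation_profile()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fp <- face_params(resolution = config$resolution)
  cases <- simulate_cohort(config$n_men, config$n_women, profile,
                           seed = config$seed, face_parameters = fp)
  manifest <- cohort_manifest(cases)
  write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  flt <- filter_cohort(manifest)
  write.csv(flt$exclusions, file.path(out, "exclusions.csv"), row.names = FALSE)
  stage_log("filter", "-", included = nrow(flt$included),
            excluded = nrow(flt$exclusions))
  if (nrow(flt$included) == 0)
    stop("no subjects pass the selection criteria; see exclusions.csv")

  flags <- NULL
  values <- NULL
  for (sid in flt$included$subject_id) {
    case <- cases[[match(sid, manifest$subject_id)]]
    sdir <- file.path(out, sid)
    sfile <- file.path(sdir, "summary.csv")
    if (file.exists(sfile)) {
      stage_log("resume", sid, skipped = TRUE)
      summ <- read.csv(sfile, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      t0 <- proc.time()[3]
      pair <- build_case(case,
                         min_region_vertices = min(config$min_region_vertices, 20))
      res <- analyze_pair(pair, config)
      summ <- res$summary
      write_case_bundle(pair, sdir)
      write_transform(res$report$transform, file.path(sdir, "registration.txt"))
      write.csv(data.frame(iteration = seq_along(res$report$rms),
                           rms_mm = res$report$rms),
                file.path(sdir, "registration_rms.csv"), row.names = FALSE)
      if (isTRUE(config$write_heatmaps))
        export_heatmap(res$field, res$scan_aligned, file.path(sdir, "heatmap"))
      write.csv(summ, sfile, row.names = FALSE)
      stage_log("analyze", sid,
                rms = sprintf("%.4f", res$report$rms[length(res$report$rms)]),
                flags = sum(summ$flag_over_3mm, na.rm = TRUE),
                secs = sprintf("%.1f", proc.time()[3] - t0))
    }
    flags <- rbind(flags, data.frame(subject_id = sid, sex = case$sex,
                                     region = summ$region,
                                     flag = summ$flag_over_3mm))
    values <- rbind(values, data.frame(subject_id = sid, region = summ$region,
                                       value = summ$p95_mm))
  }
  tables <- report_tables(flags, values, alpha = config$alpha)
  write.csv(tables$contingency, file.path(out, "table_contingency.csv"),
            row.names = FALSE)
  if (!is.null(tables$friedman))
    write.csv(tables$friedman, file.path(out, "table_friedman.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config),
         package_version = as.character(utils::packageVersion("facedev")),
         n_included = nrow(flt$included), n_excluded = nrow(flt$exclusions)),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(flags = flags, values = values, tables = tables,
                 filter = flt, out_dir = out))
}

#' Analyze an external shell/scan mesh pair
#'
#' Single-subject analysis of user-provided STL meshes: reads both meshes,
#' the scan-vertex region atlas and the landmark file, registers, measures
#' and summarizes, and writes the same per-subject outputs as the
#' simulated pipeline. A bounding-box scale mismatch (e.g. one mesh in cm)
#' or an implausibly large post-registration RMS triggers a warning.
#'
#' @param shell_path,scan_path STL file paths.
#' @param atlas_path CSV with columns `vertex_id`, `region` for the SCAN
#'   mesh ("" or missing region = unassigned).
#' @param landmarks_path CSV with columns `frame` ("shell"/"scan"),
#'   `name`, `x`, `y`, `z` (the [write_case_bundle()] layout).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the [analyze_pair()] result, invisibly.
#' @export
compare_external <- function(shell_path, scan_path, atlas_path, landmarks_path,
                             out_dir = "facedev_compare",
                             config = run_config()) {
  shell <- read_stl(shell_path)
  scan <- read_stl(scan_path)
  at <- read.csv(atlas_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("vertex_id", "region") %in% names(at)))
    stop("atlas CSV needs columns vertex_id, region")
  if (nrow(at) != nrow(scan$vertices))
    stop(sprintf("atlas has %d rows but the scan has %d vertices",
                 nrow(at), nrow(scan$vertices)))
  atlas <- rep(NA_character_, nrow(scan$vertices))
  atlas[at$vertex_id] <- ifelse(at$region == "", NA_character_, at$region)
  lm <- read.csv(landmarks_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("frame", "name", "x", "y", "z") %in% names(lm)))
    stop("landmark file needs columns frame, name, x, y, z")
  mk <- function(fr) {
    sub <- lm[lm$frame == fr, , drop = FALSE]
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$name
    m
  }
  diag_ratio <- function(m) sqrt(sum(apply(m$vertices, 2, function(v) diff(range(v)))^2))
  ratio <- diag_ratio(scan) / diag_ratio(shell)
  if (ratio < 0.5 || ratio > 2)
    warning(sprintf("bounding-box scale ratio %.2f suggests a unit mismatch", ratio))
  pair <- list(shell = shell, scan = scan,
               scan_atlas = atlas, shell_landmarks = mk("shell"),
               scan_landmarks = mk("scan"))
  n_mask <- sum(atlas %in% alignment_mask()$regions, na.rm = TRUE)
  if (n_mask >= 100) {
    res <- analyze_pair(pair, config)
  } else {
    # atlas does not cover the expression-stable mask: whole-surface fit
    message(sprintf(
      "only %d scan vertices in the alignment-mask regions; using a whole-surface fit",
      n_mask))
    rep <- icp(scan, shell,
               init = kabsch(pair$scan_landmarks, pair$shell_landmarks),
               mask = NULL, trim = config$trim, tol = config$tol,
               max_iter = config$max_iter)
    scan_aligned <- rt_apply(rep$transform, scan)
    field <- absolute_deviation(scan_aligned, shell, cap = config$cap,
                                max_valid = config$max_valid)
    res <- list(report = rep, field = field,
                summary = summarize_regions(field, atlas, prob = config$flag_prob,
                                            min_vertices = config$min_region_vertices),
                scan_aligned = scan_aligned)
  }
  final_rms <- res$report$rms[length(res$report$rms)]
  if (final_rms > 5)
    warning(sprintf("final registration RMS %.2f mm exceeds the 5 mm sanity bound; check units and overlap", final_rms))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_transform(res$report$transform, file.path(out_dir, "registration.txt"))
  export_heatmap(res$field, res$scan_aligned, file.path(out_dir, "heatmap"))
  write.csv(res$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(res)
}
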