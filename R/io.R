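#' Write / read a point cloud as ASCII PLY
#'
#' Minimal fixed-schema PLY (vertex x, y, z as floats) for exchanging
#' implant surface samples and marker clouds with mesh tools.
#'
#' @param points n x 3 matrix (mm).
#' @param path file path.
#' @export
write_ply <- function(points, path) {
  points <- as_pointset(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(points)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(points, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hd_end <- match("end_header", lines)
  if (is.na(hd_end)) stop("not an ASCII PLY file: ", path)
  nv_line <- grep("^element vertex", lines[seq_len(hd_end)], value = TRUE)
  nv <- as.integer(sub("element vertex\\s+", "", nv_line[1]))
  vals <- utils::read.table(text = lines[(hd_end + 1):(hd_end + nv)])
  as_pointset(as.matrix(vals[, 1:3]))
}

#' Serialize a simulated study to a directory
#'
#' One directory per study: marker tables and long-format truth/plan tables
#' as CSV, implant clouds as PLY, the configuration as YAML and a manifest
#' (file list, seed, counts) as JSON.
#'
#' @param study output of [generate_study()].
#' @param dir target directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(study$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(study$plan_table, file.path(dir, "plan_table.csv"),
                   row.names = FALSE)
  marker_rows <- list()
  ply_files <- character()
  for (i in seq_along(study$exams)) {
    e <- study$exams[[i]]
    tag <- sprintf("%s_t%03d_r%d", e$subject, round(e$timepoint), e$replicate)
    for (seg in c("pelvis", "femur")) {
      mk <- e[[paste0(seg, "_markers")]]
      marker_rows[[length(marker_rows) + 1L]] <- data.frame(
        subject = e$subject, timepoint = e$timepoint,
        replicate = e$replicate, segment = seg, marker_id = rownames(mk),
        x = mk[, 1], y = mk[, 2], z = mk[, 3])
    }
    for (m in names(e$implant_clouds)) for (seg in names(e$implant_clouds[[m]])) {
      f <- file.path(dir, sprintf("%s_%s_%s.ply", tag, m, seg))
      write_ply(e$implant_clouds[[m]][[seg]], f)
      ply_files <- c(ply_files, basename(f))
    }
  }
  utils::write.csv(do.call(rbind, marker_rows),
                   file.path(dir, "markers.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, n_subjects = cfg$n_subjects,
         n_exams = length(study$exams),
         files = c("config.yaml", "truth.csv", "plan_table.csv",
                   "markers.csv", ply_files)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a marker table written by [write_study()]
#'
#' Validates the CSV schema and reports the first offending row on
#' malformed input.
#'
#' @param path `markers.csv` path.
#' @export
read_markers_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("subject", "timepoint", "replicate", "segment", "marker_id",
           "x", "y", "z")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("marker CSV missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z))
  if (length(bad)) stop("non-finite marker coordinates at row ", bad[1])
  d
}
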