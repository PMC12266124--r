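# Plain-text/TIFF interchange: multi-page grayscale TIFF videos with JSON
# sidecar metadata, unit-headed CSV curves, label TIFF + CSV morphometry
# scenes.

#' Write / read a video as multi-page grayscale TIFF
#'
#' Frames are clipped to `[0, 1]` and stored 16-bit; acquisition metadata
#' (pixel size, frame rate, seed, motion model) goes to a JSON sidecar
#' `<path>.json`.
#'
#' @param video A [gen_video()] result (or any list with `frames`, `spec`).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  frames <- video$frames
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(t) pmin(pmax(frames[, , t], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  spec <- video$spec
  meta <- list(pixel_size_um = spec$pixel_size, frame_rate = spec$frame_rate,
               seed = spec$seed, motion = spec$motion$kind,
               noise_sd = spec$noise_sd, texture_scale = spec$texture_scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_video_tiff
#' @return For `read_video_tiff`: a list with `frames` (array `[y, x, t]`)
#'   and `meta` (sidecar metadata, or `NULL`).
#' @export
read_video_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, as_mat)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  list(frames = frames, meta = meta)
}

# metadata comment line, e.g. "# R_um=100 condition=immersed"
meta_line <- function(...) {
  kv <- list(...)
  paste0("# ", paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " "))
}

parse_meta_line <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (!startsWith(l1, "# ")) return(list())
  parts <- strsplit(sub("^# ", "", l1), " ", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, `[`, 2L)
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}

#' Write / read indentation curves as unit-headed CSV
#'
#' Columns `depth_um,force_uN`; indenter radius and immersion condition are
#' stored in a leading comment line.
#'
#' @param curve An `indentation_curve`.
#' @param path CSV path.
#' @return `path` / an `indentation_curve`.
#' @export
write_indentation_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_line(R_um = attr(curve, "R_um"),
                       condition = attr(curve, "condition")), con)
  write.csv(as.data.frame(curve)[c("depth_um", "force_uN")], con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_indentation_csv
#' @export
read_indentation_csv <- function(path) {
  meta <- parse_meta_line(path)
  df <- read.csv(path, comment.char = "#")
  new_indentation_curve(df$depth_um, df$force_uN,
                        as.numeric(meta$R_um %||% 100),
                        meta$condition %||% "immersed")
}

#' Write / read tensile curves as unit-headed CSV
#'
#' Columns `displacement_mm,force_mN`; cross-section and gauge length are
#' stored in a leading comment line.
#'
#' @param curve A `tensile_curve`.
#' @param path CSV path.
#' @return `path` / a `tensile_curve`.
#' @export
write_tensile_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_line(cross_section_mm2 = attr(curve, "cross_section_mm2"),
                       gauge_length_mm = attr(curve, "gauge_length_mm")), con)
  write.csv(as.data.frame(curve)[c("displacement_mm", "force_mN")], con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensile_csv
#' @export
read_tensile_csv <- function(path) {
  meta <- parse_meta_line(path)
  df <- read.csv(path, comment.char = "#")
  new_tensile_curve(df$displacement_mm, df$force_mN,
                    as.numeric(meta$cross_section_mm2 %||% NA),
                    as.numeric(meta$gauge_length_mm %||% NA))
}

#' Write / read a morphometry scene
#'
#' The tube instance labels go to a 16-bit label TIFF (`<stem>_labels.tif`),
#' marker positivity and nuclei coordinates to CSVs
#' (`<stem>_markers.csv`, `<stem>_nuclei.csv`).
#'
#' @param scene A `morphometry_scene`.
#' @param stem Path stem for the three files.
#' @return `stem` / a `morphometry_scene`.
#' @export
write_scene <- function(scene, stem) {
  tiff::writeTIFF(scene$tube_labels / 65535, paste0(stem, "_labels.tif"),
                  bits.per.sample = 16L)
  write.csv(data.frame(label = seq_along(scene$marker_positive),
                       marker_positive = scene$marker_positive),
            paste0(stem, "_markers.csv"), row.names = FALSE)
  nuc <- as.data.frame(scene$nuclei)
  nuc$pixel_size_um <- scene$pixel_size
  nuc$ref_x <- scene$reference_axis[1]
  nuc$ref_y <- scene$reference_axis[2]
  write.csv(nuc, paste0(stem, "_nuclei.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_scene
#' @export
read_scene <- function(stem) {
  labels <- round(as_mat(tiff::readTIFF(paste0(stem, "_labels.tif"))) * 65535)
  storage.mode(labels) <- "integer"
  markers <- read.csv(paste0(stem, "_markers.csv"))
  nuc <- read.csv(paste0(stem, "_nuclei.csv"))
  structure(list(
    tube_labels = labels,
    marker_positive = as.logical(markers$marker_positive[order(markers$label)]),
    nuclei = tibble::tibble(x = nuc$x, y = nuc$y),
    reference_axis = c(nuc$ref_x[1], nuc$ref_y[1]),
    pixel_size = nuc$pixel_size_um[1]),
    class = "morphometry_scene")
}
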