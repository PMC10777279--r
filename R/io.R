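#' Read and write binary masks as 8-bit grayscale PNG
#'
#' False maps to 0 and true to 255, one file per mask.
#'
#' @param mask a binary mask.
#' @param path file path.
#' @return `read_mask_png()` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_binary_mask(mask) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m >= 0.5
}

polygons_to_json <- function(polygons) {
  as.character(jsonlite::toJSON(
    lapply(polygons, function(p) unname(round(p, 6))),
    digits = 8
  ))
}

polygons_from_json <- function(s) {
  x <- jsonlite::fromJSON(s, simplifyVector = TRUE)
  if (length(x) == 0) return(list())
  if (is.array(x) && length(dim(x)) == 3) {
    x <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  }
  lapply(x, function(p) matrix(as.numeric(p), ncol = 2))
}

#' Write a study dataset to a directory
#'
#' Writes `images.csv`, `raters.csv`, `demarcations.csv` (polygon node
#' lists as JSON strings in 0-based (row, col) coordinates),
#' `config_echo.json`, and per-image skin and ground-truth masks as PNG
#' under `masks/`. The directory is assembled in a temporary sibling and
#' renamed into place, so a failed write leaves nothing partial; the parent
#' of `out_dir` must already exist. Output is byte-identical for identical
#' datasets.
#'
#' @param dataset a [study_dataset()].
#' @param out_dir target directory.
#' @param write_rater_masks also write each demarcation's rasterized mask
#'   (`<image_id>.rater_<id>.png`); off by default since masks are
#'   recoverable from the polygon records.
#' @return `out_dir`, invisibly.
#' @export
write_study_dataset <- function(dataset, out_dir, write_rater_masks = FALSE) {
  parent <- dirname(normalizePath(out_dir, mustWork = FALSE))
  if (!dir.exists(parent)) stop_cm("parent directory does not exist: ", parent)
  tmp <- tempfile("studyds_", tmpdir = parent)
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))

  write.csv(images_table(dataset), file.path(tmp, "images.csv"), row.names = FALSE)
  write.csv(raters_table(dataset), file.path(tmp, "raters.csv"), row.names = FALSE)
  dem <- demarcations_table(dataset)
  dem$polygons <- vapply(dataset$demarcations, function(d) polygons_to_json(d$polygons), character(1))
  dem$marked_area <- NULL
  write.csv(dem, file.path(tmp, "demarcations.csv"), row.names = FALSE)

  dir.create(file.path(tmp, "masks"))
  for (im in dataset$images) {
    write_mask_png(im$skin_mask, file.path(tmp, "masks", paste0(im$image_id, ".skin.png")))
    write_mask_png(im$gt_affected, file.path(tmp, "masks", paste0(im$image_id, ".gt.png")))
  }
  if (write_rater_masks) {
    for (d in dataset$demarcations) {
      write_mask_png(d$mask, file.path(
        tmp, "masks", paste0(d$image_id, ".rater_", d$rater_id, ".png")
      ))
    }
  }
  if (!is.null(dataset$config_echo)) {
    writeLines(
      jsonlite::toJSON(unclass_config(dataset$config_echo), auto_unbox = TRUE, pretty = TRUE, digits = NA),
      file.path(tmp, "config_echo.json")
    )
  }
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  if (!file.rename(tmp, out_dir)) stop_cm("could not move outputs into ", out_dir)
  ok <- TRUE
  invisible(out_dir)
}

#' Read a study dataset written by [write_study_dataset()]
#'
#' Demarcation masks are re-rasterized from the stored polygon node lists
#' and clipped to each image's skin mask.
#'
#' @param dir dataset directory.
#' @return a [study_dataset()].
#' @export
read_study_dataset <- function(dir) {
  need <- c("images.csv", "raters.csv", "demarcations.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) stop_cm("missing input file: ", file.path(dir, f))
  }
  imgs <- read.csv(file.path(dir, "images.csv"), stringsAsFactors = FALSE)
  rts <- read.csv(file.path(dir, "raters.csv"), stringsAsFactors = FALSE)
  dem <- read.csv(file.path(dir, "demarcations.csv"), stringsAsFactors = FALSE)

  images <- lapply(seq_len(nrow(imgs)), function(i) {
    id <- imgs$image_id[i]
    skin_image(
      image_id = id, photo_id = imgs$photo_id[i], view_label = imgs$view_label[i],
      skin_mask = read_mask_png(file.path(dir, "masks", paste0(id, ".skin.png"))),
      gt_affected = read_mask_png(file.path(dir, "masks", paste0(id, ".gt.png"))),
      split = imgs$split[i]
    )
  })
  names(images) <- imgs$image_id
  raters <- lapply(seq_len(nrow(rts)), function(i) {
    rater_profile(
      rts$rater_id[i], arm = rts$arm[i], enrollment_order = rts$enrollment_order[i],
      boundary_jitter_sigma = rts$boundary_jitter_sigma[i],
      region_detection_prob = rts$region_detection_prob[i],
      false_positive_rate = rts$false_positive_rate[i],
      node_budget = rts$node_budget[i]
    )
  })
  demarcations <- lapply(seq_len(nrow(dem)), function(i) {
    im <- images[[dem$image_id[i]]]
    polys <- polygons_from_json(dem$polygons[i])
    mask <- if (length(polys)) {
      rasterize_polygons(nrow(im$skin_mask), ncol(im$skin_mask), polys) & im$skin_mask
    } else {
      matrix(FALSE, nrow(im$skin_mask), ncol(im$skin_mask))
    }
    demarcation(
      rater_id = dem$rater_id[i], image_id = dem$image_id[i],
      polygons = polys, mask = mask, sequence_index = dem$sequence_index[i],
      skin_mask = im$skin_mask, rater_seq = dem$rater_seq[i]
    )
  })
  cfg <- NULL
  cfg_path <- file.path(dir, "config_echo.json")
  if (file.exists(cfg_path)) {
    raw <- jsonlite::fromJSON(paste(readLines(cfg_path), collapse = "\n"),
                              simplifyVector = TRUE)
    cfg <- tryCatch(config_from_list(raw), error = function(e) raw)
    if (!is.null(raw$master_seed)) cfg$master_seed <- raw$master_seed
  }
  study_dataset(images, raters, demarcations, config_echo = cfg)
}

# Strip S3 classes so a config serializes as plain JSON.
unclass_config <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_config)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Read a study configuration from JSON
#'
#' Accepts a JSON document whose fields mirror the arguments of
#' [study_config()]; omitted fields take their defaults. Crowd entries are
#' objects with `arm` and one of `first_r`/`top_k`.
#'
#' @param path JSON file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  config_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

config_from_list <- function(raw) {
  args <- list()
  for (f in c("height", "width", "gt_provided", "gt_withheld", "lesions",
              "view_transform", "consensus_threshold", "ranking_metric",
              "photo_reduction", "sd_pooling", "shared_bias_sigma",
              "skill_drift", "preset")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  drop_empty <- function(x) if (is.list(x) && length(x) == 0) NULL else x
  if (!is.null(raw$arms)) {
    args$arms <- lapply(raw$arms, function(a) {
      sk <- lapply(as.list(a$skill %||% list()), drop_empty)
      a$skill <- do.call(skill_distribution, sk[!vapply(sk, is.null, logical(1))])
      a
    })
  }
  if (!is.null(raw$crowds)) {
    args$crowds <- lapply(names(raw$crowds), function(nm) {
      cw <- raw$crowds[[nm]]
      crowd_spec(nm, arm = cw$arm,
                 first_r = drop_empty(cw$first_r), top_k = drop_empty(cw$top_k))
    })
    names(args$crowds) <- names(raw$crowds)
  }
  do.call(study_config, args)
}
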