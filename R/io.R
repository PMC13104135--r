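#' Read a grayscale slice stack
#'
#' Accepts a multi-page TIFF file or a directory of single-image PNG/TIFF
#' files; directory entries are taken in lexicographic filename order
#' (explicit sort, never filesystem order). 8-bit and 16-bit grayscale inputs
#' are normalized to doubles in \[0, 1\]; the original bit depth is recorded
#' for write-back.
#'
#' @param path file (multi-page TIFF) or directory (image series).
#' @return a [slice_stack()].
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("empty input: no images found in ", path)
    reads <- lapply(files, read_one_image)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    reads <- lapply(pages, normalize_page)
  } else stop("no such file or directory: ", path)
  depth <- max(vapply(reads, `[[`, integer(1), "depth"))
  slice_stack(lapply(reads, `[[`, "img"), bit_depth = depth)
}

read_one_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext == "png") {
    x <- png::readPNG(f)  # already scaled to [0,1]
    if (length(dim(x)) == 3L) {
      if (dim(x)[3] > 2L) stop("unsupported format: color input ", f)
      x <- x[, , 1]
    }
    list(img = x, depth = 8L)  # png package does not expose source depth
  } else {
    normalize_page(tiff::readTIFF(f, as.is = TRUE, info = TRUE))
  }
}

# integer (as.is=TRUE) or float page -> list(img in [0,1], depth)
normalize_page <- function(x) {
  bps <- attr(x, "bits.per.sample")
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] > 2L) stop("unsupported format: color input")
    x <- x[, , 1]
  }
  if (!is.null(bps) && bps %in% c(8L, 16L))
    return(list(img = matrix(as.double(x) / (2^bps - 1), nrow(x), ncol(x)),
                depth = as.integer(bps)))
  mx <- max(x)
  if (mx <= 1 + 1e-9 && min(x) >= 0) return(list(img = x, depth = 8L))
  depth <- if (mx > 255) 16L else 8L
  list(img = x / (2^depth - 1), depth = depth)
}

#' Write a slice stack
#'
#' Values are clipped to \[0, 1\], scaled to the integer range of `bit_depth`
#' and rounded half-to-even. A `.tif`/`.tiff` path gets one multi-page TIFF;
#' a directory path gets a numbered PNG (8-bit) or TIFF series.
#'
#' @param stack a [slice_stack()].
#' @param path output TIFF file or directory.
#' @param bit_depth 8 or 16; defaults to the stack's recorded depth.
#' @export
write_stack <- function(stack, path, bit_depth = stack$bit_depth) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  mx <- 2^bit_depth - 1
  quant <- lapply(stack$slices, function(s) round(clip01(s) * mx) / mx)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    ok <- tiff::writeTIFF(quant, path, bits.per.sample = bit_depth)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    fmt <- paste0("s%0", max(4L, nchar(as.character(stack$n))), "d.tif")
    for (i in seq_len(stack$n))
      tiff::writeTIFF(quant[[i]], file.path(path, sprintf(fmt, i - 1L)),
                      bits.per.sample = bit_depth)
  }
  invisible(NULL)
}

#' Write / read rigid transform sequences as JSON
#'
#' Per-slice records `{theta_deg, tx, ty, cumulative}`, lossless to 1e-12.
#' `tx`/`ty` are the row/col translation about the image center recorded in
#' the transform.
#'
#' @param transforms list of [rigid_transform()] objects.
#' @param path JSON path.
#' @param cumulative logical flag stored with each record.
#' @export
write_transforms <- function(transforms, path, cumulative = TRUE) {
  recs <- lapply(transforms, function(tr) {
    tc <- transform_translation(tr)
    list(theta_deg = tr$theta_deg, tx = tc[1], ty = tc[2],
         center = as.numeric(tr$center), cumulative = cumulative)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname write_transforms
#' @return `read_transforms` returns a list of [rigid_transform()]s.
#' @export
read_transforms <- function(path) {
  recs <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                   error = function(e) stop("schema error: unreadable JSON: ",
                                            conditionMessage(e)))
  lapply(recs, function(r) {
    need <- c("theta_deg", "tx", "ty", "center")
    if (!all(need %in% names(r)))
      stop("schema error: transform record missing fields ",
           paste(setdiff(need, names(r)), collapse = ", "))
    rigid_transform(r$theta_deg, c(r$tx, r$ty), unlist(r$center))
  })
}

#' Write / read displacement fields as 2-channel float32 TIFF
#'
#' Channel 1 holds row displacements, channel 2 column displacements. Each
#' channel is stored affinely rescaled to \[0, 1\] (float32 samples) with the
#' per-channel offset and range recorded in the TIFF description tag, so the
#' round-trip is lossless to float32 precision of the field's value range.
#'
#' @param field a [displacement_field()].
#' @param path TIFF path.
#' @export
write_field <- function(field, path) {
  dr <- field_drow(field); dc <- field_dcol(field)
  norm_ch <- function(x) {
    r <- range(x)
    s <- if (r[2] > r[1]) r[2] - r[1] else 1
    list(img = (x - r[1]) / s, off = r[1], scale = s)
  }
  nr <- norm_ch(dr); nc <- norm_ch(dc)
  a <- array(0, dim = c(nrow(dr), ncol(dr), 2))
  a[, , 1] <- nr$img; a[, , 2] <- nc$img
  tiff::writeTIFF(a, path, bits.per.sample = 32, reduce = FALSE)
  # scaling metadata appended after the image data; TIFF readers address
  # content through the IFD and ignore trailing bytes
  desc <- jsonlite::toJSON(list(row_off = nr$off, row_scale = nr$scale,
                                col_off = nc$off, col_scale = nc$scale),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "ab")
  writeBin(charToRaw(paste0(field_meta_marker, as.character(desc))), con)
  close(con)
  invisible(NULL)
}

field_meta_marker <- "\nEMALIGN-FIELD-META "

#' @rdname write_field
#' @export
read_field <- function(path) {
  a <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(a)) != 3L || dim(a)[3] != 2L)
    stop("format error: displacement field TIFF must have exactly 2 channels")
  sz <- file.info(path)$size
  tail_n <- min(sz, 4096)
  con <- file(path, "rb"); seek(con, sz - tail_n)
  bytes <- readBin(con, "raw", tail_n); close(con)
  marker <- charToRaw(field_meta_marker)
  hit <- grepRaw(field_meta_marker, bytes, fixed = TRUE, all = TRUE)
  if (length(hit) == 0L) stop("format error: missing field scaling metadata")
  m <- jsonlite::fromJSON(rawToChar(
    bytes[(max(hit) + length(marker)):length(bytes)]))
  displacement_field(
    matrix(a[, , 1] * m$row_scale + m$row_off, dim(a)[1], dim(a)[2]),
    matrix(a[, , 2] * m$col_scale + m$col_off, dim(a)[1], dim(a)[2]))
}

#' Default run configuration
#'
#' One flat key-namespaced list covering every stage parameter, serializable
#' to YAML with a lossless round-trip. CLI flags override config values.
#'
#' @return named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L, log_level = "info",
    rigid.max_keypoints = 1000L, rigid.nms_radius = 5, rigid.patch = 16L,
    rigid.edge_low = 0.1, rigid.edge_high = 0.2, rigid.edge_dilate = 2L,
    rigid.lpm_k = 6L, rigid.lpm_tau = 0.5, rigid.lpm_passes = 2L,
    rigid.min_matches = 8L,
    flow.levels = NA_integer_, flow.outer_iters = 3L, flow.inner_iters = 100L,
    flow.lambda = 0.15, flow.min_size = 32L,
    elastic.radius = 1L, elastic.sigma_z = 1.0, elastic.sweeps = 1L,
    eval.dog_sigmas = 2^((0:4) / 2), eval.glcm_levels = 256L,
    eval.bilateral_window = 7L, eval.bilateral_sigma_s = 2,
    eval.bilateral_sigma_r = 0.1,
    tile.patch = 1024L, tile.overlap = 128L,
    synthetic.t_max = 100, synthetic.theta_max = 35,
    synthetic.alpha = 1.0, synthetic.sigma_d = 24, synthetic.amp0 = 8,
    synthetic.noise_sigma = 0.0, synthetic.interval = 1L
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#' @param config named list (see [default_config()]).
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(NULL)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- default_config()
  vals <- yaml::read_yaml(path)
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg
}

#' Write an evaluation report
#'
#' @param report result of [evaluate_stack()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$pairs, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(summary = report$summary, pairs = report$pairs),
                         json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

# minimal leveled logger; level set per call chain via option emalign.log_level
log_msg <- function(level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  thr <- getOption("emalign.log_level", "info")
  if (levels[[level]] >= levels[[thr]])
    message(sprintf("[%s] %s", level, sprintf(...)))
  invisible(NULL)
}
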