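# Serialization: datasets as per-sample raster pairs plus a JSON manifest,
# masks as binary rasters with a JSON sidecar, parameter checkpoints, and
# an optional NIfTI slice reader for real volumes.

#' Write a phantom dataset to a split directory
#'
#' One directory per split with per-sample files: the magnitude image as a
#' 32-bit float TIFF (lossless), the label and auxiliary label maps as PNG
#' rasters, and a JSON manifest `{seed, H, W, K, sigma}` per sample.
#'
#' @param dataset list of `ImageSample`s (see [make_dataset()]).
#' @param dir output directory (created if missing).
#' @param sigma noise level recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, sigma = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    stem <- file.path(dir, sprintf("sample_%04d", i))
    tiff::writeTIFF(s$image, paste0(stem, "_image.tiff"),
                    bits.per.sample = 32L, compression = "none")
    png::writePNG(s$label_map / 255, paste0(stem, "_labels.png"))
    if (!is.null(s$aux_labels))
      png::writePNG(s$aux_labels / 255, paste0(stem, "_auxlabels.png"))
    jsonlite::write_json(
      c(s$meta, list(sigma = sigma)), paste0(stem, "_meta.json"),
      auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir split directory.
#' @return list of `ImageSample`s.
#' @export
read_dataset <- function(dir) {
  metas <- sort(list.files(dir, pattern = "_meta\\.json$", full.names = TRUE))
  lapply(metas, function(mf) {
    stem <- sub("_meta\\.json$", "", mf)
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    img <- tiff::readTIFF(paste0(stem, "_image.tiff"))
    lab <- round(png::readPNG(paste0(stem, "_labels.png")) * 255)
    storage.mode(lab) <- "integer"
    out <- list(image = img, label_map = lab, edge_map = NULL,
                meta = meta[c("seed", "H", "W", "K")])
    auxf <- paste0(stem, "_auxlabels.png")
    if (file.exists(auxf)) {
      aux <- round(png::readPNG(auxf) * 255)
      storage.mode(aux) <- "integer"
      out$aux_labels <- aux
    }
    structure(out, class = "ImageSample")
  })
}

#' Write a sampling mask (raster + JSON sidecar)
#' @param mask a `SamplingMask`.
#' @param stem output path without extension.
#' @param iteration optional acquisition-iteration index recorded for
#'   learned trajectories.
#' @return `stem`, invisibly.
#' @export
write_mask <- function(mask, stem, iteration = NULL) {
  png::writePNG(mask$matrix, paste0(stem, ".png"))
  meta <- list(kind = mask$kind, rate = mask$rate, budget = mask$budget,
               seed = mask$seed, learned = mask$learned)
  if (!is.null(iteration)) meta$iteration <- iteration
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Read a sampling mask written by [write_mask()]
#' @param stem path without extension.
#' @return a `SamplingMask`.
#' @export
read_mask <- function(stem) {
  m <- round(png::readPNG(paste0(stem, ".png")))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  new_sampling_mask(m, meta$kind, meta$rate,
                    seed = meta$seed %||% NA_integer_,
                    learned = isTRUE(meta$learned))
}

#' Save / load a parameter checkpoint
#'
#' Checkpoints hold the plain numeric values of every named parameter group
#' (`msm`, `sfrm`, `ssm`, `sim`, ...).
#' @param params parameter container.
#' @param path checkpoint file.
#' @export
save_params <- function(params, path) {
  vals <- rapply2(params, function(p) p$value)
  saveRDS(vals, path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  vals <- readRDS(path)
  wrap <- function(x) {
    if (is.list(x)) {
      # conv parameter leaves carry kh/kw alongside numeric w, b
      if (!is.null(x$w) && is.numeric(x$w)) {
        return(list(w = ad_param(x$w), b = ad_param(x$b), kh = x$kh, kw = x$kw))
      }
      return(lapply(x, wrap))
    }
    x
  }
  wrap(vals)
}

#' Write a metrics table as delimited text
#' @param metrics data frame from [evaluate_model()].
#' @param path output TSV path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract normalized slices from a NIfTI volume
#'
#' Optional entry point for real data: reads a volume with RNifti, extracts
#' axial slices and min-max normalizes each to `[0,1]`.
#'
#' @param path NIfTI file.
#' @param slices slice indices (default: middle half).
#' @return list of real matrices.
#' @export
read_nifti_slices <- function(path, slices = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_nifti_slices requires the RNifti package")
  vol <- RNifti::readNifti(path)
  nz <- dim(vol)[3]
  if (is.null(slices)) slices <- seq(nz %/% 4, nz - nz %/% 4)
  lapply(slices, function(z) {
    sl <- vol[, , z]
    rng <- range(sl)
    if (diff(rng) == 0) matrix(0, nrow(sl), ncol(sl))
    else (sl - rng[1]) / diff(rng)
  })
}
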