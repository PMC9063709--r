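## End-to-end pipeline: segment -> measure -> summarize -> yield analyses.

#' Run the full image-to-analytics pipeline
#'
#' Drives every stage over a set of calibrated images (one image = one
#' plant; multiple images with the same `plant_id` are merged), writing
#' masks, label rasters, the objects table, the plant-summary table and,
#' when biomass is available, the yield analyses.  Deterministic: the
#' same config and seed give byte-identical CSVs.
#'
#' @param images data.frame with columns `path`, `cm_per_pixel`,
#'   `plant_id` (paths to PNG/TIFF/JPEG scenes), or a list of
#'   [CalibratedImage-class] objects named by plant id.
#' @param meta data.frame of plant metadata (see [readPlantMeta()]), or a
#'   CSV path; required columns `plant_id`, `genotype_id`, `state`, and
#'   `IDB_g` for the yield stages.
#' @param out_dir output directory (created if missing).
#' @param min_area_cm2,connectivity,object_side segmentation options, see
#'   [segmentScene()].
#' @param moment_source,hull_points measurement options, see
#'   [measureObject()].
#' @param yield_q cumulative yield fractions to tabulate (default
#'   0.5, 0.75, 0.9); set NULL to skip.
#' @param seed integer seed for the sampling simulation stage.
#' @param write_rasters if TRUE, masks and label rasters are written as
#'   PNG next to the CSVs.
#' @return invisibly, a list with `objects`, `plants`, `thresholds` and
#'   (if computed) `yield_thresholds`; the same tables are written under
#'   `out_dir` as `objects.csv`, `plants_summary.csv`,
#'   `yield_thresholds.csv`.
#' @export
runPipeline <- function(images, meta, out_dir,
                        min_area_cm2 = 1, connectivity = 8L,
                        object_side = "below",
                        moment_source = "region", hull_points = "corners",
                        yield_q = c(0.5, 0.75, 0.9), seed = 1L,
                        write_rasters = FALSE) {
  if (is.character(meta)) meta <- readPlantMeta(meta)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  imgs <- if (is.data.frame(images)) {
    lapply(seq_len(nrow(images)), function(i)
      loadImage(images$path[i], images$cm_per_pixel[i],
                image_id = images$plant_id[i]))
  } else images
  allObjects <- list(); thresholds <- list()
  for (img in imgs) {
    pid <- imageId(img)
    lab <- segmentScene(img, min_area_cm2 = min_area_cm2,
                        connectivity = connectivity,
                        object_side = object_side)
    thresholds[[pid]] <- attr(lab, "threshold")
    message("segment ", pid, ": T=", attr(lab, "threshold"),
            ", floor=", attr(lab, "floor_px"), " px, K=", nObjects(lab))
    obj <- measureObjects(lab, cmPerPixel(img), image_id = pid,
                          moment_source = moment_source,
                          hull_points = hull_points)
    allObjects[[pid]] <- obj
    if (write_rasters) {
      writeMask(BinaryMask(labelMatrix(lab) > 0L),
                file.path(out_dir, paste0(pid, "_mask.png")))
      writeLabels(lab, file.path(out_dir, paste0(pid, "_labels.png")))
    }
  }
  objects <- do.call(rbind, allObjects)
  rownames(objects) <- NULL
  ## merge multi-image plants by plant_id, then summarize against metadata
  plants <- list()
  for (pid in unique(objects$image_id)) {
    mrow <- meta[meta$plant_id == pid, , drop = FALSE]
    if (nrow(mrow) == 0L) stop("plant '", pid, "' missing from metadata")
    rec <- objects[objects$image_id == pid, , drop = FALSE]
    plants[[pid]] <- summarizePlant(
      rec, pid, mrow$genotype_id[1], mrow$state[1],
      IDB_g = if ("IDB_g" %in% names(mrow)) mrow$IDB_g[1] else NA_real_,
      PH_cm = if ("PH_cm" %in% names(mrow)) mrow$PH_cm[1] else NA_real_,
      DTM_d = if ("DTM_d" %in% names(mrow)) mrow$DTM_d[1] else NA_real_)
  }
  plants <- do.call(rbind, plants)
  rownames(plants) <- NULL
  out <- list(objects = objects, plants = plants,
              thresholds = unlist(thresholds))
  if (!is.null(yield_q)) {
    if (!"IDB_g" %in% names(plants) || anyNA(plants$IDB_g))
      stop("IDB required for yield analysis; add IDB_g to the metadata")
    yt <- list()
    for (pid in plants$plant_id) {
      rec <- objects[objects$image_id == pid, , drop = FALSE]
      w <- apportionWeights(rec, plants$IDB_g[plants$plant_id == pid], pid)
      for (q in yield_q) {
        th <- yieldThresholdFraction(w$weight_g, q, w$object_id)
        yt[[length(yt) + 1L]] <- data.frame(
          plant_id = pid, q = q, k_required = th$k, N = th$N,
          percent_required = th$percent)
      }
    }
    out$yield_thresholds <- do.call(rbind, yt)
    utils::write.csv(out$yield_thresholds,
                     file.path(out_dir, "yield_thresholds.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(objects, file.path(out_dir, "objects.csv"),
                   row.names = FALSE)
  utils::write.csv(plants, file.path(out_dir, "plants_summary.csv"),
                   row.names = FALSE)
  invisible(out)
}
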