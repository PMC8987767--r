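# Morphometry: recover cell feature records from smear images. Foreground
# segmentation by intensity thresholding + connected components, per-region
# measurement of the maximum caliper (Feret) diameter, nucleus blob area,
# contrast-based nucleus state, and a ridge pass counting cornification
# creases. Debris below a minimum area, border-touching regions and
# low-solidity (overlapping) regions are excluded, mirroring the usual
# inclusion criteria for measurable cells.

#' Morphometry configuration
#'
#' @param min_cell_diameter_um Regions smaller (in equivalent area) than a
#'   disk of this diameter are discarded as debris/distractors (default 8).
#' @param min_solidity Regions with convex solidity below this are flagged
#'   as overlapping and excluded by default (default 0.8).
#' @param exclude_border Exclude regions touching the image edge (default
#'   `TRUE`).
#' @param nucleus_detect_contrast Minimum intensity drop below the
#'   cytoplasm for nucleus candidate pixels (default 0.06).
#' @param demarcation_contrast Michelson-contrast threshold between nucleus
#'   and cytoplasm separating a demarcated from an eroded nucleus (default
#'   0.2).
#' @param min_nucleus_area_um2 Blobs smaller than this are not accepted as a
#'   nucleus (default 10).
#' @param line_detect_contrast Minimum intensity drop below the cytoplasm
#'   for crease pixels (default 0.15).
#' @param min_line_fraction Minimum crease length as a fraction of the
#'   cell's Feret diameter (default 0.25).
#' @param blur_sigma Gaussian blur sigma in pixels applied before nucleus
#'   detection (default 1).
#' @param diameter_method `"feret"` (maximum caliper; default) or
#'   `"equivalent_circle"`.
#' @return An object of class `cyto_morphometry_config`.
#' @export
morphometry_config <- function(min_cell_diameter_um = 8,
                               min_solidity = 0.8,
                               exclude_border = TRUE,
                               nucleus_detect_contrast = 0.06,
                               demarcation_contrast = 0.2,
                               min_nucleus_area_um2 = 10,
                               line_detect_contrast = 0.15,
                               min_line_fraction = 0.25,
                               blur_sigma = 1,
                               diameter_method = c("feret",
                                                   "equivalent_circle")) {
  structure(list(min_cell_diameter_um = min_cell_diameter_um,
                 min_solidity = min_solidity,
                 exclude_border = exclude_border,
                 nucleus_detect_contrast = nucleus_detect_contrast,
                 demarcation_contrast = demarcation_contrast,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 line_detect_contrast = line_detect_contrast,
                 min_line_fraction = min_line_fraction,
                 blur_sigma = blur_sigma,
                 diameter_method = match.arg(diameter_method)),
            class = "cyto_morphometry_config")
}

as_smear_input <- function(image, microns_per_pixel = NULL) {
  if (inherits(image, "cyto_smear_image")) {
    return(image)
  }
  if (is.matrix(image)) {
    if (is.null(microns_per_pixel)) {
      abort("A raw raster needs an explicit `microns_per_pixel` scale.",
            class = "cytovag_error_validation")
    }
    return(structure(list(image = image,
                          mask = matrix(0L, nrow(image), ncol(image)),
                          legend = tibble(mask_id = integer(),
                                          cell_id = character(),
                                          true_class = character()),
                          microns_per_pixel = microns_per_pixel),
                     class = "cyto_smear_image"))
  }
  abort("`image` must be a cyto_smear_image or a numeric matrix.",
        class = "cytovag_error_validation")
}

# maximum caliper diameter of a pixel set, in pixels (+1 for pixel extent)
feret_px <- function(rows, cols) {
  pts <- cbind(cols, rows)
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  max(dist(pts)) + 1
}

# convex hull area of pixel centres (shoelace), with a half-perimeter
# correction so solid convex pixel sets score ~1
hull_area <- function(rows, cols) {
  pts <- cbind(cols, rows)
  hull <- grDevices::chull(pts)
  h <- pts[hull, , drop = FALSE]
  nh <- nrow(h)
  if (nh < 3) {
    return(length(rows))
  }
  x <- h[, 1]
  y <- h[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  perim <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area + perim / 2 + 1
}

#' Segment candidate cells in a smear image
#'
#' Finds foreground regions by intensity thresholding against the estimated
#' background, labels connected components, and applies the exclusion
#' rules: regions below the minimum area are debris/distractors, regions
#' touching the border cannot be measured fully, and low-solidity regions
#' are treated as overlapping cells. A blank image yields an empty result,
#' not an error.
#'
#' @param image A `cyto_smear_image` (from [render_smear()] /
#'   [read_smear_image()]) or a numeric matrix plus `microns_per_pixel`.
#' @param config A [morphometry_config()].
#' @param microns_per_pixel Scale, required only for raw matrices.
#' @return A tibble with one row per candidate region: `region_id`,
#'   `n_pixels`, `area_um2`, `centroid_x_px`, `centroid_y_px`, `feret_um`,
#'   `solidity`, `touches_border`, `overlapping`, `excluded`,
#'   `exclusion_reason`, and a `pixels` list-column of (row, col) index
#'   matrices.
#' @export
segment_cells <- function(image, config = morphometry_config(),
                          microns_per_pixel = NULL) {
  smear <- as_smear_input(image, microns_per_pixel)
  img <- smear$image
  mpp <- smear$microns_per_pixel
  if (mpp <= 0) {
    abort("`microns_per_pixel` must be positive.",
          class = "cytovag_error_validation")
  }

  bg <- median(img)
  fg <- img < bg - 0.1
  if (!any(fg)) {
    return(empty_segmentation())
  }
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- as.integer(labels)
  dim(lab) <- dim(img)

  min_area_px <- pi * (config$min_cell_diameter_um / 2)^2 / mpp^2
  ids <- seq_len(max(lab))
  rows_list <- split(row(lab)[lab > 0], lab[lab > 0])
  cols_list <- split(col(lab)[lab > 0], lab[lab > 0])

  out <- map(ids, function(id) {
    rows <- rows_list[[as.character(id)]]
    cols <- cols_list[[as.character(id)]]
    npix <- length(rows)
    small <- npix < min_area_px
    touches <- any(rows == 1 | rows == nrow(img) |
                   cols == 1 | cols == ncol(img))
    if (small) {
      sol <- NA_real_
      fer <- NA_real_
      overlapping <- NA
    } else {
      sol <- min(1, npix / hull_area(rows, cols))
      fer <- feret_px(rows, cols) * mpp
      overlapping <- sol < config$min_solidity
    }
    reason <- if (small) {
      "debris"
    } else if (touches && config$exclude_border) {
      "border"
    } else if (isTRUE(overlapping)) {
      "overlap"
    } else {
      NA_character_
    }
    tibble(region_id = id, n_pixels = npix, area_um2 = npix * mpp^2,
           centroid_x_px = mean(cols - 0.5),
           centroid_y_px = mean(rows - 0.5),
           feret_um = fer, solidity = sol, touches_border = touches,
           overlapping = overlapping,
           excluded = !is.na(reason), exclusion_reason = reason,
           pixels = list(cbind(row = rows, col = cols)))
  })
  list_rbind(out)
}

empty_segmentation <- function() {
  tibble(region_id = integer(), n_pixels = integer(), area_um2 = numeric(),
         centroid_x_px = numeric(), centroid_y_px = numeric(),
         feret_um = numeric(), solidity = numeric(),
         touches_border = logical(), overlapping = logical(),
         excluded = logical(), exclusion_reason = character(),
         pixels = list())
}

#' Measure one segmented region into a cell record
#'
#' Extracts the flowchart features from a single segmented region: the
#' maximum caliper (Feret) diameter, the nucleus blob (detected as the
#' largest compact low-intensity blob after a morphological opening that
#' removes thin creases), its area via a half-contrast boundary, the
#' nucleus state from Michelson contrast against the cytoplasm, and the
#' cornification-line count from thin dark ridge components of sufficient
#' length, merged when collinear.
#'
#' @param region One row of the [segment_cells()] result (a list or
#'   one-row tibble with a `pixels` element).
#' @param image The `cyto_smear_image` (or matrix) the region came from.
#' @param config A [morphometry_config()].
#' @param microns_per_pixel Scale for raw matrices.
#' @param cell_id Identifier for the output record.
#' @return A one-row cell feature table (with `centroid_x_px`,
#'   `centroid_y_px` carried along).
#' @export
measure_cell <- function(region, image, config = morphometry_config(),
                         microns_per_pixel = NULL, cell_id = NULL) {
  smear <- as_smear_input(image, microns_per_pixel)
  img <- smear$image
  mpp <- smear$microns_per_pixel
  if (is.data.frame(region)) {
    region <- as.list(region[1, ])
    region$pixels <- region$pixels[[1]]
  }
  px <- region$pixels
  if (any(px[, "row"] < 1) || any(px[, "row"] > nrow(img)) ||
      any(px[, "col"] < 1) || any(px[, "col"] > ncol(img))) {
    abort("Region pixels fall outside the image bounds.",
          class = "cytovag_error_validation")
  }

  rows <- px[, "row"]
  cols <- px[, "col"]
  fpx <- feret_px(rows, cols)
  diameter_um <- if (config$diameter_method == "feret") {
    fpx * mpp
  } else {
    2 * sqrt(length(rows) / pi) * mpp
  }

  # work on the bounding-box crop
  r0 <- min(rows); r1 <- max(rows)
  c0 <- min(cols); c1 <- max(cols)
  crop <- img[r0:r1, c0:c1, drop = FALSE]
  in_region <- matrix(FALSE, nrow(crop), ncol(crop))
  in_region[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE

  vals <- crop[in_region]
  cyto0 <- as.numeric(quantile(vals, 0.75))
  blur <- as.matrix(EBImage::gblur(EBImage::Image(crop),
                                   sigma = config$blur_sigma))

  candidate <- in_region & (blur < cyto0 - config$nucleus_detect_contrast)
  brush5 <- EBImage::makeBrush(5, "disc")
  opened <- as.matrix(EBImage::opening(EBImage::Image(candidate * 1),
                                       brush5)) > 0.5

  nucleus_state <- "absent"
  nucleus_area <- NA_real_
  min_nuc_px <- config$min_nucleus_area_um2 / mpp^2
  blob <- NULL
  if (any(opened)) {
    blobs <- EBImage::bwlabel(EBImage::Image(opened * 1))
    blab <- as.integer(blobs)
    dim(blab) <- dim(opened)
    sizes <- tabulate(blab[blab > 0])
    big <- which(sizes >= min_nuc_px)
    if (length(big) > 0) {
      # prefer round blobs: merged creases form elongated slabs that can
      # outsize the true nucleus
      roundness <- map_dbl(big, function(id) {
        w <- which(blab == id, arr.ind = TRUE)
        sv <- svd(sweep(w, 2, colMeans(w)))$d
        if (sv[1] == 0) 1 else sv[2] / sv[1]
      })
      round_enough <- big[roundness >= 0.4]
      if (length(round_enough) > 0) {
        blob <- blab == round_enough[which.max(sizes[round_enough])]
      }
    }
  }

  blob_dil <- NULL
  if (!is.null(blob)) {
    nuc_level <- median(crop[blob])
    blob_dil <- as.matrix(EBImage::dilate(EBImage::Image(blob * 1),
                                          brush5)) > 0.5
    cyto_level <- median(vals[vals >= cyto0 - config$nucleus_detect_contrast])
    contrast <- (cyto_level - nuc_level) / (cyto_level + nuc_level)
    nucleus_state <- if (contrast >= config$demarcation_contrast) {
      "demarcated"
    } else {
      "eroded"
    }
    # refine the boundary at the half-contrast level on the raw image: the
    # blurred image would bias a convex boundary inward by ~sigma^2/(2r)
    half <- (cyto_level + nuc_level) / 2
    refined <- in_region & blob_dil & (crop < half)
    if (!any(refined)) refined <- blob
    nucleus_area <- sum(refined) * mpp^2
  }

  # cornification creases: thin dark components away from the nucleus
  dark <- in_region & (crop < cyto0 - config$line_detect_contrast)
  if (!is.null(blob_dil)) dark <- dark & !blob_dil
  n_lines <- 0L
  if (any(dark)) {
    comp <- EBImage::bwlabel(EBImage::Image(dark * 1))
    clab <- as.integer(comp)
    dim(clab) <- dim(dark)
    feats <- map(seq_len(max(clab)), function(id) {
      w <- which(clab == id, arr.ind = TRUE)
      if (nrow(w) < 3) return(NULL)
      len <- feret_px(w[, 1], w[, 2])
      if (len < config$min_line_fraction * fpx) return(NULL)
      ctr <- colMeans(w)
      sv <- svd(sweep(w, 2, ctr))$v[, 1]
      list(center = ctr, dir = sv, len = len)
    })
    feats <- feats[!map_lgl(feats, is.null)]
    n_lines <- count_merged_lines(feats)
  }

  out <- cell_table(
    diameter_um = diameter_um,
    cornification_lines = n_lines,
    nucleus_area_um2 = nucleus_area,
    nucleus_state = nucleus_state,
    cell_id = cell_id %||% paste0("region_", region$region_id))
  out$centroid_x_px <- region$centroid_x_px %||% mean(cols - 0.5)
  out$centroid_y_px <- region$centroid_y_px %||% mean(rows - 0.5)
  out
}

# merge collinear ridge components (same orientation, same line offset)
count_merged_lines <- function(feats) {
  n <- length(feats)
  if (n <= 1) return(as.integer(n))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      di <- feats[[i]]$dir
      dj <- feats[[j]]$dir
      ang <- acos(pmin(1, abs(sum(di * dj))))
      if (ang > 15 * pi / 180) next
      # lateral offset of centre j from the infinite line through centre i
      d <- feats[[j]]$center - feats[[i]]$center
      lateral <- abs(d[1] * di[2] - d[2] * di[1])
      if (lateral < 2.5) parent[find(j)] <- find(i)
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Measure every retained cell in a smear image
#'
#' Runs [segment_cells()] and [measure_cell()] over an image and returns the
#' measured cell table; the per-region exclusion log (debris, border,
#' overlap counts and reasons) is attached as the `exclusions` attribute.
#'
#' @inheritParams segment_cells
#' @return A cell feature table with `centroid_x_px`/`centroid_y_px`
#'   columns; attribute `exclusions` holds the exclusion log tibble.
#' @examples
#' \donttest{
#' tb <- generate_cell_table("estrus", 4, seed = 2)
#' img <- render_smear(tb, seed = 2)
#' measure_smear(img)
#' }
#' @export
measure_smear <- function(image, config = morphometry_config(),
                          microns_per_pixel = NULL) {
  smear <- as_smear_input(image, microns_per_pixel)
  segs <- segment_cells(smear, config)
  kept <- segs[!segs$excluded, ]
  records <- map(seq_len(nrow(kept)), function(i) {
    measure_cell(kept[i, ], smear, config,
                 cell_id = paste0("region_", kept$region_id[i]))
  })
  out <- if (length(records) == 0) {
    tb <- cell_table(diameter_um = numeric(), cornification_lines = integer(),
                     nucleus_area_um2 = numeric(),
                     nucleus_state = character(), cell_id = character())
    tb$centroid_x_px <- numeric()
    tb$centroid_y_px <- numeric()
    tb
  } else {
    list_rbind(records)
  }
  attr(out, "exclusions") <-
    segs[segs$excluded, setdiff(names(segs), "pixels")]
  out
}

#' Attach ground-truth labels to measured records
#'
#' Looks up the rendered mask id under each measured region's centroid and
#' joins the smear legend, adding `true_class` (and the generating
#' `cell_id` as `true_cell_id`) to the measured table — the round-trip
#' companion of [render_smear()] + [measure_smear()].
#'
#' @param measured Output of [measure_smear()] on a rendered image.
#' @param smear The `cyto_smear_image` the measurements came from.
#' @return `measured` with `true_class` and `true_cell_id` columns.
#' @export
match_to_ground_truth <- function(measured, smear) {
  stopifnot(inherits(smear, "cyto_smear_image"))
  ids <- smear$mask[cbind(round(measured$centroid_y_px + 0.5),
                          round(measured$centroid_x_px + 0.5))]
  legend <- smear$legend
  idx <- match(ids, legend$mask_id)
  measured$true_class <- legend$true_class[idx]
  measured$true_cell_id <- legend$cell_id[idx]
  measured
}
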