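# Synthetic smear renderer. Cells are drawn as filled regions on a bright
# background: smooth rotated ellipses for non-cornified cells, angular
# polygons for cornified ones, with the maximum caliper (Feret) extent equal
# to the cell's diameter. Demarcated nuclei are high-contrast disks of the
# recorded area, eroded nuclei low-contrast disks, cornification lines thin
# dark creases. A ground-truth integer mask covers exactly the epithelial
# cells; erythrocyte/neutrophil distractors are background clutter only.

#' Renderer configuration
#'
#' @param microns_per_pixel Physical pixel size in µm (default 0.5).
#' @param canvas_px Canvas side length in pixels, or `NULL` to size the
#'   canvas automatically for the requested cells at roughly 25 % packing.
#' @param background Background intensity on `[0, 1]` (default 0.95).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (default 0.02).
#' @param padding_um Minimum clearance between cells and to the canvas
#'   border, in µm (default 4).
#' @param max_attempts Rejection-sampling retries per object before a
#'   placement error is raised (default 2000).
#' @param cytoplasm_range Intensity range for cytoplasm (default 0.65-0.75).
#' @param nucleus_intensity Demarcated-nucleus intensity (default 0.20).
#' @param eroded_contrast Intensity offset of an eroded nucleus below its
#'   cytoplasm (default 0.08; low contrast by construction).
#' @param line_intensity Cornification-line intensity (default 0.35).
#' @return An object of class `cyto_render_config`.
#' @export
render_config <- function(microns_per_pixel = 0.5, canvas_px = NULL,
                          background = 0.95, noise_sd = 0.02,
                          padding_um = 4, max_attempts = 2000,
                          cytoplasm_range = c(0.65, 0.75),
                          nucleus_intensity = 0.20,
                          eroded_contrast = 0.08,
                          line_intensity = 0.35) {
  if (microns_per_pixel <= 0) {
    abort("`microns_per_pixel` must be positive.",
          class = "cytovag_error_validation")
  }
  structure(list(microns_per_pixel = microns_per_pixel,
                 canvas_px = canvas_px, background = background,
                 noise_sd = noise_sd, padding_um = padding_um,
                 max_attempts = max_attempts,
                 cytoplasm_range = cytoplasm_range,
                 nucleus_intensity = nucleus_intensity,
                 eroded_contrast = eroded_contrast,
                 line_intensity = line_intensity),
            class = "cyto_render_config")
}

# polygon/ellipse outline for one cell, centred at the origin, in pixels;
# the maximum pairwise vertex distance equals diameter_px
cell_outline <- function(diameter_px, cornified, round_cell = FALSE) {
  phi <- runif(1, 0, pi)
  if (cornified) {
    nv <- sample(8:12, 1)
    aspect <- runif(1, 0.70, 0.90)
    # evenly spaced vertices with bounded jitter: keeps the polygon
    # star-shaped with a healthy inradius so the nucleus always fits
    ang <- 2 * pi * seq_len(nv) / nv +
      runif(nv, -0.25, 0.25) * 2 * pi / nv
    rad <- runif(nv, 0.82, 1)
    x <- rad * cos(ang)
    y <- aspect * rad * sin(ang)
  } else {
    nv <- 72
    aspect <- if (round_cell) runif(1, 0.85, 1) else runif(1, 0.75, 0.95)
    ang <- seq(0, 2 * pi, length.out = nv + 1)[-1]
    x <- cos(ang)
    y <- aspect * sin(ang)
  }
  xr <- x * cos(phi) - y * sin(phi)
  yr <- x * sin(phi) + y * cos(phi)
  # rescale so the maximum caliper equals the requested diameter
  dmax <- max(dist(cbind(xr, yr)))
  s <- diameter_px / dmax
  list(x = xr * s, y = yr * s, angle = phi, aspect = aspect)
}

# minimum distance from the origin to the polygon boundary (inradius for a
# star-shaped outline centred at the origin)
polygon_inradius <- function(vx, vy) {
  n <- length(vx)
  x2 <- c(vx[-1], vx[1])
  y2 <- c(vy[-1], vy[1])
  dx <- x2 - vx
  dy <- y2 - vy
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, -(vx * dx + vy * dy) / len2))
  px <- vx + t * dx
  py <- vy + t * dy
  min(sqrt(px^2 + py^2))
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, vx, vy) {
  nv <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# extent of the outline along a unit direction (projection half-widths)
outline_extent <- function(outline, nx, ny) {
  proj <- outline$x * nx + outline$y * ny
  c(lo = min(proj), hi = max(proj))
}

place_objects <- function(radii, canvas_px, pad_px, max_attempts) {
  n <- length(radii)
  cx <- numeric(n)
  cy <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    lo <- r + pad_px + 1
    hi <- canvas_px - r - pad_px - 1
    if (hi <= lo) {
      abort(sprintf(paste0("Canvas of %d px cannot hold an object of ",
                           "radius %.0f px; placed %d of %d objects."),
                    canvas_px, r, i - 1L, n),
            class = "cytovag_error_placement")
    }
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      x <- runif(1, lo, hi)
      y <- runif(1, lo, hi)
      if (i == 1 || all((x - cx[seq_len(i - 1)])^2 +
                        (y - cy[seq_len(i - 1)])^2 >
                        (r + radii[seq_len(i - 1)] + pad_px)^2)) {
        cx[i] <- x
        cy[i] <- y
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(paste0("Could not place object %d of %d after %d ",
                           "attempts; achievable count at this density: %d. ",
                           "Increase `canvas_px` or reduce the cell count."),
                    i, n, max_attempts, i - 1L),
            class = "cytovag_error_placement")
    }
  }
  list(x = cx, y = cy)
}

#' Render a cell table into a synthetic smear image
#'
#' Draws every cell of a (typically generated) feature table onto a bright
#' canvas and returns the raster together with a ground-truth label mask and
#' a legend linking mask ids to cell ids. The drawing encodes exactly the
#' features the morphometry module measures: the region's maximum caliper is
#' the cell diameter, demarcated nuclei are dark disks of the recorded area,
#' eroded nuclei the same disks at low contrast, and cornification lines
#' thin dark creases crossing the cell clear of the nucleus. Distractor
#' erythrocytes (small pale discoid cells) and neutrophils (small multi-lobed
#' cells) are drawn as background clutter outside the mask.
#'
#' @param cells A cell feature table; a `true_class` column and the
#'   generator's `distractors` attribute are used when present.
#' @param config A [render_config()].
#' @param distractors Optional named vector `c(erythrocytes = , neutrophils
#'   = )` overriding the table attribute.
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   rasters.
#' @return An object of class `cyto_smear_image`: list with `image` (numeric
#'   matrix, rows = y), `mask` (integer matrix, 0 = background), `legend`
#'   (tibble of `mask_id`, `cell_id`, `true_class`), `microns_per_pixel`.
#' @examples
#' tb <- generate_cell_table("estrus", 3, seed = 1)
#' img <- render_smear(tb, render_config(canvas_px = 300), seed = 1)
#' dim(img$image)
#' @export
render_smear <- function(cells, config = render_config(), distractors = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "cyto_render_config"))
  distractors <- distractors %||% attr(cells, "distractors") %||%
    c(erythrocytes = 0, neutrophils = 0)
  cells <- validate_cell_table(cells)
  if (!is.null(seed)) set.seed(seed)

  mpp <- config$microns_per_pixel
  n <- nrow(cells)
  n_ery <- as.integer(distractors[["erythrocytes"]] %||% 0)
  n_neu <- as.integer(distractors[["neutrophils"]] %||% 0)

  # shapes first, so the canvas can be sized from their bounding radii
  outlines <- vector("list", n)
  for (i in seq_len(n)) {
    cornified <- cells$cornification_lines[i] >= 2
    round_cell <- cells$diameter_um[i] <= 20
    outlines[[i]] <- cell_outline(cells$diameter_um[i] / mpp, cornified,
                                  round_cell)
  }
  radii <- map_dbl(outlines, ~ max(sqrt(.x$x^2 + .x$y^2)))
  ery_r <- 3.25 / mpp     # 6.5 um discoid
  neu_r <- 4.5 / mpp      # lobed cluster within ~9 um
  all_radii <- c(radii, rep(ery_r, n_ery), rep(neu_r, n_neu))

  pad_px <- config$padding_um / mpp
  canvas_px <- config$canvas_px
  if (is.null(canvas_px)) {
    if (length(all_radii) == 0) {
      canvas_px <- 256L
    } else {
      occupied <- sum((2 * all_radii + pad_px)^2)
      canvas_px <- max(256L, ceiling(sqrt(occupied / 0.25)))
    }
  }
  canvas_px <- as.integer(canvas_px)

  img <- matrix(config$background, nrow = canvas_px, ncol = canvas_px)
  mask <- matrix(0L, nrow = canvas_px, ncol = canvas_px)

  if (length(all_radii) > 0) {
    pos <- place_objects(all_radii, canvas_px, pad_px, config$max_attempts)
  } else {
    pos <- list(x = numeric(), y = numeric())
  }

  line_w <- max(2, round(1.0 / mpp))
  for (i in seq_len(n)) {
    drawn <- draw_cell(img, mask, i, cells[i, ], outlines[[i]],
                       pos$x[i], pos$y[i], mpp, config, line_w)
    img <- drawn$img
    mask <- drawn$mask
  }
  for (d in seq_len(n_ery)) {
    img <- draw_erythrocyte(img, pos$x[n + d], pos$y[n + d], mpp)
  }
  for (d in seq_len(n_neu)) {
    img <- draw_neutrophil(img, pos$x[n + n_ery + d], pos$y[n + n_ery + d],
                           mpp)
  }

  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                        nrow = nrow(img))
  }
  img <- pmin(pmax(img, 0), 1)

  legend <- tibble(
    mask_id = seq_len(n),
    cell_id = cells$cell_id,
    true_class = if ("true_class" %in% names(cells)) {
      as.character(cells$true_class)
    } else {
      NA_character_
    })
  structure(list(image = img, mask = mask, legend = legend,
                 microns_per_pixel = mpp),
            class = "cyto_smear_image")
}

draw_cell <- function(img, mask, id, cell, outline, cx, cy, mpp, config,
                      line_w) {
  vx <- outline$x + cx
  vy <- outline$y + cy
  x0 <- max(1L, floor(min(vx)))
  x1 <- min(ncol(img), ceiling(max(vx)))
  y0 <- max(1L, floor(min(vy)))
  y1 <- min(nrow(img), ceiling(max(vy)))
  gx <- rep(seq(x0, x1) - 0.5, each = y1 - y0 + 1)
  gy <- rep(seq(y0, y1) - 0.5, times = x1 - x0 + 1)
  inside <- points_in_polygon(gx, gy, vx, vy)

  rows <- rep(seq(y0, y1), times = x1 - x0 + 1)[inside]
  cols <- rep(seq(x0, x1), each = y1 - y0 + 1)[inside]
  idx <- cbind(rows, cols)
  cyto <- runif(1, config$cytoplasm_range[1], config$cytoplasm_range[2])
  img[idx] <- cyto
  mask[idx] <- id

  # nucleus disk, clamped so it always fits inside the cell body
  state <- cell$nucleus_state
  r_nuc_px <- 0
  if (state != "absent") {
    r_nuc_um <- sqrt(cell$nucleus_area_um2 / pi)
    max_fit <- 0.9 * polygon_inradius(outline$x, outline$y)
    r_nuc_px <- min(r_nuc_um / mpp, max_fit)
    level <- if (state == "demarcated") {
      config$nucleus_intensity
    } else {
      cyto - config$eroded_contrast
    }
    in_nuc <- inside & ((gx - cx)^2 + (gy - cy)^2 <= r_nuc_px^2)
    img[cbind(rep(seq(y0, y1), times = x1 - x0 + 1)[in_nuc],
              rep(seq(x0, x1), each = y1 - y0 + 1)[in_nuc])] <- level
  }

  # cornification creases: parallel chords clear of the nucleus
  k <- cell$cornification_lines
  if (k > 0) {
    psi <- outline$angle + runif(1, -0.3, 0.3)
    ux <- cos(psi)
    uy <- sin(psi)
    nx <- -uy
    ny <- ux
    ext <- outline_extent(outline, nx, ny)
    gap <- r_nuc_px + 2 / mpp + line_w
    # creases must stay separable after measurement-side blurring
    spacing <- line_w + max(4, 2 / mpp)
    cand <- c()
    hi_pos <- 0.9 * ext[["hi"]] - line_w
    if (hi_pos >= gap) cand <- c(cand, seq(gap, hi_pos, by = spacing))
    lo_pos <- 0.9 * ext[["lo"]] + line_w
    if (lo_pos <= -gap) cand <- c(cand, rev(seq(-gap, lo_pos,
                                                by = -spacing)))
    if (length(cand) > 0) {
      if (length(cand) > k) {
        cand <- cand[round(seq(1, length(cand), length.out = k))]
      }
      s <- (gx - cx) * nx + (gy - cy) * ny
      t <- (gx - cx) * ux + (gy - cy) * uy
      ext_u <- outline_extent(outline, ux, uy)
      for (off in cand) {
        on_line <- inside & abs(s - off) < line_w / 2 &
          t > 0.9 * ext_u[["lo"]] & t < 0.9 * ext_u[["hi"]]
        img[cbind(rep(seq(y0, y1), times = x1 - x0 + 1)[on_line],
                  rep(seq(x0, x1), each = y1 - y0 + 1)[on_line])] <-
          config$line_intensity
      }
    }
  }
  list(img = img, mask = mask)
}

disk_indices <- function(img, cx, cy, r) {
  x0 <- max(1L, floor(cx - r))
  x1 <- min(ncol(img), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r))
  y1 <- min(nrow(img), ceiling(cy + r))
  gx <- rep(seq(x0, x1) - 0.5, each = y1 - y0 + 1)
  gy <- rep(seq(y0, y1) - 0.5, times = x1 - x0 + 1)
  inside <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  cbind(rep(seq(y0, y1), times = x1 - x0 + 1)[inside],
        rep(seq(x0, x1), each = y1 - y0 + 1)[inside])
}

draw_erythrocyte <- function(img, cx, cy, mpp) {
  r <- 3.25 / mpp
  img[disk_indices(img, cx, cy, r)] <- 0.80
  img[disk_indices(img, cx, cy, 0.45 * r)] <- 0.88   # biconcave pale centre
  img
}

draw_neutrophil <- function(img, cx, cy, mpp) {
  n_lobes <- sample(3:4, 1)
  ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_lobes + 1)[-1]
  for (a in ang) {
    img[disk_indices(img, cx + 1.6 / mpp * cos(a), cy + 1.6 / mpp * sin(a),
                     1.5 / mpp)] <- 0.55
  }
  img
}

#' @export
print.cyto_smear_image <- function(x, ...) {
  cat(sprintf("<cyto_smear_image> %d x %d px at %.3g um/px, %d cell(s)\n",
              nrow(x$image), ncol(x$image), x$microns_per_pixel,
              nrow(x$legend)))
  invisible(x)
}

#' Write a smear image, its mask and legend to disk
#'
#' The raster is written as 16-bit grayscale TIFF (or 8-bit PNG if the path
#' ends in `.png`), the ground-truth mask as 16-bit TIFF with integer ids,
#' the legend as JSON including the µm-per-pixel scale.
#'
#' @param x A `cyto_smear_image`.
#' @param image_path Output raster path (`.tif`/`.tiff` or `.png`).
#' @param mask_path Optional mask TIFF path.
#' @param legend_path Optional legend JSON path.
#' @return `image_path`, invisibly.
#' @export
write_smear_image <- function(x, image_path, mask_path = NULL,
                              legend_path = NULL) {
  stopifnot(inherits(x, "cyto_smear_image"))
  ext <- tolower(tools::file_ext(image_path))
  if (ext == "png") {
    png::writePNG(x$image, image_path)
  } else {
    tiff::writeTIFF(x$image, image_path, bits.per.sample = 16)
  }
  if (!is.null(mask_path)) {
    tiff::writeTIFF(x$mask / 65535, mask_path, bits.per.sample = 16)
  }
  if (!is.null(legend_path)) {
    jsonlite::write_json(
      list(microns_per_pixel = x$microns_per_pixel,
           cells = x$legend),
      legend_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(image_path)
}

#' Read a smear image (and optional mask/legend) from disk
#'
#' Reads 8/16-bit grayscale or RGB PNG/TIFF; RGB is converted to luminance.
#' The scale must come from the legend JSON sidecar or the
#' `microns_per_pixel` argument.
#'
#' @param image_path Raster path.
#' @param mask_path Optional mask TIFF written by [write_smear_image()].
#' @param legend_path Optional legend JSON sidecar.
#' @param microns_per_pixel Scale override; required when no legend is
#'   given.
#' @return A `cyto_smear_image`.
#' @export
read_smear_image <- function(image_path, mask_path = NULL,
                             legend_path = NULL, microns_per_pixel = NULL) {
  ext <- tolower(tools::file_ext(image_path))
  img <- if (ext == "png") {
    png::readPNG(image_path)
  } else {
    tiff::readTIFF(image_path)
  }
  if (length(dim(img)) == 3) {
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  legend <- NULL
  if (!is.null(legend_path)) {
    leg <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
    microns_per_pixel <- microns_per_pixel %||% leg$microns_per_pixel
    legend <- as_tibble(leg$cells)
  }
  if (is.null(microns_per_pixel)) {
    abort("No scale available: supply `microns_per_pixel` or a legend JSON.",
          class = "cytovag_error_validation")
  }
  mask <- if (!is.null(mask_path)) {
    m <- tiff::readTIFF(mask_path)
    matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  } else {
    matrix(0L, nrow = nrow(img), ncol = ncol(img))
  }
  structure(list(image = img, mask = mask,
                 legend = legend %||% tibble(mask_id = integer(),
                                             cell_id = character(),
                                             true_class = character()),
                 microns_per_pixel = microns_per_pixel),
            class = "cyto_smear_image")
}
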