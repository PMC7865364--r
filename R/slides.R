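#' Generate a synthetic immunostained slide
#'
#' Emulates the quantification substrate of a CD3/CD8 immunostain: rectangular
#' region masks for the tumor center (CT) and invasive margin (IM), and one
#' marked point set per marker with homogeneous Poisson counts (expectation =
#' target density x region area) and uniform coordinates inside each region.
#' When `im_present = FALSE` the IM mask and its points are dropped, which is
#' how specimens without an identifiable invasive margin enter the pipeline.
#'
#' @param density_targets Named numeric with entries `cd3_ct`, `cd8_ct`,
#'   `cd3_im`, `cd8_im` in cells/mm^2 (IM entries ignored when
#'   `im_present = FALSE`; they may be `NA` in that case).
#' @param areas Named numeric `c(ct = , im = )`, region areas in mm^2 (> 0).
#' @param im_present Is an invasive margin present on the specimen?
#' @param seed Integer seed.
#' @return An object of class `synthetic_slide`: list with `masks` (per region:
#'   `xmin`, `xmax`, `ymin`, `ymax` in mm and `area` in mm^2), `points` (per
#'   marker: two-column matrix of coordinates in mm), and `im_present`.
#' @examples
#' sl <- generate_slide(c(cd3_ct = 500, cd8_ct = 200, cd3_im = 600, cd8_im = 250),
#'                      areas = c(ct = 2, im = 1), seed = 7)
#' quantify_density(sl, "cd3", "ct")
#' @export
generate_slide <- function(density_targets, areas = c(ct = 1, im = 1),
                           im_present = TRUE, seed = 1L) {
  regions <- if (im_present) c("ct", "im") else "ct"
  markers <- c("cd3", "cd8")
  needed <- as.vector(outer(markers, regions, paste, sep = "_"))
  if (!all(needed %in% names(density_targets)))
    stop("density_targets must name ", paste(needed, collapse = ", "), call. = FALSE)
  tg <- density_targets[needed]
  if (any(!is.finite(tg)) || any(tg < 0))
    stop("density targets must be finite and >= 0", call. = FALSE)
  if (!all(regions %in% names(areas)) || any(!is.finite(areas[regions])) ||
      any(areas[regions] <= 0))
    stop("areas must be positive for every present region", call. = FALSE)

  # CT mask at the origin; IM mask a band directly above it (disjoint)
  masks <- list(ct = rect_mask(0, areas[["ct"]]))
  if (im_present) masks$im <- rect_mask(masks$ct$ymax, areas[["im"]])

  withr::with_seed(as.integer(seed), {
    points <- lapply(markers, function(m) {
      pts <- lapply(regions, function(r) {
        msk <- masks[[r]]
        k <- stats::rpois(1, density_targets[[paste(m, r, sep = "_")]] * msk$area)
        cbind(x = stats::runif(k, msk$xmin, msk$xmax),
              y = stats::runif(k, msk$ymin, msk$ymax))
      })
      do.call(rbind, pts)
    })
    names(points) <- markers
    structure(list(masks = masks, points = points, im_present = im_present),
              class = "synthetic_slide")
  })
}

# axis-aligned rectangle of the given area, 2 mm wide, stacked from y0
rect_mask <- function(y0, area) {
  width <- 2
  list(xmin = 0, xmax = width, ymin = y0, ymax = y0 + area / width, area = area)
}

#' Quantify a marker density on a slide region
#'
#' Counts the marker's points falling inside the region mask and divides by the
#' mask area, i.e. positive cells per square millimeter. An absent region (no
#' invasive margin on the specimen) yields `NA`, not an error: missingness
#' propagates to the density quartet.
#'
#' @param slide A [generate_slide()] object.
#' @param marker `"cd3"` or `"cd8"`.
#' @param region `"ct"` or `"im"`.
#' @return Density in cells/mm^2, or `NA_real_` when the region is absent.
#' @export
quantify_density <- function(slide, marker = c("cd3", "cd8"), region = c("ct", "im")) {
  marker <- match.arg(marker)
  region <- match.arg(region)
  msk <- slide$masks[[region]]
  if (is.null(msk)) return(NA_real_)
  if (msk$area <= 0) stop("region mask has non-positive area", call. = FALSE)
  pts <- slide$points[[marker]]
  inside <- pts[, "x"] >= msk$xmin & pts[, "x"] <= msk$xmax &
    pts[, "y"] >= msk$ymin & pts[, "y"] <= msk$ymax
  sum(inside) / msk$area
}

#' Quantify the full CD3/CD8 density quartet from a slide
#'
#' @param slide A [generate_slide()] object.
#' @return Named numeric `c(cd3_ct, cd8_ct, cd3_im, cd8_im)`; IM entries are
#'   `NA` when the slide has no invasive margin.
#' @export
quantify_quartet <- function(slide) {
  c(cd3_ct = quantify_density(slide, "cd3", "ct"),
    cd8_ct = quantify_density(slide, "cd8", "ct"),
    cd3_im = quantify_density(slide, "cd3", "im"),
    cd8_im = quantify_density(slide, "cd8", "im"))
}
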