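# Landscape windows: land-use parcels, linear elements and an extent.

#' Land-use classes
#'
#' Area-based land-use classes and linear-element classes recognised by the
#' landscape metrics. `ARABLE` parcels may carry per-year crop records
#' (`RAPE`, `MAIZE`, `CEREAL`, `OTHER`) for the crop-dominance metrics;
#' `SETTLE` parcels may carry a `green_fraction` (proportion of unsealed
#' green area such as gardens).
#'
#' @format Character vectors.
#' @name landuse-classes
NULL

#' @rdname landuse-classes
#' @export
AREA_CLASSES <- c("FOREST", "GRASS", "SEMNATGRASS", "SEMNATVEG", "ARABLE",
                  "ORCHARD", "SETTLE", "OTHER")

#' @rdname landuse-classes
#' @export
LINE_CLASSES <- c("LWOOD", "LWATER", "LFRINGE", "LROAD")

#' @rdname landuse-classes
#' @export
CROP_CLASSES <- c("RAPE", "MAIZE", "CEREAL")

#' @keywords internal
is_convex <- function(p) {
  n <- nrow(p)
  if (n < 4) return(TRUE)
  j <- c(2:n, 1L); k <- c(3:n, 1L, 2L)
  cr <- (p[j, 1] - p[, 1]) * (p[k, 2] - p[j, 2]) -
        (p[j, 2] - p[, 2]) * (p[k, 1] - p[j, 1])
  all(cr >= -1e-9) || all(cr <= 1e-9)
}

#' Create a landscape window
#'
#' A landscape window is the unit of study: a square (typically 5 x 5 km)
#' extent in a projected metric CRS holding land-use parcels and linear
#' landscape elements.
#'
#' @param window_id Window label.
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param parcels Tibble with columns `class` (one of [AREA_CLASSES]),
#'   `geometry` (list of two-column vertex matrices), optional
#'   `green_fraction` (SETTLE parcels) and `crops` (list of named character
#'   vectors, year -> crop, for ARABLE parcels).
#' @param lines Tibble with columns `class` (one of [LINE_CLASSES]) and
#'   `geometry` (list of two-column polyline coordinate matrices).
#' @param validate Check geometry validity and pairwise parcel overlap
#'   (overlap is checked between convex parcels; tolerance 1e-6 m^2).
#' @return An object of class `lg_window`.
#' @export
landscape_window <- function(window_id, extent, parcels, lines = NULL,
                             validate = TRUE) {
  stopifnot(length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2])
  parcels <- tibble::as_tibble(parcels)
  if (!all(c("class", "geometry") %in% names(parcels)))
    stop("parcels needs columns 'class' and 'geometry'", call. = FALSE)
  if (!all(parcels$class %in% AREA_CLASSES))
    stop("unknown land-use class: ",
         paste(setdiff(parcels$class, AREA_CLASSES), collapse = ", "),
         call. = FALSE)
  if (!"green_fraction" %in% names(parcels)) parcels$green_fraction <- NA_real_
  if (!"crops" %in% names(parcels)) parcels$crops <- vector("list", nrow(parcels))
  if (is.null(lines)) {
    lines <- tibble::tibble(class = character(), geometry = list())
  } else {
    lines <- tibble::as_tibble(lines)
    if (!all(lines$class %in% LINE_CLASSES))
      stop("unknown linear-element class: ",
           paste(setdiff(lines$class, LINE_CLASSES), collapse = ", "),
           call. = FALSE)
  }
  if (validate) {
    for (g in parcels$geometry) validate_polygon(g, "parcel")
    np <- nrow(parcels)
    if (np > 1) {
      conv <- vapply(parcels$geometry, is_convex, logical(1))
      for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
        if (!conv[j]) next
        ov <- clip_poly_convex(parcels$geometry[[i]],
                               ensure_ccw(parcels$geometry[[j]]))
        if (!is.null(ov) && poly_area(ov) > 1e-6)
          stop("parcels ", i, " and ", j, " overlap", call. = FALSE)
      }
    }
  }
  structure(list(window_id = window_id, extent = as.numeric(extent),
                 parcels = parcels, lines = lines),
            class = "lg_window")
}

#' @export
print.lg_window <- function(x, ...) {
  e <- x$extent
  cat("<lg_window> ", x$window_id, ": ",
      round((e[3] - e[1]) / 1000, 2), " x ", round((e[4] - e[2]) / 1000, 2),
      " km, ", nrow(x$parcels), " parcels, ", nrow(x$lines),
      " linear elements\n", sep = "")
  invisible(x)
}

#' @keywords internal
extent_poly <- function(window) {
  e <- window$extent
  rect_poly(e[1], e[2], e[3], e[4])
}

# ---- GeoJSON I/O -----------------------------------------------------------
# Minimal FeatureCollection dialect: Polygon features with properties
# class / green_fraction / crops ({year: crop}); LineString features with
# property class. Coordinates are projected metres, not lon/lat.

#' Write a landscape window to GeoJSON
#'
#' @param window An [landscape_window()] object.
#' @param path Output file path.
#' @export
write_landscape_geojson <- function(window, path) {
  feat_poly <- purrr::pmap(window$parcels, function(class, geometry, green_fraction, crops) {
    props <- list(class = class)
    if (!is.na(green_fraction)) props$green_fraction <- green_fraction
    if (!is.null(crops) && length(crops))
      props$crops <- as.list(crops)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(geometry) + 1L), function(i) {
                             k <- if (i > nrow(geometry)) 1L else i
                             as.numeric(geometry[k, ])
                           })))))
  })
  feat_line <- purrr::pmap(window$lines, function(class, geometry) {
    list(type = "Feature", properties = list(class = class),
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(geometry)),
                                  function(i) as.numeric(geometry[i, ])))))
  })
  fc <- list(type = "FeatureCollection", name = window$window_id,
             bbox = window$extent, features = c(feat_poly, feat_line))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape window from GeoJSON
#'
#' @param path GeoJSON file written by [write_landscape_geojson()] or any
#'   FeatureCollection using the same `class`/`green_fraction`/`crops`
#'   properties, with a `bbox` member giving the window extent.
#' @param window_id Window label; defaults to the collection `name`.
#' @return An `lg_window`.
#' @export
read_landscape_geojson <- function(path, window_id = NULL) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$bbox)) stop("GeoJSON is missing a bbox member", call. = FALSE)
  if (is.null(window_id)) window_id <- fc$name %||% "window"
  pr <- list(); ln <- list()
  for (f in fc$features) {
    gt <- f$geometry$type
    if (gt == "Polygon") {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(c2) as.numeric(unlist(c2))))
      if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      crops <- f$properties$crops
      crops <- if (is.null(crops)) NULL else {
        v <- vapply(crops, as.character, character(1))
        names(v) <- names(crops); v
      }
      pr[[length(pr) + 1L]] <- tibble::tibble(
        class = f$properties$class,
        green_fraction = f$properties$green_fraction %||% NA_real_,
        crops = list(crops), geometry = list(m))
    } else if (gt == "LineString") {
      m <- do.call(rbind, lapply(f$geometry$coordinates,
                                 function(c2) as.numeric(unlist(c2))))
      colnames(m) <- c("x", "y")
      ln[[length(ln) + 1L]] <- tibble::tibble(class = f$properties$class,
                                             geometry = list(m))
    }
  }
  parcels <- dplyr::bind_rows(pr)
  lines <- if (length(ln)) dplyr::bind_rows(ln) else NULL
  landscape_window(window_id, as.numeric(unlist(fc$bbox)), parcels, lines,
                   validate = FALSE)
}

#' Read population nodes from CSV
#'
#' @param path CSV with columns `window`, `population`, `x`, `y` (metres)
#'   and optionally `size` (flowering-shoot count).
#' @return Tibble of nodes.
#' @export
read_nodes_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
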