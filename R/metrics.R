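# Landscape composition/configuration metrics inside buffer and strip zones.
#
# All metrics use the zone's clipped geometry: percent cover is relative to
# the clipped zone area, relative lengths divide clipped polyline length by
# the clipped area in hectares.

#' @keywords internal
bbox_of <- function(m) c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))

#' @keywords internal
bbox_overlap <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

#' Crop-year weight of an arable parcel
#'
#' The weight of a crop in a parcel is the fraction of recorded years
#' (by default the decade 2008-2017) in which the parcel grew that crop, a
#' frequency notion of crop dominance. Parcels without crop records weigh 0
#' for every named crop and contribute to ARABLE cover only.
#'
#' @param crops Named character vector (year -> crop) or `NULL`.
#' @param crop One of `"RAPE"`, `"MAIZE"`, `"CEREAL"`.
#' @return Fraction in `[0, 1]`.
#' @export
crop_weight <- function(crops, crop) {
  if (is.null(crops) || length(crops) == 0) return(0)
  mean(crops == crop)
}

#' Percent cover of a land-use class in a zone
#'
#' @param zone An `lg_zone` from [make_buffer()] or [make_strip()].
#' @param window The [landscape_window()].
#' @param class An area class (see [AREA_CLASSES]) or a crop
#'   (`RAPE`/`MAIZE`/`CEREAL`); crop covers weight each arable parcel's
#'   area by its [crop_weight()].
#' @return Percent of the (clipped) zone area in `[0, 100]`.
#' @export
percent_cover <- function(zone, window, class) {
  if (zone$area_ha <= 0) stop("zone has zero area", call. = FALSE)
  is_crop <- class %in% CROP_CLASSES
  target <- if (is_crop) "ARABLE" else class
  zb <- bbox_of(zone$geometry)
  tot <- 0
  pr <- window$parcels
  for (i in seq_len(nrow(pr))) {
    if (pr$class[i] != target) next
    g <- pr$geometry[[i]]
    if (!bbox_overlap(bbox_of(g), zb)) next
    cl <- clip_poly_convex(g, zone$geometry)
    if (is.null(cl)) next
    w <- if (is_crop) crop_weight(pr$crops[[i]], class) else 1
    tot <- tot + w * poly_area(cl)
  }
  100 * tot / (zone$area_ha * 1e4)
}

#' Relative length of a linear-element class in a zone
#'
#' Total clipped polyline length divided by zone area.
#'
#' @inheritParams percent_cover
#' @param line_class One of [LINE_CLASSES].
#' @return Length density in m/ha.
#' @export
relative_length <- function(zone, window, line_class) {
  if (zone$area_ha <= 0) stop("zone has zero area", call. = FALSE)
  ln <- window$lines
  tot <- 0
  zb <- bbox_of(zone$geometry)
  for (i in seq_len(nrow(ln))) {
    if (ln$class[i] != line_class) next
    g <- ln$geometry[[i]]
    if (!bbox_overlap(bbox_of(g), zb)) next
    for (piece in clip_polyline_convex(g, zone$geometry))
      tot <- tot + polyline_length(piece)
  }
  tot / zone$area_ha
}

#' Parallel and orthogonal length components of linear elements
#'
#' Linear elements can channel or block dispersal-vector movement depending
#' on their orientation relative to the gene-dispersal direction. Each
#' polyline feature is clipped to the zone (each connected clipped piece is
#' treated as one feature). The reference direction is the strip's long
#' axis (strip zones) or the direction from the clipped feature's
#' arc-length midpoint to the population centre (buffer zones). Each
#' straight segment of length l at angle theta to the reference contributes
#' l|cos(theta)| to the parallel and l|sin(theta)| to the orthogonal total,
#' so per segment parallel^2 + orthogonal^2 = l^2.
#'
#' A buffer feature whose midpoint coincides with the population centre has
#' no defined reference direction and is counted as fully orthogonal (and
#' flagged via the `degenerate` attribute).
#'
#' @inheritParams relative_length
#' @return Named vector `c(parallel = , orthogonal = )` in metres, with an
#'   attribute `degenerate` counting features with undefined direction.
#' @export
orientation_components <- function(zone, window, line_class) {
  par_tot <- 0; orth_tot <- 0; degen <- 0L
  ln <- window$lines
  zb <- bbox_of(zone$geometry)
  for (i in seq_len(nrow(ln))) {
    if (ln$class[i] != line_class) next
    g <- ln$geometry[[i]]
    if (!bbox_overlap(bbox_of(g), zb)) next
    for (piece in clip_polyline_convex(g, zone$geometry)) {
      if (zone$kind == "strip") {
        u <- zone$axis
      } else {
        mid <- polyline_midpoint(piece)
        d <- zone$focus - mid
        nd <- sqrt(sum(d^2))
        if (nd < 1e-9) {
          orth_tot <- orth_tot + polyline_length(piece)
          degen <- degen + 1L
          next
        }
        u <- d / nd
      }
      seg <- piece[-1, , drop = FALSE] - piece[-nrow(piece), , drop = FALSE]
      par_tot <- par_tot + sum(abs(seg %*% u))
      orth_tot <- orth_tot + sum(abs(seg[, 1] * (-u[2]) + seg[, 2] * u[1]))
    }
  }
  structure(c(parallel = par_tot, orthogonal = orth_tot), degenerate = degen)
}

#' Orthogonal-to-parallel ratio
#'
#' `(orthogonal + c) / (parallel + c)` with a 1 m stabilizer so zones with
#' no element of the class still yield a finite, order-preserving value.
#'
#' @param parallel,orthogonal Length components in metres (>= 0).
#' @param c Stabilizer in metres (default 1).
#' @return Unitless positive ratio.
#' @export
op_ratio <- function(parallel, orthogonal, c = 1) {
  if (any(parallel < 0) || any(orthogonal < 0))
    stop("length components must be >= 0", call. = FALSE)
  (orthogonal + c) / (parallel + c)
}

#' Shannon diversity of land-use types in a zone
#'
#' Natural-log Shannon index over the area proportions of the eight
#' area-based classes present in the zone (crop types are not split out).
#'
#' @inheritParams percent_cover
#' @return Unitless index >= 0.
#' @export
shannon_diversity <- function(zone, window) {
  if (zone$area_ha <= 0) stop("zone has zero area", call. = FALSE)
  areas <- vapply(AREA_CLASSES, function(cl) percent_cover(zone, window, cl),
                  numeric(1))
  p <- areas[areas > 0]
  if (length(p) == 0) return(0)
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Land-use parcel edge density in a zone
#'
#' Total length of shared boundaries between parcels of *different*
#' land-use class inside the zone, divided by the zone area. The zone's own
#' outline and the window border are not parcel boundaries and are never
#' counted, so a uniform landscape scores 0.
#'
#' @inheritParams percent_cover
#' @return Edge density in m/ha.
#' @export
edge_density <- function(zone, window) {
  if (zone$area_ha <= 0) stop("zone has zero area", call. = FALSE)
  pr <- window$parcels
  np <- nrow(pr)
  if (np < 2) return(0)
  zb <- bbox_of(zone$geometry)
  keep <- vapply(seq_len(np), function(i)
    bbox_overlap(bbox_of(pr$geometry[[i]]), zb), logical(1))
  idx <- which(keep)
  edges <- lapply(idx, function(i) poly_edges(pr$geometry[[i]]))
  bb <- lapply(idx, function(i) bbox_of(pr$geometry[[i]]))
  tot <- 0
  if (length(idx) < 2) return(0)
  for (ii in seq_len(length(idx) - 1L)) for (jj in (ii + 1L):length(idx)) {
    if (pr$class[idx[ii]] == pr$class[idx[jj]]) next
    if (!bbox_overlap(bb[[ii]], bb[[jj]])) next
    e1 <- edges[[ii]]; e2 <- edges[[jj]]
    for (a in seq_len(nrow(e1))) for (b in seq_len(nrow(e2))) {
      ov <- collinear_overlap(rbind(e1[a, 1:2], e1[a, 3:4]),
                              rbind(e2[b, 1:2], e2[b, 3:4]))
      if (is.null(ov)) next
      tt <- clip_segment_convex(ov[1, ], ov[2, ], zone$geometry)
      if (is.null(tt)) next
      tot <- tot + (tt[2] - tt[1]) * sqrt(sum((ov[2, ] - ov[1, ])^2))
    }
  }
  tot / zone$area_ha
}

#' Proportion of green urban area in a zone (PROPGREEN)
#'
#' Area-weighted mean `green_fraction` of settlement parcels clipped to the
#' zone; 0 when the zone contains no settlement.
#'
#' @inheritParams percent_cover
#' @return Unitless fraction in `[0, 1]`.
#' @export
green_settlement_fraction <- function(zone, window) {
  pr <- window$parcels
  zb <- bbox_of(zone$geometry)
  a_tot <- 0; gw <- 0
  for (i in seq_len(nrow(pr))) {
    if (pr$class[i] != "SETTLE") next
    g <- pr$geometry[[i]]
    if (!bbox_overlap(bbox_of(g), zb)) next
    cl <- clip_poly_convex(g, zone$geometry)
    if (is.null(cl)) next
    a <- poly_area(cl)
    gf <- pr$green_fraction[i]
    if (is.na(gf)) gf <- 0
    a_tot <- a_tot + a
    gw <- gw + a * gf
  }
  if (a_tot == 0) 0 else gw / a_tot
}

# All Table-catalog metrics for one zone, as a named vector. Shared by the
# node- and link-level assemblers so both levels use identical definitions.
#' @keywords internal
zone_metrics <- function(zone, window) {
  covers <- vapply(c(AREA_CLASSES[AREA_CLASSES != "OTHER"], CROP_CLASSES),
                   function(cl) percent_cover(zone, window, cl), numeric(1))
  lens <- vapply(LINE_CLASSES, function(cl) relative_length(zone, window, cl),
                 numeric(1))
  ops <- vapply(LINE_CLASSES, function(cl) {
    po <- orientation_components(zone, window, cl)
    op_ratio(po[["parallel"]], po[["orthogonal"]])
  }, numeric(1))
  names(ops) <- paste0("OP_", LINE_CLASSES)
  c(covers, lens,
    SHANNON = shannon_diversity(zone, window),
    EDGEDEN = edge_density(zone, window),
    ops,
    PROPGREEN = green_settlement_fraction(zone, window))
}

#' Node-level landscape metric table
#'
#' Computes the full metric catalog (percent covers including crop splits,
#' relative lengths of linear elements, Shannon diversity, edge density)
#' plus conditioning variables (orthogonal-to-parallel ratios `OP_*`,
#' `PROPGREEN`) in buffers of every requested distance around every
#' population. Columns are named `METRIC_scale`, e.g. `FOREST_1000`.
#'
#' @param window An [landscape_window()].
#' @param nodes Tibble with columns `window`, `population`, `x`, `y`.
#' @param scales Buffer distances in metres.
#' @return Tibble with one row per population.
#' @export
compute_node_metrics <- function(window, nodes, scales = BUFFER_DISTANCES) {
  nodes <- dplyr::filter(nodes, .data$window == .env$window$window_id)
  rows <- purrr::pmap(list(nodes$population, nodes$x, nodes$y),
    function(pop, x, y) {
      vals <- purrr::map(scales, function(s) {
        z <- make_buffer(c(x, y), s, window)
        v <- zone_metrics(z, window)
        names(v) <- paste0(names(v), "_", s)
        v
      })
      tibble::as_tibble_row(c(list(window = window$window_id, population = pop),
                              as.list(unlist(vals))))
    })
  dplyr::bind_rows(rows)
}

#' Link-level landscape metric table
#'
#' Same metric catalog as [compute_node_metrics()], computed in rectangular
#' strips between every within-window population pair at every requested
#' width-to-length ratio. Columns are named `METRIC_ratio` with `:`
#' rendered as `to`, e.g. `FOREST_1to5`. A `distance_m` column holds the
#' centre-to-centre distance.
#'
#' @param window An [landscape_window()].
#' @param nodes Tibble with columns `window`, `population`, `x`, `y`.
#' @param ratios Strip width-to-length ratios (strings like `"1:7"`).
#' @return Tibble with one row per unordered within-window pair.
#' @export
compute_link_metrics <- function(window, nodes, ratios = STRIP_RATIOS) {
  nodes <- dplyr::filter(nodes, .data$window == .env$window$window_id)
  n <- nrow(nodes)
  if (n < 2) return(tibble::tibble())
  pairs <- utils::combn(seq_len(n), 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    c1 <- c(nodes$x[i], nodes$y[i]); c2 <- c(nodes$x[j], nodes$y[j])
    vals <- purrr::map(ratios, function(r) {
      z <- make_strip(c1, c2, r, window)
      v <- zone_metrics(z, window)
      names(v) <- paste0(names(v), "_", ratio_label(r))
      v
    })
    tibble::as_tibble_row(c(list(window = window$window_id,
                                 pop1 = nodes$population[i],
                                 pop2 = nodes$population[j],
                                 distance_m = sqrt(sum((c2 - c1)^2))),
                            as.list(unlist(vals))))
  })
  dplyr::bind_rows(rows)
}
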