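#' @name spatial
#' @title M2-centric spatial statistics
#' @description
#' Proximity statistics computed per core around a center phenotype
#' (M2 macrophages by default) within a fixed radius — 250 um by default,
#' the reported maximum distance for meaningful hematopoietic cell-cell
#' communication. Distances are Euclidean between centroids, in micrometres.
#' Neighbor search uses a grid-bucket index with bucket side equal to the
#' radius, so only the 3x3 neighborhood of a center's bucket is scanned; the
#' result is identical to an all-pairs scan.
NULL

# Grid-bucket fixed-radius neighbor query.
# Returns a list with integer vectors `center`, `target` and numeric `dist`
# for every (center, target) pair with Euclidean distance <= radius.
radius_query <- function(cx, cy, tx, ty, radius) {
  empty <- list(center = integer(0), target = integer(0), dist = numeric(0))
  if (length(cx) == 0L || length(tx) == 0L) return(empty)
  ox <- min(cx, tx); oy <- min(cy, ty)
  bxt <- floor((tx - ox) / radius); byt <- floor((ty - oy) / radius)
  buckets <- split(seq_along(tx), paste(bxt, byt, sep = ","))
  bxc <- floor((cx - ox) / radius); byc <- floor((cy - oy) / radius)
  out_c <- vector("list", length(cx))
  out_t <- vector("list", length(cx))
  out_d <- vector("list", length(cx))
  for (i in seq_along(cx)) {
    keys <- as.vector(outer(bxc[i] + (-1:1), byc[i] + (-1:1), paste, sep = ","))
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d <- sqrt((tx[cand] - cx[i])^2 + (ty[cand] - cy[i])^2)
    ok <- d <= radius
    if (!any(ok)) next
    out_c[[i]] <- rep.int(i, sum(ok))
    out_t[[i]] <- cand[ok]
    out_d[[i]] <- d[ok]
  }
  list(center = unlist(out_c, use.names = FALSE) %||% integer(0),
       target = unlist(out_t, use.names = FALSE) %||% integer(0),
       dist   = unlist(out_d, use.names = FALSE) %||% numeric(0))
}

subset_label <- function(cells, label) {
  cells[cells$phenotype %in% label, c("x_um", "y_um"), drop = FALSE]
}

#' Pairwise distances between two phenotypes within a radius
#'
#' All centroid distances between cells of `center_label` and cells of
#' `target_label` that are at most `radius` apart, within one core. When the
#' two labels coincide, unordered pairs are counted once and self-pairs are
#' excluded. Either label may be a vector of labels treated as one pooled
#' population (e.g. `c("mMDSC", "pMDSC")` for MDSC).
#'
#' @param cells labeled cell table for one core
#' @param center_label phenotype label(s) of the center population
#' @param target_label phenotype label(s) of the target population
#' @param radius maximum distance in micrometres (default 250)
#' @return numeric vector of distances (possibly empty)
#' @export
pair_distances <- function(cells, center_label, target_label, radius = 250) {
  stopifnot(radius > 0)
  if (!"phenotype" %in% names(cells))
    stop_osimc("cells carry no phenotype column")
  same <- setequal(center_label, target_label)
  ctr <- subset_label(cells, center_label)
  tgt <- if (same) ctr else subset_label(cells, target_label)
  q <- radius_query(ctr$x_um, ctr$y_um, tgt$x_um, tgt$y_um, radius)
  if (same) {
    keep <- q$center < q$target   # unordered once, self excluded
    q$dist[keep]
  } else {
    q$dist
  }
}

apply_missing_policy <- function(value, missing_policy, radius) {
  if (!is.na(value)) return(value)
  switch(missing_policy,
         missing = NA_real_,
         zero = 0,
         radius_cap = radius,
         stop_osimc("unknown missing_policy: ", missing_policy))
}

#' Median pair distance with an empty-neighborhood policy
#'
#' Median of [pair_distances()] over all qualifying pairs pooled within the
#' core. Cores with no qualifying pair get the `missing_policy` value:
#' `"missing"` (NA, excluded from downstream dichotomization — the default),
#' `"zero"`, or `"radius_cap"` (the radius).
#'
#' @inheritParams pair_distances
#' @param missing_policy one of `"missing"`, `"zero"`, `"radius_cap"`
#' @return a single distance in micrometres, or NA
#' @export
median_pair_distance <- function(cells, center_label, target_label,
                                 radius = 250,
                                 missing_policy = c("missing", "zero", "radius_cap")) {
  missing_policy <- match.arg(missing_policy)
  d <- pair_distances(cells, center_label, target_label, radius)
  v <- if (length(d) == 0L) NA_real_ else median(d)
  apply_missing_policy(v, missing_policy, radius)
}

#' Composite M2-IMSC proximity
#'
#' The arithmetic mean of the per-core median M2-M2, M2-MDSC and M2-Treg
#' distances, reflecting the average spatial proximity of immunosuppressive
#' cells to M2. If any component is missing the composite is missing.
#'
#' @param medians numeric vector of the three component medians
#' @return mean of the medians, or NA if any is NA
#' @export
composite_m2_imsc_distance <- function(medians) {
  stopifnot(length(medians) >= 1L)
  if (anyNA(medians)) return(NA_real_)
  mean(medians)
}

# Area of intersection of a disc (radius r, centered at distance d from the
# core center) with the core disc (radius R), in um^2. Standard lens formula.
lens_area <- function(d, r, R) {
  if (d >= r + R) return(0)
  if (d <= abs(R - r)) return(pi * min(r, R)^2)
  r2 <- r^2; R2 <- R^2
  a1 <- r2 * acos((d^2 + r2 - R2) / (2 * d * r))
  a2 <- R2 * acos((d^2 + R2 - r2) / (2 * d * R))
  a3 <- 0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
  a1 + a2 - a3
}

# Per-center counts of target cells within the radius (center cell itself
# excluded when it belongs to the target population).
neighbor_counts <- function(cells, center_label, target_label, radius = 250) {
  ctr_idx <- which(cells$phenotype %in% center_label)
  tgt_idx <- which(cells$phenotype %in% target_label)
  if (length(ctr_idx) == 0L) return(integer(0))
  q <- radius_query(cells$x_um[ctr_idx], cells$y_um[ctr_idx],
                    cells$x_um[tgt_idx], cells$y_um[tgt_idx], radius)
  self <- tgt_idx[q$target] == ctr_idx[q$center]
  tabulate(q$center[!self], nbins = length(ctr_idx))
}

#' Cell density around the center phenotype
#'
#' For each center (M2) cell, the number of target cells within the radius;
#' the per-core density is the median of these counts divided by the area of
#' the region, in cells per mm^2. By default the area is the full query disc
#' pi*r^2; with `clip_area = TRUE` it is the mean intersection area of the
#' query disc with the circular core, which removes the edge bias of centers
#' near the core boundary.
#'
#' @inheritParams pair_distances
#' @param clip_area clip the query disc to the core boundary?
#' @param core_center numeric length-2, core disc center in um (needed when
#'   `clip_area = TRUE`; default half the diameter in each axis)
#' @param core_diameter core diameter in um (default 1000)
#' @return density in cells/mm^2, or NA if the core has no center cell
#' @export
density_around <- function(cells, target_label, center_label = "M2",
                           radius = 250, clip_area = FALSE,
                           core_center = NULL, core_diameter = 1000) {
  counts <- neighbor_counts(cells, center_label, target_label, radius)
  if (length(counts) == 0L) return(NA_real_)
  if (clip_area) {
    if (is.null(core_center)) core_center <- rep(core_diameter / 2, 2)
    ctr <- subset_label(cells, center_label)
    d <- sqrt((ctr$x_um - core_center[1])^2 + (ctr$y_um - core_center[2])^2)
    area_um2 <- mean(vapply(d, lens_area, numeric(1), r = radius,
                            R = core_diameter / 2))
  } else {
    area_um2 <- pi * radius^2
  }
  median(counts) / (area_um2 / 1e6)
}

#' Summed IMSC counts around M2
#'
#' Sum over the constituent immunosuppressive populations (M2, pooled MDSC,
#' Treg) of the median per-M2 counts within the radius.
#'
#' @inheritParams density_around
#' @param target_sets named list of label vectors (default the IMSC
#'   constituents)
#' @return total median count, or NA if the core has no center cell
#' @export
imsc_count_sum <- function(cells, center_label = "M2", radius = 250,
                           target_sets = list(M2 = "M2",
                                              MDSC = c("mMDSC", "pMDSC"),
                                              Treg = "Treg")) {
  meds <- vapply(target_sets, function(tl) {
    counts <- neighbor_counts(cells, center_label, tl, radius)
    if (length(counts) == 0L) NA_real_ else median(counts)
  }, numeric(1))
  if (all(is.na(meds))) return(NA_real_)
  sum(meds, na.rm = TRUE)
}

#' Per-core spatial metric table
#'
#' Computes, for every core, the median pair distances from the center
#' phenotype to each target set, the composite M2-IMSC proximity (mean of
#' the three medians), the median-count densities, and the summed IMSC
#' count.
#'
#' @param cells labeled cell table (all cores)
#' @param radius radius in um (default 250)
#' @param center_label center phenotype (default `"M2"`)
#' @param target_sets named list of pooled target label sets
#' @param missing_policy empty-neighborhood policy for median distances
#' @param clip_area clip density areas to the core boundary?
#' @param core_diameter core diameter in um (used when `clip_area = TRUE`)
#' @return data.frame, one row per core: `dist_<name>` median distances,
#'   `dist_composite`, `density_<name>`, `imsc_count_sum`
#' @export
spatial_metrics <- function(cells, radius = 250, center_label = "M2",
                            target_sets = list(M2 = "M2",
                                               MDSC = c("mMDSC", "pMDSC"),
                                               Treg = "Treg"),
                            missing_policy = c("missing", "zero", "radius_cap"),
                            clip_area = FALSE, core_diameter = 1000) {
  missing_policy <- match.arg(missing_policy)
  cells <- validate_cell_table(cells)
  if (!"phenotype" %in% names(cells))
    stop_osimc("cells carry no phenotype column")
  rows <- lapply(split(cells, cells$core_id), function(cc) {
    meds <- vapply(target_sets, function(tl)
      median_pair_distance(cc, center_label, tl, radius, missing_policy),
      numeric(1))
    dens <- vapply(target_sets, function(tl)
      density_around(cc, tl, center_label, radius, clip_area,
                     core_diameter = core_diameter),
      numeric(1))
    out <- data.frame(core_id = cc$core_id[1L], stringsAsFactors = FALSE)
    for (nm in names(target_sets)) out[[paste0("dist_", nm)]] <- meds[[nm]]
    out$dist_composite <- composite_m2_imsc_distance(meds)
    for (nm in names(target_sets)) out[[paste0("density_", nm)]] <- dens[[nm]]
    out$imsc_count_sum <- imsc_count_sum(cc, center_label, radius, target_sets)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- res$core_id
  res
}
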