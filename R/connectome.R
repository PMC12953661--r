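# Connectome construction from streamlines, and lesion-based disconnection.
# Voxel convention: 0-based index = floor(mm / voxel_size); see sim_geometry.R.

point_to_voxel <- function(p, voxel_size, dims) {
  v <- floor(p / voxel_size)
  v <- pmin(pmax(v, 0), dims - 1L)   # clamp points on the outer boundary
  as.integer(v) + 1L                 # 1-based for R array access
}

#' Assign streamline endpoints to parcellation nodes
#'
#' Each endpoint maps to the node whose labeled voxel contains it; an
#' endpoint falling in background is assigned to the nearest labeled voxel
#' center within `search_radius_mm` (2 mm by default, the convention of
#' standard connectome builders). Streamlines with an unassignable endpoint,
#' or with both endpoints in the same node, are flagged excluded.
#'
#' @param tractogram a `tractogram`.
#' @param parcellation a `parcellation` on the same grid.
#' @param search_radius_mm nearest-voxel search radius (>= 0).
#' @return data.frame with one row per streamline: `node_a`, `node_b`
#'   (NA when unassigned), `excluded`, `reason`.
#' @export
assign_endpoints <- function(tractogram, parcellation, search_radius_mm = 2) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(parcellation, "parcellation"))
  if (search_radius_mm < 0) stop_config("search radius must be >= 0")
  lab <- parcellation$label_grid
  dims <- dim(lab)
  vs <- parcellation$voxel_size
  labeled <- which(lab > 0, arr.ind = TRUE)
  lab_vals <- lab[labeled]
  lab_ctr <- (labeled - 0.5) * vs

  locate <- function(p) {
    if (any(p < 0) || any(p >= dims * vs)) {
      # outside the grid entirely: only the radius search can rescue it
      v <- NA_integer_
    } else {
      v <- lab[matrix(point_to_voxel(p, vs, dims), 1)]
    }
    if (!is.na(v) && v > 0) return(v)
    if (search_radius_mm > 0 && nrow(lab_ctr) > 0) {
      d2 <- (lab_ctr[, 1] - p[1])^2 + (lab_ctr[, 2] - p[2])^2 +
        (lab_ctr[, 3] - p[3])^2
      i <- which.min(d2)
      if (d2[i] <= search_radius_mm^2) return(lab_vals[i])
    }
    NA_integer_
  }

  n <- length(tractogram$streamlines)
  node_a <- node_b <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    pts <- tractogram$streamlines[[s]]
    node_a[s] <- locate(pts[1, ])
    node_b[s] <- locate(pts[nrow(pts), ])
  }
  excluded <- is.na(node_a) | is.na(node_b) | (node_a == node_b)
  reason <- rep(NA_character_, n)
  reason[is.na(node_a) | is.na(node_b)] <- "unassigned_endpoint"
  reason[!is.na(node_a) & !is.na(node_b) & node_a == node_b] <- "self_loop"
  data.frame(node_a = node_a, node_b = node_b,
             excluded = excluded, reason = reason, stringsAsFactors = FALSE)
}

#' Build count and FA-weighted connectivity matrices
#'
#' @param assignments output of [assign_endpoints()] for the same tractogram.
#' @param tractogram the `tractogram` supplying per-streamline mean FA.
#' @param nodes node metadata table (from the parcellation).
#' @return object of class `connectome`: symmetric zero-diagonal `count` and
#'   `fa` matrices (FA entry = mean FA of connecting streamlines, 0 where no
#'   streamline) plus `nodes`.
#' @export
build_connectome <- function(assignments, tractogram, nodes) {
  stopifnot(nrow(assignments) == length(tractogram$streamlines))
  n <- max(nodes$node_id)
  cnt <- matrix(0, n, n)
  fasum <- matrix(0, n, n)
  keep <- which(!assignments$excluded)
  for (s in keep) {
    i <- assignments$node_a[s]; j <- assignments$node_b[s]
    cnt[i, j] <- cnt[i, j] + 1
    cnt[j, i] <- cnt[j, i] + 1
    fasum[i, j] <- fasum[i, j] + tractogram$fa[s]
    fasum[j, i] <- fasum[j, i] + tractogram$fa[s]
  }
  fa <- ifelse(cnt > 0, fasum / pmax(cnt, 1), 0)
  dimnames(cnt) <- dimnames(fa) <- list(nodes$node_id, nodes$node_id)
  structure(list(count = cnt, fa = fa, nodes = nodes), class = "connectome")
}

resample_polyline <- function(pts, step) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  L <- sum(seg)
  if (L == 0) return(pts[1, , drop = FALSE])
  at <- unique(c(seq(0, L, by = step), L))
  cum <- c(0, cumsum(seg))
  out <- matrix(0, length(at), 3)
  for (k in seq_along(at)) {
    i <- findInterval(at[k], cum, rightmost.closed = TRUE)
    i <- min(i, length(seg))
    t <- if (seg[i] > 0) (at[k] - cum[i]) / seg[i] else 0
    out[k, ] <- pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
  }
  out
}

#' Flag streamlines intersecting a lesion mask
#'
#' Polylines are resampled at half-voxel steps (bounded-error stand-in for
#' exact segment-voxel clipping); a streamline intersects iff any resampled
#' point falls in a lesion voxel.
#'
#' @param tractogram a `tractogram`.
#' @param lesion_mask a `lesion_mask` aligned to the parcellation grid.
#' @return logical vector, one entry per streamline.
#' @export
intersect_lesions <- function(tractogram, lesion_mask) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(lesion_mask, "lesion_mask"))
  dims <- dim(lesion_mask$mask)
  vs <- lesion_mask$voxel_size
  step <- vs / 2
  vapply(tractogram$streamlines, function(pts) {
    rp <- resample_polyline(pts, step)
    inside <- rp[, 1] >= 0 & rp[, 1] < dims[1] * vs &
      rp[, 2] >= 0 & rp[, 2] < dims[2] * vs &
      rp[, 3] >= 0 & rp[, 3] < dims[3] * vs
    rp <- rp[inside, , drop = FALSE]
    if (!nrow(rp)) return(FALSE)
    idx <- cbind(floor(rp[, 1] / vs), floor(rp[, 2] / vs),
                 floor(rp[, 3] / vs)) + 1L
    any(lesion_mask$mask[idx])
  }, logical(1))
}

classify_streamlines <- function(assignments, node_table) {
  hem <- setNames(node_table$hemisphere, node_table$node_id)
  sup <- setNames(node_table$supratentorial, node_table$node_id)
  a <- as.character(assignments$node_a); b <- as.character(assignments$node_b)
  cls <- rep(NA_character_, nrow(assignments))
  ok <- !assignments$excluded
  ha <- hem[a]; hb <- hem[b]
  inter <- ok & ((ha == "L" & hb == "R") | (ha == "R" & hb == "L"))
  intra <- ok & ha == hb & ha %in% c("L", "R") & sup[a] & sup[b]
  cls[inter] <- "inter"
  cls[intra] <- "intra"
  cls[ok & !inter & !intra] <- "other"
  cls
}

#' Lesion-based disconnection indices and hemispheric partition measures
#'
#' Splits assigned streamlines into supratentorial intra-hemispheric,
#' inter-hemispheric, and other (midline nodes or non-supratentorial
#' intra-hemispheric) classes; reports the percentage of lesioned
#' streamlines per class, the commissural ratio (inter-hemispheric over all
#' assigned streamlines), and a per-node-pair disconnectivity matrix.
#'
#' The source analysis does not state whether disconnection percentages use
#' class-specific or whole-tractogram denominators; both are implemented and
#' `denominator = "class"` is the default. A class with zero streamlines
#' yields a missing (NA) index, never 0.
#'
#' @param assignments output of [assign_endpoints()].
#' @param intersections logical vector from [intersect_lesions()].
#' @param node_table node metadata (node_id, hemisphere, supratentorial).
#' @param denominator `"class"` or `"total"`.
#' @return object of class `disconnection_result`.
#' @export
disconnection_indices <- function(assignments, intersections, node_table,
                                  denominator = c("class", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(assignments) == length(intersections))
  cls <- classify_streamlines(assignments, node_table)
  ok <- !assignments$excluded
  s_total <- sum(ok)
  tot <- c(intra = sum(cls == "intra", na.rm = TRUE),
           inter = sum(cls == "inter", na.rm = TRUE),
           other = sum(cls == "other", na.rm = TRUE))
  les <- c(intra = sum(cls == "intra" & intersections, na.rm = TRUE),
           inter = sum(cls == "inter" & intersections, na.rm = TRUE),
           other = sum(cls == "other" & intersections, na.rm = TRUE))
  pct <- function(class) {
    den <- if (denominator == "class") tot[[class]] else s_total
    if (den == 0) NA_real_ else 100 * les[[class]] / den
  }
  n <- max(node_table$node_id)
  dtot <- matrix(0, n, n); dles <- matrix(0, n, n)
  for (s in which(ok)) {
    i <- assignments$node_a[s]; j <- assignments$node_b[s]
    dtot[i, j] <- dtot[i, j] + 1; dtot[j, i] <- dtot[j, i] + 1
    if (intersections[s]) {
      dles[i, j] <- dles[i, j] + 1; dles[j, i] <- dles[j, i] + 1
    }
  }
  dmat <- ifelse(dtot > 0, dles / pmax(dtot, 1), 0)
  structure(list(
    s_total = s_total, class_totals = tot, class_lesioned = les,
    intra_disc_pct = pct("intra"), inter_disc_pct = pct("inter"),
    commissural_ratio = if (s_total == 0) NA_real_ else tot[["inter"]] / s_total,
    disconnectivity = dmat, denominator = denominator
  ), class = "disconnection_result")
}
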