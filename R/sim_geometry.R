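# Coordinate convention (shared with connectome_build): world coordinates in
# mm, grid origin at the corner, 0-based voxel index = floor(coord / voxel);
# voxel centers at (index + 0.5) * voxel.

#' Simulate a toy node parcellation
#'
#' Lays node label regions out on a lattice, half in each hemisphere (left =
#' x below the midsagittal plane). An odd remainder yields one midline (MID)
#' node straddling the plane. Nodes in the lower ~35% of the z-extent are
#' flagged infratentorial (cerebellum-like), the rest supratentorial.
#'
#' @param n_nodes number of nodes (>= 2); default mirrors the 253-node atlas.
#' @param grid_shape integer vector of voxel counts per axis.
#' @param voxel_size voxel edge length in mm.
#' @param seed unused (construction is deterministic); kept for API symmetry.
#' @return object of class `parcellation`: `label_grid` (integer array,
#'   0 = background), `voxel_size`, and `nodes` (node_id, hemisphere,
#'   supratentorial, centroid mm).
#' @export
simulate_parcellation <- function(n_nodes = 253L, grid_shape = c(48L, 48L, 48L),
                                  voxel_size = 1, seed = NULL) {
  if (n_nodes < 2L) stop_config("n_nodes must be >= 2")
  grid_shape <- as.integer(grid_shape)
  lab <- array(0L, dim = grid_shape)
  n_side <- n_nodes %/% 2L
  has_mid <- n_nodes %% 2L == 1L
  half_x <- grid_shape[1] %/% 2L

  lattice_dims <- function(n, ext) {
    # minimal (kx,ky,kz) with product >= n, roughly proportional to extents
    best <- NULL
    for (kx in 1:n) for (ky in 1:n) {
      kz <- ceiling(n / (kx * ky))
      if (kx * ky * kz >= n) {
        score <- max(kx / ext[1], ky / ext[2], kz / ext[3])
        if (is.null(best) || score < best$score)
          best <- list(k = c(kx, ky, kz), score = score)
      }
    }
    best$k
  }

  place_block <- function(x0, x1, y0, y1, z0, z1, id) {
    # label the central core of the block so regions stay disjoint
    cx <- max(x0 + 1L, x0 + (x1 - x0) %/% 4L):min(x1 - 1L, x1 - (x1 - x0) %/% 4L)
    cy <- max(y0 + 1L, y0 + (y1 - y0) %/% 4L):min(y1 - 1L, y1 - (y1 - y0) %/% 4L)
    cz <- max(z0 + 1L, z0 + (z1 - z0) %/% 4L):min(z1 - 1L, z1 - (z1 - z0) %/% 4L)
    if (!length(cx) || !length(cy) || !length(cz) ||
        min(cx) < 1 || max(cx) > grid_shape[1] ||
        min(cy) < 1 || max(cy) > grid_shape[2] ||
        min(cz) < 1 || max(cz) > grid_shape[3])
      stop_config("n_nodes exceeds grid capacity")
    lab[cx, cy, cz] <<- id
  }

  ids <- integer(0); hemi <- character(0)
  if (n_side > 0L) {
    k <- lattice_dims(n_side, c(half_x, grid_shape[2], grid_shape[3]))
    if (any(c(half_x, grid_shape[2], grid_shape[3]) %/% k < 3L))
      stop_config("n_nodes exceeds grid capacity")
    nid <- 0L
    for (side in c("L", "R")) {
      xoff <- if (side == "L") 0L else grid_shape[1] - half_x
      cnt <- 0L
      for (iz in seq_len(k[3])) for (iy in seq_len(k[2])) for (ix in seq_len(k[1])) {
        if (cnt >= n_side) break
        cnt <- cnt + 1L; nid <- nid + 1L
        bx <- half_x %/% k[1]; by <- grid_shape[2] %/% k[2]; bz <- grid_shape[3] %/% k[3]
        place_block(xoff + (ix - 1L) * bx + 1L, xoff + ix * bx,
                    (iy - 1L) * by + 1L, iy * by,
                    (iz - 1L) * bz + 1L, iz * bz, nid)
        ids <- c(ids, nid); hemi <- c(hemi, side)
      }
    }
  }
  if (has_mid) {
    nid <- n_nodes
    w <- max(2L, grid_shape[1] %/% 12L)
    place_block(half_x - w + 1L, half_x + w,
                grid_shape[2] %/% 3L, 2L * grid_shape[2] %/% 3L,
                grid_shape[3] %/% 3L, 2L * grid_shape[3] %/% 3L, nid)
    ids <- c(ids, nid); hemi <- c(hemi, "MID")
  }

  cent <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    (colMeans(w) - 0.5) * voxel_size
  }, numeric(3)))
  supra <- cent[, 3] >= 0.35 * grid_shape[3] * voxel_size
  nodes <- data.frame(node_id = ids, hemisphere = hemi,
                      supratentorial = supra,
                      cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node_id), ]
  rownames(nodes) <- NULL
  structure(list(label_grid = lab, voxel_size = voxel_size, nodes = nodes),
            class = "parcellation")
}

#' Simulate a toy tractogram over a parcellation
#'
#' Streamlines are 3-D polylines joining random points inside two distinct
#' node regions, with a vertical sinusoidal bow so they are not straight
#' lines; the x-coordinate is linear between endpoints, so a streamline
#' crosses the midsagittal plane iff its endpoints lie in opposite
#' hemispheres. Each streamline carries a Beta-distributed mean FA in (0,1].
#'
#' @param parcellation a [simulate_parcellation()] result.
#' @param n_streamlines count.
#' @param commissural_fraction target fraction of left-right streamlines.
#' @param fa_params `c(shape1, shape2)` of the Beta FA distribution.
#' @param seed integer seed.
#' @param step_mm approximate inter-point spacing.
#' @return object of class `tractogram`: `streamlines` (list of k x 3 mm
#'   matrices) and `fa` (numeric vector).
#' @export
simulate_tractogram <- function(parcellation, n_streamlines = 1000L,
                                commissural_fraction = 0.2,
                                fa_params = c(8, 4), seed = 1L,
                                step_mm = 1) {
  stopifnot(inherits(parcellation, "parcellation"))
  check_prob(commissural_fraction, "commissural_fraction")
  nodes <- parcellation$nodes
  left <- nodes$node_id[nodes$hemisphere == "L"]
  right <- nodes$node_id[nodes$hemisphere == "R"]
  if (commissural_fraction > 0 && (!length(left) || !length(right)))
    stop_data("unreachable node pairs: commissural streamlines need nodes in both hemispheres")
  vox_by_node <- lapply(seq_len(max(nodes$node_id)), function(i)
    which(parcellation$label_grid == i, arr.ind = TRUE))
  vs <- parcellation$voxel_size
  with_seed(seed, {
    sl <- vector("list", n_streamlines)
    fa <- pmax(stats::rbeta(n_streamlines, fa_params[1], fa_params[2]), 1e-3)
    pick <- function(v, k = 1L) v[sample.int(length(v), k)]
    for (s in seq_len(n_streamlines)) {
      comm <- runif(1) < commissural_fraction
      pair <- NULL
      for (try in 1:50) {
        if (comm) {
          pair <- c(pick(left), pick(right))
        } else {
          h <- if (length(left) >= 2 && length(right) >= 2)
            list(left, right)[[sample.int(2, 1)]]
          else if (length(left) >= 2) left else if (length(right) >= 2) right
          else NULL
          if (is.null(h)) break
          pair <- pick(h, 2L)
        }
        if (!is.null(pair) && pair[1] != pair[2]) break
        pair <- NULL
      }
      if (is.null(pair))
        stop_data("unreachable node pairs after max retries (",
                  "L=", length(left), ", R=", length(right), " nodes)")
      pt <- function(id) {
        vx <- vox_by_node[[id]]
        v <- vx[sample.int(nrow(vx), 1), ]
        (v - 0.5) * vs + runif(3, -0.4, 0.4) * vs
      }
      a <- pt(pair[1]); b <- pt(pair[2])
      len <- sqrt(sum((b - a)^2))
      k <- max(2L, ceiling(len / step_mm) + 1L)
      t <- seq(0, 1, length.out = k)
      pts <- cbind(a[1] + t * (b[1] - a[1]),
                   a[2] + t * (b[2] - a[2]),
                   a[3] + t * (b[3] - a[3]) + runif(1, 0, 1) * sin(pi * t))
      sl[[s]] <- pts
    }
    structure(list(streamlines = sl, fa = fa), class = "tractogram")
  })
}

#' Simulate a binary lesion mask
#'
#' Places spherical lesion foci biased toward the grid center (a crude
#' periventricular bias) until the achieved volume is within one
#' focus-volume of the target; volume is reported in mL.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_size_mm voxel edge length in mm.
#' @param target_lv_ml target lesion volume in mL (>= 0).
#' @param n_foci nominal number of foci.
#' @param seed integer seed.
#' @param concentration higher values concentrate foci toward the center.
#' @return object of class `lesion_mask`: `mask` (logical array),
#'   `voxel_size`, `lv_ml`.
#' @export
simulate_lesions <- function(grid_shape, voxel_size_mm = 1, target_lv_ml = 0,
                             n_foci = 3L, seed = 1L, concentration = 5) {
  grid_shape <- as.integer(grid_shape)
  if (target_lv_ml < 0) stop_config("target_lv_ml must be >= 0")
  grid_ml <- prod(grid_shape) * voxel_size_mm^3 / 1000
  if (target_lv_ml > grid_ml)
    stop_config("target LV ", target_lv_ml, " mL exceeds grid volume ",
                signif(grid_ml, 4), " mL")
  mask <- array(FALSE, dim = grid_shape)
  if (target_lv_ml > 0) {
    target_mm3 <- target_lv_ml * 1000
    focus_mm3 <- target_mm3 / n_foci
    r <- (3 * focus_mm3 / (4 * pi))^(1 / 3)
    ext <- grid_shape * voxel_size_mm
    ax <- (seq_len(grid_shape[1]) - 0.5) * voxel_size_mm
    ay <- (seq_len(grid_shape[2]) - 0.5) * voxel_size_mm
    az <- (seq_len(grid_shape[3]) - 0.5) * voxel_size_mm
    with_seed(seed, {
      placed <- 0L
      repeat {
        ctr <- pmin(pmax(ext / 2 + rnorm(3, 0, ext / (2 * concentration)), r),
                    ext - r)
        d2 <- outer(outer((ax - ctr[1])^2, (ay - ctr[2])^2, "+"),
                    (az - ctr[3])^2, "+")
        mask <- mask | (d2 <= r^2)
        placed <- placed + 1L
        ach <- sum(mask) * voxel_size_mm^3
        if (ach >= target_mm3 - focus_mm3 || placed >= n_foci + 50L) break
      }
    })
  }
  structure(list(mask = mask, voxel_size = voxel_size_mm,
                 lv_ml = sum(mask) * voxel_size_mm^3 / 1000),
            class = "lesion_mask")
}
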