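# Voxelized scenario geometry.
#
# Conventions (documented once, used everywhere):
#   * z is the longitudinal bone axis; the distal end is at z = 0 (fixed),
#     the proximal end at z = segment_length (loaded).
#   * +x is anterior, +y is medial (right-side convention).
#   * Cells are cubes of edge `voxel_size`; a cell belongs to a region by
#     its center.  Cells are indexed 0-based in (ix, iy, iz) and stored
#     column-major as id = 1 + ix + nx*(iy + ny*iz).
#   * Nodes live on the lattice corners, id = 1 + ix + (nx+1)*(iy + (ny+1)*iz).

cell_id <- function(ix, iy, iz, dims) {
  1L + ix + dims[1] * (iy + dims[2] * iz)
}

# 26-neighborhood dilation of a logical array
dilate26 <- function(a) {
  d <- dim(a)
  out <- a
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ii <- if (di == 0) seq_len(d[1]) else if (di > 0) c(1L, seq_len(d[1] - 1L)) else c(seq_len(d[1] - 1L) + 1L, d[1])
    jj <- if (dj == 0) seq_len(d[2]) else if (dj > 0) c(1L, seq_len(d[2] - 1L)) else c(seq_len(d[2] - 1L) + 1L, d[2])
    kk <- if (dk == 0) seq_len(d[3]) else if (dk > 0) c(1L, seq_len(d[3] - 1L)) else c(seq_len(d[3] - 1L) + 1L, d[3])
    out <- out | a[ii, jj, kk]
  }
  out
}

node_id <- function(ix, iy, iz, dims) {
  1L + ix + (dims[1] + 1L) * (iy + (dims[2] + 1L) * iz)
}

#' Cell center coordinates of a voxel model
#'
#' @param model A `voxel_model`.
#' @return An `ncell` x 3 matrix of (x, y, z) cell-center coordinates (mm).
#' @export
cell_centers <- function(model) {
  d <- model$dims; h <- model$spacing
  xs <- model$origin[1] + (seq_len(d[1]) - 0.5) * h
  ys <- model$origin[2] + (seq_len(d[2]) - 0.5) * h
  zs <- model$origin[3] + (seq_len(d[3]) - 0.5) * h
  cbind(x = rep(xs, times = d[2] * d[3]),
        y = rep(rep(ys, each = d[1]), times = d[3]),
        z = rep(zs, each = d[1] * d[2]))
}

#' Build a voxel model of an idealized fracture scenario
#'
#' Generates the labeled cell grid: hollow-cylinder cortex, intramedullary
#' nail, medullary (canal) soft tissue, the fracture gap of the requested
#' morphology separating fragment 0 (proximal) from fragment 1 (distal)
#' (plus fragment 2 for a wedge), and a callus annulus labeled
#' `healing_domain` spanning the gap plus an axial margin.  Quadrants are
#' assigned azimuthally about each slice centroid, and the load-application
#' patches and fixed distal base are precomputed.
#'
#' Fixation detail: within `lock_length` of either segment end the
#' nail-bone clearance is closed (interlocking bands; nail bonded to bone).
#' Elsewhere the clearance is occupied by at least one voxel layer of soft
#' medullary tissue, so interfragmentary movement is governed by the nail
#' spanning between the locking bands, as in a locked nail construct.
#' All interfaces share nodes (bonded); there is no contact mechanics.
#'
#' @param config A [scenario_config()].
#' @return An object of class `voxel_model`: a list with `dims`, `spacing`,
#'   `origin`, per-cell integer vectors `region`, `fragment`, `quadrant`,
#'   logical vectors `gap_cell` and `evolving`, the load patches, the fixed
#'   base nodes, and the originating `config`.
#' @export
build_scenario <- function(config) {
  validate_scenario_config(config)
  h <- config$voxel_size
  r_out <- config$outer_diameter / 2
  r_cal <- config$callus_diameter / 2
  r_nail <- config$nail_diameter / 2
  # the nail-bone clearance is resolved by at least one voxel of soft
  # medullary tissue wherever the nail is not interlocked
  r_canal <- if (r_nail > 0) max(config$canal_diameter / 2, r_nail + h) else
    config$canal_diameter / 2
  r_endo <- r_out - config$cortical_thickness  # endosteal radius

  nx <- as.integer(ceiling(config$callus_diameter / h))
  ny <- nx
  nz <- as.integer(max(3L, round(config$segment_length / h)))
  dims <- c(nx, ny, nz)
  origin <- c(-nx * h / 2, -ny * h / 2, 0)

  model <- structure(list(
    dims = dims, spacing = h, origin = origin,
    bone_type = config$bone_type, config = config
  ), class = "voxel_model")

  ctr <- cell_centers(model)
  x <- ctr[, 1]; y <- ctr[, 2]; z <- ctr[, 3]
  r <- sqrt(x^2 + y^2)
  zmid <- nz * h / 2

  # fracture-zone membership: soft interfragmentary cells and, for a wedge,
  # the interposed fragment
  gap_half <- config$gap_width / 2
  frag <- rep(-1L, length(x))
  in_zone <- rep(FALSE, length(x))  # axial fracture zone (soft + wedge)
  is_wedge_cell <- rep(FALSE, length(x))
  if (config$fracture_kind == "transverse") {
    # layer counting: round(gap/h) whole cell layers form the gap
    nlay <- round(config$gap_width / h)
    k0 <- floor(nz / 2 - nlay / 2)
    lay <- floor(z / h)
    in_zone <- lay >= k0 & lay < k0 + nlay
    above <- lay >= k0 + nlay
  } else if (config$fracture_kind == "oblique") {
    a <- tan(config$oblique_angle * pi / 180)
    zcut <- zmid + a * x
    in_zone <- abs(z - zcut) <= gap_half
    above <- z > zcut + gap_half
  } else { # wedge
    span_half <- config$wedge_span / 2 * pi / 180
    az0 <- config$wedge_azimuth * pi / 180
    dang <- atan2(y, x) - az0
    dang <- atan2(sin(dang), cos(dang))  # wrap to (-pi, pi]
    zone_half <- config$wedge_height / 2 + config$gap_width
    in_zone <- abs(z - zmid) <= zone_half
    above <- z > zmid + zone_half
    is_wedge_cell <- in_zone & abs(z - zmid) <= config$wedge_height / 2 &
      abs(dang) <= span_half & r <= r_out & r > r_endo
  }

  region <- rep(.REGION[["outside"]], length(x))
  inside_bone <- r <= r_out
  cortical <- inside_bone & r > r_endo
  cancellous <- r <= r_endo & r > r_canal
  canal <- r <= r_canal & r > r_nail
  nail <- r_nail > 0 & r <= r_nail

  region[cortical] <- .REGION[["cortical"]]
  region[cancellous] <- .REGION[["cancellous"]]
  region[canal] <- .REGION[["canal"]]
  region[nail] <- .REGION[["nail"]]

  # healing domain: fracture zone (all soft cells within the callus radius)
  # plus the callus annulus over the axial margin
  zone_z <- if (any(in_zone)) range(z[in_zone]) else c(zmid, zmid)
  span_lo <- zone_z[1] - config$axial_margin
  span_hi <- zone_z[2] + config$axial_margin
  in_span <- z >= span_lo - 1e-9 & z <= span_hi + 1e-9

  soft_zone <- in_zone & r <= r_cal & !nail & !is_wedge_cell
  periosteal <- !in_zone & in_span & r <= r_cal & r > r_out
  region[soft_zone] <- .REGION[["healing_domain"]]
  region[periosteal] <- .REGION[["healing_domain"]]

  # Nail interface: a smooth nail does not osseointegrate, and voxelization
  # can leave tissue cells sharing nodes (edges/corners) with nail cells
  # even across a thin clearance ring, which would couple them rigidly.
  # Every bone or healing cell touching the nail is therefore relabeled
  # canal (reamed endosteal margin / fibrous sliding interface), so outside
  # the interlocking bands the nail couples to tissue only through soft,
  # non-ossifying medullary tissue.
  if (any(nail)) {
    touch <- dilate26(array(region == .REGION[["nail"]], dims))
    conv <- as.vector(touch) & !is_wedge_cell &
      region %in% .REGION[c("cortical", "cancellous", "healing_domain")]
    region[conv] <- .REGION[["canal"]]
  }

  # fragment identities for bone cells (after all region conversions)
  bone <- region %in% .REGION[c("cortical", "cancellous")]
  frag[bone & !in_zone & above] <- 0L
  frag[bone & !in_zone & !above] <- 1L
  frag[is_wedge_cell & bone] <- 2L

  # interlocking bands: the clearance ring couples nail to bone through a
  # compliant locking interface (screws plus local bone), not rigidly
  lock <- (z <= config$lock_length | z >= nz * h - config$lock_length) &
    region == .REGION[["canal"]]

  gap_cell <- soft_zone & r <= r_out & region == .REGION[["healing_domain"]]
  evolving <- region == .REGION[["healing_domain"]] |
    (bone & in_span) | frag == 2L

  model$region <- as.integer(region)
  model$fragment <- frag
  model$lock_cell <- lock
  model$gap_cell <- gap_cell
  model$evolving <- evolving
  model$gap_zrange <- c(span_lo, span_hi)
  model$zone_zrange <- if (any(in_zone)) zone_z else c(zmid, zmid)

  model <- partition_quadrants(model)

  # fixed distal base: all nodes on z = 0 faces of active bottom-layer cells
  act <- model$region != .REGION[["outside"]]
  dim(act) <- dims
  base_cells <- which(act[, , 1], arr.ind = TRUE)
  bn <- integer(0)
  if (nrow(base_cells) > 0) {
    i0 <- base_cells[, 1] - 1L; j0 <- base_cells[, 2] - 1L
    bn <- unique(c(node_id(i0, j0, 0L, dims), node_id(i0 + 1L, j0, 0L, dims),
                   node_id(i0, j0 + 1L, 0L, dims),
                   node_id(i0 + 1L, j0 + 1L, 0L, dims)))
  }
  model$fixed_base <- sort(bn)
  model$fixed_base_mode <- "full"

  model$load_patches <- build_load_patches(model)
  model$cache <- new.env(parent = emptyenv())
  model
}

# Load patches: consistent nodal weights for uniform traction over the top
# faces of proximal bone cells.  Each top face spreads its tributary area
# equally over its four corner nodes.  The tibia splits the surface into a
# medial (y >= 0) and a lateral (y < 0) patch; the femur (and generic
# models) uses a single "axial" patch.
build_load_patches <- function(model) {
  dims <- model$dims; h <- model$spacing
  reg <- array(model$region, dims)
  nz <- dims[3]
  top <- which(matrix(reg[, , nz] %in% .REGION[c("cortical", "cancellous")],
                      dims[1], dims[2]), arr.ind = TRUE)
  if (nrow(top) == 0) return(list())
  i0 <- top[, 1] - 1L; j0 <- top[, 2] - 1L
  ys <- model$origin[2] + (top[, 2] - 0.5) * h
  corner <- cbind(node_id(i0, j0, nz, dims), node_id(i0 + 1L, j0, nz, dims),
                  node_id(i0, j0 + 1L, nz, dims),
                  node_id(i0 + 1L, j0 + 1L, nz, dims))
  mk <- function(faces) {
    if (length(faces) == 0) return(NULL)
    nd <- as.vector(corner[faces, , drop = FALSE])
    w <- tapply(rep(1 / 4, length(nd)), nd, sum)
    nodes <- as.integer(names(w))
    list(nodes = nodes, weights = as.numeric(w) / sum(w))
  }
  if (model$bone_type == "tibia") {
    med <- mk(which(ys >= 0)); lat <- mk(which(ys < 0))
    patches <- list(medial = med, lateral = lat)
    patches[!vapply(patches, is.null, logical(1))]
  } else {
    list(axial = mk(seq_len(nrow(top))))
  }
}

#' Assign anatomical quadrants to the labeled cells
#'
#' Partitions bone and healing-domain cells of every axial slice into four
#' 90-degree azimuthal sectors about the slice centroid, centered on +x
#' (anterior), +y (medial), -x (posterior) and -y (lateral).  Ties on a
#' sector boundary are broken toward anterior on the anterior boundaries
#' and toward medial/lateral on the posterior ones, which keeps the
#' partition exactly mirror-symmetric about the x-z plane.  Slices with no
#' labeled cells are skipped with a warning.
#'
#' @param model A `voxel_model`.
#' @return The model with its per-cell `quadrant` field (re)assigned.
#' @export
partition_quadrants <- function(model) {
  dims <- model$dims; h <- model$spacing
  ctr <- cell_centers(model)
  q <- rep(.QUADRANT[["none"]], prod(dims))
  labeled <- model$region %in% .REGION[c("cortical", "cancellous",
                                         "healing_domain")]
  iz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  degenerate <- 0L
  for (k in seq_len(dims[3])) {
    sel <- labeled & iz == k
    if (!any(sel)) { degenerate <- degenerate + 1L; next }
    cx <- mean(ctr[sel, 1]); cy <- mean(ctr[sel, 2])
    dx <- ctr[sel, 1] - cx; dy <- ctr[sel, 2] - cy
    # ties: toward anterior on the anterior boundaries, and toward
    # medial/lateral on the posterior ones (keeps the partition exactly
    # mirror-symmetric about the x-z plane)
    qk <- ifelse(dx >= abs(dy), .QUADRANT[["anterior"]],
          ifelse(-dx > abs(dy), .QUADRANT[["posterior"]],
          ifelse(dy > 0, .QUADRANT[["medial"]], .QUADRANT[["lateral"]])))
    q[sel] <- qk
  }
  if (degenerate > 0)
    warning(degenerate, " slice(s) without labeled cells skipped in quadrant partition")
  model$quadrant <- as.integer(q)
  model
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<voxel_model> %d x %d x %d cells @ %g mm (%s)\n",
              d[1], d[2], d[3], x$spacing, x$bone_type))
  tab <- table(factor(x$region, levels = .REGION, labels = names(.REGION)))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  fragments: %s; evolving cells: %d\n",
              paste(sort(unique(x$fragment[x$fragment >= 0])), collapse = ","),
              sum(x$evolving)))
  invisible(x)
}

#' Initial tissue composition and vascularity
#'
#' Cortical and cancellous bone starts as 100% lamellar, fully vascularized
#' tissue; the healing domain and all soft interfragmentary tissue start as
#' avascular fibrous connective tissue.  Medullary (canal) cells are soft,
#' vascularized tissue (marrow); they do not evolve but act as a vascular
#' source.  Nail and outside cells carry no tissue.
#'
#' @param model A `voxel_model`.
#' @param devascularize_fragment Optional fragment id whose bone cells start
#'   with vascularity 0 (default taken from the scenario config); models a
#'   surgically devascularized interposed fragment.
#' @return An object of class `tissue_state`: per-cell fractions `lamellar`,
#'   `woven`, `cartilage`, `fibrous`, plus `vascularity` and `day = 0`.
#' @export
initial_state <- function(model,
                          devascularize_fragment =
                            model$config$devascularize_fragment) {
  n <- prod(model$dims)
  zero <- numeric(n)
  st <- structure(list(
    day = 0L, lamellar = zero, woven = zero, cartilage = zero,
    fibrous = zero, vascularity = zero
  ), class = "tissue_state")
  bone <- model$region %in% .REGION[c("cortical", "cancellous")]
  soft <- model$region %in% .REGION[c("canal", "healing_domain")]
  st$lamellar[bone] <- 1
  st$vascularity[bone] <- 1
  st$fibrous[soft] <- 1
  st$vascularity[model$region == .REGION[["canal"]]] <- 1
  if (!is.null(devascularize_fragment)) {
    st$vascularity[model$fragment == devascularize_fragment] <- 0
  }
  st
}

#' @export
print.tissue_state <- function(x, ...) {
  evolv <- x$lamellar + x$woven + x$cartilage + x$fibrous > 0
  cat(sprintf("<tissue_state> day %d, %d tissue-bearing cells\n",
              x$day, sum(evolv)))
  cat(sprintf("  mean fractions: lam %.3f wov %.3f car %.3f fib %.3f; vasc %.3f\n",
              mean(x$lamellar[evolv]), mean(x$woven[evolv]),
              mean(x$cartilage[evolv]), mean(x$fibrous[evolv]),
              mean(x$vascularity[evolv])))
  invisible(x)
}
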