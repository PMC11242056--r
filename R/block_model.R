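# Minimal rectangular voxel models for verification problems (patch test,
# path-search oracles, toy dynamics).  Not part of the scenario generator;
# internal.

# A solid block of cortical bone, optionally with `mid_layers` middle cell
# layers labeled healing_domain separating fragment 0 (top) from fragment 1
# (bottom).  base mode "axial" leaves lateral contraction free (patch test);
# "full" clamps the base like the scenario models.
make_block_model <- function(nx, ny, nz, h = 1, mid_layers = 0L,
                             base_mode = "full") {
  dims <- c(as.integer(nx), as.integer(ny), as.integer(nz))
  model <- structure(list(
    dims = dims, spacing = h, origin = c(0, 0, 0),
    bone_type = "femur", config = NULL
  ), class = "voxel_model")
  ncell <- prod(dims)
  iz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  region <- rep(.REGION[["cortical"]], ncell)
  frag <- integer(ncell)
  k0 <- (dims[3] - mid_layers) %/% 2L
  mid <- iz > k0 & iz <= k0 + mid_layers
  region[mid] <- .REGION[["healing_domain"]]
  frag[mid] <- -1L
  frag[!mid & iz > k0] <- 0L
  frag[!mid & iz <= k0] <- 1L
  model$region <- region
  model$fragment <- frag
  model$quadrant <- rep(.QUADRANT[["anterior"]], ncell)
  model$gap_cell <- mid
  model$evolving <- mid
  model$gap_zrange <- c(k0 * h, (k0 + mid_layers) * h)

  i0 <- rep(0:(dims[1] - 1L), times = dims[2])
  j0 <- rep(0:(dims[2] - 1L), each = dims[1])
  model$fixed_base <- sort(unique(c(
    node_id(i0, j0, 0L, dims), node_id(i0 + 1L, j0, 0L, dims),
    node_id(i0, j0 + 1L, 0L, dims), node_id(i0 + 1L, j0 + 1L, 0L, dims))))
  model$fixed_base_mode <- base_mode
  model$load_patches <- build_load_patches(model)
  model$cache <- new.env(parent = emptyenv())
  model
}
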