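# Voxel hexahedral linear elasticity.
#
# Trilinear 8-node hexahedra on the cell lattice, 2x2x2 Gauss integration.
# For isotropic material the element stiffness separates as
#   ke = lambda * Kl + mu * Km
# with Kl, Km depending only on the voxel edge length, so daily reassembly
# reduces to one fused multiply-add over a precomputed sparse pattern.
# The reduced (free-DOF) system is SPD and solved with CHOLMOD; inside a
# simulation loop the previous factorization is reused as a preconditioner
# for conjugate-gradient refinement and refreshed only when convergence
# degrades (see solve_displacements).

# element geometry factors: Kl, Km (24 x 24) and the centroid strain
# operator B0 (6 x 24, engineering shear rows)
hex_parts <- function(h) {
  xi_n <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  et_n <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  ze_n <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  Bmat <- function(xi, et, ze) {
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      dNx <- 0.125 * xi_n[a] * (1 + et * et_n[a]) * (1 + ze * ze_n[a]) * 2 / h
      dNy <- 0.125 * (1 + xi * xi_n[a]) * et_n[a] * (1 + ze * ze_n[a]) * 2 / h
      dNz <- 0.125 * (1 + xi * xi_n[a]) * (1 + et * et_n[a]) * ze_n[a] * 2 / h
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dNx
      B[2, c0 + 2] <- dNy
      B[3, c0 + 3] <- dNz
      B[4, c0 + 1] <- dNy; B[4, c0 + 2] <- dNx
      B[5, c0 + 2] <- dNz; B[5, c0 + 3] <- dNy
      B[6, c0 + 1] <- dNz; B[6, c0 + 3] <- dNx
    }
    B
  }
  L <- matrix(0, 6, 6); L[1:3, 1:3] <- 1
  M <- diag(c(2, 2, 2, 1, 1, 1))
  Kl <- matrix(0, 24, 24); Km <- matrix(0, 24, 24)
  g <- 1 / sqrt(3); detJ <- (h / 2)^3
  for (xi in c(-g, g)) for (et in c(-g, g)) for (ze in c(-g, g)) {
    B <- Bmat(xi, et, ze)
    Kl <- Kl + crossprod(B, L %*% B) * detJ
    Km <- Km + crossprod(B, M %*% B) * detJ
  }
  list(Kl = Kl, Km = Km, B0 = Bmat(0, 0, 0))
}

# one-time mesh/DOF/pattern setup, cached on the model
fem_setup <- function(model) {
  cache <- model$cache
  if (!is.null(cache$fem)) return(cache$fem)
  dims <- model$dims; h <- model$spacing
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nn <- (nx + 1L) * (ny + 1L) * (nz + 1L)

  active_cells <- which(model$region != .REGION[["outside"]])
  nel <- length(active_cells)
  if (nel == 0) stop("model has no active cells")
  check_anchored(model)
  c0 <- active_cells - 1L
  ei <- c0 %% nx; ej <- (c0 %/% nx) %% ny; ek <- c0 %/% (nx * ny)
  loc <- cbind(c(0L,1L,1L,0L,0L,1L,1L,0L),
               c(0L,0L,1L,1L,0L,0L,1L,1L),
               c(0L,0L,0L,0L,1L,1L,1L,1L))
  conn <- matrix(0L, nel, 8)
  for (a in 1:8)
    conn[, a] <- node_id(ei + loc[a, 1], ej + loc[a, 2], ek + loc[a, 3], dims)
  edof <- matrix(0L, nel, 24)
  for (a in 1:8) {
    base <- 3L * (conn[, a] - 1L)
    edof[, 3L * (a - 1L) + 1L] <- base + 1L
    edof[, 3L * (a - 1L) + 2L] <- base + 2L
    edof[, 3L * (a - 1L) + 3L] <- base + 3L
  }

  active_nodes <- sort(unique(as.vector(conn)))
  all_dof <- as.vector(rbind(3L * (active_nodes - 1L) + 1L,
                             3L * (active_nodes - 1L) + 2L,
                             3L * (active_nodes - 1L) + 3L))
  fixed_dof <- fixed_dofs(model, active_nodes)
  free_dof <- setdiff(all_dof, fixed_dof)
  nfree <- length(free_dof)
  if (nfree == 0) stop("all degrees of freedom are fixed")
  freemap <- integer(3L * nn)
  freemap[free_dof] <- seq_len(nfree)

  # kept triplets: free x free, upper triangle in free numbering
  ii <- rep(seq_len(24), times = 24); jj <- rep(seq_len(24), each = 24)
  GI <- matrix(freemap[edof[, ii]], nel, 576)
  GJ <- matrix(freemap[edof[, jj]], nel, 576)
  keep <- GI > 0L & GJ > 0L & GI <= GJ
  trip_e <- row(keep)[keep] - 1L          # 0-based element index
  trip_k <- (col(keep)[keep] - 1L)        # 0-based entry in flattened ke
  ti <- GI[keep]; tj <- GJ[keep]
  rm(GI, GJ, keep)

  ord <- order(tj, ti)
  ti_s <- ti[ord]; tj_s <- tj[ord]
  new_entry <- c(TRUE, ti_s[-1] != ti_s[-length(ti_s)] |
                       tj_s[-1] != tj_s[-length(tj_s)])
  pos_sorted <- cumsum(new_entry)
  trip_pos <- integer(length(ti))
  trip_pos[ord] <- pos_sorted - 1L        # 0-based position in @x
  nnz <- pos_sorted[length(pos_sorted)]
  i_slot <- ti_s[new_entry] - 1L
  col_of <- tj_s[new_entry]
  p_slot <- c(0L, cumsum(tabulate(col_of, nbins = nfree)))

  hp <- hex_parts(h)
  fem <- list(
    active_cells = active_cells, conn = conn, edof = edof,
    active_nodes = active_nodes, fixed_dof = fixed_dof,
    free_dof = free_dof, nfree = nfree, freemap = freemap, nn = nn,
    trip_e = trip_e, trip_k = trip_k, trip_pos = trip_pos, nnz = nnz,
    i_slot = i_slot, p_slot = p_slot,
    Kl = as.vector(hp$Kl), Km = as.vector(hp$Km), B0 = hp$B0
  )
  cache$fem <- fem
  fem
}

# fixed DOFs at the distal base.  mode "full" clamps all components of the
# base nodes; mode "axial" fixes only uz plus a minimal 3-point lateral
# restraint (statically determinate: useful for patch tests where lateral
# contraction must remain free).
fixed_dofs <- function(model, active_nodes) {
  base <- intersect(model$fixed_base, active_nodes)
  if (length(base) == 0) stop("model has no fixed base nodes")
  mode <- if (is.null(model$fixed_base_mode)) "full" else model$fixed_base_mode
  if (mode == "full") {
    as.vector(rbind(3L * (base - 1L) + 1L, 3L * (base - 1L) + 2L,
                    3L * (base - 1L) + 3L))
  } else if (mode == "axial") {
    dims <- model$dims
    b0 <- base - 1L
    bi <- b0 %% (dims[1] + 1L); bj <- (b0 %/% (dims[1] + 1L)) %% (dims[2] + 1L)
    n1 <- base[order(bi, bj)][1]                       # pin: ux, uy
    n2 <- base[order(-bi, bj)][1]                      # pin: uy (stops rotation)
    fx <- c(3L * (base - 1L) + 3L, 3L * (n1 - 1L) + 1L, 3L * (n1 - 1L) + 2L)
    if (n2 != n1) fx <- c(fx, 3L * (n2 - 1L) + 2L)
    sort(unique(fx))
  } else stop("unknown fixed_base_mode: ", mode)
}

# assemble the reduced stiffness matrix for per-cell properties
assemble_stiffness <- function(model, props, fem = fem_setup(model)) {
  E <- props$E[fem$active_cells]
  nu <- props$nu[fem$active_cells]
  if (anyNA(E) || any(E <= 0)) stop("all active cells need a positive modulus")
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  x <- cpp_fill_stiffness(fem$Kl, fem$Km, lambda, mu,
                          fem$trip_e, fem$trip_k, fem$trip_pos, fem$nnz)
  new("dsCMatrix", uplo = "U", Dim = c(fem$nfree, fem$nfree),
      p = fem$p_slot, i = fem$i_slot, x = x)
}

# reduced load vector from the model's patches and a load case
assemble_loads <- function(model, loadcase, fem = fem_setup(model)) {
  f <- numeric(3L * fem$nn)
  for (nm in names(loadcase$patch_split)) {
    patch <- model$load_patches[[nm]]
    if (is.null(patch))
      stop("load case names patch '", nm, "' absent from the model")
    Fp <- loadcase$total_peak_force * loadcase$patch_split[[nm]]
    for (c in 1:3) {
      d <- 3L * (patch$nodes - 1L) + c
      f[d] <- f[d] + Fp * loadcase$direction[c] * patch$weights
    }
  }
  f[fem$free_dof]
}

#' Solve the daily elasticity problem on the voxel model
#'
#' Assembles the trilinear-hexahedron linear-elasticity system for the
#' given per-cell properties, with the distal base fully fixed and the
#' load-case forces distributed over the load patches by tributary-area
#' weights, and solves for the nodal displacements.
#'
#' By default a fresh sparse Cholesky factorization is computed.  When a
#' persistent `context` environment is supplied (as [simulate_healing()]
#' does), the most recent factorization is reused as the preconditioner of
#' a conjugate-gradient iteration warm-started from the previous day's
#' displacements, and is refreshed whenever convergence to `tol` is not
#' reached within `max_iter` iterations.  Either path satisfies the
#' discrete equilibrium residual `||K u - f|| / ||f|| <= tol`.
#'
#' @param model A `voxel_model`.
#' @param props Per-cell properties from [mixture_properties()].
#' @param loadcase A [load_case()].
#' @param tol Relative equilibrium residual tolerance (default 1e-8).
#' @param context Optional environment carrying solver state between calls.
#' @param max_iter CG iteration cap before the factorization is refreshed.
#' @return A list with `u` (nodes x 3 displacement matrix, mm; zero rows on
#'   unused nodes), `residual` (relative equilibrium residual) and
#'   `refactored` (logical).
#' @export
solve_displacements <- function(model, props, loadcase, tol = 1e-8,
                                context = NULL, max_iter = 30L) {
  fem <- fem_setup(model)
  K <- assemble_stiffness(model, props, fem)
  f <- assemble_loads(model, loadcase, fem)
  nf <- sqrt(sum(f^2))
  refactored <- FALSE

  factorize <- function(K) {
    tryCatch(
      Matrix::Cholesky(K, LDL = FALSE, perm = TRUE, super = TRUE),
      error = function(e) singular_system_diagnosis(model, e)
    )
  }

  if (nf == 0) {
    u_free <- numeric(fem$nfree)
    res <- 0
    if (!is.null(context)) context$u_free <- u_free
  } else if (is.null(context)) {
    ch <- factorize(K)
    u_free <- as.numeric(Matrix::solve(ch, f))
    res <- sqrt(sum((as.numeric(K %*% u_free) - f)^2)) / nf
    refactored <- TRUE
  } else {
    if (is.null(context$ch)) {
      context$ch <- factorize(K)
      refactored <- TRUE
    }
    x0 <- if (is.null(context$u_free)) numeric(fem$nfree) else context$u_free
    sol <- pcg_solve(K, f, context$ch, x0, tol, max_iter)
    if (sol$rel > tol) {
      context$ch <- Matrix::update(context$ch, K)
      refactored <- TRUE
      sol <- pcg_solve(K, f, context$ch, sol$x, tol, 5L)
    }
    u_free <- sol$x
    res <- sol$rel
    context$u_free <- u_free
  }
  if (nf > 0 && res > tol * 10)
    warning(sprintf("equilibrium residual %.2e exceeds tolerance %.1e", res, tol))

  u <- matrix(0, fem$nn, 3)
  u[cbind((fem$free_dof - 1L) %/% 3L + 1L, (fem$free_dof - 1L) %% 3L + 1L)] <-
    u_free
  list(u = u, residual = res, refactored = refactored)
}

# preconditioned conjugate gradients with a (possibly stale) Cholesky
# factorization as preconditioner
pcg_solve <- function(K, b, ch, x0, tol, maxit) {
  nb <- sqrt(sum(b^2))
  x <- x0
  r <- b - as.numeric(K %*% x)
  rel <- sqrt(sum(r^2)) / nb
  if (rel <= tol) return(list(x = x, rel = rel, iter = 0L))
  z <- as.numeric(Matrix::solve(ch, r))
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / nb
    if (rel <= tol) return(list(x = x, rel = rel, iter = it))
    z <- as.numeric(Matrix::solve(ch, r))
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  list(x = x, rel = rel, iter = maxit)
}

# every face-connected component of active cells must reach the fixed
# base, else the stiffness matrix is singular (floating fragment)
check_anchored <- function(model) {
  act <- model$region != .REGION[["outside"]]
  lab <- cpp_components(model$dims, act)
  dims <- model$dims
  base_cells <- which(act & rep(seq_len(dims[3]), each = dims[1] * dims[2]) == 1L)
  anchored <- unique(lab[base_cells])
  floating <- setdiff(unique(lab[lab > 0]), anchored)
  if (length(floating) > 0) {
    frags <- sort(unique(model$fragment[lab %in% floating & model$fragment >= 0]))
    stop("singular elasticity system: ", length(floating),
         " active component(s) not connected to the fixed base",
         if (length(frags) > 0)
           paste0(" (floating fragment id(s): ", paste(frags, collapse = ", "), ")"),
         call. = FALSE)
  }
  invisible(TRUE)
}

singular_system_diagnosis <- function(model, err) {
  check_anchored(model)
  stop("singular elasticity system: ", conditionMessage(err), call. = FALSE)
}

#' Strain field from a displacement solution
#'
#' Evaluates the small-strain tensor at every active cell centroid and
#' derives the two mechano-regulation stimuli: the dilatational strain
#' (volumetric trace, signed, negative in compression) and the distortional
#' strain (octahedral shear), computed from the principal-strain invariants
#' as `(2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)`.
#'
#' @param model A `voxel_model`.
#' @param u Nodal displacement matrix from [solve_displacements()].
#' @return An object of class `strain_field`: per-cell `eps` (ncell x 6,
#'   engineering shear components, zero on inactive cells), `distortional`
#'   and `dilatational` vectors.
#' @export
compute_strains <- function(model, u) {
  fem <- fem_setup(model)
  uv <- as.numeric(t(u))  # dof-ordered: (ux1, uy1, uz1, ux2, ...)
  eps_act <- cpp_cell_strains(fem$B0, uv, fem$edof)
  ncell <- prod(model$dims)
  eps <- matrix(0, ncell, 6)
  colnames(eps) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gzx")
  eps[fem$active_cells, ] <- eps_act
  dil <- eps[, 1] + eps[, 2] + eps[, 3]
  # invariants with tensor shear components e_ij = g_ij / 2:
  # (e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2 = 2 (I1^2 - 3 I2)
  exy <- eps[, 4] / 2; eyz <- eps[, 5] / 2; ezx <- eps[, 6] / 2
  I1 <- dil
  I2 <- eps[, 1] * eps[, 2] + eps[, 2] * eps[, 3] + eps[, 3] * eps[, 1] -
    exy^2 - eyz^2 - ezx^2
  dist <- (2 / 3) * sqrt(2 * pmax(0, I1^2 - 3 * I2))
  structure(list(eps = eps, distortional = dist, dilatational = dil),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  nz <- x$distortional != 0 | x$dilatational != 0
  cat(sprintf("<strain_field> %d cells with strain\n", sum(nz)))
  if (any(nz))
    cat(sprintf("  distortional max %.3e; dilatational range [%.3e, %.3e]\n",
                max(x$distortional), min(x$dilatational[nz]),
                max(x$dilatational[nz])))
  invisible(x)
}
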