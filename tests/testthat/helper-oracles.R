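# Independent reference implementations used as oracles.  These are kept
# deliberately naive (array dilation, explicit per-cell loops) so they share
# no code path with the package internals they check.

# flood-fill reachability by repeated 6-neighbor dilation on a logical array
oracle_bridged <- function(dims, pass, seeds, targets) {
  a <- array(pass, dims)
  reach <- array(FALSE, dims)
  reach[seeds] <- a[seeds]
  dilate <- function(r) {
    g <- r
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    g[-1, , ] <- g[-1, , ] | r[-nx, , ]
    g[-nx, , ] <- g[-nx, , ] | r[-1, , ]
    g[, -1, ] <- g[, -1, ] | r[, -ny, ]
    g[, -ny, ] <- g[, -ny, ] | r[, -1, ]
    g[, , -1] <- g[, , -1] | r[, , -nz]
    g[, , -nz] <- g[, , -nz] | r[, , -1]
    g & a
  }
  repeat {
    grown <- dilate(reach)
    if (identical(grown, reach)) break
    reach <- grown
  }
  any(reach[targets])
}

# a 12^3 toy model: fragment 1 in the bottom `nb` layers, fragment 0 in the
# top `nb` layers, healing domain in between; one quadrant
toy_bridge_model <- function(n = 12, nb = 4) {
  callusim:::make_block_model(n, n, n, h = 1, mid_layers = n - 2 * nb)
}

# random lamellar field on a toy model (bone stays lamellar 1); the random
# overall scale moves the pass density across the percolation regime so
# both bridged and unbridged fields occur
random_lamellar_state <- function(model) {
  st <- initial_state(model)
  mid <- model$region == 5L  # healing domain
  st$lamellar[mid] <- pmin(1, runif(sum(mid)) * runif(1, 0.55, 1.6))
  st
}

# Naive per-cell re-derivation of the daily update equations (fuzzify,
# vascularity, tissue transfers) for tiny grids.  Strains are taken as
# given; only the update equations are re-derived.
reference_day_update <- function(model, state, strains, rules) {
  dims <- model$dims
  ncell <- prod(dims)
  memb <- function(d) {
    ramp <- function(x, b) {
      w <- rules$shoulder * abs(b)
      if (x <= b - w / 2) 0 else if (x >= b + w / 2) 1 else (x - (b - w / 2)) / w
    }
    r <- c(ramp(d, rules$eta_min), ramp(d, rules$low_hi),
           ramp(d, rules$mid_hi), ramp(d, rules$destroy_hi))
    c(under = 1 - r[1], low = r[1] - r[2], mod = r[2] - r[3],
      high = r[3] - r[4], exc = r[4])
  }
  memb_comp <- function(v) {
    w <- rules$shoulder * abs(rules$compress_thresh)
    b <- rules$compress_thresh
    1 - (if (v <= b - w / 2) 0 else if (v >= b + w / 2) 1 else (v - (b - w / 2)) / w)
  }
  new_state <- state
  # vascularity first (as the package does), using the old vascularity
  vold <- state$vascularity
  for (c0 in which(model$evolving)) {
    i <- (c0 - 1) %% dims[1]
    j <- ((c0 - 1) %/% dims[1]) %% dims[2]
    k <- (c0 - 1) %/% (dims[1] * dims[2])
    nbv <- 0
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii >= 0 && jj >= 0 && kk >= 0 && ii < dims[1] && jj < dims[2] && kk < dims[3])
        nbv <- max(nbv, vold[1 + ii + dims[1] * (jj + dims[2] * kk)])
    }
    m <- memb(strains$distortional[c0])
    gain <- rules$v_rate / model$spacing * nbv * (1 - m[["exc"]])
    if (strains$distortional[c0] > rules$gamma_angio) gain <- 0
    new_state$vascularity[c0] <- min(1, vold[c0] + gain)
  }
  for (c0 in which(model$evolving)) {
    m <- memb(strains$distortional[c0])
    mc <- memb_comp(strains$dilatational[c0])
    gate <- as.numeric(new_state$vascularity[c0] >= rules$v_min)
    a1 <- min(m[["low"]], gate)
    a2 <- min(m[["mod"]], mc)
    a3 <- min(max(m[["low"]], m[["mod"]]), gate)
    a4 <- max(m[["low"]], m[["under"]])
    a5 <- m[["under"]]
    a6 <- m[["exc"]]
    lam <- state$lamellar[c0]; wov <- state$woven[c0]
    car <- state$cartilage[c0]; fib <- state$fibrous[c0]
    cf <- rules$k_woven * a1 + rules$k_chondro * a2
    sf <- if (cf > 1) 1 / cf else 1
    t_fw <- rules$k_woven * a1 * sf * fib
    t_fc <- rules$k_chondro * a2 * sf * fib
    cc <- rules$k_endo * a3 + rules$k_destroy * a6
    sc <- if (cc > 1) 1 / cc else 1
    t_cw <- rules$k_endo * a3 * sc * car
    t_cf <- rules$k_destroy * a6 * sc * car
    cw <- rules$k_remodel * a4 + rules$k_resorb * a5 + rules$k_destroy * a6
    sw <- if (cw > 1) 1 / cw else 1
    t_wl <- rules$k_remodel * a4 * sw * wov
    t_wf <- (rules$k_resorb * a5 + rules$k_destroy * a6) * sw * wov
    cl <- rules$k_resorb * a5 + rules$k_destroy * a6
    sl <- if (cl > 1) 1 / cl else 1
    t_lf <- cl * sl * lam
    new_state$fibrous[c0] <- fib - t_fw - t_fc + t_cf + t_wf + t_lf
    new_state$woven[c0] <- wov + t_fw + t_cw - t_wl - t_wf
    new_state$cartilage[c0] <- car + t_fc - t_cw - t_cf
    new_state$lamellar[c0] <- lam + t_wl - t_lf
  }
  new_state$day <- state$day + 1L
  new_state
}

# coarse configuration used for fast full-pipeline tests
coarse_tibia_config <- function(...) {
  tibia_shaft_config(voxel_size = 3, segment_length = 36, lock_length = 6, ...)
}
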