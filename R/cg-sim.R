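## Elastic + anchor + pressure forces on every vertex (n x 3) and the
## corresponding potential energy.  Pressure acts along +z with per-vertex
## force p_nn_um2 * area0 inside the pressure region.
cg_forces <- function(sys, press_force_z = NULL) {
  X <- sys$X
  e1 <- sys$edges[, 1L]; e2 <- sys$edges[, 2L]
  d <- X[e2, , drop = FALSE] - X[e1, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  k <- sys$config$spring_k
  t_e <- k * (len - sys$rest_len)
  u <- d / len
  fe <- u * t_e                      # force on e1 toward e2 when stretched
  idx <- c(e1, e2)
  contrib <- rbind(fe, -fe)
  Fv <- rowsum(contrib, idx)
  ## rowsum sorts groups; all vertices appear in >=1 edge on this mesh
  Fv <- Fv[order(as.integer(rownames(Fv))), , drop = FALSE]
  energy <- sum(0.5 * k * (len - sys$rest_len)^2)
  if (length(sys$anchors)) {
    ka <- sys$config$anchor_k
    dx <- X[sys$anchors, , drop = FALSE] - sys$X0[sys$anchors, , drop = FALSE]
    Fv[sys$anchors, ] <- Fv[sys$anchors, ] - ka * dx
    energy <- energy + 0.5 * ka * sum(dx^2)
  }
  if (!is.null(press_force_z)) {
    Fv[, 3L] <- Fv[, 3L] + press_force_z
    energy <- energy - sum(press_force_z * X[, 3L])
  }
  list(F = Fv, energy = energy)
}

#' Describe a mechanical load on the membrane system
#'
#' Either a prescribed ring displacement (indentation depth) or a target
#' indentation force, plus an aspiration pressure applied inside the ring.
#'
#' @param force_nN target total vertical reaction at the pipette ring (nN);
#'   solved for by bisecting the ring depth.  Mutually exclusive with
#'   `depth_um`.
#' @param depth_um prescribed downward ring displacement (um).
#' @param pressure_mbar aspiration pressure inside the ring (mbar),
#'   converted internally at 1 mbar = 0.1 nN/um^2 and applied as upward
#'   per-vertex normal forces (membrane pulled into the pipette).
#' @param pressure_radius_um radius of the pressurized region; defaults to
#'   the pipette ring radius.  (Setting it to the patch radius loads the
#'   whole patch uniformly, e.g. for small-deflection checks.)
#' @return a `load_state` list.
#' @export
load_state <- function(force_nN = NULL, depth_um = NULL, pressure_mbar = 0,
                       pressure_radius_um = NULL) {
  if (!is.null(force_nN) && !is.null(depth_um))
    stop("give either 'force_nN' or 'depth_um', not both", call. = FALSE)
  stopifnot_scalar(pressure_mbar, "pressure_mbar", nonneg = TRUE)
  structure(list(force_nN = force_nN, depth_um = depth_um,
                 pressure_mbar = pressure_mbar,
                 pressure_radius_um = pressure_radius_um,
                 converged = FALSE, residual = NA_real_,
                 reaction_nN = NA_real_),
            class = "load_state")
}

## Quasi-static relaxation: backtracking gradient descent on the energy.
## Fixed dofs: boundary (all), ring band (z only, when depth prescribed).
cg_relax <- function(sys, press_force_z, ring, depth_um, tol, max_iter) {
  n <- nrow(sys$X)
  fixed_all <- sys$boundary
  if (!is.null(depth_um)) sys$X[ring, 3L] <- -depth_um
  sys$X[fixed_all, ] <- sys$X0[fixed_all, ]
  fr <- cg_forces(sys, press_force_z)
  E <- fr$energy
  mask <- matrix(TRUE, n, 3L)
  mask[fixed_all, ] <- FALSE
  if (!is.null(depth_um)) mask[ring, 3L] <- FALSE
  step <- 0.1 / sys$config$spring_k
  energies <- E
  for (it in seq_len(max_iter)) {
    G <- fr$F * mask
    res <- max(abs(G))
    if (res < tol) break
    repeat {
      Xn <- sys$X + step * G
      sn <- sys; sn$X <- Xn
      frn <- cg_forces(sn, press_force_z)
      if (frn$energy <= E || step < 1e-12 / sys$config$spring_k) break
      step <- step / 2
    }
    sys$X <- Xn
    fr <- frn
    E <- frn$energy
    energies <- c(energies, E)
    step <- step * 1.1
  }
  G <- fr$F * mask
  sys$residual <- max(abs(G))
  sys$converged <- sys$residual < tol
  sys$energy_trace <- energies
  ## reaction: net vertical elastic+pressure force on the constrained ring
  sys$reaction_nN <- if (!is.null(depth_um)) sum(fr$F[ring, 3L]) else 0
  sys
}

#' Apply a mechanical load and relax to equilibrium
#'
#' The pipette ring band is displaced downward (displacement control, or
#' force control via bisection on the depth until the total vertical
#' reaction matches the target force); aspiration applies upward per-vertex
#' forces `p * A_vertex` inside the ring.  The system is relaxed by
#' damped (backtracking) gradient descent until the residual force on all
#' free degrees of freedom falls below `tol`.
#'
#' @param sys a `membrane_system` from [build_membrane_system()].
#' @param load a [load_state()].
#' @param tol residual force tolerance (nN), default 1e-4.
#' @param max_iter maximum relaxation iterations, default 20000.
#' @return the relaxed `membrane_system`, with `load` (including
#'   `converged`, `residual`, `reaction_nN`, solved `depth_um`) attached.
#' @export
apply_load <- function(sys, load, tol = 1e-4, max_iter = 20000) {
  stopifnot(inherits(sys, "membrane_system"), inherits(load, "load_state"))
  cfg <- sys$config
  ring <- which(abs(sys$r_xy - cfg$pipette_radius_um) <= cfg$pipette_wall_um)
  pr <- if (is.null(load$pressure_radius_um)) cfg$pipette_radius_um
        else load$pressure_radius_um
  press <- NULL
  if (load$pressure_mbar > 0) {
    inside <- sys$r_xy < pr & !(seq_len(nrow(sys$X)) %in% sys$boundary)
    press <- numeric(nrow(sys$X))
    press[inside] <- load$pressure_mbar * MBAR_TO_NN_PER_UM2 *
      sys$area0[inside]
  }
  if (!is.null(load$force_nN)) {
    if (!length(ring)) stop("no vertices in the pipette ring band",
                            call. = FALSE)
    ## secant iteration on depth; reaction is monotone in depth
    d1 <- 0; r1 <- 0
    d2 <- 0.1
    out <- cg_relax(sys, press, ring, d2, tol, max_iter)
    r2 <- out$reaction_nN
    for (i in seq_len(25L)) {
      if (abs(r2 - load$force_nN) < max(0.02 * abs(load$force_nN), tol))
        break
      slope <- (r2 - r1) / (d2 - d1)
      d_new <- d2 + (load$force_nN - r2) / slope
      d_new <- max(d_new, d2 / 4)
      d1 <- d2; r1 <- r2; d2 <- d_new
      warm <- sys; warm$X <- out$X
      out <- cg_relax(warm, press, ring, d2, tol, max_iter)
      r2 <- out$reaction_nN
    }
    load$depth_um <- d2
    load$reaction_nN <- r2
  } else {
    depth <- if (is.null(load$depth_um)) NULL else load$depth_um
    use_ring <- if (is.null(depth)) integer(0) else ring
    out <- cg_relax(sys, press, use_ring,
                    if (is.null(depth)) NULL else depth, tol, max_iter)
    load$reaction_nN <- out$reaction_nN
  }
  if (!out$converged)
    stop(sprintf("relaxation did not converge (residual %.3g nN)",
                 out$residual), call. = FALSE)
  load$converged <- out$converged
  load$residual <- out$residual
  out$load <- load
  out
}

#' Per-vertex local membrane tension
#'
#' 2D virial-style estimator: each edge's virial `t_e * l_e` is shared
#' half-and-half between its endpoint vertices, and the isotropic tension
#' is half the stress trace, so the vertex tension is
#' `sum(incident t_e * l_e) / (4 * vertex area)`; units nN/um = mN/m.
#' On a uniform triangular lattice at isotropic strain s this equals
#' `sqrt(3) * k * s / (1 + s)`, which is also the string tension governing
#' transverse deflections (checked against the clamped-disc solution
#' `w = p (R^2 - r^2) / (4 T0)`).
#'
#' @param sys a (relaxed) `membrane_system`.
#' @return numeric vector of per-vertex tensions.
#' @export
measure_tension <- function(sys) {
  X <- sys$X
  e1 <- sys$edges[, 1L]; e2 <- sys$edges[, 2L]
  len <- sqrt(rowSums((X[e2, , drop = FALSE] - X[e1, , drop = FALSE])^2))
  t_e <- sys$config$spring_k * (len - sys$rest_len)
  w <- t_e * len
  acc <- rowsum(c(w, w), c(e1, e2))
  s <- numeric(nrow(X))
  s[as.integer(rownames(acc))] <- acc[, 1L]
  A <- vertex_areas(X, sys$triangles, nrow(X))
  s / (4 * pmax(A, 1e-12))
}

#' Radial tension profile and confinement length
#'
#' Bins the tension change (relative to the resting tension) radially
#' outside the pipette ring; the confinement length is the distance beyond
#' the ring at which the mean tension change first falls below 10% of its
#' peak.  A flat profile (no measurable peak) is flagged as undefined.
#'
#' @param sys a relaxed `membrane_system`.
#' @param tension optional precomputed [measure_tension()] vector.
#' @param bin_um radial bin width (um), default the mesh edge length.
#' @param peak_frac confinement threshold as a fraction of the peak,
#'   default 0.1.
#' @return a `tension_profile`: list with `r_um` (bin centers, distance
#'   from pipette center), `delta_T` (nN/um), `peak_delta_T`,
#'   `confinement_um` (distance beyond the ring; NA when undefined),
#'   `confined` (logical), `far_field_frac`.
#' @export
tension_profile <- function(sys, tension = NULL, bin_um = NULL,
                            peak_frac = 0.1) {
  if (is.null(tension)) tension <- measure_tension(sys)
  cfg <- sys$config
  if (is.null(bin_um)) bin_um <- cfg$edge_len_um
  r <- sqrt(rowSums(sys$X[, 1:2, drop = FALSE]^2))
  outside <- r > cfg$pipette_radius_um + cfg$pipette_wall_um &
    r < cfg$patch_radius_um - 1.5 * cfg$edge_len_um
  dT <- tension - sys$resting_tension
  br <- seq(cfg$pipette_radius_um, cfg$patch_radius_um, by = bin_um)
  bin <- findInterval(r[outside], br)
  prof <- tapply(dT[outside], bin, mean)
  r_c <- br[as.integer(names(prof))] + bin_um / 2
  prof <- as.numeric(prof)
  peak <- max(prof)
  if (peak <= 1e-9 * max(abs(sys$resting_tension), 1)) {
    return(structure(list(r_um = r_c, delta_T = prof, peak_delta_T = peak,
                          confinement_um = NA_real_, confined = FALSE,
                          far_field_frac = NA_real_),
                     class = "tension_profile"))
  }
  below <- which(prof < peak_frac * peak & seq_along(prof) > which.max(prof))
  conf <- if (length(below)) r_c[below[1L]] - cfg$pipette_radius_um
          else NA_real_
  far <- mean(prof[r_c > max(r_c) - 2 * bin_um]) / peak
  structure(list(r_um = r_c, delta_T = prof, peak_delta_T = peak,
                 confinement_um = conf, confined = !is.na(conf),
                 far_field_frac = far),
            class = "tension_profile")
}
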