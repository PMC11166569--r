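#' Configuration for the coarse-grained membrane system
#'
#' A triangulated circular membrane patch of harmonic springs under
#' isotropic pre-tension, optionally tethered to the (static) cytoskeleton
#' by anchor springs, disturbed by a hollow cylindrical pipette of 1-um
#' ring radius.  This is a deliberately simplified desk-scale stand-in for
#' a full particle-based cell model: no explicit solvent, quasi-static
#' relaxation instead of dynamics, and cortex plus cytoskeleton collapsed
#' into anchor springs of tunable density and stiffness.
#'
#' @param patch_radius_um patch radius (um), default 3.
#' @param edge_len_um target mesh edge length (um), default 0.15 (the
#'   coarse preset; 0.05 gives the fine mesh at ~45k vertices).
#' @param spring_k edge spring constant (nN/um), default 2.
#' @param pre_strain isotropic pre-strain of the resting state (builds the
#'   resting membrane tension), default 0.01.
#' @param anchor_spacing_um mean nearest-anchor spacing (um); `NULL` or
#'   `Inf` disables anchors (bleb-like membrane).
#' @param anchor_k anchor spring constant (nN/um), default 5.
#' @param pipette_radius_um pipette ring radius (um), default 1.
#' @param pipette_wall_um ring band half-width (um), default half an edge.
#' @param jitter_frac random in-plane jitter of interior lattice points as
#'   a fraction of the edge length, default 0.
#' @param seed RNG seed (anchor placement, jitter).
#' @return an object of class `membrane_config`.
#' @export
membrane_config <- function(patch_radius_um = 3, edge_len_um = 0.15,
                            spring_k = 2, pre_strain = 0.01,
                            anchor_spacing_um = 0.5, anchor_k = 5,
                            pipette_radius_um = 1,
                            pipette_wall_um = edge_len_um / 2,
                            jitter_frac = 0, seed = NULL) {
  stopifnot_scalar(patch_radius_um, "patch_radius_um", positive = TRUE)
  stopifnot_scalar(edge_len_um, "edge_len_um", positive = TRUE)
  stopifnot_scalar(spring_k, "spring_k", positive = TRUE)
  stopifnot_scalar(pre_strain, "pre_strain", nonneg = TRUE)
  if (pipette_radius_um >= patch_radius_um)
    stop("pipette ring must lie inside the patch interior", call. = FALSE)
  structure(list(patch_radius_um = patch_radius_um,
                 edge_len_um = edge_len_um, spring_k = spring_k,
                 pre_strain = pre_strain,
                 anchor_spacing_um = anchor_spacing_um,
                 anchor_k = anchor_k,
                 pipette_radius_um = pipette_radius_um,
                 pipette_wall_um = pipette_wall_um,
                 jitter_frac = jitter_frac, seed = seed),
            class = "membrane_config")
}

## Triangular-lattice disc mesh.  Returns vertices (n x 2), edge index
## matrix (m x 2), and triangle index matrix.
triangular_disc_mesh <- function(R, L) {
  h <- L * sqrt(3) / 2
  jmax <- ceiling(R / h) + 1L
  imax <- ceiling(R / L) + 1L
  pts <- list(); key <- character(0)
  id <- new.env()
  verts <- NULL
  rows <- -jmax:jmax
  coords <- do.call(rbind, lapply(rows, function(j) {
    xs <- ((-imax):imax + 0.5 * (abs(j) %% 2)) * L
    cbind(x = xs, y = j * h, i = (-imax):imax, j = j)
  }))
  keep <- sqrt(coords[, "x"]^2 + coords[, "y"]^2) <= R + 1e-9
  coords <- coords[keep, , drop = FALSE]
  n <- nrow(coords)
  ## neighbor edges by distance cutoff within adjacent lattice rows
  ord <- order(coords[, "j"], coords[, "i"])
  coords <- coords[ord, , drop = FALSE]
  xy <- coords[, c("x", "y")]
  cut2 <- (1.3 * L)^2
  e1 <- integer(0); e2 <- integer(0)
  rowidx <- split(seq_len(n), coords[, "j"])
  jlev <- as.integer(names(rowidx))
  for (ri in seq_along(jlev)) {
    a <- rowidx[[ri]]
    ## same-row neighbors
    if (length(a) > 1L) {
      d2 <- (xy[a[-1L], 1L] - xy[a[-length(a)], 1L])^2
      ok <- d2 < cut2
      e1 <- c(e1, a[-length(a)][ok]); e2 <- c(e2, a[-1L][ok])
    }
    ## next-row neighbors
    ri2 <- which(jlev == jlev[ri] + 1L)
    if (length(ri2)) {
      b <- rowidx[[ri2]]
      for (v in a) {
        d2 <- (xy[b, 1L] - xy[v, 1L])^2 + (xy[b, 2L] - xy[v, 2L])^2
        w <- b[d2 < cut2]
        e1 <- c(e1, rep(v, length(w))); e2 <- c(e2, w)
      }
    }
  }
  edges <- cbind(e1, e2)
  ## triangles: for every edge, shared neighbors with larger index
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1L]]] <- c(adj[[edges[k, 1L]]], edges[k, 2L])
    adj[[edges[k, 2L]]] <- c(adj[[edges[k, 2L]]], edges[k, 1L])
  }
  tri <- list()
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > max(a, b)]
    if (length(common))
      tri[[length(tri) + 1L]] <- cbind(a, b, common)
  }
  tris <- if (length(tri)) do.call(rbind, tri) else
    matrix(integer(0), 0, 3)
  list(xy = xy, edges = edges, triangles = tris)
}

#' Build and relax the reference membrane system
#'
#' Constructs the triangulated disc, imposes the prescribed isotropic
#' pre-strain by shortening the spring rest lengths, places anchors with
#' the requested mean nearest-neighbor spacing, clamps the patch boundary,
#' and stores the (already force-balanced) flat reference state.
#'
#' @param cfg a [membrane_config()].
#' @return a `membrane_system`: list with `X` (n x 3 positions, um),
#'   `X0` (reference), `edges`, `rest_len`, `triangles`, `boundary`
#'   (clamped vertex ids), `anchors` (vertex ids), `area0` (reference
#'   per-vertex Voronoi-style areas, um^2), `r_xy` (radial position),
#'   `config`, `resting_tension` (nN/um).
#' @export
build_membrane_system <- function(cfg) {
  stopifnot(inherits(cfg, "membrane_config"))
  mesh <- triangular_disc_mesh(cfg$patch_radius_um, cfg$edge_len_um)
  n <- nrow(mesh$xy)
  with_seed(cfg$seed, {
    xy <- mesh$xy
    r <- sqrt(rowSums(xy^2))
    ## clamp the rim band plus any vertex with an incomplete neighborhood:
    ## the affine pre-strained state is then an exact equilibrium
    deg <- tabulate(c(mesh$edges), n)
    boundary <- which(r > cfg$patch_radius_um - 0.75 * cfg$edge_len_um |
                        deg < 6L)
    if (cfg$jitter_frac > 0) {
      interior <- setdiff(seq_len(n), boundary)
      xy[interior, ] <- xy[interior, ] +
        matrix(stats::rnorm(2 * length(interior),
                            sd = cfg$jitter_frac * cfg$edge_len_um),
               ncol = 2L)
    }
    X <- cbind(xy, z = 0)
    lens <- sqrt(rowSums((X[mesh$edges[, 2L], ] - X[mesh$edges[, 1L], ])^2))
    rest_len <- lens / (1 + cfg$pre_strain)
    anchors <- integer(0)
    if (!is.null(cfg$anchor_spacing_um) && is.finite(cfg$anchor_spacing_um)) {
      ## Poisson point process: mean NN distance 0.5/sqrt(lambda)
      lambda <- (0.5 / cfg$anchor_spacing_um)^2
      n_anchor <- max(1L, round(lambda * pi * cfg$patch_radius_um^2))
      anchors <- sample(setdiff(seq_len(n), boundary),
                        min(n_anchor, n - length(boundary)))
    }
    ## reference per-vertex area: incident triangle areas / 3
    area0 <- vertex_areas(X, mesh$triangles, n)
    sys <- structure(list(X = X, X0 = X, edges = mesh$edges,
                          rest_len = rest_len, triangles = mesh$triangles,
                          boundary = boundary, anchors = anchors,
                          area0 = area0, r_xy = r, config = cfg),
                     class = "membrane_system")
    sys$resting_tension <- mean(measure_tension(sys)[r < 0.8 * cfg$patch_radius_um])
    sys
  })
}

vertex_areas <- function(X, triangles, n) {
  A <- numeric(n)
  if (!nrow(triangles)) return(A)
  v1 <- X[triangles[, 2L], ] - X[triangles[, 1L], ]
  v2 <- X[triangles[, 3L], ] - X[triangles[, 1L], ]
  cx <- v1[, 2L] * v2[, 3L] - v1[, 3L] * v2[, 2L]
  cy <- v1[, 3L] * v2[, 1L] - v1[, 1L] * v2[, 3L]
  cz <- v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L]
  ta <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  for (c in 1:3) {
    acc <- rowsum(ta / 3, triangles[, c])
    A[as.integer(rownames(acc))] <- A[as.integer(rownames(acc))] + acc[, 1L]
  }
  A
}
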