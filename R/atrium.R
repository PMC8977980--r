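#' Atrial surface mesh container
#'
#' @param vertices n x 3 numeric matrix, mm
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @param voltage_mv optional per-vertex bipolar voltage, mV (NA = unobserved)
#' @param region optional per-vertex region label (factor over
#'   [region_levels()])
#' @param pv_ostia list of integer vertex loops (one per pulmonary vein)
#' @param laa_apex vertex index of the appendage apex landmark
#' @param laa_neck integer vertex loop around the appendage neck
#' @param mitral_rim integer vertex loop of the mitral ring
#' @param ablation_line list of integer vertex loops (WACPVI), or `NULL`
#' @param region_seeds named list of seed vertex indices for segmentation
#' @param cycle_length_ms optional per-vertex cycle length
#' @return an `atrium_mesh` object
#' @export
new_atrium_mesh <- function(vertices, faces, voltage_mv = NULL, region = NULL,
                            pv_ostia = list(), laa_apex = NULL,
                            laa_neck = NULL, mitral_rim = NULL,
                            ablation_line = NULL, region_seeds = NULL,
                            cycle_length_ms = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (!is.null(voltage_mv)) stopifnot(length(voltage_mv) == nrow(vertices))
  structure(list(vertices = vertices, faces = as.matrix(faces),
                 voltage_mv = voltage_mv, region = region,
                 pv_ostia = pv_ostia, laa_apex = laa_apex,
                 laa_neck = laa_neck, mitral_rim = mitral_rim,
                 ablation_line = ablation_line,
                 region_seeds = region_seeds,
                 cycle_length_ms = cycle_length_ms),
            class = "atrium_mesh")
}

#' @export
print.atrium_mesh <- function(x, ...) {
  cat("atrium_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces,",
      length(x$pv_ostia), "PV ostia",
      if (!is.null(x$voltage_mv)) "; voltage present" else "", "\n")
  invisible(x)
}

#' The nine left-atrial region labels
#' @return character vector of the 9 region names
#' @export
region_levels <- function() {
  c("LAA", "PV_antra", "posterior", "roof", "lateral",
    "septum", "anterior", "floor", "mitral")
}

# smoothstep ramp on [0,1]
.smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Generate a synthetic left-atrium shell with known ground truth
#'
#' Builds a closed triangulated ellipsoidal shell with four tubular pulmonary
#' vein (PV) stubs and one appendage (LAA) protrusion, a per-vertex bipolar
#' voltage field (a base value overridden inside fibrosis patches), planted
#' ground-truth region labels, PV ostium loops, a mitral-rim loop, landmark
#' seed vertices for segmentation, and (optionally) a closed WACPVI ablation
#' line encircling each PV pair.
#'
#' The anatomical frame is x = lateral(+)/septal(-), y = posterior(+)/
#' anterior(-), z = roof(+)/floor(-). The default shell is a 33-mm-radius
#' sphere (cavity volume ~150 cm3, typical of a persistent-AF left atrium);
#' `semi_axes_mm` allows ellipsoidal variants.
#'
#' @param n_vertices approximate vertex count (>= 500)
#' @param pv_count number of PV stubs (4)
#' @param laa include the appendage protrusion
#' @param fibrosis_patches list of `list(center = xyz, radius_mm, voltage_mv)`
#'   patches overriding the base voltage
#' @param base_voltage_mv healthy-tissue voltage (default 1.0)
#' @param ablation_line add a WACPVI line around each PV pair
#' @param semi_axes_mm ellipsoid semi-axes, mm
#' @param roughness_mm SD of radial surface roughness (default 0.15)
#' @param seed integer seed controlling the roughness draw
#' @return an `atrium_mesh` with planted `region` ground truth
#' @export
make_synthetic_atrium <- function(n_vertices = 900, pv_count = 4, laa = TRUE,
                                  fibrosis_patches = list(),
                                  base_voltage_mv = 1.0,
                                  ablation_line = TRUE,
                                  semi_axes_mm = c(33, 33, 33),
                                  roughness_mm = 0.15,
                                  seed = 1L) {
  if (n_vertices < 500) stop("n_vertices must be >= 500", call. = FALSE)
  if (pv_count != 4) stop("pv_count must be 4", call. = FALSE)
  if (base_voltage_mv < 0 ||
      any(vapply(fibrosis_patches, function(p) p$voltage_mv < 0, logical(1)))) {
    stop("invalid parameter: voltages must be non-negative", call. = FALSE)
  }

  # UV sphere grid sized to hit ~n_vertices
  n_phi <- max(10L, round(sqrt(n_vertices / 2)))
  n_theta <- 2L * n_phi
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  phi <- seq(0, pi, length.out = n_phi + 2L)[2:(n_phi + 1L)]
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(grid$phi) * cos(grid$theta),
                sin(grid$phi) * sin(grid$theta),
                cos(grid$phi))
  dirs <- rbind(c(0, 0, 1), dirs, c(0, 0, -1))   # poles first/last
  nv <- nrow(dirs)

  # anatomical feature directions (unit)
  # veins emerge left/right-laterally so a posterior wall remains between
  # the two antral pairs; ipsilateral veins share a merged antrum
  pv_dirs <- rbind(
    LSPV = c(0.72, 0.52, 0.45),
    LIPV = c(0.75, 0.57, -0.33),
    RSPV = c(-0.72, 0.52, 0.45),
    RIPV = c(-0.75, 0.57, -0.33))
  pv_dirs <- pv_dirs / sqrt(rowSums(pv_dirs^2))
  laa_dir <- c(0.72, -0.58, 0.38); laa_dir <- laa_dir / sqrt(sum(laa_dir^2))
  mitral_dir <- c(0, -0.45, -0.89); mitral_dir <- mitral_dir / sqrt(sum(mitral_dir^2))
  wall_dirs <- rbind(
    posterior = c(0, 1, 0.05),
    roof = c(0, 0.05, 1),
    lateral = c(1, 0.15, -0.05),
    septum = c(-1, -0.15, -0.05),
    anterior = c(0, -1, 0.15),
    floor = c(0.25, 0.35, -1))
  wall_dirs <- wall_dirs / sqrt(rowSums(wall_dirs^2))

  pv_cap <- 14 * pi / 180      # angular radius of each PV ostium
  laa_cap <- 22 * pi / 180
  pv_h <- 0.40                 # radial bump height fractions
  laa_h <- 0.50

  # angular distance of every vertex to each feature direction
  ang_to <- function(u) acos(pmin(1, pmax(-1, dirs %*% u)))
  pv_ang <- vapply(1:4, function(j) ang_to(pv_dirs[j, ]), numeric(nv))
  laa_ang <- as.vector(ang_to(laa_dir))
  mitral_ang <- as.vector(ang_to(mitral_dir))

  # radial bump factor for stubs/appendage
  bump <- rep(1, nv)
  for (j in 1:4) {
    bump <- bump + pv_h * .smoothstep(1 - pv_ang[, j] / pv_cap)
  }
  if (laa) bump <- bump + laa_h * .smoothstep(1 - laa_ang / laa_cap)

  radii <- sqrt(1 / ((dirs[, 1] / semi_axes_mm[1])^2 +
                       (dirs[, 2] / semi_axes_mm[2])^2 +
                       (dirs[, 3] / semi_axes_mm[3])^2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rough <- if (roughness_mm > 0) stats::rnorm(nv, 0, roughness_mm) else 0
  vertices <- dirs * (radii * bump + rough)

  # faces of the UV sphere (poles + grid strips)
  idx <- function(i_t, i_p) 1L + i_t + (i_p - 1L) * n_theta + 1L  # grid offset by top pole
  faces <- list()
  for (i_t in 0:(n_theta - 1L)) {
    nxt <- (i_t + 1L) %% n_theta
    faces[[length(faces) + 1L]] <- c(1L, idx(nxt, 1L), idx(i_t, 1L))
    faces[[length(faces) + 1L]] <- c(nv, idx(i_t, n_phi), idx(nxt, n_phi))
    for (i_p in 1:(n_phi - 1L)) {
      a <- idx(i_t, i_p); b <- idx(nxt, i_p)
      c2 <- idx(i_t, i_p + 1L); d <- idx(nxt, i_p + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(a, d, c2)
    }
  }
  faces <- do.call(rbind, faces)

  # planted ground-truth regions (construction frame); arc lengths use the
  # local radius so the 1-cm antral band is metric, not angular
  mean_r <- mean(radii)
  vnorm <- sqrt(rowSums(vertices^2))
  seed_ang <- cbind(ang_to(wall_dirs["posterior", ]),
                    ang_to(wall_dirs["roof", ]), ang_to(wall_dirs["lateral", ]),
                    ang_to(wall_dirs["septum", ]), ang_to(wall_dirs["anterior", ]),
                    ang_to(wall_dirs["floor", ]), mitral_ang)
  seed_names <- c("posterior", "roof", "lateral", "septum",
                  "anterior", "floor", "mitral")
  region <- seed_names[apply(seed_ang, 1L, which.min)]
  in_antra <- rep(FALSE, nv)
  for (j in 1:4) {
    band <- pmax(pv_ang[, j] - pv_cap, 0) * vnorm <= 10
    if (j == 1L) {
      # LAA ridge truncates the left-superior antrum: vertices nearer the
      # appendage neck than the LSPV ostium stay on the appendage side
      band <- band & !(pmax(laa_ang - laa_cap, 0) <
                         pmax(pv_ang[, j] - pv_cap, 0))
    }
    in_antra <- in_antra | band
  }
  region[in_antra] <- "PV_antra"
  region[laa_ang <= laa_cap] <- "LAA"       # the appendage itself
  region <- factor(region, levels = region_levels())

  # landmarks: ostium loops = cap-boundary vertices, apex/seed vertices
  one_ring <- .vertex_adjacency(faces, nv)
  pv_ostia <- lapply(1:4, function(j) {
    inside <- pv_ang[, j] <= pv_cap
    which(inside & vapply(seq_len(nv), function(v)
      any(!inside[one_ring[[v]]]), logical(1)))
  })
  names(pv_ostia) <- rownames(pv_dirs)
  mitral_cap <- 18 * pi / 180
  mitral_inside <- mitral_ang <= mitral_cap
  mitral_rim <- which(mitral_inside & vapply(seq_len(nv), function(v)
    any(!mitral_inside[one_ring[[v]]]), logical(1)))
  laa_apex <- which.min(laa_ang)
  laa_inside <- laa_ang <= laa_cap
  laa_neck <- which(laa_inside & vapply(seq_len(nv), function(v)
    any(!laa_inside[one_ring[[v]]]), logical(1)))
  region_seeds <- list(
    posterior = which.min(seed_ang[, 1L]),
    roof = which.min(seed_ang[, 2L]),
    lateral = which.min(seed_ang[, 3L]),
    septum = which.min(seed_ang[, 4L]),
    anterior = which.min(seed_ang[, 5L]),
    floor = which.min(seed_ang[, 6L]),
    mitral = which.min(mitral_ang))

  # voltage field
  voltage <- rep(base_voltage_mv, nv)
  for (p in fibrosis_patches) {
    d <- sqrt(colSums((t(vertices) - p$center)^2))
    voltage[d <= p$radius_mm] <- p$voltage_mv
  }

  # WACPVI: one closed line around each ipsilateral PV pair
  abl <- NULL
  if (ablation_line) {
    abl <- lapply(list(c(1L, 2L), c(3L, 4L)), function(pair) {
      axis <- colMeans(pv_dirs[pair, ])
      axis <- axis / sqrt(sum(axis^2))
      a <- as.vector(ang_to(axis))
      # encircle both ostia with a small margin
      lim <- max(vapply(pair, function(j)
        max(a[pv_ang[, j] <= pv_cap]), numeric(1))) + 4 / mean_r
      inside <- a <= lim
      which(inside & vapply(seq_len(nv), function(v)
        any(!inside[one_ring[[v]]]), logical(1)))
    })
    names(abl) <- c("left", "right")
  }

  new_atrium_mesh(vertices, faces, voltage_mv = voltage, region = region,
                  pv_ostia = pv_ostia, laa_apex = laa_apex,
                  laa_neck = laa_neck, mitral_rim = mitral_rim,
                  ablation_line = abl, region_seeds = region_seeds)
}

# list of 1-ring neighbor vertices
.vertex_adjacency <- function(faces, nv) {
  adj <- vector("list", nv)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  sp <- split(e[, 2L], e[, 1L])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- unique(sp[[nm]])
  adj
}

#' Per-vertex area weights (one third of incident triangle areas)
#'
#' @param mesh an `atrium_mesh`
#' @return numeric vertex areas, mm^2
#' @export
vertex_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], ] - v[f[, 1L], ]
  b <- v[f[, 3L], ] - v[f[, 1L], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nrow(v))
  for (k in 1:3) {
    t <- tapply(tri_area, f[, k], sum)
    w[as.integer(names(t))] <- w[as.integer(names(t))] + t / 3
  }
  w
}

#' Center a mesh at the origin
#'
#' Pre-alignment step before registration: translates the mesh so the vertex
#' centroid is exactly at (0, 0, 0).
#'
#' @param mesh an `atrium_mesh`
#' @return the centered mesh
#' @export
center_mesh <- function(mesh) {
  mesh$vertices <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  mesh
}
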