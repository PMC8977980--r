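#' Geodesic distance graph of a triangulated mesh
#'
#' Builds an igraph whose shortest paths approximate geodesic distances on
#' the surface: 1-ring edges plus 2-ring chords (Euclidean weights). The
#' chords reduce the anisotropy of the graph metric on smooth shells.
#'
#' @param mesh an `atrium_mesh`
#' @param second_ring add 2-ring chord edges (default TRUE)
#' @return an igraph with a `weight` edge attribute, mm
#' @export
mesh_graph <- function(mesh, second_ring = TRUE) {
  f <- mesh$faces
  v <- mesh$vertices
  nv <- nrow(v)
  e1 <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  e1 <- unique(t(apply(e1, 1L, sort)))
  edges <- e1
  if (second_ring) {
    adj <- .vertex_adjacency(f, nv)
    extra <- list()
    for (a in seq_len(nv)) {
      nb2 <- unique(unlist(adj[adj[[a]]]))
      nb2 <- nb2[nb2 > a & !(nb2 %in% adj[[a]])]
      if (length(nb2)) extra[[length(extra) + 1L]] <- cbind(a, nb2)
    }
    if (length(extra)) edges <- rbind(edges, do.call(rbind, extra))
  }
  w <- sqrt(rowSums((v[edges[, 1L], , drop = FALSE] -
                       v[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distances from a set of source vertices
#'
#' @param graph a [mesh_graph()]
#' @param sources integer vertex indices
#' @return numeric vector: per-vertex shortest-path distance to the nearest
#'   source, mm
#' @export
geodesic_from <- function(graph, sources) {
  d <- igraph::distances(graph, v = sources)
  apply(d, 2L, min)
}

#' Segment the left-atrial shell into its nine regions
#'
#' The appendage (LAA) is the surface enclosed by the neck loop. PV antra
#' are the vein surfaces enclosed by the ostium loops plus all vertices
#' within `antra_mm` geodesic distance of any ostium loop (the 1-cm antral
#' band), except that the left-superior antrum is truncated at the ridge
#' between the vein and the appendage: vertices geodesically closer to the
#' appendage neck than to the left-superior ostium stay on the appendage
#' side. All remaining vertices are assigned by a geodesic Voronoi
#' partition seeded at the seven wall/mitral landmarks; every vertex
#' receives exactly one label.
#'
#' @param mesh an `atrium_mesh` with `pv_ostia`, `laa_neck` and
#'   `region_seeds` landmarks
#' @param antra_mm antral band width, mm (default 10 = the 1-cm rule)
#' @param graph optional precomputed [mesh_graph()]
#' @return factor of region labels over [region_levels()]
#' @export
segment_regions <- function(mesh, antra_mm = 10, graph = NULL) {
  if (length(mesh$pv_ostia) == 0L) stop("segmentation error: missing landmark pv_ostia", call. = FALSE)
  if (is.null(mesh$laa_neck)) stop("segmentation error: missing landmark laa_neck", call. = FALSE)
  if (is.null(mesh$region_seeds)) stop("segmentation error: missing landmark region_seeds", call. = FALSE)
  need <- setdiff(c("posterior", "roof", "lateral", "septum",
                    "anterior", "floor", "mitral"), names(mesh$region_seeds))
  if (length(need)) {
    stop("segmentation error: missing landmark region_seeds for ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(graph)) graph <- mesh_graph(mesh)
  nv <- nrow(mesh$vertices)

  d_ost <- vapply(mesh$pv_ostia, function(loop)
    geodesic_from(graph, loop), numeric(nv))
  d_neck <- geodesic_from(graph, mesh$laa_neck)
  # enclosed surfaces: cutting the ostium/neck loops out of the 1-ring graph
  # separates vein and appendage interiors from the main shell
  g1 <- mesh_graph(mesh, second_ring = FALSE)
  enclosed_by <- function(loops) {
    loop_v <- unique(unlist(loops))
    comp <- igraph::components(igraph::delete_vertices(g1, loop_v))$membership
    keep <- setdiff(seq_len(nv), loop_v)
    main <- which.max(tabulate(comp))
    out <- rep(FALSE, nv)
    out[keep[comp != main]] <- TRUE
    out[loop_v] <- TRUE
    out
  }
  in_vein <- enclosed_by(mesh$pv_ostia)
  in_laa <- enclosed_by(list(mesh$laa_neck))
  in_antra <- in_vein
  for (j in seq_along(mesh$pv_ostia)) {
    band <- d_ost[, j] <= antra_mm
    is_lspv <- identical(names(mesh$pv_ostia)[j], "LSPV") ||
      (is.null(names(mesh$pv_ostia)) && j == 1L)
    if (is_lspv) {
      band <- band & !(d_neck < d_ost[, j])
    }
    in_antra <- in_antra | band
  }

  seeds <- unlist(mesh$region_seeds[c("posterior", "roof", "lateral",
                                      "septum", "anterior", "floor", "mitral")])
  d_seed <- vapply(seeds, function(s) geodesic_from(graph, s), numeric(nv))
  lab <- c("posterior", "roof", "lateral", "septum", "anterior",
           "floor", "mitral")[apply(d_seed, 1L, which.min)]
  lab[in_antra] <- "PV_antra"
  lab[in_laa] <- "LAA"
  factor(lab, levels = region_levels())
}

#' Classify driver sites against the WACPVI ablation line
#'
#' Geodesic point-in-region test: removing the closed ablation-line loops
#' from the surface graph splits the shell into components; the components
#' containing PV ostium vertices are the encircled (ablated) region. A site
#' is mapped to its nearest vertex; sites on the line itself count as inside
#' (boundary sites are presumed ablated).
#'
#' @param mesh an `atrium_mesh` with a closed `ablation_line`
#' @param site_positions n x 3 matrix of driver-site coordinates, mm
#' @return character vector `"inside"` / `"outside"`, one per site
#' @export
classify_driver_location <- function(mesh, site_positions) {
  if (is.null(mesh$ablation_line) || length(mesh$ablation_line) == 0L) {
    stop("classification error: no ablation line on this map", call. = FALSE)
  }
  site_positions <- matrix(as.numeric(site_positions), ncol = 3L)
  line_v <- unique(unlist(mesh$ablation_line))
  g <- mesh_graph(mesh, second_ring = FALSE)
  g_cut <- igraph::delete_vertices(g, line_v)
  keep <- setdiff(seq_len(nrow(mesh$vertices)), line_v)
  comp <- igraph::components(g_cut)$membership
  comp_of <- rep(NA_integer_, nrow(mesh$vertices))
  comp_of[keep] <- comp
  ost <- setdiff(unique(unlist(mesh$pv_ostia)), line_v)
  if (length(ost) == 0L) {
    stop("classification error: ablation line swallows all PV ostia", call. = FALSE)
  }
  inside_comps <- unique(comp_of[ost])
  # sanity: a line that does not separate the shell is not closed
  if (length(unique(comp)) < 2L) {
    stop("classification error: ablation line is not closed", call. = FALSE)
  }
  vapply(seq_len(nrow(site_positions)), function(i) {
    d <- colSums((t(mesh$vertices) - site_positions[i, ])^2)
    v <- which.min(d)
    if (v %in% line_v) "inside"
    else if (comp_of[v] %in% inside_comps) "inside"
    else "outside"
  }, character(1))
}

#' Patient-level RAc location class
#'
#' @param site_classes character vector from [classify_driver_location()]
#'   (length 0 = no rotational sites)
#' @return `"none"`, `"inside_only"` or `"outside"` (outside if any site is
#'   outside the line)
#' @export
rac_location_class <- function(site_classes) {
  if (length(site_classes) == 0L) return("none")
  if (any(site_classes == "outside")) "outside" else "inside_only"
}

#' Area-weighted voltage metrics of a mapped shell
#'
#' Vertex values are weighted by one third of the summed areas of their
#' incident triangles; fractions are strictly-below the thresholds, in
#' percent. Unobserved vertices (NA voltage) are excluded from numerator and
#' denominator.
#'
#' @param mesh an `atrium_mesh` with `voltage_mv`
#' @param thresholds_mv voltage thresholds, mV (defaults 0.5 / 0.35 / 0.1,
#'   the scar-surrogate cutoffs)
#' @return list `mean_voltage_mv`, `area_fraction_below` (named %, per
#'   threshold), `region_mean_mv` (named, if regions present),
#'   `observed_area_mm2`
#' @export
voltage_metrics <- function(mesh, thresholds_mv = c(0.5, 0.35, 0.1)) {
  if (is.null(mesh$voltage_mv) || all(is.na(mesh$voltage_mv))) {
    stop("undefined metric: no observed voltage on this mesh", call. = FALSE)
  }
  w <- vertex_areas(mesh)
  v <- mesh$voltage_mv
  obs <- !is.na(v)
  wt <- w[obs]; vt <- v[obs]
  frac <- vapply(thresholds_mv, function(th)
    100 * sum(wt[vt < th]) / sum(wt), numeric(1))
  names(frac) <- paste0("<", thresholds_mv, " mV")
  region_mean <- NULL
  if (!is.null(mesh$region)) {
    r <- mesh$region[obs]
    region_mean <- vapply(split(seq_along(vt), r), function(i)
      if (length(i)) sum(wt[i] * vt[i]) / sum(wt[i]) else NA_real_, numeric(1))
  }
  list(mean_voltage_mv = sum(wt * vt) / sum(wt),
       area_fraction_below = frac,
       region_mean_mv = region_mean,
       observed_area_mm2 = sum(wt))
}
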