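#' Write an acquisition bundle to disk
#'
#' One directory per bundle: `bundle.json` (map and patient identifiers plus
#' the acquisition list), and one subdirectory per acquisition containing
#' `geometry.json` (electrode positions, ring/spline/bipole maps),
#' `unipolar.csv` / `bipolar.csv` (one column per channel, header = channel
#' name) and `meta.json` (rate, duration, map position, ground truth if
#' any). Numeric values are serialized with full double precision.
#'
#' @param acquisitions list of `acquisition` objects (may be empty)
#' @param path target directory
#' @param map_id,patient_id identifiers stored in `bundle.json`
#' @param force overwrite an existing directory
#' @return `path`, invisibly
#' @export
write_acquisition_bundle <- function(acquisitions, path,
                                     map_id = "map1", patient_id = "patient1",
                                     force = FALSE) {
  if (dir.exists(path) && !force) {
    stop("refusing to overwrite existing directory ", path,
         " (use force = TRUE)", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  names_acq <- sprintf("acq_%03d", seq_along(acquisitions))
  jsonlite::write_json(
    list(map_id = map_id, patient_id = patient_id, acquisitions = names_acq),
    file.path(path, "bundle.json"), auto_unbox = TRUE)
  for (k in seq_along(acquisitions)) {
    a <- acquisitions[[k]]
    d <- file.path(path, names_acq[k])
    dir.create(d, showWarnings = FALSE)
    g <- a$geometry
    jsonlite::write_json(list(
      electrode_positions = unname(as.matrix(g$electrode_positions)),
      spline_index = g$spline_index, ring_index = g$ring_index,
      bipole_pairs = unname(g$bipole_pairs), bipole_ring = g$bipole_ring,
      ring_radii_mm = g$ring_radii_mm, deployment = g$deployment,
      channel_names = rownames(g$electrode_positions),
      bipole_names = rownames(g$bipole_pairs)),
      file.path(d, "geometry.json"), digits = NA, auto_unbox = TRUE)
    utils::write.csv(as.data.frame(a$unipolar), file.path(d, "unipolar.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(a$bipolar), file.path(d, "bipolar.csv"),
                     row.names = FALSE)
    gt <- a$ground_truth
    jsonlite::write_json(list(
      sampling_rate_hz = a$sampling_rate_hz, duration_s = a$duration_s,
      map_position = a$map_position,
      ground_truth = if (!is.null(gt)) list(
        pattern = gt$pattern, cycle_length_ms = gt$cycle_length_ms,
        n_beats = gt$n_beats, lat_table = gt$lat_table,
        source_position = gt$source_position, chirality = gt$chirality,
        jitter_sd_ms = gt$jitter_sd_ms, seed = gt$seed)),
      file.path(d, "meta.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read and validate an acquisition bundle
#'
#' Round-trips bundles written by [write_acquisition_bundle()]. Structure is
#' validated before anything is computed: required files, 20 unipolar and 15
#' bipolar channels matching the geometry, and finite samples (NaN/NA values
#' are reported with channel and sample index).
#'
#' @param path bundle directory
#' @return list of class `acquisition_bundle`: `acquisitions`, `map_id`,
#'   `patient_id`, `path`
#' @export
read_acquisition_bundle <- function(path) {
  need <- file.path(path, "bundle.json")
  if (!file.exists(need)) stop("missing input: ", need, call. = FALSE)
  meta <- jsonlite::read_json(need, simplifyVector = TRUE)
  acqs <- lapply(meta$acquisitions, function(nm) {
    d <- file.path(path, nm)
    for (f in c("geometry.json", "unipolar.csv", "bipolar.csv", "meta.json")) {
      if (!file.exists(file.path(d, f))) {
        stop("missing input: ", file.path(d, f), call. = FALSE)
      }
    }
    gj <- jsonlite::read_json(file.path(d, "geometry.json"),
                              simplifyVector = TRUE)
    geometry <- make_catheter_geometry(ring_radii_mm = gj$ring_radii_mm,
                                       deployment = gj$deployment)
    pos <- as.matrix(gj$electrode_positions)
    dimnames(pos) <- dimnames(geometry$electrode_positions)
    geometry$electrode_positions <- pos
    uni <- as.matrix(utils::read.csv(file.path(d, "unipolar.csv"),
                                     check.names = FALSE))
    bip <- as.matrix(utils::read.csv(file.path(d, "bipolar.csv"),
                                     check.names = FALSE))
    if (ncol(uni) != 20L) {
      stop("schema error in ", d, ": expected 20 unipolar channels, found ",
           ncol(uni), call. = FALSE)
    }
    if (ncol(bip) != nrow(geometry$bipole_pairs)) {
      stop("schema error in ", d, ": expected ", nrow(geometry$bipole_pairs),
           " bipolar channels, found ", ncol(bip), call. = FALSE)
    }
    bad <- which(!is.finite(uni), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("data error in ", d, ": non-finite sample at (channel ",
           bad[1L, 2L], ", sample ", bad[1L, 1L], ")",
           if (nrow(bad) > 1L) paste0(" and ", nrow(bad) - 1L, " more"),
           call. = FALSE)
    }
    am <- jsonlite::read_json(file.path(d, "meta.json"), simplifyVector = TRUE)
    if (abs(am$duration_s - nrow(uni) / am$sampling_rate_hz) > 1e-6) {
      stop("schema error in ", d, ": duration does not match sample count / rate",
           call. = FALSE)
    }
    gt <- NULL
    if (!is.null(am$ground_truth) && length(am$ground_truth)) {
      gt <- am$ground_truth
      gt$lat_table <- lapply(gt$lat_table, as.numeric)
      class(gt) <- "activation_field"
    }
    acq <- new_acquisition(uni, geometry, am$sampling_rate_hz,
                           map_position = am$map_position, ground_truth = gt)
    acq$bipolar <- bip   # keep the serialized values verbatim
    acq
  })
  structure(list(acquisitions = acqs, map_id = meta$map_id,
                 patient_id = meta$patient_id, path = path),
            class = "acquisition_bundle")
}

#' @export
print.acquisition_bundle <- function(x, ...) {
  cat("acquisition_bundle:", length(x$acquisitions), "acquisition(s), map",
      x$map_id, ", patient", x$patient_id, "\n")
  invisible(x)
}

#' Write an atrial mesh as ASCII PLY
#'
#' Per-vertex `voltage` (float, NaN for unobserved) and `region` (int, index
#' into [region_levels()], 0 for unlabeled) properties are stored alongside
#' the coordinates; landmarks (PV ostia, appendage apex, mitral rim,
#' ablation line, region seeds) are serialized in a header comment.
#'
#' @param mesh an `atrium_mesh`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  landmarks <- jsonlite::toJSON(list(
    pv_ostia = mesh$pv_ostia, laa_apex = mesh$laa_apex,
    laa_neck = mesh$laa_neck, mitral_rim = mesh$mitral_rim,
    ablation_line = mesh$ablation_line,
    region_seeds = mesh$region_seeds), auto_unbox = TRUE, null = "null")
  volt <- if (is.null(mesh$voltage_mv)) rep(NaN, nv) else mesh$voltage_mv
  volt[is.na(volt)] <- NaN
  reg <- if (is.null(mesh$region)) rep(0L, nv) else {
    r <- match(as.character(mesh$region), region_levels())
    r[is.na(r)] <- 0L
    r
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("comment afdm_landmarks", landmarks),
    paste("element vertex", nv),
    "property float x", "property float y", "property float z",
    "property float voltage", "property int region",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(paste(format(mesh$vertices[, 1L], digits = 10, trim = TRUE),
                   format(mesh$vertices[, 2L], digits = 10, trim = TRUE),
                   format(mesh$vertices[, 3L], digits = 10, trim = TRUE),
                   format(volt, digits = 10, trim = TRUE),
                   reg), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
  invisible(path)
}

#' Read an atrial mesh from ASCII PLY
#'
#' Accepts general ASCII PLY with at least x/y/z vertex properties; a
#' missing `voltage` property loads with voltage flagged absent (`NULL`).
#' Open or non-manifold shells load with a warning only (clinical shells may
#' be open at the valve).
#'
#' @param path PLY file
#' @return an `atrium_mesh`
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply") {
    stop("parse error at line 1: not a PLY file", call. = FALSE)
  }
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("parse error: no end_header", call. = FALSE)
  hdr <- lines[seq_len(hdr_end)]
  nv <- nf <- NULL
  vprops <- character(0)
  element <- ""
  landmarks <- NULL
  for (i in seq_along(hdr)) {
    tok <- strsplit(trimws(hdr[i]), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "format" && tok[2L] != "ascii") {
      stop("parse error at line ", i, ": only ascii PLY is supported", call. = FALSE)
    }
    if (tok[1L] == "comment" && length(tok) >= 2L &&
        tok[2L] == "afdm_landmarks") {
      landmarks <- jsonlite::fromJSON(sub("^\\s*comment afdm_landmarks ", "",
                                          hdr[i]), simplifyVector = TRUE)
    }
    if (tok[1L] == "element") {
      element <- tok[2L]
      if (element == "vertex") nv <- as.integer(tok[3L])
      if (element == "face") nf <- as.integer(tok[3L])
    }
    if (tok[1L] == "property" && element == "vertex" && tok[2L] != "list") {
      vprops <- c(vprops, tok[length(tok)])
    }
  }
  if (is.null(nv) || is.null(nf)) {
    stop("parse error: vertex/face element missing in header", call. = FALSE)
  }
  vlines <- lines[(hdr_end + 1L):(hdr_end + nv)]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  if (ncol(vdat) != length(vprops)) {
    stop("parse error at line ", hdr_end + 1L,
         ": vertex columns do not match declared properties", call. = FALSE)
  }
  colnames(vdat) <- vprops
  flines <- lines[(hdr_end + nv + 1L):(hdr_end + nv + nf)]
  fdat <- strsplit(trimws(flines), "\\s+")
  faces <- t(vapply(seq_along(fdat), function(k) {
    v <- as.integer(fdat[[k]])
    if (v[1L] != 3L) {
      stop("parse error at line ", hdr_end + nv + k,
           ": only triangular faces are supported", call. = FALSE)
    }
    v[2:4] + 1L
  }, integer(3)))
  voltage <- if ("voltage" %in% vprops) {
    v <- vdat[, "voltage"]
    v[is.nan(v)] <- NA_real_
    v
  } else NULL
  region <- if ("region" %in% vprops) {
    r <- as.integer(vdat[, "region"])
    factor(ifelse(r >= 1L, region_levels()[r], NA_character_),
           levels = region_levels())
  } else NULL
  # openness check: boundary edges appear in only one face
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  if (any(cnt != 2L)) warning("mesh shell is open or non-manifold")
  lm <- function(x) if (is.null(landmarks)) NULL else landmarks[[x]]
  new_atrium_mesh(vdat[, c("x", "y", "z")], faces,
                  voltage_mv = voltage, region = region,
                  pv_ostia = if (is.null(lm("pv_ostia"))) list() else
                    lapply(lm("pv_ostia"), as.integer),
                  laa_apex = lm("laa_apex"),
                  laa_neck = lm("laa_neck"),
                  mitral_rim = lm("mitral_rim"),
                  ablation_line = if (is.null(lm("ablation_line"))) NULL else
                    lapply(lm("ablation_line"), as.integer),
                  region_seeds = lm("region_seeds"))
}

#' Read / write a cohort table as CSV
#'
#' @param cohort a `cohort_table`
#' @param path CSV file
#' @return `read_cohort` returns a `cohort_table`; `write_cohort` the path
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("gender" %in% names(out)) {
    out$gender <- factor(out$gender, levels = c("men", "women"))
  }
  if ("rac_location_class" %in% names(out)) {
    out$rac_location_class <- factor(out$rac_location_class,
                                     levels = c("none", "inside_only",
                                                "outside"))
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Expand a per-class counts table into a patient-level table
#'
#' Worked-example helper: contingency counts (one row per RAc location
#' class with the number of patients and of recurrences) become one row per
#' patient so the cohort statistics run unchanged on printed tables.
#'
#' @param counts data.frame with `class`, `n`, `recurrence` columns
#' @return a minimal `cohort_table` with `rac_location_class`, `recurrence`
#' @export
counts_to_cohort <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    data.frame(
      rac_location_class = counts$class[i],
      recurrence = rep(c(TRUE, FALSE),
                       c(counts$recurrence[i],
                         counts$n[i] - counts$recurrence[i])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rac_location_class <- factor(out$rac_location_class,
                                   levels = c("none", "inside_only",
                                              "outside"))
  class(out) <- c("cohort_table", "data.frame")
  out
}
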