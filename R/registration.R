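#' Non-rigid ICP registration of an atrial mesh onto a reference shell
#'
#' Merges a patient mesh into the reference anatomy in two stages. First a
#' rigid alignment: when both meshes carry anatomical landmarks (PV ostium
#' centroids, appendage apex, mitral-rim centroid) the initial pose is the
#' Kabsch/SVD fit of the paired landmarks -- closest-point correspondences
#' alone observe rotation poorly on a near-spherical shell -- followed by
#' iterative-closest-point refinement (closest-point correspondences +
#' Kabsch update). Then a non-rigid refinement: at each stiffness level of
#' a decreasing schedule, symmetric closest-point correspondences are
#' recomputed -- each source vertex is pulled toward the average of its
#' forward nearest reference vertex and of the reference vertices that
#' claim it in reverse, which suppresses tangential sliding -- and a
#' per-vertex displacement field `D` is solved from
#'
#'   `(I + lambda * L'L) D = C - X`
#'
#' where `L` is the graph Laplacian of the source mesh, so the displacement
#' is smooth at high stiffness and tracks the target closely as stiffness
#' decreases. Iteration stops when the mean displacement change drops below
#' `tol_mm` or `max_iter` is reached.
#'
#' Both meshes must be centered (see [center_mesh()]).
#'
#' @param source,reference `atrium_mesh` objects, centered
#' @param stiffness_schedule decreasing positive stiffness values
#' @param max_iter correspondence iterations per stiffness level
#' @param tol_mm convergence tolerance on the mean vertex displacement change
#' @param rigid_iter iterations of the rigid pre-alignment
#' @return a `registration` object: `displacement` (n x 3, applied after the
#'   rigid pose), `correspondence` (source vertex -> reference vertex),
#'   `rigid` (list `R`, `t`), `rms_pre_mm`, `rms_post_mm`, `converged`,
#'   `stiffness_schedule`
#' @export
nonrigid_icp <- function(source, reference,
                         stiffness_schedule = c(50, 20, 8, 3, 1, 0.3),
                         max_iter = 20L, tol_mm = 1e-3,
                         rigid_iter = 30L) {
  if (any(diff(stiffness_schedule) >= 0) || any(stiffness_schedule <= 0)) {
    stop("stiffness_schedule must be positive and strictly decreasing", call. = FALSE)
  }
  X0 <- source$vertices
  Y <- reference$vertices
  n <- nrow(X0)

  rms_pre <- .nn_rms(X0, Y)

  kabsch <- function(A, B) {
    ma <- colMeans(A); mb <- colMeans(B)
    S <- crossprod(sweep(A, 2, ma), sweep(B, 2, mb))
    sv <- svd(S)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    list(R = R, t = mb - as.vector(R %*% ma))
  }

  # rigid ICP refinement (Kabsch on closest-point correspondences) from a
  # given initial pose
  refine <- function(R0, t0) {
    X <- sweep(X0 %*% t(R0), 2, t0, `+`)
    R <- R0; tvec <- t0
    for (it in seq_len(rigid_iter)) {
      nn <- .nn_index(X, Y)
      k <- kabsch(X0, Y[nn, , drop = FALSE])
      Xn <- sweep(X0 %*% t(k$R), 2, k$t, `+`)
      done <- max(abs(Xn - X)) < tol_mm
      X <- Xn; R <- k$R; tvec <- k$t
      if (done) break
    }
    list(R = R, t = tvec, X = X, rms = .nn_rms(X, Y))
  }

  # candidate poses: identity-initialized and landmark-initialized ICP
  lms <- .registration_landmarks(source)
  lmr <- .registration_landmarks(reference)
  have_lm <- !is.null(lms) && !is.null(lmr) && nrow(lms) == nrow(lmr)
  cand <- list(refine(diag(3), c(0, 0, 0)))
  if (have_lm) {
    k <- kabsch(lms, lmr)
    cand[[2L]] <- refine(k$R, k$t)
  }
  # a pure deformation can mislead the landmark pose: keep identity unless
  # the landmark-initialized pose fits the surface clearly better
  best <- if (length(cand) == 2L && cand[[2L]]$rms < 0.95 * cand[[1L]]$rms) {
    cand[[2L]]
  } else cand[[1L]]
  R <- best$R; tvec <- best$t
  Xr <- best$X                             # rigidly aligned source

  # anatomical point anchors for the non-rigid stage: appendage apex and
  # the seven region seed vertices, pinned to their reference counterparts
  anchor_src <- .anchor_vertices(source)
  anchor_tgt_v <- .anchor_vertices(reference)
  have_anchors <- length(anchor_src) > 0 &&
    length(anchor_src) == length(anchor_tgt_v)

  # graph Laplacian of the source mesh (umbrella weights)
  adj <- .vertex_adjacency(source$faces, n)
  ii <- rep(seq_len(n), lengths(adj))
  jj <- unlist(adj)
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(rep(-1, length(ii)), lengths(adj)),
                            dims = c(n, n))
  LtL <- Matrix::crossprod(L)
  I_n <- Matrix::Diagonal(n)

  wts <- rep(1, n)
  if (have_anchors) wts[anchor_src] <- 30
  Wd <- Matrix::Diagonal(n, wts)
  D <- matrix(0, n, 3)
  converged <- TRUE
  for (lambda in stiffness_schedule) {
    A <- Wd + lambda * LtL
    level_converged <- FALSE
    for (it in seq_len(max_iter)) {
      X <- Xr + D
      nnf <- .nn_index(X, Y)
      Tf <- Y[nnf, , drop = FALSE]
      # reverse correspondences: reference vertices claiming each source
      nnr <- .nn_index(Y, X)
      Tr <- matrix(NA_real_, n, 3)
      cnt <- tabulate(nnr, n)
      for (k in 1:3) {
        s <- tapply(Y[, k], nnr, sum)
        vi <- as.integer(names(s))
        Tr[vi, k] <- as.numeric(s) / cnt[vi]
      }
      C <- (Tf + ifelse(is.na(Tr), Tf, Tr)) / 2
      if (have_anchors) C[anchor_src, ] <- Y[anchor_tgt_v, , drop = FALSE]
      Dn <- as.matrix(Matrix::solve(A, as.matrix(Wd %*% (C - Xr))))
      delta <- mean(sqrt(rowSums((Dn - D)^2)))
      D <- Dn
      if (delta < tol_mm) { level_converged <- TRUE; break }
    }
    if (!level_converged) converged <- FALSE
  }
  X <- Xr + D
  nn <- .nn_index(X, Y)
  rms_post <- sqrt(mean(rowSums((X - Y[nn, , drop = FALSE])^2)))

  structure(list(displacement = D,
                 correspondence = nn,
                 rigid = list(R = R, t = tvec),
                 rms_pre_mm = rms_pre,
                 rms_post_mm = rms_post,
                 converged = converged,
                 stiffness_schedule = stiffness_schedule,
                 source_vertices = X0,
                 registered_vertices = X),
            class = "registration")
}

# anatomically identifiable anchor vertices: appendage apex and the seven
# region seed vertices; empty when the mesh carries no landmarks
.anchor_vertices <- function(mesh) {
  if (length(mesh$pv_ostia) == 0L || is.null(mesh$laa_apex) ||
      is.null(mesh$mitral_rim) || is.null(mesh$region_seeds)) {
    return(integer(0))
  }
  seeds <- unlist(mesh$region_seeds[c("posterior", "roof", "lateral",
                                      "septum", "anterior", "floor",
                                      "mitral")])
  as.integer(c(mesh$laa_apex, seeds))
}

# paired anatomical landmark positions: PV ostium centroids, appendage
# apex, mitral-rim centroid (NULL when any is missing)
.registration_landmarks <- function(mesh) {
  if (length(mesh$pv_ostia) == 0L || is.null(mesh$laa_apex) ||
      is.null(mesh$mitral_rim)) {
    return(NULL)
  }
  rbind(
    t(vapply(mesh$pv_ostia, function(loop)
      colMeans(mesh$vertices[loop, , drop = FALSE]), numeric(3))),
    mesh$vertices[mesh$laa_apex, ],
    colMeans(mesh$vertices[mesh$mitral_rim, , drop = FALSE]))
}

# index of the nearest row of Y for each row of X (chunked brute force)
.nn_index <- function(X, Y, chunk = 512L) {
  n <- nrow(X)
  out <- integer(n)
  Yt <- t(Y)
  y2 <- colSums(Yt^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    G <- X[s:e, , drop = FALSE] %*% Yt
    D2 <- outer(rowSums(X[s:e, , drop = FALSE]^2), y2, `+`) - 2 * G
    out[s:e] <- max.col(-D2, ties.method = "first")
  }
  out
}

.nn_rms <- function(X, Y) {
  nn <- .nn_index(X, Y)
  sqrt(mean(rowSums((X - Y[nn, , drop = FALSE])^2)))
}

#' @export
print.registration <- function(x, ...) {
  cat("registration: rms", round(x$rms_pre_mm, 3), "->",
      round(x$rms_post_mm, 3), "mm;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Map points through a registration onto the reference frame
#'
#' Applies the rigid pose, then the displacement of the nearest source
#' vertex. Used to carry acquisition anchors and driver sites of a patient
#' map onto the reference shell.
#'
#' @param registration a [nonrigid_icp()] result
#' @param points n x 3 matrix in the source-mesh frame, mm
#' @return n x 3 matrix in the reference frame
#' @export
map_points <- function(registration, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  p <- sweep(points %*% t(registration$rigid$R), 2, registration$rigid$t, `+`)
  nn <- .nn_index(points, registration$source_vertices)
  p + registration$displacement[nn, , drop = FALSE]
}

#' Project point values onto reference-mesh vertices
#'
#' Each point maps to its nearest reference vertex; multiple values landing
#' on one vertex are averaged; points farther than `max_distance_mm` from
#' the surface are dropped and counted; vertices receiving nothing are
#' flagged unobserved (NA).
#'
#' @param points n x 3 matrix in the reference frame, mm
#' @param values numeric vector, one per point
#' @param reference the reference `atrium_mesh`
#' @param max_distance_mm drop radius (default 10)
#' @return list `values` (per-vertex means, NA where unobserved),
#'   `n_points` (per-vertex multiplicity), `n_dropped`
#' @export
project_scalars <- function(points, values, reference, max_distance_mm = 10) {
  points <- matrix(as.numeric(points), ncol = 3L)
  stopifnot(length(values) == nrow(points))
  Y <- reference$vertices
  nn <- .nn_index(points, Y)
  d <- sqrt(rowSums((points - Y[nn, , drop = FALSE])^2))
  keep <- d <= max_distance_mm
  out <- rep(NA_real_, nrow(Y))
  cnt <- integer(nrow(Y))
  if (any(keep)) {
    sums <- tapply(values[keep], nn[keep], sum)
    ns <- tapply(values[keep], nn[keep], length)
    vi <- as.integer(names(sums))
    out[vi] <- as.numeric(sums) / as.numeric(ns)
    cnt[vi] <- as.integer(ns)
  }
  list(values = out, n_points = cnt, n_dropped = sum(!keep))
}
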