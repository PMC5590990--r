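#' Structural mesh for valve tissue
#'
#' Holds membrane triangles (leaflets, gate), truss elements (chordae
#' tendineae, possibly with fork-shaped branched insertions sharing an
#' insertion node), per-element fiber frames and material bindings, and
#' named node sets (annulus boundary, belly markers, chordal origins,
#' clamped edges).
#'
#' Fiber frames are given per triangle as a circumferential direction;
#' the constructor projects it into the element plane, normalizes it and
#' builds the orthogonal in-plane radial direction.
#'
#' @param nodes n x 3 node coordinates (m), the stress-free reference.
#' @param triangles t x 3 integer connectivity (1-based), or `NULL`.
#' @param thickness Membrane thickness (m), scalar or per element.
#' @param fiber_dir t x 3 matrix of approximate circumferential directions
#'   (projected in-plane), or `NULL` for the default (first edge).
#' @param tri_material Character vector (length t) of material names bound
#'   to triangles; see `materials`.
#' @param trusses s x 2 integer connectivity, or `NULL`.
#' @param truss_area Cross-section area (m^2), scalar or per truss.
#' @param truss_material Character vector of material names per truss.
#' @param materials Named list mapping material names to [mhgo_params()]
#'   or [ogden_params()] objects.
#' @param node_sets Named list of integer node index vectors.
#' @param density Tissue density (kg/m^3), default 1100.
#' @return An object of class `structural_mesh` with precomputed reference
#'   geometry (element areas, inverse material-frame edge matrices, truss
#'   rest lengths, lumped nodal masses).
#' @export
structural_mesh <- function(nodes, triangles = NULL, thickness = 4e-4,
                            fiber_dir = NULL, tri_material = NULL,
                            trusses = NULL, truss_area = 4e-7,
                            truss_material = NULL, materials = list(),
                            node_sets = list(), density = 1100) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  mesh <- list(nodes = nodes, density = density, node_sets = node_sets,
               materials = materials)
  if (!is.null(triangles)) {
    triangles <- matrix(as.integer(triangles), ncol = 3)
    if (any(triangles < 1 | triangles > n))
      stop("element connectivity references invalid nodes")
    t <- nrow(triangles)
    thickness <- rep_len(thickness, t)
    if (any(thickness <= 0)) stop("thickness must be > 0")
    p1 <- nodes[triangles[, 1], , drop = FALSE]
    p2 <- nodes[triangles[, 2], , drop = FALSE]
    p3 <- nodes[triangles[, 3], , drop = FALSE]
    e1 <- p2 - p1; e2 <- p3 - p1
    nrm <- row_cross(e1, e2)
    a2 <- sqrt(rowSums(nrm^2))
    if (any(a2 < 1e-18)) stop("degenerate (zero-area) triangle in mesh")
    nrm <- nrm / a2
    if (is.null(fiber_dir)) fiber_dir <- e1
    fiber_dir <- as.matrix(fiber_dir)
    # project into element plane and orthonormalize
    f1 <- fiber_dir - rowSums(fiber_dir * nrm) * nrm
    l1 <- sqrt(rowSums(f1^2))
    if (any(l1 < 1e-12)) stop("fiber direction parallel to element normal")
    f1 <- f1 / l1
    f2 <- row_cross(nrm, f1)
    # reference edge matrix in the material frame and its inverse
    d11 <- rowSums(e1 * f1); d12 <- rowSums(e2 * f1)
    d21 <- rowSums(e1 * f2); d22 <- rowSums(e2 * f2)
    dtm <- d11 * d22 - d12 * d21
    if (any(abs(dtm) < 1e-18)) stop("degenerate reference element")
    mesh$triangles <- triangles
    mesh$thickness <- thickness
    mesh$fiber_e1 <- f1
    mesh$fiber_e2 <- f2
    mesh$area0 <- a2 / 2
    e3 <- p3 - p2
    mesh$ell <- pmin(sqrt(rowSums(e1^2)),
                     pmin(sqrt(rowSums(e2^2)), sqrt(rowSums(e3^2))))
    mesh$G <- cbind(g11 = d22 / dtm, g12 = -d12 / dtm,
                    g21 = -d21 / dtm, g22 = d11 / dtm)
    if (is.null(tri_material)) tri_material <- rep("default", t)
    mesh$tri_material <- rep_len(tri_material, t)
  }
  if (!is.null(trusses)) {
    trusses <- matrix(as.integer(trusses), ncol = 2)
    if (any(trusses < 1 | trusses > n))
      stop("truss connectivity references invalid nodes")
    s <- nrow(trusses)
    truss_area <- rep_len(truss_area, s)
    if (any(truss_area <= 0)) stop("truss area must be > 0")
    dvec <- nodes[trusses[, 2], , drop = FALSE] -
      nodes[trusses[, 1], , drop = FALSE]
    mesh$trusses <- trusses
    mesh$truss_area <- truss_area
    mesh$truss_L0 <- sqrt(rowSums(dvec^2))
    if (is.null(truss_material)) truss_material <- rep("chordae", s)
    mesh$truss_material <- rep_len(truss_material, s)
  }
  mesh$mass <- lumped_mass(mesh, n)
  structure(mesh, class = "structural_mesh")
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# row-sum (here: per-element equal split) lumped nodal masses
lumped_mass <- function(mesh, n) {
  m <- numeric(n)
  if (!is.null(mesh$triangles)) {
    em <- mesh$density * mesh$thickness * mesh$area0 / 3
    for (k in 1:3) {
      mm <- tapply(em, mesh$triangles[, k], sum)
      idx <- as.integer(names(mm))
      m[idx] <- m[idx] + as.numeric(mm)
    }
  }
  if (!is.null(mesh$trusses)) {
    tm <- mesh$density * mesh$truss_area * mesh$truss_L0 / 2
    for (k in 1:2) {
      mm <- tapply(tm, mesh$trusses[, k], sum)
      idx <- as.integer(names(mm))
      m[idx] <- m[idx] + as.numeric(mm)
    }
  }
  m
}

#' @export
print.structural_mesh <- function(x, ...) {
  cat("structural mesh:", nrow(x$nodes), "nodes,",
      if (is.null(x$triangles)) 0 else nrow(x$triangles), "membrane triangles,",
      if (is.null(x$trusses)) 0 else nrow(x$trusses), "trusses\n")
  invisible(x)
}

#' Volume enclosed by a closed triangulated surface
#'
#' Divergence-theorem volume `sum det(p1, p2, p3) / 6` over outward-
#' oriented triangles.
#'
#' @param nodes n x 3 coordinates (m).
#' @param triangles t x 3 connectivity.
#' @return Volume (m^3).
#' @export
mesh_volume <- function(nodes, triangles) {
  p1 <- nodes[triangles[, 1], , drop = FALSE]
  p2 <- nodes[triangles[, 2], , drop = FALSE]
  p3 <- nodes[triangles[, 3], , drop = FALSE]
  sum(rowSums(p1 * row_cross(p2, p3))) / 6
}
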