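#' Build a quadratic-triangle mesh of the vessel wall ring
#'
#' Constructs a structured annular mesh between the lumen and EEM
#' contours: both contours are resampled at a common set of angles
#' around the lumen centroid, corner nodes are placed on radial rays
#' interpolating lumen to EEM, each quadrilateral cell is split into two
#' triangles, and midside nodes complete the 6-node (quadratic)
#' elements. Elements take the tissue label of the plaque component
#' polygon containing their centroid (calcium over lipid where both),
#' else `"wall"`.
#'
#' @param geometry a [VesselGeometry-class] (or
#'   [ReferenceGeometry-class]).
#' @param targetEdgeLength requested element edge length (mm); controls
#'   both the circumferential and radial subdivision.
#' @param nCirc,nRad optional explicit subdivision counts overriding
#'   `targetEdgeLength`.
#' @return A [VesselMesh-class].
#' @examples
#' m <- buildMesh(ringGeometry(), targetEdgeLength = 0.2)
#' m
#' @export
buildMesh <- function(geometry, targetEdgeLength = 0.08,
                      nCirc = NULL, nRad = NULL) {
  stopifnot(targetEdgeLength > 0)
  centre <- polygonCentroid(geometry@lumen)
  rl <- sqrt(lumenArea(geometry) / pi)
  if (is.null(nCirc))
    nCirc <- max(24L, as.integer(ceiling(2 * pi * rl / targetEdgeLength)))
  inner <- resampleContour(geometry@lumen, centre, nCirc)
  outer <- resampleContour(geometry@eem, centre, nCirc)
  thick <- sqrt(rowSums((outer - inner)^2))
  if (any(thick <= 0)) stop("degenerate contour pair: non-positive wall thickness")
  if (is.null(nRad))
    nRad <- max(2L, as.integer(round(mean(thick) / targetEdgeLength)))

  # corner node grid: (nRad + 1) rings of nCirc nodes
  idx <- function(j, i) j * nCirc + ((i - 1L) %% nCirc) + 1L  # j in 0..nRad
  corners <- matrix(0, (nRad + 1L) * nCirc, 2)
  for (j in 0:nRad) {
    f <- j / nRad
    corners[idx(j, 1:nCirc), ] <- inner * (1 - f) + outer * f
  }

  tris <- matrix(0L, 2L * nRad * nCirc, 3L)
  k <- 0L
  for (j in seq_len(nRad) - 1L) for (i in seq_len(nCirc)) {
    a <- idx(j, i); b <- idx(j, i + 1L); cc <- idx(j + 1L, i + 1L); d <- idx(j + 1L, i)
    # CCW corner order (the wall ring lies radially outside the inner edge)
    tris[k + 1L, ] <- c(a, cc, b)
    tris[k + 2L, ] <- c(a, d, cc)
    k <- k + 2L
  }

  # midside nodes on unique edges
  ne <- nrow(tris)
  edgeKey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  e1 <- edgeKey(tris[, 1], tris[, 2])
  e2 <- edgeKey(tris[, 2], tris[, 3])
  e3 <- edgeKey(tris[, 3], tris[, 1])
  allKeys <- c(e1, e2, e3)
  uk <- unique(allKeys)
  midId <- stats::setNames(seq_along(uk) + nrow(corners), uk)
  pairFromKey <- do.call(rbind, strsplit(uk, "_"))
  pa <- as.integer(pairFromKey[, 1]); pb <- as.integer(pairFromKey[, 2])
  midCoords <- (corners[pa, , drop = FALSE] + corners[pb, , drop = FALSE]) / 2
  nodes <- rbind(corners, midCoords)
  elements <- cbind(tris, matrix(midId[allKeys], ne, 3L))
  storage.mode(elements) <- "integer"

  # tissue labels by centroid containment
  centz <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
            nodes[elements[, 3], ]) / 3
  tissue <- rep("wall", ne)
  for (cmp in geometry@components) {
    inside <- pointsInPolygon(centz, cmp$polygon)
    if (cmp$tissue == "lipid") tissue[inside & tissue == "wall"] <- "lipid"
    else tissue[inside] <- "calcium"
  }

  innerCorner <- idx(0L, 1:nCirc)
  outerCorner <- idx(nRad, 1:nCirc)
  lumenEdges <- cbind(innerCorner, innerCorner[c(2:nCirc, 1L)],
                      midId[edgeKey(innerCorner, innerCorner[c(2:nCirc, 1L)])])
  outerMid <- midId[edgeKey(outerCorner, outerCorner[c(2:nCirc, 1L)])]
  storage.mode(lumenEdges) <- "integer"
  dimnames(lumenEdges) <- NULL

  new("VesselMesh", nodes = nodes, elements = elements, tissue = tissue,
      lumenNodes = as.integer(c(innerCorner, lumenEdges[, 3])),
      outerNodes = as.integer(c(outerCorner, outerMid)),
      lumenEdges = lumenEdges)
}

#' Element areas (reference configuration)
#'
#' Signed corner-triangle areas; straight-sided quadratic elements so
#' the corner area is exact.
#'
#' @param mesh a [VesselMesh-class].
#' @return numeric vector, one area (mm^2) per element.
#' @export
elementAreas <- function(mesh) {
  n <- mesh@nodes; e <- mesh@elements
  x1 <- n[e[, 1], 1]; y1 <- n[e[, 1], 2]
  x2 <- n[e[, 2], 1]; y2 <- n[e[, 2], 2]
  x3 <- n[e[, 3], 1]; y3 <- n[e[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Total mesh area
#' @param mesh a [VesselMesh-class].
#' @return sum of element areas (mm^2).
#' @export
meshArea <- function(mesh) sum(elementAreas(mesh))

# Per-element circumferential fibre directions (unit tangents about the
# lumen centroid), used for the anisotropic wall tissue.
elementFibers <- function(mesh, centre = NULL) {
  if (is.null(centre)) {
    inner <- mesh@nodes[mesh@lumenEdges[, 1], , drop = FALSE]
    centre <- colMeans(inner)
  }
  e <- mesh@elements
  cx <- (mesh@nodes[e[, 1], 1] + mesh@nodes[e[, 2], 1] + mesh@nodes[e[, 3], 1]) / 3
  cy <- (mesh@nodes[e[, 1], 2] + mesh@nodes[e[, 2], 2] + mesh@nodes[e[, 3], 2]) / 3
  th <- atan2(cy - centre[2], cx - centre[1])
  cbind(-sin(th), cos(th))
}

#' Export a mesh (with optional point data) as legacy ASCII VTK
#'
#' Writes a standard text unstructured-grid file (quadratic-triangle
#' cells, integer tissue tags as cell data) readable by ParaView and
#' meshio.
#'
#' @param mesh a [VesselMesh-class].
#' @param file output path.
#' @param pointData optional named list of per-node numeric vectors
#'   (e.g. principal stress/strain).
#' @return `file`, invisibly.
#' @export
writeMeshVtk <- function(mesh, file, pointData = list()) {
  n <- nrow(mesh@nodes); ne <- nrow(mesh@elements)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vessel wall mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(mesh@nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 7L * ne), con)
  utils::write.table(cbind(6L, mesh@elements - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(22L, ne)), con)  # VTK_QUADRATIC_TRIANGLE
  writeLines(c(sprintf("CELL_DATA %d", ne), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh@tissue, c("wall", "lipid", "calcium")) - 1L), con)
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(pointData)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(pointData[[nm]], digits = 10), con)
    }
  }
  invisible(file)
}
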