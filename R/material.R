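#' Create a material parameter set
#'
#' Parameters of the modified Mooney-Rivlin strain energy (see
#' [MaterialParams-class] and the methods vignette). Dimensional
#' parameters are in kPa.
#'
#' @param c1,c2,D1 kPa. @param D2,K2 unitless. @param K1 kPa.
#' @param kappaVol volumetric penalty modulus (kPa); large relative to
#'   the shear scale enforces near-incompressibility.
#' @param anisotropic add the circumferential-fibre I4 term.
#' @return A [MaterialParams-class] object.
#' @export
materialParams <- function(c1, c2 = 0, D1 = 0, D2 = 1, K1 = 0, K2 = 1,
                           kappaVol = 2e3, anisotropic = FALSE) {
  new("MaterialParams", c1 = c1, c2 = c2, D1 = D1, D2 = D2, K1 = K1,
      K2 = K2, kappaVol = kappaVol, anisotropic = anisotropic)
}

#' Literature material parameters for the three vessel tissues
#'
#' Lipid-rich necrotic core and calcification are isotropic; the
#' remaining vessel tissue ("wall") is anisotropic with circumferential
#' fibres. Values: lipid c1=0.5, c2=0, D1=0.5, D2=1.5; calcification
#' c1=92, c2=0, D1=36, D2=2; other tissue c1=-278.7, c2=24.35, D1=133.7,
#' D2=2, K1=7.19, K2=23.5 (kPa where dimensional).
#'
#' @param kappaVol volumetric penalty for all tissues (kPa).
#' @param anisotropicWall use the fibre term for the wall tissue.
#' @return Named list of [MaterialParams-class]: `wall`, `lipid`,
#'   `calcium`.
#' @examples
#' mats <- vesselMaterials()
#' mats$wall
#' @export
vesselMaterials <- function(kappaVol = 2e3, anisotropicWall = TRUE) {
  list(
    wall = materialParams(c1 = -278.7, c2 = 24.35, D1 = 133.7, D2 = 2,
                          K1 = 7.19, K2 = 23.5, kappaVol = kappaVol,
                          anisotropic = anisotropicWall),
    lipid = materialParams(c1 = 0.5, c2 = 0, D1 = 0.5, D2 = 1.5,
                           kappaVol = kappaVol),
    calcium = materialParams(c1 = 92, c2 = 0, D1 = 36, D2 = 2,
                             kappaVol = kappaVol))
}

paramVector <- function(p) {
  c(p@c1, p@c2, p@D1, p@D2, p@K1, p@K2, p@kappaVol,
    as.numeric(p@anisotropic))
}

#' Kinematic state from an in-plane deformation gradient
#'
#' @param F2d 2 x 2 in-plane deformation gradient.
#' @param lambdaZ axial stretch (generalized plane strain).
#' @param fiber in-plane reference fibre direction (unit 2-vector).
#' @return list with `F2d`, `lambdaZ`, `fiber`, the 3x3 right
#'   Cauchy-Green tensor `C`, invariants `I1`, `I2`, `I4` and `J`.
#' @examples
#' st <- deformationState(diag(2))
#' st$I1  # 3 at the reference
#' @export
deformationState <- function(F2d, lambdaZ = 1, fiber = c(1, 0)) {
  stopifnot(is.matrix(F2d), all(dim(F2d) == 2))
  J <- det(F2d) * lambdaZ
  if (!is.finite(J) || J <= 0) stop("inverted deformation state (J <= 0)")
  fiber <- fiber / sqrt(sum(fiber^2))
  Fz <- rbind(cbind(F2d, 0), c(0, 0, lambdaZ))
  C <- t(Fz) %*% Fz
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  n3 <- c(fiber, 0)
  I4 <- drop(n3 %*% C %*% n3)
  list(F2d = F2d, lambdaZ = lambdaZ, fiber = fiber, C = C,
       I1 = I1, I2 = I2, I4 = I4, J = J)
}

#' Strain energy density
#'
#' Evaluates the modified Mooney-Rivlin energy (deviatoric-invariant
#' form plus volumetric penalty) at a deformation state. Zero at the
#' reference for every tissue.
#'
#' @param state a [deformationState()].
#' @param params a [MaterialParams-class].
#' @return energy density (kPa).
#' @export
strainEnergy <- function(state, params) {
  mrEnergyCpp(as.numeric(state$F2d), state$lambdaZ, paramVector(params),
              state$fiber)
}

#' Cauchy stress tensor
#'
#' Analytic push-forward sigma = (2/J) X (dW/dC) X^T of the strain
#' energy; block-diagonal (in-plane 2x2 plus sigma_zz) under generalized
#' plane strain.
#'
#' @inheritParams strainEnergy
#' @return 3 x 3 symmetric Cauchy stress (kPa).
#' @export
cauchyStress <- function(state, params) {
  mrCauchyCpp(as.numeric(state$F2d), state$lambdaZ, paramVector(params),
              state$fiber)
}

#' Principal values of a symmetric tensor
#'
#' @param tensor symmetric 2x2 or 3x3 matrix.
#' @param tol asymmetry tolerance (relative to the largest entry).
#' @return numeric vector of eigenvalues sorted decreasing; first is the
#'   maximum principal value, last the minimum.
#' @examples
#' principalValues(diag(c(3, 1)))       # 3 1
#' principalValues(matrix(c(0, 1, 1, 0), 2))  # 1 -1
#' @export
principalValues <- function(tensor, tol = 1e-8) {
  stopifnot(is.matrix(tensor), nrow(tensor) == ncol(tensor))
  scale <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > tol * scale)
    stop("tensor is not symmetric within tolerance")
  sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}
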