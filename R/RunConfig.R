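#' RunConfig: all tunable parameters of the segmentation pipelines
#'
#' One object carries every tunable of both pipelines, pre-filled with the
#' trained defaults. Slots group as:
#' \describe{
#'   \item{preprocessing}{\code{diffIterations}, \code{conductance},
#'     \code{diffTimeStep} (Perona-Malik smoothing); \code{gamma} (Gaussian
#'     std, px, of the edge-scale filter); \code{kappa}, \code{beta} (sigmoid
#'     shape/center on the 0-255 gradient scale); \code{theta} (binarization
#'     divisor, operating range 1.1-1.5).}
#'   \item{region growing}{\code{W}: gray-level homogeneity threshold. On the
#'     binary preprocessed image any value in (0,1] works.}
#'   \item{liver level set}{\code{mu} (distance regularization), \code{lambda}
#'     (length weight), \code{alpha} (balloon magnitude), \code{liverIterations},
#'     \code{omega} (initial step height), \code{dt}, \code{epsilon} (Dirac
#'     width), \code{sigma} (edge-indicator Gaussian std), \code{gain}
#'     (intensity gain applied before differentiation, 8-bit convention).}
#'   \item{tumor branch}{\code{nu}, \code{deltaReg}, \code{licIterations},
#'     \code{licDt}, kernel \code{a}, \code{tau}, \code{rho}; \code{mapIters},
#'     \code{emIters}, \code{pottsBeta}; \code{vartheta} (tumor balloon
#'     magnitude), \code{tumorIterations}.}
#'   \item{plumbing}{\code{seed} for every stochastic step; optional
#'     convergence surrogate \code{convWindow}/\code{convTol} (0 = off,
#'     matching the fixed-iteration experiments).}
#' }
#'
#' @slot diffIterations,conductance,diffTimeStep Perona-Malik parameters.
#' @slot gamma,kappa,beta,theta preprocessing chain parameters.
#' @slot W region-growing homogeneity threshold.
#' @slot mu,lambda,alpha,liverIterations,omega,dt,epsilon,sigma,gain liver
#'   level set parameters.
#' @slot lambda1,lambda2 Chan-Vese region weights.
#' @slot nu,deltaReg,licIterations,licDt,a,tau,rho local-intensity-clustering
#'   parameters.
#' @slot mapIters,emIters,pottsBeta HMRF-EM parameters.
#' @slot vartheta,tumorIterations tumor level set parameters.
#' @slot convWindow,convTol convergence surrogate (0 disables).
#' @slot seed RNG seed.
#' @export
setClass("RunConfig",
  representation(
    diffIterations = "numeric", conductance = "numeric", diffTimeStep = "numeric",
    gamma = "numeric", kappa = "numeric", beta = "numeric", theta = "numeric",
    W = "numeric",
    mu = "numeric", lambda = "numeric", alpha = "numeric",
    liverIterations = "numeric", omega = "numeric", dt = "numeric",
    epsilon = "numeric", sigma = "numeric", gain = "numeric",
    lambda1 = "numeric", lambda2 = "numeric",
    nu = "numeric", deltaReg = "numeric", licIterations = "numeric",
    licDt = "numeric", a = "numeric", tau = "numeric", rho = "numeric",
    mapIters = "numeric", emIters = "numeric", pottsBeta = "numeric",
    vartheta = "numeric", tumorIterations = "numeric",
    convWindow = "numeric", convTol = "numeric",
    seed = "numeric"),
  validity = function(object) {
    if (object@theta <= 1) return("theta must be > 1")
    if (object@omega < 2) return("omega must be >= 2")
    iters <- c(object@diffIterations, object@liverIterations,
               object@licIterations, object@mapIters, object@emIters,
               object@tumorIterations)
    if (any(iters < 0)) return("iteration counts must be >= 0")
    if (object@mu * object@dt >= 0.25)
      return("stability requires mu * dt < 0.25")
    if (object@diffTimeStep <= 0 || object@diffTimeStep > 0.25)
      return("diffusion time step must lie in (0, 0.25]")
    if (object@gamma <= 0) return("gamma must be > 0")
    if (object@kappa == 0) return("kappa must be nonzero")
    if (object@W <= 0) return("W must be > 0")
    if (object@epsilon <= 0) return("epsilon must be > 0")
    if (object@rho < 1) return("rho must be >= 1")
    if (object@tau <= 0) return("tau must be > 0")
    TRUE
  })

#' Build a RunConfig with trained defaults
#'
#' Any slot can be overridden by name. Defaults are the trained operating
#' point: preprocessing gamma = 0.5, kappa = -1.5, beta = 4, theta = 1.25
#' (operating range 1.1-1.5); liver level set mu = 0.04, lambda = 5,
#' alpha = 10, 100 iterations, omega = 4; local intensity clustering a = 1,
#' tau = 4, rho = 3, nu = 1, deltaReg = 1, 100 iterations; HMRF-EM 15 MAP /
#' 15 EM iterations; tumor level set vartheta = 3, 200 iterations.
#'
#' @param ... named overrides of any \linkS4class{RunConfig} slot.
#' @return A validated \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig(theta = 1.2, seed = 7)
#' cfg@alpha
#' @export
runConfig <- function(...) {
  defaults <- list(
    diffIterations = 10, conductance = 0.1, diffTimeStep = 0.125,
    gamma = 0.5, kappa = -1.5, beta = 4, theta = 1.25,
    W = 0.5,
    mu = 0.04, lambda = 5, alpha = 10, liverIterations = 100,
    omega = 4, dt = 1, epsilon = 1.5, sigma = 0.5, gain = 255,
    lambda1 = 1, lambda2 = 1,
    nu = 1, deltaReg = 1, licIterations = 100, licDt = 0.2,
    a = 1, tau = 4, rho = 3,
    mapIters = 15, emIters = 15, pottsBeta = 0.5,
    vartheta = 3, tumorIterations = 200,
    convWindow = 0, convTol = 0,
    seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown RunConfig parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  do.call(new, c(list(Class = "RunConfig"), defaults))
}

#' Read a RunConfig from a YAML or JSON file
#'
#' The file holds flat keys mirroring the \linkS4class{RunConfig} slots.
#' Values given in \code{...} override values from the file (the CLI uses
#' this to let flags win over the config file).
#'
#' @param path path to a .yaml/.yml or .json file, or NULL for pure defaults.
#' @param ... named overrides applied after the file.
#' @return A validated \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    }
    if (!is.list(vals)) stop("config file must hold a flat mapping")
  }
  override <- list(...)
  vals[names(override)] <- override
  do.call(runConfig, vals)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig (trained defaults unless overridden)\n")
  cat(sprintf("  preprocess: diffusion %d it (c=%.3g, dt=%.3g), gamma=%.3g, kappa=%.3g, beta=%.3g, theta=%.3g\n",
              as.integer(object@diffIterations), object@conductance,
              object@diffTimeStep, object@gamma, object@kappa, object@beta,
              object@theta))
  cat(sprintf("  region grow: W=%.3g\n", object@W))
  cat(sprintf("  liver LSM: mu=%.3g lambda=%.3g alpha=%.3g t=%d omega=%.3g dt=%.3g eps=%.3g sigma=%.3g gain=%.3g\n",
              object@mu, object@lambda, object@alpha,
              as.integer(object@liverIterations), object@omega, object@dt,
              object@epsilon, object@sigma, object@gain))
  cat(sprintf("  tumor: LIC %d it (nu=%.3g, delta=%.3g, a=%.3g tau=%.3g rho=%.3g), HMRF %d/%d (beta=%.3g), unified vartheta=%.3g t=%d\n",
              as.integer(object@licIterations), object@nu, object@deltaReg,
              object@a, object@tau, object@rho, as.integer(object@mapIters),
              as.integer(object@emIters), object@pottsBeta, object@vartheta,
              as.integer(object@tumorIterations)))
  cat(sprintf("  seed: %d\n", as.integer(object@seed)))
})
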