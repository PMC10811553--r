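#' @useDynLib avnode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp runif rnorm rbinom cov quantile density sd median
#'   setNames wilcox.test shapiro.test cor.test ecdf
#' @importFrom utils read.csv write.csv head tail
NULL

#' Canonical names of the twelve model parameters
#'
#' The AV-node model has six parameters per pathway: the minimal refractory
#' period \code{rmin}, its prolongation \code{dr} and time constant
#' \code{taur}, and the minimal conduction delay \code{dmin}, its
#' prolongation \code{dd} and time constant \code{taud} (all in ms). The
#' fast-pathway block precedes the slow-pathway block.
#'
#' @return Character vector of length 12.
#' @export
theta_names <- function() {
  c("fp_rmin", "fp_dr", "fp_taur", "fp_dmin", "fp_dd", "fp_taud",
    "sp_rmin", "sp_dr", "sp_taur", "sp_dmin", "sp_dd", "sp_taud")
}

#' Construct the parameters of one AV-node pathway
#'
#' @param r_min Minimal refractory period (ms).
#' @param delta_r Maximal refractory-period prolongation (ms).
#' @param tau_r Refractory-period recovery time constant (ms).
#' @param d_min Minimal conduction delay per node (ms).
#' @param delta_d Maximal conduction-delay prolongation (ms).
#' @param tau_d Conduction-delay recovery time constant (ms).
#' @return A named numeric vector of class \code{pathway_params}.
#' @export
pathway_params <- function(r_min, delta_r, tau_r, d_min, delta_d, tau_d) {
  x <- c(rmin = r_min, dr = delta_r, taur = tau_r,
         dmin = d_min, dd = delta_d, taud = tau_d)
  if (any(!is.finite(x)) || any(x < 0))
    stop("pathway parameters must be finite and non-negative")
  structure(x, class = "pathway_params")
}

#' Construct the full 12-parameter AV-node model vector
#'
#' Bundles fast-pathway (FP) and slow-pathway (SP) parameters into the model
#' parameter vector theta, serialized in the fixed canonical order given by
#' [theta_names()].
#'
#' @param fp,sp Objects from [pathway_params()], or numeric 6-vectors in the
#'   order rmin, dr, taur, dmin, dd, taud.
#' @return Named numeric 12-vector of class \code{avn_params}.
#' @export
avn_params <- function(fp, sp) {
  fp <- unclass(fp); sp <- unclass(sp)
  if (length(fp) != 6L || length(sp) != 6L)
    stop("each pathway needs exactly 6 parameters")
  theta <- as.numeric(c(fp, sp))
  names(theta) <- theta_names()
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("model parameters must be finite and non-negative")
  structure(theta, class = "avn_params")
}

#' Coerce a flat numeric vector to an AV-node parameter vector
#'
#' @param x Numeric vector of length 12 in canonical order (see
#'   [theta_names()]).
#' @return An \code{avn_params} object.
#' @export
as_avn_params <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 12L) stop("theta must have length 12")
  avn_params(x[1:6], x[7:12])
}

#' @export
print.avn_params <- function(x, ...) {
  m <- matrix(unclass(x), nrow = 2, byrow = TRUE,
              dimnames = list(c("FP", "SP"),
                              c("rmin", "dr", "taur", "dmin", "dd", "taud")))
  cat("AV-node model parameters (ms):\n")
  print(round(m, 2))
  invisible(x)
}

#' Parameter box bounds for the GA and the ABC sampler
#'
#' The search box for the genetic algorithm and the wider prior support for
#' the ABC sampler (which must accommodate the full posterior width). The GA
#' box is contained in the ABC box. Values in ms, per coordinate of the
#' canonical 12-vector.
#'
#' @param flavor Either \code{"GA"} or \code{"ABC"}.
#' @return List with numeric 12-vectors \code{lower} and \code{upper} (named
#'   by [theta_names()]) and the \code{flavor} string.
#' @export
avn_bounds <- function(flavor = c("GA", "ABC")) {
  flavor <- match.arg(flavor)
  if (flavor == "GA") {
    lo <- c(rmin = 100, dr = 0, taur = 25, dmin = 2, dd = 0, taud = 25)
    hi <- c(rmin = 1000, dr = 1000, taur = 500, dmin = 50, dd = 100, taud = 500)
  } else {
    lo <- c(rmin = 30, dr = 0, taur = 10, dmin = 0.1, dd = 0, taud = 10)
    hi <- c(rmin = 1300, dr = 1300, taur = 700, dmin = 80, dd = 130, taud = 700)
  }
  lower <- rep(unname(lo), 2); upper <- rep(unname(hi), 2)
  names(lower) <- names(upper) <- theta_names()
  list(lower = lower, upper = upper, flavor = flavor)
}

#' Canonicalize the pathway labels of parameter vectors
#'
#' The model is exchangeable in its two pathways, so every parameter vector
#' has a mirror twin with the pathway blocks swapped that produces the same
#' RR statistics. Optimizers and samplers work on the canonical half-space
#' where the fast-pathway block has the larger minimal refractory period —
#' physiologically the fast pathway conducts quickly and recovers slowly.
#' The refractory periods bound the RR intervals directly and are the
#' strongly identified coordinates, which makes them the reliable labelling
#' axis; merging the mirror modes also stops populations from going
#' artificially bimodal.
#'
#' @param theta Numeric 12-vector or matrix with 12 columns (canonical
#'   column order).
#' @return The input with pathway blocks swapped wherever
#'   \code{fp_rmin < sp_rmin}.
#' @export
canonicalize_theta <- function(theta) {
  if (is.null(dim(theta))) {
    if (theta[[1]] < theta[[7]]) {
      nm <- names(theta)
      theta <- theta[c(7:12, 1:6)]
      names(theta) <- nm
    }
    return(theta)
  }
  swap <- theta[, 1] < theta[, 7]
  if (any(swap))
    theta[swap, ] <- theta[swap, c(7:12, 1:6), drop = FALSE]
  theta
}

in_bounds <- function(theta, bounds) {
  all(theta >= bounds$lower & theta <= bounds$upper)
}

clip_to_bounds <- function(theta, bounds) {
  pmin(pmax(theta, bounds$lower), bounds$upper)
}

#' Read or write parameter vectors as flat CSV
#'
#' One row per parameter vector, 12 columns with the canonical header names
#' of [theta_names()].
#'
#' @param path File path.
#' @param theta Matrix (rows = vectors) or a single 12-vector, for writing.
#' @return \code{read_theta_csv}: numeric matrix with canonical column names.
#' @export
read_theta_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (!all(theta_names() %in% names(d)))
    stop("parameter CSV must contain the canonical 12 columns")
  as.matrix(d[, theta_names(), drop = FALSE])
}

#' @rdname read_theta_csv
#' @export
write_theta_csv <- function(theta, path) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  colnames(theta) <- theta_names()
  write.csv(as.data.frame(theta), path, row.names = FALSE)
  invisible(path)
}
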