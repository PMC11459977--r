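## Iterative reconstruction: MLEM, OSEM, ordered-subsets one-step-late with
## median root prior (OS-OSL-MRP), ordered-subsets separable paraboloidal
## surrogates with quadratic prior (OS-SPS-QP).

#' Create a reconstruction configuration
#'
#' @param algorithm `"MLEM"`, `"OSEM"`, `"OS_OSL_MRP"` or `"OS_SPS_QP"`.
#' @param n_subsets number of angularly interleaved subsets; MLEM forces 1.
#' @param n_subiterations total subset updates (one pass over one subset each).
#' @param penalisation_factor prior weight PF (>= 0).
#' @param alpha,gamma relaxation schedule `lambda_n = alpha / (1 + gamma n)`
#'   for OS-SPS-QP, with `n` the completed full-iteration counter.
#' @param initial_image optional [image_volume()] start; default uniform 1
#'   inside the mask, 0 outside.
#' @param save_every save an image snapshot every this many subiterations
#'   (0 = only the final image).
#' @param track_objective record the Poisson log-likelihood (minus the penalty
#'   for penalized algorithms) after every subiteration; costs one full
#'   forward projection each time unless `n_subsets = 1`.
#' @param relax_per `"iteration"` (default) or `"subiteration"`: what advances
#'   the relaxation counter `n`.
#' @export
recon_config <- function(algorithm = c("OSEM", "MLEM", "OS_OSL_MRP", "OS_SPS_QP"),
                         n_subsets = 1L, n_subiterations,
                         penalisation_factor = 0, alpha = 1, gamma = 0.1,
                         initial_image = NULL, save_every = 0L,
                         track_objective = FALSE,
                         relax_per = c("iteration", "subiteration")) {
  algorithm <- match.arg(toupper(gsub("-", "_", algorithm[1])),
                         c("OSEM", "MLEM", "OS_OSL_MRP", "OS_SPS_QP"))
  relax_per <- match.arg(relax_per)
  if (algorithm == "MLEM" && n_subsets != 1)
    stop("MLEM requires n_subsets = 1")
  stopifnot(n_subsets >= 1, n_subiterations >= 1, penalisation_factor >= 0)
  structure(list(algorithm = algorithm, n_subsets = as.integer(n_subsets),
                 n_subiterations = as.integer(n_subiterations),
                 penalisation_factor = penalisation_factor,
                 alpha = alpha, gamma = gamma, initial_image = initial_image,
                 save_every = as.integer(save_every),
                 track_objective = isTRUE(track_objective),
                 relax_per = relax_per),
            class = "recon_config")
}

#' Partition views into angularly interleaved subsets
#'
#' View `k` goes to subset `k mod n_subsets`, so subsets are balanced to
#' within one view and angularly interleaved.
#'
#' @param n_views number of views.
#' @param n_subsets number of subsets (`<= n_views`).
#' @return list of integer view-index vectors.
#' @export
make_subsets <- function(n_views, n_subsets) {
  stopifnot(n_subsets >= 1, n_subsets <= n_views)
  lapply(seq_len(n_subsets), function(s) seq(s, n_views, by = n_subsets))
}

## forward-project selected views, returning list(yhat = list per view)
.subset_forward <- function(prj, x, views) {
  lapply(views, function(v) as.numeric(.view_mat(prj, v) %*% x) *
           prj$detector$orbit$n_orbits)
}

## EM ratio backprojection over a subset: t(A_S) (m_S / yhat_S), 0/0 -> 0
.em_numerator <- function(prj, x, views, measured) {
  num <- numeric(prj$n_vox)
  sc <- prj$detector$orbit$n_orbits
  for (v in views) {
    A <- .view_mat(prj, v)
    yhat <- as.numeric(A %*% x) * sc
    m <- as.numeric(measured[v, , ])
    ratio <- ifelse(yhat > 0, m / yhat, 0)
    num <- num + as.numeric(Matrix::crossprod(A, ratio)) * sc
  }
  num
}

#' One OSEM (or MLEM) multiplicative update over a subset
#'
#' `x <- x / s_S * t(A_S) (m_S / (A_S x))`; voxels with zero subset
#' sensitivity are left unchanged and 0/0 ratios are treated as 0.
#'
#' @param x numeric voxel vector (current estimate).
#' @param projector a [pinhole_projector()].
#' @param measured measured projection array `[n_views, n_axial, n_transaxial]`.
#' @param views view indices of the subset.
#' @param sensitivity subset sensitivity vector `t(A_S) 1` (precomputed).
#' @return updated voxel vector.
#' @export
osem_update <- function(x, projector, measured, views, sensitivity) {
  if (all(sensitivity <= 0)) stop("all-zero sensitivity for this subset")
  num <- .em_numerator(projector, x, views, measured)
  upd <- sensitivity > 0
  x[upd] <- x[upd] * num[upd] / sensitivity[upd]
  x
}

#' One OS-OSL update with median root prior
#'
#' One-step-late: the OSEM numerator is divided by
#' `s_S (1 + PF (x - med(x)) / med(x))` with the median over each voxel's
#' 3x3x3 neighbourhood evaluated at the current estimate; the dimensionless
#' median-root gradient is scaled by the subset sensitivity `s_S` so that PF
#' weights the prior independently of the absolute weight/count scale.
#' Voxels whose neighbourhood median is zero get no penalty; non-positive
#' denominators are clamped to a small positive value (count reported via
#' attribute `n_clamped`).
#'
#' @inheritParams osem_update
#' @param pf penalisation factor (PF); `pf = 0` reduces to [osem_update()].
#' @return updated voxel vector.
#' @export
os_osl_mrp_update <- function(x, projector, measured, views, sensitivity,
                              pf = 1) {
  if (all(sensitivity <= 0)) stop("all-zero sensitivity for this subset")
  d <- dim(projector$grid$voxels)
  med <- cpp_median3(x, d[1], d[2], d[3])
  pen <- ifelse(med > 0, (x - med) / med, 0)
  ## the MRP gradient is dimensionless while the sensitivity carries the
  ## (tiny) absolute detection probabilities, so the penalty enters scaled by
  ## the subset sensitivity; PF then weights prior against likelihood
  ## independently of the count/weight scale
  denom <- sensitivity * (1 + pf * pen)
  nclamp <- sum(denom <= 0 & sensitivity > 0)
  eps <- 1e-8 * max(sensitivity)
  denom <- pmax(denom, eps)
  num <- .em_numerator(projector, x, views, measured)
  upd <- sensitivity > 0
  x[upd] <- x[upd] * num[upd] / denom[upd]
  attr(x, "n_clamped") <- nclamp
  x
}

#' One relaxed OS-SPS update with quadratic prior
#'
#' Additive separable-paraboloidal-surrogate step with precomputed data-term
#' curvature `D = t(A) (c * A 1)`, `c_i = 1/m_i` for `m_i > 0` (else 0), a
#' 26-neighbourhood quadratic prior (weights 1/distance), subset gradient
#' scaled by the number of subsets, and projection onto `x >= 0`. Voxels with
#' zero total curvature are skipped.
#'
#' @inheritParams osem_update
#' @param curv precomputed data curvature vector `D` (see
#'   [sps_data_curvature()]).
#' @param pf penalisation factor.
#' @param lambda relaxation step `lambda_n`.
#' @param n_subsets subset count (gradient scale).
#' @param mask logical voxel vector; updates confined to it.
#' @return updated voxel vector.
#' @export
os_sps_qp_update <- function(x, projector, measured, views, curv, pf, lambda,
                             n_subsets, mask = NULL) {
  d <- dim(projector$grid$voxels)
  sc <- projector$detector$orbit$n_orbits
  grad <- numeric(projector$n_vox)
  for (v in views) {
    A <- .view_mat(projector, v)
    yhat <- as.numeric(A %*% x) * sc
    m <- as.numeric(measured[v, , ])
    r <- ifelse(yhat > 0, m / yhat - 1, 0)
    grad <- grad + as.numeric(Matrix::crossprod(A, r)) * sc
  }
  qp <- cpp_quad_prior(x, d[1], d[2], d[3])
  denom <- curv + pf * qp$curv
  step <- ifelse(denom > 0,
                 lambda * (n_subsets * grad - pf * qp$grad) / denom, 0)
  xn <- pmax(x + step, 0)
  if (!is.null(mask)) xn[!mask] <- 0
  xn
}

#' Precompute the OS-SPS data-term curvature
#'
#' `D = t(A) (c * A 1)` over all views, with `c_i = 1/m_i` for `m_i > 0` and 0
#' otherwise (optimal precomputed curvature of the Poisson surrogate at the
#' data).
#'
#' @param projector a [pinhole_projector()].
#' @param measured measured projection array.
#' @return numeric voxel vector.
#' @export
sps_data_curvature <- function(projector, measured) {
  ones <- rep(1, projector$n_vox)
  ones[!as.logical(projector$mask)] <- 0
  D <- numeric(projector$n_vox)
  sc <- projector$detector$orbit$n_orbits
  for (v in seq_along(projector$angles)) {
    A <- .view_mat(projector, v)
    a1 <- as.numeric(A %*% ones) * sc
    m <- as.numeric(measured[v, , ])
    ci <- ifelse(m > 0, 1 / m, 0)
    D <- D + as.numeric(Matrix::crossprod(A, ci * a1)) * sc
  }
  D
}

## Poisson log-likelihood sum(m log yhat - yhat) over bins with yhat > 0
.poisson_ll <- function(m, yhat) {
  ok <- yhat > 0
  sum(m[ok] * log(yhat[ok]) - yhat[ok])
}

#' Iterative reconstruction
#'
#' Runs the configured algorithm with angularly interleaved subsets processed
#' sequentially. Deterministic given its inputs. OSEM with one subset is MLEM.
#'
#' @param measured a [projection_data()] (or matching array).
#' @param projector a [pinhole_projector()].
#' @param config a [recon_config()].
#' @return object of class `recon_result`: list with `image` (final
#'   [image_volume()]), `snapshots` (named list of [image_volume()], one per
#'   `save_every` checkpoint), `trace` (data.frame of subiteration and, when
#'   tracked, objective), and `config`.
#' @export
reconstruct <- function(measured, projector, config) {
  stopifnot(inherits(config, "recon_config"))
  m <- if (inherits(measured, "projection_data")) measured$views else measured
  nv <- length(projector$angles)
  if (dim(m)[1] != nv) stop("measured views do not match the projector orbit")
  subsets <- make_subsets(nv, config$n_subsets)
  mask <- as.logical(projector$mask)

  x <- if (!is.null(config$initial_image)) {
    as.numeric(config$initial_image$voxels)
  } else {
    ifelse(mask, 1, 0)
  }

  sens <- lapply(subsets, function(vs) .sensitivity(projector, vs))
  alg <- config$algorithm
  pf <- config$penalisation_factor
  curv <- if (alg == "OS_SPS_QP") sps_data_curvature(projector, m)

  snapshots <- list()
  trace <- data.frame(subiteration = integer(0), objective = numeric(0))
  d <- dim(projector$grid$voxels)

  for (t in seq_len(config$n_subiterations)) {
    s <- ((t - 1) %% config$n_subsets) + 1
    if (alg %in% c("MLEM", "OSEM")) {
      x <- osem_update(x, projector, m, subsets[[s]], sens[[s]])
    } else if (alg == "OS_OSL_MRP") {
      x <- os_osl_mrp_update(x, projector, m, subsets[[s]], sens[[s]], pf = pf)
      attr(x, "n_clamped") <- NULL
    } else {
      n <- if (config$relax_per == "iteration")
        (t - 1) %/% config$n_subsets else t - 1
      lambda <- config$alpha / (1 + config$gamma * n)
      x <- os_sps_qp_update(x, projector, m, subsets[[s]], curv, pf = pf,
                            lambda = lambda, n_subsets = config$n_subsets,
                            mask = mask)
    }
    if (config$track_objective) {
      yhat <- forward_project(projector,
                              image_volume(array(x, d), projector$grid$voxel_size,
                                           projector$grid$z_spacing,
                                           projector$grid$origin))$views
      obj <- .poisson_ll(as.numeric(m), as.numeric(yhat))
      if (pf > 0 && alg == "OS_SPS_QP") {
        ## R(x) homogeneous quadratic => R(x) = x . grad(x) / 2
        qp <- cpp_quad_prior(x, d[1], d[2], d[3])
        obj <- obj - pf * 0.5 * sum(x * qp$grad)
      }
      trace <- rbind(trace, data.frame(subiteration = t, objective = obj))
    }
    if (config$save_every > 0 && t %% config$save_every == 0) {
      snapshots[[sprintf("subiter_%03d", t)]] <-
        image_volume(array(x, d), projector$grid$voxel_size,
                     projector$grid$z_spacing, projector$grid$origin)
    }
  }
  structure(list(
    image = image_volume(array(x, d), projector$grid$voxel_size,
                         projector$grid$z_spacing, projector$grid$origin),
    snapshots = snapshots, trace = trace, config = config),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, %d subiterations (%d subsets), %d snapshots\n",
              x$config$algorithm, x$config$n_subiterations,
              x$config$n_subsets, length(x$snapshots)))
  invisible(x)
}
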