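#' Voxel-wise eigenvector centrality by matrix-free power iteration
#'
#' Treats every in-mask voxel as a node of a whole-brain graph whose edge
#' weights are the pairwise Pearson correlations of the voxel timecourses,
#' rescaled to `M = (C + 1) / 2` so all weights are nonnegative. By
#' Perron-Frobenius, the dominant eigenvector of `M` is then unique and
#' nonnegative; its entries are the eigenvector centrality values: a voxel
#' is central when it is strongly connected to other central voxels.
#'
#' The dominant eigenvector is computed by power iteration without ever
#' materializing the voxel-by-voxel matrix: with `Z` the t x V array of
#' z-scored timecourses, `M v` is evaluated as
#' `(crossprod(Z, Z %*% v) / T + sum(v)) / 2`. The iteration starts from
#' the uniform positive unit vector (inside the positive cone, and
#' deterministic) and stops when the L2 change of the iterate falls below
#' `tol`.
#'
#' @param x A `cleaned_bold`, [bold_dataset()], 4D array, or a t x V
#'   matrix of timecourses.
#' @param mask 3D mask (defaults to the object's mask; required for bare 4D
#'   arrays, ignored for matrices). Zero-variance voxels are dropped from
#'   the mask with a warning.
#' @param tol Convergence tolerance on the L2 iterate difference.
#' @param max_iter Maximum number of power iterations; non-convergence
#'   yields a warning and `converged = FALSE`, never an error.
#' @param similarity `"add1half"` (default, `(C+1)/2`) or `"abs"`
#'   (absolute correlation; requires materializing the matrix and is
#'   subject to the same size guard as [dense_ecm()]).
#' @return An object of class `ec_map`: `values` (per in-mask voxel,
#'   nonnegative, unit Euclidean norm), `map` (3D array, zeros outside the
#'   mask; `NULL` for matrix input), `mask`, `iterations`, `converged`,
#'   `eigenvalue` (Rayleigh quotient of the final iterate) and
#'   `rayleigh_path` (per-iteration Rayleigh quotients).
#' @export
fast_ecm <- function(x, mask = NULL, tol = 1e-9, max_iter = 1000,
                     similarity = c("add1half", "abs")) {
  similarity <- match.arg(similarity)
  ext <- extract_timecourses(x, mask)
  Y <- ext$Y; mask <- ext$mask
  nt <- nrow(Y); nv <- ncol(Y)
  if (nv == 0) stop_invalid("mask is empty")
  if (nt < 2) stop_invalid("need at least 2 volumes")

  Z <- center_scale_pop(Y)
  drop <- attr(Z, "zero_variance")
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance voxel(s) from the mask",
                    sum(drop)))
    if (!is.null(mask)) { idx <- which(mask); mask[idx[drop]] <- FALSE }
    Z <- Z[, !drop, drop = FALSE]
    nv <- ncol(Z)
  }

  if (similarity == "abs") {
    if (nv > 5000) stop_invalid("similarity 'abs' requires <= 5000 voxels (got %d)", nv)
    M <- abs(crossprod(Z) / nt)
    mv <- function(v) as.vector(M %*% v)
  } else {
    mv <- function(v) (as.vector(crossprod(Z, Z %*% v)) / nt + sum(v)) / 2
  }

  v <- rep(1 / sqrt(nv), nv)
  converged <- FALSE
  iterations <- 0L
  rayleigh <- numeric(0)
  lambda <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- mv(v)
    lambda <- sum(v * w)
    rayleigh[i] <- lambda
    w <- w / sqrt(sum(w^2))
    iterations <- i
    if (sqrt(sum((w - v)^2)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged) {
    warning(sprintf("power iteration did not converge in %d iterations", max_iter))
  }
  new_ec_map(v, mask, iterations, converged, lambda, rayleigh,
             similarity = similarity)
}

#' Dense eigendecomposition oracle for eigenvector centrality
#'
#' Materializes the full voxel-by-voxel similarity matrix and returns the
#' eigenvector of its largest eigenvalue, sign-fixed to be nonnegative.
#' Intended for validating [fast_ecm()] on small problems; refuses more
#' than 5000 in-mask voxels.
#'
#' @inheritParams fast_ecm
#' @return An `ec_map` (with `iterations = NA`).
#' @export
dense_ecm <- function(x, mask = NULL, similarity = c("add1half", "abs")) {
  similarity <- match.arg(similarity)
  ext <- extract_timecourses(x, mask)
  Y <- ext$Y; mask <- ext$mask
  nv <- ncol(Y)
  if (nv == 0) stop_invalid("mask is empty")
  if (nv > 5000) {
    stop_invalid("dense_ecm is a validation oracle; mask has %d voxels (guard: 5000)", nv)
  }
  Z <- center_scale_pop(Y)
  drop <- attr(Z, "zero_variance")
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance voxel(s) from the mask", sum(drop)))
    if (!is.null(mask)) { idx <- which(mask); mask[idx[drop]] <- FALSE }
    Z <- Z[, !drop, drop = FALSE]
  }
  C <- crossprod(Z) / nrow(Z)
  M <- if (similarity == "abs") abs(C) else (C + 1) / 2
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  new_ec_map(v, mask, NA_integer_, TRUE, e$values[1], numeric(0),
             similarity = similarity)
}

# Accept cleaned_bold / bold_dataset / 4D array / t x V matrix.
extract_timecourses <- function(x, mask) {
  if (inherits(x, "cleaned_bold")) {
    mask <- mask %||% x$mask
    list(Y = mask_matrix(x$data, mask), mask = mask)
  } else if (inherits(x, "bold_dataset")) {
    mask <- mask %||% x$brain_mask
    list(Y = mask_matrix(x$data, mask), mask = mask)
  } else if (is.array(x) && length(dim(x)) == 4L) {
    if (is.null(mask)) stop_invalid("a mask is required for bare 4D arrays")
    list(Y = mask_matrix(x, mask), mask = mask)
  } else if (is.matrix(x)) {
    list(Y = x, mask = mask)
  } else {
    stop_invalid("unsupported input type for timecourse extraction")
  }
}

# Population-normalized z-scoring of columns; flags zero-variance columns.
center_scale_pop <- function(Y) {
  Y <- sweep(Y, 2, colMeans(Y), "-")
  sds <- sqrt(colMeans(Y^2))
  zero <- sds == 0 | !is.finite(sds)
  sds[zero] <- 1
  out <- sweep(Y, 2, sds, "/")
  attr(out, "zero_variance") <- zero
  out
}

new_ec_map <- function(values, mask, iterations, converged, eigenvalue,
                       rayleigh, similarity) {
  map <- NULL
  if (!is.null(mask)) {
    map <- array(0, dim(mask))
    map[mask] <- values
  }
  structure(list(values = values, map = map, mask = mask,
                 iterations = iterations, converged = converged,
                 eigenvalue = eigenvalue, rayleigh_path = rayleigh,
                 similarity = similarity),
            class = "ec_map")
}

#' @export
print.ec_map <- function(x, ...) {
  cat(sprintf("<ec_map> %d voxels, eigenvalue %.6g, %s in %s iterations\n",
              length(x$values), x$eigenvalue,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              ifelse(is.na(x$iterations), "NA", x$iterations)))
  invisible(x)
}

#' Write an EC map as NIfTI with a JSON sidecar
#'
#' @param ec An `ec_map` (must carry a mask/3D map).
#' @param path Output NIfTI path; a `.json` sidecar with iterations,
#'   eigenvalue and convergence information is written alongside.
#' @param voxel_size Voxel size recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_ec_map <- function(ec, path, voxel_size = 1.2) {
  stopifnot(inherits(ec, "ec_map"), !is.null(ec$map))
  img <- RNifti::asNifti(structure(ec$map, pixdim = rep(voxel_size, 3)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(iterations = ec$iterations, eigenvalue = ec$eigenvalue,
         converged = ec$converged, similarity = ec$similarity),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-voxel centrality change between two sessions
#'
#' @param map_a,map_b `ec_map` objects of the same subject on the same
#'   grid (typically an earlier and a later session).
#' @param day_pair Optional length-2 character, e.g. `c("d1", "d5")`.
#' @return An object of class `ec_delta`: `values` (map_b minus map_a on
#'   the intersection mask), `mask`, `day_pair`.
#' @export
ec_delta <- function(map_a, map_b, day_pair = NULL) {
  stopifnot(inherits(map_a, "ec_map"), inherits(map_b, "ec_map"))
  if (is.null(map_a$mask) || is.null(map_b$mask) ||
      !identical(dim(map_a$mask), dim(map_b$mask))) {
    stop_invalid("EC maps must share one voxel grid")
  }
  if (!isTRUE(map_a$converged) || !isTRUE(map_b$converged)) {
    warning("computing a change map from non-converged EC maps")
  }
  inter <- map_a$mask & map_b$mask
  structure(list(values = map_b$map[inter] - map_a$map[inter],
                 mask = inter, day_pair = day_pair),
            class = "ec_delta")
}
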