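#' BOLD dataset container
#'
#' Bundles a 4D BOLD array with its repetition time, voxel size, tissue
#' masks and (optionally) motion parameters. Masks must be mutually
#' disjoint; the brain mask must be nonempty.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr Repetition time in seconds.
#' @param voxel_size Isotropic voxel size in mm.
#' @param brain_mask,wm_mask,csf_mask 3D logical/0-1 arrays on the same grid
#'   (white matter and CSF masks optional).
#' @param motion Optional t x 6 matrix (3 translations in mm, 3 rotations in
#'   radians).
#' @return An object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, tr, voxel_size = 1.2, brain_mask,
                         wm_mask = NULL, csf_mask = NULL, motion = NULL) {
  stopifnot(length(dim(data)) == 4L)
  assert_scalar_pos(tr, "tr")
  assert_scalar_pos(voxel_size, "voxel_size")
  if (dim(data)[4] < 2L) stop_invalid("need at least 2 volumes")
  grid <- dim(data)[1:3]
  as_mask <- function(m, name) {
    if (is.null(m)) return(NULL)
    if (!identical(dim(m), as.integer(grid))) {
      stop_invalid("%s does not match the data grid", name)
    }
    array(as.logical(m), dim = grid)
  }
  brain_mask <- as_mask(brain_mask, "brain_mask")
  wm_mask <- as_mask(wm_mask, "wm_mask")
  csf_mask <- as_mask(csf_mask, "csf_mask")
  if (!any(brain_mask)) stop_invalid("brain_mask is empty")
  for (pair in list(list(brain_mask, wm_mask, "brain/wm"),
                    list(brain_mask, csf_mask, "brain/csf"),
                    list(wm_mask, csf_mask, "wm/csf"))) {
    if (!is.null(pair[[1]]) && !is.null(pair[[2]]) &&
        any(pair[[1]] & pair[[2]])) {
      stop_invalid("masks overlap: %s", pair[[3]])
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != dim(data)[4] || ncol(motion) != 6L) {
      stop_invalid("motion must be a t x 6 matrix aligned to the volumes")
    }
  }
  structure(list(data = data, tr = tr, voxel_size = voxel_size,
                 brain_mask = brain_mask, wm_mask = wm_mask,
                 csf_mask = csf_mask, motion = motion),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_dataset> %dx%dx%d grid, %d volumes, TR %.3g s, %d brain voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$brain_mask)))
  invisible(x)
}

# Extract the t x V matrix of in-mask timecourses.
mask_matrix <- function(data4d, mask) {
  d <- dim(data4d)
  t(matrix(data4d, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE])
}

# Write a t x V matrix back into a 4D array (zeros elsewhere).
unmask_matrix <- function(Y, mask, grid) {
  flat <- matrix(0, prod(grid), nrow(Y))
  flat[as.vector(mask), ] <- t(Y)
  array(flat, c(grid, nrow(Y)))
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path Path to a NIfTI-1 file (.nii or .nii.gz) with 4 dimensions.
#'   The repetition time is taken from the header (pixdim\\[4\\]).
#' @param brain_mask,wm_mask,csf_mask Optional paths to mask NIfTIs.
#' @param motion Optional path to a motion-parameter TSV (6 columns).
#' @return A [bold_dataset()].
#' @export
read_bold <- function(path, brain_mask = NULL, wm_mask = NULL,
                      csf_mask = NULL, motion = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop_invalid("'%s' is %dD; a 4D BOLD series is required",
                 path, length(dim(arr)))
  }
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L) pd[4] else NA_real_
  if (!is.finite(tr) || tr <= 0) {
    stop_invalid("'%s' has no positive TR in its header", path)
  }
  read_mask <- function(p) {
    if (is.null(p)) return(NULL)
    as.array(RNifti::readNifti(p)) > 0.5
  }
  bm <- read_mask(brain_mask)
  if (is.null(bm)) bm <- array(TRUE, dim(arr)[1:3])
  mot <- if (!is.null(motion)) {
    as.matrix(utils::read.table(motion, header = TRUE, sep = "\t"))
  }
  bold_dataset(arr, tr = tr, voxel_size = pd[1],
               brain_mask = bm, wm_mask = read_mask(wm_mask),
               csf_mask = read_mask(csf_mask), motion = mot)
}

#' Write a BOLD dataset (and its masks) as NIfTI
#'
#' Data are stored as float32 with the TR in the header. Masks are written
#' next to the main file as `<stem>_brain.nii.gz` etc.; motion parameters
#' as `<stem>_motion.tsv`.
#'
#' @param bold A [bold_dataset()] or `cleaned_bold`.
#' @param path Output path (.nii or .nii.gz).
#' @param masks Write the mask/motion sidecars too?
#' @return Invisibly, `path`.
#' @export
write_bold <- function(bold, path, masks = TRUE) {
  vs <- bold$voxel_size %||% 1
  img <- RNifti::asNifti(structure(bold$data,
                                   pixdim = c(vs, vs, vs, bold$tr)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  if (masks) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    wm <- function(m, suffix) {
      if (is.null(m)) return()
      mi <- RNifti::asNifti(structure(array(as.numeric(m), dim(m)),
                                      pixdim = c(vs, vs, vs)),
                            datatype = "uint8")
      RNifti::writeNifti(mi, paste0(stem, "_", suffix, ".nii.gz"))
    }
    wm(bold$brain_mask, "brain")
    wm(bold$wm_mask, "wm")
    wm(bold$csf_mask, "csf")
    if (!is.null(bold$motion)) {
      mo <- as.data.frame(bold$motion)
      names(mo) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
      utils::write.table(mo, paste0(stem, "_motion.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
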