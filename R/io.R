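#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the voxel spacing in the header.
#' \code{writeNiftiVolume} accepts 2-D (slice), 3-D or 4-D arrays;
#' \code{readNiftiVolume} returns the array with a \code{pixdim}
#' attribute.
#'
#' @param data numeric array.
#' @param pixdim voxel spacing in mm, one value per spatial dimension.
#' @param path file path (.nii or .nii.gz).
#' @return \code{readNiftiVolume}: the array with attribute
#'   \code{pixdim}; \code{writeNiftiVolume}: the path, invisibly.
#' @export
writeNiftiVolume <- function(data, pixdim, path) {
  nd <- min(length(dim(data)), 3L)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- pixdim[seq_len(nd)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Read and write FSL-dialect b-tables
#'
#' The b-values as a single space-separated row (\code{<prefix>.bval})
#' and the b-vectors as three rows of N entries (\code{<prefix>.bvec}).
#'
#' @param bvals numeric vector.
#' @param bvecs N x 3 matrix of gradient directions.
#' @param prefix file path prefix.
#' @return \code{readBTable}: list with \code{bvals} and \code{bvecs};
#'   \code{writeBTable}: the two paths, invisibly.
#' @export
writeBTable <- function(bvals, bvecs, prefix) {
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3)
  bvalPath <- paste0(prefix, ".bval")
  bvecPath <- paste0(prefix, ".bvec")
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bvalPath)
  writeLines(apply(t(bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' @rdname writeBTable
#' @export
readBTable <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  raw <- scan(paste0(prefix, ".bvec"), quiet = TRUE)
  bvecs <- t(matrix(raw, nrow = 3, byrow = TRUE))
  colnames(bvecs) <- c("x", "y", "z")
  list(bvals = bvals, bvecs = bvecs)
}

#' Read and write the subject table
#'
#' Tab-separated with header \code{subject_id group age sex}.
#'
#' @param subjects data.frame.
#' @param path file path.
#' @return \code{readSubjectTable}: the data.frame;
#'   \code{writeSubjectTable}: the path, invisibly.
#' @export
writeSubjectTable <- function(subjects, path) {
  stopifnot(all(c("subject_id", "group", "age", "sex") %in%
                names(subjects)))
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSubjectTable
#' @export
readSubjectTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write streamlines as a tab-separated table
#'
#' One row per streamline point: \code{streamline_id area point_index x
#' y z} (mm coordinates).
#'
#' @param tracts list of \code{\linkS4class{TractSet}} objects.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeStreamlineTable <- function(tracts, path) {
  rows <- list()
  sid <- 0L
  for (t in tracts) {
    for (s in streamlines(t)) {
      sid <- sid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        streamline_id = sid, area = t@area,
        point_index = seq_len(nrow(s)),
        x = s[, 1], y = s[, 2], z = s[, 3])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
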