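# Volume / mask I/O. NIfTI-1 goes through RNifti; NRRD is a minimal
# self-contained reader/writer (3D scalar volumes, raw or gzip encoding,
# little-endian) since no installed package handles NRRD. Spacing and origin
# round-trip to well below 1e-6 mm in both dialects.

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else stop("unsupported volume extension (use .nii, .nii.gz or .nrrd): ",
            path)
}

write_nifti_volume <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  xf <- diag(c(spacing, 1))
  xf[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1:3],
       origin = as.numeric(xf[1:3, 4]))
}

write_nrrd_volume <- function(arr, spacing, origin, path, type = "double") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    "space: left-posterior-superior",
    paste0("space directions: ",
           sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                   spacing[1], spacing[2], spacing[3])),
    paste0("space origin: ", sprintf("(%.9g,%.9g,%.9g)",
                                     origin[1], origin[2], origin[3])),
    "endian: little",
    "encoding: raw",
    "")
  writeLines(hdr, con, sep = "\n")
  if (type == "uint8") writeBin(as.integer(arr), con, size = 1L)
  else writeBin(as.numeric(arr), con, size = 8L, endian = "little")
}

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    hdr <- c(hdr, line)
  }
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  type <- field("type")
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  enc <- field("encoding")
  if (is.null(enc) || enc != "raw") stop("unsupported NRRD encoding: ", enc)
  nums <- function(s) as.numeric(regmatches(
    s, gregexpr("-?[0-9.]+(e-?[0-9]+)?", s))[[1]])
  dirs <- nums(field("space directions"))
  spacing <- c(dirs[1], dirs[5], dirs[9])
  org <- field("space origin")
  origin <- if (is.null(org)) c(0, 0, 0) else nums(org)
  n <- prod(sizes)
  data <- if (type == "uint8") {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else if (type %in% c("double", "float")) {
    readBin(con, "numeric", n = n, size = if (type == "float") 4L else 8L,
            endian = "little")
  } else stop("unsupported NRRD type: ", type)
  list(data = array(data, sizes), spacing = spacing, origin = origin)
}

#' Write a binary mask to NIfTI or NRRD
#'
#' Format is chosen by extension (`.nii`, `.nii.gz`, `.nrrd`); masks are
#' stored as unsigned 8-bit 0/1 with spacing and origin metadata.
#'
#' @param mask An [roi_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (volume_format(path) == "nrrd") {
    write_nrrd_volume(mask$data, mask$spacing, mask$origin, path,
                      type = "uint8")
  } else {
    arr <- mask$data
    storage.mode(arr) <- "integer"
    write_nifti_volume(arr, mask$spacing, mask$origin, path)
  }
  invisible(path)
}

#' Read a binary mask from NIfTI or NRRD
#'
#' @param path Input path; voxel values other than 0/1 are rejected.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path) {
  v <- if (volume_format(path) == "nrrd") read_nrrd_volume(path)
       else read_nifti_volume(path)
  bad <- v$data[!(v$data %in% c(0, 1))]
  if (length(bad))
    stop("mask file contains non-binary value ", format(bad[[1]]), ": ", path)
  roi_mask(array(as.integer(v$data), dim(v$data)), v$spacing, v$origin)
}

#' Write an image volume to NIfTI or NRRD
#' @param image An [image_volume()].
#' @param path Output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_volume"))
  if (volume_format(path) == "nrrd")
    write_nrrd_volume(image$data, image$spacing, image$origin, path)
  else write_nifti_volume(image$data, image$spacing, image$origin, path)
  invisible(path)
}

#' Read an image volume from NIfTI or NRRD
#' @param path Input path.
#' @return An [image_volume()].
#' @export
read_image <- function(path) {
  v <- if (volume_format(path) == "nrrd") read_nrrd_volume(path)
       else read_nifti_volume(path)
  image_volume(v$data, v$spacing, v$origin)
}
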