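sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Save / load volumes as NIfTI with a JSON sidecar
#'
#' Volumes are written as NIfTI-1 (float64) with the voxel size in
#' `pixdim`; acquisition metadata (nucleus, TR, TE) and the world origin
#' live in a JSON sidecar next to the image, so the round trip is
#' bit-exact and independent of NIfTI header dialects.
#'
#' @param volume an [na_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `save_volume` returns `path` invisibly; `load_volume` the volume.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "na_volume"))
  if (any(is.na(volume$data)))
    stop("cannot save a volume with NA (absent) voxels")
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  meta <- list(nucleus = volume$nucleus, tr_ms = volume$tr_ms,
               te_ms = volume$te_ms, origin_mm = volume$origin_mm)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("not a 3-D volume: ", path, " has dimensions ",
         paste(d, collapse = "x"))
  data <- array(as.numeric(img), dim = d)
  if (any(!is.finite(data)))
    stop("volume contains non-finite values: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  meta <- list(nucleus = "NA23", tr_ms = NA_real_, te_ms = NA_real_,
               origin_mm = c(0, 0, 0))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    got <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  na_volume(data, voxel_size_mm = vox,
            origin_mm = as.numeric(unlist(meta$origin_mm)),
            nucleus = meta$nucleus,
            tr_ms = if (is.null(meta$tr_ms)) NA_real_ else meta$tr_ms,
            te_ms = if (is.null(meta$te_ms)) NA_real_ else meta$te_ms)
}

#' Save / load label maps as integer NIfTI with a JSON sidecar legend
#'
#' @param labelmap an [na_labelmap()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
save_label_map <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "na_labelmap"))
  img <- RNifti::asNifti(labelmap$labels)
  RNifti::pixdim(img) <- labelmap$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "int32")
  meta <- list(legend = as.list(labelmap$legend),
               origin_mm = labelmap$origin_mm)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_label_map
#' @export
load_label_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L) stop("not a 3-D label map: ", path)
  vals <- as.numeric(img)
  if (any(vals != round(vals)))
    stop("label map contains non-integer values: ", path)
  legend <- AT_LABELS
  origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    got <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(got$legend)) legend <- unlist(got$legend)
    if (!is.null(got$origin_mm)) origin <- as.numeric(got$origin_mm)
  }
  na_labelmap(array(as.integer(vals), dim = d),
              voxel_size_mm = RNifti::pixdim(img)[1:3],
              origin_mm = origin, legend = legend)
}

#' Write result records as CSV
#'
#' Stable column order, header always written (an empty record list gives
#' a header-only file), UTF-8.
#'
#' @param rows a data.frame, or a list of identically-named lists.
#' @param path output CSV path.
#' @export
write_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (length(rows)) {
      nms <- lapply(rows, names)
      if (any(vapply(nms, function(n) !identical(n, nms[[1]]), logical(1))))
        stop("ragged records: all rows must share the same field names")
      df <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      df <- data.frame()
    }
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
}
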