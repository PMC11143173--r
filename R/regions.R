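#' The canonical four-region audiovisual speech network
#'
#' Returns the fixed set of left-hemisphere regions over which all models are
#' defined: precentral gyrus (PrG, articulatory motor cortex), posterior
#' superior temporal gyrus (pSTG, multisensory integration), mid superior
#' temporal gyrus (mSTG, auditory speech), and fusiform gyrus (FuG, visual
#' lip-movement processing). The order of the labels fixes the row/column
#' order of every coupling matrix in the package (rows = targets, columns =
#' sources). MNI coordinates and the sphere radius are carried as metadata
#' only; no image handling happens in this package.
#'
#' @param names character vector of exactly 4 distinct region labels.
#' @param mni 4x3 integer matrix of MNI peak coordinates (rows follow
#'   `names`).
#' @param radius_mm sphere radius metadata in mm.
#' @return An object of class `region_set` with elements `names`, `roles`,
#'   `mni`, `radius_mm`.
#' @examples
#' speech_regions()
#' @export
speech_regions <- function(names = c("PrG", "pSTG", "mSTG", "FuG"),
                           mni = default_region_mni(),
                           radius_mm = 8) {
  if (length(names) != 4L || anyDuplicated(names))
    stop("a region set must contain exactly 4 distinct labels", call. = FALSE)
  mni <- as.matrix(mni)
  if (!all(dim(mni) == c(4L, 3L)))
    stop("mni must be a 4x3 coordinate matrix", call. = FALSE)
  rownames(mni) <- names
  colnames(mni) <- c("x", "y", "z")
  roles <- c("articulatory motor cortex",
             "multisensory speech integration",
             "auditory speech processing",
             "visual lip-movement processing")
  names(roles) <- names
  structure(list(names = names, roles = roles, mni = mni,
                 radius_mm = radius_mm),
            class = "region_set")
}

#' @rdname speech_regions
#' @export
default_region_mni <- function() {
  matrix(c(-54,   0,  48,
           -54, -39,  18,
           -54, -18,   3,
           -30, -78, -18),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("PrG", "pSTG", "mSTG", "FuG"), c("x", "y", "z")))
}

canonical_region_names <- c("PrG", "pSTG", "mSTG", "FuG")

is_canonical_regions <- function(regions) {
  inherits(regions, "region_set") &&
    identical(regions$names, canonical_region_names)
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set (", paste(x$names, collapse = ", "), ")\n", sep = "")
  for (nm in x$names)
    cat(sprintf("  %-5s %-34s MNI (%4d, %4d, %4d)\n", nm, x$roles[[nm]],
                x$mni[nm, 1], x$mni[nm, 2], x$mni[nm, 3]))
  cat("  sphere radius:", x$radius_mm, "mm (metadata)\n")
  invisible(x)
}
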