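#' Landmark configuration
#'
#' A single digitized vertebra: a matrix of 3D landmark coordinates plus
#' specimen-level metadata. Coordinates are in the original (arbitrary)
#' scanner units until Procrustes superimposition.
#'
#' @param coords numeric matrix, landmarks x 3.
#' @param specimen_id character scalar, unique within a vertebral position.
#' @param species character scalar, binomial or any consistent species key.
#' @param position vertebral position label; one of
#'   `CF, CM, CL, TF, TM, TD, TL, LF, LM, LL` (first/middle/last vertebra of
#'   the cervical, thoracic and lumbar regions, plus the diaphragmatic
#'   thoracic TD), or `NA` when not yet assigned.
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id, species = specimen_id,
                            position = NA_character_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("landmark coordinates must have 3 columns (x, y, z), got ",
         ncol(coords))
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in configuration '", specimen_id, "'")
  if (!is.na(position) && !position %in% VERTEBRAL_POSITIONS)
    stop("unknown vertebral position '", position, "'; expected one of ",
         paste(VERTEBRAL_POSITIONS, collapse = ", "))
  structure(
    list(coords = unname(coords),
         specimen_id = as.character(specimen_id),
         species = as.character(species),
         position = as.character(position)),
    class = "landmark_config")
}

#' Recognised vertebral position labels
#'
#' First/middle/last sampled vertebra of each presacral region plus the
#' diaphragmatic thoracic vertebra (TD).
#' @export
VERTEBRAL_POSITIONS <- c("CF", "CM", "CL",
                         "TF", "TM", "TD", "TL",
                         "LF", "LM", "LL")

#' Landmark dataset
#'
#' An ordered collection of [landmark_config()] objects spanning specimens
#' and vertebral positions. Within a position all configurations must share
#' one landmark count and specimen ids must be unique.
#'
#' @param configurations list of `landmark_config` objects.
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(configurations) {
  if (!is.list(configurations) ||
      !all(vapply(configurations, inherits, logical(1), "landmark_config")))
    stop("'configurations' must be a list of landmark_config objects")
  ds <- structure(list(configurations = configurations),
                  class = "landmark_dataset")
  validate_landmark_dataset(ds)
  ds
}

validate_landmark_dataset <- function(ds) {
  pos <- positions(ds)
  for (p in unique(pos)) {
    idx <- if (is.na(p)) which(is.na(pos)) else which(pos == p)
    sel <- ds$configurations[idx]
    nl <- vapply(sel, function(cf) nrow(cf$coords), integer(1))
    if (length(unique(nl)) > 1L)
      stop("position '", p, "' mixes landmark counts: ",
           paste(unique(nl), collapse = ", "))
    ids <- vapply(sel, `[[`, character(1), "specimen_id")
    if (anyDuplicated(ids))
      stop("duplicate specimen_id within position '", p, "': ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(ds)
}

#' @export
length.landmark_dataset <- function(x) length(x$configurations)

#' Specimen ids, species and positions of a dataset
#' @param ds a `landmark_dataset`.
#' @return character vector, one entry per configuration.
#' @export
specimen_ids <- function(ds) {
  vapply(ds$configurations, `[[`, character(1), "specimen_id")
}

#' @rdname specimen_ids
#' @export
species_of <- function(ds) {
  vapply(ds$configurations, `[[`, character(1), "species")
}

#' @rdname specimen_ids
#' @export
positions <- function(ds) {
  vapply(ds$configurations, `[[`, character(1), "position")
}

#' Subset a dataset to one vertebral position
#' @param ds a `landmark_dataset`.
#' @param position position label.
#' @return a `landmark_dataset` holding only that position's configurations.
#' @export
subset_position <- function(ds, position) {
  keep <- positions(ds) == position
  if (!any(keep))
    stop("no configurations at position '", position, "'")
  landmark_dataset(ds$configurations[keep])
}

#' Stack a dataset into a landmarks x 3 x specimens array
#'
#' All configurations must share one landmark count (subset to one position
#' first if needed). The geomorph-style p x k x n layout.
#'
#' @param ds a `landmark_dataset`.
#' @return numeric array with dimnames on the third margin = specimen ids.
#' @export
as_coord_array <- function(ds) {
  nl <- vapply(ds$configurations, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(nl)) > 1L)
    stop("configurations mix landmark counts (",
         paste(unique(nl), collapse = ", "),
         "); subset to one position first")
  n <- length(ds)
  a <- array(NA_real_, c(nl[1], 3L, n),
             dimnames = list(NULL, c("x", "y", "z"), specimen_ids(ds)))
  for (i in seq_len(n)) a[, , i] <- ds$configurations[[i]]$coords
  a
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("landmark_config: ", x$specimen_id, " (", x$species, "), position ",
      x$position, ", ", nrow(x$coords), " landmarks\n", sep = "")
  invisible(x)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  pos <- positions(x)
  cat("landmark_dataset: ", length(x), " configurations, ",
      length(unique(species_of(x))), " species\n", sep = "")
  if (length(x)) {
    tab <- table(pos)
    cat("  positions: ",
        paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}
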