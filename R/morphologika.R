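#' Read a Morphologika landmark file
#'
#' Morphologika is a plain-text landmark interchange format declaring the
#' number of individuals, landmarks and dimensions, followed by optional
#' `[names]`, `[labels]`/`[labelvalues]` blocks and the coordinate block.
#' Two dialects are accepted: the bracketed one (`[Individuals]`,
#' `[landmarks]`, `[dimensions]`, ...) and a bare-count one whose first three
#' non-empty lines are the individual, landmark and dimension counts followed
#' directly by coordinates.
#'
#' Species and vertebral-position metadata are taken from `[labels]` columns
#' named (case-insensitively) `species` and `position` when present;
#' otherwise species defaults to the specimen name.
#'
#' @param path path to a Morphologika file.
#' @return a [landmark_dataset()].
#' @export
read_morphologika <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw)
  nonempty <- which(lines != "")
  if (!length(nonempty)) stop("empty Morphologika file: ", path)

  if (startsWith(tolower(lines[nonempty[1]]), "["))
    parse_morphologika_bracketed(lines, path)
  else
    parse_morphologika_bare(lines, path)
}

parse_int_line <- function(lines, i, what) {
  v <- suppressWarnings(as.integer(lines[i]))
  if (is.na(v) || v < 1L)
    stop("line ", i, ": expected a positive integer for ", what,
         ", got '", lines[i], "'")
  v
}

parse_morphologika_bracketed <- function(lines, path) {
  is_key <- grepl("^\\[.+\\]$", lines)
  keys <- tolower(gsub("^\\[(.+)\\]$", "\\1", lines))
  keys[!is_key] <- NA

  section <- function(name) {
    i <- which(is_key & keys == name)
    if (length(i) > 1L)
      stop("duplicate [", name, "] section in ", path)
    if (!length(i)) return(NULL)
    j <- i + 1L
    nxt <- which(is_key & seq_along(lines) > i)
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    idx <- j:end
    idx[lines[idx] != ""]
  }

  ind_idx <- section("individuals")
  lm_idx <- section("landmarks")
  dim_idx <- section("dimensions")
  if (is.null(ind_idx) || is.null(lm_idx) || is.null(dim_idx))
    stop("malformed Morphologika header in ", path,
         ": need [Individuals], [landmarks] and [dimensions]")
  n_ind <- parse_int_line(lines, ind_idx[1], "[Individuals]")
  n_lm <- parse_int_line(lines, lm_idx[1], "[landmarks]")
  n_dim <- parse_int_line(lines, dim_idx[1], "[dimensions]")
  if (n_dim != 3L)
    stop("line ", dim_idx[1], ": only 3-dimensional landmark data supported, ",
         "file declares ", n_dim)

  names_idx <- section("names")
  ids <- if (is.null(names_idx)) sprintf("ind_%d", seq_len(n_ind))
         else lines[names_idx]
  if (length(ids) != n_ind)
    stop("[names] block lists ", length(ids), " individuals but header ",
         "declares ", n_ind)

  labels_idx <- section("labels")
  labval_idx <- section("labelvalues")
  species <- ids
  posn <- rep(NA_character_, n_ind)
  if (!is.null(labels_idx) && !is.null(labval_idx)) {
    lab_names <- tolower(strsplit(paste(lines[labels_idx], collapse = " "),
                                  "\\s+")[[1]])
    vals <- strsplit(lines[labval_idx], "\\s+")
    if (length(vals) != n_ind)
      stop("[labelvalues] lists ", length(vals), " rows but header declares ",
           n_ind, " individuals")
    for (i in seq_len(n_ind)) {
      if (length(vals[[i]]) != length(lab_names))
        stop("line ", labval_idx[i], ": expected ", length(lab_names),
             " label values, got ", length(vals[[i]]))
    }
    valmat <- do.call(rbind, vals)
    if ("species" %in% lab_names)
      species <- gsub("_", " ", valmat[, match("species", lab_names)])
    if ("position" %in% lab_names)
      posn <- valmat[, match("position", lab_names)]
  }

  raw_idx <- section("rawpoints")
  if (is.null(raw_idx)) stop("missing [rawpoints] section in ", path)
  # drop per-individual separator lines (start with ' in the wild)
  coord_idx <- raw_idx[!startsWith(lines[raw_idx], "'")]
  read_coord_block(lines, coord_idx, n_ind, n_lm, ids, species, posn)
}

parse_morphologika_bare <- function(lines, path) {
  idx <- which(lines != "")
  if (length(idx) < 3L) stop("truncated Morphologika file: ", path)
  n_ind <- parse_int_line(lines, idx[1], "individual count")
  n_lm <- parse_int_line(lines, idx[2], "landmark count")
  n_dim <- parse_int_line(lines, idx[3], "dimension count")
  if (n_dim != 3L)
    stop("line ", idx[3], ": only 3-dimensional landmark data supported")
  body <- idx[-(1:3)]
  coord_idx <- body[!startsWith(lines[body], "'")]
  ids <- sprintf("ind_%d", seq_len(n_ind))
  read_coord_block(lines, coord_idx, n_ind, n_lm, ids, ids,
                   rep(NA_character_, n_ind))
}

read_coord_block <- function(lines, coord_idx, n_ind, n_lm, ids, species,
                             posn) {
  if (length(coord_idx) != n_ind * n_lm)
    stop("coordinate block has ", length(coord_idx), " rows; header declares ",
         n_ind, " individuals x ", n_lm, " landmarks = ", n_ind * n_lm)
  configs <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    rows <- coord_idx[((i - 1L) * n_lm + 1L):(i * n_lm)]
    m <- matrix(NA_real_, n_lm, 3L)
    for (r in seq_along(rows)) {
      v <- suppressWarnings(as.numeric(strsplit(lines[rows[r]], "[\\s,]+",
                                                perl = TRUE)[[1]]))
      if (length(v) != 3L || anyNA(v))
        stop("line ", rows[r], ": expected 3 numeric coordinates, got '",
             lines[rows[r]], "'")
      m[r, ] <- v
    }
    configs[[i]] <- landmark_config(m, ids[i], species[i], posn[i])
  }
  landmark_dataset(configs)
}

#' Write a landmark dataset as a Morphologika file
#'
#' Emits the bracketed dialect with `[names]` and, when any metadata is
#' present, `[labels] species position` / `[labelvalues]`. Coordinates are
#' written at full double precision so a read/write round trip reproduces
#' them exactly.
#'
#' @param ds a [landmark_dataset()]; all configurations must share one
#'   landmark count.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_morphologika <- function(ds, path) {
  if (!inherits(ds, "landmark_dataset")) stop("'ds' must be a landmark_dataset")
  if (!length(ds)) stop("refusing to write an empty dataset")
  nl <- vapply(ds$configurations, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(nl)) > 1L)
    stop("heterogeneous landmark counts (",
         paste(unique(nl), collapse = ", "), "); cannot write one file")
  n <- length(ds)
  ids <- specimen_ids(ds)
  sp <- gsub(" ", "_", species_of(ds))
  posn <- positions(ds)
  posn[is.na(posn)] <- "NA"
  out <- c("[Individuals]", n, "[landmarks]", nl[1], "[dimensions]", 3,
           "[names]", ids,
           "[labels]", "species position",
           "[labelvalues]", paste(sp, posn),
           "[rawpoints]")
  for (i in seq_len(n)) {
    cf <- ds$configurations[[i]]
    out <- c(out, paste0("'", cf$specimen_id),
             apply(cf$coords, 1L,
                   function(r) paste(sprintf("%.17g", r), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
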