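#' Ecological category levels
#'
#' Running speed follows the fast / intermediate (half-bound) / slow scheme;
#' hunting mode the pursuit / ambush / pounce / occasional scheme.
#' @export
SPEED_LEVELS <- c("fast", "intermediate", "slow")

#' @rdname SPEED_LEVELS
#' @export
HUNTING_LEVELS <- c("pursuit", "ambush", "pounce", "occasional")

# 1-based landmark indices dropped per region to reach the common
# 30-landmark scheme.
CONSOLIDATION_DROPS <- list(
  cervical = c(16L, 17L, 33L, 34L),  # 34 -> 30
  thoracic = c(16L, 17L),            # 32 -> 30
  lumbar   = c(16L, 17L, 18L, 19L, 35L, 36L)  # 36 -> 30
)

CONSOLIDATION_INPUT <- c(cervical = 34L, thoracic = 32L, lumbar = 36L)

#' Consolidate a regional landmarking scheme to 30 landmarks
#'
#' The full digitizing protocol uses 34 landmarks on cervical, 32 on thoracic
#' and 36 on lumbar vertebrae. For cross-element comparability each region is
#' reduced to the same 30 landmarks by dropping region-specific points
#' (1-based indices): cervical 16, 17, 33, 34; thoracic 16, 17; lumbar 16,
#' 17, 18, 19, 35, 36. The relative order of retained landmarks is preserved.
#'
#' @param config a [landmark_config()] with the full regional landmark count.
#' @param region one of `"cervical"`, `"thoracic"`, `"lumbar"`.
#' @return a `landmark_config` with exactly 30 landmarks.
#' @export
consolidate_landmarks <- function(config,
                                  region = c("cervical", "thoracic",
                                             "lumbar")) {
  region <- match.arg(region)
  if (!inherits(config, "landmark_config"))
    stop("'config' must be a landmark_config")
  need <- CONSOLIDATION_INPUT[[region]]
  if (nrow(config$coords) != need)
    stop(region, " consolidation expects ", need, " landmarks, got ",
         nrow(config$coords))
  keep <- setdiff(seq_len(need), CONSOLIDATION_DROPS[[region]])
  landmark_config(config$coords[keep, , drop = FALSE],
                  config$specimen_id, config$species, config$position)
}

#' Pick first, middle and last vertebra indices per region
#'
#' Subsampling protocol for columns with varying vertebral counts: within
#' each region take the first, middle and last vertebra; for an even count
#' `n` the "middle" is the vertebra after the midpoint, index `n/2 + 1`.
#' Cervical counts refer to the C3..Cn candidates (C1 and C2 are excluded
#' upstream for their atypical morphology), so a count of 5 selects C3, C5
#' and C7. The diaphragmatic thoracic vertebra (TD) is anatomical metadata
#' supplied per specimen, not computed here.
#'
#' @param region_counts named list/vector with entries `cervical`,
#'   `thoracic`, `lumbar`: number of candidate vertebrae per region.
#' @return named integer vector of ordinal indices within each region for
#'   positions CF, CM, CL, TF, TM, TL, LF, LM, LL.
#' @export
select_positions <- function(region_counts) {
  need <- c("cervical", "thoracic", "lumbar")
  if (!all(need %in% names(region_counts)))
    stop("region_counts must name cervical, thoracic and lumbar counts")
  pick <- function(n, region) {
    n <- as.integer(n)
    if (n < 3L)
      stop(region, " count ", n,
           " < 3: cannot pick distinct first/middle/last vertebrae")
    mid <- if (n %% 2L == 0L) n %/% 2L + 1L else (n + 1L) %/% 2L
    c(first = 1L, middle = mid, last = n)
  }
  cv <- pick(region_counts[["cervical"]], "cervical")
  th <- pick(region_counts[["thoracic"]], "thoracic")
  lu <- pick(region_counts[["lumbar"]], "lumbar")
  c(CF = cv[["first"]], CM = cv[["middle"]], CL = cv[["last"]],
    TF = th[["first"]], TM = th[["middle"]], TL = th[["last"]],
    LF = lu[["first"]], LM = lu[["middle"]], LL = lu[["last"]])
}

#' Read a species ecology table
#'
#' Delimited text with header columns `species`, `speed`, `hunting`.
#' Speed levels are `fast`, `intermediate`, `slow`; the literature synonym
#' `half-bound` (any of `half-bound`, `half_bound`, `halfbound`) is mapped to
#' `intermediate`. Hunting levels are `pursuit`, `ambush`, `pounce`,
#' `occasional`.
#'
#' @param path path to a CSV (or other single-character-delimited) file.
#' @param sep field separator, default comma.
#' @return a data.frame of class `ecology_table` with character columns
#'   `species`, `speed`, `hunting`, one row per species.
#' @export
read_ecology_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("species", "speed", "hunting")
  if (!all(need %in% names(df)))
    stop("ecology table must have columns species, speed, hunting; found: ",
         paste(names(df), collapse = ", "))
  df <- df[need]
  df$speed <- tolower(trimws(df$speed))
  df$hunting <- tolower(trimws(df$hunting))
  df$speed[df$speed %in% c("half-bound", "half_bound", "halfbound")] <-
    "intermediate"
  bad_sp <- which(!df$speed %in% SPEED_LEVELS)
  if (length(bad_sp))
    stop("unknown speed level(s) in row(s) ",
         paste(bad_sp, collapse = ", "), ": ",
         paste(unique(df$speed[bad_sp]), collapse = ", "))
  bad_h <- which(!df$hunting %in% HUNTING_LEVELS)
  if (length(bad_h))
    stop("unknown hunting level(s) in row(s) ",
         paste(bad_h, collapse = ", "), ": ",
         paste(unique(df$hunting[bad_h]), collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicate species rows: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  class(df) <- c("ecology_table", "data.frame")
  df
}
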