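#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree with total root-to-tip depth normalized to 1, so
#' Brownian rates are per total tree depth. Reproducible given a seed.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @return an ultrametric `ape::phylo` with tips `sp01, sp02, ...`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tree
}

random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Deterministic non-degenerate template vertebra
#'
#' A helical 30-landmark template (unit centroid size) used as the base
#' shape of the simulator. `variant` perturbs the helix pitch/radius so each
#' vertebral position gets a distinct but reproducible template.
#'
#' @param n_landmarks number of landmarks (default 30).
#' @param variant integer selecting a deterministic variant.
#' @return landmarks x 3 matrix, centered, unit centroid size.
#' @export
base_vertebra_shape <- function(n_landmarks = 30L, variant = 1L) {
  t <- seq(0, 4 * pi, length.out = n_landmarks)
  rad <- 1 + 0.25 * sin((variant %% 5 + 1) * t / 4)
  m <- cbind(rad * cos(t), rad * sin(t),
             (0.5 + 0.1 * variant) * t / (4 * pi))
  m <- center_config(m)
  m / centroid_size(m)
}

# project a 90-vector onto the "pure shape" subspace: orthogonal to the
# three per-axis translation directions and the radial (scale) direction at
# the base shape
pure_shape_projection <- function(v, base) {
  p <- nrow(base)
  basis <- cbind(
    as.vector(matrix(rep(c(1, 0, 0), each = p), ncol = 3)),
    as.vector(matrix(rep(c(0, 1, 0), each = p), ncol = 3)),
    as.vector(matrix(rep(c(0, 0, 1), each = p), ncol = 3)),
    as.vector(base))
  basis <- qr.Q(qr(basis))
  v - basis %*% crossprod(basis, v)
}

#' Ground truth for a synthetic vertebral dataset
#'
#' Fixes everything the generator needs: a pure-birth phylogeny, balanced
#' random speed (3 levels) and hunting (4 levels) assignments drawn
#' independently of each other and of the tree, and per-level "pure shape"
#' effect vectors (orthogonal to translation and scale directions) of given
#' magnitude. Shape deviations evolve by Brownian motion (rate `sigma_bm^2`
#' per unit tree depth, i.i.d. across the 3p shape coordinates) and
#' specimens add isotropic digitizing noise `sigma_noise`.
#'
#' Default magnitudes: `sigma_bm = 0.03` Procrustes units over the tree
#' depth, `sigma_noise = 0.01`, a speed effect of `3 * sigma_bm` and a
#' weaker hunting effect of `1.5 * sigma_bm` (displacement-vector norms in
#' Procrustes units), mirroring a system where running speed carries the
#' stronger vertebral signal.
#'
#' @param n_species number of species (default 43).
#' @param positions vertebral position labels to simulate.
#' @param n_landmarks landmarks per vertebra.
#' @param sigma_bm Brownian-motion SD per unit tree depth (shape units).
#' @param sigma_noise within-species (digitizing) SD per coordinate.
#' @param speed_effect,hunting_effect norms of the per-level displacement
#'   vectors.
#' @param seed integer seed.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(n_species = 43L,
                             positions = VERTEBRAL_POSITIONS,
                             n_landmarks = 30L,
                             sigma_bm = 0.03,
                             sigma_noise = 0.01,
                             speed_effect = 3 * sigma_bm,
                             hunting_effect = 1.5 * sigma_bm,
                             seed = 1L) {
  stopifnot(sigma_bm >= 0, sigma_noise >= 0,
            speed_effect >= 0, hunting_effect >= 0)
  tree <- simulate_tree(n_species, seed)
  species <- tree$tip.label
  # balanced random, mutually independent category assignments
  speed <- sample(rep_len(SPEED_LEVELS, n_species))
  hunting <- sample(rep_len(HUNTING_LEVELS, n_species))
  bases <- lapply(seq_along(positions), function(i)
    base_vertebra_shape(n_landmarks, variant = i))
  names(bases) <- positions
  mk_effects <- function(levels, magnitude, base) {
    out <- lapply(levels, function(l) {
      v <- pure_shape_projection(stats::rnorm(3L * nrow(base)), base)
      drop(v / sqrt(sum(v^2)) * magnitude)
    })
    names(out) <- levels
    out
  }
  effects <- lapply(positions, function(p) list(
    speed = mk_effects(SPEED_LEVELS, speed_effect, bases[[p]]),
    hunting = mk_effects(HUNTING_LEVELS, hunting_effect, bases[[p]])))
  names(effects) <- positions
  structure(
    list(tree = tree, species = species,
         speed = stats::setNames(speed, species),
         hunting = stats::setNames(hunting, species),
         base_shapes = bases, effects = effects,
         sigma_bm = sigma_bm, sigma_noise = sigma_noise,
         speed_effect = speed_effect, hunting_effect = hunting_effect,
         seed = seed),
    class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth: ", length(x$species), " species x ",
      length(x$base_shapes), " positions; sigma_bm = ", x$sigma_bm,
      ", sigma_noise = ", x$sigma_noise, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

species_mean_vector <- function(truth, position, species) {
  base <- as.vector(truth$base_shapes[[position]])
  eff <- truth$effects[[position]]
  base + eff$speed[[truth$speed[[species]]]] +
    eff$hunting[[truth$hunting[[species]]]]
}

#' Simulate a landmark dataset with known structure
#'
#' Species mean shapes are `base + BM deviate + speed effect + hunting
#' effect`; Brownian deviates are drawn with covariance `sigma_bm^2 * C`
#' across species (C from [bm_covariance()]) independently for each of the
#' 3p coordinates. Each specimen adds isotropic noise and is then given a
#' random rigid motion and scale (species log-sizes evolve by Brownian
#' motion around scanner-scale 50), so superimposition has real work to do.
#' Optionally writes Morphologika, Newick, ecology CSV and a truth summary
#' JSON to `dir`.
#'
#' @param truth a [simulation_truth()].
#' @param n_specimens_per_species 1 or 2 specimens per species (vector
#'   recycled over species).
#' @param positions subset of the truth's positions to emit.
#' @param seed integer seed for this draw.
#' @param dir optional output directory for file artifacts.
#' @return list with `dataset` ([landmark_dataset()]), `ecology`
#'   (`ecology_table`), `tree`, `truth`, and (if `dir` given) `files`.
#' @export
simulate_dataset <- function(truth, n_specimens_per_species = 1L,
                             positions = names(truth$base_shapes),
                             seed = truth$seed, dir = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!all(positions %in% names(truth$base_shapes)))
    stop("unknown position(s): ",
         paste(setdiff(positions, names(truth$base_shapes)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  species <- truth$species
  ns <- length(species)
  nspec <- rep_len(as.integer(n_specimens_per_species), ns)
  C <- bm_covariance(truth$tree, species)
  L <- t(chol(C + diag(1e-12, ns)))
  # species scanner sizes: BM on log size
  log_size <- log(50) + drop(L %*% stats::rnorm(ns)) * 0.2
  p <- nrow(truth$base_shapes[[positions[1]]])
  configs <- list()
  for (pos in positions) {
    dev <- L %*% matrix(stats::rnorm(ns * 3L * p), ns) * truth$sigma_bm
    for (s in seq_len(ns)) {
      mu <- species_mean_vector(truth, pos, species[s]) + dev[s, ]
      for (r in seq_len(nspec[s])) {
        v <- mu + stats::rnorm(3L * p) * truth$sigma_noise
        m <- matrix(v, ncol = 3L)
        m <- m * exp(log_size[s] + stats::rnorm(1, 0, 0.02))
        m <- m %*% random_rotation()
        m <- sweep(m, 2L, stats::runif(3L, -100, 100), `+`)
        id <- sprintf("%s_%d", species[s], r)
        configs[[length(configs) + 1L]] <-
          landmark_config(m, id, species[s], pos)
      }
    }
  }
  ds <- landmark_dataset(configs)
  eco <- data.frame(species = species,
                    speed = unname(truth$speed[species]),
                    hunting = unname(truth$hunting[species]),
                    stringsAsFactors = FALSE)
  class(eco) <- c("ecology_table", "data.frame")
  out <- list(dataset = ds, ecology = eco, tree = truth$tree, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(landmarks = file.path(dir, "landmarks.txt"),
               ecology = file.path(dir, "ecology.csv"),
               tree = file.path(dir, "tree.nwk"),
               truth = file.path(dir, "truth.json"))
    write_morphologika(ds, files[["landmarks"]])
    utils::write.csv(eco, files[["ecology"]], row.names = FALSE)
    ape::write.tree(truth$tree, files[["tree"]])
    jsonlite::write_json(
      list(n_species = length(species), positions = positions,
           sigma_bm = truth$sigma_bm, sigma_noise = truth$sigma_noise,
           speed_effect = truth$speed_effect,
           hunting_effect = truth$hunting_effect,
           seed = truth$seed,
           speed = as.list(truth$speed), hunting = as.list(truth$hunting)),
      files[["truth"]], auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}

#' Draw a pseudo-fossil configuration at a known group mean
#'
#' Stands in for an extinct specimen of known ecology: the configuration is
#' the chosen category level's mean shape (base + effect vector, no
#' phylogenetic deviate) plus isotropic noise, under a random rigid motion
#' and scale. It is never part of any training set.
#'
#' @param truth a [simulation_truth()].
#' @param group a level of either the speed or the hunting category.
#' @param position vertebral position label.
#' @param sigma_noise noise SD (defaults to the truth's).
#' @param seed integer seed.
#' @return a [landmark_config()] with specimen id `fossil_<group>`.
#' @export
make_pseudofossil <- function(truth, group, position = names(
                                truth$base_shapes)[1],
                              sigma_noise = truth$sigma_noise, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  eff <- truth$effects[[position]]
  if (is.null(eff)) stop("unknown position '", position, "'")
  avg <- function(vs) Reduce(`+`, vs) / length(vs)
  # the group mean over a balanced population carries the average effect of
  # the other (crossed) category
  if (group %in% SPEED_LEVELS) vec <- eff$speed[[group]] + avg(eff$hunting)
  else if (group %in% HUNTING_LEVELS) vec <- eff$hunting[[group]] +
      avg(eff$speed)
  else stop("unknown group '", group, "'; expected a speed or hunting level")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(truth$base_shapes[[position]])
  v <- as.vector(truth$base_shapes[[position]]) + vec +
    stats::rnorm(3L * p) * sigma_noise
  m <- matrix(v, ncol = 3L) * stats::runif(1, 30, 80)
  m <- m %*% random_rotation()
  m <- sweep(m, 2L, stats::runif(3L, -100, 100), `+`)
  landmark_config(m, paste0("fossil_", group), paste0("fossil_", group),
                  position)
}
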