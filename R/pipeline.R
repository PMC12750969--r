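default_pipeline_config <- function() {
  list(
    output_dir = "vertecol_run",
    seed = 1L,
    positions = NULL,            # default: every position in the data
    combinations = list(),       # named list, e.g. list(all = c("TF","LM"))
    analyses = list(permanova = TRUE, pgls = TRUE, cva = TRUE,
                    fossil = TRUE),
    n_permutations = 999L,
    report_alpha = 0.005,        # reporting convention for significance
    strong_support = 0.95,
    cva_variance_threshold = 0.95,
    scale_blocks = TRUE,
    species_mean = "after_gpa",  # or "before_gpa"
    tangent = FALSE,
    input = list(landmarks = NULL, ecology = NULL, tree = NULL,
                 fossil_landmarks = NULL)
  )
}

#' Build or load a pipeline run configuration
#'
#' Either pass a named list of overrides or the path of a YAML file with the
#' same structure. Unknown keys are an error; unspecified keys take package
#' defaults. Use [write_config_template()] to generate a commented template.
#'
#' @param x named list of settings or path to a YAML file.
#' @return validated config list of class `run_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  cfg <- default_pipeline_config()
  bad <- setdiff(names(x), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(x)) {
    if (k %in% c("analyses", "input"))
      cfg[[k]] <- utils::modifyList(cfg[[k]], as.list(x[[k]]))
    else cfg[[k]] <- x[[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_permutations <- as.integer(cfg$n_permutations)
  if (!cfg$species_mean %in% c("after_gpa", "before_gpa"))
    stop("species_mean must be 'after_gpa' or 'before_gpa'")
  structure(cfg, class = "run_config")
}

#' Write a commented configuration template
#'
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path = "vertecol_config.yaml") {
  cfg <- default_pipeline_config()
  cfg$positions <- c("CF", "LF")
  cfg$combinations <- list(all = c("CF", "LF"))
  cfg$input <- list(landmarks = "landmarks.txt", ecology = "ecology.csv",
                    tree = "tree.nwk", fossil_landmarks = NULL)
  writeLines(c(
    "# vertecol pipeline configuration (all keys optional except input paths)",
    yaml::as.yaml(cfg)), path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

species_block <- function(ds_pos, cfg) {
  if (cfg$species_mean == "before_gpa") {
    # per-species superimposition and averaging first, then a global GPA of
    # the species mean shapes
    spp <- species_of(ds_pos)
    configs <- lapply(unique(spp), function(s) {
      sel <- which(spp == s)
      if (length(sel) == 1L) {
        cf <- ds_pos$configurations[[sel]]
        m <- center_config(cf$coords) / centroid_size(cf$coords)
        return(landmark_config(m, s, s, cf$position))
      }
      sub <- landmark_dataset(ds_pos$configurations[sel])
      blk <- generalized_procrustes(sub, tangent = cfg$tangent)
      landmark_config(apply(blk$aligned, c(1, 2), mean), s, s,
                      ds_pos$configurations[[sel[1]]]$position)
    })
    blk <- generalized_procrustes(landmark_dataset(configs),
                                  tangent = cfg$tangent)
    # centroid sizes: species means of the raw sizes
    raw <- vapply(ds_pos$configurations, function(cf)
      centroid_size(cf$coords), numeric(1))
    blk$centroid_sizes <- stats::setNames(
      vapply(blk$specimen_ids, function(s) mean(raw[spp == s]), numeric(1)),
      blk$specimen_ids)
    blk
  } else {
    blk <- generalized_procrustes(ds_pos, tangent = cfg$tangent)
    species_mean_shapes(blk)
  }
}

analyse_space <- function(label, scores_matrix, space, sizes, eco, tree, cfg,
                          out, results) {
  species <- rownames(scores_matrix)
  eco_row <- eco[match(species, eco$species), ]
  seed <- cfg$seed

  if (isTRUE(cfg$analyses$permanova)) {
    run_stage(paste0("permanova:", label), {
      rows <- list()
      for (cat in c("speed", "hunting")) {
        grp <- eco_row[[cat]]
        glob <- permanova(scores_matrix, grp, n_perm = cfg$n_permutations,
                          seed = seed)
        pw <- pairwise_permanova(scores_matrix, grp,
                                 n_perm = cfg$n_permutations, seed = seed)
        gdf <- as.data.frame(glob)
        gdf$p_adjusted <- NA_real_
        rows[[cat]] <- cbind(category = cat,
                             rbind(gdf[names(pw)], pw))
      }
      tab <- do.call(rbind, rows)
      tab$significant <- !is.na(tab$p_value) & tab$p_value <= cfg$report_alpha
      utils::write.csv(tab, file.path(out, paste0("permanova_", label,
                                                  ".csv")),
                       row.names = FALSE)
      results$permanova[[label]] <- tab
    })
  }

  if (isTRUE(cfg$analyses$pgls) && !is.null(tree)) {
    run_stage(paste0("pgls:", label), {
      in_tree <- species %in% tree$tip.label
      if (!all(in_tree))
        warning("dropping species absent from the tree: ",
                paste(species[!in_tree], collapse = ", "), call. = FALSE)
      sp <- species[in_tree]
      C <- bm_covariance(prune_tree(tree, sp), sp)
      Y <- scores_matrix[sp, , drop = FALSE]
      er <- eco_row[in_tree, ]
      fits <- list(
        speed = pgls_fit(Y, factor(er$speed), C, cfg$n_permutations,
                         seed = seed, predictor = "speed"),
        hunting = pgls_fit(Y, factor(er$hunting), C, cfg$n_permutations,
                           seed = seed + 1L, predictor = "hunting"),
        centroid_size = pgls_fit(Y, log(sizes[sp]), C, cfg$n_permutations,
                                 seed = seed + 2L,
                                 predictor = "centroid_size"))
      tab <- do.call(rbind, lapply(fits, as.data.frame))
      tab <- cbind(block = label, tab)
      tab$significant <- tab$p_value <= cfg$report_alpha
      utils::write.csv(tab, file.path(out, paste0("pgls_", label, ".csv")),
                       row.names = FALSE)
      results$pgls[[label]] <- tab
    })
  }

  models <- list()
  if (isTRUE(cfg$analyses$cva)) {
    run_stage(paste0("cva:", label), {
      rows <- list()
      for (cat in c("speed", "hunting")) {
        grp <- factor(eco_row[[cat]])
        model <- cva_from_space(space, grp,
                                threshold = cfg$cva_variance_threshold)
        rep <- classify(model, mode = "leave-one-out")
        models[[cat]] <- model
        rows[[cat]] <- data.frame(
          block = label, category = cat, k = model$k, r = model$r,
          mode = rep$mode, accuracy = rep$accuracy,
          correct = sum(diag(rep$confusion)), total = sum(rep$confusion))
      }
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(out, paste0("cva_", label, ".csv")),
                       row.names = FALSE)
      results$cva[[label]] <- tab
    })
  }
  results$models[[label]] <- models
  invisible(NULL)
}

#' Run the full vertebral ecomorphology pipeline
#'
#' From one configuration: reads landmark, ecology and tree inputs (or
#' accepts in-memory objects), superimposes each requested vertebral
#' position, computes species means, PCA variance tables, global and
#' pairwise PERMANOVA for speed and hunting, PGLS against speed, hunting and
#' log centroid size, CVA leave-one-out accuracies, multi-block combined
#' spaces, and fossil projections with Mahalanobis membership
#' probabilities. All CSV artifacts plus a JSON manifest (config, seeds,
#' file checksums) are written to `output_dir`; reruns with an identical
#' config reproduce the outputs byte for byte.
#'
#' @param config a `run_config` from [pipeline_config()], a list of
#'   overrides, or a YAML path.
#' @param data optional in-memory inputs overriding the config's file paths:
#'   a list with `dataset`, `ecology`, `tree`, `fossil` (a
#'   `landmark_dataset`).
#' @return invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(config = list(), data = NULL) {
  cfg <- if (inherits(config, "run_config")) config else pipeline_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # ---- validation & input -------------------------------------------------
  ds <- eco <- tree <- fossil <- NULL
  run_stage("validate", {
    if (!is.null(data$dataset)) ds <- data$dataset
    else {
      if (is.null(cfg$input$landmarks))
        stop("no landmark input (config input.landmarks or data$dataset)")
      if (!file.exists(cfg$input$landmarks))
        stop("landmark file not found: ", cfg$input$landmarks)
      ds <- read_morphologika(cfg$input$landmarks)
    }
    if (!is.null(data$ecology)) eco <- data$ecology
    else {
      if (is.null(cfg$input$ecology)) stop("no ecology input")
      eco <- read_ecology_table(cfg$input$ecology)
    }
    if (!is.null(data$tree)) tree <- data$tree
    else if (!is.null(cfg$input$tree)) tree <- read_newick(cfg$input$tree)
    if (!is.null(data$fossil)) fossil <- data$fossil
    else if (!is.null(cfg$input$fossil_landmarks))
      fossil <- read_morphologika(cfg$input$fossil_landmarks)
    have <- unique(positions(ds))
    if (is.null(cfg$positions)) cfg$positions <- have
    missing <- setdiff(cfg$positions, have)
    if (length(missing))
      stop("position(s) named in config but absent from the data: ",
           paste(missing, collapse = ", "))
    for (combo in cfg$combinations) {
      missing <- setdiff(combo, cfg$positions)
      if (length(missing))
        stop("combination uses position(s) not analysed: ",
             paste(missing, collapse = ", "))
    }
    no_eco <- setdiff(unique(species_of(ds)), eco$species)
    if (length(no_eco))
      stop("species without ecology rows: ", paste(no_eco, collapse = ", "))
  })

  results <- new.env(parent = emptyenv())
  results$pca <- list(); results$permanova <- list()
  results$pgls <- list(); results$cva <- list(); results$models <- list()
  results$fossil <- list(); results$blocks <- list(); results$spaces <- list()

  # ---- per-position analyses ---------------------------------------------
  for (pos in cfg$positions) {
    blk <- run_stage(paste0("gpa:", pos),
                     species_block(subset_position(ds, pos), cfg))
    results$blocks[[pos]] <- blk
    space <- run_stage(paste0("pca:", pos), fit_pca(blk))
    results$spaces[[pos]] <- space
    vt <- data.frame(component = seq_along(space$eigenvalues),
                     eigenvalue = space$eigenvalues,
                     variance_fraction = space$variance_fraction,
                     cumulative = cumsum(space$variance_fraction))
    utils::write.csv(vt, file.path(out, paste0("pca_variance_", pos, ".csv")),
                     row.names = FALSE)
    results$pca[[pos]] <- vt
    analyse_space(pos, vectorize_block(blk), space, blk$centroid_sizes,
                  eco, tree, cfg, out, results)
  }

  # ---- combinations -------------------------------------------------------
  for (cname in names(cfg$combinations)) {
    combo <- cfg$combinations[[cname]]
    mbs <- run_stage(paste0("combine:", cname),
                     combine_blocks(results$blocks[combo],
                                    scale_blocks = cfg$scale_blocks))
    results$spaces[[cname]] <- mbs
    vt <- data.frame(component = seq_along(mbs$eigenvalues),
                     eigenvalue = mbs$eigenvalues,
                     variance_fraction = mbs$variance_fraction,
                     cumulative = cumsum(mbs$variance_fraction))
    utils::write.csv(vt, file.path(out, paste0("pca_variance_", cname,
                                               ".csv")), row.names = FALSE)
    results$pca[[cname]] <- vt
    sizes <- rowMeans(vapply(results$blocks[combo], function(b)
      b$centroid_sizes[mbs$specimen_ids], numeric(length(mbs$specimen_ids))))
    analyse_space(cname, structure(mbs$scores,
                                   dimnames = list(mbs$specimen_ids, NULL)),
                  mbs, sizes, eco, tree, cfg, out, results)
  }

  # ---- fossil predictions -------------------------------------------------
  if (isTRUE(cfg$analyses$fossil) && !is.null(fossil) &&
      isTRUE(cfg$analyses$cva)) {
    run_stage("fossil", {
      fpos <- unique(positions(fossil))
      rows <- list()
      predict_one <- function(label, model, proj, cat, id) {
        pred <- membership_probabilities(model, proj, specimen_id = id,
                                         position = label,
                                         category_set = cat)
        as.data.frame(pred)
      }
      for (pos in intersect(cfg$positions, fpos)) {
        fcfg <- subset_position(fossil, pos)$configurations[[1]]
        for (cat in c("speed", "hunting")) {
          model <- results$models[[pos]][[cat]]
          if (is.null(model)) next
          proj <- project_external(model, fcfg)
          rows[[paste(pos, cat)]] <-
            predict_one(pos, model, proj, cat, fcfg$specimen_id)
        }
      }
      for (cname in names(cfg$combinations)) {
        mbs <- results$spaces[[cname]]
        bpos <- vapply(mbs$block_meta, `[[`, character(1), "position")
        usable <- intersect(bpos, fpos)
        if (!length(usable)) next
        # restrict the combined space to positions preserved in the fossil
        mbs_f <- if (length(usable) < length(bpos))
          combine_blocks(results$blocks[usable],
                         scale_blocks = cfg$scale_blocks)
        else mbs
        eco_row <- eco[match(mbs_f$specimen_ids, eco$species), ]
        cfgs <- lapply(usable, function(p)
          subset_position(fossil, p)$configurations[[1]])
        names(cfgs) <- usable
        id <- cfgs[[1]]$specimen_id
        for (cat in c("speed", "hunting")) {
          model <- cva_from_space(mbs_f, factor(eco_row[[cat]]),
                                  threshold = cfg$cva_variance_threshold)
          proj <- project_external(model, cfgs)
          rows[[paste(cname, cat)]] <-
            predict_one(cname, model, proj, cat, id)
        }
      }
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      utils::write.csv(tab, file.path(out, "fossil_predictions.csv"),
                       row.names = FALSE)
      results$fossil <- tab
    })
  }

  # ---- manifest -----------------------------------------------------------
  cfg_plain <- unclass(cfg)
  cfg_file <- file.path(out, "config_resolved.yaml")
  writeLines(yaml::as.yaml(cfg_plain), cfg_file)
  files <- sort(list.files(out, pattern = "\\.csv$", full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("vertecol")),
    seed = cfg$seed,
    n_permutations = cfg$n_permutations,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pca = results$pca, permanova = results$permanova,
                 pgls = results$pgls, cva = results$cva,
                 fossil = results$fossil, spaces = results$spaces,
                 blocks = results$blocks, manifest = manifest,
                 config = cfg))
}
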