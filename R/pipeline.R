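# End-to-end orchestration under a single declarative config: synthetic
# landscape -> occurrence prep -> predictor stack -> pseudo-absences ->
# fits -> ensembles -> evaluation -> importance -> projection/overlap.
# Every stage is seeded from the one global seed and logged as JSON lines.

#' Demo configuration for the bundled synthetic study
#'
#' A small two-region landscape and a reduced design (3 pseudo-absence sets
#' x 2 repetitions, RF + CTA) that completes in minutes while exercising
#' every pipeline stage.
#'
#' @param seed Global seed.
#' @return A named list usable by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = seed,
    landscape = list(
      n_rows = 60, n_cols = 100, cell_size_m = 1000, n_layers = 6,
      smoothness = 3, intercept = -0.5,
      coefficients = c(env01 = 2, env02 = -1),
      n_occ_A = 500, n_occ_B = 80, n_effort_points = 8000
    ),
    cu_thresholds = c(A = 1000, B = 15000),
    pa = list(n_sets = 3, mode = c(A = "cell", B = "buffer")),
    cv = list(train_frac = 0.7, n_reps = 2),
    algorithms = list(RF = list(ntree = 200), CTA = list()),
    ensemble_schemes = c("EMmean", "EMca", "EMwmean"),
    boyce = list(window_width = 0.1, n_windows = 101),
    importance = list(n_shuffles = 9),
    independent = list(n_points = 120),
    overlap = list(species = c(focal1 = 40, focal2 = 25))
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly through [yaml::write_yaml()].
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `read_config()` returns the configuration list.
#' @export
write_config <- function(config, path) {
  # named atomic vectors serialize as YAML maps (so names survive the trip)
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (!is.null(names(x)) && length(x)) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml flattens named numeric vectors to lists; restore the ones we use
  for (nm in c("cu_thresholds")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (!is.null(cfg$landscape$coefficients)) {
    cfg$landscape$coefficients <- unlist(cfg$landscape$coefficients)
  }
  if (!is.null(cfg$pa$mode)) cfg$pa$mode <- unlist(cfg$pa$mode)
  if (!is.null(cfg$ensemble_schemes)) cfg$ensemble_schemes <- unlist(cfg$ensemble_schemes)
  if (!is.null(cfg$overlap$species)) cfg$overlap$species <- unlist(cfg$overlap$species)
  cfg
}

log_stage <- function(log_path, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(rec)
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic study system defined by the config
#' and writes a deterministic artifact tree: JSON-lines log, run manifest,
#' evaluation/importance/contrast/overlap tables (CSV) and suitability maps
#' (ESRI ASCII grids). Identical config (and seed) gives identical tables.
#'
#' @param config Configuration list (see [demo_config()]).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a list with the key in-memory results (`presences`,
#'   `eval_members`, `eval_candidates`, `best_id`, `importance`,
#'   `contrasts`, `maps`, `independent`, `overlap`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  seed <- config$seed

  # --- landscape + occurrences ---------------------------------------------
  ls_args <- config$landscape
  land <- synth_landscape(
    n_rows = ls_args$n_rows, n_cols = ls_args$n_cols,
    cell_size_m = ls_args$cell_size_m %||% 1000,
    n_layers = ls_args$n_layers, smoothness = ls_args$smoothness,
    coefficients = ls_args$coefficients, intercept = ls_args$intercept,
    n_occ_A = ls_args$n_occ_A, n_occ_B = ls_args$n_occ_B,
    n_effort_points = ls_args$n_effort_points, seed = seed
  )
  log_stage(log_path, "landscape", n_records = nrow(land$occurrences),
            n_layers = length(land$stack$layers), seed = seed)

  # --- occurrence prep ------------------------------------------------------
  occ0 <- land$occurrences
  occ1 <- basic_clean(occ0, land$grid, land$stack)
  occ2 <- filter_uncertainty(occ1, config$cu_thresholds)
  presences <- thin_to_cells(occ2, land$grid)
  log_stage(log_path, "occurrence_prep",
            rows_in = nrow(occ0), after_clean = nrow(occ1),
            after_cu = nrow(occ2), presence_cells = nrow(presences),
            dropped_clean = as.list(attr(occ1, "dropped")),
            dropped_cu = as.list(attr(occ2, "dropped")))

  # --- predictor stack ------------------------------------------------------
  pruned <- prune_collinear(land$stack, threshold = 0.7)
  stack <- standardize_stack(pruned$stack)
  stack <- add_effort_layer(stack, land$effort)
  jsonlite::write_json(pruned$report, file.path(out_dir, "collinearity.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(log_path, "predictor_stack",
            kept = length(pruned$report$kept),
            dropped = nrow(pruned$report$dropped),
            effort_mean_nonzero = land$effort$mean_nonzero)

  # --- pseudo-absences ------------------------------------------------------
  regions <- sort(unique(presences$region))
  n_per_region <- vapply(regions, function(r) sum(presences$region == r), integer(1))
  eligible <- lapply(regions, function(reg) {
    if (config$pa$mode[[reg]] == "buffer") {
      eligible_cells_bufferexcl(occ2[occ2$region == reg, ], land$grid, stack, reg)
    } else {
      eligible_cells_cellexcl(presences, land$grid, stack, reg)
    }
  })
  names(eligible) <- regions
  pa_seed <- stage_seed(seed, "pa")
  pa_sets <- draw_pa_sets(eligible, n_per_region, n_sets = config$pa$n_sets,
                          base_seed = pa_seed, grid = land$grid)
  log_stage(log_path, "pseudo_absence", base_seed = pa_seed,
            n_sets = length(pa_sets),
            totals = as.list(n_per_region * length(pa_sets)))

  # --- fits over PA sets x repetitions -------------------------------------
  split_seed <- stage_seed(seed, "splits")
  fit_base <- stage_seed(seed, "fit")
  algs <- names(config$algorithms)
  runs <- list()  # keyed "alg|set|rep"
  frames <- list()
  plans <- list()
  for (s in seq_along(pa_sets)) {
    frames[[s]] <- assemble_frame(presences, pa_sets[[s]], stack)
    plans[[s]] <- split_train_valid(frames[[s]],
                                    train_frac = config$cv$train_frac,
                                    rep_seeds = split_seed + s * 100 +
                                      seq_len(config$cv$n_reps))
    for (r in seq_len(config$cv$n_reps)) {
      train <- frames[[s]][plans[[s]][[r]]$train, ]
      for (a in algs) {
        key <- sprintf("%s|%d|%d", a, s, r)
        runs[[key]] <- fit_sdm(a, train, hyperparams = config$algorithms[[a]],
                               seed = fit_seed(fit_base, a, s, r))
      }
    }
  }
  log_stage(log_path, "fit", n_fits = length(runs),
            algorithms = algs, n_sets = length(pa_sets),
            n_reps = config$cv$n_reps)

  # --- member + candidate evaluation ---------------------------------------
  bw <- config$boyce
  member_rows <- list()
  member_scores <- list()
  for (s in seq_along(pa_sets)) {
    for (r in seq_len(config$cv$n_reps)) {
      vidx <- plans[[s]][[r]]$valid
      vrows <- frames[[s]][vidx, ]
      for (a in algs) {
        key <- sprintf("%s|%d|%d", a, s, r)
        member_scores[[key]] <- predict_sdm(runs[[key]], vrows)
        member_rows[[key]] <- vrows
      }
    }
  }
  eval_members <- do.call(rbind, lapply(names(runs), function(key) {
    ev <- evaluate_regional(member_rows[[key]], member_scores[[key]],
                            regions = regions,
                            window_width = bw$window_width,
                            n_windows = bw$n_windows)
    cbind(id = key, ev)
  }))

  avg_eval <- function(tbl, id) {
    out <- do.call(rbind, lapply(c(regions, "pooled"), function(reg) {
      sub <- tbl[tbl$region == reg, ]
      data.frame(id = id, region = reg, tss = mean(sub$tss),
                 boyce = mean(sub$boyce, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    out
  }
  # per-algorithm candidates: mean of member metrics over splits and sets
  eval_candidates <- do.call(rbind, lapply(algs, function(a) {
    avg_eval(eval_members[startsWith(eval_members$id, paste0(a, "|")), ], a)
  }))
  # global candidates: combine algorithm members within each (set, rep)
  for (scheme in config$ensemble_schemes) {
    per_split <- list()
    for (s in seq_along(pa_sets)) {
      for (r in seq_len(config$cv$n_reps)) {
        keys <- sprintf("%s|%d|%d", algs, s, r)
        sc <- do.call(cbind, member_scores[keys])
        stats_tbl <- eval_members[match(keys, eval_members$id), ]
        pooled <- eval_members[eval_members$id %in% keys &
                                 eval_members$region == "pooled", ]
        comb <- combine_scores(sc, scheme,
                               tss = pooled$tss,
                               thresholds = pooled$threshold)
        per_split[[sprintf("%d|%d", s, r)]] <-
          evaluate_regional(member_rows[[keys[1]]], comb, regions = regions,
                            window_width = bw$window_width,
                            n_windows = bw$n_windows)
      }
    }
    eval_candidates <- rbind(eval_candidates,
                             avg_eval(cbind(id = scheme,
                                            do.call(rbind, per_split)),
                                      scheme))
  }
  utils::write.csv(eval_members, file.path(out_dir, "eval_members.csv"),
                   row.names = FALSE)
  utils::write.csv(eval_candidates, file.path(out_dir, "eval_candidates.csv"),
                   row.names = FALSE)
  # a candidate whose Boyce is undefined in a region (degenerate score
  # distribution, e.g. coarse committee votes) cannot enter the joint-mean
  # selection; drop it with a log entry
  ids <- unique(eval_candidates$id)
  selectable <- ids[vapply(ids, function(i) {
    sub <- eval_candidates[eval_candidates$id == i &
                             eval_candidates$region != "pooled", ]
    !anyNA(c(sub$tss, sub$boyce)) && all(is.finite(c(sub$tss, sub$boyce)))
  }, logical(1))]
  best_id <- select_best(eval_candidates[eval_candidates$id %in% selectable, ])
  log_stage(log_path, "evaluation", n_members = length(runs),
            dropped_candidates = setdiff(ids, selectable),
            best = as.character(best_id))

  # --- importance + region contrasts ---------------------------------------
  # evaluation rows: validation partition of the first PA set, per repetition
  imp_seed <- stage_seed(seed, "importance")
  if (best_id %in% algs) {
    imp_fits <- list()
    for (s in seq_along(pa_sets)) {
      for (r in seq_len(config$cv$n_reps)) {
        imp_fits[[sprintf("set%d_rep%d", s, r)]] <-
          runs[[sprintf("%s|%d|%d", best_id, s, r)]]
      }
    }
  } else {
    imp_fits <- list()
    for (s in seq_along(pa_sets)) {
      for (r in seq_len(config$cv$n_reps)) {
        keys <- sprintf("%s|%d|%d", algs, s, r)
        pooled <- eval_members[eval_members$id %in% keys &
                                 eval_members$region == "pooled", ]
        imp_fits[[sprintf("set%d_rep%d", s, r)]] <-
          make_ensemble(runs[keys], scheme = best_id,
                        tss = pooled$tss, thresholds = pooled$threshold,
                        id = best_id)
      }
    }
  }
  imp_rows <- do.call(rbind, lapply(seq_len(config$cv$n_reps), function(r) {
    frames[[1]][plans[[1]][[r]]$valid, ]
  }))
  raw_imp <- importance_table(imp_fits, imp_rows,
                              n_shuffles = config$importance$n_shuffles,
                              seed = imp_seed)
  imp <- scale_importances(raw_imp)
  utils::write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  breg <- fit_beta_glmm(imp)
  contrasts <- if (breg$converged) {
    region_contrasts(breg, invasive = regions[1])
  } else {
    data.frame(predictor = character(0), estimate = numeric(0),
               se = numeric(0), z = numeric(0), p = numeric(0))
  }
  utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  log_stage(log_path, "importance", n_rows = nrow(imp),
            glmm_converged = breg$converged)

  # --- projection, independent validation, overlap -------------------------
  final <- if (best_id %in% algs) {
    make_ensemble(imp_fits, scheme = "EMmean", id = paste0(best_id, ".EMmean"))
  } else {
    pooled <- eval_members[eval_members$region == "pooled", ]
    make_ensemble(runs, scheme = best_id,
                  tss = pooled$tss[match(names(runs), pooled$id)],
                  thresholds = pooled$threshold[match(names(runs), pooled$id)],
                  id = best_id)
  }
  map_std <- project_map(final, stack, effort_mode = "standardized")
  map_obs <- project_map(final, stack, effort_mode = "observed")
  write_ascii_grid(map_std$values, land$grid,
                   file.path(out_dir, "suitability_standardized.asc"))
  write_ascii_grid(map_obs$values, land$grid,
                   file.path(out_dir, "suitability_observed.asc"))

  proj_seed <- stage_seed(seed, "projection")
  indep <- NULL
  if (!is.null(config$independent)) {
    # emulate a systematic monitoring program: random terrestrial sites in
    # the invasive region, presence labels Bernoulli(truth suitability)
    indep_pts <- with_seed(proj_seed, {
      cells <- which(!is.na(land$grid$region) & land$grid$region == regions[1] &
                       complete_cells(stack))
      take <- sample(cells, min(config$independent$n_points, length(cells)))
      row <- ((take - 1L) %% land$grid$n_rows) + 1L
      col <- ((take - 1L) %/% land$grid$n_rows) + 1L
      ctr <- xy_from_cell(land$grid, row, col)
      data.frame(x = ctr$x, y = ctr$y,
                 label = stats::rbinom(length(take), 1,
                                       land$truth$suitability[cbind(row, col)]))
    })
    agg <- aggregate_independent(indep_pts, land$grid)
    sc <- map_std$values[cbind(agg$row, agg$col)]
    ok <- !is.na(sc) & length(unique(agg$label)) == 2
    indep <- if (any(ok)) {
      ot <- optimal_tss(agg$label[!is.na(sc)], sc[!is.na(sc)])
      cs <- confusion_summary(agg$label[!is.na(sc)], sc[!is.na(sc)], ot$threshold)
      bi <- tryCatch(boyce_index(sc[!is.na(sc) & agg$label == 1],
                                 sc[!is.na(sc) & agg$label == 0]),
                     error = function(e) NA_real_)
      data.frame(tss = ot$tss, threshold = ot$threshold, boyce = bi,
                 accuracy = cs$accuracy, sensitivity = cs$sensitivity,
                 specificity = cs$specificity, kappa = cs$kappa,
                 balanced_accuracy = cs$balanced_accuracy,
                 n_points = nrow(agg))
    }
    utils::write.csv(indep, file.path(out_dir, "independent_validation.csv"),
                     row.names = FALSE)
  }

  overlap <- NULL
  if (!is.null(config$overlap)) {
    sp <- config$overlap$species
    overlap <- do.call(rbind, lapply(seq_along(sp), function(i) {
      pts <- with_seed(proj_seed + i, {
        cells <- which(!is.na(map_std$values))
        take <- sample(cells, sp[i], replace = TRUE)
        row <- ((take - 1L) %% land$grid$n_rows) + 1L
        col <- ((take - 1L) %/% land$grid$n_rows) + 1L
        ctr <- xy_from_cell(land$grid, row, col)
        data.frame(longitude = ctr$x, latitude = ctr$y)
      })
      overlap_summary(map_std, pts, species = names(sp)[i])
    }))
    utils::write.csv(overlap, file.path(out_dir, "overlap.csv"),
                     row.names = FALSE)
  }
  log_stage(log_path, "projection",
            effort_constant = map_std$effort_constant,
            independent = !is.null(indep), overlap = !is.null(overlap))

  manifest <- list(
    seed = seed,
    algorithms = algs,
    n_pa_sets = length(pa_sets),
    n_reps = config$cv$n_reps,
    n_fits = length(runs),
    pa_base_seed = pa_seed,
    presence_cells = as.list(n_per_region),
    pa_totals = as.list(n_per_region * length(pa_sets)),
    effort_mean_nonzero = land$effort$mean_nonzero,
    collinearity = pruned$report,
    best = as.character(best_id)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    land = land, presences = presences, stack = stack, pa_sets = pa_sets,
    frames = frames, plans = plans, runs = runs,
    eval_members = eval_members, eval_candidates = eval_candidates,
    best_id = best_id, importance = imp, betareg = breg,
    contrasts = contrasts, maps = list(standardized = map_std,
                                       observed = map_obs),
    independent = indep, overlap = overlap, manifest = manifest
  ))
}
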