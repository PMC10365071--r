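# Readers/writers for the on-disk cohort layout, graph artifacts and
# model checkpoints. All formats are plain text: TSV/CSV, Matrix Market
# for adjacencies, JSON for configs and checkpoints.

#' Write a cohort to a directory
#'
#' Layout: `thickness/<subject>.tsv` (columns roi_id, vertex_id,
#' thickness_mm), optionally `thickness_followup/`, plus
#' `phenotypes.csv`, `labels.csv` and a `manifest.json` recording the
#' generating config and seed.
#'
#' @param cohort a [generate_cohort()] result, or a list with at least
#'   `thickness`, `phenotypes`, `labels`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "thickness"), recursive = TRUE, showWarnings = FALSE)
  write_thickness_dir(cohort$thickness, file.path(dir, "thickness"))
  if (!is.null(cohort$thickness_followup)) {
    dir.create(file.path(dir, "thickness_followup"), showWarnings = FALSE)
    write_thickness_dir(cohort$thickness_followup,
                        file.path(dir, "thickness_followup"))
  }
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  lab <- data.frame(subject = names(cohort$labels),
                    label = as.character(cohort$labels),
                    stringsAsFactors = FALSE)
  if (!is.null(cohort$amyloid_status)) {
    lab$amyloid <- cohort$amyloid_status[lab$subject]
  }
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(config = unclass(cohort$config),
                   affected_rois = cohort$affected_rois,
                   n_subjects = nrow(cohort$thickness$values))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_thickness_dir <- function(thickness, dir) {
  vroi <- as.character(thickness$vertex_roi)
  vid <- stats::ave(seq_along(vroi), vroi, FUN = seq_along)
  for (id in subjects(thickness)) {
    # %.17g keeps doubles bit-exact through the text round-trip
    df <- data.frame(roi_id = vroi, vertex_id = vid,
                     thickness_mm = sprintf("%.17g", thickness$values[id, ]))
    utils::write.table(df, file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a thickness directory
#'
#' Reads every `<subject>.tsv` (columns roi_id, vertex_id,
#' thickness_mm), validates that all subjects share an identical
#' `(roi_id, vertex count)` structure, and optionally checks ROI names
#' against the 34-region left-hemisphere Desikan-Killiany atlas.
#'
#' @param path directory of per-subject TSV files
#' @param atlas if TRUE, require exactly the [dk_lh_atlas()] ROIs
#' @return a [thickness_dataset()]
#' @export
read_thickness_dir <- function(path, atlas = FALSE) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) abort_fmt("no .tsv files under %s", path)
  ids <- sub("\\.tsv$", "", basename(files))
  ref <- NULL
  values <- NULL
  for (i in seq_along(files)) {
    df <- utils::read.table(files[i], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("roi_id", "vertex_id", "thickness_mm")
    if (!all(need %in% names(df))) {
      abort_fmt("subject %s: expected columns %s", ids[i],
                paste(need, collapse = ", "))
    }
    key <- paste(df$roi_id, df$vertex_id)
    if (is.null(ref)) {
      ref <- list(key = key, roi = df$roi_id)
      values <- matrix(NA_real_, length(files), nrow(df),
                       dimnames = list(ids, NULL))
    } else if (!identical(key, ref$key)) {
      miss <- setdiff(ref$key, key)
      roi <- if (length(miss)) strsplit(miss[1], " ")[[1]][1] else
        strsplit(setdiff(key, ref$key)[1], " ")[[1]][1]
      abort_fmt("subject %s: vertex structure mismatch at ROI %s", ids[i], roi)
    }
    values[i, ] <- df$thickness_mm
  }
  if (atlas) {
    unknown <- setdiff(unique(ref$roi), dk_lh_atlas())
    if (length(unknown)) {
      abort_fmt("unknown ROI(s) in atlas mode: %s",
                paste(unknown, collapse = ", "))
    }
  }
  thickness_dataset(values, ref$roi)
}

#' Read a phenotype CSV
#' @param path CSV with columns subject, age, gender, apoe4_count
#' @return data.frame with gender as a factor
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject" %in% names(df)) abort_fmt("phenotype CSV needs a 'subject' column")
  if ("gender" %in% names(df)) df$gender <- factor(df$gender)
  df
}

#' Read a label CSV
#' @param path CSV with columns subject, label
#' @return named factor of labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(factor(df$label), df$subject)
}

#' Write an adjacency matrix as Matrix Market plus an edge-list TSV
#' @param W symmetric adjacency matrix
#' @param path output path (`.mtx`; an `.edges.tsv` is written alongside)
#' @return `path`, invisibly
#' @export
write_adjacency <- function(W, path) {
  Matrix::writeMM(Matrix::Matrix(W, sparse = TRUE), path)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1], to = idx[, 2], weight = W[idx])
  utils::write.table(edges, sub("\\.mtx$", ".edges.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency matrix from Matrix Market
#' @param path `.mtx` path
#' @return dense symmetric matrix
#' @export
read_adjacency <- function(path) {
  as.matrix(Matrix::readMM(path))
}

#' Save a trained model as a JSON checkpoint
#'
#' Weights, attention parameters, class levels, config and loss history
#' in one portable JSON document.
#'
#' @param model a trained model
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unb_gcn_model"))
  obj <- list(
    classes = model$classes,
    config = unclass(model$config),
    history = model$history,
    n_nodes = model$n_nodes, n_features = model$n_features,
    theta = lapply(model$params$theta, function(m) list(dim = dim(m),
                                                        data = as.numeric(m))),
    attention = if (!is.null(model$params$attention)) {
      list(W = list(dim = dim(model$params$attention$W),
                    data = as.numeric(model$params$attention$W)),
           b = model$params$attention$b)
    },
    attention_map = if (!is.null(model$attention_map)) {
      list(dim = dim(model$attention_map),
           data = as.numeric(model$attention_map))
    }
  )
  # I(17) significant digits keeps weights bit-exact through the round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path `.json` path
#' @return an `unb_gcn_model`
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  unflat <- function(x) matrix(as.numeric(x$data), x$dim[1], x$dim[2])
  params <- list(theta = lapply(obj$theta, unflat), attention = NULL)
  if (!is.null(obj$attention) && length(obj$attention)) {
    params$attention <- list(W = unflat(obj$attention$W),
                             b = as.numeric(obj$attention$b))
  }
  cfg <- do.call(model_config, obj$config[names(formals(model_config))])
  structure(
    list(params = params, classes = obj$classes, history = obj$history,
         attention_map = if (!is.null(obj$attention_map) && length(obj$attention_map))
           unflat(obj$attention_map),
         config = cfg, n_nodes = obj$n_nodes, n_features = obj$n_features),
    class = "unb_gcn_model"
  )
}

#' Full run configuration
#'
#' Serializable description of an end-to-end run: either simulate a
#' cohort (`simulate = TRUE`) or read one from `cohort_dir`, then
#' biomarkers -> population graph -> training -> evaluation ->
#' attention ranking.
#'
#' @param out_dir artifact output directory
#' @param simulate generate the cohort instead of reading it?
#' @param cohort_dir cohort directory (non-simulate mode)
#' @param cohort [cohort_config()] used in simulate mode
#' @param model [model_config()]
#' @param edge [edge_spec()]
#' @param classes the two diagnostic classes to classify
#' @param atlas validate ROI names against the atlas?
#' @param n_repeats,test_fraction cross-validation protocol
#' @param C power constant for minimum sample sizes
#' @param n_boot bootstrap resamples for AUC confidence intervals
#' @param seed master seed
#' @return an object of class `run_config`
#' @export
run_config <- function(out_dir, simulate = TRUE, cohort_dir = NULL,
                       cohort = cohort_config(), model = model_config(),
                       edge = default_edge_spec(),
                       classes = c("AD", "CU"), atlas = NULL,
                       n_repeats = 10L, test_fraction = 0.1,
                       C = power_constant(), n_boot = 2000L, seed = 1L) {
  if (!simulate && (is.null(cohort_dir) || !dir.exists(cohort_dir))) {
    abort_fmt("cohort_dir must exist when simulate = FALSE")
  }
  if (is.null(atlas)) atlas <- simulate && cohort$n_rois == 34L
  structure(
    list(out_dir = out_dir, simulate = simulate, cohort_dir = cohort_dir,
         cohort = cohort, model = model, edge = edge, classes = classes,
         atlas = atlas, n_repeats = as.integer(n_repeats),
         test_fraction = test_fraction, C = C,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()]
#' @param path `.json` path
#' @return `path` / the `run_config`
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else if (!is.null(names(x)) && length(x) > 1L) {
      as.list(x)  # named vectors become JSON objects, keeping names
    } else {
      x
    }
  }
  jsonlite::write_json(strip(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- do.call(cohort_config, {
    cc <- obj$cohort
    cc$longitudinal_decline <- unlist(cc$longitudinal_decline)
    cc[names(formals(cohort_config))[names(formals(cohort_config)) %in% names(cc)]]
  })
  model <- do.call(model_config, obj$model[names(formals(model_config))])
  edge <- edge_spec(lapply(obj$edge, function(e) e))
  run_config(out_dir = obj$out_dir, simulate = obj$simulate,
             cohort_dir = obj$cohort_dir, cohort = cohort, model = model,
             edge = edge, classes = obj$classes, atlas = obj$atlas,
             n_repeats = obj$n_repeats, test_fraction = obj$test_fraction,
             C = obj$C, n_boot = obj$n_boot, seed = obj$seed)
}

#' Run the full pipeline
#'
#' Simulate or load a cohort, compute covariate-adjusted atrophy
#' patterns and per-ROI biomarkers, build the phenotype population
#' graph, cross-validate the classifier on the two configured classes,
#' train a final model on all labeled nodes, rank ROIs by attention and
#' compute the longitudinal statistics (when a follow-up visit is
#' available). Writes `unb.csv`, `adjacency.mtx`, `metrics.csv`,
#' `attention.csv`, `model.json`, `stats.json` and `run.log` under
#' `out_dir`.
#'
#' @param config a [run_config()]
#' @return invisibly, a list bundle with the computed objects
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = logf, append = TRUE)
  }
  log_line("master seed %d", config$seed)

  if (config$simulate) {
    cc <- config$cohort
    cc$seed <- config$seed
    cohort <- generate_cohort(do.call(cohort_config, unclass(cc)))
    log_line("simulated cohort: %d AD / %d MCI / %d CU, %d ROIs",
             cc$n_ad, cc$n_mci, cc$n_cu, cc$n_rois)
  } else {
    cohort <- list(
      thickness = read_thickness_dir(file.path(config$cohort_dir, "thickness"),
                                     atlas = config$atlas),
      phenotypes = read_phenotypes(file.path(config$cohort_dir, "phenotypes.csv")),
      labels = read_labels(file.path(config$cohort_dir, "labels.csv"))
    )
    fdir <- file.path(config$cohort_dir, "thickness_followup")
    if (dir.exists(fdir)) {
      cohort$thickness_followup <- read_thickness_dir(fdir, atlas = config$atlas)
    }
    log_line("loaded cohort from %s: %d subjects", config$cohort_dir,
             nrow(cohort$thickness$values))
  }

  pipe <- unb_pipeline(cohort$thickness, cohort$phenotypes, cohort$labels,
                       atlas = config$atlas)
  utils::write.csv(pipe$unb, file.path(config$out_dir, "unb.csv"))
  log_line("UNB matrix: %d subjects x %d ROIs", nrow(pipe$unb), ncol(pipe$unb))

  ids <- rownames(pipe$unb)
  labels <- cohort$labels[ids]
  keep <- !is.na(labels) & labels %in% config$classes
  feats <- pipe$unb[keep, , drop = FALSE]
  phen <- cohort$phenotypes[match(ids[keep], cohort$phenotypes$subject), ,
                            drop = FALSE]
  labs <- droplevels(factor(labels[keep], levels = config$classes))
  W <- build_adjacency(phen, config$edge)
  write_adjacency(W, file.path(config$out_dir, "adjacency.mtx"))
  log_line("population graph: %d nodes, %d edges", nrow(W),
           sum(W[upper.tri(W)] > 0))

  cv <- cross_validate(feats, phen, labs, config = config$model,
                       n_repeats = config$n_repeats,
                       test_fraction = config$test_fraction,
                       spec = config$edge,
                       positive_class = config$classes[1L],
                       seed = config$seed)
  utils::write.csv(cv$splits, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  log_line("CV mean: ACC %.3f SEN %.3f SPE %.3f AUC %.3f",
           cv$mean["ACC"], cv$mean["SEN"], cv$mean["SPE"], cv$mean["AUC"])

  final_graph <- population_graph(
    X = feats, W = W, labels = labs,
    train_mask = rep(TRUE, nrow(feats)),
    test_mask = rep(FALSE, nrow(feats)), phenotypes = phen)
  model <- train_gcn(final_graph, config$model)
  save_model(model, file.path(config$out_dir, "model.json"))

  attn <- NULL
  if (config$model$attention_enabled) {
    attn <- rank_roi_attention(model, roi_names = colnames(feats))
    utils::write.csv(attn, file.path(config$out_dir, "attention.csv"),
                     row.names = FALSE)
    log_line("top attention ROI: %s (%.4f)", attn$roi[1],
             attn$normalized_weight[1])
  }

  stats_out <- list(seed = config$seed, C = config$C, n_boot = config$n_boot)
  total <- rowSums(pipe$unb)
  if (length(unique(labels[!is.na(labels)])) >= 2 &&
      all(config$classes %in% labels)) {
    ra <- roc_auc(total[keep], labs, positive_class = config$classes[1L],
                  n_boot = config$n_boot, seed = config$seed)
    stats_out$total_unb_auc <- ra$auc
    stats_out$total_unb_auc_ci <- ra$ci
  }
  if (!is.null(cohort$thickness_followup)) {
    unb_fu <- unb_matrix(
      adjust_glm(cohort$thickness_followup, cohort$phenotypes,
                 fit_subjects = subjects(pipe$cu_reference)),
      pipe$group_pattern, pipe$cu_reference)
    total_fu <- rowSums(unb_fu)[ids]
    mss <- lapply(levels(droplevels(labels)), function(g) {
      gi <- which(!is.na(labels) & labels == g)
      if (length(gi) < 2) return(NULL)
      min_sample_size(total[gi], total_fu[gi], C = config$C)$n
    })
    names(mss) <- levels(droplevels(labels))
    stats_out$min_sample_size <- mss[!vapply(mss, is.null, logical(1))]
    log_line("minimum sample sizes: %s",
             paste(names(stats_out$min_sample_size),
                   unlist(stats_out$min_sample_size), collapse = ", "))
  }
  jsonlite::write_json(stats_out, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(cohort = cohort, unb = pipe$unb, graph = final_graph,
                 cv = cv, model = model, attention = attn,
                 stats = stats_out))
}
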