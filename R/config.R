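# Run configuration: a nested YAML/JSON file validated against the known
# schema, flattened onto model_config(). Unknown keys are reported with
# their full path rather than silently ignored.

.config_schema <- list(
  featurization = c("resolution", "patch", "spread", "min_extent", "cutoff",
                    "max_neighbors", "knn_k", "pos_sigma", "pos_rbf", "n_anchors",
                    "abs_bins", "n_rbf"),
  model = c("L", "H", "A", "max_atoms", "use_images", "positional_mode",
            "H_graph", "gnn_layers"),
  pretrain = c("mask_rate", "corrupt_split", "n_pairs", "epsilon",
               "epochs", "batch", "lr", "weight_decay", "warmup_frac",
               "task_weights"),
  finetune = c("epochs", "batch", "split", "seed", "top_n", "direction"),
  paths = c("structures", "properties", "checkpoint", "out_dir", "cache")
)

#' Read and validate a run configuration file
#'
#' Accepts YAML (needs the `yaml` package) or JSON. Sections and keys are
#' checked against the schema; violations are reported with field paths.
#' Omitted values fall back to the [model_config()] defaults.
#'
#' @param path configuration file, or `NULL` for all defaults.
#' @return list with `cfg` (a `crysformer_config`), `train` overrides and
#'   `paths`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configuration requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (section in names(raw)) {
    if (!section %in% names(.config_schema)) {
      stop("unknown config section: ", section)
    }
    bad <- setdiff(names(raw[[section]]), .config_schema[[section]])
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste(paste0(section, ".", bad), collapse = ", "))
    }
  }
  gv <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  cfg <- model_config(
    L = gv("model", "L", 12L), H = gv("model", "H", 768L),
    A = gv("model", "A", 12L),
    max_atoms = gv("model", "max_atoms", 512L),
    use_images = gv("model", "use_images", TRUE),
    positional_mode = gv("model", "positional_mode", "relative"),
    H_graph = gv("model", "H_graph", 256L),
    gnn_layers = gv("model", "gnn_layers", 2L),
    resolution = gv("featurization", "resolution", 50L),
    patch = gv("featurization", "patch", 5L),
    spread = gv("featurization", "spread", 0.15),
    min_extent = gv("featurization", "min_extent", 20),
    cutoff = gv("featurization", "cutoff", 5),
    max_neighbors = gv("featurization", "max_neighbors", 8L),
    knn_k = gv("featurization", "knn_k", 8L),
    pos_sigma = gv("featurization", "pos_sigma", 0.05),
    pos_rbf = gv("featurization", "pos_rbf", 64L),
    n_anchors = gv("featurization", "n_anchors", 4L),
    abs_bins = gv("featurization", "abs_bins", 100L),
    n_rbf = gv("featurization", "n_rbf", 16L),
    mask_rate = gv("pretrain", "mask_rate", 0.15),
    corrupt_split = gv("pretrain", "corrupt_split", c(0.8, 0.1, 0.1)),
    n_pairs = gv("pretrain", "n_pairs", 200L),
    epsilon = gv("pretrain", "epsilon", 1.1),
    task_weights = gv("pretrain", "task_weights", c(1, 1, 1, 1)),
    pretrain_epochs = gv("pretrain", "epochs", 50L),
    pretrain_batch = gv("pretrain", "batch", 512L),
    lr = gv("pretrain", "lr", 1e-4),
    weight_decay = gv("pretrain", "weight_decay", 1e-2),
    warmup_frac = gv("pretrain", "warmup_frac", 0.05),
    finetune_epochs = gv("finetune", "epochs", 50L),
    finetune_batch = gv("finetune", "batch", 32L),
    split = gv("finetune", "split", c(0.8, 0.1, 0.1))
  )
  list(cfg = cfg,
       finetune_seed = gv("finetune", "seed", 1L),
       top_n = gv("finetune", "top_n", 10L),
       direction = gv("finetune", "direction", "lowest"),
       paths = raw$paths)
}

read_structures_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.cif$", full.names = TRUE))
  if (!length(files)) stop("no CIF files under ", dir)
  out <- lapply(files, function(f) {
    s <- read_cif(f)
    assign_molecules(to_p1(s))
  })
  names(out) <- vapply(files, function(f) {
    tools::file_path_sans_ext(basename(f))
  }, character(1))
  out
}

#' Command-line entry point
#'
#' Dispatches the `featurize`, `pretrain`, `finetune`, `predict`, `fewshot`,
#' `explain` and `make-fixtures` commands. Designed to be driven by the
#' `crysformer` Rscript shim (see `inst/cli/crysformer.R`); everything it
#' does is available directly through the exported functions.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: crysformer <featurize|pretrain|finetune|predict|fewshot|",
        "explain|make-fixtures> [--config cfg.yaml] [--seed N] ...\n",
        sep = "")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opt <- list(config = NULL, seed = 1L, out = "runs", n = 50L,
              checkpoint = NULL, structures = NULL, properties = NULL,
              holdout = NULL, epochs = NULL, cif = NULL, target = "density")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opt)) stop("unknown option --", key)
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opt$seed <- as.integer(opt$seed)
  rc <- read_run_config(opt$config)
  cfg <- rc$cfg
  if (!is.null(rc$paths$structures) && is.null(opt$structures)) {
    opt$structures <- rc$paths$structures
  }
  if (!is.null(rc$paths$properties) && is.null(opt$properties)) {
    opt$properties <- rc$paths$properties
  }
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  status <- 0L
  if (cmd == "make-fixtures") {
    ds <- make_dataset(as.integer(opt$n), seed = opt$seed,
                       target = opt$target, dir = opt$out)
    cat(sprintf("wrote %d fixtures under %s\n", nrow(ds$table), opt$out))
  } else if (cmd == "featurize") {
    structures <- read_structures_dir(opt$structures)
    feats <- lapply(structures, function(s) {
      pf <- persistence_features(s, cfg$min_extent, cfg$resolution,
                                 cfg$spread)
      pf$diagrams <- NULL
      pf
    })
    cache <- file.path(opt$out, "features.rds")
    saveRDS(list(hash = featurization_hash(cfg), features = feats), cache)
    cat("persistence features cached at", cache, "\n")
  } else if (cmd == "pretrain") {
    structures <- read_structures_dir(opt$structures)
    # symmetry labels come from the original CIF setting, before expansion
    raw <- lapply(sort(list.files(opt$structures, pattern = "\\.cif$",
                                  full.names = TRUE)), read_cif)
    groups <- vapply(raw, function(s) s$space_group, integer(1))
    elements <- sort(unique(unlist(lapply(structures, `[[`, "elements"))))
    model <- crysformer_model(cfg, elements, seed = opt$seed)
    model <- pretrain(model, unname(structures), groups,
                      epochs = if (is.null(opt$epochs)) NULL else
                        as.integer(opt$epochs),
                      seed = opt$seed, verbose = TRUE)
    ck <- file.path(opt$out, "pretrained.rds")
    save_checkpoint(model, ck)
    utils::write.csv(model$history, file.path(opt$out, "pretrain_log.csv"),
                     row.names = FALSE)
    cat("checkpoint written to", ck, "\n")
  } else if (cmd %in% c("finetune", "fewshot")) {
    structures <- read_structures_dir(opt$structures)
    tab <- utils::read.csv(opt$properties, stringsAsFactors = FALSE)
    model <- load_checkpoint(opt$checkpoint,
                             expect_hash = featurization_hash(cfg))
    if (cmd == "finetune") {
      tab <- assign_split(tab, seed = rc$finetune_seed, split = cfg$split)
      ft <- finetune(model, structures, tab,
                     epochs = if (is.null(opt$epochs)) NULL else
                       as.integer(opt$epochs),
                     seed = opt$seed, top_n = rc$top_n,
                     direction = rc$direction, verbose = TRUE)
      utils::write.csv(ft$report$predictions,
                       file.path(opt$out, "predictions.csv"),
                       row.names = FALSE)
      jsonlite::write_json(ft$report[c("mae", "r2", "top_n",
                                       "top_n_overlap")],
                           file.path(opt$out, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      save_finetuned(ft, file.path(opt$out, "finetuned.rds"))
      print(ft)
    } else {
      fs <- few_shot_protocol(model, structures, tab,
                              holdout_tag = opt$holdout,
                              seed = opt$seed,
                              stage1_epochs = if (is.null(opt$epochs)) NULL
                              else as.integer(opt$epochs),
                              stage2_epochs = if (is.null(opt$epochs)) NULL
                              else as.integer(opt$epochs),
                              direction = rc$direction)
      utils::write.csv(fs, file.path(opt$out, "fewshot.csv"),
                       row.names = FALSE)
      print(fs)
    }
  } else if (cmd == "predict") {
    structures <- read_structures_dir(opt$structures)
    ft <- load_finetuned(opt$checkpoint)
    preds <- predict(ft, structures)
    utils::write.csv(preds, file.path(opt$out, "predictions.csv"),
                     row.names = FALSE)
    cat("predictions written to", file.path(opt$out, "predictions.csv"),
        "\n")
  } else if (cmd == "explain") {
    model <- load_checkpoint(opt$checkpoint,
                             expect_hash = featurization_hash(cfg))
    s <- assign_molecules(to_p1(read_cif(opt$cif)))
    res <- attribute(model, s, pos_seed = opt$seed)
    paths <- export_attribution(res, s, opt$out)
    cat("attribution written:", paste(paths, collapse = ", "), "\n")
  } else {
    stop("unknown command: ", cmd)
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
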