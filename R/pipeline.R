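# Configuration, seeding and pipeline glue.  A run configuration is a
# nested list with one block per stage; every stochastic stage derives its
# seed from the global seed plus the stage name, so a single integer
# reproduces an entire experiment.

#' Default run configuration
#'
#' All stage defaults in one place, including the estimation-task training
#' conditions (reducer architecture/training constants and regressor
#' settings).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "patternfit_run",
    log_level = "info",
    stages = c("generate", "encode"),
    generate = list(
      dataset = "selection",        # "selection" or "estimation"
      size = 128L,
      fast = FALSE,
      n_train = 9700L,
      n_val = 600L,
      box = c(0.6, 1.0),
      render = TRUE
    ),
    encode = list(
      encoder = "spectral_fallback",
      blur_sigma = 1.5
    ),
    select = list(
      target = NULL,
      top_n = 5L,
      crop_scan = FALSE,
      map_k = 50L
    ),
    dimred = list(
      batch_size = 32L,
      learning_rate = 0.001,
      weight_decay = 0.001,
      margin = 0.1,
      epsilon = 0.2,
      n_grid = 10L,
      max_epochs = 100L,
      patience = 20L
    ),
    sdnpe = list(
      n_stages = 150L,
      learning_rate = 0.087,
      max_depth = 3L,
      lattice_cell = 0.005,
      lattice_n = 100L,
      images_per_group = 20L
    ),
    stability = list(
      f_u = 0.51, g_u = 0.81, q = 0, D_u = 0.1, D_v = 1.0
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!length(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop("unknown configuration key", if (length(bad) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' YAML or JSON; unknown keys are an error, missing keys take their
#' defaults, and the fully resolved configuration is returned.
#'
#' @param path configuration file; `NULL` or an empty file yields the
#'   defaults.
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  validate_config(user)
}

#' @rdname load_config
#' @param config partial configuration list.
#' @export
validate_config <- function(config = list()) {
  merge_config(default_config(), config)
}

config_hash <- function(x) {
  j <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  # FNV-1a over the serialized config
  h <- 2166136261
  for (b in utf8ToInt(j)) {
    h <- bitwXor(as.integer(h %% 2147483648), b) * 16777619 %% 2147483648
    h <- h %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

stage_current <- function(out_dir, stage, hash) {
  f <- file.path(out_dir, paste0(stage, ".hash"))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash)
}

stage_mark <- function(out_dir, stage, hash) {
  writeLines(hash, file.path(out_dir, paste0(stage, ".hash")))
}

#' Run the configured pipeline stages
#'
#' Stages execute in dependency order (generate, encode, then select
#' and/or dimred+sdnpe).  A stage is skipped when its artifacts already
#' exist under `out_dir` with an unchanged configuration hash, so
#' re-running an identical configuration performs no recomputation.
#'
#' @param config resolved configuration (see [load_config()]).
#' @return run log: list of executed/skipped stages with artifact paths.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(started = format(Sys.time()), stages = list(),
              config_hash = config_hash(config))
  manifest_csv <- file.path(out_dir, "manifest.csv")
  store_base <- file.path(out_dir, "store")

  run_stage <- function(stage, hash_src, artifacts, fn) {
    h <- config_hash(list(stage = stage, cfg = hash_src,
                          seed = config$seed))
    if (stage_current(out_dir, stage, h) && all(file.exists(artifacts))) {
      log$stages[[stage]] <<- list(status = "skipped",
                                   artifacts = artifacts)
      return(invisible(NULL))
    }
    fn()
    stage_mark(out_dir, stage, h)
    log$stages[[stage]] <<- list(status = "run", artifacts = artifacts)
  }

  if ("generate" %in% config$stages) {
    g <- config$generate
    run_stage("generate", g, manifest_csv, function() {
      m <- if (g$dataset == "selection") {
        build_selection_dataset(
          selection_config(size = g$size, fast = g$fast),
          out_dir = file.path(out_dir, "images"),
          seed = derive_seed(config$seed, "generate"), render = g$render)
      } else {
        build_estimation_dataset(n_train = g$n_train, n_val = g$n_val,
                                 box = g$box,
                                 seed = derive_seed(config$seed, "generate"),
                                 size = g$size)
      }
      write_manifest(m, manifest_csv)
    })
  }
  if ("encode" %in% config$stages) {
    e <- config$encode
    if (!file.exists(manifest_csv)) {
      stop("missing upstream artifact for stage 'encode': run 'generate'")
    }
    run_stage("encode", e, paste0(store_base, ".rds"), function() {
      m <- read_manifest(manifest_csv)
      if (m$model[1] == "turing" && !is.null(m$f_v)) {
        imgs <- render_estimation_images(m)
        st <- encode_dataset(m, encoder_spec(e$encoder,
                                             input_size = nrow(imgs[[1]])),
                             images = imgs, blur_sigma = e$blur_sigma)
      } else {
        st <- encode_dataset(m, encoder_spec(e$encoder),
                             blur_sigma = e$blur_sigma)
      }
      save_store(st, store_base)
    })
  }
  if ("select" %in% config$stages) {
    s <- config$select
    if (!file.exists(paste0(store_base, ".rds"))) {
      stop("missing upstream artifact for stage 'select': run 'encode'")
    }
    run_stage("select", s, file.path(out_dir, "selection.json"), function() {
      st <- load_store(store_base)
      if (is.null(s$target)) stop("select stage requires a target image")
      tgt <- read_image(s$target)
      rk <- if (isTRUE(s$crop_scan)) {
        crop_scan_select(tgt, st, encoder_spec(config$encode$encoder,
                                               input_size = nrow(tgt)),
                         top_n = s$top_n)
      } else {
        v <- encode(blur(tgt, config$encode$blur_sigma),
                    encoder_spec(config$encode$encoder,
                                 input_size = nrow(tgt)))
        rank_similar(v, st, top_n = s$top_n)
      }
      jsonlite::write_json(
        list(target = s$target, crop_ratio = attr(rk, "crop_ratio"),
             ranking = as.data.frame(rk)),
        file.path(out_dir, "selection.json"), auto_unbox = TRUE,
        digits = NA)
    })
  }
  log$finished <- format(Sys.time())
  jsonlite::write_json(log, file.path(out_dir, "runlog.json"),
                       auto_unbox = TRUE)
  invisible(log)
}
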