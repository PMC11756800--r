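# Dataset manifests.  A manifest is a data.frame with one row per image:
# model, param_json (the full re-generation recipe), seed, time_point,
# path, split - plus a composition-summary attribute.  Every row can be
# re-rendered byte-for-byte from its recorded recipe.

#' Default selection-dataset composition
#'
#' Per-model image counts of the default model-selection dataset
#' (total 1799).  Pass scaled-down counts for quick experiments.
#'
#' @param counts named integer vector of images per model.
#' @param size image side length in pixels.
#' @param fast use shorter integration settings for the PDE models
#'   (coarser steps; intended for reduced-size experiments).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(counts = c(turing = 228L, kt = 288L,
                                        gray_scott = 486L,
                                        edwards_wilkinson = 99L,
                                        eden = 182L, dla = 300L,
                                        l_system = 133L, phase_field = 83L),
                             size = 128L, fast = FALSE) {
  known <- c("turing", "kt", "gray_scott", "edwards_wilkinson", "eden",
             "dla", "l_system", "phase_field")
  stopifnot(all(names(counts) %in% known), all(counts >= 0))
  structure(list(counts = counts, size = as.integer(size), fast = fast),
            class = "selection_config")
}

# Per-model row recipes.  Each returns a list of param records (one per
# image) drawn deterministically from the dataset seed.
selection_recipes <- function(config, seed) {
  size <- config$size
  fast <- config$fast
  cnt <- function(m) {
    if (m %in% names(config$counts)) as.integer(config$counts[[m]]) else 0L
  }
  rows <- list()
  add <- function(model, params, seed_i, time_point = NA_integer_) {
    rows[[length(rows) + 1L]] <<- list(model = model, params = params,
                                       seed = seed_i,
                                       time_point = time_point)
  }
  # Turing: unique parameter draws in the estimation box
  n <- cnt("turing")
  if (n > 0) {
    fv <- with_seed(derive_seed(seed, "sel_turing_fv"), runif(n, 0.6, 1.0))
    gv <- with_seed(derive_seed(seed, "sel_turing_gv"), runif(n, 0.6, 1.0))
    for (i in seq_len(n)) {
      add("turing", list(f_v = fv[i], g_v = gv[i], size = size,
                         dt = 0.2, steps = if (fast) 2000L else 10000L),
          derive_seed(seed, paste0("sel_turing_", i)))
    }
  }
  # KT: unique kernel draws
  n <- cnt("kt")
  if (n > 0) {
    dr <- with_seed(derive_seed(seed, "sel_kt"), {
      # short-range activation / mid-range inhibition tuned to the same
      # wavelength band as the Turing task (the KT model's design target),
      # with near-balanced kernel mass so the state neither saturates nor
      # dies under clipping
      list(act_r = sample(1:3, n, replace = TRUE),
           gap = sample(2:4, n, replace = TRUE),
           act_amp = runif(n, 0.05, 0.12),
           balance = runif(n, 0.95, 1.25))
    })
    disc_count <- function(r_in, r_out) {
      w <- ceiling(r_out)
      d <- sqrt(outer((-w:w)^2, (-w:w)^2, "+"))
      sum(d > r_in & d <= r_out)
    }
    for (i in seq_len(n)) {
      a_r <- dr$act_r[i]
      i_r <- a_r + dr$gap[i]
      n_act <- disc_count(-1, a_r)
      n_inh <- disc_count(a_r, i_r)
      add("kt", list(act_amp = dr$act_amp[i], act_r = a_r,
                     inh_amp = dr$act_amp[i] * n_act / n_inh * dr$balance[i],
                     inh_r = i_r, size = size,
                     steps = if (fast) 60L else 100L),
          derive_seed(seed, paste0("sel_kt_", i)))
    }
  }
  # Gray-Scott: simulations x capture times
  n <- cnt("gray_scott")
  if (n > 0) {
    caps <- if (fast) c(500L, 1000L, 2000L, 4000L, 8000L, 16000L) else
      c(1000L, 2000L, 4000L, 8000L, 16000L, 32000L)
    nsim <- ceiling(n / length(caps))
    Fk <- with_seed(derive_seed(seed, "sel_gs"),
                    list(F = runif(nsim, 0.022, 0.062),
                         k = runif(nsim, 0.05, 0.066)))
    made <- 0L
    for (i in seq_len(nsim)) {
      for (tp in caps) {
        if (made >= n) break
        add("gray_scott", list(F = Fk$F[i], k = Fk$k[i], size = size,
                               capture = caps, sim_id = i),
            derive_seed(seed, paste0("sel_gs_", i)), time_point = tp)
        made <- made + 1L
      }
    }
  }
  # Edwards-Wilkinson: parameter sets x replicates
  n <- cnt("edwards_wilkinson")
  if (n > 0) {
    nset <- max(1L, n %/% 3L)
    pr <- with_seed(derive_seed(seed, "sel_ew"),
                    list(nu = runif(nset, 0.5, 2.0),
                         amp = runif(nset, 0.5, 2.0)))
    for (i in seq_len(n)) {
      s <- ((i - 1L) %% nset) + 1L
      add("edwards_wilkinson",
          list(nu = pr$nu[s], noise_amp = pr$amp[s], dt = 0.1,
               steps = if (fast) 200L else 500L, size = size, set = s),
          derive_seed(seed, paste0("sel_ew_", i)))
    }
  }
  # Eden: parameter sets x replicates
  n <- cnt("eden")
  if (n > 0) {
    nset <- max(1L, n %/% 7L)
    ev <- with_seed(derive_seed(seed, "sel_eden"),
                    sample(round(size^2 * c(0.05, 0.1, 0.2, 0.3)), nset,
                           replace = TRUE))
    for (i in seq_len(n)) {
      s <- ((i - 1L) %% nset) + 1L
      add("eden", list(n_events = ev[s], size = size, set = s),
          derive_seed(seed, paste0("sel_eden_", i)))
    }
  }
  # DLA: parameter sets x replicates
  n <- cnt("dla")
  if (n > 0) {
    nset <- max(1L, n %/% 10L)
    np <- with_seed(derive_seed(seed, "sel_dla"),
                    sample(round(size * c(2, 4, 6)), nset, replace = TRUE))
    for (i in seq_len(n)) {
      s <- ((i - 1L) %% nset) + 1L
      add("dla", list(n_particles = np[s], size = size, set = s),
          derive_seed(seed, paste0("sel_dla_", i)))
    }
  }
  # L-system: unique specs from a few production templates
  n <- cnt("l_system")
  if (n > 0) {
    templates <- list(
      list(axiom = "F", prod = c(F = "F[+F]F[-F]F")),
      list(axiom = "F", prod = c(F = "FF[+F][-F]")),
      list(axiom = "F", prod = c(F = "F[+F][-F[+F]]F")),
      list(axiom = "X", prod = c(X = "F[+X][-X]FX", F = "FF")))
    dr <- with_seed(derive_seed(seed, "sel_ls"),
                    list(tmpl = sample(length(templates), n, replace = TRUE),
                         ang = runif(n, 15, 35),
                         iter = sample(3:5, n, replace = TRUE)))
    for (i in seq_len(n)) {
      tm <- templates[[dr$tmpl[i]]]
      add("l_system", list(axiom = tm$axiom, productions = as.list(tm$prod),
                           iterations = dr$iter[i], angle = dr$ang[i],
                           size = size),
          derive_seed(seed, paste0("sel_ls_", i)))
    }
  }
  # Phase field: unique anisotropy draws (replicate noise via seed)
  n <- cnt("phase_field")
  if (n > 0) {
    dr <- with_seed(derive_seed(seed, "sel_pf"),
                    list(delta = runif(n, 0.02, 0.08),
                         j = sample(c(4L, 6L), n, replace = TRUE),
                         th0 = runif(n, 0, pi / 3)))
    for (i in seq_len(n)) {
      add("phase_field", list(delta = dr$delta[i], j_mode = dr$j[i],
                              theta0 = dr$th0[i], size = size,
                              steps = if (fast) 1200L else 2000L),
          derive_seed(seed, paste0("sel_pf_", i)))
    }
  }
  rows
}

# Render one manifest row back to its image (deterministic from the recipe).
render_row <- function(model, params, seed) {
  p <- params
  img <- switch(model,
    turing = normalize_field(simulate_turing(
      turing_params(p$f_v, p$g_v), size = p$size, dt = p$dt,
      steps = p$steps, seed = seed)),
    kt = normalize_field(simulate_kt(
      kt_params(act_amp = p$act_amp, act_r = p$act_r, inh_amp = p$inh_amp,
                inh_r = p$inh_r, steps = p$steps),
      size = p$size, seed = seed)),
    gray_scott = {
      snaps <- simulate_gray_scott(
        gray_scott_params(F = p$F, k = p$k,
                          capture_times = as.integer(unlist(p$capture))),
        size = p$size, seed = seed)
      normalize_field(snaps[[match(p$time_point, unlist(p$capture))]])
    },
    edwards_wilkinson = normalize_field(simulate_edwards_wilkinson(
      ew_params(nu = p$nu, noise_amp = p$noise_amp, dt = p$dt,
                steps = p$steps), size = p$size, seed = seed)),
    eden = simulate_growth(growth_config("eden", p$n_events),
                           size = p$size, seed = seed)$grid,
    dla = simulate_growth(growth_config("dla", p$n_particles),
                          size = p$size, seed = seed)$grid,
    l_system = generate_l_system(
      l_system_spec(axiom = p$axiom, productions = unlist(p$productions),
                    iterations = p$iterations, angle = p$angle),
      size = p$size),
    phase_field = normalize_field(simulate_phase_field(
      phase_field_params(delta = p$delta, j_mode = p$j_mode,
                         theta0 = p$theta0, steps = p$steps),
      size = p$size, seed = seed)),
    stop("unknown model: ", model))
  img
}

#' Regenerate the image of a manifest row
#'
#' @param manifest a dataset manifest.
#' @param i row index.
#' @return the row's image, recomputed from its recorded recipe.
#' @export
regenerate_row <- function(manifest, i) {
  p <- jsonlite::fromJSON(manifest$param_json[i])
  p$time_point <- manifest$time_point[i]
  render_row(manifest$model[i], p, manifest$seed[i])
}

#' Build the model-selection dataset
#'
#' Samples per-model parameter recipes (counts per [selection_config()],
#' default: the 1799-image composition) and optionally renders each image
#' to an 8-bit grayscale PNG.
#'
#' @param config a [selection_config()].
#' @param out_dir output directory for PNGs (created if needed).
#' @param seed dataset seed; every row derives its own sub-seed.
#' @param render write the PNG files (rendering the full default dataset
#'   takes several minutes; the manifest itself is instant).
#' @return the manifest data.frame with a `composition` attribute.
#' @export
build_selection_dataset <- function(config = selection_config(),
                                    out_dir = tempfile("selset"),
                                    seed = 1L, render = TRUE) {
  rows <- selection_recipes(config, seed)
  n <- length(rows)
  manifest <- data.frame(
    model = vapply(rows, `[[`, character(1), "model"),
    param_json = vapply(rows, function(r)
      as.character(jsonlite::toJSON(r$params, auto_unbox = TRUE, digits = NA)),
      character(1)),
    seed = vapply(rows, `[[`, numeric(1), "seed"),
    time_point = vapply(rows, function(r) as.integer(r$time_point),
                        integer(1)),
    stringsAsFactors = FALSE)
  manifest$path <- if (n > 0) {
    file.path(out_dir, sprintf("%s_%05d.png", manifest$model, seq_len(n)))
  } else character(0)
  manifest$split <- rep("all", n)
  if (anyDuplicated(manifest$path)) stop("duplicate output path in manifest")
  if (render && n > 0) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    # Gray-Scott rows share simulations: render per simulation, not per row
    done <- rep(FALSE, n)
    gs <- which(manifest$model == "gray_scott")
    if (length(gs)) {
      key <- manifest$seed[gs]
      for (s in unique(key)) {
        idx <- gs[key == s]
        p <- jsonlite::fromJSON(manifest$param_json[idx[1]])
        caps <- as.integer(unlist(p$capture))
        snaps <- simulate_gray_scott(
          gray_scott_params(F = p$F, k = p$k, capture_times = caps),
          size = p$size, seed = manifest$seed[idx[1]])
        for (i in idx) {
          img <- normalize_field(snaps[[match(manifest$time_point[i], caps)]])
          write_image(img, manifest$path[i])
          done[i] <- TRUE
        }
      }
    }
    for (i in which(!done)) {
      write_image(regenerate_row(manifest, i), manifest$path[i])
    }
  }
  comp <- table(manifest$model)
  attr(manifest, "composition") <- comp
  attr(manifest, "total") <- n
  manifest
}

#' Build the Turing parameter-estimation dataset manifest
#'
#' Draws `(f_v, g_v)` uniformly from the box (default \[0.6, 1.0\]^2) with
#' the fixed reaction constants, split into disjoint train/validation sets.
#' Labels are the drawn `(f_v, g_v)`.
#'
#' @param n_train,n_val row counts (defaults 9700 / 600).
#' @param box c(lo, hi) for both parameters.
#' @param seed dataset seed.
#' @param size image side length.
#' @param dt,steps Turing integration settings recorded in the recipes.
#' @return manifest data.frame with columns model, param_json, seed,
#'   time_point, path, split, f_v, g_v.
#' @export
build_estimation_dataset <- function(n_train = 9700L, n_val = 600L,
                                     box = c(0.6, 1.0), seed = 1L,
                                     size = 128L, dt = 0.2,
                                     steps = 10000L) {
  stopifnot(n_train >= 0, n_val >= 0, box[1] < box[2])
  corners <- expand.grid(f_v = box, g_v = box)
  for (i in seq_len(nrow(corners))) {
    p <- turing_params(corners$f_v[i], corners$g_v[i])
    # valid when the homogeneous state sheds a growing mode at some
    # wavenumber (a diffusion-driven band, or a homogeneous instability
    # that the cubic term saturates into a pattern)
    if (growth_rate(0, p) <= 0 && !has_positive_band(p)) {
      stop("box outside simulator-valid region: no growing mode at ",
           "corner (", corners$f_v[i], ", ", corners$g_v[i], ")")
    }
  }
  n <- n_train + n_val
  fv <- with_seed(derive_seed(seed, "est_fv"), runif(n, box[1], box[2]))
  gv <- with_seed(derive_seed(seed, "est_gv"), runif(n, box[1], box[2]))
  manifest <- data.frame(
    model = "turing",
    param_json = vapply(seq_len(n), function(i)
      as.character(jsonlite::toJSON(list(f_v = fv[i], g_v = gv[i],
                                         size = size, dt = dt,
                                         steps = steps),
                                    auto_unbox = TRUE, digits = NA)),
      character(1)),
    seed = vapply(seq_len(n), function(i)
      derive_seed(seed, paste0("est_img_", i)), numeric(1)),
    time_point = NA_integer_,
    path = sprintf("turing_est_%05d.png", seq_len(n)),
    split = rep(c("train", "val"), c(n_train, n_val)),
    f_v = fv, g_v = gv,
    stringsAsFactors = FALSE)
  attr(manifest, "box") <- box
  manifest
}

#' Render estimation-dataset images in memory
#'
#' @param manifest output of [build_estimation_dataset()] (or subset).
#' @param progress print a dot every 200 images.
#' @return list of images, row-aligned with the manifest.
#' @export
render_estimation_images <- function(manifest, progress = FALSE) {
  n <- nrow(manifest)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- jsonlite::fromJSON(manifest$param_json[i])
    out[[i]] <- normalize_field(simulate_turing(
      turing_params(p$f_v, p$g_v), size = p$size, dt = p$dt, steps = p$steps,
      seed = manifest$seed[i]))
    if (progress && i %% 200L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Write / read a manifest as CSV plus JSON composition sidecar
#'
#' @param manifest a dataset manifest.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  comp <- as.list(table(manifest$model))
  jsonlite::write_json(list(total = nrow(manifest), composition = comp),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(m, "composition") <- table(m$model)
  m
}
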