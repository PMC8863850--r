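#' Tissue-texture specification
#'
#' Describes one procedurally generated tissue class: a flat background gray
#' scattered with darker disk "blobs" plus pixel noise. The textures make no
#' attempt at histologic realism — only separability between classes matters,
#' so downstream tile classifiers can be trained and validated without
#' clinical images.
#'
#' @param class_name tissue label.
#' @param background_gray background level, 0--255.
#' @param blob_gray blob fill level, 0--255.
#' @param blob_density expected blobs per 10,000 px^2.
#' @param blob_radius blob radius in px.
#' @param noise_sd additive Gaussian pixel noise sd (gray levels).
#' @param tile_size tile edge in px (default 299; minimum 32).
#' @return a `texture_spec` list.
#' @export
texture_spec <- function(class_name, background_gray, blob_gray = 0,
                         blob_density = 0, blob_radius = 0, noise_sd = 0,
                         tile_size = 299L) {
  if (tile_size < 32L) stop_tf("tile_size must be >= 32")
  for (g in c(background_gray, blob_gray)) {
    if (g < 0 || g > 255) stop_tf("gray levels must lie in [0, 255]")
  }
  structure(list(class_name = class_name, background_gray = background_gray,
                 blob_gray = blob_gray, blob_density = blob_density,
                 blob_radius = blob_radius, noise_sd = noise_sd,
                 tile_size = as.integer(tile_size)),
            class = "texture_spec")
}

#' Default specifications for the 10 tissue classes
#'
#' One spec per label used by the tissue-type classifier: cancer,
#' non-tumoral mucosa, hyperplastic mucosa, adenoma, lymphoid tissue, smooth
#' muscle, vessels, fat, nerve, and non-material background. Parameters are
#' chosen so classes are separable by construction (distinct background
#' levels and blob statistics); the background class is pure white so it is
#' rejected by the tissue pixel threshold.
#'
#' @param tile_size tile edge in px.
#' @return named list of `texture_spec`.
#' @export
default_texture_specs <- function(tile_size = 299L) {
  p <- list(
    cancer              = c(210,  40, 3.0,  6, 12),
    non_tumoral_mucosa  = c(230,  70, 1.5, 10,  8),
    hyperplastic_mucosa = c(240,  95, 0.8, 14,  6),
    adenoma             = c(220,  55, 2.0,  8, 10),
    lymphoid_tissue     = c(200,  25, 6.0,  3, 10),
    smooth_muscle       = c(190,  85, 0.5, 20, 14),
    vessels             = c(235,  60, 0.4, 16,  5),
    fat                 = c(250, 105, 1.0, 12,  3),
    nerve               = c(215,  95, 1.2,  9,  7),
    background          = c(255,   0, 0.0,  0,  0)
  )
  specs <- lapply(names(p), function(nm) {
    v <- p[[nm]]
    texture_spec(nm, background_gray = v[1], blob_gray = v[2],
                 blob_density = v[3], blob_radius = v[4], noise_sd = v[5],
                 tile_size = tile_size)
  })
  names(specs) <- names(p)
  specs
}

## One procedural texture tile as a gray matrix in [0, 255].
render_texture <- function(spec) {
  ts <- spec$tile_size
  img <- matrix(spec$background_gray, ts, ts)
  n_blobs <- stats::rpois(1L, spec$blob_density * ts^2 / 1e4)
  if (n_blobs > 0L && spec$blob_radius > 0) {
    cx <- runif(n_blobs, 1, ts); cy <- runif(n_blobs, 1, ts)
    r <- spec$blob_radius
    for (b in seq_len(n_blobs)) {
      xs <- max(1L, floor(cx[b] - r)):min(ts, ceiling(cx[b] + r))
      ys <- max(1L, floor(cy[b] - r)):min(ts, ceiling(cy[b] + r))
      d2 <- outer((ys - cy[b])^2, (xs - cx[b])^2, `+`)
      img[ys, xs][d2 <= r^2] <- spec$blob_gray
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + rnorm(ts^2, sd = spec$noise_sd)
  }
  pmin(pmax(img, 0), 255)
}

#' Generate labeled tissue-texture tiles
#'
#' Draws `n_per_class` tiles for each texture spec, reproducibly under the
#' seed. Stands in for the labeled clinical tile sets used to train the
#' tissue-type classifier.
#'
#' @param specs list of `texture_spec` with unique class names.
#' @param n_per_class tiles per class (>= 1).
#' @param seed integer RNG seed.
#' @return list with `images` (list of gray matrices) and `labels`
#'   (character vector, parallel to `images`).
#' @export
generate_tissue_tiles <- function(specs, n_per_class, seed = 1L) {
  if (length(specs) == 0L) stop_tf("specs must be non-empty")
  if (n_per_class < 1L) stop_tf("n_per_class must be >= 1")
  nms <- vapply(specs, `[[`, "", "class_name")
  if (anyDuplicated(nms)) stop_tf("duplicate class names in texture specs")
  set.seed(seed)
  images <- vector("list", length(specs) * n_per_class)
  labels <- character(length(images))
  k <- 0L
  for (sp in specs) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      images[[k]] <- render_texture(sp)
      labels[k] <- sp$class_name
    }
  }
  list(images = images, labels = labels)
}

#' Synthetic cohort configuration
#'
#' Parameters of the case-cohort generator. Per-tile metastatic
#' probabilities follow a two-level hierarchy: a case-level mean drawn
#' around the class-conditional mode (`p_met_mode_neg` / `p_met_mode_pos`,
#' defaults 0.53 and 0.73 — the modal tile probabilities of LNM-negative and
#' LNM-positive training cases), then truncated-normal tile draws around
#' that mean. Prevalence defaults to 0.078 (the 7.8% cohort LNM rate) and
#' tumor locations are drawn per class from the 3-group odds observed in
#' the clinical training set (rectal enrichment among positives).
#'
#' @param n_cases number of cases.
#' @param prevalence LNM-positive fraction, in (0, 1).
#' @param tiles_meanlog,tiles_sdlog log-normal parameters of tiles per case.
#' @param p_met_mode_neg,p_met_mode_pos class-conditional modes of the
#'   per-tile metastatic probability, in (0, 1).
#' @param p_met_sd within-case tile sd (default 0.12).
#' @param case_mean_sd between-case sd of the case-level mean (default 0.08).
#' @param p_cancer_shape1,p_cancer_shape2 Beta parameters of the
#'   cancer-class probability, skewed toward 1.
#' @param location_odds list with `negative` and `positive` probability
#'   vectors over the 3 location groups (cecum/ascending/transverse,
#'   descending/sigmoid, rectum).
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 600L, prevalence = 0.078,
                          tiles_meanlog = 6.7, tiles_sdlog = 0.7,
                          p_met_mode_neg = 0.53, p_met_mode_pos = 0.73,
                          p_met_sd = 0.12, case_mean_sd = 0.08,
                          p_cancer_shape1 = 6, p_cancer_shape2 = 1.5,
                          location_odds = list(
                            negative = c(193, 138, 174) / 505,
                            positive = c(10, 9, 24) / 43),
                          seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop_tf("prevalence must be in (0, 1)")
  for (m in c(p_met_mode_neg, p_met_mode_pos)) {
    if (m <= 0 || m >= 1) stop_tf("probability modes must be in (0, 1)")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic case cohort of tile-probability records
#'
#' Draws case labels, locations, tile counts and per-tile (cancer,
#' metastatic) probabilities according to a [cohort_config()]. Fully
#' reproducible under the config seed.
#'
#' @param config a `cohort_config`.
#' @return a `synthetic_cohort`: list with `cases` (case_id, lnm_label,
#'   location_group) and `tiles` (case_id, tile_id, p_cancer, p_met).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases
  lab <- rbinom(n, 1L, config$prevalence)
  if (sum(lab) == 0L) {
    warning("no LNM-positive case drawn at this n_cases and prevalence")
  }
  case_id <- sprintf("case_%04d", seq_len(n))
  loc <- integer(n)
  for (cls in 0:1) {
    idx <- which(lab == cls)
    odds <- if (cls == 1L) config$location_odds$positive else config$location_odds$negative
    if (length(idx)) loc[idx] <- sample.int(3L, length(idx), replace = TRUE, prob = odds)
  }
  mode <- ifelse(lab == 1L, config$p_met_mode_pos, config$p_met_mode_neg)
  case_mean <- rtruncnorm_resample(n, mode, config$case_mean_sd, 0.01, 0.99)
  n_tiles <- pmax(1L, as.integer(round(rlnorm(n, config$tiles_meanlog, config$tiles_sdlog))))
  tot <- sum(n_tiles)
  tile_case <- rep(case_id, n_tiles)
  p_met <- rtruncnorm_resample(tot, rep(case_mean, n_tiles), config$p_met_sd, 0, 1)
  p_cancer <- rbeta(tot, config$p_cancer_shape1, config$p_cancer_shape2)
  tiles <- data.frame(
    case_id = tile_case,
    tile_id = paste0(tile_case, "_t", unlist(lapply(n_tiles, seq_len), use.names = FALSE)),
    p_cancer = p_cancer, p_met = p_met,
    stringsAsFactors = FALSE
  )
  cases <- data.frame(
    case_id = case_id,
    lnm_label = ifelse(lab == 1L, "positive", "negative"),
    location_group = loc,
    stringsAsFactors = FALSE
  )
  structure(list(cases = cases, tiles = tiles, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes `cases.csv`, `tiles.csv` and the generator config as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$cases, file.path(dir, "cases.csv"), row.names = FALSE)
  write.csv(cohort$tiles, file.path(dir, "tiles.csv"), row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir directory containing `cases.csv` and `tiles.csv`.
#' @return a `synthetic_cohort` (config is NULL if no sidecar present).
#' @export
read_cohort <- function(dir) {
  cases <- read.csv(file.path(dir, "cases.csv"), stringsAsFactors = FALSE)
  tiles <- read.csv(file.path(dir, "tiles.csv"), stringsAsFactors = FALSE)
  cfgp <- file.path(dir, "cohort_config.json")
  cfg <- if (file.exists(cfgp)) {
    x <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
    x$location_odds <- lapply(x$location_odds, as.numeric)
    structure(x, class = "cohort_config")
  }
  structure(list(cases = cases, tiles = tiles, config = cfg),
            class = "synthetic_cohort")
}
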