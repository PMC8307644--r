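default_grade_params <- function() {
  # Mean lesion counts per grade for the three archetypes; totals are
  # strictly increasing in grade and grade 0 carries none, so lesion burden
  # encodes the ordinal label.
  list(
    microaneurysm = list(mean = c(0, 3, 6, 10, 14), radius = c(0.5, 1.1)),
    hemorrhage    = list(mean = c(0, 0.5, 2, 4, 7), radius = c(1.0, 2.4)),
    exudate       = list(mean = c(0, 0.5, 2, 4, 7), radius = c(1.0, 2.2))
  )
}

#' Specification of a synthetic fundus dataset
#'
#' Describes a seeded generator of fundus-like color images with a 5-grade
#' ordinal label. Each image shows a dark surround, a circular retinal
#' field, a bright optic disc and a few vessel strokes; lesion archetypes
#' (small dark dots ~ microaneurysms, irregular dark blobs ~ hemorrhages,
#' bright patches ~ exudates) are drawn with per-grade mean counts that grow
#' strictly with the grade. The default class counts follow a long-tailed
#' 65:6:13:2:2 profile (grade 0 dominant, grades 3-4 rare), emulating the
#' severe imbalance of real retinopathy screening collections.
#'
#' @param num_classes Number of grades K (default 5).
#' @param class_counts Images per grade; strictly positive, length K.
#' @param image_size `(H, W)` in pixels.
#' @param grade_params Per-archetype mean counts (length-K vectors) and
#'   radius ranges in pixels; see `default_grade_params()` in the source.
#' @param background_noise_sd Additive Gaussian pixel noise s.d.
#' @param seed Dataset seed; per-image seeds derive from `(seed, index)`.
#' @return A list of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(num_classes = 5L,
                                   class_counts = c(1400L, 130L, 280L, 45L, 45L),
                                   image_size = c(32L, 32L),
                                   grade_params = default_grade_params(),
                                   background_noise_sd = 0.02,
                                   seed = 0L) {
  if (length(class_counts) != num_classes) {
    stop_shape("class_counts must have length %d", num_classes)
  }
  if (any(class_counts < 1L)) stop("class counts must all be positive", call. = FALSE)
  totals <- Reduce(`+`, lapply(grade_params, function(a) a$mean))
  if (length(totals) != num_classes || any(diff(totals) <= 0) || totals[1] != 0) {
    stop("mean total lesion count must be 0 at grade 0 and strictly increasing",
         call. = FALSE)
  }
  structure(list(num_classes = as.integer(num_classes),
                 class_counts = as.integer(class_counts),
                 image_size = as.integer(image_size),
                 grade_params = grade_params,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

# Paint a filled disc (soft edge) of color `col` scaled by `strength` into
# image array `img` at center (cy, cx).
paint_disc <- function(img, cy, cx, radius, col, strength = 1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  m <- clamp((radius + 0.5 - sqrt((yy - cy)^2 + (xx - cx)^2)), 0, 1) * strength
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - m) + col[ch] * m
  img
}

# Irregular blob: a short random walk of overlapping small discs.
paint_blob <- function(img, cy, cx, radius, col, steps = 4L) {
  for (s in seq_len(steps)) {
    img <- paint_disc(img, cy, cx, radius * stats::runif(1, 0.5, 0.9), col)
    cy <- cy + stats::rnorm(1, sd = radius * 0.7)
    cx <- cx + stats::rnorm(1, sd = radius * 0.7)
  }
  img
}

#' Render one synthetic fundus image
#'
#' Deterministic given `(grade, spec, stream_seed)`: the same call returns
#' pixel-identical rasters. Lesion counts are Poisson draws around the
#' grade's archetype means (grade 0 draws none by construction).
#'
#' @param grade Integer grade in `[0, K)`.
#' @param spec A [synthetic_dataset_spec()].
#' @param stream_seed Seed for this image's random stream.
#' @return An `H x W x 3` array with values in `[0, 1]`.
#' @export
generate_fundus_image <- function(grade, spec, stream_seed = 0L) {
  K <- spec$num_classes
  if (length(grade) != 1L || is.na(grade) || grade < 0 || grade >= K) {
    stop(sprintf("grade must lie in [0, %d)", K), call. = FALSE)
  }
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(as.integer(stream_seed), {
    img <- array(0.04, c(H, W, 3))
    cy0 <- H / 2 + stats::runif(1, -1, 1); cx0 <- W / 2 + stats::runif(1, -1, 1)
    R <- 0.46 * min(H, W)
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    rr <- sqrt((yy - cy0)^2 + (xx - cx0)^2)
    field <- clamp(R + 0.5 - rr, 0, 1)
    shade <- 1 - 0.35 * (rr / R)^2             # mild radial falloff
    base <- c(0.62, 0.30, 0.12)                # reddish retinal tint
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - field) + base[ch] * shade * field
    # optic disc: bright spot offset from center
    ang <- stats::runif(1, 0, 2 * pi)
    dcy <- cy0 + 0.55 * R * sin(ang); dcx <- cx0 + 0.55 * R * cos(ang)
    img <- paint_disc(img, dcy, dcx, 0.17 * R, c(0.95, 0.85, 0.55))
    # 2-4 curved vessel strokes walking out of the disc
    for (v in seq_len(sample(2:4, 1))) {
      py <- dcy; px <- dcx
      dir <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(18L)) {
        img <- paint_disc(img, py, px, 0.55, c(0.38, 0.10, 0.06), strength = 0.8)
        dir <- dir + stats::rnorm(1, sd = 0.35)
        py <- py + 1.1 * sin(dir); px <- px + 1.1 * cos(dir)
      }
    }
    # lesions inside the field, counts around the grade's means
    lesion_site <- function() {
      a <- stats::runif(1, 0, 2 * pi); r <- sqrt(stats::runif(1)) * 0.85 * R
      c(cy0 + r * sin(a), cx0 + r * cos(a))
    }
    gp <- spec$grade_params
    n_ma <- stats::rpois(1, gp$microaneurysm$mean[grade + 1])
    n_he <- stats::rpois(1, gp$hemorrhage$mean[grade + 1])
    n_ex <- stats::rpois(1, gp$exudate$mean[grade + 1])
    for (i in seq_len(n_ma)) {
      s <- lesion_site()
      img <- paint_disc(img, s[1], s[2], stats::runif(1, gp$microaneurysm$radius[1],
                                                      gp$microaneurysm$radius[2]),
                        c(0.15, 0.02, 0.02))
    }
    for (i in seq_len(n_he)) {
      s <- lesion_site()
      img <- paint_blob(img, s[1], s[2], stats::runif(1, gp$hemorrhage$radius[1],
                                                      gp$hemorrhage$radius[2]),
                        c(0.20, 0.02, 0.02))
    }
    for (i in seq_len(n_ex)) {
      s <- lesion_site()
      img <- paint_blob(img, s[1], s[2], stats::runif(1, gp$exudate$radius[1],
                                                      gp$exudate$radius[2]),
                        c(0.98, 0.92, 0.60), steps = 3L)
    }
    img <- img + array(stats::rnorm(H * W * 3, sd = spec$background_noise_sd), c(H, W, 3))
    clamp(img, 0, 1)
  })
}

#' Generate a labeled synthetic dataset
#'
#' Produces exactly `class_counts[g]` images per grade. Per-image seeds are
#' derived from `(spec$seed, image index)`, so each image is reproducible
#' independently of generation order.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @return A list of class `labeled_image_set` with `images` (list of
#'   `H x W x 3` arrays in `[0, 1]`), `labels` (0-based grades) and `spec`.
#' @export
generate_dataset <- function(spec) {
  if (any(spec$class_counts < 1L)) stop("every class needs a positive count", call. = FALSE)
  labels <- rep(seq_len(spec$num_classes) - 1L, times = spec$class_counts)
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    images[[i]] <- generate_fundus_image(labels[i], spec, derive_seed(spec$seed, i))
  }
  structure(list(images = images, labels = labels, spec = spec),
            class = "labeled_image_set")
}

subset_image_set <- function(ds, idx) {
  structure(list(images = ds$images[idx], labels = ds$labels[idx], spec = ds$spec),
            class = "labeled_image_set")
}

#' Stratified train/test split
#'
#' Splits per grade so every grade appears in both parts whenever its count
#' permits; a grade with a single image goes to training with a warning.
#'
#' @param ds A `labeled_image_set`.
#' @param test_fraction In (0, 1).
#' @param seed Integer seed.
#' @return `list(train =, test =)` of `labeled_image_set`s.
#' @export
train_test_split <- function(ds, test_fraction = 0.2, seed = 0L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  test_idx <- integer(0)
  with_seed(as.integer(seed), {
    for (g in sort(unique(ds$labels))) {
      members <- which(ds$labels == g)
      if (length(members) == 1L) {
        warning(sprintf("grade %d has a single image; assigned to training", g))
        next
      }
      n_test <- max(1L, round(length(members) * test_fraction))
      n_test <- min(n_test, length(members) - 1L)
      test_idx <- c(test_idx, sample(members, n_test))
    }
  })
  list(train = subset_image_set(ds, setdiff(seq_along(ds$labels), test_idx)),
       test = subset_image_set(ds, sort(test_idx)))
}

#' Write / read an image dataset on disk
#'
#' `write_dataset()` stores PNGs, a two-column `labels.csv`
#' (filename, grade) and a YAML copy of the generator spec.
#' `read_image_dataset()` loads any user-supplied directory laid out the
#' same way (PNG images plus a filename,grade CSV).
#'
#' @param ds A `labeled_image_set`.
#' @param dir Output directory (created if missing).
#' @param labels_csv CSV path, default `dir/labels.csv`.
#' @return The directory (write) or a `labeled_image_set` (read).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- sprintf("img_%05d.png", seq_along(ds$labels))
  for (i in seq_along(ds$labels)) {
    png::writePNG(ds$images[[i]], file.path(dir, fn[i]))
  }
  utils::write.csv(data.frame(filename = fn, grade = ds$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(ds$spec)) {
    sp <- ds$spec
    yaml::write_yaml(list(num_classes = sp$num_classes,
                          class_counts = sp$class_counts,
                          image_size = sp$image_size,
                          background_noise_sd = sp$background_noise_sd,
                          seed = sp$seed),
                     file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_image_dataset <- function(dir, labels_csv = file.path(dir, "labels.csv")) {
  tab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("filename", "grade") %in% names(tab))) {
    stop("labels CSV needs columns 'filename' and 'grade'", call. = FALSE)
  }
  images <- lapply(tab$filename, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  structure(list(images = images, labels = as.integer(tab$grade), spec = NULL),
            class = "labeled_image_set")
}
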