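# The stated augmentation families (rotation, mirroring, brightness change,
# Gaussian noise) and the x20 dataset expansion.

AUG_MODES <- c("identity", "rotate", "mirror", "brightness", "gaussian_noise",
               "compose")

#' Augmentation specification
#'
#' @param mode one of `"identity"`, `"rotate"` (magnitude = degrees in
#'   (-180, 180]), `"mirror"` (magnitude = `"horizontal"` or `"vertical"`),
#'   `"brightness"` (magnitude = multiplicative factor > 0),
#'   `"gaussian_noise"` (magnitude = noise sd in intensity units), or
#'   `"compose"` (magnitude = list of specs applied in order).
#' @param magnitude mode-specific, see above.
#' @param seed seed for stochastic modes (Gaussian noise).
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(mode, magnitude = NULL, seed = 1L) {
  if (!mode %in% AUG_MODES)
    stop(sprintf("unknown augmentation mode '%s'; valid modes: %s",
                 mode, paste(AUG_MODES, collapse = ", ")), call. = FALSE)
  if (mode == "rotate")
    stopifnot(is.numeric(magnitude), magnitude > -180, magnitude <= 180)
  if (mode == "mirror") {
    magnitude <- magnitude %||% "horizontal"
    stopifnot(magnitude %in% c("horizontal", "vertical"))
  }
  if (mode == "brightness") stopifnot(is.numeric(magnitude), magnitude > 0)
  if (mode == "gaussian_noise") stopifnot(is.numeric(magnitude), magnitude >= 0)
  structure(list(mode = mode, magnitude = magnitude, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Apply one augmentation to a grayscale image
#'
#' Output has the same height/width as the input, with intensities clipped
#' to `[0, 1]`.  Mirroring and 180-degree rotation are involutions;
#' brightness factor 1 is the identity.  Rotation uses bilinear resampling
#' with reflected borders so no black corners appear.
#'
#' @param image `[0, 1]` intensity matrix.
#' @param spec an [augmentation_spec()].
#' @return augmented intensity matrix, same size.
#' @export
augment_image <- function(image, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  out <- switch(spec$mode,
    identity = image,
    mirror = if (spec$magnitude == "horizontal")
               image[, rev(seq_len(ncol(image))), drop = FALSE]
             else image[rev(seq_len(nrow(image))), , drop = FALSE],
    rotate = {
      deg <- spec$magnitude
      if (deg == 180) image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))), drop = FALSE]
      else rotate_bilinear_cpp(image, deg)
    },
    brightness = image * spec$magnitude,
    gaussian_noise = with_local_seed(spec$seed,
      image + matrix(stats::rnorm(length(image), 0, spec$magnitude),
                     nrow(image), ncol(image))),
    compose = {
      cur <- image
      for (s in spec$magnitude) cur <- augment_image(cur, s)
      cur
    })
  pmin(pmax(out, 0), 1)
}

#' Default expansion plan
#'
#' The first slots follow a fixed schedule over the stated augmentation
#' families -- identity, horizontal mirror, rotations of +/-5, +/-10 and
#' +/-15 degrees, brightness factors 0.8/0.9/1.1/1.2, and Gaussian noise
#' with sd 0.01/0.02/0.03 (15 slots) -- and any remaining slots are seeded
#' random two-step compositions of those families, so the default factor of
#' 20 uses 5 random compositions.
#'
#' @param factor number of output images per input image (default 20).
#' @param seed seed for the random compositions and noise draws.
#' @return an `expansion_plan`: list with `factor`, `seed` and `specs` (one
#'   [augmentation_spec()] per slot).
#' @export
default_expansion_plan <- function(factor = 20L, seed = 1L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("expansion factor must be >= 1")
  base <- c(
    list(augmentation_spec("identity"),
         augmentation_spec("mirror", "horizontal")),
    lapply(c(-15, -10, -5, 5, 10, 15), function(d) augmentation_spec("rotate", d)),
    lapply(c(0.8, 0.9, 1.1, 1.2), function(f) augmentation_spec("brightness", f)),
    lapply(seq_along(c(0.01, 0.02, 0.03)), function(i)
      augmentation_spec("gaussian_noise", c(0.01, 0.02, 0.03)[i], seed = seed + i))
  )
  specs <- base[seq_len(min(factor, length(base)))]
  n_extra <- factor - length(specs)
  if (n_extra > 0) {
    extras <- with_local_seed(seed, {
      lapply(seq_len(n_extra), function(i) {
        deg <- stats::runif(1, -20, 20)
        br <- stats::runif(1, 0.75, 1.25)
        sd <- stats::runif(1, 0, 0.03)
        steps <- list(augmentation_spec("rotate", deg),
                      augmentation_spec("brightness", br),
                      augmentation_spec("gaussian_noise", sd, seed = seed + 100L + i))
        if (stats::runif(1) < 0.5)
          steps <- c(list(augmentation_spec("mirror", "horizontal")), steps)
        augmentation_spec("compose", steps)
      })
    })
    specs <- c(specs, extras)
  }
  structure(list(factor = factor, seed = as.integer(seed), specs = specs),
            class = "expansion_plan")
}

#' Serialize / deserialize an expansion plan as YAML
#'
#' @param plan an `expansion_plan`.
#' @param path YAML file path.
#' @export
write_expansion_plan <- function(plan, path) {
  strip <- function(s) {
    if (inherits(s, "augmentation_spec"))
      return(list(mode = s$mode,
                  magnitude = if (s$mode == "compose") lapply(s$magnitude, strip)
                              else s$magnitude,
                  seed = s$seed))
    s
  }
  yaml::write_yaml(list(factor = plan$factor, seed = plan$seed,
                        specs = lapply(plan$specs, strip)), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname write_expansion_plan
#' @export
read_expansion_plan <- function(path) {
  y <- yaml::read_yaml(path)
  rebuild <- function(s) {
    mag <- if (identical(s$mode, "compose")) lapply(s$magnitude, rebuild) else s$magnitude
    augmentation_spec(s$mode, mag, seed = s$seed %||% 1L)
  }
  structure(list(factor = as.integer(y$factor), seed = as.integer(y$seed),
                 specs = lapply(y$specs, rebuild)),
            class = "expansion_plan")
}

#' Expand a dataset by a fixed factor
#'
#' Every record yields exactly `factor` augmented copies; the four labels
#' (and any boxes) are copied unchanged to every copy.  Deterministic under
#' the plan's seed.  With `out_dir = NULL` the augmented pixels are kept in
#' memory on each record (`$image`); otherwise they are written as PNGs and
#' referenced by path.
#'
#' @param manifest a `dataset_manifest` (records may carry `$image` pixels;
#'   otherwise images are loaded from `image_path`).
#' @param plan an `expansion_plan` (default [default_expansion_plan()]).
#' @param out_dir output directory for augmented images, or `NULL` to keep
#'   pixels in memory.
#' @return the expanded `dataset_manifest` with `factor * N` records.
#' @export
expand_dataset <- function(manifest, plan = default_expansion_plan(),
                           out_dir = NULL) {
  if (length(manifest$records) == 0L) stop("expand_dataset: empty manifest")
  if (plan$factor < 1L) stop("expand_dataset: factor must be >= 1")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", length(manifest$records) * plan$factor)
  k <- 0L
  for (r in manifest$records) {
    img <- r[["image"]] %||% load_gray_image(r$image_path)
    for (j in seq_len(plan$factor)) {
      aug <- augment_image(img, plan$specs[[j]])
      k <- k + 1L
      rec <- r
      rec$label$image_id <- paste0(r$label$image_id, "_aug", j)
      if (is.null(out_dir)) {
        rec$image <- aug
      } else {
        rec$image <- NULL
        rec$image_path <- file.path(out_dir, paste0(rec$label$image_id, ".png"))
        save_gray_image(aug, rec$image_path)
      }
      out[[k]] <- rec
    }
  }
  structure(list(records = out, root = out_dir %||% manifest$root),
            class = "dataset_manifest")
}
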