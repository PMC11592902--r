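# Synthetic single-cell cytology image generator.
#
# Every image contains one elliptical cytoplasm region with an interior
# elliptical nucleus; class identity is carried primarily by the
# nucleus-to-cytoplasm area fraction, mirroring how cervical dysplasia raises
# the nuclear-cytoplasmic ratio.  Generation is fully deterministic given
# (spec, seed, size) so the whole training stack is testable offline.

#' Define one synthetic cell class
#'
#' @param class_id non-negative integer class identifier
#' @param count number of images to generate for the class
#' @param nucleus_frac length-2 numeric in (0,1): the range the
#'   nucleus/cytoplasm area fraction is drawn from (uniformly, per image)
#' @param noise_sd standard deviation (grey levels, 0-255 scale) of additive
#'   Gaussian texture noise
#' @param stain stain intensity in `[0,1]`; darkens cytoplasm and nucleus
#' @param group one of "normal", "abnormal", "benign"
#' @param name directory/class name (default `class_<id>`)
#' @return an object of class `cyto_class_spec`
#' @export
class_spec <- function(class_id, count, nucleus_frac = c(0.1, 0.2),
                       noise_sd = 6, stain = 0.5,
                       group = c("normal", "abnormal", "benign"),
                       name = NULL) {
  group <- match.arg(group)
  if (length(class_id) != 1L || class_id < 0 || class_id != floor(class_id))
    stop("class_id must be a single integer >= 0")
  if (length(count) != 1L || count < 1)
    stop("count must be a single integer >= 1")
  if (length(nucleus_frac) != 2L || any(nucleus_frac <= 0) ||
      any(nucleus_frac >= 1) || nucleus_frac[1] >= nucleus_frac[2])
    stop("nucleus_frac must be an increasing pair inside (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (stain < 0 || stain > 1) stop("stain must be in [0, 1]")
  structure(list(class_id = as.integer(class_id), count = as.integer(count),
                 nucleus_frac = as.numeric(nucleus_frac),
                 noise_sd = noise_sd, stain = stain, group = group,
                 name = name %||% sprintf("class_%d", as.integer(class_id))),
            class = "cyto_class_spec")
}

.ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic cell image
#'
#' The cytoplasm ellipse is placed near the image centre; the nucleus ellipse
#' lies fully inside it with area fraction drawn uniformly from the class
#' definition's range.  With `noise_sd = 0` the image is exactly piecewise constant
#' (background / cytoplasm / nucleus levels set by `stain`).
#'
#' @param spec a [class_spec()]
#' @param seed integer seed; output is fully determined by (spec, seed, size)
#' @param size length-2 integer (height, width), each >= 32
#' @return an object of class `cyto_image`: list with `pixels` (H x W matrix
#'   of grey values in `[0, 255]`), `class_id`, `group`, the drawn
#'   `nucleus_frac`, and logical `nucleus_mask` / `cyto_mask` matrices
#' @export
generate_cell_image <- function(spec, seed, size = c(64L, 64L)) {
  stopifnot(inherits(spec, "cyto_class_spec"))
  if (length(size) != 2L || any(size < 32))
    stop("size must be two integers >= 32")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  with_seed(seed, {
    bg <- 235 - 25 * spec$stain
    cyto_lv <- 185 - 70 * spec$stain
    nuc_lv <- 95 - 60 * spec$stain
    cy <- H / 2 + stats::runif(1, -0.04, 0.04) * H
    cx <- W / 2 + stats::runif(1, -0.04, 0.04) * W
    a <- stats::runif(1, 0.64, 0.84) * W / 2
    b <- stats::runif(1, 0.64, 0.84) * H / 2
    th <- stats::runif(1, 0, pi)
    f <- stats::runif(1, spec$nucleus_frac[1], spec$nucleus_frac[2])
    ecc <- stats::runif(1, 0.85, 1.18)
    an <- sqrt(f * a * b * ecc)
    bn <- sqrt(f * a * b / ecc)
    # keep the nucleus strictly inside the cytoplasm
    mscale <- min(a / an, b / bn)
    room <- max(mscale - 1, 0)
    off <- 0.5 * room * min(an, bn)
    ncy <- cy + stats::runif(1, -off, off)
    ncx <- cx + stats::runif(1, -off, off)
    cmask <- .ellipse_mask(H, W, cy, cx, a, b, th)
    nmask <- .ellipse_mask(H, W, ncy, ncx, an, bn, th)
    nmask <- nmask & cmask
    img <- matrix(bg, H, W)
    img[cmask] <- cyto_lv
    img[nmask] <- nuc_lv
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
    img <- pmin(pmax(round(img), 0), 255)
    structure(list(pixels = img, class_id = spec$class_id,
                   group = spec$group, nucleus_frac = f,
                   nucleus_mask = nmask, cyto_mask = cmask),
              class = "cyto_image")
  })
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes one subdirectory per class containing `count` PNG files plus a
#' `manifest.csv` (columns path, class, group) at the root.  Per-image seeds
#' derive from (seed, class_id, index) with a stable hash, so regeneration is
#' independent of generation order.
#'
#' @param specs list of [class_spec()] with distinct class ids
#' @param seed dataset seed
#' @param size image size (height, width)
#' @param out_dir output directory (created if missing)
#' @param overwrite allow writing into an existing non-empty directory
#' @return a dataset manifest (class `cyto_manifest`): data.frame with
#'   columns path, class, class_id, group; attributes `class_counts`, `root`
#' @export
generate_dataset <- function(specs, seed, size = c(64L, 64L), out_dir,
                             overwrite = FALSE) {
  if (inherits(specs, "cyto_class_spec")) specs <- list(specs)
  ids <- vapply(specs, function(s) s$class_id, 1L)
  if (anyDuplicated(ids)) stop("class ids must be distinct across specs")
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("out_dir exists and is not empty; set overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in specs[order(ids)]) {
    cdir <- file.path(out_dir, s$name)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(s$count)) {
      im <- generate_cell_image(s, derive_seed(seed, s$class_id, i), size)
      p <- file.path(cdir, sprintf("%04d.png", i))
      png::writePNG(im$pixels / 255, p)
      rows[[length(rows) + 1L]] <- data.frame(
        path = p, class = s$name, class_id = s$class_id, group = s$group,
        stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man[, c("path", "class", "group")],
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  as_manifest(man, root = out_dir)
}

#' @keywords internal
as_manifest <- function(df, root = NA_character_) {
  df <- df[order(df$class_id, df$path), , drop = FALSE]
  rownames(df) <- NULL
  map <- unique(df[, c("class_id", "class")])
  map <- map[order(map$class_id), , drop = FALSE]
  counts <- as.integer(table(factor(df$class_id, levels = map$class_id)))
  structure(df, class = c("cyto_manifest", "data.frame"),
            class_counts = counts,
            class_names = map$class, root = root)
}

#' Per-class counts of a manifest (ordered by class id)
#' @param manifest a `cyto_manifest`
#' @return named integer vector
#' @export
manifest_counts <- function(manifest) {
  stats::setNames(attr(manifest, "class_counts"),
                  attr(manifest, "class_names"))
}

#' @export
print.cyto_manifest <- function(x, ...) {
  cnt <- manifest_counts(x)
  cat(sprintf("Dataset manifest: %d images, %d classes (root: %s)\n",
              nrow(x), length(cnt), attr(x, "root")))
  print(cnt)
  invisible(x)
}

# Reference class tables for the two public Pap-smear collections the
# generator presets emulate.  `published_total` is the total the source
# publication prints for SipaKMeD (4049); the per-class rows sum to 4031 --
# the discrepancy is the publication's, and group percentages quoted there
# only reproduce against the published total.
.sipakmed_table <- function() {
  data.frame(
    class = c("superficial_intermediate", "parabasal", "koilocytotic",
              "dyskeratotic", "metaplastic"),
    count = c(813L, 787L, 825L, 813L, 793L),
    group = c("normal", "normal", "abnormal", "abnormal", "benign"),
    stringsAsFactors = FALSE)
}

.herlev_table <- function() {
  data.frame(
    class = c("moderate_dysplasia", "carcinoma_in_situ", "severe_dysplasia",
              "mild_dysplasia", "columnar", "superficial_squamous",
              "intermediate_squamous"),
    count = c(146L, 150L, 197L, 182L, 98L, 74L, 70L),
    group = c("abnormal", "abnormal", "abnormal", "abnormal",
              "normal", "normal", "normal"),
    stringsAsFactors = FALSE)
}

#' Dataset composition of the emulated Pap-smear collections
#'
#' Returns the per-class reference counts and the normal/abnormal/benign
#' group percentages.  For SipaKMeD, percentages are computed against the
#' published total (4049) even though the per-class rows sum to 4031; the
#' table is reported as published.
#'
#' @param dataset "sipakmed" or "herlev"
#' @return list with `table` (per-class data.frame), `total` (sum of rows),
#'   `published_total`, and `group_percent` (named, percent of published
#'   total)
#' @export
class_composition <- function(dataset = c("sipakmed", "herlev")) {
  dataset <- match.arg(dataset)
  tab <- if (dataset == "sipakmed") .sipakmed_table() else .herlev_table()
  pub <- if (dataset == "sipakmed") 4049L else 917L
  grp <- tapply(tab$count, tab$group, sum)
  list(table = tab, total = sum(tab$count), published_total = pub,
       group_percent = stats::setNames(100 * as.numeric(grp) / pub,
                                       names(grp)),
       group_counts = grp)
}

# nucleus-fraction ranges per preset class: abnormal cells get the larger
# nuclear-cytoplasmic ratios, as in real dysplasia grading
.herlev_fracs <- list(
  moderate_dysplasia = c(0.32, 0.40), carcinoma_in_situ = c(0.50, 0.62),
  severe_dysplasia = c(0.41, 0.49), mild_dysplasia = c(0.23, 0.31),
  columnar = c(0.15, 0.22), superficial_squamous = c(0.04, 0.08),
  intermediate_squamous = c(0.09, 0.14))

.sipakmed_fracs <- list(
  superficial_intermediate = c(0.04, 0.09), parabasal = c(0.17, 0.25),
  koilocytotic = c(0.27, 0.36), dyskeratotic = c(0.38, 0.48),
  metaplastic = c(0.10, 0.16))

.preset_manifest <- function(tab, fracs, scale, seed, size, out_dir,
                             overwrite, noise_sd) {
  counts <- as.integer(floor(tab$count * scale + 0.5))
  if (any(counts < 2))
    stop("scale too small: every class needs a count of at least 2")
  specs <- lapply(seq_len(nrow(tab)), function(i)
    class_spec(i - 1L, counts[i], nucleus_frac = fracs[[tab$class[i]]],
               noise_sd = noise_sd, stain = 0.5, group = tab$group[i],
               name = tab$class[i]))
  if (is.null(out_dir)) out_dir <- tempfile("cyto_preset_")
  generate_dataset(specs, seed, size, out_dir, overwrite)
}

#' Herlev-like synthetic preset (7 classes, 917 images at scale 1)
#'
#' Class counts are `round(scale * {146,150,197,182,98,74,70})` with the
#' published normal/abnormal grouping; nucleus-fraction ranges separate the
#' classes morphologically.
#'
#' @param scale in (0, 1]; every scaled class count must be >= 2
#' @param seed dataset seed
#' @param size image size
#' @param out_dir output directory (default: fresh temporary directory)
#' @param overwrite passed to [generate_dataset()]
#' @param noise_sd texture noise level
#' @return a `cyto_manifest`
#' @export
herlev_like_preset <- function(scale = 1, seed = 1L, size = c(64L, 64L),
                               out_dir = NULL, overwrite = FALSE,
                               noise_sd = 6) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  .preset_manifest(.herlev_table(), .herlev_fracs, scale, seed, size,
                   out_dir, overwrite, noise_sd)
}

#' SipaKMeD-like synthetic preset (5 classes, 4031 images at scale 1)
#' @inheritParams herlev_like_preset
#' @return a `cyto_manifest`
#' @export
sipakmed_like_preset <- function(scale = 1, seed = 1L, size = c(64L, 64L),
                                 out_dir = NULL, overwrite = FALSE,
                                 noise_sd = 6) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  .preset_manifest(.sipakmed_table(), .sipakmed_fracs, scale, seed, size,
                   out_dir, overwrite, noise_sd)
}

#' Two-class imbalanced specs (majority normal, minority abnormal)
#'
#' Convenience for imbalance experiments: a low nucleus-fraction majority
#' class and a high-fraction minority class.
#' @param n_major,n_minor class counts
#' @param noise_sd texture noise level
#' @return list of two [class_spec()]
#' @export
two_class_specs <- function(n_major, n_minor, noise_sd = 6) {
  list(class_spec(0L, n_major, nucleus_frac = c(0.06, 0.14),
                  noise_sd = noise_sd, group = "normal", name = "normal"),
       class_spec(1L, n_minor, nucleus_frac = c(0.30, 0.45),
                  noise_sd = noise_sd, group = "abnormal", name = "abnormal"))
}

#' Two-class specs with overlapping morphology (stress preset)
#'
#' Unlike [two_class_specs()], the nucleus-fraction ranges overlap
#' (majority 0.08-0.26, minority 0.18-0.34): even a Bayes-optimal
#' classifier cannot fully separate the classes, and under imbalance the
#' cost-unaware boundary sacrifices minority recall.  This preset is
#' substantially harder than the separable one — small models need far
#' longer budgets to learn it at all — and is provided for stress testing
#' rather than for the routine imbalance experiment.
#' @inheritParams two_class_specs
#' @return list of two [class_spec()]
#' @export
overlapping_two_class_specs <- function(n_major, n_minor, noise_sd = 10) {
  list(class_spec(0L, n_major, nucleus_frac = c(0.08, 0.26),
                  noise_sd = noise_sd, group = "normal", name = "normal"),
       class_spec(1L, n_minor, nucleus_frac = c(0.18, 0.34),
                  noise_sd = noise_sd, group = "abnormal", name = "abnormal"))
}
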