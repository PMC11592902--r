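# Loading class-labelled image trees, preprocessing, augmentation, and the
# stratified 70/15/15 + 5-fold splitting protocol.

#' Read a single-cell image file as a grey-level matrix (0-255)
#'
#' PNG is read natively; BMP through a built-in uncompressed 8/24-bit reader;
#' JPEG through EBImage when that package is installed.  Colour images are
#' collapsed to luminance.
#' @param path image file
#' @return numeric matrix in `[0, 255]`
#' @export
read_cell_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("unreadable image: ", path)),
    bmp = read_bmp(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG support requires the EBImage package: ", path)
      tryCatch(.ebimage_gray(path),
               error = function(e) stop("unreadable image: ", path))
    },
    stop("unsupported image format (need png/bmp/jpeg): ", path))
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    arr <- if (ch >= 3)
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr[, , 1]
  }
  round(arr * 255)
}

.ebimage_gray <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- EBImage::imageData(img)
  if (length(d) == 3L) m <- m[, , seq_len(min(3, d[3])), drop = FALSE]
  # EBImage stores x,y; transpose to row = y
  if (length(dim(m)) == 3L) aperm(m, c(2, 1, 3)) else t(m)
}

#' Minimal uncompressed BMP reader (8-bit greyscale or 24-bit BGR)
#' @keywords internal
#' @export
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 2)
  if (!identical(rawToChar(hdr), "BM")) stop("unreadable image: ", path)
  readBin(con, "raw", 8)
  offset <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "raw", 4)                           # DIB header size
  W <- readBin(con, "integer", 1, 4, endian = "little")
  H <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "raw", 2)                           # planes
  bpp <- readBin(con, "integer", 1, 2, endian = "little")
  comp <- readBin(con, "integer", 1, 4, endian = "little")
  if (comp != 0 || !(bpp %in% c(8L, 24L)))
    stop("unsupported BMP variant (need uncompressed 8/24-bit): ", path)
  seek(con, offset)
  bytes_pp <- bpp %/% 8L
  stride <- ((W * bytes_pp + 3L) %/% 4L) * 4L
  data <- readBin(con, "raw", stride * abs(H))
  img <- matrix(0, abs(H), W)
  for (r in seq_len(abs(H))) {
    row <- as.integer(data[(r - 1L) * stride + seq_len(W * bytes_pp)])
    line <- if (bpp == 8L) row
    else {
      b <- row[seq(1, length(row), 3)]
      g <- row[seq(2, length(row), 3)]
      rr <- row[seq(3, length(row), 3)]
      0.299 * rr + 0.587 * g + 0.114 * b
    }
    # BMP rows are stored bottom-up when H > 0
    img[if (H > 0) abs(H) - r + 1L else r, ] <- line
  }
  img / 255
}

#' Write a grey matrix (0-255) as an uncompressed 8-bit BMP
#' @keywords internal
#' @export
write_bmp <- function(img, path) {
  H <- nrow(img); W <- ncol(img)
  stride <- ((W + 3L) %/% 4L) * 4L
  off <- 14L + 40L + 256L * 4L
  sz <- off + stride * H
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(sz, 0L, off)), con, 4, endian = "little")
  writeBin(as.integer(c(40L, W, H)), con, 4, endian = "little")
  writeBin(as.integer(c(1L, 8L)), con, 2, endian = "little")
  writeBin(as.integer(c(0L, stride * H, 2835L, 2835L, 256L, 0L)), con, 4,
           endian = "little")
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))  # B,G,R,reserved per entry
  writeBin(as.vector(pal), con)
  v <- pmin(pmax(round(img), 0), 255)
  for (r in seq_len(H)) {
    line <- as.raw(c(v[H - r + 1L, ], rep(0L, stride - W)))
    writeBin(line, con)
  }
  invisible(path)
}

#' Load a class-labelled image tree into a manifest
#'
#' Each immediate subdirectory of `root` is a class; class ids are assigned
#' contiguously in sorted directory-name order, and records are sorted by
#' (class, filename).  Every file is decoded once to guarantee readability;
#' an unreadable or unsupported file aborts with its path.  Group flags are
#' recovered from a `manifest.csv` at the root when present.
#'
#' @param root directory containing one subdirectory per class
#' @return a `cyto_manifest`
#' @export
load_image_tree <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  dirs <- dirs[vapply(dirs, function(d)
    length(list.files(d, pattern = "\\.(png|bmp|jpg|jpeg)$",
                      ignore.case = TRUE)) > 0, TRUE)]
  if (!length(dirs)) stop("no class subdirectories with images under ", root)
  groups <- NULL
  mpath <- file.path(root, "manifest.csv")
  if (file.exists(mpath)) {
    mm <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    if (all(c("class", "group") %in% names(mm)))
      groups <- stats::setNames(mm$group, mm$class)[!duplicated(mm$class)]
  }
  rows <- list()
  for (i in seq_along(dirs)) {
    cls <- basename(dirs[i])
    files <- sort(list.files(dirs[i], pattern = "\\.(png|bmp|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) read_cell_image(f)  # readability contract
    rows[[i]] <- data.frame(path = files, class = cls,
                            class_id = i - 1L,
                            group = if (!is.null(groups) && cls %in% names(groups))
                              groups[[cls]] else "unknown",
                            stringsAsFactors = FALSE)
  }
  as_manifest(do.call(rbind, rows), root = root)
}

#' Preprocessing configuration
#' @param target_size length-2 integer target (height, width); default
#'   244 x 244
#' @param normalize rescale grey values to `[0, 1]`
#' @return a `preproc_config`
#' @export
preproc_config <- function(target_size = c(244L, 244L), normalize = TRUE) {
  if (length(target_size) != 2L || any(target_size < 1))
    stop("target_size must be two positive integers")
  structure(list(target_size = as.integer(target_size),
                 normalize = isTRUE(normalize)), class = "preproc_config")
}

#' Resize and normalise one image
#' @param image numeric matrix of grey values in `[0, 255]`
#' @param config a [preproc_config()]
#' @return matrix of `config$target_size` with values in `[0, 1]` (when
#'   normalising)
#' @export
preprocess <- function(image, config = preproc_config()) {
  if (!is.matrix(image) || !length(image)) stop("image must be a non-empty matrix")
  out <- bilinear_resize(image, config$target_size[1], config$target_size[2])
  if (config$normalize) out <- pmin(pmax(out / 255, 0), 1)
  out
}

#' Augmentation configuration
#'
#' The transform families follow standard practice for cytology crops:
#' random rotation, horizontal/vertical flips, isotropic zoom and shifts.
#' @param rotation_max_deg maximum absolute rotation (degrees)
#' @param hflip,vflip enable random flips (probability 1/2 each)
#' @param zoom_range multiplicative zoom interval (low <= high)
#' @param shift_fraction maximum shift as a fraction of each dimension, in
#'   `[0, 0.5)`
#' @param seed augmentation stream seed
#' @return an `augment_config`
#' @export
augment_config <- function(rotation_max_deg = 20, hflip = TRUE, vflip = TRUE,
                           zoom_range = c(0.9, 1.1), shift_fraction = 0.1,
                           seed = 0L) {
  if (zoom_range[1] > zoom_range[2]) stop("zoom_range low must be <= high")
  if (shift_fraction < 0 || shift_fraction >= 0.5)
    stop("shift_fraction must be in [0, 0.5)")
  structure(list(rotation_max_deg = rotation_max_deg, hflip = isTRUE(hflip),
                 vflip = isTRUE(vflip), zoom_range = as.numeric(zoom_range),
                 shift_fraction = shift_fraction, seed = as.integer(seed)),
            class = "augment_config")
}

#' Apply a random label-preserving augmentation to a preprocessed image
#'
#' Deterministic given (`config$seed`, `sample_seed`).  With all transforms
#' disabled (zero rotation/shift, unit zoom, flips off) this is the identity.
#' @param image numeric matrix (preprocessed, `[0, 1]`)
#' @param config an [augment_config()]
#' @param sample_seed per-sample seed
#' @return matrix of the same shape
#' @export
augment <- function(image, config = augment_config(), sample_seed = 0L) {
  H <- nrow(image); W <- ncol(image)
  with_seed(derive_seed(config$seed, sample_seed), {
    ang <- if (config$rotation_max_deg > 0)
      stats::runif(1, -config$rotation_max_deg, config$rotation_max_deg) *
        pi / 180 else 0
    fh <- config$hflip && stats::runif(1) < 0.5
    fv <- config$vflip && stats::runif(1) < 0.5
    zm <- if (diff(config$zoom_range) > 0)
      stats::runif(1, config$zoom_range[1], config$zoom_range[2])
    else config$zoom_range[1]
    sy <- if (config$shift_fraction > 0)
      stats::runif(1, -config$shift_fraction, config$shift_fraction) * H else 0
    sx <- if (config$shift_fraction > 0)
      stats::runif(1, -config$shift_fraction, config$shift_fraction) * W else 0
    identityish <- ang == 0 && !fh && !fv && zm == 1 && sy == 0 && sx == 0
    if (identityish) return(image)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    gy <- matrix(seq_len(H), H, W) - cy
    gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    if (fh) gx <- -gx
    if (fv) gy <- -gy
    # inverse map: rotate by -ang, scale by 1/zoom, then un-shift
    ca <- cos(-ang); sa <- sin(-ang)
    ys <- (gy * ca - gx * sa) / zm + cy - sy
    xs <- (gy * sa + gx * ca) / zm + cx - sx
    matrix(bilinear_sample(image, as.vector(ys), as.vector(xs)), H, W)
  })
}

#' Split specification (stratified, largest-remainder apportionment)
#' @param fractions train/val/test fractions summing to 1
#' @param seed shuffle seed
#' @return a `split_spec`
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), seed = 0L) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values in (0,1) summing to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 rounding = "largest_remainder"), class = "split_spec")
}

#' Stratified train/validation/test split of a manifest
#'
#' Within each class, counts follow largest-remainder apportionment of the
#' fractions with ties broken toward the earlier split (train > val > test);
#' sample assignment is a seeded shuffle.  The three manifests partition the
#' input.
#' @param manifest a `cyto_manifest`
#' @param spec a [split_spec()]
#' @return named list of manifests: train, val, test
#' @export
stratified_split <- function(manifest, spec = split_spec()) {
  cnt <- manifest_counts(manifest)
  if (any(cnt < 3))
    stop("every class needs at least 3 samples to split; smallest has ",
         min(cnt))
  parts <- list(train = NULL, val = NULL, test = NULL)
  for (cls in names(cnt)) {
    rows <- which(manifest$class == cls)
    n <- length(rows)
    alloc <- largest_remainder(n, spec$fractions)
    perm <- with_seed(derive_seed(spec$seed, match(cls, names(cnt))),
                      sample.int(n))
    rows <- rows[perm]
    idx <- list(train = rows[seq_len(alloc[1])],
                val = rows[alloc[1] + seq_len(alloc[2])],
                test = rows[alloc[1] + alloc[2] + seq_len(alloc[3])])
    for (k in names(parts))
      parts[[k]] <- rbind(parts[[k]], manifest[idx[[k]], , drop = FALSE])
  }
  lapply(parts, as_manifest, root = attr(manifest, "root"))
}

#' Stratified k-fold partition of a manifest
#'
#' @param manifest typically the union of training and validation manifests
#' @param k number of folds
#' @param seed shuffle seed
#' @return list of k elements, each `list(fit = manifest, holdout = manifest)`;
#'   holdouts are disjoint and exhaustive
#' @export
kfold <- function(manifest, k = 5L, seed = 0L) {
  cnt <- manifest_counts(manifest)
  if (any(cnt < k))
    stop("every class needs at least k = ", k, " samples; smallest has ",
         min(cnt))
  fold_of <- integer(nrow(manifest))
  for (cls in names(cnt)) {
    rows <- which(manifest$class == cls)
    perm <- with_seed(derive_seed(seed, 1000L + match(cls, names(cnt))),
                      sample.int(length(rows)))
    fold_of[rows[perm]] <- rep_len(seq_len(k), length(rows))
  }
  lapply(seq_len(k), function(f)
    list(fit = as_manifest(manifest[fold_of != f, , drop = FALSE],
                           root = attr(manifest, "root")),
         holdout = as_manifest(manifest[fold_of == f, , drop = FALSE],
                               root = attr(manifest, "root"))))
}

#' Load, preprocess and stack the images of a manifest
#'
#' @param manifest a `cyto_manifest`
#' @param config a [preproc_config()]
#' @return list: `x` an array (n, H, W), `y` integer class ids (1-based),
#'   `group` character vector
#' @export
load_images <- function(manifest, config = preproc_config()) {
  n <- nrow(manifest)
  H <- config$target_size[1]; W <- config$target_size[2]
  x <- array(0, c(n, H, W))
  for (i in seq_len(n))
    x[i, , ] <- preprocess(read_cell_image(manifest$path[i]), config)
  list(x = x, y = manifest$class_id + 1L, group = manifest$group)
}
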