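# Disk formats: grayscale PNG images (16-bit for images, 8-bit for
# masks and heatmaps), CSV label/log tables, JSON manifests and YAML
# configuration files.  Reading goes through png::readPNG, which
# handles 8- and 16-bit grayscale; writing 16-bit grayscale PNG is done
# by a minimal encoder below because no installed writer emits 16-bit
# samples.

.crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        cc <- n
        for (k in 1:8)
          cc <- if (bitwAnd(cc, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(cc, 1L))  # 0xEDB88320
          else bitwShiftR(cc, 1L)
        t[n + 1] <- cc
      }
      tab <<- t
    }
    tab
  }
})

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

.u32be <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

.png_chunk <- function(type, data) {
  tb <- charToRaw(type)
  c(.u32be(length(data)), tb, data, .u32be(.crc32(c(tb, data))))
}

#' Write a grayscale PNG
#'
#' Minimal grayscale PNG encoder supporting 8- and 16-bit samples.
#' Values are clipped to `[0, 1]` and quantized to the requested bit
#' depth; output bytes are fully deterministic (no timestamps or
#' ancillary chunks), so identical matrices give identical files.
#'
#' @param m Numeric matrix with values in `[0, 1]` (rows are scanlines).
#' @param path Output path.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(m, path, bits = 16L) {
  stopifnot(is.matrix(m), bits %in% c(8L, 16L))
  H <- nrow(m); W <- ncol(m)
  mx <- 2^bits - 1
  V <- t(round(pmin(pmax(m, 0), 1) * mx))  # column i = scanline i
  if (bits == 16L) {
    D <- matrix(0L, 2 * W, H)
    D[seq(1, 2 * W, 2), ] <- V %/% 256L
    D[seq(2, 2 * W, 2), ] <- V %% 256L
  } else {
    D <- matrix(as.integer(V), W, H)
  }
  Fm <- rbind(0L, D)  # filter byte 0 before each scanline
  idat <- memCompress(as.raw(Fm), type = "gzip")
  ihdr <- c(.u32be(W), .u32be(H), as.raw(c(bits, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale PNG and standardizes pixel values to
#' `[0, 1]` regardless of bit depth.  Multi-channel files are collapsed
#' to their first channel.
#'
#' @param path PNG file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' Write a synthetic dataset to disk
#'
#' Lays out `dir/images/<id>.png` (16-bit grayscale),
#' `dir/masks/<id>.png` (8-bit, 0/255), `dir/labels.csv` with columns
#' `id,label`, and `dir/manifest.json`.
#'
#' @param dataset An `lem_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (im in dataset$images) {
    write_gray_png(im$pixels, file.path(dir, "images",
                                        paste0(im$id, ".png")), bits = 16L)
    if (!is.null(im$mask))
      write_gray_png((im$mask > 0) * 1, file.path(dir, "masks",
                                                  paste0(im$id, ".png")),
                     bits = 8L)
  }
  labels <- data.frame(id = vapply(dataset$images, `[[`, "", "id"),
                       label = lem_labels(dataset))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  write_manifest(file.path(dir, "manifest.json"), command = "generate",
                 params = dataset[c("n", "image_size", "class_balance",
                                    "noise_sd", "max_lesion_frac")],
                 seed = dataset$seed, outputs = dir)
  invisible(dir)
}

#' Read a dataset from disk
#'
#' Reads the layout written by [write_dataset()] (masks are optional;
#' any directory with `images/` and `labels.csv` in that layout works).
#'
#' @param dir Dataset directory.
#' @return An `lem_dataset`.
#' @export
read_dataset <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("missing labels.csv in ", dir)
  labels <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(labels)))
  images <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$id[i]
    px <- read_gray_png(file.path(dir, "images", paste0(id, ".png")))
    mp <- file.path(dir, "masks", paste0(id, ".png"))
    mask <- if (file.exists(mp)) (read_gray_png(mp) > 0.5) * 1 else NULL
    structure(list(pixels = px, label = as.integer(labels$label[i]),
                   mask = mask, id = id), class = "lem_image")
  })
  size <- nrow(images[[1]]$pixels)
  meta <- list(seed = NA_integer_)
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    if (!is.null(man$seed)) meta$seed <- as.integer(man$seed)
  }
  structure(list(images = images, n = length(images), image_size = size,
                 seed = meta$seed), class = "lem_dataset")
}

#' Write a run manifest
#'
#' Every artifact-producing command records what produced its outputs:
#' the command name, parameters, seed, input/output paths, package
#' version and a timestamp.
#'
#' @param path Manifest path (JSON).
#' @param command Command name.
#' @param params Named list of parameters.
#' @param seed Integer seed, if any.
#' @param inputs,outputs Character vectors of paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params = list(), seed = NULL,
                           inputs = character(0), outputs = character(0)) {
  jsonlite::write_json(list(
    command = command, params = params, seed = seed,
    inputs = inputs, outputs = outputs,
    package = "lemap",
    version = as.character(utils::packageVersion("lemap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read or write a configuration file
#'
#' The configuration file is YAML with one entry per [lem_config()]
#' field.  Every field must be present explicitly -- in particular the
#' free factors `gamma` and `mu` -- so that no hidden defaults enter a
#' run.
#'
#' @param path Config file path.
#' @return `read_config` returns an `lem_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  vals <- yaml::yaml.load_file(path)
  required <- setdiff(names(formals(lem_config)), "alpha_ramp")
  missing <- setdiff(required, names(vals))
  if (length(missing) > 0)
    stop("configuration file must set every field explicitly; missing: ",
         paste(missing, collapse = ", "))
  do.call(lem_config, vals[intersect(names(vals), names(formals(lem_config)))])
}

#' @rdname read_config
#' @param config An `lem_config` to serialize.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configuration files")
  stopifnot(inherits(config, "lem_config"))
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}
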