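#' Gland annotation polygon
#'
#' A closed, simple polygon outlining one epithelial gland, in 0-based pixel
#' coordinates (x = column, y = row) of the analysis-resolution image, together
#' with the identifier of its core and the core-level class label. Every gland
#' inherits its core's diagnosis: all glands of a core read malignant are
#' labelled malignant, and likewise for benign.
#'
#' @param vertices Two-column numeric matrix (x, y) of polygon vertices in
#'   order; the first vertex implicitly follows the last (closed curve).
#' @param core_id Core identifier.
#' @param label Class label, `"benign"` or `"malignant"`.
#' @param gland_id Identifier of the gland within its core.
#' @param check_simple Verify that the polygon is non-self-intersecting
#'   (O(n^2); disable for large trusted polygons).
#' @return An object of class `GlandAnnotation`.
#' @export
gland_annotation <- function(vertices, core_id, label,
                             gland_id = "g1", check_simple = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || !is.numeric(vertices))
    stop("`vertices` must be a two-column numeric (x, y) matrix")
  # collapse an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (n >= 2 && all(vertices[1, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3)
    stop("a gland polygon needs at least 3 distinct vertices")
  if (any(!is.finite(vertices))) stop("polygon vertices must be finite")
  label <- match.arg(label, c("benign", "malignant"))
  if (check_simple && polygon_self_intersects(vertices))
    stop(sprintf("polygon for gland '%s' of core '%s' is self-intersecting",
                 gland_id, core_id))
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(
    list(vertices = vertices, core_id = as.character(core_id),
         gland_id = as.character(gland_id), label = label),
    class = "GlandAnnotation")
}

#' @export
print.GlandAnnotation <- function(x, ...) {
  cat(sprintf("<GlandAnnotation %s/%s> %s, %d vertices, area %.1f px^2\n",
              x$core_id, x$gland_id, x$label, nrow(x$vertices),
              polygon_area(x$vertices)))
  invisible(x)
}

#' Shoelace area of a polygon
#' @param vertices Two-column (x, y) vertex matrix.
#' @return Unsigned area in squared pixel units.
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Proper-crossing test between non-adjacent edge pairs; shared endpoints of
# consecutive edges are not intersections.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n > 2000) return(FALSE)  # generator-scale polygons are simple by construction
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    d1 <- (x2[i] - x1[i]) * (y1[js] - y1[i]) - (y2[i] - y1[i]) * (x1[js] - x1[i])
    d2 <- (x2[i] - x1[i]) * (y2[js] - y1[i]) - (y2[i] - y1[i]) * (x2[js] - x1[i])
    d3 <- (x2[js] - x1[js]) * (y1[i] - y1[js]) - (y2[js] - y1[js]) * (x1[i] - x1[js])
    d4 <- (x2[js] - x1[js]) * (y2[i] - y1[js]) - (y2[js] - y1[js]) * (x2[i] - x1[js])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Read gland annotations
#'
#' Reads gland outlines from an ImageJ `.roi` file, a `.zip` archive of
#' ImageJ ROIs, or the package's polygon JSON dialect
#' `{core_id, label, glands: [[[x, y], ...], ...]}`. Vertex coordinates are
#' divided by `scale` (the ratio of the annotation resolution to the analysis
#' resolution) and rounded to the analysis pixel grid. Labels come from the
#' JSON itself or, for ImageJ files, from a sidecar core-label table.
#'
#' @param path Annotation file (`.roi`, `.zip`, or `.json`).
#' @param scale Annotation-to-analysis resolution ratio (e.g. 1 when glands
#'   were annotated on the analysis-resolution image).
#' @param core_id Core identifier; defaults to the file stem for ImageJ input.
#' @param labels Named character vector or data frame (`core_id`, `label`)
#'   mapping cores to class labels; required for ImageJ input.
#' @return List of [gland_annotation()] objects.
#' @export
read_annotations <- function(path, scale = 1, core_id = NULL, labels = NULL) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    return(read_annotations_json(path, scale))
  }
  if (is.null(core_id)) core_id <- tools::file_path_sans_ext(basename(path))
  label <- lookup_core_label(core_id, labels)
  if (ext == "roi") {
    v <- read_imagej_roi(path)
    return(list(make_scaled_annotation(v, scale, core_id, label, "g1")))
  }
  if (ext == "zip") {
    exdir <- tempfile("rois")
    files <- utils::unzip(path, exdir = exdir)
    files <- sort(files[tolower(tools::file_ext(files)) == "roi"])
    if (!length(files)) stop(sprintf("no .roi entries found in %s", path))
    return(lapply(seq_along(files), function(i)
      make_scaled_annotation(read_imagej_roi(files[i]), scale, core_id, label,
                             sprintf("g%d", i))))
  }
  stop(sprintf("unsupported annotation format: .%s", ext))
}

read_annotations_json <- function(path, scale) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$core_id) || is.null(doc$label) || is.null(doc$glands))
    stop("annotation JSON must contain core_id, label and glands")
  glands <- doc$glands
  if (is.array(glands) && length(dim(glands)) == 3) {
    # equally sized polygons simplify to an n_glands x n_vertices x 2 array
    glands <- lapply(seq_len(dim(glands)[1]), function(i) glands[i, , ])
  } else if (is.matrix(glands) || is.data.frame(glands)) {
    glands <- list(glands)
  }
  lapply(seq_along(glands), function(i) {
    v <- as.matrix(glands[[i]])
    make_scaled_annotation(v, scale, doc$core_id, doc$label, sprintf("g%d", i))
  })
}

make_scaled_annotation <- function(v, scale, core_id, label, gland_id) {
  v <- round(v / scale)
  v <- collapse_duplicate_vertices(v)
  gland_annotation(v, core_id, label, gland_id)
}

lookup_core_label <- function(core_id, labels) {
  if (is.null(labels))
    stop("ImageJ annotations need a core-label table (`labels`)")
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$label),
                              as.character(labels$core_id))
  }
  if (!core_id %in% names(labels))
    stop(sprintf("core '%s' not present in the label table", core_id))
  unname(labels[core_id])
}

#' Read a core-label table
#' @param path CSV file with columns `core_id,label`.
#' @return Data frame with character `core_id` and `label` columns.
#' @export
read_core_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("core_id", "label") %in% names(df)))
    stop("label table must have columns core_id and label")
  bad <- setdiff(unique(df$label), c("benign", "malignant"))
  if (length(bad))
    stop(sprintf("unknown label(s) in table: %s", paste(bad, collapse = ", ")))
  df$core_id <- as.character(df$core_id)
  df
}

#' Write annotations in the polygon JSON dialect
#' @param annotations List of [gland_annotation()] for one core.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(annotations, path) {
  stopifnot(length(annotations) > 0)
  core_id <- annotations[[1]]$core_id
  label <- annotations[[1]]$label
  doc <- list(core_id = core_id, label = label,
              glands = lapply(annotations, function(a)
                unname(apply(a$vertices, 1, function(r) r, simplify = FALSE))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

collapse_duplicate_vertices <- function(v) {
  n <- nrow(v)
  if (n < 2) return(v)
  keep <- c(TRUE, rowSums(abs(v[-1, , drop = FALSE] -
                              v[-n, , drop = FALSE])) > 0)
  v <- v[keep, , drop = FALSE]
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  v
}

#' Rasterize a gland polygon to a binary mask
#'
#' Marks every pixel whose center lies inside the polygon under the even-odd
#' rule; pixels whose centers fall exactly on the boundary are included.
#' Pixel centers are at integer coordinates (0-based), matching the
#' annotation convention.
#'
#' @param g A [gland_annotation()].
#' @param shape Raster dimensions `c(rows, cols)`.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_gland_mask <- function(g, shape) {
  stopifnot(inherits(g, "GlandAnnotation"), length(shape) == 2)
  v <- g$vertices
  if (polygon_area(v) == 0)
    stop(sprintf("degenerate zero-area polygon for gland %s/%s",
                 g$core_id, g$gland_id))
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  ymin <- max(0L, floor(min(v[, 2]))); ymax <- min(nr - 1L, ceiling(max(v[, 2])))
  if (ymax < ymin) return(mask)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  for (y in ymin:ymax) {
    # even-odd scanline: count crossings of the horizontal line through y;
    # half-open vertex rule avoids double counting, boundary handled below
    cross <- ((y1 <= y) & (y2 > y)) | ((y2 <= y) & (y1 > y))
    if (!any(cross)) xs <- numeric(0)
    else xs <- sort(x1[cross] + (y - y1[cross]) / (y2[cross] - y1[cross]) *
                      (x2[cross] - x1[cross]))
    if (length(xs) >= 2) {
      for (k in seq(1, length(xs) - 1, by = 2)) {
        a <- ceiling(xs[k] - 1e-9); b <- floor(xs[k + 1] + 1e-9)
        a <- max(a, 0); b <- min(b, nc - 1L)
        if (b >= a) mask[y + 1L, (a:b) + 1L] <- TRUE
      }
    }
    # boundary inclusion for horizontal edges at this scanline
    horiz <- which(y1 == y & y2 == y)
    for (e in horiz) {
      a <- max(0, ceiling(min(x1[e], x2[e]))); b <- min(nc - 1L, floor(max(x1[e], x2[e])))
      if (b >= a) mask[y + 1L, (a:b) + 1L] <- TRUE
    }
  }
  mask
}

#' Check that all polygon vertices are inside an image raster
#' @param g A [gland_annotation()].
#' @param shape Raster dimensions `c(rows, cols)`.
#' @return `TRUE` invisibly; errors when out of bounds.
#' @export
check_annotation_bounds <- function(g, shape) {
  v <- g$vertices
  if (any(v[, 1] < 0 | v[, 1] > shape[2] - 1 | v[, 2] < 0 | v[, 2] > shape[1] - 1))
    stop(sprintf("gland %s/%s has vertices outside the %dx%d raster",
                 g$core_id, g$gland_id, shape[1], shape[2]))
  invisible(TRUE)
}
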