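#' Target patterns and organ masks
#'
#' A target pattern is the anatomical setpoint of a morphogenesis task: an
#' `height x width` integer grid whose entries are cell types in
#' `{1, ..., n_types}`. Organ masks name sub-regions of the pattern (e.g. the
#' eyes and mouth of the smiley fixture) as boolean grids, optionally with a
#' one-cell boundary ring of adjacent non-organ tissue used by the
#' boundary-augmented rejuvenation protocols.
#'
#' Grids are stored as R matrices with `mat[r, c]` the cell in row `r`,
#' column `c` (1-based internally; the JSON file dialect uses 0-based
#' `[row, col]` coordinates). Flattened cell indices follow R's column-major
#' order throughout the package.
#'
#' @param types integer matrix of cell types.
#' @param n_types number of distinct cell types `N_G`; defaults to
#'   `max(types)`.
#' @param organs optional named list of [organ_mask()] objects.
#' @return an object of class `nca_pattern` with fields `width`, `height`,
#'   `n_types`, `types` and optionally `organs`.
#' @seealso [make_smiley()], [make_stripe()], [read_pattern()]
#' @export
target_pattern <- function(types, n_types = max(types), organs = NULL) {
  if (!is.matrix(types)) stop("`types` must be a matrix")
  storage.mode(types) <- "integer"
  if (anyNA(types) || any(types < 1L) || any(types > n_types)) {
    stop(sprintf("cell types must be integers in 1..%d", n_types))
  }
  p <- list(width = ncol(types), height = nrow(types),
            n_types = as.integer(n_types), types = types, organs = organs)
  class(p) <- "nca_pattern"
  if (!is.null(organs)) {
    for (o in organs) check_mask_disjoint(o, p)
    nm <- vapply(organs, function(o) o$name, "")
    for (i in seq_along(organs)) for (j in seq_len(i - 1L)) {
      if (any(organs[[i]]$cells & organs[[j]]$cells)) {
        stop(sprintf("organ masks '%s' and '%s' overlap", nm[i], nm[j]))
      }
    }
  }
  p
}

check_mask_disjoint <- function(mask, pattern) {
  if (nrow(mask$cells) != pattern$height || ncol(mask$cells) != pattern$width) {
    stop("organ mask dimensions do not match the pattern grid")
  }
  invisible(TRUE)
}

#' @export
print.nca_pattern <- function(x, ...) {
  cat(sprintf("Target pattern: %d x %d grid, %d cell types\n",
              x$height, x$width, x$n_types))
  if (!is.null(x$organs)) {
    cat("Organs:", paste(names(x$organs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct an organ mask
#'
#' @param name organ name (e.g. `"LeftEye"`).
#' @param cells logical matrix marking organ cells.
#' @param boundary optional logical matrix marking the one-cell boundary ring
#'   of adjacent non-organ tissue; usually filled in by [dilate_boundary()].
#' @return an object of class `organ_mask` with fields `name`, `cells`,
#'   `boundary_cells` and `n_target_cells`.
#' @export
organ_mask <- function(name, cells, boundary = NULL) {
  if (!is.matrix(cells) || !is.logical(cells)) stop("`cells` must be a logical matrix")
  if (!any(cells)) stop("organ mask must contain at least one cell")
  if (!is.null(boundary)) {
    stopifnot(is.logical(boundary), all(dim(boundary) == dim(cells)))
    if (any(boundary & cells)) stop("boundary cells must not overlap organ cells")
  }
  m <- list(name = name, cells = cells, boundary_cells = boundary,
            n_target_cells = sum(cells))
  class(m) <- "organ_mask"
  m
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf("Organ mask '%s': %d cells%s\n", x$name, x$n_target_cells,
              if (is.null(x$boundary_cells)) "" else
                sprintf(", %d boundary cells", sum(x$boundary_cells))))
  invisible(x)
}

#' Compute the one-cell boundary ring around an organ
#'
#' Dilates the organ cells with the Moore (8-neighbor) structuring element,
#' removes the organ itself, and clips to the grid, yielding the ring of
#' adjacent non-organ tissue used by boundary-augmented organ scoring and
#' interventions.
#'
#' @param mask an [organ_mask()].
#' @param pattern the [target_pattern()] the mask belongs to (supplies grid
#'   dimensions).
#' @return the mask with its `boundary_cells` field filled in.
#' @export
dilate_boundary <- function(mask, pattern) {
  check_mask_disjoint(mask, pattern)
  if (!any(mask$cells)) stop("cannot dilate an empty organ mask")
  h <- pattern$height; w <- pattern$width
  dil <- matrix(FALSE, h, w)
  idx <- which(mask$cells, arr.ind = TRUE)
  for (dr in -1:1) for (dc in -1:1) {
    r <- idx[, 1] + dr; c <- idx[, 2] + dc
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    dil[cbind(r[ok], c[ok])] <- TRUE
  }
  organ_mask(mask$name, mask$cells, boundary = dil & !mask$cells)
}

#' The canonical 16 x 16 smiley-face fixture
#'
#' Builds the package's canonical morphogenesis target: a 16 x 16 grid with
#' three cell types (1 = background, 2 = face, 3 = organ), a roughly circular
#' face, two 2 x 2 eye blocks and a one-cell-thick mouth arc, together with
#' the three named organ masks (`LeftEye`, `RightEye`, `Mouth`), each with
#' its boundary ring filled in. The layout is versioned: it is defined once
#' here and shipped verbatim at `inst/extdata/smiley.json`.
#'
#' The pattern is reminiscent of the bioelectric craniofacial prepattern of
#' the developing amphibian face; its exact pixel layout is a fixed package
#' decision, since the experiments the platform supports are pattern-agnostic.
#'
#' @return a [target_pattern()] with `organs` attached.
#' @examples
#' p <- make_smiley()
#' table(p$types)
#' @export
make_smiley <- function() {
  h <- 16L; w <- 16L
  types <- matrix(1L, h, w)
  ctr <- (1 + 16) / 2  # 8.5 in 1-based coordinates
  for (r in 1:h) for (c in 1:w) {
    if ((r - ctr)^2 + (c - ctr)^2 <= 6.8^2) types[r, c] <- 2L
  }
  eyeL <- matrix(FALSE, h, w); eyeL[5:6, 5:6] <- TRUE
  eyeR <- matrix(FALSE, h, w); eyeR[5:6, 11:12] <- TRUE
  mouth <- matrix(FALSE, h, w)
  mouth[11, 6:11] <- TRUE
  mouth[10, c(5, 12)] <- TRUE
  types[eyeL | eyeR | mouth] <- 3L
  pat <- target_pattern(types, n_types = 3L)
  organs <- list(LeftEye = organ_mask("LeftEye", eyeL),
                 RightEye = organ_mask("RightEye", eyeR),
                 Mouth = organ_mask("Mouth", mouth))
  organs <- lapply(organs, dilate_boundary, pattern = pat)
  target_pattern(types, n_types = 3L, organs = organs)
}

#' Small toy patterns for fast experiments and tests
#'
#' `make_stripe()` builds a two-type vertical stripe (left half type 1, right
#' half type 2) on a small grid, the standard scaled-down evolution task. A
#' 2 x 2 `Block` organ mask inside the type-2 region (with boundary ring) is
#' attached so organ-level monitoring and rejuvenation protocols can be
#' exercised on the toy organism.
#'
#' @param width,height grid dimensions (defaults 4 x 4).
#' @return a [target_pattern()] with a `Block` organ attached.
#' @export
make_stripe <- function(width = 4L, height = 4L) {
  types <- matrix(1L, height, width)
  types[, (width %/% 2 + 1):width] <- 2L
  pat <- target_pattern(types, n_types = 2L)
  cells <- matrix(FALSE, height, width)
  r0 <- max(1L, height %/% 2); c0 <- max(1L, width - 1L)
  cells[r0:min(height, r0 + 1L), c0:min(width, c0 + 1L)] <- TRUE
  block <- dilate_boundary(organ_mask("Block", cells), pat)
  target_pattern(types, n_types = 2L, organs = list(Block = block))
}

#' Read and write target patterns
#'
#' Two plain-text formats are supported, chosen by file extension:
#' * `.txt` (or anything not `.json`): one grid row per line, space-separated
#'   integers; organ masks are not stored.
#' * `.json`: `{"width", "height", "n_types", "types": [[...]],
#'   "organs": {name: {"cells": [[r, c], ...]}}}` with 0-based row/col
#'   coordinates.
#'
#' Reading a written pattern reproduces it exactly (bit-exact integer grids).
#'
#' @param path file path.
#' @param n_types optional expected number of cell types; values outside
#'   `{1..n_types}` raise a format error.
#' @return for `read_pattern`, a [target_pattern()] (with organs when the
#'   JSON file stores them).
#' @export
read_pattern <- function(path, n_types = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    types <- js$types
    if (!is.matrix(types)) types <- do.call(rbind, lapply(types, as.integer))
    storage.mode(types) <- "integer"
    nt <- if (is.null(n_types)) as.integer(js$n_types) else as.integer(n_types)
    organs <- NULL
    if (!is.null(js$organs) && length(js$organs)) {
      organs <- lapply(names(js$organs), function(nm) {
        cm <- matrix(FALSE, js$height, js$width)
        cc <- js$organs[[nm]]$cells
        cc <- if (is.matrix(cc)) cc else matrix(unlist(cc), ncol = 2, byrow = TRUE)
        cm[cbind(cc[, 1] + 1L, cc[, 2] + 1L)] <- TRUE
        m <- organ_mask(nm, cm)
        bc <- js$organs[[nm]]$boundary_cells
        if (!is.null(bc) && length(bc)) {
          bm <- matrix(FALSE, js$height, js$width)
          bc <- if (is.matrix(bc)) bc else matrix(unlist(bc), ncol = 2, byrow = TRUE)
          bm[cbind(bc[, 1] + 1L, bc[, 2] + 1L)] <- TRUE
          m <- organ_mask(nm, cm, boundary = bm)
        }
        m
      })
      names(organs) <- names(js$organs)
    }
    return(target_pattern(types, n_types = nt, organs = organs))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), function(x) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) stop("pattern file contains non-integer entries")
    v
  })
  if (length(unique(lengths(rows))) != 1L) stop("ragged rows in pattern file")
  types <- do.call(rbind, rows)
  nt <- if (is.null(n_types)) max(types) else as.integer(n_types)
  target_pattern(types, n_types = nt)
}

#' @rdname read_pattern
#' @param pattern a [target_pattern()].
#' @export
write_pattern <- function(pattern, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    organs <- NULL
    if (!is.null(pattern$organs)) {
      organs <- lapply(pattern$organs, function(o) {
        out <- list(cells = unname(which(o$cells, arr.ind = TRUE) - 1L))
        if (!is.null(o$boundary_cells)) {
          out$boundary_cells <- unname(which(o$boundary_cells, arr.ind = TRUE) - 1L)
        }
        out
      })
    }
    js <- list(width = pattern$width, height = pattern$height,
               n_types = pattern$n_types,
               types = unname(pattern$types), organs = organs)
    jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    writeLines(apply(pattern$types, 1L, paste, collapse = " "), path)
  }
  invisible(path)
}

#' @rdname make_stripe
#' @details `make_toy_face()` builds an 8 x 8 miniature of the smiley
#'   fixture's anatomy — a background ring (type 1), a 6 x 6 face block
#'   (type 2), two 2 x 2 eye blocks and a 4-cell mouth bar of the organ type
#'   (type 3) — with `LeftEye`, `RightEye` and `Mouth` organ masks and their
#'   boundary rings attached. Small organs of a distinct type embedded in
#'   host tissue are the structures whose loss drives long-term fitness
#'   decline, so this is the standard toy for scaled-down aging and
#'   rejuvenation experiments.
#' @export
make_toy_face <- function() {
  types <- matrix(1L, 8L, 8L)
  types[2:7, 2:7] <- 2L
  types[3:4, 3:4] <- 3L
  types[3:4, 6:7] <- 3L
  types[6, 3:6] <- 3L
  pat <- target_pattern(types, n_types = 3L)
  mk <- function(nm, rows, cols) {
    m <- matrix(FALSE, 8L, 8L)
    m[rows, cols] <- TRUE
    dilate_boundary(organ_mask(nm, m), pat)
  }
  organs <- list(LeftEye = mk("LeftEye", 3:4, 3:4),
                 RightEye = mk("RightEye", 3:4, 6:7),
                 Mouth = mk("Mouth", 6L, 3:6))
  target_pattern(types, n_types = 3L, organs = organs)
}

# flattened (column-major) indices of a logical grid mask
mask_index <- function(mask_matrix) which(as.vector(mask_matrix))
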