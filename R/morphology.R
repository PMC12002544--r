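#' @include AllClasses.R
NULL

# Coerce an MRVolume or array to a logical mask array, insisting on
# binary content.
.asMaskArray <- function(x, what = "mask") {
  a <- if (is(x, "MRVolume")) x@data else x
  if (is.logical(a)) return(a)
  v <- a[!is.nan(a)]
  if (length(v) != length(a) || !all(v == 0 | v == 1))
    stop(what, " is not a binary mask")
  array(a == 1, dim = dim(a))
}

# Wrap a logical array like the input object (MRVolume in -> MRVolume out).
.wrapLike <- function(template, arr) {
  if (is(template, "MRVolume")) mrVolume(arr, template@affine, "") else arr
}

#' Discrete spherical structuring element
#'
#' All integer voxel offsets with Euclidean norm at most `radius` — the
#' "sphere-shaped structuring element of radius n voxels" used for
#' perilesional and concentric shell construction. Radii are interpreted
#' in voxel units (the reference grid is isotropic 1 mm; on anisotropic
#' grids the radius is still in voxels and a warning is emitted by the
#' VOI builder).
#'
#' @param radius integer radius >= 0, in voxels.
#' @return Integer matrix with one offset (x, y, z) per row, containing
#'   the origin and closed under negation. `radius = 1` has 7 offsets
#'   (origin + 6 face neighbours), `radius = 2` has 33.
#' @export
makeBall <- function(radius) {
  if (length(radius) != 1L || radius < 0 || radius != round(radius))
    stop("radius must be a single non-negative integer")
  r <- as.integer(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= r^2, , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Translate a logical array by an integer offset, filling with FALSE.
.shiftMask <- function(m, off) {
  d <- dim(m)
  if (any(abs(off) >= d)) return(array(FALSE, d))
  dst <- src <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o) }
    else        { dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a] }
  }
  out <- array(FALSE, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation and erosion with a spherical structuring element
#'
#' Shift-accumulate morphology on 3D logical masks. `dilateMask` ORs the
#' mask translated by every ball offset; `erodeMask` keeps a voxel only
#' when the whole ball around it lies inside the mask (so erosion output
#' is always a subset of the input, and a single voxel erodes to empty).
#'
#' @param mask binary [MRVolume-class] or logical/0-1 array.
#' @param ball offset matrix from [makeBall()].
#' @return Mask of the same type as the input.
#' @export
dilateMask <- function(mask, ball = makeBall(1)) {
  m <- .asMaskArray(mask)
  out <- array(FALSE, dim(m))
  if (any(m)) for (i in seq_len(nrow(ball))) {
    out <- out | .shiftMask(m, ball[i, ])
  }
  .wrapLike(mask, out)
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, ball = makeBall(1)) {
  m <- .asMaskArray(mask)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(ball))) {
    out <- out & .shiftMask(m, -ball[i, ])
    if (!any(out)) break
  }
  .wrapLike(mask, out)
}

# Neighbourhood offsets for connected components.
.connectivityOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

#' Label connected lesion components
#'
#' Breadth-first connected-component labelling of a binary lesion mask so
#' that each focal lesion can be analysed individually. Components are
#' maximal under the chosen neighbourhood (26-connectivity by default,
#' the standard for lesion labelling; 6-connectivity available). Labels
#' are assigned in deterministic order: component 1 contains the first
#' true voxel in array order.
#'
#' @param mask binary [MRVolume-class] or logical/0-1 array.
#' @param connectivity 26 (vertex/edge/face neighbours) or 6 (face only).
#' @return A [LesionComponents-class] object.
#' @export
labelLesions <- function(mask, connectivity = 26) {
  m <- .asMaskArray(mask, "lesion mask")
  d <- dim(m)
  offs <- .connectivityOffsets(as.integer(connectivity))
  labels <- array(0L, d)
  seeds <- which(m)
  lab <- 0L
  rows <- list()
  for (s in seeds) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    size <- 1L
    bb <- arrayInd(s, d)
    bbMin <- bb[1, ]; bbMax <- bb[1, ]
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        nc <- co + matrix(offs[i, ], nrow(co), 3, byrow = TRUE)
        ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] &
              nc[, 2] >= 1 & nc[, 2] <= d[2] &
              nc[, 3] >= 1 & nc[, 3] <= d[3]
        if (!any(ok)) next
        ni <- nc[ok, 1] + d[1] * (nc[ok, 2] - 1) + d[1] * d[2] * (nc[ok, 3] - 1)
        ni <- ni[m[ni] & labels[ni] == 0L]
        if (length(ni)) {
          labels[ni] <- lab
          nxt <- c(nxt, ni)
        }
      }
      frontier <- unique(nxt)
      if (length(frontier)) {
        co2 <- arrayInd(frontier, d)
        bbMin <- pmin(bbMin, apply(co2, 2, min))
        bbMax <- pmax(bbMax, apply(co2, 2, max))
        size <- size + length(frontier)
      }
    }
    rows[[lab]] <- data.frame(label = lab, n_voxels = size,
                              x0 = bbMin[1], x1 = bbMax[1],
                              y0 = bbMin[2], y1 = bbMax[2],
                              z0 = bbMin[3], z1 = bbMax[3],
                              dropped = FALSE, reason = "")
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), n_voxels = integer(0),
               x0 = integer(0), x1 = integer(0), y0 = integer(0),
               y1 = integer(0), z0 = integer(0), z1 = integer(0),
               dropped = logical(0), reason = character(0))
  new("LesionComponents", labels = labels, count = lab, perLesion = per)
}
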