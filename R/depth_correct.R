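#' Temporal mode filter over a stack of depth frames
#'
#' A consumer depth camera jitters: across consecutive frames a pixel's
#' value fluctuates within a small range around the true distance, and the
#' true value is the one measured most often. This filter therefore assigns
#' each pixel the most frequent nonzero value across the stack. Zeros are
#' sentinel values for unmeasured pixels, not data, so they never take part
#' in the vote; a pixel is 0 in the output only if it is unmeasured in every
#' frame. Ties are broken toward the smallest value so the result is
#' deterministic.
#'
#' @param stack List of depth matrices with identical dimensions (typically
#'   30 consecutive frames).
#' @return A single depth matrix.
#' @export
temporal_mode <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("'stack' must be a non-empty list of depth frames")
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1L || is.null(dims[[1]]))
    stop("all frames must be matrices with identical dimensions")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  n <- length(stack)
  if (n == 1L) return(stack[[1]])

  vals <- unlist(stack, use.names = FALSE)
  px <- rep.int(seq_len(h * w), n)
  keep <- vals > 0
  vals <- vals[keep]; px <- px[keep]
  out <- numeric(h * w)
  if (length(vals)) {
    # count (pixel, value) pairs via run-length encoding on sorted keys
    ord <- order(px, vals)
    px <- px[ord]; vals <- vals[ord]
    key <- px * 65536 + vals          # doubles are exact here (< 2^53)
    r <- rle(key)
    rpx <- px[cumsum(r$lengths)]
    rval <- vals[cumsum(r$lengths)]
    # per pixel keep the value with the highest count; ties -> smallest value
    sel <- order(rpx, -r$lengths, rval)
    first <- !duplicated(rpx[sel])
    out[rpx[sel][first]] <- rval[sel][first]
  }
  matrix(out, h, w)
}

#' Fill unmeasured depth pixels with a 7x7 valid-neighbor mean
#'
#' Depth pixels at object edges are often unmeasured (value 0). Each zero
#' pixel is replaced by the mean of the *measured* (nonzero) pixels inside
#' its 7x7 window; a plain mean would drag filled values toward the zero
#' sentinel. Within one pass all replacements are computed from the same
#' input image; passes repeat until no zeros remain (holes wider than the
#' window fill inward pass by pass) or a pass makes no progress.
#'
#' @param depth Depth matrix (mm, 0 = unmeasured) with at least one
#'   measured pixel.
#' @param window Odd window size (default 7).
#' @return Depth matrix without unmeasured pixels (unless an isolated
#'   zero-connected region is unreachable, which cannot happen when at
#'   least one pixel of every 7x7 neighborhood chain is measured).
#' @export
fill_unmeasured <- function(depth, window = 7L) {
  if (!is.matrix(depth)) stop("'depth' must be a matrix")
  if (all(depth == 0)) stop("cannot fill an all-zero depth image")
  if (window %% 2L != 1L) stop("'window' must be odd")
  r <- (window - 1L) %/% 2L
  repeat {
    zero <- depth == 0
    if (!any(zero)) break
    s <- box_sum(depth, r)
    cnt <- box_sum((!zero) * 1, r)
    fill <- zero & cnt > 0
    if (!any(fill)) break               # isolated holes beyond reach
    depth[fill] <- s[fill] / cnt[fill]
  }
  depth
}

# Sum over a (2r+1)x(2r+1) box at every pixel, zero-padded at the borders;
# computed with a summed-area table.
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 1L, w + 1L)
  p[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  ri <- seq_len(h); ci <- seq_len(w)
  r2 <- pmin(ri + r, h) + 1L; r1 <- pmax(ri - r, 1L)
  c2 <- pmin(ci + r, w) + 1L; c1 <- pmax(ci - r, 1L)
  p[r2, c2] - p[r1, c2] - p[r2, c1] + p[r1, c1]
}

#' Correct a raw depth capture
#'
#' Capture-level correction pipeline: [temporal_mode()] across the frame
#' stack, then [fill_unmeasured()] for pixels that stayed unmeasured in
#' every frame. Runs on raw stacks before any alignment.
#'
#' @inheritParams temporal_mode
#' @inheritParams fill_unmeasured
#' @return A corrected depth matrix with no unmeasured pixels.
#' @export
correct_capture <- function(stack, window = 7L) {
  fill_unmeasured(temporal_mode(stack), window = window)
}

#' Compensate warped depth values against the background table
#'
#' Warping the post-meal depth image moves pixels but keeps their measured
#' distances, so a food surface can end up "below" the table it was moved
#' onto. What the warp should preserve is the height of each surface point
#' above the table. Given a background depth image `b` of the empty table,
#' the warped value at target pixel `(xt, yt)` originating from source
#' pixel `(x, y)` is corrected to
#' `d_comp(xt, yt) = d(x, y) - (b(x, y) - b(xt, yt))`,
#' which subtracts the table-height difference between the two locations.
#' Source pixels are recovered through the same nearest-neighbor inverse
#' mapping the warp used, so the value and its correction refer to the same
#' source pixel. Unmeasured (0) warped pixels pass through unchanged.
#'
#' @param warped_depth Depth image already warped by [warp_image()] with
#'   homography `H` (nearest-neighbor).
#' @param background Corrected depth image of the empty table (no zeros),
#'   in the fixed camera frame.
#' @param H The homography used for the warp (post -> pre pixel
#'   coordinates).
#' @return Compensated depth matrix; negative results are clamped to 0 and
#'   their count is attached as attribute `"clamped"` (and reported with a
#'   message when nonzero).
#' @export
compensate_warped_depth <- function(warped_depth, background, H) {
  if (!identical(dim(warped_depth), dim(background)))
    stop("warped depth and background dimensions differ")
  if (any(background <= 0))
    stop("background must be corrected first (it contains unmeasured pixels)")
  h <- nrow(warped_depth); w <- ncol(warped_depth)
  Hinv <- solve(unclass(H))
  xt <- rep(0:(w - 1L), each = h)
  yt <- rep(0:(h - 1L), times = w)
  den <- Hinv[3, 1] * xt + Hinv[3, 2] * yt + Hinv[3, 3]
  xs <- round((Hinv[1, 1] * xt + Hinv[1, 2] * yt + Hinv[1, 3]) / den)
  ys <- round((Hinv[2, 1] * xt + Hinv[2, 2] * yt + Hinv[2, 3]) / den)
  ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
  b_src <- numeric(h * w)
  b_src[ok] <- background[cbind(ys[ok] + 1L, xs[ok] + 1L)]
  b_tgt <- as.vector(background)
  d <- as.vector(warped_depth)
  comp <- ifelse(ok & d > 0, d - (b_src - b_tgt), d)
  clamped <- sum(comp < 0)
  if (clamped > 0) {
    message(clamped, " compensated depth value(s) fell below 0 and were clamped")
    comp[comp < 0] <- 0
  }
  structure(matrix(comp, h, w), clamped = clamped)
}
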