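#' Rasterize polygon node loops onto a pixel grid
#'
#' A pixel (r, c) is marked when its centre (r + 0.5, c + 0.5), in 0-based
#' (row, col) continuous coordinates, lies inside the loop arrangement.
#' Under the default `"winding"` (nonzero winding number) rule,
#' consistently-oriented overlapping loops union while an opposite-oriented
#' loop cuts a hole — this is the rule the package uses everywhere, because
#' it both unions independently drawn overlapping outlines and round-trips
#' masks whose regions contain holes (see [mask_to_polygons()]). The
#' `"evenodd"` rule (joint parity) is provided for cross-checks.
#'
#' @param height,width grid dimensions in pixels.
#' @param polygons list of closed loops, each an `n x 2` (row, col) matrix.
#' @param rule fill rule, `"winding"` (default) or `"evenodd"`.
#' @return a logical `height x width` binary mask.
#' @export
rasterize_polygons <- function(height, width, polygons, rule = c("winding", "evenodd")) {
  rule <- match.arg(rule)
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 1 || width < 1) stop_cm("grid must be at least 1 x 1")
  polygons <- lapply(polygons, function(p) {
    storage.mode(p) <- "double"
    p
  })
  rasterize_loops_cpp(height, width, polygons, rule == "winding")
}

#' Label connected components of a mask
#'
#' @param mask a binary mask.
#' @param connectivity 4 (default) or 8.
#' @return integer matrix of component labels (0 = background, 1..k in
#'   first-encountered order).
#' @export
label_components <- function(mask, connectivity = 4) {
  mask <- as_binary_mask(mask)
  if (!connectivity %in% c(4, 8)) stop_cm("connectivity must be 4 or 8")
  label_components_cpp(mask, as.integer(connectivity))
}

#' Trace a mask's boundary as polygon node loops
#'
#' Walks the edges between true and false pixels (or the frame border),
#' producing closed loops on the integer corner grid in 0-based (row, col)
#' coordinates. Outer boundaries and hole boundaries come out with opposite
#' orientations, so rasterizing the loops with the `"winding"` rule
#' reproduces the input mask exactly; collinear runs are merged.
#'
#' @param mask a binary mask.
#' @return list of closed loops (`n x 2` matrices); empty list for an
#'   all-false mask.
#' @export
mask_to_polygons <- function(mask) {
  mask <- as_binary_mask(mask)
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask

  # Directed boundary edges: interior kept on a fixed side so that outer
  # loops and hole loops acquire opposite orientations. Vertex keys encode
  # (corner_row, corner_col) on the (h+1) x (w+1) corner grid.
  tr <- which(mask, arr.ind = TRUE)
  if (nrow(tr) == 0) return(list())
  r <- tr[, 1]
  c <- tr[, 2]
  up <- !pad[cbind(r, c + 1)]
  dn <- !pad[cbind(r + 2, c + 1)]
  lf <- !pad[cbind(r + 1, c)]
  rt <- !pad[cbind(r + 1, c + 2)]
  # 0-based corner coordinates of pixel (r-1, c-1): rows r-1, r; cols c-1, c
  key <- function(rr, cc) rr * (w + 1) + cc
  from <- c(
    key(r[up] - 1, c[up] - 1), # top edge: (r-1,c-1) -> (r-1,c)
    key(r[rt] - 1, c[rt]),     # right edge: (r-1,c) -> (r,c)
    key(r[dn], c[dn]),         # bottom edge: (r,c) -> (r,c-1)
    key(r[lf], c[lf] - 1)      # left edge: (r,c-1) -> (r-1,c-1)
  )
  to <- c(
    key(r[up] - 1, c[up]),
    key(r[rt], c[rt]),
    key(r[dn], c[dn] - 1),
    key(r[lf] - 1, c[lf] - 1)
  )

  # Stitch directed edges into closed loops. Any Eulerian decomposition
  # yields the same winding field, so at degree-4 corners the first unused
  # outgoing edge is taken.
  ord <- order(from)
  from <- from[ord]
  to <- to[ord]
  n <- length(from)
  starts <- c(1L, which(diff(from) > 0) + 1L) # first edge index per from-key
  start_of <- new.env(hash = TRUE, size = n)
  for (i in seq_along(starts)) {
    assign(as.character(from[starts[i]]), starts[i], envir = start_of)
  }
  used <- logical(n)
  next_unused <- function(v) {
    i <- get0(as.character(v), envir = start_of, ifnotfound = NA_integer_)
    if (is.na(i)) return(NA_integer_)
    while (i <= n && from[i] == v) {
      if (!used[i]) return(i)
      i <- i + 1L
    }
    NA_integer_
  }
  loops <- list()
  for (e0 in seq_len(n)) {
    if (used[e0]) next
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      nx <- next_unused(to[e])
      if (is.na(nx)) break
      e <- nx
    }
    verts <- from[path]
    loop <- cbind(verts %/% (w + 1), verts %% (w + 1))
    loops[[length(loops) + 1L]] <- simplify_collinear(loop)
  }
  loops
}

# Drop vertices interior to straight runs of a closed loop.
simplify_collinear <- function(loop) {
  n <- nrow(loop)
  if (n <= 3) return(loop)
  prv <- loop[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- loop[c(2:n, 1), , drop = FALSE]
  d1 <- loop - prv
  d2 <- nxt - loop
  keep <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1] != 0
  if (sum(keep) < 3) return(loop)
  loop[keep, , drop = FALSE]
}

#' Resample a closed loop to at most a given number of nodes
#'
#' Nodes are placed at equal arc-length spacing along the loop, emulating a
#' rater tracing an outline with a limited node budget. Loops already within
#' budget are returned unchanged.
#'
#' @param loop `n x 2` matrix of (row, col) vertices.
#' @param n_nodes maximum node count (>= 3).
#' @return `m x 2` matrix with `m <= max(n_nodes, 3)`.
#' @export
resample_loop <- function(loop, n_nodes) {
  n_nodes <- max(3L, as.integer(n_nodes))
  if (nrow(loop) <= n_nodes) return(loop)
  closed <- rbind(loop, loop[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- total * (seq_len(n_nodes) - 1) / n_nodes
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  t0 <- (targets - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] + t0 * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
}

# Signed area (shoelace) in (x = col, y = row) coordinates; the package's
# canonical "outer" orientation (as produced by mask_to_polygons for outer
# boundaries) has positive sign.
loop_signed_area <- function(loop) {
  x <- loop[, 2]
  y <- loop[, 1]
  nx <- c(x[-1], x[1])
  ny <- c(y[-1], y[1])
  sum(x * ny - nx * y) / 2
}

ensure_outer_orientation <- function(loop) {
  if (loop_signed_area(loop) < 0) loop[rev(seq_len(nrow(loop))), , drop = FALSE] else loop
}
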