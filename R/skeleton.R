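# Morphological thinning and skeleton tracing for membrane segmentations.
#
# Thinning follows Zhang & Suen (1984), implemented with whole-matrix shift
# operations so each sub-iteration is vectorised. Components are thinned
# inside their bounding boxes, so cost scales with membrane area rather
# than image area.

shift_mat <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

zhang_suen_thin <- function(img) {
  img <- img > 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours p2..p9 clockwise from north (row - 1)
      p2 <- shift_mat(img, 1, 0)   # value of northern neighbour at each pixel
      p3 <- shift_mat(img, 1, -1)
      p4 <- shift_mat(img, 0, -1)
      p5 <- shift_mat(img, -1, -1)
      p6 <- shift_mat(img, -1, 0)
      p7 <- shift_mat(img, -1, 1)
      p8 <- shift_mat(img, 0, 1)
      p9 <- shift_mat(img, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- img & B >= 2 & B <= 6 & A == 1
      if (step == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# 8-connected component labelling of a binary matrix; returns an integer
# matrix of labels (0 = background)
label_components <- function(mask) {
  idx <- which(mask > 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  key <- matrix(0L, nrow(mask), ncol(mask))
  key[idx] <- seq_along(idx)
  edges <- list()
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    a <- key
    b <- shift_int(key, off[1], off[2])
    both <- a > 0L & b > 0L
    if (any(both)) edges[[length(edges) + 1]] <- cbind(a[both], b[both])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  lab[idx] <- igraph::components(g)$membership[seq_along(idx)]
  lab
}

shift_int <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

# m-adjacency neighbour list for a set of skeleton pixels: 8-adjacency, but
# a diagonal edge is dropped when the two pixels also share an orthogonal
# skeleton neighbour (keeps unit-wide curves at degree two)
skeleton_graph <- function(px) {
  n <- nrow(px)
  key <- paste(px[, 1], px[, 2])
  idx <- setNames(seq_len(n), key)
  at <- function(r, c) idx[paste(r, c)]
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- px[i, 1]; c <- px[i, 2]
    ortho <- c(at(r - 1, c), at(r + 1, c), at(r, c - 1), at(r, c + 1))
    diag_ <- c(at(r - 1, c - 1), at(r - 1, c + 1),
               at(r + 1, c - 1), at(r + 1, c + 1))
    keep_diag <- !is.na(diag_)
    if (any(keep_diag)) {
      # drop diagonal neighbours already reachable through a shared
      # orthogonal pixel
      for (j in which(keep_diag)) {
        dr <- px[diag_[j], 1] - r
        dc <- px[diag_[j], 2] - c
        if (!is.na(at(r + dr, c)) || !is.na(at(r, c + dc))) {
          keep_diag[j] <- FALSE
        }
      }
    }
    nbrs[[i]] <- unname(c(ortho[!is.na(ortho)], diag_[keep_diag]))
  }
  nbrs
}

# order the pixels of one skeleton component into a trace by walking the
# m-adjacency graph; returns NULL for components that are not simple paths
# or cycles (junctions)
trace_component <- function(px, max_branch_nodes = 0) {
  nbrs <- skeleton_graph(px)
  deg <- lengths(nbrs)
  n_junction <- sum(deg >= 3)
  if (n_junction > max_branch_nodes) return(NULL)
  endpoints <- which(deg == 1)
  if (length(endpoints) > 2) return(NULL)
  start <- if (length(endpoints) > 0) endpoints[1] else 1L
  n <- nrow(px)
  visited <- logical(n)
  order <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    order[i] <- cur
    visited[cur] <- TRUE
    nxt <- nbrs[[cur]][!visited[nbrs[[cur]]]]
    if (length(nxt) == 0) {
      if (i < n) return(NULL)  # disconnected under m-adjacency
      break
    }
    cur <- nxt[1]
  }
  closed <- length(endpoints) == 0 &&
    start %in% nbrs[[order[n]]] && n >= 4
  list(points = px[order, , drop = FALSE], closed = closed)
}

new_membrane_trace <- function(points, closed, pixel_size) {
  structure(list(points = points, closed = closed, pixel_size = pixel_size),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %d points, %s, %.1f A/px\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              x$pixel_size))
  invisible(x)
}

#' Skeletonize a binary membrane segmentation
#'
#' Reduces each connected component of a binary mask to its one-pixel-wide
#' skeleton by morphological thinning, orders the skeleton pixels into a
#' trace by walking neighbouring pixels, and classifies each trace as
#' closed (a loop) or open (an arc). Components whose skeleton contains
#' more junction pixels than `max_branch_nodes` — highly aggregated or
#' overlapping membrane shapes for which tracing is ambiguous — are
#' discarded and counted.
#'
#' @param mask A binary matrix (0/1 or logical).
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @param max_branch_nodes Junction pixels tolerated per component before
#'   it is discarded (default 0).
#' @param min_points Minimum skeleton length (pixels) for a trace to be
#'   kept.
#'
#' @return A list of `membrane_trace` objects with attribute
#'   `n_discarded`, the number of ambiguous components dropped.
#' @export
skeletonize <- function(mask, pixel_size, max_branch_nodes = 0,
                        min_points = 8) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort("`mask` must be a binary (0/1) matrix.")
  }
  check_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) abort("`pixel_size` must be positive.")
  if (!any(mask > 0)) {
    return(structure(list(), n_discarded = 0L))
  }

  labels <- label_components(mask)
  n_comp <- max(labels)
  traces <- list()
  n_discarded <- 0L
  for (comp in seq_len(n_comp)) {
    w <- which(labels == comp, arr.ind = TRUE)
    if (nrow(w) < min_points) next
    rr <- range(w[, 1]); cc <- range(w[, 2])
    sub <- matrix(FALSE, rr[2] - rr[1] + 3, cc[2] - cc[1] + 3)
    sub[cbind(w[, 1] - rr[1] + 2, w[, 2] - cc[1] + 2)] <- TRUE
    thin <- zhang_suen_thin(sub)
    px <- which(thin, arr.ind = TRUE)
    px[, 1] <- px[, 1] + rr[1] - 2L
    px[, 2] <- px[, 2] + cc[1] - 2L
    if (nrow(px) < min_points) next
    tr <- trace_component(px, max_branch_nodes)
    if (is.null(tr)) {
      n_discarded <- n_discarded + 1L
      next
    }
    traces[[length(traces) + 1]] <-
      new_membrane_trace(tr$points, tr$closed, pixel_size)
  }
  structure(traces, n_discarded = n_discarded)
}

#' Keep only closed membrane traces
#'
#' Only closed-segmented vesicles enter the morphometric analysis; open
#' arcs (partly segmented or image-border membranes) are excluded.
#'
#' @param traces A list of `membrane_trace` objects from [skeletonize()].
#' @return The closed traces, as a list.
#' @export
select_closed <- function(traces) {
  Filter(function(tr) isTRUE(tr$closed), traces)
}
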