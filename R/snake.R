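#' Greedy active-contour parameters
#'
#' Weights and controls of the slice-wise greedy snake. The energy of a
#' candidate node position is
#' `alpha * E_cont + beta * E_curv - gamma * E_ext + delta * E_dev`, where
#' `E_cont` is the squared forward difference along the contour (written with
#' a positive square, so a negative `alpha` makes minimization expansive --
#' the default), `E_curv` the squared central second difference (bending
#' stiffness), `E_ext` the squared gradient-magnitude image sampled at the
#' candidate (edge attraction), and `E_dev = d^4` with `d` the distance to
#' the nearest node of the previous slice's contour (inter-slice coupling;
#' zero on the first slice). With `normalize = TRUE` (default) each raw term
#' is min-max normalized over the search window before weighting, the
#' standard greedy-snake practice that puts the four incommensurate scales on
#' a common footing; `normalize = FALSE` uses the raw terms.
#'
#' @param alpha continuity weight; negative expands the contour.
#' @param beta curvature (stiffness) weight.
#' @param gamma edge-attraction weight.
#' @param delta inter-slice deviation weight.
#' @param s_min minimum node spacing in pixels (>= 1); a node is deleted when
#'   spacing falls below it.
#' @param s_max maximum node spacing in pixels; a midpoint is inserted when
#'   spacing exceeds it. Default `4 * s_min`.
#' @param max_iter iteration cap per slice.
#' @param window odd side length (>= 3) of the square search neighbourhood.
#' @param normalize min-max normalize energy terms over the window.
#' @param flat_tol flatness guard for the normalized external term: a search
#'   window whose gradient range is below `flat_tol` times the slice's
#'   maximum squared gradient is treated as featureless (zero edge term)
#'   rather than having its noise floor stretched to full weight.
#' @param dev_mode `"vertices"` measures `d` to the previous contour's nodes
#'   (the literal rule); `"segments"` to its polyline edges.
#' @param resample_each_iter interleave node insertion/deletion with greedy
#'   passes (default) or resample once after convergence.
#' @return A `snake_params` list.
#' @export
snake_params <- function(alpha = -1, beta = 0.2, gamma = 2, delta = 1,
                         s_min = 3, s_max = 4 * s_min, max_iter = 30L,
                         window = 3L, normalize = TRUE, flat_tol = 1e-3,
                         dev_mode = c("vertices", "segments"),
                         resample_each_iter = TRUE) {
  dev_mode <- match.arg(dev_mode)
  window <- as.integer(window)
  max_iter <- as.integer(max_iter)
  if (s_min < 1) stop("s_min must be >= 1 pixel", call. = FALSE)
  if (s_max <= s_min) stop("s_max must exceed s_min", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 s_min = s_min, s_max = s_max, max_iter = max_iter,
                 window = window, normalize = isTRUE(normalize),
                 flat_tol = flat_tol, dev_mode = dev_mode,
                 resample_each_iter = isTRUE(resample_each_iter)),
            class = "snake_params")
}

#' Closed discrete contour
#'
#' An ordered closed polygon of real-valued node positions in the 0-based
#' pixel coordinates of one cross-section image (first coordinate along the
#' image's first index).
#'
#' @param nodes n x 2 numeric matrix of node positions; n >= 3.
#' @param slice_index index of the cross section the contour lives on.
#' @return A `snake_contour`.
#' @export
snake_contour <- function(nodes, slice_index = NA_integer_) {
  nodes <- matrix(as.numeric(nodes), ncol = 2L)
  if (nrow(nodes) < 3L)
    stop("a contour needs at least 3 nodes", call. = FALSE)
  if (any(!is.finite(nodes)))
    stop("contour nodes must be finite", call. = FALSE)
  structure(list(nodes = nodes, slice_index = as.integer(slice_index)),
            class = "snake_contour")
}

#' @export
print.snake_contour <- function(x, ...) {
  cat(sprintf("<snake_contour> %d nodes%s\n", nrow(x$nodes),
              if (is.na(x$slice_index)) ""
              else sprintf(" on slice %d", x$slice_index)))
  invisible(x)
}

#' Circular starting contour
#'
#' Nodes equally spaced counter-clockwise on a circle around a user-chosen
#' seed point. When `n_nodes` is omitted it is sized so the initial spacing
#' is about `2 * s_min`: `n = ceiling(2 * pi * radius / (2 * s_min))`, at
#' least 3.
#'
#' @param center length-2 seed position (pixels).
#' @param radius circle radius in pixels, > 0.
#' @param n_nodes number of nodes (>= 3), or `NULL` for the sizing rule.
#' @param s_min minimum spacing used by the sizing rule.
#' @param slice_index slice the contour belongs to.
#' @return A [snake_contour()].
#' @export
init_circle <- function(center, radius, n_nodes = NULL, s_min = 3,
                        slice_index = NA_integer_) {
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  if (is.null(n_nodes)) n_nodes <- max(3L, ceiling(pi * radius / s_min))
  if (n_nodes < 3L) stop("n_nodes must be >= 3", call. = FALSE)
  th <- 2 * pi * (seq_len(n_nodes) - 1L) / n_nodes
  snake_contour(cbind(center[1] + radius * cos(th),
                      center[2] + radius * sin(th)), slice_index)
}

#' Squared gradient-magnitude image
#'
#' `||grad I||^2` by central differences with replicated borders (Sobel
#' available as an option); the quantity the snake's external energy samples.
#'
#' @param image 2-D numeric matrix.
#' @param method `"central"` or `"sobel"`.
#' @return matrix of the same shape, non-negative.
#' @export
gradient_image <- function(image, method = c("central", "sobel")) {
  method <- match.arg(method)
  image <- as.matrix(image)
  d <- dim(image)
  sh <- function(dr, dc) {
    r <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    c <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
    image[r, c, drop = FALSE]
  }
  if (method == "central") {
    gx <- (sh(1L, 0L) - sh(-1L, 0L)) / 2
    gy <- (sh(0L, 1L) - sh(0L, -1L)) / 2
  } else {
    gx <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L) -
           sh(-1L, -1L) - 2 * sh(-1L, 0L) - sh(-1L, 1L)) / 8
    gy <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L) -
           sh(-1L, -1L) - 2 * sh(0L, -1L) - sh(1L, -1L)) / 8
  }
  gx * gx + gy * gy
}

# bilinear sample of a matrix at 0-based (u, v); out-of-bounds -> fill
.bilinear <- function(mat, uv, fill = 0) {
  a <- mat
  dim(a) <- c(dim(mat), 1L)
  .trilinear(a, cbind(uv, 0), fill = fill)
}

# distance from candidate points to the previous contour (vertices or
# polyline segments); cand is m x 2
.dist_to_prev <- function(cand, prev_nodes, mode = "vertices") {
  m <- nrow(cand)
  k <- nrow(prev_nodes)
  if (mode == "vertices") {
    du <- outer(cand[, 1], prev_nodes[, 1], "-")
    dv <- outer(cand[, 2], prev_nodes[, 2], "-")
    return(sqrt(.rowMins(du * du + dv * dv)))
  }
  a <- prev_nodes
  b <- prev_nodes[c(2:k, 1L), , drop = FALSE]
  e <- b - a
  len2 <- pmax(rowSums(e * e), 1e-300)
  pu <- outer(cand[, 1], a[, 1], "-")
  pv <- outer(cand[, 2], a[, 2], "-")
  tt <- sweep(sweep(pu, 2L, e[, 1], "*") + sweep(pv, 2L, e[, 2], "*"),
              2L, len2, "/")
  tt <- pmin(pmax(tt, 0), 1)
  du <- pu - sweep(tt, 2L, e[, 1], "*")
  dv <- pv - sweep(tt, 2L, e[, 2], "*")
  sqrt(.rowMins(du * du + dv * dv))
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

# Raw energy terms for candidate positions of node i. Returns an m x 4
# matrix (cont, curv, ext, dev) and a validity flag per candidate.
.energy_terms <- function(cand, v_prev, v_next, grad, prev_nodes, params,
                          mask = NULL) {
  d <- dim(grad)
  valid <- cand[, 1] >= 0 & cand[, 1] <= d[1] - 1L &
           cand[, 2] >= 0 & cand[, 2] <= d[2] - 1L
  if (!is.null(mask)) {
    ri <- pmin(pmax(round(cand[, 1]) + 1L, 1L), d[1])
    ci <- pmin(pmax(round(cand[, 2]) + 1L, 1L), d[2])
    valid <- valid & !(mask[cbind(ri, ci)] > 0)
  }
  t_cont <- (v_next[1] - cand[, 1])^2 + (v_next[2] - cand[, 2])^2
  t_curv <- (v_next[1] - 2 * cand[, 1] + v_prev[1])^2 +
            (v_next[2] - 2 * cand[, 2] + v_prev[2])^2
  t_ext <- .bilinear(grad, cand)
  t_dev <- if (is.null(prev_nodes)) rep(0, nrow(cand))
           else .dist_to_prev(cand, prev_nodes, params$dev_mode)^4
  list(terms = cbind(t_cont, t_curv, t_ext, t_dev), valid = valid)
}

# weight raw terms into energies, optionally min-max normalizing each term
# over the valid candidates of the window. ext_floor guards the image term:
# a window whose gradient range is below it (negligible against the slice's
# global gradient scale) is treated as flat instead of having sensor noise
# amplified to full weight.
.weigh_terms <- function(terms, valid, params, ext_floor = 0) {
  w <- c(params$alpha, params$beta, -params$gamma, params$delta)
  tm <- terms
  if (params$normalize) {
    for (j in 1:4) {
      col <- terms[valid, j]
      if (length(col)) {
        lo <- min(col); hi <- max(col)
        thr <- if (j == 3L) max(1e-12, ext_floor) else 1e-12
        tm[, j] <- if (hi - lo > thr) (terms[, j] - lo) / (hi - lo) else 0
      }
    }
  }
  e <- as.numeric(tm %*% w)
  e[!valid] <- Inf
  e
}

#' Energy of a candidate position for one contour node
#'
#' Evaluates the four-term energy balance (continuity, curvature, edge,
#' inter-slice deviation) that the greedy iteration minimizes; see
#' [snake_params()] for the terms. In normalized mode the min-max statistics
#' are taken over the search window centered on the node's current position,
#' as during a greedy pass. Candidates outside the image (or in a forbidden
#' `mask` pixel) have infinite energy.
#'
#' @param contour a [snake_contour()].
#' @param i node index (1-based).
#' @param candidate length-2 candidate position (pixels).
#' @param grad a [gradient_image()] of the slice.
#' @param prev previous slice's contour, or `NULL` (first slice: the
#'   deviation term is zero).
#' @param params a [snake_params()].
#' @param mask optional binary matrix marking forbidden pixels.
#' @return scalar energy.
#' @export
node_energy <- function(contour, i, candidate, grad, prev = NULL,
                        params = snake_params(), mask = NULL) {
  stopifnot(inherits(contour, "snake_contour"))
  n <- nrow(contour$nodes)
  v_prev <- contour$nodes[if (i == 1L) n else i - 1L, ]
  v_next <- contour$nodes[if (i == n) 1L else i + 1L, ]
  prev_nodes <- if (is.null(prev)) NULL else prev$nodes
  cand <- rbind(as.numeric(candidate))
  if (!params$normalize) {
    et <- .energy_terms(cand, v_prev, v_next, grad, prev_nodes, params, mask)
    return(.weigh_terms(et$terms, et$valid, params)[1])
  }
  ext_floor <- params$flat_tol * max(grad)
  # window statistics around the node's current position, candidate appended
  offs <- .window_offsets(params$window)
  win <- sweep(offs, 2L, contour$nodes[i, ], "+")
  all_cand <- rbind(win, cand)
  et <- .energy_terms(all_cand, v_prev, v_next, grad, prev_nodes, params,
                      mask)
  # normalize with the window's statistics only
  terms <- et$terms
  wvalid <- et$valid[seq_len(nrow(win))]
  w <- c(params$alpha, params$beta, -params$gamma, params$delta)
  tm <- terms
  for (j in 1:4) {
    col <- terms[seq_len(nrow(win)), j][wvalid]
    if (length(col)) {
      lo <- min(col); hi <- max(col)
      thr <- if (j == 3L) max(1e-12, ext_floor) else 1e-12
      tm[, j] <- if (hi - lo > thr) (terms[, j] - lo) / (hi - lo) else 0
    }
  }
  e <- as.numeric(tm %*% w)
  e[!et$valid] <- Inf
  e[nrow(all_cand)]
}

# window offsets ordered by preference: null move first, then increasing
# offset magnitude, then row-major
.window_offsets <- function(window) {
  h <- (window - 1L) %/% 2L
  g <- expand.grid(du = -h:h, dv = -h:h)
  g <- g[order(g$du^2 + g$dv^2, g$du, g$dv), ]
  as.matrix(g)
}

#' One greedy pass over all contour nodes
#'
#' Visits nodes in order; each node moves to the integer-pixel offset in its
#' `window x window` neighbourhood minimizing [node_energy()], updates in
#' place, and the pass reports how many nodes moved. Ties prefer the current
#' position, then the smallest offset magnitude, then row-major order.
#'
#' @inheritParams node_energy
#' @return list with the updated `contour` and `moved`, the move count.
#' @export
greedy_iterate <- function(contour, grad, prev = NULL,
                           params = snake_params(), mask = NULL) {
  stopifnot(inherits(contour, "snake_contour"))
  offs <- .window_offsets(params$window)
  nodes <- contour$nodes
  n <- nrow(nodes)
  prev_nodes <- if (is.null(prev)) NULL else prev$nodes
  ext_floor <- params$flat_tol * max(grad)
  moved <- 0L
  for (i in seq_len(n)) {
    v_prev <- nodes[if (i == 1L) n else i - 1L, ]
    v_next <- nodes[if (i == n) 1L else i + 1L, ]
    cand <- sweep(offs, 2L, nodes[i, ], "+")
    et <- .energy_terms(cand, v_prev, v_next, grad, prev_nodes, params,
                        mask)
    e <- .weigh_terms(et$terms, et$valid, params, ext_floor)
    best <- which.min(e)   # first minimum in preference order
    if (best != 1L && is.finite(e[best])) {
      nodes[i, ] <- cand[best, ]
      moved <- moved + 1L
    }
  }
  list(contour = snake_contour(nodes, contour$slice_index), moved = moved)
}

#' Enforce node-spacing bounds by insertion and deletion
#'
#' Midpoints are inserted between neighbours spaced more than `s_max` apart,
#' then the second node of any pair closer than `s_min` is deleted (never
#' dropping below 3 nodes); both passes repeat until the spacing bounds hold.
#'
#' @param contour a [snake_contour()].
#' @param params a [snake_params()].
#' @return the resampled [snake_contour()].
#' @export
resample_nodes <- function(contour, params = snake_params()) {
  stopifnot(inherits(contour, "snake_contour"))
  nodes <- contour$nodes
  # deleting a node merges two short edges into one that can exceed s_max,
  # so insertion and deletion alternate until both bounds hold
  for (round in 1:100) {
    changed <- FALSE
    repeat {   # insertion: split every over-long edge at its midpoint
      n <- nrow(nodes)
      nxt <- nodes[c(2:n, 1L), , drop = FALSE]
      sp <- sqrt(rowSums((nxt - nodes)^2))
      long <- sp > params$s_max
      if (!any(long)) break
      changed <- TRUE
      out <- vector("list", n)
      for (i in seq_len(n)) {
        out[[i]] <- if (long[i])
          rbind(nodes[i, ], (nodes[i, ] + nxt[i, ]) / 2)
        else rbind(nodes[i, ])
      }
      nodes <- do.call(rbind, out)
    }
    repeat {   # deletion: drop the second node of under-spaced pairs
      n <- nrow(nodes)
      if (n <= 3L) break
      sp <- sqrt(rowSums((nodes[c(2:n, 1L), , drop = FALSE] - nodes)^2))
      short <- which(sp < params$s_min)
      if (!length(short)) break
      drop <- logical(n)
      for (i in short) {
        j <- if (i == n) 1L else i + 1L
        if (!drop[i] && !drop[j] && sum(!drop) > 3L) drop[j] <- TRUE
      }
      if (!any(drop)) break
      changed <- TRUE
      nodes <- nodes[!drop, , drop = FALSE]
    }
    if (!changed) break
  }
  snake_contour(nodes, contour$slice_index)
}

#' Segment one cross section with the greedy snake
#'
#' Alternates [greedy_iterate()] and (by default) [resample_nodes()] until a
#' pass moves no node or `max_iter` passes have run.
#'
#' @param image 2-D cross-section image.
#' @param init initial [snake_contour()] (a circle on the first slice, the
#'   previous slice's result thereafter).
#' @param prev previous slice's contour for the deviation energy, or `NULL`.
#' @param params a [snake_params()].
#' @param mask optional binary matrix of forbidden pixels.
#' @param grad precomputed [gradient_image()]; computed from `image` if
#'   missing.
#' @return the converged [snake_contour()], with attributes `iterations`
#'   (greedy passes run) and `converged`.
#' @export
segment_slice <- function(image, init, prev = NULL, params = snake_params(),
                          mask = NULL, grad = NULL) {
  stopifnot(inherits(init, "snake_contour"))
  if (is.null(grad)) grad <- gradient_image(image)
  contour <- init
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    step <- greedy_iterate(contour, grad, prev, params, mask)
    contour <- step$contour
    iterations <- it
    if (params$resample_each_iter)
      contour <- tryCatch(resample_nodes(contour, params),
                          error = function(e)
                            stop("segmentation failure: contour collapsed: ",
                                 conditionMessage(e), call. = FALSE))
    if (step$moved == 0L) { converged <- TRUE; break }
  }
  if (!params$resample_each_iter)
    contour <- resample_nodes(contour, params)
  if (nrow(contour$nodes) < 3L)
    stop("segmentation failure: contour collapsed below 3 nodes",
         call. = FALSE)
  attr(contour, "iterations") <- iterations
  attr(contour, "converged") <- converged
  contour
}

#' Segment a whole cross-section stack by slice propagation
#'
#' Starts from a circular contour around `seed` on `start_index` and walks
#' the stack: each subsequent slice is initialized with the previous slice's
#' result, which also supplies the deviation-energy coupling. Slices listed
#' in `overrides` are taken verbatim (standing in for manual correction) and
#' serve as the coupling contour for their successors. A failed slice is
#' recorded and propagation continues from the last good contour.
#'
#' @param xsecs a `cross_section_stack` from [resample_cross_sections()].
#' @param seed length-2 pixel position inside the lumen on the start slice.
#' @param params a [snake_params()].
#' @param start_index slice to start from (default 1).
#' @param overrides named list of [snake_contour()]s keyed by slice index
#'   (as names), or `NULL`.
#' @param mask forbidden-pixel mask: a single matrix applied to every slice,
#'   or a list per slice, or `NULL`.
#' @param direction `"forward"` (increasing slice index from the start, the
#'   default) or `"both"` (also backward from the start).
#' @param init_radius_px radius of the starting circle.
#' @return A `contour_set`: `contours` (per slice; `NULL` where failed),
#'   `iterations`, `converged`, `failed`, plus the stack's `pixel_size` and
#'   `step`.
#' @export
segment_stack <- function(xsecs, seed, params = snake_params(),
                          start_index = 1L, overrides = NULL, mask = NULL,
                          direction = c("forward", "both"),
                          init_radius_px = 2 * params$s_min) {
  stopifnot(inherits(xsecs, "cross_section_stack"))
  direction <- match.arg(direction)
  ns <- length(xsecs$images)
  if (start_index < 1L || start_index > ns)
    stop("start_index out of range", call. = FALSE)
  contours <- vector("list", ns)
  iterations <- integer(ns)
  converged <- logical(ns)
  failed <- logical(ns)
  slice_mask <- function(k) {
    if (is.null(mask)) NULL
    else if (is.list(mask)) mask[[k]]
    else mask
  }
  do_slice <- function(k, init, prev) {
    ov <- if (!is.null(overrides)) overrides[[as.character(k)]] else NULL
    if (!is.null(ov)) {
      stopifnot(inherits(ov, "snake_contour"))
      return(snake_contour(ov$nodes, k))
    }
    segment_slice(xsecs$images[[k]], init, prev, params,
                  mask = slice_mask(k))
  }
  walk <- function(indices, first_init) {
    prev <- NULL
    init <- first_init
    for (k in indices) {
      res <- tryCatch(do_slice(k, init, prev), error = function(e) e)
      if (inherits(res, "error")) {
        failed[k] <<- TRUE
        warning(sprintf("slice %d: %s", k, conditionMessage(res)),
                call. = FALSE)
      } else {
        res$slice_index <- as.integer(k)
        contours[[k]] <<- res
        iterations[k] <<- attr(res, "iterations") %||% 0L
        converged[k] <<- is.null(attr(res, "converged")) ||
                         isTRUE(attr(res, "converged"))
        prev <- res
        init <- snake_contour(res$nodes, k)
      }
    }
  }
  first <- init_circle(seed, init_radius_px, s_min = params$s_min,
                       slice_index = start_index)
  walk(start_index:ns, first)
  if (direction == "both" && start_index > 1L) {
    base <- contours[[start_index]]
    walk((start_index - 1L):1L,
         if (is.null(base)) first else snake_contour(base$nodes,
                                                     start_index - 1L))
  }
  structure(list(contours = contours, iterations = iterations,
                 converged = converged, failed = failed,
                 pixel_size = xsecs$pixel_size, step = xsecs$step),
            class = "contour_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d slices (%d segmented, %d failed), step %.3g mm\n",
              length(x$contours), sum(!vapply(x$contours, is.null, TRUE)),
              sum(x$failed), x$step))
  invisible(x)
}

#' Read and write contours as JSON
#'
#' Contours are stored as an array of records with the slice index, the node
#' list in pixel coordinates, and the pixel size. `read_contours` returns a
#' named list of [snake_contour()]s keyed by slice index -- the format
#' accepted by `segment_stack(overrides = )`.
#'
#' @param contours a `contour_set` or list of [snake_contour()]s.
#' @param path JSON file path.
#' @param pixel_size_mm in-plane pixel size recorded alongside.
#' @return `read_contours`: named list of [snake_contour()]s.
#' @export
write_contours <- function(contours, path, pixel_size_mm = NA_real_) {
  if (inherits(contours, "contour_set")) {
    pixel_size_mm <- contours$pixel_size
    contours <- contours$contours
  }
  keep <- !vapply(contours, is.null, TRUE)
  recs <- lapply(which(keep), function(k) {
    ct <- contours[[k]]
    list(slice = if (is.na(ct$slice_index)) k else ct$slice_index,
         pixel_size_mm = pixel_size_mm,
         nodes = unname(apply(ct$nodes, 1L, as.list)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path))
    stop("contour file not found: ", path, call. = FALSE)
  recs <- jsonlite::read_json(path)
  out <- list()
  for (r in recs) {
    nodes <- do.call(rbind, lapply(r$nodes, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    out[[as.character(r$slice)]] <- snake_contour(nodes,
                                                  as.integer(r$slice))
  }
  out
}
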