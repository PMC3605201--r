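# ---- self-organizing map -------------------------------------------------

#' SOM configuration
#'
#' @param rows,cols grid dimensions (rows*cols >= 4). Defaults to a roughly
#'   square grid with ~10 documents per neuron when built via [fit_infomap()].
#' @param epochs training epochs.
#' @param initial_radius initial Gaussian neighborhood radius (default
#'   max(rows, cols)/2).
#' @param learning_rate initial rate (online mode only).
#' @param mode "batch" (deterministic, order-independent) or "online".
#' @param seed RNG seed for the coarse-group initial guess.
#' @return list of class \code{mm_som_config}.
#' @export
som_config <- function(rows, cols, epochs = 20L, initial_radius = NULL,
                       learning_rate = 0.05, mode = c("batch", "online"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (rows * cols < 4L) stop("grid must have at least 4 neurons")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (is.null(initial_radius)) initial_radius <- max(rows, cols) / 2
  structure(list(rows = rows, cols = cols, epochs = as.integer(epochs),
                 initial_radius = initial_radius,
                 learning_rate = learning_rate, mode = mode,
                 seed = as.integer(seed)),
            class = "mm_som_config")
}

som_grid <- function(rows, cols) {
  expand.grid(c = seq_len(cols), r = seq_len(rows))[, c("r", "c")]
}

# squared Euclidean doc->prototype distances: n x ncell
cross_dist2 <- function(X, W) {
  outer(rowSums(X^2), rep(1, nrow(W))) - 2 * X %*% t(W) +
    outer(rep(1, nrow(X)), rowSums(W^2))
}

#' Coarse-group-rebalanced initial prototypes
#'
#' Documents are clustered into g = max(4, floor(sqrt(rows*cols))) coarse
#' groups with seeded k-means; centroids are placed on the grid by a greedy
#' similarity-preserving assignment (the most populous centroid at the grid
#' center, each subsequent centroid at the free cell whose already-placed
#' neighbors it resembles most); unfilled cells are interpolated from placed
#' neighbors. This initial guess replaces random initialization and reduces the
#' risk of the SOM converging to a poor configuration.
#'
#' @param vectors content-vector matrix (docs x d).
#' @param config an \code{mm_som_config}.
#' @return prototype matrix (rows*cols x d), row-major cell order.
#' @export
initialize_rebalanced <- function(vectors, config) {
  ncell <- config$rows * config$cols
  n <- nrow(vectors)
  if (n < ncell / 4) {
    stop("too few documents (", n, ") for a ", config$rows, "x", config$cols,
         " grid; use a smaller grid")
  }
  g <- max(4L, floor(sqrt(ncell)))
  g <- min(g, n)
  uniq <- unique(vectors)
  km <- NULL
  if (nrow(uniq) <= g) {
    centers <- uniq[rep(seq_len(nrow(uniq)), length.out = g), , drop = FALSE]
    sizes <- rep(ceiling(n / g), g)
  } else {
    km <- with_local_seed(config$seed, stats::kmeans(
      vectors, centers = g, iter.max = 50L, nstart = 5L))
    centers <- km$centers
    sizes <- km$size
  }

  grid <- som_grid(config$rows, config$cols)
  W <- matrix(NA_real_, nrow = ncell, ncol = ncol(vectors))
  placed <- rep(FALSE, ncell)
  center_cell <- which.min((grid$r - (config$rows + 1) / 2)^2 +
                             (grid$c - (config$cols + 1) / 2)^2)
  ord <- order(-sizes)
  for (idx in seq_along(ord)) {
    ci <- ord[idx]
    if (idx > ncell) break
    if (idx == 1L) {
      cell <- center_cell
    } else {
      free <- which(!placed)
      # score each free cell by mean cosine to its placed grid neighbors
      score <- vapply(free, function(cl) {
        nb <- grid_neighbors(cl, grid)
        nb <- nb[placed[nb]]
        if (!length(nb)) return(-Inf)
        mean(W[nb, , drop = FALSE] %*% centers[ci, ]) /
          max(sqrt(sum(centers[ci, ]^2)), 1e-12)
      }, 0)
      if (all(!is.finite(score))) {
        cell <- free[1]
      } else {
        cell <- free[which.max(score)]
      }
    }
    W[cell, ] <- centers[ci, ]
    placed[cell] <- TRUE
  }
  # interpolate unplaced cells from placed neighbors until full
  while (any(!placed)) {
    prog <- FALSE
    for (cl in which(!placed)) {
      nb <- grid_neighbors(cl, grid)
      nb <- nb[placed[nb]]
      if (length(nb)) {
        W[cl, ] <- colMeans(W[nb, , drop = FALSE])
        placed[cl] <- TRUE
        prog <- TRUE
      }
    }
    if (!prog) {
      W[!placed, ] <- matrix(colMeans(centers), nrow = sum(!placed),
                             ncol = ncol(vectors), byrow = TRUE)
      placed[] <- TRUE
    }
  }
  W
}

# 4-neighborhood on the grid, by cell index
grid_neighbors <- function(cell, grid) {
  r <- grid$r[cell]; c <- grid$c[cell]
  which((abs(grid$r - r) + abs(grid$c - c)) == 1L)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Train the information map
#'
#' Standard Kohonen updates with a Gaussian neighborhood and linearly decaying
#' radius. In batch mode (default) each epoch recomputes best-matching units
#' for all documents and sets each prototype to the neighborhood-weighted mean
#' of the data; this is deterministic and independent of document order. Online
#' mode applies per-document winner-take-all updates with a decaying learning
#' rate.
#'
#' @param vectors content-vector matrix (docs x d, rownames = doc ids).
#' @param config an \code{mm_som_config}.
#' @param init optional initial prototypes (default [initialize_rebalanced()]).
#' @return object of class \code{mm_infomap}: prototypes, assignments
#'   (doc_id -> cell), grid layout, quantization error.
#' @export
train_som <- function(vectors, config, init = NULL) {
  if (is.null(init)) init <- initialize_rebalanced(vectors, config)
  W <- init
  grid <- som_grid(config$rows, config$cols)
  gd2 <- as.matrix(stats::dist(grid))^2
  n <- nrow(vectors)
  for (e in seq_len(config$epochs)) {
    sigma <- max(config$initial_radius * (1 - (e - 1) / config$epochs), 0.5)
    H <- exp(-gd2 / (2 * sigma^2))
    if (config$mode == "batch") {
      bmu <- max.col(-cross_dist2(vectors, W), ties.method = "first")
      A <- H[bmu, , drop = FALSE]           # n x ncell weights
      denom <- colSums(A)
      num <- t(A) %*% vectors
      upd <- denom > 1e-12
      W[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    } else {
      alpha <- config$learning_rate * (1 - (e - 1) / config$epochs)
      for (j in seq_len(n)) {
        d2 <- colSums((t(W) - vectors[j, ])^2)
        b <- which.min(d2)
        h <- alpha * H[b, ]
        W <- W + h * (matrix(vectors[j, ], nrow(W), ncol(W), byrow = TRUE) - W)
      }
    }
  }
  bmu <- max.col(-cross_dist2(vectors, W), ties.method = "first")
  pd <- stats::dist(W)
  structure(
    list(prototypes = W, grid = grid,
         rows = config$rows, cols = config$cols,
         assignments = stats::setNames(bmu, rownames(vectors)),
         mean_proto_dist = mean(pd),
         topic_labels = NULL, config = config),
    class = "mm_infomap"
  )
}

#' Build and train an information map with default sizing
#'
#' Grid side defaults to ceiling(sqrt(n/10)) (about 10 documents per neuron),
#' floored at 2.
#'
#' @param vectors content-vector matrix.
#' @param rows,cols optional explicit grid; both derived from n when NULL.
#' @param ... passed to [som_config()].
#' @return trained \code{mm_infomap}.
#' @export
fit_infomap <- function(vectors, rows = NULL, cols = NULL, ...) {
  if (is.null(rows) || is.null(cols)) {
    side <- max(2L, ceiling(sqrt(nrow(vectors) / 10)))
    rows <- if (is.null(rows)) side else rows
    cols <- if (is.null(cols)) side else cols
  }
  train_som(vectors, som_config(rows, cols, ...))
}

#' @export
print.mm_infomap <- function(x, ...) {
  cat("<mm_infomap>", x$rows, "x", x$cols, "grid,",
      length(x$assignments), "documents",
      if (!is.null(x$topic_labels)) paste0(", ", max(x$topic_labels), " topics"),
      "\n")
  invisible(x)
}

#' Mean quantization error of a trained map
#'
#' @param map an \code{mm_infomap}.
#' @param vectors content-vector matrix.
#' @return mean Euclidean distance of each vector to its winning prototype.
#' @export
quantization_error <- function(map, vectors) {
  W <- if (is.matrix(map)) map else map$prototypes
  d2 <- cross_dist2(vectors, W)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Label map neurons with main topics
#'
#' Each neuron is first labeled with the top-level taxonomy branch (child of
#' the root) most frequent among the recognized occurrences of its assigned
#' documents; empty neurons inherit the label of the nearest labeled neuron.
#' Connected same-label regions are then merged (smallest region into its most
#' similar grid-adjacent region) until exactly M topic regions remain.
#'
#' @param map a trained \code{mm_infomap}.
#' @param analysis the \code{mm_analysis} the map was trained on.
#' @param M target number of main topics.
#' @return the map with \code{topic_labels} (integer 1..M per neuron) and
#'   \code{topic_branches} (dominant branch taxon per topic) filled in.
#' @export
label_topics <- function(map, analysis, M) {
  lex <- analysis$lexicon
  ncell <- nrow(map$prototypes)
  # top-level branch of each group = ancestor chain element at level 2
  branch_of_group <- vapply(names(lex$group_taxon), function(g) {
    chain <- taxon_chain(lex$group_taxon[[g]], lex)
    lv <- lex$taxon_level[chain]
    b <- chain[lv == 2L]
    if (length(b)) b[1] else lex$root
  }, "")
  dg <- analysis$doc_groups
  dg <- dg[unname(lex$group_sig[dg$group_id]) > 0, , drop = FALSE]
  dg$cell <- map$assignments[dg$doc_id]
  dg$branch <- branch_of_group[dg$group_id]
  agg <- stats::aggregate(count ~ cell + branch, data = dg, FUN = sum)
  n_branch <- length(unique(agg$branch))
  if (M > n_branch) {
    stop("M = ", M, " exceeds the ", n_branch,
         " top-level branches present in the corpus")
  }
  lab <- rep(NA_character_, ncell)
  for (cl in unique(agg$cell)) {
    sub <- agg[agg$cell == cl, ]
    sub <- sub[order(-sub$count, sub$branch), ]
    lab[cl] <- sub$branch[1]
  }
  # empty neurons: nearest labeled neuron on the grid (prototype distance ties)
  if (anyNA(lab)) {
    labeled <- which(!is.na(lab))
    for (cl in which(is.na(lab))) {
      gd <- (map$grid$r[labeled] - map$grid$r[cl])^2 +
        (map$grid$c[labeled] - map$grid$c[cl])^2
      lab[cl] <- lab[labeled[which.min(gd)]]
    }
  }
  # connected components of equal-label cells
  region <- integer(ncell)
  nreg <- 0L
  for (cl in seq_len(ncell)) {
    if (region[cl] == 0L) {
      nreg <- nreg + 1L
      queue <- cl
      region[cl] <- nreg
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        nb <- grid_neighbors(cur, map$grid)
        nb <- nb[region[nb] == 0L & lab[nb] == lab[cur]]
        region[nb] <- nreg
        queue <- c(queue, nb)
      }
    }
  }
  # merge smallest region into most-similar adjacent region until M remain
  while (length(unique(region)) > M) {
    sizes <- table(region)
    smallest <- as.integer(names(sizes)[order(sizes, as.integer(names(sizes)))][1])
    cells <- which(region == smallest)
    adj <- unique(unlist(lapply(cells, grid_neighbors, grid = map$grid)))
    adj_regions <- setdiff(unique(region[adj]), smallest)
    if (!length(adj_regions)) break
    cen_s <- colMeans(map$prototypes[cells, , drop = FALSE])
    simto <- vapply(adj_regions, function(rg) {
      cen <- colMeans(map$prototypes[region == rg, , drop = FALSE])
      -sum((cen - cen_s)^2)
    }, 0)
    target <- adj_regions[which.max(simto)]
    region[region == smallest] <- target
  }
  # renumber 1..M in row-major order of first occurrence
  ids <- unique(region)
  topic <- match(region, ids)
  map$topic_labels <- topic
  map$topic_branches <- vapply(seq_len(max(topic)), function(m) {
    tb <- table(lab[topic == m])
    names(tb)[which.max(tb)]
  }, "")
  map
}

#' Serialize / restore an information map as JSON
#' @param map an \code{mm_infomap}; \code{path} a file path.
#' @rdname infomap_io
#' @export
write_infomap <- function(map, path) {
  obj <- list(rows = map$rows, cols = map$cols,
              prototypes = map$prototypes,
              assignments = as.list(map$assignments),
              mean_proto_dist = map$mean_proto_dist,
              topic_labels = map$topic_labels,
              topic_branches = map$topic_branches)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname infomap_io
#' @export
read_infomap <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(
    list(prototypes = as.matrix(obj$prototypes),
         grid = som_grid(obj$rows, obj$cols),
         rows = obj$rows, cols = obj$cols,
         assignments = unlist(obj$assignments),
         mean_proto_dist = obj$mean_proto_dist,
         topic_labels = obj$topic_labels,
         topic_branches = obj$topic_branches,
         config = NULL),
    class = "mm_infomap"
  )
}
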