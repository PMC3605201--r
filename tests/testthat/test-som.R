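test_that("coarse-group initialization places similar prototypes contiguously", {
  X <- two_blob_vectors(n = 120, d = 8, sep = 5)
  cfg <- som_config(4, 4, seed = 1)
  W <- initialize_rebalanced(X, cfg)
  expect_equal(dim(W), c(16, 8))
  # two well-separated blobs: each cell's prototype is near one blob mean;
  # the cells of each side must form a connected region on the grid
  side <- ifelse(rowMeans(W) > 2.5, 2L, 1L)
  grid <- expand.grid(c = 1:4, r = 1:4)[, c("r", "c")]
  connected <- function(cells) {
    if (length(cells) <= 1) return(TRUE)
    seen <- cells[1]
    repeat {
      nb <- cells[vapply(cells, function(x) {
        any(abs(grid$r[x] - grid$r[seen]) + abs(grid$c[x] - grid$c[seen]) == 1)
      }, TRUE)]
      new <- union(seen, nb)
      if (length(new) == length(seen)) break
      seen <- new
    }
    length(seen) == length(cells)
  }
  expect_true(connected(which(side == 1)))
  expect_true(connected(which(side == 2)))

  # identical vectors for all docs -> all prototypes equal
  Xc <- matrix(1, nrow = 30, ncol = 5,
               dimnames = list(sprintf("c%02d", 1:30), NULL))
  Wc <- initialize_rebalanced(Xc, som_config(3, 3, seed = 1))
  expect_equal(max(apply(Wc, 2, function(col) diff(range(col)))), 0)

  expect_error(initialize_rebalanced(X[1:2, ], som_config(4, 4)), "smaller grid")
})

test_that("training reduces quantization error and recovers planted clusters", {
  X <- two_blob_vectors(n = 200, d = 10, sep = 4, seed = 1)
  cfg <- som_config(4, 4, epochs = 15, seed = 1)
  W0 <- initialize_rebalanced(X, cfg)
  map <- train_som(X, cfg, init = W0)
  expect_lte(quantization_error(map, X), quantization_error(W0, X) + 1e-9)

  # planted 2-cluster purity of neuron assignments
  truth <- attr(X, "labels")
  purity <- sum(vapply(split(truth, map$assignments), function(v) {
    max(table(v))
  }, 0)) / length(truth)
  expect_gte(purity, 0.9)

  # QE is invariant to doc order
  perm <- sample(nrow(X))
  expect_equal(quantization_error(map, X[perm, ]), quantization_error(map, X))
})

test_that("batch training is deterministic and order-independent", {
  X <- two_blob_vectors(n = 100, d = 6, sep = 3, seed = 7)
  cfg <- som_config(3, 4, epochs = 10, seed = 5)
  m1 <- train_som(X, cfg)
  m2 <- train_som(X, cfg)
  expect_identical(m1$prototypes, m2$prototypes)   # bit-identical rerun
  # permuting presentation order leaves the batch map unchanged
  perm <- rev(seq_len(nrow(X)))
  m3 <- train_som(X[perm, ], som_config(3, 4, epochs = 10, seed = 5),
                  init = initialize_rebalanced(X, cfg))
  expect_equal(m3$prototypes, m1$prototypes, tolerance = 1e-12)
})

test_that("trained maps are topographically ordered", {
  run <- standard_run()
  W <- run$map$prototypes
  grid <- run$map$grid
  pd <- as.matrix(stats::dist(W))
  gd <- as.matrix(stats::dist(grid))
  adjacent <- gd > 0 & gd < 1.5
  far <- gd >= 1.5
  expect_lt(mean(pd[adjacent]), mean(pd[far]))
})

test_that("noise increases quantization error in expectation", {
  X <- two_blob_vectors(n = 80, d = 6, sep = 3, seed = 3)
  cfg <- som_config(3, 3, epochs = 10, seed = 3)
  map <- train_som(X, cfg)
  qe0 <- quantization_error(map, X)
  set.seed(11)
  worse <- mean(vapply(1:20, function(i) {
    quantization_error(map, X + matrix(stats::rnorm(length(X), sd = 0.5),
                                       nrow = nrow(X)))
  }, 0))
  expect_gt(worse, qe0)
})

test_that("topic labeling yields exactly M connected regions", {
  run <- standard_run()
  map <- run$map
  M <- run$M
  expect_equal(sort(unique(map$topic_labels)), seq_len(M))
  # each topic region is connected on the grid
  for (m in seq_len(M)) {
    cells <- which(map$topic_labels == m)
    if (length(cells) <= 1) next
    seen <- cells[1]
    repeat {
      nb <- cells[vapply(cells, function(x) {
        any(abs(map$grid$r[x] - map$grid$r[seen]) +
              abs(map$grid$c[x] - map$grid$c[seen]) == 1)
      }, TRUE)]
      new <- union(seen, nb)
      if (length(new) == length(seen)) break
      seen <- new
    }
    expect_length(seen, length(cells))
  }
  # asking for more topics than branches present fails
  expect_error(label_topics(map, run$analysis, M = 40), "branches")
})

test_that("maps serialize to JSON and back", {
  run <- standard_run()
  p <- tempfile(fileext = ".json")
  write_infomap(run$map, p)
  m2 <- read_infomap(p)
  expect_equal(unname(m2$prototypes), unname(run$map$prototypes))
  expect_equal(m2$topic_labels, run$map$topic_labels)
  expect_equal(m2$assignments, run$map$assignments)
})
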