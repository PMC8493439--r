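# Fixtures shared across test files; everything is built in code.

# 10x10x10 volume, fully masked: 990 voxels at 100 and 10 at 200, the ten
# bright voxels forming a single straight (hence 26-connected) line.
toy_flair <- function(voxdim = 1) {
  data <- array(100, c(10, 10, 10))
  data[1:10, 1, 1] <- 200
  flair_volume(data, array(TRUE, c(10, 10, 10)), rep(voxdim, 3))
}

toy_bright_idx <- function() which(array(seq_len(1000), c(10, 10, 10)) <= 10)

# A path graph v1-v2-...-vn dressed as a surface_mesh (degenerate faces;
# only edges/adjacency are exercised by cluster finding).
path_mesh <- function(n = 5) {
  verts <- cbind(seq_len(n), 0, 0)
  edges <- cbind(seq_len(n - 1), 2:n)
  adj <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L, if (i < n) i + 1L)))
  structure(list(vertices = verts,
                 faces = matrix(c(1L, min(2L, n), min(2L, n)), ncol = 3),
                 adjacency = adj, edges = edges),
            class = "surface_mesh")
}

# Brute-force BFS connected components of a vertex subset under edge
# adjacency; independent oracle for cluster finding.
bfs_components <- function(vertices, edges) {
  vertices <- sort(vertices)
  if (!length(vertices)) return(list())
  nbr <- function(v) {
    hits <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
    intersect(hits, vertices)
  }
  unseen <- vertices
  comps <- list()
  while (length(unseen)) {
    queue <- unseen[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(nbr(v), comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Brute-force 3-D connected component labeling (set-growing), oracle for
# label_components_3d.
bfs_components_3d <- function(mask, connectivity) {
  dm <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  fg <- which(mask)
  comps <- list()
  unseen <- fg
  while (length(unseen)) {
    queue <- unseen[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      p <- arrayInd(v, dm)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > dm)) next
        lin <- q[1] + (q[2] - 1) * dm[1] + (q[3] - 1) * dm[1] * dm[2]
        if (mask[lin] && !(lin %in% comp)) queue <- c(queue, lin)
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  comps
}

# Closed-form normal-equations OLS oracle.
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  b <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% b)
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * s2)
  tv <- b / se
  list(b = b, se = se, t = tv, p = 2 * pt(-abs(tv), df), df = df)
}

# Mean of a normal truncated below at `lower`.
truncnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
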